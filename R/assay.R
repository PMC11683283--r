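# Assay quantification: 4PL dose-response / IC50, fold ratios, wound-healing
# rate, 2^-ddCt, caliper tumor volume, fold activity.

#' Four-parameter logistic curve
#'
#' `y = bottom + (top - bottom) / (1 + (x / ic50)^hill)`. With `hill > 0`
#' the response decreases with dose (viability curves); the inflection is at
#' `x = ic50` where `y = (top + bottom) / 2`.
#'
#' @param x Dose (same unit as `ic50`).
#' @param top,bottom Upper/lower asymptotes.
#' @param ic50 Inflection dose (relative IC50).
#' @param hill Hill slope.
#' @return Response values.
#' @export
four_pl <- function(x, top = 100, bottom = 0, ic50, hill = 1) {
  bottom + (top - bottom) / (1 + (x / ic50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares 4PL fit with multi-start initialisation: the IC50 start is
#' tried on a log-spaced grid across the dose range (hill starts 0.5, 1, 2),
#' keeping the converged fit with the lowest residual sum of squares.
#' The reported `ic50` is the relative IC50 (inflection dose); the absolute
#' IC50 (dose where the response crosses 50 % of control) is reported
#' alongside. An optional bootstrap (resampling replicates within dose,
#' seeded) gives a percentile confidence interval for the IC50.
#'
#' @param doses Dose vector (must contain >= 4 distinct positive doses).
#' @param responses Response vector (percent viability), same length.
#' @param n_boot Bootstrap resamples for the IC50 CI (0 = skip).
#' @param seed Seed for the bootstrap stream.
#' @param normalize Rescale responses so the mean response at the lowest dose
#'   is 100 % before fitting (vehicle-control normalisation).
#' @return An object of class `trf_4pl_fit`: list with `top`, `bottom`,
#'   `hill`, `ic50`, `ic50_absolute`, `rss`, `converged`, `ci_ic50`
#'   (2.5/97.5 percentile bootstrap interval or NAs), and the `fit` object.
#'   `ic50` is `NA` when the fit did not converge or the dose range shows no
#'   transition.
#' @examples
#' d <- rep(10^seq(-1, 3, length.out = 8), each = 3)
#' y <- four_pl(d, ic50 = 50)
#' fit_4pl(d, y, n_boot = 0)$ic50  # 50
#' @export
fit_4pl <- function(doses, responses, n_boot = 199L, seed = 1L,
                    normalize = FALSE) {
  stopifnot(length(doses) == length(responses), all(doses > 0),
            all(is.finite(responses)))
  if (length(unique(doses)) < 4L) {
    stop("need at least 4 distinct doses", call. = FALSE)
  }
  if (normalize) {
    base <- mean(responses[doses == min(doses)])
    responses <- responses / base * 100
  }
  dat <- data.frame(x = doses, y = responses)

  fit_once <- function(dat) {
    span <- diff(range(dat$y))
    if (span < 1e-8) return(NULL)  # flat: no transition in range
    starts <- expand.grid(
      lic50 = seq(log(min(dat$x)), log(max(dat$x)), length.out = 7),
      hill = c(0.5, 1, 2))
    best <- NULL
    for (s in seq_len(nrow(starts))) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          y ~ bottom + (top - bottom) / (1 + exp(hill * (log(x) - lic50))),
          data = dat,
          start = list(top = max(dat$y), bottom = min(dat$y),
                       hill = starts$hill[s], lic50 = starts$lic50[s]),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
    best
  }

  best <- fit_once(dat)
  if (is.null(best)) {
    return(structure(list(top = NA_real_, bottom = NA_real_, hill = NA_real_,
                          ic50 = NA_real_, ic50_absolute = NA_real_,
                          rss = NA_real_, converged = FALSE,
                          ci_ic50 = c(NA_real_, NA_real_), fit = NULL,
                          diagnostic = "no transition in dose range or fit failure"),
                     class = "trf_4pl_fit"))
  }
  cf <- stats::coef(best$fit)
  ic50 <- exp(unname(cf["lic50"]))
  top <- unname(cf["top"]); bottom <- unname(cf["bottom"])
  hill <- unname(cf["hill"])
  # sanity: inflection inside a sensible window of the dose range
  converged <- is.finite(ic50) && ic50 > 0 &&
    ic50 > min(doses) / 100 && ic50 < max(doses) * 100 &&
    (top - bottom) > 1e-6
  # absolute IC50: dose where the curve crosses 50 (percent-of-control scale)
  ic50_abs <- if (converged && (top > 50) == (bottom < 50) && top != bottom) {
    ic50 * exp(log((top - bottom) / (50 - bottom) - 1) / hill)
  } else NA_real_

  ci <- c(NA_real_, NA_real_)
  if (converged && n_boot > 0) {
    set.seed(derive_seed(seed, "fit_4pl_boot"))
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(split(seq_along(doses), doses), function(ii) {
        sample(ii, length(ii), replace = TRUE)
      }), use.names = FALSE)
      bb <- fit_once(dat[idx, , drop = FALSE])
      if (is.null(bb)) return(NA_real_)
      exp(unname(stats::coef(bb$fit)["lic50"]))
    }, 0)
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 20) {
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
  }
  structure(list(top = top, bottom = bottom, hill = hill,
                 ic50 = if (converged) ic50 else NA_real_,
                 ic50_absolute = ic50_abs, rss = best$rss,
                 converged = converged, ci_ic50 = ci, fit = best$fit,
                 diagnostic = if (converged) NULL else "inflection outside plausible range"),
            class = "trf_4pl_fit")
}

#' @export
print.trf_4pl_fit <- function(x, ...) {
  if (!x$converged) {
    cat("4PL fit: not converged (", x$diagnostic, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("4PL fit: IC50 = %.3g (relative), top %.1f, bottom %.1f, hill %.2f, RSS %.3g\n",
              x$ic50, x$top, x$bottom, x$hill, x$rss))
  if (all(is.finite(x$ci_ic50))) {
    cat(sprintf("  bootstrap 95%% CI for IC50: [%.3g, %.3g]\n",
                x$ci_ic50[1], x$ci_ic50[2]))
  }
  invisible(x)
}

#' Ratio of two IC50 values with unit conversion
#'
#' Both concentrations are converted to a common unit (nM) before taking the
#' exact quotient `a / b`; optional rounding uses round-half-even
#' ([base::round()]) to the stated digits.
#'
#' @param a,b Concentrations.
#' @param unit_a,unit_b Units, `"nM"` or `"uM"`.
#' @param digits If not `NULL`, round the ratio to this many digits.
#' @return Dimensionless ratio.
#' @examples
#' ic50_fold_ratio(1.55, 9.49, unit_a = "uM", unit_b = "nM", digits = 0)  # 163
#' @export
ic50_fold_ratio <- function(a, b, unit_a = "nM", unit_b = "nM", digits = NULL) {
  to_nM <- function(x, unit) {
    switch(match.arg(unit, c("nM", "uM")), nM = x, uM = x * 1000)
  }
  bn <- to_nM(b, unit_b)
  if (bn <= 0) stop("denominator concentration must be > 0", call. = FALSE)
  ratio <- to_nM(a, unit_a) / bn
  if (!is.null(digits)) ratio <- round(ratio, digits)
  ratio
}

#' Wound healing rate
#'
#' Percent closure of a scratch wound between time 0 and a later time point:
#' `100 * (area_t0 - area_t) / area_t0`. Negative values (wound growth) are
#' allowed with a warning.
#'
#' @param area_t0 Wound area at time 0 (must be > 0).
#' @param area_t Wound area at the later time point (same unit).
#' @return Healing rate in percent, at most 100.
#' @examples
#' wound_healing_rate(100, 40)  # 60
#' @export
wound_healing_rate <- function(area_t0, area_t) {
  if (any(area_t0 <= 0)) stop("baseline wound area must be > 0", call. = FALSE)
  whr <- 100 * (area_t0 - area_t) / area_t0
  if (any(whr < 0)) warning("negative healing rate: wound area increased")
  whr
}

#' Relative quantification by the 2^-ddCt method
#'
#' `ddct = (CT_target,treated - CT_ref,treated) -
#' (CT_target,control - CT_ref,control)`; fold change is `2^-ddct`.
#' Replicate vectors are averaged before differencing.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   CT values (scalars or replicate vectors; must be finite).
#' @return A list with `ddct` (CT units) and `fold` (`2^-ddct`).
#' @examples
#' ddct_fold(25, 18, 24, 18)$fold  # 0.5
#' @export
ddct_fold <- function(ct_target_treated, ct_ref_treated,
                      ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated, ct_target_control, ct_ref_control)
  if (!all(is.finite(cts))) stop("CT values must be finite", call. = FALSE)
  ddct <- (mean(ct_target_treated) - mean(ct_ref_treated)) -
    (mean(ct_target_control) - mean(ct_ref_control))
  list(ddct = ddct, fold = 2^-ddct)
}

#' Compute 2^-ddCt from a CT table
#'
#' Convenience wrapper over [ddct_fold()] for tables shaped like
#' [generate_qpcr_ct()] output.
#'
#' @param ct_table Data.frame with columns `condition`
#'   (`control`/`treated`), `gene` (`target`/`reference`), `ct`.
#' @return As [ddct_fold()].
#' @export
ddct_fold_table <- function(ct_table) {
  pick <- function(cond, gene) {
    ct_table$ct[ct_table$condition == cond & ct_table$gene == gene]
  }
  ddct_fold(pick("treated", "target"), pick("treated", "reference"),
            pick("control", "target"), pick("control", "reference"))
}

#' Tumor volume from caliper measurements
#'
#' `volume = width^2 * length / 2` (mm^3). If `width > length` the two are
#' swapped with a warning (the caliper convention takes width as the smaller
#' diameter).
#'
#' @param width,length Tumor diameters in mm, both > 0.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(4, 8)  # 64
#' @export
tumor_volume <- function(width, length) {
  if (any(width <= 0) || any(length <= 0)) {
    stop("tumor dimensions must be > 0", call. = FALSE)
  }
  swap <- width > length
  if (any(swap)) {
    warning("width > length for some measurements; swapping")
    tmp <- width[swap]
    width[swap] <- length[swap]
    length[swap] <- tmp
  }
  width^2 * length / 2
}

#' Summarise a caliper table into growth curves
#'
#' Computes per-animal volumes with [tumor_volume()] and per-group, per-day
#' mean and SD curves, plus the final-day treated/control mean volume ratio.
#'
#' @param caliper Data.frame like [generate_tumor_growth()] output: `group`,
#'   `mouse`, `day`, `width_mm`, `length_mm`.
#' @return A list: `curves` (data.frame `group`, `day`, `mean_volume`,
#'   `sd_volume`, `n`), `final_volume_ratio` (treated/control at the last
#'   day, NA if a group is absent).
#' @export
growth_summary <- function(caliper) {
  stopifnot(all(c("group", "mouse", "day", "width_mm", "length_mm") %in%
                  names(caliper)))
  caliper$volume <- tumor_volume(caliper$width_mm, caliper$length_mm)
  agg <- stats::aggregate(volume ~ group + day, caliper, function(v) {
    c(mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  curves <- data.frame(group = agg$group, day = agg$day,
                       mean_volume = agg$volume[, "mean"],
                       sd_volume = agg$volume[, "sd"],
                       n = agg$volume[, "n"], stringsAsFactors = FALSE)
  last <- max(curves$day)
  mt <- curves$mean_volume[curves$group == "treated" & curves$day == last]
  mc <- curves$mean_volume[curves$group == "control" & curves$day == last]
  ratio <- if (length(mt) == 1L && length(mc) == 1L) mt / mc else NA_real_
  list(curves = curves[order(curves$group, curves$day), ],
       final_volume_ratio = ratio)
}

#' Fold activity of a treated signal over control
#'
#' Plain quotient, e.g. caspase-3 colorimetric activity fold induction.
#'
#' @param treated_signal,control_signal Assay signals; control must be > 0.
#' @return `treated_signal / control_signal`.
#' @export
fold_activity <- function(treated_signal, control_signal) {
  if (any(control_signal <= 0)) stop("control signal must be > 0", call. = FALSE)
  treated_signal / control_signal
}
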