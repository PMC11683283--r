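---
title: "Methods: thermodynamic tRF screening and knockdown characterisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thermodynamic tRF screening and knockdown characterisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trfscreen)
```

## The problem

Transfer RNAs are cleaved by specific nucleases into stable fragments (tRFs
and tRNA halves) from their 5' and 3' ends. Exogenous tRFs can act as small
interfering RNAs: a fragment whose sequence is largely complementary to a
site in the 3'UTR of an oncogene transcript can silence that gene through the
RNAi pathway. `trfscreen` implements the computational chain used to find
such a fragment and to characterise the resulting knockdown: build candidate
fragments from a tRNA library, score each fragment's hybridisation with a
target 3'UTR by thermodynamic stability, rank and filter the candidates, and
quantify the downstream consequences (differential expression, pathway
suppression, dose-response potency, qPCR fold changes, wound closure and
tumor growth).

Because real screening libraries and sequencing datasets of this kind are
typically not public, the package also contains seeded generators that
produce every input with the statistical structure the analysis assumes, so
the whole chain runs — and is tested — end to end without external data.

## Duplex model

The screen's core statistic is the minimum free energy (MFE) of the
intermolecular RNA:RNA duplex between a fragment and a candidate site,
computed by `duplex_mfe()`. The model is the standard nearest-neighbor
hybridisation free energy at 37 °C, in the style of RNAhybrid-type
target-site scanners:

* a duplex structure is a chain of base pairs (Watson–Crick or G·U),
  strictly increasing along the fragment and strictly decreasing along the
  site — intramolecular pairing and pseudoknots are impossible by
  construction;
* adjacent pairs contribute Turner 2004 ΔG°37 stacking energies (all 21
  distinct Watson–Crick and wobble pair-of-pair classes). The Watson–Crick
  entries are embedded at their published two-decimal values; the G·U
  entries at the 0.1 kcal/mol precision in which the reference parameter
  distribution ships them;
* unpaired stretches between consecutive pairs are charged a size-dependent
  bulge or internal-loop initiation penalty (published tables up to size 6,
  Jacobson–Stockmayer extrapolation `ΔG(n) = ΔG(6) + 1.079·ln(n/6)` above),
  with at most `max_loop = 15` unpaired bases per strand between two pairs;
* a duplex initiation term of +4.09 kcal/mol is added once, and +0.45
  kcal/mol for each duplex end closed by an A·U or G·U pair (a single-pair
  duplex is charged both ends);
* dangling ends and coaxial stacking are excluded. This keeps the model
  exactly enumerable, and its effect on candidate *ranking* is second order;
  the flag-bearing structure of `energy_model()` leaves room to add them
  later.

Temperature is fixed at 37 °C; only ΔG°37 values are used (no
enthalpy/entropy rescaling).

### Numerical exactness and the enumeration oracle

All energies are held internally as integer centi-kcal/mol, so sums are
exact and independent of summation order. This lets the test suite demand
*exact float equality* between the dynamic program and an independent
brute-force enumerator (`duplex_mfe_brute()`) that scores every legal
structure on short sequences — about two thousand random pairs of lengths
4–8 nt in the shipped tests.

The traceback is deterministic: candidate predecessors are examined in a
canonical order (stack, then bulges by increasing size with query-side
first, then internal loops by increasing total size and 5'-most query
position), and the first strict improvement wins. Equal-energy co-optimal
structures therefore resolve reproducibly, though not necessarily
symmetrically between the two strand orderings; the MFE itself is exactly
symmetric, and the tests verify that every reported structure attains it.

### Complementarity rate

The complementarity rate is `100 × (paired fragment positions) / (fragment
length)`, reported to one decimal, with G·U wobbles counted as paired (they
are hydrogen-bonded). The fragment length is used as the denominator; at the
canonical 22-nt fragment length, a site with 16 paired positions scores
72.7 % — the smallest paired count exceeding a 72 % criterion. Other
definitions (e.g. paired fraction of the site span) exist; this one is fixed
and documented rather than configurable because downstream thresholds are
calibrated to it.

## Scanning and screening

`scan_utr()` slides a window (default 40 nt, step 5 nt, always including the
final full window) along the UTR, scores each window, and merges overlapping
hits greedily from the lowest MFE, breaking ties by leftmost coordinate.
UTRs shorter than the window are scored as one whole-UTR window. Reported
coordinates are 1-based inclusive on the UTR sense strand; all internal
arithmetic is 0-based.

`run_screen()` takes each fragment's best site, filters at `mfe_max`
(default −20 kcal/mol) and `comp_min` (default 72 %), sorts by (MFE
ascending, complementarity descending, fragment id) and assigns dense ranks
on the (MFE, complementarity) key. The defaults are screening *policy*:
they are deliberately permissive enough to admit a strong 22-nt site with
margin, and both are prominently configurable. One best site per fragment
is reported by default (`all_sites = TRUE` retains all merged sites).

## Synthetic data: what it emulates, and what it does not

All generators are pure functions of `sim_config()`; a master seed drives
per-generator substreams through a documented 31-bit string hash
(`derive_seed(seed, stream)`), so individual generators are reproducible and
order-independent.

* **tRNA library** — uniform-random sequences (GC bias 0.55, lengths 70–90
  nt) with isotype-like labels. Only pairing structure matters to the
  screen, so no cloverleaf folding, modification chemistry or genomic
  context is emulated; conclusions about *real* tRF libraries require real
  sequences.
* **Planted site** — the UTR embeds the reverse complement of a chosen
  fragment with an exact number of non-pairing mismatches and G·U
  conversions at seeded positions. Decoding the site recovers the fragment
  up to exactly those positions (a tested round-trip).
* **Counts** — negative-binomial (dispersion 0.1) around log-normal
  baseline means, two groups of 6 samples; 10 % of genes shifted ±2 log2
  units, and a designated 50-gene "PI3K-Akt-like" set shifted −1 log2 unit.
  Library-size variation, batch effects, and count-level mean–variance
  trends beyond NB are not emulated, which is why the per-gene test below is
  validated for *calibration* on this generator's null, not on real data.
* **Dose-response** — viability from a four-parameter logistic curve with
  multiplicative log-normal noise (CV 5 %), 8 log-spaced doses, 3
  replicates. Preset IC50s (10.0, 27.54, 216.5, 103.8, 167.0, 9.49 and
  1550 nM) cover a tRF mimic and a taxane comparator across parental,
  resistant and normal colon lines; hill slope 1 and asymptotes 100/0 are
  conventional choices since only the IC50s are anchored. Dose grids span
  each preset's transition (about two decades either side of the IC50), as
  a plate layout would be designed.
* **qPCR / wound / caliper tables** — Gaussian CT noise (sd 0.15),
  Gaussian area noise, and exponential tumor growth with a smooth treatment
  multiplier calibrated so the expected final treated/control volume ratio
  equals the multiplier (default 0.5).

Passing tests on these generators demonstrate that the *computations* are
correct and calibrated under their stated assumptions; they do not
demonstrate anything about laboratory reproducibility of a particular
biological system.

## Differential expression and enrichment

TPM normalisation divides counts by gene length (kb) and rescales each
sample to one million (`tpm_normalize()`; the column-sum property is tested
to 1e−6 relative).

`call_degs()` uses a per-gene two-tailed Welch t-test on `log2(TPM + 1)`,
with fold change `log2((mean_T + 1)/(mean_C + 1))`. The package fixes the
sign convention as treated-vs-control: knocked-down genes have *negative*
log2FC and are called `down` at `log2fc < −1, p < 0.05`. (Volcano plots in
parts of the literature invert this, labelling down-regulated genes with
positive log2FC computed control-over-treated; the fixed convention here
avoids that ambiguity.) Benjamini–Hochberg FDR is reported alongside, but
calls filter on raw p at the conventional thresholds. A negative-binomial
modelling framework (DESeq2/edgeR-style) is deliberately not wrapped here:
the per-gene t-test is the transparent, self-contained choice for a
generator-validated chain, and its type-I error is verified to sit inside
the 99 % binomial band of 0.05 on a 2,000-gene null simulation. Genes
constant across all samples get `p = 1` by convention.

`hierarchical_bicluster()` clusters genes and samples by complete linkage
on Euclidean distances of `log2(TPM + 1)` — the defaults of the heatmap
tools commonly used for expression panels. `hclust` is deterministic given
input order; ties resolve to the earlier merge.

`gsea_es()` implements the classic weighted Kolmogorov–Smirnov running sum:
walking down the ranked list, set members step up by `|statistic|^p`
(normalised over the set, `p = 1` by default), non-members step down by
`1/(N − k)`; the enrichment score is the signed maximum deviation. For a set
occupying the top k positions the running sum peaks at exactly 1 immediately
after the last hit — a useful hand-checkable anchor that the tests verify
against direct enumeration. Significance uses gene-label permutations (the
appropriate null at desk scale, where sample-label permutation has too few
arrangements), seeded, with a +1 pseudo-observation and same-direction
extremity counting. `hypergeom_ora()` gives the exact upper-tail
hypergeometric over-representation p-value with BH correction across sets;
tests verify it against direct combinatorial enumeration on universes ≤ 25.

## Assay quantification

`fit_4pl()` fits `y = bottom + (top − bottom)/(1 + (x/ic50)^hill)` by
Levenberg–Marquardt least squares (via minpack.lm) with multi-start
initialisation over a 7-point log-dose grid × 3 hill starts, keeping the
lowest-RSS converged fit. The reported IC50 is the *relative* IC50 (the
inflection dose), matching the convention of the standard fitting tools;
the absolute IC50 (crossing of 50 % of control) is reported alongside.
Viability can be normalised to the lowest-dose mean (`normalize = TRUE`)
when raw absorbances are supplied. The fit is declared non-converged when
the response is flat or the inflection lands implausibly far outside the
dose range, and no IC50 is reported in that case. A seeded bootstrap
(resampling replicates within dose) yields a percentile CI; coverage is
checked in the tests at reduced replicates with a wide band.

The remaining quantities are closed-form and exact:

* fold ratio of two IC50s after central nM/µM unit conversion
  (round-half-even when rounding is requested);
* wound healing rate `100 × (area_0 − area_t)/area_0` (negative, with a
  warning, if the wound grew);
* `2^−ΔΔCT` relative quantification, replicate-averaged, with exact
  antisymmetry under swapping treated and control;
* caliper tumor volume `width² × length / 2` (width and length swapped,
  with a warning, if given in the wrong order), and per-group mean ± SD
  growth curves with the final-day treated/control volume ratio.

## Problem sizes and runtimes

The shipped tests and the acceptance script run entirely on generated data
at desk scale: 50-tRNA libraries against 300-nt UTRs (about 55 windows per
fragment), 2,000-gene count matrices at 6 samples per group, 1,000
permutations for GSEA p-values, 2,000 random short duplexes for the
DP-vs-enumeration check, and 24-point dose-response tables. These sizes were
chosen as the smallest at which the statistical checks (type-I calibration,
planted-signal recovery, permutation significance) are stable.

## Known limitations

* The duplex model omits dangling ends, coaxial stacking, and
  sequence-dependent loop terms; absolute MFEs therefore differ from
  full-featured folding engines by version- and convention-dependent
  amounts, which matters when comparing against externally computed
  energies. Site accessibility (target secondary structure) is not
  modelled at all.
* The screen scans one UTR; transcriptome-wide off-target enumeration is
  structurally supported (the scan is per-sequence) but not exercised.
* The DEG test is a per-gene Welch t on log2 TPM — appropriate for the
  generator's assumptions and transparent to validate, but not a
  replacement for count-model frameworks on real RNA-seq.
* Synthetic tRNAs are random sequences; no claim is made that screening
  statistics on them transfer to any real tRNA complement.
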