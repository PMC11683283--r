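#include <Rcpp.h>
using namespace Rcpp;

// Intermolecular RNA:RNA duplex minimum free energy by nearest-neighbor
// dynamic programming. No intramolecular structure, no dangling ends.
//
// q: query (tRF) base codes 0..3 = A,C,G,U, 5'->3'
// t: target site codes, given REVERSED (3'->5' of the sense site), so a
//    duplex is a strictly increasing chain of pairs (i, k) in both indices.
// Energies are integer centi-kcal/mol throughout; sums are exact.
//
// Scoring of a chain of pairs p1 < p2 < ... < pm:
//   duplex_init
//   + terminal penalty at p1 and pm when that pair is A.U or G.U
//   + for consecutive pairs with a unpaired on q and b unpaired on t:
//       a==0 && b==0 -> stack energy
//       a==0 || b==0 -> bulge penalty of size a+b   (a,b <= max_loop)
//       else         -> internal loop penalty of size a+b
//
// Tie-breaking in the traceback is deterministic: predecessors are examined
// stack first, then bulges by increasing size (query-side bulge before
// target-side), then internal loops by increasing total size and 5'-most
// query position; the first strict improvement is kept, so ties resolve to
// the earliest candidate in that order.

static inline int pair_type(int x, int y) {
  // 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG, -1 none
  if (x == 0 && y == 3) return 0;
  if (x == 3 && y == 0) return 1;
  if (x == 1 && y == 2) return 2;
  if (x == 2 && y == 1) return 3;
  if (x == 2 && y == 3) return 4;
  if (x == 3 && y == 2) return 5;
  return -1;
}

static inline bool wobbly_end(int pt) {
  return pt == 0 || pt == 1 || pt == 4 || pt == 5;
}

// [[Rcpp::export(name = ".duplex_dp_cpp")]]
List duplex_dp_cpp(IntegerVector q, IntegerVector t,
                   IntegerMatrix stack, IntegerVector bulge,
                   IntegerVector internal, int init, int term,
                   int max_loop, int big) {
  const int n = q.size(), m = t.size();
  IntegerMatrix D(n, m), prev_i(n, m), prev_k(n, m);
  IntegerMatrix PT(n, m);

  for (int i = 0; i < n; ++i)
    for (int k = 0; k < m; ++k)
      PT(i, k) = pair_type(q[i], t[k]);

  int best = big, best_i = -1, best_k = -1;

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      const int pt = PT(i, k);
      if (pt < 0) { D(i, k) = big; continue; }
      const int tp = wobbly_end(pt) ? term : 0;
      // option: (i,k) opens the duplex (it is the 5'-most pair)
      int d = tp;
      int pi = -1, pk = -1;

      // canonical candidate order for deterministic tie-breaking
      // 1) stack
      if (i > 0 && k > 0 && PT(i - 1, k - 1) >= 0 && D(i - 1, k - 1) < big) {
        int cand = D(i - 1, k - 1) + stack(PT(i - 1, k - 1), pt);
        if (cand < d) { d = cand; pi = i - 1; pk = k - 1; }
      }
      // 2) bulges by increasing size, query side first
      for (int s = 1; s <= max_loop; ++s) {
        // query-side bulge: a = s, b = 0
        if (i - 1 - s >= 0 && k - 1 >= 0 && D(i - 1 - s, k - 1) < big &&
            bulge[s - 1] < big) {
          int cand = D(i - 1 - s, k - 1) + bulge[s - 1];
          if (cand < d) { d = cand; pi = i - 1 - s; pk = k - 1; }
        }
        // target-side bulge: a = 0, b = s
        if (i - 1 >= 0 && k - 1 - s >= 0 && D(i - 1, k - 1 - s) < big &&
            bulge[s - 1] < big) {
          int cand = D(i - 1, k - 1 - s) + bulge[s - 1];
          if (cand < d) { d = cand; pi = i - 1; pk = k - 1 - s; }
        }
      }
      // 3) internal loops by increasing total size, then 5'-most query pos
      for (int tot = 2; tot <= 2 * max_loop; ++tot) {
        for (int a = std::max(1, tot - max_loop);
             a <= std::min(max_loop, tot - 1); ++a) {
          int b = tot - a;
          int ii = i - 1 - a, kk = k - 1 - b;
          if (ii < 0 || kk < 0) continue;
          if (D(ii, kk) >= big || internal[tot - 1] >= big) continue;
          int cand = D(ii, kk) + internal[tot - 1];
          if (cand < d) { d = cand; pi = ii; pk = kk; }
        }
      }
      D(i, k) = d;
      prev_i(i, k) = pi;
      prev_k(i, k) = pk;
      int closed = d + tp + init;
      if (closed < best) { best = closed; best_i = i; best_k = k; }
    }
  }

  if (best_i < 0) {
    return List::create(_["mfe_cents"] = NA_INTEGER,
                        _["pairs_q"] = IntegerVector(0),
                        _["pairs_t"] = IntegerVector(0));
  }

  // traceback from the 3'-most pair
  std::vector<int> pq, pk_v;
  int i = best_i, k = best_k;
  while (i >= 0) {
    pq.push_back(i + 1);      // 1-based on the query
    pk_v.push_back(k + 1);    // 1-based on the reversed target
    int ni = prev_i(i, k), nk = prev_k(i, k);
    i = ni; k = nk;
  }
  std::reverse(pq.begin(), pq.end());
  std::reverse(pk_v.begin(), pk_v.end());

  return List::create(_["mfe_cents"] = best,
                      _["pairs_q"] = wrap(pq),
                      _["pairs_t"] = wrap(pk_v));
}
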