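#include <Rcpp.h>
using namespace Rcpp;

// Fixed-margin sampling of r x c non-negative integer tables from the
// multiple-hypergeometric (independence conditional on margins) law.
// Cells are filled row-wise; each cell is drawn from its exact conditional
// distribution given the margins remaining at that point, by inverting the
// conditional CDF built from log-factorial weights:
//   P(a) = C(cj, a) C(S - cj, r - a) / C(S, r)
// with r the remaining row margin, cj the remaining margin of the current
// column and S the total remaining margin of the not-yet-finished columns.
// Uses R's RNG, so draws are reproducible under set.seed().

// [[Rcpp::export]]
IntegerVector rcpp_patefield(IntegerVector row_margins,
                             IntegerVector col_margins,
                             int n_draws) {
  const int nr = row_margins.size();
  const int nc = col_margins.size();
  long total = 0;
  for (int i = 0; i < nr; ++i) {
    if (row_margins[i] < 0) stop("negative row margin");
    total += row_margins[i];
  }
  long ctot = 0;
  for (int j = 0; j < nc; ++j) {
    if (col_margins[j] < 0) stop("negative column margin");
    ctot += col_margins[j];
  }
  if (total != ctot) stop("row and column margin sums differ");

  // log-factorial table 0..total
  std::vector<double> lf(total + 1);
  lf[0] = 0.0;
  for (long k = 1; k <= total; ++k) lf[k] = lf[k - 1] + std::log((double) k);

  IntegerVector out(nr * nc * (R_xlen_t) n_draws);
  std::vector<int> colrem(nc);

  for (int d = 0; d < n_draws; ++d) {
    for (int j = 0; j < nc; ++j) colrem[j] = col_margins[j];
    long unassigned = total;
    int *tab = &out[(R_xlen_t) d * nr * nc];

    for (int i = 0; i < nr; ++i) {
      int r = row_margins[i];
      long S = unassigned;  // remaining margin over columns j..nc-1
      for (int j = 0; j < nc - 1; ++j) {
        int cj = colrem[j];
        int lo = r + cj - (int) S; if (lo < 0) lo = 0;
        int hi = r < cj ? r : cj;
        int a;
        if (hi <= lo) {
          a = lo;
        } else {
          // P(lo) from log-factorials, then the ratio recurrence
          double lp = lf[cj] - lf[lo] - lf[cj - lo]
                    + lf[S - cj] - lf[r - lo] - lf[S - cj - r + lo]
                    - (lf[S] - lf[r] - lf[S - r]);
          double p = std::exp(lp);
          double u = unif_rand();
          a = lo;
          double cum = p;
          while (cum < u && a < hi) {
            p *= (double) (cj - a) * (double) (r - a)
               / ((double) (a + 1) * (double) (S - cj - r + a + 1));
            ++a;
            cum += p;
          }
        }
        tab[i + j * nr] = a;
        colrem[j] -= a;
        r -= a;
        S -= cj;  // column j leaves the universe for the rest of row i
      }
      tab[i + (nc - 1) * nr] = r;  // last column is forced
      colrem[nc - 1] -= r;
      unassigned -= row_margins[i];
    }
  }

  out.attr("dim") = IntegerVector::create(nr, nc, n_draws);
  return out;
}
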