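#include <Rcpp.h>
using namespace Rcpp;

// Base encoding used throughout: A=0, C=1, G=2, U=3 (see encode_rna()).
// Pair codes follow the order of the bundled stack table rows:
// 0=CG 1=GC 2=GU 3=UG 4=AU 5=UA; -1 = not pairable.
static inline int pair_code(int a, int b) {
  if (a == 1 && b == 2) return 0;
  if (a == 2 && b == 1) return 1;
  if (a == 2 && b == 3) return 2;
  if (a == 3 && b == 2) return 3;
  if (a == 0 && b == 3) return 4;
  if (a == 3 && b == 0) return 5;
  return -1;
}

static inline bool is_gu(int p) { return p == 2 || p == 3; }
static inline bool is_weak_end(int p) { return p >= 2; }  // GU, UG, AU, UA

struct Stretch {
  int len, gu, mstart, hstart;  // 0-based starts; hstart = leftmost half index
  Stretch() : len(0), gu(0), mstart(-1), hstart(-1) {}
};

// true if cand is strictly preferred over best
static inline bool better(const Stretch &cand, const Stretch &best) {
  if (cand.len != best.len) return cand.len > best.len;
  if (cand.len == 0) return false;
  if (cand.gu != best.gu) return cand.gu < best.gu;
  if (cand.mstart != best.mstart) return cand.mstart < best.mstart;
  return cand.hstart < best.hstart;
}

// Longest run of consecutive paired positions between motif (5'->3') and
// half (antiparallel, 3'->5'), i.e. motif[a+k] pairs half[j-k].  All
// stretches live on diagonals of constant s = a + j.  Sliding window with
// at most max_gu G:U pairs inside each run of pairable positions.
static Stretch best_stretch(const int *m, int nm, const int *h, int nh,
                            int max_gu) {
  Stretch best;
  for (int s = 0; s <= nm + nh - 2; ++s) {
    int alo = s - (nh - 1); if (alo < 0) alo = 0;
    int ahi = s; if (ahi > nm - 1) ahi = nm - 1;
    int l = alo, gu = 0;
    for (int a = alo; a <= ahi; ++a) {
      int p = pair_code(m[a], h[s - a]);
      if (p < 0) { l = a + 1; gu = 0; continue; }
      if (is_gu(p)) ++gu;
      while (gu > max_gu) {
        if (is_gu(pair_code(m[l], h[s - l]))) --gu;
        ++l;
      }
      Stretch cand;
      cand.len = a - l + 1;
      cand.gu = gu;
      cand.mstart = l;
      cand.hstart = s - a;  // leftmost half index of the span
      if (better(cand, best)) best = cand;
    }
  }
  return best;
}

// Stretch free energy: sum of nearest-neighbor stacks (stack(p1, p2) in
// physical orientation, 6x6, kcal/mol) + duplex_init + terminal penalties
// for weak (A:U / G:U) closing pairs.  The stretch starts at motif index
// mstart and half index hstart (leftmost), length len.
static double stretch_dg(const int *m, const int *h, int mstart, int hstart,
                         int len, const double *stack, double init,
                         double term_au) {
  int hj = hstart + len - 1;  // half index paired with motif[mstart]
  int prev = pair_code(m[mstart], h[hj]);
  double dg = init + (is_weak_end(prev) ? term_au : 0.0);
  for (int k = 1; k < len; ++k) {
    int p = pair_code(m[mstart + k], h[hj - k]);
    dg += stack[prev + 6 * p];  // column-major: (row = prev, col = p)
    prev = p;
  }
  dg += is_weak_end(prev) ? term_au : 0.0;
  return dg;
}

// [[Rcpp::export(name = ".best_stretch_cpp")]]
IntegerVector best_stretch_cpp(IntegerVector motif, IntegerVector half,
                               int max_gu) {
  Stretch b = best_stretch(INTEGER(motif), motif.size(), INTEGER(half),
                           half.size(), max_gu);
  return IntegerVector::create(b.len, b.gu, b.mstart, b.hstart);
}

// [[Rcpp::export(name = ".stretch_dg_cpp")]]
double stretch_dg_cpp(IntegerVector motif, IntegerVector half, int mstart,
                      int hstart, int len, NumericMatrix stack, double init,
                      double term_au) {
  return stretch_dg(INTEGER(motif), INTEGER(half), mstart, hstart, len,
                    REAL(stack), init, term_au);
}

// Full scan: every motif against every half.  half_max_gu gives the wobble
// allowance per half (derived from its 5'/3' end).  Returns one row per
// (motif, half) whose best stretch passes both the length and the energy
// criterion, in (motif, half) input order.
// [[Rcpp::export(name = ".scan_cpp")]]
DataFrame scan_cpp(List motifs, List halves, IntegerVector half_max_gu,
                   int min_stretch, NumericMatrix stack, double init,
                   double term_au, double dg_cutoff) {
  int nmot = motifs.size(), nhal = halves.size();
  std::vector<int> mi, hi, len, gu, ms, hs;
  std::vector<double> dg;
  std::vector<IntegerVector> mv(nmot), hv(nhal);
  for (int i = 0; i < nmot; ++i) mv[i] = motifs[i];
  for (int j = 0; j < nhal; ++j) hv[j] = halves[j];
  const double *st = REAL(stack);
  for (int i = 0; i < nmot; ++i) {
    const int *m = INTEGER(mv[i]);
    int nm = mv[i].size();
    for (int j = 0; j < nhal; ++j) {
      const int *h = INTEGER(hv[j]);
      int nh = hv[j].size();
      Stretch b = best_stretch(m, nm, h, nh, half_max_gu[j]);
      if (b.len < min_stretch) continue;
      double e = stretch_dg(m, h, b.mstart, b.hstart, b.len, st, init,
                            term_au);
      if (e > dg_cutoff) continue;
      mi.push_back(i + 1); hi.push_back(j + 1);
      len.push_back(b.len); gu.push_back(b.gu);
      ms.push_back(b.mstart); hs.push_back(b.hstart);
      dg.push_back(e);
    }
  }
  return DataFrame::create(_["motif_i"] = mi, _["half_i"] = hi,
                           _["stretch_len"] = len, _["gu_count"] = gu,
                           _["motif_start"] = ms, _["half_start"] = hs,
                           _["dg37"] = dg);
}

// Hit counts for the shuffle null: like scan_cpp but only tallies a
// (motif class) x (half class) count matrix, avoiding data-frame
// construction inside the 1000-iteration loop.  Classes are 1-based;
// strata are aggregated from the matrix on the R side.
// [[Rcpp::export(name = ".scan_count_cpp")]]
NumericMatrix scan_count_cpp(List motifs, List halves,
                             IntegerVector half_max_gu, int min_stretch,
                             NumericMatrix stack, double init, double term_au,
                             double dg_cutoff, IntegerVector motif_class,
                             int n_motif_class, IntegerVector half_class,
                             int n_half_class) {
  int nmot = motifs.size(), nhal = halves.size();
  NumericMatrix out(n_motif_class, n_half_class);
  std::vector<IntegerVector> mv(nmot), hv(nhal);
  for (int i = 0; i < nmot; ++i) mv[i] = motifs[i];
  for (int j = 0; j < nhal; ++j) hv[j] = halves[j];
  const double *st = REAL(stack);
  for (int i = 0; i < nmot; ++i) {
    const int *m = INTEGER(mv[i]);
    int nm = mv[i].size();
    for (int j = 0; j < nhal; ++j) {
      const int *h = INTEGER(hv[j]);
      Stretch b = best_stretch(m, nm, h, hv[j].size(), half_max_gu[j]);
      if (b.len < min_stretch) continue;
      double e = stretch_dg(m, h, b.mstart, b.hstart, b.len, st, init,
                            term_au);
      if (e > dg_cutoff) continue;
      out(motif_class[i] - 1, half_class[j] - 1) += 1;
    }
  }
  return out;
}
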