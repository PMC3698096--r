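#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// ---- shared helpers --------------------------------------------------------

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// pair type 1..6 for AT TA GC CG GT TG, 0 = not pairable
static inline int pair_type(int a, int b) {
  if (a < 0 || b < 0) return 0;
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 1 && b == 2) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

// ---- single-stem nearest-neighbour MFE folding -----------------------------

struct FoldParams {
  double stack[7][7];          // [outer][inner], 1-based pair types
  std::vector<double> hairpin; // index = loop size, valid from 3
  std::vector<double> bulge;   // index = loop size, valid from 1
  std::vector<double> internal;// index = total loop size, valid from 2
  double asym_coef;
  double asym_max;
  double js_coef;              // Jacobson-Stockmayer extrapolation coefficient
  int maxloop;
};

static double tab_extrap(const std::vector<double>& tab, int n, int lo, double js) {
  int hi = (int)tab.size() - 1;
  if (n <= hi) return tab[n];
  return tab[hi] + js * std::log((double)n / (double)hi);
  (void)lo;
}

static FoldParams read_params(List params) {
  FoldParams fp;
  NumericMatrix st = params["stack"];
  for (int i = 1; i <= 6; ++i)
    for (int j = 1; j <= 6; ++j)
      fp.stack[i][j] = st(i - 1, j - 1);
  NumericVector h = params["hairpin"], b = params["bulge"], il = params["internal"];
  // stored in R as values for sizes starting at hairpin_min etc.; re-index
  fp.hairpin.assign(3 + h.size(), 1e9);
  for (int i = 0; i < h.size(); ++i) fp.hairpin[3 + i] = h[i];
  fp.bulge.assign(1 + b.size(), 1e9);
  for (int i = 0; i < b.size(); ++i) fp.bulge[1 + i] = b[i];
  fp.internal.assign(2 + il.size(), 1e9);
  for (int i = 0; i < il.size(); ++i) fp.internal[2 + i] = il[i];
  fp.asym_coef = as<double>(params["asym_coef"]);
  fp.asym_max = as<double>(params["asym_max"]);
  fp.js_coef = as<double>(params["js_coef"]);
  fp.maxloop = as<int>(params["maxloop"]);
  return fp;
}

static inline double hairpin_e(const FoldParams& fp, int n) {
  if (n < 3) return 1e9;
  return tab_extrap(fp.hairpin, n, 3, fp.js_coef);
}
static inline double interior_e(const FoldParams& fp, int pt_out, int pt_in,
                                int s1, int s2) {
  if (s1 == 0 && s2 == 0) return fp.stack[pt_out][pt_in];
  if (s1 == 0 || s2 == 0) return tab_extrap(fp.bulge, s1 + s2, 1, fp.js_coef);
  double asym = fp.asym_coef * std::abs(s1 - s2);
  if (asym > fp.asym_max) asym = fp.asym_max;
  return tab_extrap(fp.internal, s1 + s2, 2, fp.js_coef) + asym;
}

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq, List params) {
  const int n = (int)seq.size();
  FoldParams fp = read_params(params);
  std::vector<int> code(n);
  for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);

  const double INF = 1e9;
  // V[i*n+j]: MFE of single-stem structure closed by pair (i,j)
  std::vector<double> V((size_t)n * n, INF);
  for (int d = 4; d < n; ++d) {
    for (int i = 0; i + d < n; ++i) {
      int j = i + d;
      int pt = pair_type(code[i], code[j]);
      if (!pt) continue;
      double best = hairpin_e(fp, j - i - 1);
      int kmax = std::min(i + 1 + fp.maxloop, j - 5);
      for (int k = i + 1; k <= kmax; ++k) {
        int s1 = k - i - 1;
        int lmin = std::max(k + 4, j - 1 - (fp.maxloop - s1));
        for (int l = j - 1; l >= lmin; --l) {
          double vkl = V[(size_t)k * n + l];
          if (vkl >= INF / 2) continue;
          int ptin = pair_type(code[k], code[l]);
          double e = vkl + interior_e(fp, pt, ptin, s1, j - l - 1);
          if (e < best) best = e;
        }
      }
      V[(size_t)i * n + j] = best;
    }
  }

  // pick the best closing pair (ties: smallest i, then smallest j)
  double emin = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 4; j < n; ++j)
      if (V[(size_t)i * n + j] < emin - 1e-9) {
        emin = V[(size_t)i * n + j];
        bi = i; bj = j;
      }

  std::string db(n, '.');
  if (bi >= 0) {
    int i = bi, j = bj;
    while (true) {
      db[i] = '('; db[j] = ')';
      double target = V[(size_t)i * n + j];
      int pt = pair_type(code[i], code[j]);
      if (std::abs(hairpin_e(fp, j - i - 1) - target) < 1e-7) break;
      bool found = false;
      int kmax = std::min(i + 1 + fp.maxloop, j - 5);
      for (int k = i + 1; k <= kmax && !found; ++k) {
        int s1 = k - i - 1;
        int lmin = std::max(k + 4, j - 1 - (fp.maxloop - s1));
        for (int l = j - 1; l >= lmin; --l) {
          double vkl = V[(size_t)k * n + l];
          if (vkl >= INF / 2) continue;
          int ptin = pair_type(code[k], code[l]);
          if (std::abs(vkl + interior_e(fp, pt, ptin, s1, j - l - 1) - target) < 1e-7) {
            i = k; j = l; found = true; break;
          }
        }
      }
      if (!found) break; // defensive; cannot happen if tables are finite
    }
  }
  return List::create(_["structure"] = db, _["energy"] = (bi >= 0 ? emin : 0.0));
}

// ---- 3' adapter trimming ---------------------------------------------------

// Leftmost occurrence of the adapter prefix with >= min_overlap overlap and
// <= max_mismatch mismatches. Returns insert length, or -1 when no adapter.
// [[Rcpp::export]]
IntegerVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                               int min_overlap = 6, int max_mismatch = 1) {
  const int alen = (int)adapter.size();
  IntegerVector out(reads.size());
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    const char* s = CHAR(STRING_ELT(reads, r));
    int len = (int)std::strlen(s);
    int ins = -1;
    for (int o = 0; o <= len - min_overlap; ++o) {
      int ov = std::min(len - o, alen);
      int mm = 0;
      for (int i = 0; i < ov; ++i) {
        if (s[o + i] != adapter[i] && ++mm > max_mismatch) break;
      }
      if (mm <= max_mismatch) { ins = o; break; }
    }
    out[r] = ins;
  }
  return out;
}

// ---- Hamming utilities -----------------------------------------------------

// Pairwise mismatch counts for equal-length string pairs; col1 = mismatches
// (or -1 if > max_mm), col2 = first mismatch position (0-based, -1 if none).
// [[Rcpp::export]]
IntegerMatrix hamming_pairs_cpp(CharacterVector a, CharacterVector b, int max_mm) {
  IntegerMatrix out(a.size(), 2);
  for (R_xlen_t r = 0; r < a.size(); ++r) {
    const char* x = CHAR(STRING_ELT(a, r));
    const char* y = CHAR(STRING_ELT(b, r));
    int n = (int)std::strlen(x);
    int mm = 0, first = -1;
    for (int i = 0; i < n; ++i) {
      if (x[i] != y[i]) {
        if (first < 0) first = i;
        if (++mm > max_mm) { mm = -1; break; }
      }
    }
    out(r, 0) = mm;
    out(r, 1) = (mm > 0) ? first : -1;
  }
  return out;
}

// All start positions (0-based) in subject where query matches with at most
// max_mm mismatches (plus strand of the subject only).
// [[Rcpp::export]]
DataFrame hamming_scan_cpp(std::string subject, std::string query, int max_mm) {
  const int n = (int)subject.size(), m = (int)query.size();
  std::vector<int> pos, mms;
  for (int o = 0; o + m <= n; ++o) {
    int mm = 0;
    for (int i = 0; i < m; ++i)
      if (subject[o + i] != query[i] && ++mm > max_mm) break;
    if (mm <= max_mm) { pos.push_back(o); mms.push_back(mm); }
  }
  return DataFrame::create(_["pos"] = pos, _["mm"] = mms);
}

// ---- seed-weighted miRNA:UTR duplex alignment ------------------------------

// Local affine-gap alignment of the reversed mature (so the miRNA reads
// 3'->5' against the UTR window 5'->3'). Positions 2-8 from the miRNA 5' end
// carry weight 4. Watson-Crick +5, G:U wobble +1, mismatch -3, gap open -9,
// gap extend -4; gaps that leave a miRNA base unaligned are scaled by that
// base's weight.
// [[Rcpp::export]]
List duplex_score_cpp(std::string mirna, std::string window,
                      double match = 5, double wobble = 1, double mismatch = -3,
                      double gap_open = -9, double gap_extend = -4,
                      int seed_from = 2, int seed_to = 8, double seed_weight = 4) {
  const int L = (int)mirna.size(), N = (int)window.size();
  std::string r(mirna.rbegin(), mirna.rend());
  std::vector<double> w(L + 1, 1.0);
  for (int i = 1; i <= L; ++i) {
    int p = L + 1 - i; // original 5'-based miRNA position of r[i-1]
    if (p >= seed_from && p <= seed_to) w[i] = seed_weight;
  }
  auto sub = [&](char mb, char ub) -> double {
    int a = base_code(mb), b = base_code(ub);
    int pt = pair_type(a, b);
    if (pt >= 1 && pt <= 4) return match;
    if (pt == 5 || pt == 6) return wobble;
    return mismatch;
  };
  const double NEG = -1e9;
  std::vector<double> M((L + 1) * (N + 1), 0.0), Ix((L + 1) * (N + 1), NEG),
      Iy((L + 1) * (N + 1), NEG);
  auto idx = [&](int i, int j) { return i * (N + 1) + j; };
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    for (int j = 1; j <= N; ++j) {
      double diag = std::max(M[idx(i - 1, j - 1)],
                             std::max(Ix[idx(i - 1, j - 1)], Iy[idx(i - 1, j - 1)]));
      double m = diag + w[i] * sub(r[i - 1], window[j - 1]);
      if (m < 0) m = 0;
      M[idx(i, j)] = m;
      Ix[idx(i, j)] = std::max(M[idx(i - 1, j)] + gap_open * w[i],
                               Ix[idx(i - 1, j)] + gap_extend * w[i]);
      Iy[idx(i, j)] = std::max(M[idx(i, j - 1)] + gap_open,
                               Iy[idx(i, j - 1)] + gap_extend);
      if (m > best + 1e-9) { best = m; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj) through M until a 0 cell
  std::string am, au, line;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = Ix, 2 = Iy
  while (i > 0 && j > 0) {
    if (state == 0) {
      double cur = M[idx(i, j)];
      if (cur <= 1e-9) break;
      double s = w[i] * sub(r[i - 1], window[j - 1]);
      am += r[i - 1];
      au += window[j - 1];
      int pt = pair_type(base_code(r[i - 1]), base_code(window[j - 1]));
      line += (pt >= 1 && pt <= 4) ? '|' : (pt >= 5 ? ':' : ' ');
      double prevM = M[idx(i - 1, j - 1)], prevX = Ix[idx(i - 1, j - 1)],
             prevY = Iy[idx(i - 1, j - 1)];
      double need = cur - s;
      --i; --j;
      if (std::abs(prevM - need) < 1e-6) state = 0;
      else if (std::abs(prevX - need) < 1e-6) state = 1;
      else state = 2;
      if (state == 0 && prevM <= 1e-9) break;
    } else if (state == 1) {
      am += r[i - 1]; au += '-'; line += ' ';
      double cur = Ix[idx(i, j)];
      state = (std::abs(M[idx(i - 1, j)] + gap_open * w[i] - cur) < 1e-6) ? 0 : 1;
      --i;
    } else {
      am += '-'; au += window[j - 1]; line += ' ';
      double cur = Iy[idx(i, j)];
      state = (std::abs(M[idx(i, j - 1)] + gap_open - cur) < 1e-6) ? 0 : 2;
      --j;
    }
  }
  std::reverse(am.begin(), am.end());
  std::reverse(au.begin(), au.end());
  std::reverse(line.begin(), line.end());
  // aligned span: r rows i+1..bi -> miRNA positions (5'-based) L-bi+1 .. L-i
  return List::create(
      _["score"] = best,
      _["mirna_from"] = (best > 0 ? L - bi + 1 : NA_INTEGER),
      _["mirna_to"] = (best > 0 ? L - i : NA_INTEGER),
      _["window_from"] = (best > 0 ? j + 1 : NA_INTEGER),
      _["window_to"] = (best > 0 ? bj : NA_INTEGER),
      _["aligned_mirna_3to5"] = am, _["pairing"] = line, _["aligned_utr"] = au);
}
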