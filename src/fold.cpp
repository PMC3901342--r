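#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Nucleotide encoding: A=0, C=1, G=2, U/T=3, other=-1.
static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'U': case 'u': case 'T': case 't': return 3;
  default: return -1;
  }
}

// Pair types indexed as in the energy tables:
// 1=CG, 2=GC, 3=GU, 4=UG, 5=AU, 6=UA, 0=not pairable.
static inline int pairtype(int a, int b) {
  if (a == 1 && b == 2) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 2 && b == 3) return 3;
  if (a == 3 && b == 2) return 4;
  if (a == 0 && b == 3) return 5;
  if (a == 3 && b == 0) return 6;
  return 0;
}

static const double INF_E = 1e9;

// Minimum free energy over single stem-loop secondary structures.
//
// A single stem-loop is a chain of nested pairs (i1,j1) > (i2,j2) > ... >
// (ik,jk): consecutive pairs are separated by a stack (both sides
// contiguous), a bulge (one side gapped) or an internal loop (both sides
// gapped), and the innermost pair closes a hairpin loop of >= min_hairpin
// unpaired bases. Energies: nearest-neighbor stacking for adjacent pairs,
// loop initiation penalties by total loop size, and a terminal penalty on
// the exterior-most pair when it is AU/UA/GU/UG. Exterior unpaired bases
// contribute nothing.
//
// stack:    6x6 matrix, stack[outer-1][inner-1], outer pair (i,j) stacked on
//           inner pair (i+1,j-1), kcal/mol.
// hairpin:  loop initiation by loop size 0..30 (sizes > 30 use the size-30
//           value); bulge, internal likewise by total loop size.
// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq,
                  NumericMatrix stack,
                  NumericVector hairpin,
                  NumericVector bulge,
                  NumericVector internal,
                  double terminal_au,
                  int min_hairpin,
                  int max_loop) {
  int n = seq.size();
  std::vector<int> x(n);
  for (int i = 0; i < n; ++i) {
    x[i] = enc(seq[i]);
    if (x[i] < 0) stop("non-ACGTU character in sequence");
  }
  int hmax = hairpin.size() - 1;
  int bmax = bulge.size() - 1;
  int imax = internal.size() - 1;

  // V[i][j]: MFE of a single stem-loop closed by pair (i,j).
  std::vector<std::vector<double> > V(n, std::vector<double>(n, INF_E));
  std::vector<std::vector<int> > TK(n, std::vector<int>(n, -2));
  std::vector<std::vector<int> > TL(n, std::vector<int>(n, -2));

  for (int span = min_hairpin + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      int tij = pairtype(x[i], x[j]);
      if (tij == 0) continue;
      int loop = j - i - 1;
      double best = INF_E;
      int bk = -2, bl = -2;
      if (loop >= min_hairpin) {
        best = hairpin[loop > hmax ? hmax : loop];
        bk = -1; bl = -1;  // hairpin closure
      }
      for (int k = i + 1; k < j - 1; ++k) {
        int n1 = k - i - 1;
        if (n1 > max_loop) break;
        for (int l = j - 1; l > k; --l) {
          int n2 = j - l - 1;
          if (n1 + n2 > max_loop) break;
          if (V[k][l] >= INF_E) continue;
          int tkl = pairtype(x[k], x[l]);
          if (tkl == 0) continue;
          double e;
          if (n1 == 0 && n2 == 0) {
            e = stack(tij - 1, tkl - 1);
          } else if (n1 == 0 || n2 == 0) {
            int sz = n1 + n2;
            e = bulge[sz > bmax ? bmax : sz];
          } else {
            int sz = n1 + n2;
            e = internal[sz > imax ? imax : sz];
          }
          double cand = V[k][l] + e;
          if (cand < best) { best = cand; bk = k; bl = l; }
        }
      }
      if (best < INF_E) { V[i][j] = best; TK[i][j] = bk; TL[i][j] = bl; }
    }
  }

  double w = 0.0;
  int wi = -1, wj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (V[i][j] >= INF_E) continue;
      int t = pairtype(x[i], x[j]);
      double e = V[i][j] + (t >= 3 ? terminal_au : 0.0);
      if (e < w) { w = e; wi = i; wj = j; }
    }
  }

  std::string db(n, '.');
  IntegerVector pt(n, 0);
  if (wi >= 0) {
    int i = wi, j = wj;
    while (i >= 0) {
      db[i] = '('; db[j] = ')';
      pt[i] = j + 1; pt[j] = i + 1;  // 1-based pair table
      int k = TK[i][j], l = TL[i][j];
      if (k < 0) break;
      i = k; j = l;
    }
  }
  return List::create(_["structure"] = db,
                      _["delta_g"] = (wi >= 0 ? w : 0.0),
                      _["pairs"] = pt);
}

// Verify candidate tag placements against a chromosome. For candidate r,
// query[r] is placed at 1-based position start[r]; mismatches are allowed
// only at the four outermost query positions (1, 2, L-1, L) and at most
// max_end_mm in total. Returns the mismatch count, or -1 when the
// placement is out of bounds, has an interior mismatch, or exceeds the
// budget.
// [[Rcpp::export]]
IntegerVector verify_tag_hits(std::string chrom, IntegerVector start,
                              CharacterVector query, int max_end_mm) {
  int n = start.size();
  int clen = chrom.size();
  IntegerVector out(n, -1);
  for (int r = 0; r < n; ++r) {
    const char *q = CHAR(STRING_ELT(query, r));
    int L = std::strlen(q);
    int s = start[r] - 1;
    if (s < 0 || s + L > clen) continue;
    int mm = 0;
    bool ok = true;
    for (int t = 0; t < L; ++t) {
      if (chrom[s + t] != q[t]) {
        if (t <= 1 || t >= L - 2) {
          if (++mm > max_end_mm) { ok = false; break; }
        } else { ok = false; break; }
      }
    }
    if (ok) out[r] = mm;
  }
  return out;
}

// Best adapter-prefix match in each read: the match consuming the most
// adapter bases wins, ties broken by the leftmost start. A match at
// 0-based read position s covers ov = min(len(adapter), L - s) bases and
// qualifies when ov >= min_overlap and mismatches <= floor(rate * ov).
// Returns the 0-based start of the matched adapter (== insert length),
// or -1 when no qualifying match exists.
// [[Rcpp::export]]
IntegerVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                               int min_overlap, double max_mismatch_rate) {
  int nr = reads.size();
  int alen = adapter.size();
  IntegerVector out(nr, -1);
  for (int r = 0; r < nr; ++r) {
    if (reads[r] == NA_STRING) continue;
    const char *s = CHAR(STRING_ELT(reads, r));
    int L = std::strlen(s);
    for (int st = 0; st <= L - min_overlap; ++st) {
      int ov = std::min(alen, L - st);
      if (ov < min_overlap) break;
      int allowed = (int)std::floor(max_mismatch_rate * ov + 1e-9);
      int mm = 0;
      bool ok = true;
      for (int t = 0; t < ov; ++t) {
        if (s[st + t] != adapter[t] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { out[r] = st; break; }  // first hit is longest + leftmost
    }
  }
  return out;
}
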