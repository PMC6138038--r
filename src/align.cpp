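#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// banded global alignment of two nucleotide strings with affine gaps.
// Band is placed around the offset diagonal j - i in [lo, hi]; lo/hi are
// widened by the length difference so the corner (n, m) is always inside.
// Gap model: first gapped position costs gap_open, each further gap_extend.
// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string s1, std::string s2,
                      double match, double mismatch,
                      double gap_open, double gap_extend, int band) {
  const int n = (int)s1.size(), m = (int)s2.size();
  const int lo = std::min(0, m - n) - band;
  const int hi = std::max(0, m - n) + band;
  const int W = hi - lo + 1;

  // rolling score rows, full traceback (state of predecessor per cell/state)
  std::vector<double> Mprev(W, NEG_INF), Iprev(W, NEG_INF), Dprev(W, NEG_INF);
  std::vector<double> Mcur(W, NEG_INF), Icur(W, NEG_INF), Dcur(W, NEG_INF);
  // traceback codes: 0 = M, 1 = I (gap in s2, consumes s1), 2 = D (gap in s1),
  // 9 = unset
  std::vector<unsigned char> tbM((size_t)(n + 1) * W, 9),
      tbI((size_t)(n + 1) * W, 9), tbD((size_t)(n + 1) * W, 9);

  // row i = 0
  for (int j = 0; j <= m; ++j) {
    int c = j - 0 - lo;
    if (c < 0 || c >= W) continue;
    if (j == 0) { Mprev[c] = 0.0; }
    else {
      Dprev[c] = gap_open + (j - 1) * gap_extend;
      tbD[(size_t)0 * W + c] = (j == 1) ? 0 : 2;
    }
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Icur.begin(), Icur.end(), NEG_INF);
    std::fill(Dcur.begin(), Dcur.end(), NEG_INF);
    int jmin = std::max(0, i + lo), jmax = std::min(m, i + hi);
    for (int j = jmin; j <= jmax; ++j) {
      int c = j - i - lo;
      size_t idx = (size_t)i * W + c;
      if (j > 0) {
        // M: diagonal from (i-1, j-1), same band column c
        double sub;
        char a = s1[i - 1], b = s2[j - 1];
        if (a == 'N' || b == 'N') sub = 0.0;
        else sub = (a == b) ? match : mismatch;
        double bm = Mprev[c], bi = Iprev[c], bd = Dprev[c];
        double best = bm; unsigned char st = 0;
        if (bi > best) { best = bi; st = 1; }
        if (bd > best) { best = bd; st = 2; }
        if (best > NEG_INF) { Mcur[c] = best + sub; tbM[idx] = st; }
      }
      // I: from (i-1, j) -> band column c + 1 in previous row
      if (c + 1 < W) {
        double bm = Mprev[c + 1] + gap_open;
        double bi = Iprev[c + 1] + gap_extend;
        double bd = Dprev[c + 1] + gap_open;
        double best = bm; unsigned char st = 0;
        if (bi > best) { best = bi; st = 1; }
        if (bd > best) { best = bd; st = 2; }
        if (best > NEG_INF) { Icur[c] = best; tbI[idx] = st; }
      }
      // D: from (i, j-1) -> band column c - 1 in current row
      if (j > 0 && c - 1 >= 0) {
        double bm = Mcur[c - 1] + gap_open;
        double bd = Dcur[c - 1] + gap_extend;
        double bi = Icur[c - 1] + gap_open;
        double best = bm; unsigned char st = 0;
        if (bd > best) { best = bd; st = 2; }
        if (bi > best) { best = bi; st = 1; }
        if (best > NEG_INF) { Dcur[c] = best; tbD[idx] = st; }
      }
    }
    std::swap(Mprev, Mcur); std::swap(Iprev, Icur); std::swap(Dprev, Dcur);
  }
  int cend = m - n - lo;
  if (cend < 0 || cend >= W)
    stop("band too narrow to reach the alignment end");
  double sm = Mprev[cend], si = Iprev[cend], sd = Dprev[cend];
  double best = sm; unsigned char state = 0;
  if (si > best) { best = si; state = 1; }
  if (sd > best) { best = sd; state = 2; }
  if (best == NEG_INF)
    stop("band too narrow: no alignment path within the band");

  // traceback
  std::string a1, a2;
  a1.reserve(n + m); a2.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t idx = (size_t)i * W + (j - i - lo);
    if (state == 0) {
      unsigned char p = tbM[idx];
      a1.push_back(s1[i - 1]); a2.push_back(s2[j - 1]);
      --i; --j; state = p;
    } else if (state == 1) {
      unsigned char p = tbI[idx];
      a1.push_back(s1[i - 1]); a2.push_back('-');
      --i; state = p;
    } else {
      unsigned char p = tbD[idx];
      a1.push_back('-'); a2.push_back(s2[j - 1]);
      --j; state = p;
    }
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());
  return List::create(_["aligned1"] = a1, _["aligned2"] = a2,
                      _["score"] = best);
}

// Frameshift-aware global alignment of a DNA string against a protein
// position-specific scoring profile.
//
// scores: 20 x C matrix of per-column residue log-odds (row order fixed by
//         the caller); codon_aa: length-64 integer map from codon index
//         (4*4*first + 4*second + third with A=0,C=1,G=2,T=3) to the row in
//         `scores`, -1 for stop, -2 for unresolvable (N-containing handled
//         by caller via index -2).
// Moves into a profile column j:
//   match  consume 3 nt, score = column log-odds of the translated codon
//   fs4    consume 4 nt (+1 frameshift), score = fs_penalty + log-odds of
//          the first 3 nt
//   fs2    consume 2 nt (-1 frameshift), score = fs_penalty, residue 'X'
//   delete consume 0 nt, affine gap in the DNA
// An insert move consumes 3 nt against no column (affine gap in the profile).
// Stop codons score stop_score; codons with N score 0 and emit 'X'.
// Ties are broken match > delete > insert > fs4 > fs2, then by predecessor
// state M > D > I.
// [[Rcpp::export(name = ".fs_align_cpp")]]
List fs_align_cpp(IntegerVector dna_idx, NumericMatrix scores,
                  IntegerVector codon_aa, std::string aa_letters,
                  double fs_penalty, double gap_open, double gap_extend,
                  double stop_score) {
  const int n = dna_idx.size();
  const int C = scores.ncol();
  const int NA_BASE = -1;  // N in the dna

  // codon score lookup for a window starting at 0-based dna position p
  auto codon_row = [&](int p) -> int {
    int a = dna_idx[p], b = dna_idx[p + 1], c = dna_idx[p + 2];
    if (a == NA_BASE || b == NA_BASE || c == NA_BASE) return -2;
    return codon_aa[16 * a + 4 * b + c];
  };
  auto col_score = [&](int row, int j) -> double {
    if (row == -2) return 0.0;        // ambiguous codon: neutral
    if (row == -1) return stop_score; // stop codon inside the alignment
    return scores(row, j - 1);
  };
  auto residue = [&](int row) -> char {
    if (row < 0) return (row == -1) ? '*' : 'X';
    return aa_letters[row];
  };

  // DP over (i = nt consumed 0..n, j = columns consumed 0..C), 3 states.
  const int SM = 0, SD = 1, SI = 2;
  size_t NC = (size_t)(n + 1) * (C + 1);
  std::vector<double> V(3 * NC, NEG_INF);
  // move codes: 0 match, 1 delete, 2 insert, 3 fs4, 4 fs2; +8*predstate
  std::vector<unsigned char> TB(3 * NC, 255);
  auto at = [&](int s, int i, int j) -> size_t {
    return (size_t)s * NC + (size_t)i * (C + 1) + j;
  };
  V[at(SM, 0, 0)] = 0.0;

  // candidate bookkeeping with tie-break: higher score wins; on exact tie the
  // lower move rank wins, then the lower predecessor state.
  struct Cand { double sc; int rank; int pred; bool ok; };
  auto better = [](const Cand &a, const Cand &b) -> bool {
    if (!b.ok) return a.ok;
    if (!a.ok) return false;
    if (a.sc != b.sc) return a.sc > b.sc;
    if (a.rank != b.rank) return a.rank < b.rank;
    return a.pred < b.pred;
  };

  for (int i = 0; i <= n; ++i) {
    for (int j = 0; j <= C; ++j) {
      if (i == 0 && j == 0) continue;
      // --- state M (last move consumed >=2 nt against a column) ---
      {
        Cand best = {NEG_INF, 0, 0, false};
        if (j >= 1) {
          // match (3 nt)
          if (i >= 3) {
            int row = codon_row(i - 3);
            double add = col_score(row, j);
            for (int p = 0; p < 3; ++p) {
              double v = V[at(p, i - 3, j - 1)];
              if (v > NEG_INF) {
                Cand c = {v + add, 0, p, true};
                if (better(c, best)) best = c;
              }
            }
          }
          // fs4 (+1): 4 nt, first 3 translated
          if (i >= 4) {
            int row = codon_row(i - 4);
            double add = fs_penalty + col_score(row, j);
            for (int p = 0; p < 3; ++p) {
              double v = V[at(p, i - 4, j - 1)];
              if (v > NEG_INF) {
                Cand c = {v + add, 3, p, true};
                if (better(c, best)) best = c;
              }
            }
          }
          // fs2 (-1): 2 nt, residue unknown
          if (i >= 2) {
            for (int p = 0; p < 3; ++p) {
              double v = V[at(p, i - 2, j - 1)];
              if (v > NEG_INF) {
                Cand c = {v + fs_penalty, 4, p, true};
                if (better(c, best)) best = c;
              }
            }
          }
        }
        if (best.ok) {
          V[at(SM, i, j)] = best.sc;
          TB[at(SM, i, j)] = (unsigned char)(best.rank + 8 * best.pred);
        }
      }
      // --- state D (delete profile column, 0 nt) ---
      if (j >= 1) {
        Cand best = {NEG_INF, 0, 0, false};
        for (int p = 0; p < 3; ++p) {
          double v = V[at(p, i, j - 1)];
          if (v > NEG_INF) {
            double pen = (p == SD) ? gap_extend : gap_open;
            Cand c = {v + pen, 1, p, true};
            if (better(c, best)) best = c;
          }
        }
        if (best.ok) {
          V[at(SD, i, j)] = best.sc;
          TB[at(SD, i, j)] = (unsigned char)(best.rank + 8 * best.pred);
        }
      }
      // --- state I (insert dna codon, 3 nt, no column) ---
      if (i >= 3) {
        Cand best = {NEG_INF, 0, 0, false};
        for (int p = 0; p < 3; ++p) {
          double v = V[at(p, i - 3, j)];
          if (v > NEG_INF) {
            double pen = (p == SI) ? gap_extend : gap_open;
            Cand c = {v + pen, 2, p, true};
            if (better(c, best)) best = c;
          }
        }
        if (best.ok) {
          V[at(SI, i, j)] = best.sc;
          TB[at(SI, i, j)] = (unsigned char)(best.rank + 8 * best.pred);
        }
      }
    }
  }

  Cand fin = {NEG_INF, 0, 0, false};
  for (int p = 0; p < 3; ++p) {
    double v = V[at(p, n, C)];
    if (v > NEG_INF) {
      Cand c = {v, 0, p, true};
      if (better(c, fin)) fin = c;
    }
  }
  if (!fin.ok)
    stop("no global frameshift-aware alignment path (dna too short?)");

  // traceback
  std::string row_rev;            // one char per profile column, reversed
  std::vector<int> fs_pos, fs_kind;
  std::vector<int> ins_cols;      // profile column after which an insert sits
  int i = n, j = C, s = fin.pred;
  while (i > 0 || j > 0) {
    unsigned char code = TB[at(s, i, j)];
    int mv = code % 8, pred = code / 8;
    if (s == SM) {
      if (mv == 0) { row_rev.push_back(residue(codon_row(i - 3))); i -= 3; }
      else if (mv == 3) {
        row_rev.push_back(residue(codon_row(i - 4)));
        fs_pos.push_back(i - 4 + 1); fs_kind.push_back(+1); i -= 4;
      } else {
        row_rev.push_back('X');
        fs_pos.push_back(i - 2 + 1); fs_kind.push_back(-1); i -= 2;
      }
      --j;
    } else if (s == SD) {
      row_rev.push_back('-'); --j;
    } else {
      ins_cols.push_back(j); i -= 3;
    }
    s = pred;
  }
  std::reverse(row_rev.begin(), row_rev.end());
  std::reverse(fs_pos.begin(), fs_pos.end());
  std::reverse(fs_kind.begin(), fs_kind.end());
  std::reverse(ins_cols.begin(), ins_cols.end());
  return List::create(
      _["aa_row"] = row_rev, _["score"] = fin.sc,
      _["fs_dna_position"] = IntegerVector(fs_pos.begin(), fs_pos.end()),
      _["fs_kind"] = IntegerVector(fs_kind.begin(), fs_kind.end()),
      _["insert_after_column"] =
          IntegerVector(ins_cols.begin(), ins_cols.end()));
}
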