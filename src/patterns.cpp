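#include <Rcpp.h>
using namespace Rcpp;

// Site-pattern classification for an outgroup-anchored quartet.
//
// A site is classified by the partition of the four sampled bases
// (outgroup, P1, hybrid, P2) into identity classes, written as a
// restricted-growth string with the outgroup always labelled 'A'.
// There are exactly 15 such classes (the set partitions of 4 items),
// listed here in lexicographic order; indices are fixed and shared
// with the R side:
//
//  1 AAAA   2 AAAB   3 AABA   4 AABB   5 AABC
//  6 ABAA   7 ABAB   8 ABAC   9 ABBA  10 ABBB
// 11 ABBC  12 ABCA  13 ABCB  14 ABCC  15 ABCD
//
// Input rows are integer-coded sequences (0..3 = A,C,G,T; negative =
// gap/ambiguous).  With several individuals per group, counts are
// averaged over the supplied individual combinations (fractional
// counts), so `sum(counts) + skipped == n_sites` always holds.

static inline int pattern_class(int o, int x1, int x2, int x3) {
  // restricted growth string over (o, x1, x2, x3)
  int lab[4];
  int codes[4] = {o, x1, x2, x3};
  int next = 0;
  int seen_code[4];
  int seen_lab[4];
  int nseen = 0;
  for (int i = 0; i < 4; ++i) {
    int c = codes[i];
    int found = -1;
    for (int j = 0; j < nseen; ++j) {
      if (seen_code[j] == c) { found = seen_lab[j]; break; }
    }
    if (found < 0) {
      found = next++;
      seen_code[nseen] = c;
      seen_lab[nseen] = found;
      ++nseen;
    }
    lab[i] = found;
  }
  // map the RGS (lab[0] is always 0) to the 1..15 index above
  int a = lab[1], b = lab[2], c = lab[3];
  // enumerate: lab[1] in {0,1}, lab[2] in {0..2}, lab[3] in {0..3}
  if (a == 0) {
    if (b == 0) return (c == 0) ? 1 : 2;              // AAAA, AAAB
    // b == 1
    if (c == 0) return 3;                              // AABA
    if (c == 1) return 4;                              // AABB
    return 5;                                          // AABC
  }
  // a == 1
  if (b == 0) {
    if (c == 0) return 6;                              // ABAA
    if (c == 1) return 7;                              // ABAB
    return 8;                                          // ABAC
  }
  if (b == 1) {
    if (c == 0) return 9;                              // ABBA
    if (c == 1) return 10;                             // ABBB
    return 11;                                         // ABBC
  }
  // b == 2
  if (c == 0) return 12;                               // ABCA
  if (c == 1) return 13;                               // ABCB
  if (c == 2) return 14;                               // ABCC
  return 15;                                           // ABCD
}

// [[Rcpp::export(name = ".pattern_counts_cpp")]]
List pattern_counts_cpp(IntegerMatrix og, IntegerMatrix p1,
                        IntegerMatrix hy, IntegerMatrix p2,
                        IntegerMatrix combos, IntegerVector block,
                        int nblocks) {
  const int L = og.ncol();
  if (p1.ncol() != L || hy.ncol() != L || p2.ncol() != L)
    stop("sequence groups differ in length");
  if (block.size() != L) stop("block vector must have one entry per site");
  const int ncomb = combos.ncol();
  if (combos.nrow() != 4) stop("combos must have 4 rows");
  NumericMatrix counts(15, nblocks);
  NumericVector skipped(nblocks);
  const double w = 1.0 / ncomb;
  for (int k = 0; k < ncomb; ++k) {
    const int io = combos(0, k) - 1, i1 = combos(1, k) - 1,
              ih = combos(2, k) - 1, i2 = combos(3, k) - 1;
    if (io < 0 || io >= og.nrow() || i1 < 0 || i1 >= p1.nrow() ||
        ih < 0 || ih >= hy.nrow() || i2 < 0 || i2 >= p2.nrow())
      stop("combo index out of range");
    for (int s = 0; s < L; ++s) {
      const int bl = block[s] - 1;
      if (bl < 0 || bl >= nblocks) stop("block id out of range");
      const int o = og(io, s), a = p1(i1, s), h = hy(ih, s), b = p2(i2, s);
      if (o < 0 || a < 0 || h < 0 || b < 0) {
        skipped[bl] += w;
      } else {
        counts(pattern_class(o, a, h, b) - 1, bl) += w;
      }
    }
  }
  return List::create(_["counts"] = counts, _["skipped"] = skipped,
                      _["n_combos"] = ncomb);
}
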