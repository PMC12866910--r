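#include <Rcpp.h>
using namespace Rcpp;

// Positional Burrows-Wheeler transform over a binary haplotype panel, with
// Durbin-style long-match reporting for out-of-panel query haplotypes.
//
// Conventions (0-based, half-open):
//   a(i,k) : haplotype row at sorted index i after processing sites < k
//            (haplotypes sorted by reversed prefix over sites [0,k))
//   d(i,k) : start of the longest common suffix (w.r.t. sites < k) between
//            a(i,k) and a(i-1,k); sentinel d(0,k) = k (empty match)
//   u(i,k) : number of 0-allele haplotypes among sorted indices < i at site k
//   cnt[k] : total number of 0 alleles at site k

// [[Rcpp::export]]
List pbwt_build_cpp(const IntegerMatrix& alleles) {
  const int M = alleles.nrow(), N = alleles.ncol();
  if (M < 1 || N < 1) stop("panel must have at least 1 haplotype and 1 site");
  IntegerMatrix a(M, N + 1), d(M, N + 1), u(M + 1, N);
  IntegerVector cnt(N);
  std::vector<int> a0(M), d0(M), a1(M), d1(M);
  for (int i = 0; i < M; ++i) { a(i, 0) = i; d(i, 0) = 0; }
  for (int k = 0; k < N; ++k) {
    int p = k + 1, q = k + 1, ia = 0, ib = 0;
    u(0, k) = 0;
    for (int i = 0; i < M; ++i) {
      const int hap = a(i, k), dd = d(i, k);
      if (dd > p) p = dd;
      if (dd > q) q = dd;
      const int al = alleles(hap, k);
      if (al != 0 && al != 1) stop("non-binary allele in panel at site %d", k);
      if (al == 0) { a0[ia] = hap; d0[ia] = p; p = 0; ++ia; }
      else         { a1[ib] = hap; d1[ib] = q; q = 0; ++ib; }
      u(i + 1, k) = ia;
    }
    cnt[k] = ia;
    for (int i = 0; i < ia; ++i) { a(i, k + 1) = a0[i]; d(i, k + 1) = d0[i]; }
    for (int i = 0; i < ib; ++i) { a(ia + i, k + 1) = a1[i]; d(ia + i, k + 1) = d1[i]; }
  }
  return List::create(_["a"] = a, _["d"] = d, _["u"] = u, _["cnt"] = cnt,
                      _["M"] = M, _["N"] = N);
}

// All maximal exact matches of length >= L between an external query z and
// every panel haplotype. The query's virtual insertion position t is swept
// through the sorted orders; f/g track the match start with the immediate
// neighbour above/below. Matches are reported exactly once, when they
// terminate (allele mismatch at site k, or end of chromosome).
// [[Rcpp::export]]
DataFrame pbwt_query_cpp(const List& index, const IntegerMatrix& alleles,
                         const IntegerVector& z, const int L) {
  const IntegerMatrix a = index["a"], d = index["d"], u = index["u"];
  const IntegerVector cnt = index["cnt"];
  const int M = index["M"], N = index["N"];
  if (z.size() != N) stop("query length %d != panel site count %d",
                          (int)z.size(), N);
  if (L < 1 || L > N) stop("L must be in 1..N");
  std::vector<int> out_ref, out_s, out_e;
  int t = 0, f = 0, g = 0;
  for (int k = 0; k < N; ++k) {
    const int q = z[k];
    if (q != 0 && q != 1) stop("non-binary allele in query at site %d", k);
    // scan upward from the insertion point: s is the match start between z
    // and the haplotype at sorted index i (non-decreasing as i moves away)
    int s = f, fnew = k + 1;
    bool fset = false;
    for (int i = t - 1; i >= 0; --i) {
      if (fset && s > k - L) break;
      const int hap = a(i, k);
      if (alleles(hap, k) == q) {
        if (!fset) { fnew = s; fset = true; }
      } else if (s <= k - L) {
        out_ref.push_back(hap); out_s.push_back(s); out_e.push_back(k);
      }
      if (d(i, k) > s) s = d(i, k);
    }
    // scan downward
    s = g;
    int gnew = k + 1;
    bool gset = false;
    for (int i = t; i < M; ++i) {
      if (gset && s > k - L) break;
      const int hap = a(i, k);
      if (alleles(hap, k) == q) {
        if (!gset) { gnew = s; gset = true; }
      } else if (s <= k - L) {
        out_ref.push_back(hap); out_s.push_back(s); out_e.push_back(k);
      }
      if (i + 1 < M && d(i + 1, k) > s) s = d(i + 1, k);
    }
    const int uk = u(t, k);
    t = (q == 0) ? uk : cnt[k] + (t - uk);
    f = fnew;
    g = gnew;
  }
  // matches still alive at the end of the chromosome
  {
    int s = f;
    for (int i = t - 1; i >= 0; --i) {
      if (s > N - L) break;
      out_ref.push_back(a(i, N)); out_s.push_back(s); out_e.push_back(N);
      if (d(i, N) > s) s = d(i, N);
    }
    s = g;
    for (int i = t; i < M; ++i) {
      if (s > N - L) break;
      out_ref.push_back(a(i, N)); out_s.push_back(s); out_e.push_back(N);
      if (i + 1 < M && d(i + 1, N) > s) s = d(i + 1, N);
    }
  }
  return DataFrame::create(_["ref_row"] = out_ref, _["start"] = out_s,
                           _["end"] = out_e);
}
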