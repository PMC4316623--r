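#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// Haplotypes as recombination mosaics of K founder rows.  switch_prob[j] is
// the probability that the copied founder is redrawn (uniformly among all K)
// in the interval preceding SNP j; switch_prob[0] is ignored.  Uses the R RNG
// so results are governed by set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_mosaic_haplotypes(const IntegerMatrix& founders, int n,
                                    const NumericVector& switch_prob) {
  const int K = founders.nrow(), S = founders.ncol();
  if (K < 1) stop("need at least one founder haplotype");
  if (switch_prob.size() != S) stop("switch_prob must have one entry per SNP");
  IntegerMatrix H(n, S);
  for (int i = 0; i < n; ++i) {
    int f = (int)(unif_rand() * K);
    if (f == K) f = K - 1;
    for (int j = 0; j < S; ++j) {
      if (j > 0 && unif_rand() < switch_prob[j]) {
        f = (int)(unif_rand() * K);
        if (f == K) f = K - 1;
      }
      H(i, j) = founders(f, j);
    }
  }
  return H;
}

// Flip the minimum number of randomly chosen entries per column so that the
// column sum equals target[j].  Returns a modified copy.
// [[Rcpp::export]]
IntegerMatrix cpp_match_freq(const IntegerMatrix& H, const IntegerVector& target) {
  const int n = H.nrow(), S = H.ncol();
  if (target.size() != S) stop("target must have one count per SNP");
  IntegerMatrix M = clone(H);
  for (int j = 0; j < S; ++j) {
    int c = 0;
    for (int i = 0; i < n; ++i) c += M(i, j);
    int t = target[j];
    if (t < 0 || t > n) stop("target count out of range");
    while (c > t) {  // flip random carriers to ancestral
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      if (M(i, j) == 1) { M(i, j) = 0; --c; }
    }
    while (c < t) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;
      if (M(i, j) == 0) { M(i, j) = 1; ++c; }
    }
  }
  return M;
}

static inline double pair_fraction(const std::unordered_map<long long, int>& cnt,
                                   double npairs) {
  double s = 0.0;
  for (const auto& kv : cnt) {
    double c = kv.second;
    s += c * (c - 1.0) / 2.0;
  }
  return s / npairs;
}

// Site-specific extended haplotype homozygosity profile from a core SNP in
// one direction.  Element d of the result is the probability that two random
// haplotypes are identical over all SNPs from the core to the SNP d steps
// away (core included); it is non-increasing in d.  direction is +1 or -1;
// the profile runs to the end of the panel.
// [[Rcpp::export]]
NumericVector cpp_ehhs_profile(const IntegerMatrix& H, int core, int direction) {
  const int n = H.nrow(), S = H.ncol();
  if (core < 1 || core > S) stop("core SNP out of range");
  if (direction != 1 && direction != -1) stop("direction must be +1 or -1");
  const int c0 = core - 1;
  const int len = (direction == 1) ? (S - 1 - c0) : c0;
  NumericVector out(len);
  const double npairs = n * (n - 1.0) / 2.0;
  std::vector<long long> g(n);
  // refine by the core allele first
  for (int i = 0; i < n; ++i) g[i] = H(i, c0);
  for (int d = 1; d <= len; ++d) {
    const int j = c0 + direction * d;
    std::unordered_map<long long, long long> remap;
    std::unordered_map<long long, int> cnt;
    long long next = 0;
    for (int i = 0; i < n; ++i) {
      long long key = g[i] * 2LL + H(i, j);
      auto it = remap.find(key);
      if (it == remap.end()) { remap[key] = next; g[i] = next; ++next; }
      else g[i] = it->second;
      ++cnt[g[i]];
    }
    out[d - 1] = pair_fraction(cnt, npairs);
    if (out[d - 1] == 0.0) {  // all singletons: stays 0
      for (int d2 = d + 1; d2 <= len; ++d2) out[d2 - 1] = 0.0;
      break;
    }
  }
  return out;
}

// Integrated EHHS (iES) for every SNP: trapezoid integral of the EHHS
// profile over physical distance (bp), both directions from the core,
// truncated at the first SNP whose EHHS drops below `decay` (that segment is
// included) or at `max_ext` bp from the core, whichever comes first.  The
// core contributes EHHS = 1 at zero width.  Haplotypes that fall into
// singleton identity groups are dropped from the walk: they can never
// contribute another identical pair.
// [[Rcpp::export]]
NumericVector cpp_ies(const IntegerMatrix& H, const NumericVector& pos,
                      double decay, double max_ext) {
  const int n = H.nrow(), S = H.ncol();
  if (pos.size() != S) stop("pos must have one entry per SNP");
  NumericVector ies(S);
  const double npairs = n * (n - 1.0) / 2.0;
  std::vector<int> g(n), act(n), nxt(n), remap(2 * n + 2), cnt(n + 1);
  for (int c = 0; c < S; ++c) {
    double total = 0.0;
    for (int dir = -1; dir <= 1; dir += 2) {
      int na = n;
      for (int i = 0; i < n; ++i) { act[i] = i; g[i] = H(i, c); }
      double eprev = 1.0, pprev = pos[c];
      for (int j = c + dir; j >= 0 && j < S; j += dir) {
        if (std::abs(pos[j] - pos[c]) > max_ext) break;
        // refine identity groups by the allele at j (group ids < na)
        std::fill(remap.begin(), remap.begin() + 2 * na + 2, -1);
        std::fill(cnt.begin(), cnt.begin() + na + 1, 0);
        int next = 0;
        for (int a = 0; a < na; ++a) {
          const int i = act[a];
          const int key = g[i] * 2 + H(i, j);
          if (remap[key] < 0) remap[key] = next++;
          g[i] = remap[key];
          ++cnt[g[i]];
        }
        double s = 0.0;
        for (int q = 0; q < next; ++q) s += cnt[q] * (cnt[q] - 1.0) / 2.0;
        const double e = s / npairs;
        total += 0.5 * (eprev + e) * std::abs(pos[j] - pprev);
        eprev = e; pprev = pos[j];
        if (e < decay) break;
        // drop haplotypes in singleton groups
        int keep = 0;
        for (int a = 0; a < na; ++a) {
          if (cnt[g[act[a]]] > 1) nxt[keep++] = act[a];
        }
        for (int a = 0; a < keep; ++a) act[a] = nxt[a];
        na = keep;
        if (na == 0) break;
      }
    }
    ies[c] = total;
  }
  return ies;
}
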