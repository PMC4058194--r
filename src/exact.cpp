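#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <functional>
using namespace Rcpp;

// Exhaustive maximiser of W(M) = 2|Gamma(M)| - sum_g |Gamma(g)| over all
// size-k column subsets.  Columns are bit-packed (64 samples per word) so a
// candidate set costs k word-OR passes plus one popcount pass; enumeration
// is lexicographic in column order and only strict improvements replace the
// incumbent, so the first optimum in column order wins ties (the R wrapper
// orders columns by gene id to obtain id-lexicographic tie-breaking).
// [[Rcpp::export]]
List exact_max_weight_cpp(const IntegerMatrix& A, const int k) {
  const int m = A.nrow(), n = A.ncol();
  if (k < 1 || k > n) stop("k out of range");
  const int words = (m + 63) / 64;

  std::vector<uint64_t> bits(static_cast<size_t>(words) * n, 0);
  std::vector<long> counts(n, 0);
  for (int j = 0; j < n; ++j) {
    uint64_t* col = &bits[static_cast<size_t>(j) * words];
    long c = 0;
    for (int i = 0; i < m; ++i) {
      if (A(i, j) != 0) {
        col[i >> 6] |= static_cast<uint64_t>(1) << (i & 63);
        ++c;
      }
    }
    counts[j] = c;
  }

  std::vector<uint64_t> prefix(static_cast<size_t>(k + 1) * words, 0);
  std::vector<int> idx(k), best_idx(k);
  long best_w = -4611686018427387904L;
  double n_eval = 0;

  std::function<void(int, int, long)> rec = [&](int depth, int start, long csum) {
    if (depth == k) {
      const uint64_t* u = &prefix[static_cast<size_t>(k) * words];
      long cov = 0;
      for (int w = 0; w < words; ++w) cov += __builtin_popcountll(u[w]);
      const long wgt = 2 * cov - csum;
      n_eval += 1;
      if (wgt > best_w) {
        best_w = wgt;
        best_idx = idx;
      }
      return;
    }
    const uint64_t* p = &prefix[static_cast<size_t>(depth) * words];
    uint64_t* q = &prefix[static_cast<size_t>(depth + 1) * words];
    for (int j = start; j <= n - (k - depth); ++j) {
      idx[depth] = j;
      const uint64_t* col = &bits[static_cast<size_t>(j) * words];
      for (int w = 0; w < words; ++w) q[w] = p[w] | col[w];
      rec(depth + 1, j + 1, csum + counts[j]);
    }
  };
  rec(0, 0, 0);

  IntegerVector out(best_idx.begin(), best_idx.end());
  for (int i = 0; i < k; ++i) out[i] += 1;  // 1-based for R
  return List::create(_["indices"] = out,
                      _["weight"] = static_cast<double>(best_w),
                      _["evaluated"] = n_eval);
}

static inline long popcount_words(const uint64_t* u, int words) {
  long c = 0;
  for (int w = 0; w < words; ++w) c += __builtin_popcountll(u[w]);
  return c;
}

// Bit-pack a binary matrix column-wise (64 samples per word) for the fast
// evaluators below.  Returned blob: raw bytes of words*n uint64 words plus
// per-column mutation counts.
// [[Rcpp::export]]
List pack_mutations_cpp(const IntegerMatrix& A) {
  const int m = A.nrow(), n = A.ncol();
  const int words = (m + 63) / 64;
  RawVector blob(static_cast<size_t>(words) * n * sizeof(uint64_t));
  uint64_t* bits = reinterpret_cast<uint64_t*>(RAW(blob));
  std::fill(bits, bits + static_cast<size_t>(words) * n, 0);
  IntegerVector counts(n);
  for (int j = 0; j < n; ++j) {
    uint64_t* col = bits + static_cast<size_t>(j) * words;
    int c = 0;
    for (int i = 0; i < m; ++i) {
      if (A(i, j) != 0) {
        col[i >> 6] |= static_cast<uint64_t>(1) << (i & 63);
        ++c;
      }
    }
    counts[j] = c;
  }
  return List::create(_["bits"] = blob, _["words"] = words, _["m"] = m,
                      _["n"] = n, _["counts"] = counts);
}

// W(M) for each column (one gene set of 1-based indices per column of `sets`).
// [[Rcpp::export]]
NumericVector packed_weights_cpp(const List& packed, const IntegerMatrix& sets) {
  const RawVector blob = packed["bits"];
  const uint64_t* bits = reinterpret_cast<const uint64_t*>(RAW(blob));
  const int words = packed["words"];
  const IntegerVector counts = packed["counts"];
  const int k = sets.nrow(), P = sets.ncol();
  NumericVector out(P);
  std::vector<uint64_t> u(words);
  for (int p = 0; p < P; ++p) {
    std::fill(u.begin(), u.end(), 0);
    long csum = 0;
    for (int t = 0; t < k; ++t) {
      const int j = sets(t, p) - 1;
      const uint64_t* col = bits + static_cast<size_t>(j) * words;
      for (int w = 0; w < words; ++w) u[w] |= col[w];
      csum += counts[j];
    }
    out[p] = static_cast<double>(2 * popcount_words(u.data(), words) - csum);
  }
  return out;
}

// Greedy best-improvement 1-swap local search on W(M): repeatedly scan every
// (member out, non-member in) swap and apply the best strictly-improving one.
// Deterministic (no RNG, fixed scan order); returns the local optimum.
// [[Rcpp::export]]
List local_search_cpp(const List& packed, const IntegerVector& set0) {
  const RawVector blob = packed["bits"];
  const uint64_t* bits = reinterpret_cast<const uint64_t*>(RAW(blob));
  const int words = packed["words"];
  const int n = packed["n"];
  const IntegerVector counts = packed["counts"];
  const int k = set0.size();
  std::vector<int> set(k);
  for (int t = 0; t < k; ++t) set[t] = set0[t] - 1;
  std::vector<bool> in_set(n, false);
  for (int t = 0; t < k; ++t) in_set[set[t]] = true;

  std::vector<uint64_t> rest(words), cand(words);
  double evals = 0;

  long cur_w;
  {
    std::vector<uint64_t> u(words, 0);
    long csum = 0;
    for (int t = 0; t < k; ++t) {
      const uint64_t* col = bits + static_cast<size_t>(set[t]) * words;
      for (int w = 0; w < words; ++w) u[w] |= col[w];
      csum += counts[set[t]];
    }
    cur_w = 2 * popcount_words(u.data(), words) - csum;
  }

  bool improved = true;
  while (improved) {
    improved = false;
    long best_w = cur_w;
    int best_out = -1, best_in = -1;
    for (int t = 0; t < k; ++t) {
      std::fill(rest.begin(), rest.end(), 0);
      long csum_rest = 0;
      for (int s = 0; s < k; ++s) {
        if (s == t) continue;
        const uint64_t* col = bits + static_cast<size_t>(set[s]) * words;
        for (int w = 0; w < words; ++w) rest[w] |= col[w];
        csum_rest += counts[set[s]];
      }
      for (int j = 0; j < n; ++j) {
        if (in_set[j]) continue;
        const uint64_t* col = bits + static_cast<size_t>(j) * words;
        for (int w = 0; w < words; ++w) cand[w] = rest[w] | col[w];
        const long wgt = 2 * popcount_words(cand.data(), words) -
          (csum_rest + counts[j]);
        evals += 1;
        if (wgt > best_w) {
          best_w = wgt;
          best_out = t;
          best_in = j;
        }
      }
    }
    if (best_out >= 0) {
      in_set[set[best_out]] = false;
      in_set[best_in] = true;
      set[best_out] = best_in;
      cur_w = best_w;
      improved = true;
    }
  }

  IntegerVector out(set.begin(), set.end());
  for (int t = 0; t < k; ++t) out[t] += 1;
  std::sort(out.begin(), out.end());
  return List::create(_["set"] = out, _["weight"] = static_cast<double>(cur_w),
                      _["evaluated"] = evals);
}

// Metropolis chain over size-k sets with stationary density ~ c^W(M):
// uniform single-gene-swap proposal, acceptance min(1, c^delta).  Uses R's
// RNG so runs are reproducible under set.seed(); the trajectory is recorded
// every `thin` iterations.
// [[Rcpp::export]]
List mcmc_chain_cpp(const List& packed, const IntegerVector& start,
                    const double iterations, const double c, const int thin) {
  const RawVector blob = packed["bits"];
  const uint64_t* bits = reinterpret_cast<const uint64_t*>(RAW(blob));
  const int words = packed["words"];
  const int n = packed["n"];
  const IntegerVector counts = packed["counts"];
  const int k = start.size();

  std::vector<int> set(k);
  std::vector<bool> in_set(n, false);
  for (int t = 0; t < k; ++t) {
    set[t] = start[t] - 1;
    in_set[set[t]] = true;
  }
  std::vector<uint64_t> u(words);
  auto weight_of = [&](const std::vector<int>& s) -> long {
    std::fill(u.begin(), u.end(), 0);
    long csum = 0;
    for (int t = 0; t < k; ++t) {
      const uint64_t* col = bits + static_cast<size_t>(s[t]) * words;
      for (int w = 0; w < words; ++w) u[w] |= col[w];
      csum += counts[s[t]];
    }
    return 2 * popcount_words(u.data(), words) - csum;
  };

  long cur_w = weight_of(set);
  std::vector<int> best_set = set;
  long best_w = cur_w;
  double accepted_worse = 0, evals = 1;
  const double log_c = std::log(c);

  const R_xlen_t n_rec = static_cast<R_xlen_t>(iterations / thin);
  NumericVector rec_it(n_rec), rec_cur(n_rec), rec_best(n_rec);
  R_xlen_t rec = 0;

  std::vector<int> prop(k);
  for (double i = 1; i <= iterations; ++i) {
    prop = set;
    const int pos = static_cast<int>(unif_rand() * k) % k;
    int g;
    do {
      g = static_cast<int>(unif_rand() * n) % n;
    } while (in_set[g]);
    prop[pos] = g;
    const long prop_w = weight_of(prop);
    evals += 1;
    const double delta = static_cast<double>(prop_w - cur_w);
    if (delta >= 0 || unif_rand() < std::exp(log_c * delta)) {
      if (delta < 0) accepted_worse += 1;
      in_set[set[pos]] = false;
      in_set[g] = true;
      set = prop;
      cur_w = prop_w;
      if (cur_w > best_w) {
        best_w = cur_w;
        best_set = set;
      }
    }
    if (rec < n_rec && static_cast<long long>(i) % thin == 0) {
      rec_it[rec] = i;
      rec_cur[rec] = static_cast<double>(cur_w);
      rec_best[rec] = static_cast<double>(best_w);
      ++rec;
    }
  }

  IntegerVector out(best_set.begin(), best_set.end());
  for (int t = 0; t < k; ++t) out[t] += 1;
  std::sort(out.begin(), out.end());
  NumericVector tr_it(rec), tr_cur(rec), tr_best(rec);
  for (R_xlen_t r = 0; r < rec; ++r) {
    tr_it[r] = rec_it[r];
    tr_cur[r] = rec_cur[r];
    tr_best[r] = rec_best[r];
  }
  return List::create(_["set"] = out, _["weight"] = static_cast<double>(best_w),
                      _["accepted_worse"] = accepted_worse,
                      _["evaluated"] = evals,
                      _["iteration"] = tr_it,
                      _["current"] = tr_cur,
                      _["best"] = tr_best);
}

// Greedy forward selection: start from one gene and repeatedly add the gene
// that maximises W of the grown set (first index wins ties), up to size k.
// [[Rcpp::export]]
List greedy_grow_cpp(const List& packed, const int start_gene, const int k) {
  const RawVector blob = packed["bits"];
  const uint64_t* bits = reinterpret_cast<const uint64_t*>(RAW(blob));
  const int words = packed["words"];
  const int n = packed["n"];
  const IntegerVector counts = packed["counts"];

  std::vector<int> set;
  set.reserve(k);
  std::vector<bool> in_set(n, false);
  std::vector<uint64_t> base(words, 0), cand(words);
  long csum = 0;
  double evals = 0;

  int g0 = start_gene - 1;
  set.push_back(g0);
  in_set[g0] = true;
  {
    const uint64_t* col = bits + static_cast<size_t>(g0) * words;
    for (int w = 0; w < words; ++w) base[w] = col[w];
    csum = counts[g0];
  }

  while (static_cast<int>(set.size()) < k) {
    long best_w = -4611686018427387904L;
    int best_j = -1;
    for (int j = 0; j < n; ++j) {
      if (in_set[j]) continue;
      const uint64_t* col = bits + static_cast<size_t>(j) * words;
      for (int w = 0; w < words; ++w) cand[w] = base[w] | col[w];
      const long wgt = 2 * popcount_words(cand.data(), words) -
        (csum + counts[j]);
      evals += 1;
      if (wgt > best_w) {
        best_w = wgt;
        best_j = j;
      }
    }
    const uint64_t* col = bits + static_cast<size_t>(best_j) * words;
    for (int w = 0; w < words; ++w) base[w] |= col[w];
    csum += counts[best_j];
    set.push_back(best_j);
    in_set[best_j] = true;
  }

  IntegerVector out(set.begin(), set.end());
  for (int t = 0; t < k; ++t) out[t] += 1;
  std::sort(out.begin(), out.end());
  return List::create(_["set"] = out, _["evaluated"] = evals);
}
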