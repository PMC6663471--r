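#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Co-assignment counts across an ensemble of partitions.
// labs: N x R integer matrix, column r = module labels of partition r.
// Returns N x N matrix with counts[i,j] = #{r : labs(i,r) == labs(j,r)},
// diagonal = R.
// [[Rcpp::export]]
IntegerMatrix cpp_assoc_counts(IntegerMatrix labs) {
  int n = labs.nrow(), r = labs.ncol();
  IntegerMatrix out(n, n);
  for (int k = 0; k < r; ++k) {
    for (int j = 0; j < n; ++j) {
      int lj = labs(j, k);
      for (int i = 0; i < j; ++i) {
        if (labs(i, k) == lj) { out(i, j) += 1; }
      }
    }
  }
  for (int j = 0; j < n; ++j) {
    out(j, j) = r;
    for (int i = 0; i < j; ++i) out(j, i) = out(i, j);
  }
  return out;
}

// Pooled off-diagonal co-assignment counts under the permutation null.
// For each of n_perm repetitions every partition's labels are shuffled
// across nodes (preserving module sizes) and the resulting association
// counts for all node pairs are appended to the pool. Uses R's RNG so
// results are governed by set.seed().
// [[Rcpp::export]]
NumericVector cpp_null_assoc_pool(IntegerMatrix labs, int n_perm) {
  int n = labs.nrow(), r = labs.ncol();
  R_xlen_t npair = (R_xlen_t)n * (n - 1) / 2;
  NumericVector pool(npair * n_perm);
  std::vector<int> perm(n), shuf(n * r);
  for (int p = 0; p < n_perm; ++p) {
    // one node permutation per partition
    for (int k = 0; k < r; ++k) {
      for (int i = 0; i < n; ++i) perm[i] = i;
      for (int i = n - 1; i > 0; --i) {
        int j = (int)(unif_rand() * (i + 1));
        if (j > i) j = i;
        std::swap(perm[i], perm[j]);
      }
      for (int i = 0; i < n; ++i) shuf[(size_t)k * n + i] = labs(perm[i], k);
    }
    R_xlen_t base = (R_xlen_t)p * npair, idx = 0;
    for (int j = 0; j < n; ++j) {
      for (int i = 0; i < j; ++i) {
        int cnt = 0;
        for (int k = 0; k < r; ++k)
          if (shuf[(size_t)k * n + i] == shuf[(size_t)k * n + j]) ++cnt;
        pool[base + idx++] = cnt;
      }
    }
  }
  return pool;
}

// Number of node pairs co-assigned in both partitions, for every pair of
// columns of labs. Returns T x T matrix of w values (diagonal = pairs
// co-assigned within each partition).
// [[Rcpp::export]]
NumericMatrix cpp_pair_w(IntegerMatrix labs) {
  int n = labs.nrow(), t = labs.ncol();
  NumericMatrix w(t, t);
  std::vector<int> kmax(t);
  for (int c = 0; c < t; ++c) {
    int m = 0;
    for (int i = 0; i < n; ++i) m = std::max(m, labs(i, c));
    kmax[c] = m;
  }
  for (int a = 0; a < t; ++a) {
    for (int b = a; b < t; ++b) {
      // contingency table of (label_a, label_b)
      int ka = kmax[a], kb = kmax[b];
      std::vector<double> tab((size_t)ka * kb, 0.0);
      for (int i = 0; i < n; ++i)
        tab[(size_t)(labs(i, a) - 1) * kb + (labs(i, b) - 1)] += 1.0;
      double s = 0.0;
      for (size_t q = 0; q < tab.size(); ++q) s += tab[q] * (tab[q] - 1.0) / 2.0;
      w(a, b) = s;
      w(b, a) = s;
    }
  }
  return w;
}

// 2-D median filter with edge-replication padding, odd square kernel.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix m, int k) {
  int n1 = m.nrow(), n2 = m.ncol(), h = k / 2;
  NumericMatrix out(n1, n2);
  std::vector<double> buf((size_t)k * k);
  for (int j = 0; j < n2; ++j) {
    for (int i = 0; i < n1; ++i) {
      size_t q = 0;
      for (int dj = -h; dj <= h; ++dj) {
        int jj = std::min(std::max(j + dj, 0), n2 - 1);
        for (int di = -h; di <= h; ++di) {
          int ii = std::min(std::max(i + di, 0), n1 - 1);
          buf[q++] = m(ii, jj);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + q / 2, buf.begin() + q);
      double med = buf[q / 2];
      if (q % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + q / 2 - 1, buf.begin() + q);
        med = (med + buf[q / 2 - 1]) / 2.0;
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Multilevel (Louvain) modularity optimization on a dense, possibly
// signed, symmetric weight matrix. Positive and negative weights are
// kept as separate layers with their own configuration-model null terms
// (two-layer signed modularity): moving node i into community c gains
//   (Sp - g*kp_i*totp_c/2mp) - (Sn - g*kn_i*totn_c/2mn).
// On a nonnegative matrix this reduces to classic weighted Louvain.
// Node visiting order is randomized via R's RNG.
// [[Rcpp::export]]
IntegerVector cpp_louvain(NumericMatrix W, double gamma) {
  int n0 = W.nrow();
  std::vector<double> Wp((size_t)n0 * n0, 0.0), Wn((size_t)n0 * n0, 0.0);
  for (int j = 0; j < n0; ++j)
    for (int i = 0; i < n0; ++i) {
      double w = W(i, j);
      if (w > 0) Wp[(size_t)j * n0 + i] = w;
      else if (w < 0) Wn[(size_t)j * n0 + i] = -w;
    }
  std::vector<int> glob(n0);
  for (int i = 0; i < n0; ++i) glob[i] = i;
  int n = n0;
  for (int level = 0; level < 50; ++level) {
    std::vector<double> kp(n, 0.0), kn(n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) {
        kp[i] += Wp[(size_t)j * n + i];
        kn[i] += Wn[(size_t)j * n + i];
      }
    double m2p = 0.0, m2n = 0.0;
    for (int i = 0; i < n; ++i) { m2p += kp[i]; m2n += kn[i]; }
    std::vector<int> comm(n), sz(n, 1);
    std::vector<double> totp(kp), totn(kn);
    for (int i = 0; i < n; ++i) comm[i] = i;
    std::vector<int> order(n);
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    std::vector<double> Sp(n, 0.0), Sn(n, 0.0);
    std::vector<int> seen;
    seen.reserve(n);
    bool moved_any = false, moved = true;
    int pass = 0;
    while (moved && pass < 100) {
      moved = false;
      ++pass;
      for (int oi = 0; oi < n; ++oi) {
        int i = order[oi];
        int ci = comm[i];
        seen.clear();
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double wp = Wp[(size_t)j * n + i], wn = Wn[(size_t)j * n + i];
          if (wp != 0.0 || wn != 0.0) {
            int c = comm[j];
            if (Sp[c] == 0.0 && Sn[c] == 0.0) seen.push_back(c);
            Sp[c] += wp;
            Sn[c] += wn;
          }
        }
        // remove i from its community
        totp[ci] -= kp[i];
        totn[ci] -= kn[i];
        sz[ci] -= 1;
        double gain_stay =
          (sz[ci] > 0 ?
             ((m2p > 0 ? Sp[ci] - gamma * kp[i] * totp[ci] / m2p : 0.0) -
              (m2n > 0 ? Sn[ci] - gamma * kn[i] * totn[ci] / m2n : 0.0))
           : 0.0);
        int best = ci;
        double best_gain = gain_stay;
        for (size_t q = 0; q < seen.size(); ++q) {
          int c = seen[q];
          if (c == ci) continue;
          double g =
            (m2p > 0 ? Sp[c] - gamma * kp[i] * totp[c] / m2p : 0.0) -
            (m2n > 0 ? Sn[c] - gamma * kn[i] * totn[c] / m2n : 0.0);
          if (g > best_gain + 1e-12) { best_gain = g; best = c; }
        }
        if (best_gain < -1e-12) {
          // better off alone: reuse an empty community label
          for (int c = 0; c < n; ++c)
            if (sz[c] == 0) { best = c; break; }
        }
        comm[i] = best;
        totp[best] += kp[i];
        totn[best] += kn[i];
        sz[best] += 1;
        if (best != ci) { moved = true; moved_any = true; }
        for (size_t q = 0; q < seen.size(); ++q) {
          Sp[seen[q]] = 0.0;
          Sn[seen[q]] = 0.0;
        }
      }
    }
    // renumber communities consecutively
    std::vector<int> renum(n, -1);
    int K = 0;
    for (int i = 0; i < n; ++i)
      if (renum[comm[i]] < 0) renum[comm[i]] = K++;
    for (int v = 0; v < n0; ++v) glob[v] = renum[comm[glob[v]]];
    if (!moved_any || K == n) break;
    // aggregate
    std::vector<double> nWp((size_t)K * K, 0.0), nWn((size_t)K * K, 0.0);
    for (int j = 0; j < n; ++j) {
      int cj = renum[comm[j]];
      for (int i = 0; i < n; ++i) {
        int ci2 = renum[comm[i]];
        nWp[(size_t)cj * K + ci2] += Wp[(size_t)j * n + i];
        nWn[(size_t)cj * K + ci2] += Wn[(size_t)j * n + i];
      }
    }
    Wp.swap(nWp);
    Wn.swap(nWn);
    n = K;
  }
  IntegerVector out(n0);
  for (int i = 0; i < n0; ++i) out[i] = glob[i] + 1;
  return out;
}

// Pooled-null cutoff: builds the same permutation pool as
// cpp_null_assoc_pool but returns its type-7 quantile directly, avoiding
// a round trip of n_perm * N(N-1)/2 values through R.
// [[Rcpp::export]]
double cpp_null_assoc_cutoff(IntegerMatrix labs, int n_perm, double prob) {
  NumericVector pool = cpp_null_assoc_pool(labs, n_perm);
  R_xlen_t n = pool.size();
  if (n == 1) return pool[0];
  double h = (n - 1) * prob;
  R_xlen_t lo = (R_xlen_t)std::floor(h);
  std::nth_element(pool.begin(), pool.begin() + lo, pool.end());
  double xlo = pool[lo];
  if (lo + 1 >= n || h == (double)lo) return xlo;
  double xhi = *std::min_element(pool.begin() + lo + 1, pool.end());
  return xlo + (h - lo) * (xhi - xlo);
}
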