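#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Collapsed Gibbs samplers for LDA and for zero-inflated LDA (ZIGD prior on
// the subcommunity taxon profiles). Reads are stored explicitly (one entry
// per sequencing read) so the per-read resampling is faithful to the model;
// sufficient statistics are the taxon-in-community counts n[j][i] and the
// community-in-sample counts m[d][j].
//
// All randomness comes from R's RNG (unif_rand), so set.seed() in R governs
// the chains.

static inline int sample_index(const std::vector<double> &p, double total) {
  double u = unif_rand() * total;
  double acc = 0.0;
  int K = (int)p.size();
  for (int j = 0; j < K; ++j) {
    acc += p[j];
    if (u <= acc) return j;
  }
  return K - 1;
}

// state code for tiny-instance enumeration checks: sum_r z[r] K^r (+ delta bits)
static inline double z_code(const std::vector<int> &z, int K) {
  double code = 0.0, mult = 1.0;
  for (size_t r = 0; r < z.size(); ++r) {
    code += z[r] * mult;
    mult *= K;
  }
  return code;
}

// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector doc, IntegerVector taxon, IntegerVector z0,
                   int D, int V, int K, double alpha, double eta,
                   int n_iter, int burn_in, int thin,
                   bool store_draws, bool trace, bool check_invariants) {
  int N = doc.size();
  std::vector<int> z(z0.begin(), z0.end());
  std::vector<std::vector<int>> n(K, std::vector<int>(V, 0));
  std::vector<int> nsum(K, 0);
  std::vector<std::vector<int>> m(D, std::vector<int>(K, 0));
  std::vector<int> depth(D, 0);
  for (int r = 0; r < N; ++r) {
    n[z[r]][taxon[r]]++; nsum[z[r]]++; m[doc[r]][z[r]]++; depth[doc[r]]++;
  }

  int n_keep = 0;
  for (int it = burn_in; it < n_iter; ++it)
    if ((it - burn_in) % thin == 0) n_keep++;

  NumericVector beta_sum(K * V), theta_sum(D * K);
  NumericVector beta_draws(store_draws ? n_keep * K * V : 0);
  NumericVector theta_draws(store_draws ? n_keep * D * K : 0);
  NumericVector trace_codes(trace ? (n_iter - burn_in) : 0);

  std::vector<double> p(K);
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    for (int r = 0; r < N; ++r) {
      int d = doc[r], i = taxon[r], c = z[r];
      n[c][i]--; nsum[c]--; m[d][c]--;
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = (n[j][i] + eta) / (nsum[j] + V * eta) * (m[d][j] + alpha);
        tot += p[j];
      }
      int jn = sample_index(p, tot);
      z[r] = jn;
      n[jn][i]++; nsum[jn]++; m[d][jn]++;
    }
    if (check_invariants) {
      for (int j = 0; j < K; ++j) {
        long s = 0; for (int i = 0; i < V; ++i) s += n[j][i];
        long sm = 0; for (int d = 0; d < D; ++d) sm += m[d][j];
        if (s != nsum[j] || s != sm)
          stop("LDA sampler: count bookkeeping violated");
      }
    }
    if (it >= burn_in) {
      if (trace) trace_codes[it - burn_in] = z_code(z, K);
      if ((it - burn_in) % thin == 0) {
        for (int j = 0; j < K; ++j)
          for (int i = 0; i < V; ++i) {
            double b = (n[j][i] + eta) / (nsum[j] + V * eta);
            beta_sum[j + K * i] += b;
            if (store_draws) beta_draws[j + K * i + K * V * kept] = b;
          }
        for (int d = 0; d < D; ++d)
          for (int j = 0; j < K; ++j) {
            double t = (m[d][j] + alpha) / (depth[d] + K * alpha);
            theta_sum[d + D * j] += t;
            if (store_draws) theta_draws[d + D * j + D * K * kept] = t;
          }
        kept++;
      }
    }
  }

  NumericMatrix beta_hat(K, V), theta_hat(D, K);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < V; ++i) beta_hat(j, i) = beta_sum[j + K * i] / kept;
  for (int d = 0; d < D; ++d)
    for (int j = 0; j < K; ++j) theta_hat(d, j) = theta_sum[d + D * j] / kept;

  List out = List::create(
    _["beta"] = beta_hat, _["theta"] = theta_hat,
    _["z"] = IntegerVector(z.begin(), z.end()), _["n_kept"] = kept);
  if (store_draws) {
    beta_draws.attr("dim") = IntegerVector::create(K, V, n_keep);
    theta_draws.attr("dim") = IntegerVector::create(D, K, n_keep);
    out["beta_draws"] = beta_draws;
    out["theta_draws"] = theta_draws;
  }
  if (trace) out["trace"] = trace_codes;
  return out;
}

// Posterior-predictive taxon profile for one community under the ZIGD prior,
// given current counts and structural-zero pattern: the stick-breaking
// posterior mean. Support always includes the last taxon; entries off
// support are exactly zero. Writes into bhat (length V); `suffix` is a
// caller-provided scratch buffer of length V (no per-call allocation — this
// sits in the innermost sampling loop).
static inline void zigd_beta_hat(const int *nj, const int *del,
                                 double a, double b, int V,
                                 double *bhat, int *suffix) {
  // suffix[i] = total count strictly after position i
  int trail = 0;
  for (int i = V - 1; i >= 0; --i) { suffix[i] = trail; trail += nj[i]; }
  double stick = 1.0;
  for (int i = 0; i < V - 1; ++i) {
    if (del[i]) { bhat[i] = 0.0; continue; }
    double an = a + nj[i];
    double q = an / (an + b + suffix[i]);
    bhat[i] = q * stick;
    stick -= q * stick;
  }
  bhat[V - 1] = stick;
}

// Same, ignoring the structural-zero pattern (full support); used as the
// guard when a taxon is transiently excluded from every community.
static inline void zigd_beta_hat_full(const int *nj, double a, double b,
                                      int V, double *bhat, int *suffix) {
  int trail = 0;
  for (int i = V - 1; i >= 0; --i) { suffix[i] = trail; trail += nj[i]; }
  double stick = 1.0;
  for (int i = 0; i < V - 1; ++i) {
    double an = a + nj[i];
    double q = an / (an + b + suffix[i]);
    bhat[i] = q * stick;
    stick -= q * stick;
  }
  bhat[V - 1] = stick;
}

// log marginal likelihood of one community's reads under the collapsed
// ZIGD prior: sum over non-terminal support members of
// lbeta(a + n_t, b + T_t) - lbeta(a, b), T_t the trailing count
static double gd_log_marginal(const std::vector<int> &nj,
                              const std::vector<int> &del,
                              double a, double b, int V, double lb_ab) {
  double lp = 0.0;
  long trail = 0;
  for (int t = V - 1; t >= 0; --t) {
    if (t < V - 1 && !del[t]) lp += R::lbeta(a + nj[t], b + trail) - lb_ab;
    trail += nj[t];
  }
  return lp;
}

// [[Rcpp::export]]
List zinlda_gibbs_cpp(IntegerVector doc, IntegerVector taxon, IntegerVector z0,
                      int D, int V, int K,
                      double alpha, double pi, double a, double b,
                      int n_iter, int burn_in, int thin, bool block_moves,
                      int move_reps,
                      bool store_draws, bool trace, bool check_invariants) {
  int N = doc.size();
  std::vector<int> z(z0.begin(), z0.end());
  std::vector<std::vector<int>> n(K, std::vector<int>(V, 0));
  std::vector<std::vector<int>> del(K, std::vector<int>(V, 0));
  std::vector<std::vector<int>> m(D, std::vector<int>(K, 0));
  std::vector<int> depth(D, 0);
  for (int r = 0; r < N; ++r) {
    n[z[r]][taxon[r]]++; m[doc[r]][z[r]]++; depth[doc[r]]++;
  }

  // cached posterior-mean profiles, one row per community
  std::vector<int> suffix(V);
  std::vector<std::vector<double>> bhat(K, std::vector<double>(V));
  for (int j = 0; j < K; ++j)
    zigd_beta_hat(n[j].data(), del[j].data(), a, b, V, bhat[j].data(), suffix.data());

  int n_keep = 0;
  for (int it = burn_in; it < n_iter; ++it)
    if ((it - burn_in) % thin == 0) n_keep++;

  NumericVector beta_sum(K * V), theta_sum(D * K), delta_sum(K * V);
  NumericVector beta_draws(store_draws ? n_keep * K * V : 0);
  NumericVector theta_draws(store_draws ? n_keep * D * K : 0);
  IntegerVector delta_draws(store_draws ? n_keep * K * V : 0);
  NumericVector trace_codes(trace ? (n_iter - burn_in) : 0);

  const double lb_ab = R::lbeta(a, b);
  std::vector<double> p(K), fb(V), saved(V);
  long n_fallback = 0;
  int kept = 0;

  // read indices grouped by taxon (ascending, hence doc-sorted within
  // taxon); used by the taxon-block exchange move
  std::vector<std::vector<int>> taxon_reads(V);
  for (int r = 0; r < N; ++r) taxon_reads[taxon[r]].push_back(r);
  std::vector<int> src_set(K), tgt_set(K);

  for (int it = 0; it < n_iter; ++it) {
    // --- z scan: resample every read's subcommunity assignment ---
    for (int r = 0; r < N; ++r) {
      int d = doc[r], i = taxon[r], c = z[r];
      n[c][i]--; m[d][c]--;
      // keep the pre-decrement profile row: if the read stays put the
      // post-increment state is identical and the O(V) rebuild is skipped
      std::copy(bhat[c].begin(), bhat[c].end(), saved.begin());
      zigd_beta_hat(n[c].data(), del[c].data(), a, b, V, bhat[c].data(), suffix.data());
      double tot = 0.0;
      for (int j = 0; j < K; ++j) {
        p[j] = bhat[j][i] * (m[d][j] + alpha);
        tot += p[j];
      }
      if (tot <= 0.0) {
        // taxon transiently excluded from every community: fall back to the
        // no-inflation (full-support) conditional so the chain cannot halt
        n_fallback++;
        for (int j = 0; j < K; ++j) {
          zigd_beta_hat_full(n[j].data(), a, b, V, fb.data(), suffix.data());
          p[j] = fb[i] * (m[d][j] + alpha);
          tot += p[j];
        }
      }
      int jn = sample_index(p, tot);
      z[r] = jn;
      n[jn][i]++; m[d][jn]++;
      if (jn == c) {
        std::copy(saved.begin(), saved.end(), bhat[c].begin());
      } else {
        zigd_beta_hat(n[jn].data(), del[jn].data(), a, b, V, bhat[jn].data(), suffix.data());
      }
    }

    // --- taxon-block exchange (Metropolis-Hastings): propose moving all
    // reads of one taxon held by one community to a community currently
    // holding none of them, exchanging the two cells' structural-zero
    // indicators along with the reads. The read-level scan mixes poorly
    // across the bimodal "taxon present in j" / "taxon absent from j"
    // states because an occupied cell is self-reinforcing and a switched-on
    // indicator blocks re-entry; this move jumps between the modes
    // directly. Source and empty-target are drawn uniformly and the
    // indicator swap makes the proposal an involution on cell pairs, so
    // the proposal is symmetric and the acceptance ratio is the joint
    // probability ratio (community marginals + sample factors; the
    // Bernoulli prior cancels because the indicator multiset is
    // preserved). ---
    for (int rep = 0; block_moves && K > 1 && rep < move_reps; ++rep) {
      for (int i = 0; i < V; ++i) {
        int ns = 0, nt = 0;
        for (int j = 0; j < K; ++j) {
          if (n[j][i] > 0) src_set[ns++] = j;
          else tgt_set[nt++] = j;
        }
        if (ns == 0 || nt == 0) continue;
        int is_ = (int)(unif_rand() * ns); if (is_ >= ns) is_ = ns - 1;
        int it_ = (int)(unif_rand() * nt); if (it_ >= nt) it_ = nt - 1;
        int js = src_set[is_], jt = tgt_set[it_];
        if (i == V - 1 && del[jt][i]) continue;  // terminal stick stays open
        int k = n[js][i];
        int dswap = del[jt][i];   // del[js][i] is 0 while the cell is occupied
        double logr = -gd_log_marginal(n[js], del[js], a, b, V, lb_ab)
                      - gd_log_marginal(n[jt], del[jt], a, b, V, lb_ab);
        n[js][i] = 0; n[jt][i] = k;
        del[js][i] = dswap; del[jt][i] = 0;
        logr += gd_log_marginal(n[js], del[js], a, b, V, lb_ab)
              + gd_log_marginal(n[jt], del[jt], a, b, V, lb_ab);
        n[js][i] = k; n[jt][i] = 0;
        del[js][i] = 0; del[jt][i] = dswap;
        // sample factors over the docs holding moved reads
        const std::vector<int> &tr = taxon_reads[i];
        for (size_t s = 0; s < tr.size(); ) {
          int d = doc[tr[s]];
          int kd = 0;
          size_t s2 = s;
          while (s2 < tr.size() && doc[tr[s2]] == d) {
            if (z[tr[s2]] == js) kd++;
            s2++;
          }
          if (kd > 0) {
            logr += R::lgammafn(m[d][jt] + alpha + kd)
                  - R::lgammafn(m[d][jt] + alpha)
                  + R::lgammafn(m[d][js] + alpha - kd)
                  - R::lgammafn(m[d][js] + alpha);
          }
          s = s2;
        }
        if (log(unif_rand()) < logr) {
          for (size_t s = 0; s < tr.size(); ++s) {
            int r2 = tr[s];
            if (z[r2] == js) {
              z[r2] = jt;
              m[doc[r2]][js]--; m[doc[r2]][jt]++;
            }
          }
          n[js][i] = 0; n[jt][i] = k;
          del[js][i] = dswap; del[jt][i] = 0;
          zigd_beta_hat(n[js].data(), del[js].data(), a, b, V,
                        bhat[js].data(), suffix.data());
          zigd_beta_hat(n[jt].data(), del[jt].data(), a, b, V,
                        bhat[jt].data(), suffix.data());
        }
      }
    }

    // --- pair repartition (Metropolis-Hastings): for one taxon and one
    // pair of communities, jointly re-assign every read of that taxon
    // currently held by the pair between the two sides, and resample the
    // pair's structural-zero indicators for sides left empty. The
    // proposal is an informed sequential urn over the pair's reads in
    // fixed (sample, read) order: each read picks a side with probability
    // proportional to the sample's base mixture count (Dirichlet-
    // multinomial predictive within the sample) times a rich-get-richer
    // taxon-count term. The same urn replay scores the current
    // assignment, so this is an independence-type MH step within the
    // slice; it can move a taxon's whole allocation -- including across
    // an evidence-locked indicator -- in a single accepted move, which
    // the one-read-at-a-time scan cannot do (an occupied cell is
    // self-reinforcing and a switched-on indicator blocks re-entry). ---
    if (block_moves && K > 1) {
      static thread_local std::vector<int> pr_idx, pr_doc, sideA, sideB;
      for (int rep = 0; rep < move_reps; ++rep) {
      for (int i = 0; i < V; ++i) {
        const std::vector<int> &tr = taxon_reads[i];
        if (tr.empty()) continue;
        int j1 = (int)(unif_rand() * K); if (j1 >= K) j1 = K - 1;
        int j2 = (int)(unif_rand() * (K - 1)); if (j2 >= K - 1) j2 = K - 2;
        if (j2 >= j1) j2++;
        if (n[j1][i] == 0 && n[j2][i] == 0) continue;
        int pair_[2] = {j1, j2};
        // collect the pair's reads of taxon i (already doc-sorted) and
        // per-doc base mixture counts with the pair's taxon-i reads
        // removed (state-independent)
        pr_idx.clear(); pr_doc.clear(); sideA.clear();
        for (size_t s = 0; s < tr.size(); ++s) {
          int r2 = tr[s];
          if (z[r2] == j1 || z[r2] == j2) {
            pr_idx.push_back(r2);
            pr_doc.push_back(doc[r2]);
            sideA.push_back(z[r2] == j1 ? 0 : 1);
          }
        }
        if (pr_idx.empty()) continue;
        // urn replay: log-probability of an assignment; e[2] tracks reads
        // of the current doc already assigned per side, c[2] the taxon
        // totals per side
        // informed sequential urn: each read picks a side with weight
        // (sample base count + alpha + reads of this sample already
        // placed there) times the community's sequential generalized-
        // Dirichlet predictive for one more read of this taxon,
        // (a + c) / (a + b + T0 + c) with T0 the trailing counts at later
        // taxa, times a state-independent stick-prefix factor. This is
        // the exact blockwise conditional up to the (slowly varying)
        // dependence of earlier-position trailing counts on c, so
        // proposals land close to the posterior's own responsibilities
        // and realistic partial splits are generated.
        double D0[2], F[2];
        for (int sI = 0; sI < 2; ++sI) {
          int jj = pair_[sI];
          long trail = 0;
          for (int t = i + 1; t < V; ++t) trail += n[jj][t];
          D0[sI] = a + b + trail;
          // prefix factor over earlier support members, with the pair's
          // taxon-i reads removed from their trailing counts (base state)
          double lf = 0.0;
          long trail_t = trail;   // counts after position t, base at t = i-1
          for (int t = i - 1; t >= 0; --t) {
            if (t + 1 != i) trail_t += n[jj][t + 1];
            if (!del[jj][t]) {
              lf += std::log((b + trail_t) / (a + n[jj][t] + b + trail_t));
            }
          }
          F[sI] = std::exp(lf);
        }
        auto urn_logq = [&](const std::vector<int> &sides, bool sample,
                            std::vector<int> *out) {
          // probability ratios are accumulated multiplicatively and
          // folded into the log only near underflow: log() per read would
          // dominate the whole sweep
          double lq = 0.0, acc = 1.0;
          int c[2] = {0, 0};
          int e[2] = {0, 0};
          int cur_doc = -1;
          int mbase[2] = {0, 0};
          for (size_t s = 0; s < pr_idx.size(); ++s) {
            int d = pr_doc[s];
            if (d != cur_doc) {
              cur_doc = d; e[0] = e[1] = 0;
              // base mixture counts: remove this doc's pair-i reads
              int k1 = 0, k2 = 0;
              for (size_t s2 = s; s2 < pr_idx.size() && pr_doc[s2] == d;
                   ++s2) {
                if (sideA[s2] == 0) k1++; else k2++;
              }
              mbase[0] = m[d][j1] - k1;
              mbase[1] = m[d][j2] - k2;
            }
            double w[2];
            for (int sI = 0; sI < 2; ++sI)
              w[sI] = (mbase[sI] + alpha + e[sI]) * F[sI] *
                      (a + c[sI]) / (D0[sI] + c[sI]);
            int ch;
            if (sample) {
              ch = (unif_rand() * (w[0] + w[1]) < w[0]) ? 0 : 1;
              out->push_back(ch);
            } else {
              ch = sides[s];
            }
            acc *= w[ch] / (w[0] + w[1]);
            if (acc < 1e-280) { lq += std::log(acc); acc = 1.0; }
            e[ch]++; c[ch]++;
          }
          return lq + std::log(acc);
        };
        sideB.clear();
        double logq_B = urn_logq(sideB, true, &sideB);
        double logq_A = urn_logq(sideA, false, nullptr);
        int tA[2] = {0, 0}, tB[2] = {0, 0};
        for (size_t s = 0; s < pr_idx.size(); ++s) {
          tA[sideA[s]]++; tB[sideB[s]]++;
        }
        // indicator handling for sides empty in a state (positions before
        // the terminal stick); the collapsed conditional phi depends only
        // on counts at later taxa, which the move does not touch
        int dA[2] = {del[j1][i], del[j2][i]}, dB[2] = {0, 0};
        if (i < V - 1) {
          for (int sI = 0; sI < 2; ++sI) {
            if (tA[sI] > 0 && tB[sI] > 0) continue;
            long trail = 0;
            for (int t = i + 1; t < V; ++t) trail += n[pair_[sI]][t];
            double phi = pi / (pi + (1.0 - pi) *
                               std::exp(R::lbeta(a, b + trail) - lb_ab));
            if (tB[sI] == 0) {
              int dd = (unif_rand() < phi) ? 1 : 0;
              dB[sI] = dd;
              logq_B += std::log(dd ? phi : 1.0 - phi);
            }
            if (tA[sI] == 0) {
              logq_A += std::log(dA[sI] ? phi : 1.0 - phi);
            }
          }
        }
        // joint ratio pi(B)/pi(A): community marginals, indicator prior,
        // per-sample mixture factors
        double logr = 0.0;
        logr -= gd_log_marginal(n[j1], del[j1], a, b, V, lb_ab)
              + gd_log_marginal(n[j2], del[j2], a, b, V, lb_ab);
        n[j1][i] = tB[0]; n[j2][i] = tB[1];
        del[j1][i] = dB[0]; del[j2][i] = dB[1];
        logr += gd_log_marginal(n[j1], del[j1], a, b, V, lb_ab)
              + gd_log_marginal(n[j2], del[j2], a, b, V, lb_ab);
        n[j1][i] = tA[0]; n[j2][i] = tA[1];
        del[j1][i] = dA[0]; del[j2][i] = dA[1];
        if (pi > 0 && pi < 1) {
          logr += (dB[0] + dB[1] - dA[0] - dA[1]) *
                  (std::log(pi) - std::log(1.0 - pi));
        } else if (pi <= 0 && (dB[0] || dB[1])) {
          logr = R_NegInf;
        }
        // per-doc mixture-count changes
        {
          size_t s = 0;
          while (s < pr_idx.size()) {
            int d = pr_doc[s];
            int shift = 0;   // net reads moving to side j1 in this doc
            while (s < pr_idx.size() && pr_doc[s] == d) {
              shift += (sideB[s] == 0) - (sideA[s] == 0);
              s++;
            }
            if (shift != 0) {
              logr += R::lgammafn(m[d][j1] + alpha + shift)
                    - R::lgammafn(m[d][j1] + alpha)
                    + R::lgammafn(m[d][j2] + alpha - shift)
                    - R::lgammafn(m[d][j2] + alpha);
            }
          }
        }
        logr += logq_A - logq_B;
        if (log(unif_rand()) < logr) {
          for (size_t s = 0; s < pr_idx.size(); ++s) {
            if (sideA[s] == sideB[s]) continue;
            int r2 = pr_idx[s];
            int gain = pair_[sideB[s]], lose = pair_[sideA[s]];
            z[r2] = gain;
            m[doc[r2]][lose]--; m[doc[r2]][gain]++;
          }
          n[j1][i] = tB[0]; n[j2][i] = tB[1];
          del[j1][i] = dB[0]; del[j2][i] = dB[1];
          zigd_beta_hat(n[j1].data(), del[j1].data(), a, b, V,
                        bhat[j1].data(), suffix.data());
          zigd_beta_hat(n[j2].data(), del[j2].data(), a, b, V,
                        bhat[j2].data(), suffix.data());
        }
      }
      }
    }

    // --- delta scan: resample structural-zero indicators (positions
    // 1..V-1; the last stick position is never inflated). Given z the
    // indicators are conditionally independent; fixed (j, ascending i)
    // order keeps runs reproducible. ---
    for (int j = 0; j < K; ++j) {
      long trail = 0;
      std::vector<long> trailing(V, 0);
      for (int i = V - 1; i >= 0; --i) { trailing[i] = trail; trail += n[j][i]; }
      for (int i = 0; i < V - 1; ++i) {
        if (n[j][i] > 0) { del[j][i] = 0; continue; }
        if (pi <= 0.0) { del[j][i] = 0; continue; }
        double lratio = R::lbeta(a, b + trailing[i]) - lb_ab;
        double p1 = pi / (pi + (1.0 - pi) * std::exp(lratio));
        del[j][i] = (unif_rand() < p1) ? 1 : 0;
      }
      zigd_beta_hat(n[j].data(), del[j].data(), a, b, V, bhat[j].data(), suffix.data());
    }

    if (check_invariants) {
      for (int j = 0; j < K; ++j) {
        long s = 0, sm = 0;
        for (int i = 0; i < V; ++i) {
          s += n[j][i];
          if (del[j][i] && n[j][i] > 0)
            stop("zinLDA sampler: read assigned to a structural zero");
        }
        for (int d = 0; d < D; ++d) sm += m[d][j];
        if (s != sm) stop("zinLDA sampler: count bookkeeping violated");
      }
      for (int d = 0; d < D; ++d) {
        long s = 0; for (int j = 0; j < K; ++j) s += m[d][j];
        if (s != depth[d]) stop("zinLDA sampler: sample depth violated");
      }
    }

    if (it >= burn_in) {
      if (trace) {
        double code = z_code(z, K), mult = 1.0;
        for (size_t r = 0; r < z.size(); ++r) mult *= K;
        double dcode = 0.0, dm = 1.0;
        for (int j = 0; j < K; ++j)
          for (int i = 0; i < V - 1; ++i) { dcode += del[j][i] * dm; dm *= 2; }
        trace_codes[it - burn_in] = code + mult * dcode;
      }
      if ((it - burn_in) % thin == 0) {
        for (int j = 0; j < K; ++j)
          for (int i = 0; i < V; ++i) {
            beta_sum[j + K * i] += bhat[j][i];
            delta_sum[j + K * i] += del[j][i];
            if (store_draws) {
              beta_draws[j + K * i + K * V * kept] = bhat[j][i];
              delta_draws[j + K * i + K * V * kept] = del[j][i];
            }
          }
        for (int d = 0; d < D; ++d)
          for (int j = 0; j < K; ++j) {
            double t = (m[d][j] + alpha) / (depth[d] + K * alpha);
            theta_sum[d + D * j] += t;
            if (store_draws) theta_draws[d + D * j + D * K * kept] = t;
          }
        kept++;
      }
    }
  }

  NumericMatrix beta_mean(K, V), theta_hat(D, K), pi_hat(K, V);
  IntegerMatrix delta_final(K, V);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < V; ++i) {
      beta_mean(j, i) = beta_sum[j + K * i] / kept;
      pi_hat(j, i) = delta_sum[j + K * i] / kept;
      delta_final(j, i) = del[j][i];
    }
  for (int d = 0; d < D; ++d)
    for (int j = 0; j < K; ++j) theta_hat(d, j) = theta_sum[d + D * j] / kept;

  List out = List::create(
    _["beta_mean"] = beta_mean, _["theta"] = theta_hat, _["pi_hat"] = pi_hat,
    _["delta_final"] = delta_final,
    _["z"] = IntegerVector(z.begin(), z.end()),
    _["n_kept"] = kept, _["n_fallback"] = (double)n_fallback);
  if (store_draws) {
    beta_draws.attr("dim") = IntegerVector::create(K, V, n_keep);
    theta_draws.attr("dim") = IntegerVector::create(D, K, n_keep);
    delta_draws.attr("dim") = IntegerVector::create(K, V, n_keep);
    out["beta_draws"] = beta_draws;
    out["theta_draws"] = theta_draws;
    out["delta_draws"] = delta_draws;
  }
  if (trace) out["trace"] = trace_codes;
  return out;
}
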