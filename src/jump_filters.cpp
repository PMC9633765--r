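#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Forward filtering for the change-point frequency learner on a 1-D grid.
// Each trial: mix the posterior with the flat prior (jump step), multiply
// by the Bernoulli likelihood of the observed stimulus, renormalise; the
// prediction for the next trial integrates theta against the jump-mixed
// posterior. KL is between successive filtering posteriors.
// [[Rcpp::export]]
List jump_frequency_filter(LogicalVector h, double p_jump, int resolution,
                           bool compute_stats) {
  const int n = h.size();
  const int k = resolution;
  const double flat = 1.0 / k;
  std::vector<double> theta(k), post(k, flat), newpost(k);
  for (int i = 0; i < k; ++i) theta[i] = (i + 0.5) / k;

  NumericVector pred(n), pmean(n), psd(n), kl(n);
  bool underflow = false;
  for (int t = 0; t < n; ++t) {
    double tot = 0.0;
    const bool high = h[t];
    for (int i = 0; i < k; ++i) {
      const double mixed = (1.0 - p_jump) * post[i] + p_jump * flat;
      const double lik = high ? theta[i] : 1.0 - theta[i];
      newpost[i] = mixed * lik;
      tot += newpost[i];
    }
    if (tot <= 0.0 || !std::isfinite(tot)) {
      underflow = true;
      std::fill(newpost.begin(), newpost.end(), flat);
      tot = 1.0;
    }
    double pr = 0.0, m = 0.0, m2 = 0.0, klv = 0.0;
    for (int i = 0; i < k; ++i) {
      const double np = newpost[i] / tot;
      newpost[i] = np;
      pr += ((1.0 - p_jump) * np + p_jump * flat) * theta[i];
      m += np * theta[i];
      if (compute_stats) {
        m2 += np * theta[i] * theta[i];
        if (t > 0 && np > 0.0) {
          klv += np * (std::log(std::max(np, 1e-300)) -
                       std::log(std::max(post[i], 1e-300)));
        }
      }
    }
    pred[t] = pr;
    pmean[t] = m;
    if (compute_stats) {
      psd[t] = std::sqrt(std::max(m2 - m * m, 0.0));
      kl[t] = (t > 0) ? klv : 0.0;
    }
    std::swap(post, newpost);
  }
  return List::create(_["pred"] = pred, _["mean"] = pmean, _["sd"] = psd,
                      _["kl"] = kl, _["underflow"] = underflow);
}

// Forward filtering for the change-point transition learner on the joint
// 2-D grid over (theta_{H|L}, theta_{L|H}). A jump resamples both
// probabilities together, so the joint posterior is filtered as a whole.
// The first trial carries no transition evidence (no predecessor).
// [[Rcpp::export]]
List jump_transition_filter(LogicalVector h, double p_jump, int resolution,
                            bool compute_stats) {
  const int n = h.size();
  const int k = resolution;
  const int kk = k * k;
  const double flat = 1.0 / kk;
  std::vector<double> theta(k), post(kk, flat), newpost(kk), marg(k);
  for (int i = 0; i < k; ++i) theta[i] = (i + 0.5) / k;

  NumericVector pred(n), pmean(n), psd(n), kl(n);
  bool underflow = false;
  for (int t = 0; t < n; ++t) {
    const bool cur = h[t];
    const double stay = 1.0 - p_jump;
    const double inject = p_jump * flat;
    double tot = 0.0;
    if (t == 0) {
      for (int idx = 0; idx < kk; ++idx) {
        newpost[idx] = stay * post[idx] + inject;
        tot += newpost[idx];
      }
    } else {
      const bool prev = h[t - 1];
      // index idx = i + j*k: i runs over theta_{H|L}, j over theta_{L|H};
      // the likelihood touches only the axis conditioned on prev
      if (!prev) {
        for (int j = 0; j < k; ++j) {
          const int off = j * k;
          for (int i = 0; i < k; ++i) {
            const double lik = cur ? theta[i] : 1.0 - theta[i];
            newpost[off + i] = (stay * post[off + i] + inject) * lik;
            tot += newpost[off + i];
          }
        }
      } else {
        for (int j = 0; j < k; ++j) {
          const double lik = cur ? 1.0 - theta[j] : theta[j];
          const int off = j * k;
          for (int i = 0; i < k; ++i) {
            newpost[off + i] = (stay * post[off + i] + inject) * lik;
            tot += newpost[off + i];
          }
        }
      }
    }
    if (tot <= 0.0 || !std::isfinite(tot)) {
      underflow = true;
      std::fill(newpost.begin(), newpost.end(), flat);
      tot = 1.0;
    }
    const double inv_tot = 1.0 / tot;
    double klv = 0.0;
    std::fill(marg.begin(), marg.end(), 0.0);
    if (compute_stats && t > 0) {
      for (int j = 0; j < k; ++j) {
        const int off = j * k;
        double mj = 0.0;
        for (int i = 0; i < k; ++i) {
          const double np = newpost[off + i] * inv_tot;
          newpost[off + i] = np;
          if (cur) mj += np; else marg[i] += np;
          if (np > 0.0) {
            klv += np * (std::log(std::max(np, 1e-300)) -
                         std::log(std::max(post[off + i], 1e-300)));
          }
        }
        if (cur) marg[j] = mj;
      }
    } else {
      for (int j = 0; j < k; ++j) {
        const int off = j * k;
        double mj = 0.0;
        for (int i = 0; i < k; ++i) {
          const double np = newpost[off + i] * inv_tot;
          newpost[off + i] = np;
          if (cur) mj += np; else marg[i] += np;
        }
        if (cur) marg[j] = mj;
      }
    }
    // predictive for t+1 through the jump-mixed posterior, using the
    // conditional component selected by the current stimulus
    double pr = 0.0, m = 0.0, m2 = 0.0;
    for (int a = 0; a < k; ++a) {
      const double mm = (1.0 - p_jump) * marg[a] + p_jump * (1.0 / k);
      const double th = cur ? 1.0 - theta[a] : theta[a];
      pr += mm * th;
      m += marg[a] * th;
      m2 += marg[a] * th * th;
    }
    pred[t] = pr;
    pmean[t] = m;
    if (compute_stats) {
      psd[t] = std::sqrt(std::max(m2 - m * m, 0.0));
      kl[t] = (t > 0) ? klv : 0.0;
    }
    std::swap(post, newpost);
  }
  return List::create(_["pred"] = pred, _["mean"] = pmean, _["sd"] = psd,
                      _["kl"] = kl, _["underflow"] = underflow);
}
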