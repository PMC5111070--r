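#include <Rcpp.h>
using namespace Rcpp;

// Bayesian SECR with data augmentation (Bernoulli encounter model).
//
// Model: z_i ~ Bern(psi); activity centers s_i uniform over the state
// space (optionally restricted to habitat cells); y_ij ~ Binomial(K, z_i *
// p_ij) with p_ij = p0 * exp(-d_ij^2 / (2 sigma^2)). Flat priors:
// p0, psi ~ U(0,1), sigma ~ U(0, sigma_max). Metropolis-within-Gibbs:
// random-walk MH for p0, sigma and the centers of real individuals; Gibbs
// for z (undetected individuals) and psi. NSuper = sum(z).

static inline bool in_habitat(double x, double y,
                              const IntegerMatrix &hab,
                              double hxmin, double hymin, double hcell,
                              double xmin, double xmax,
                              double ymin, double ymax) {
  if (x < xmin || x > xmax || y < ymin || y > ymax) return false;
  if (hab.nrow() == 0) return true;
  int nr = hab.nrow(), nc = hab.ncol();
  int col = (int)std::floor((x - hxmin) / hcell);
  int row = nr - 1 - (int)std::floor((y - hymin) / hcell);
  if (col < 0 || col >= nc || row < 0 || row >= nr) return false;
  return hab(row, col) > 0;
}

// log-likelihood of individual i's counts given center (sx, sy)
static inline double ll_ind(const IntegerMatrix &y, int i, double sx,
                            double sy, const NumericVector &tx,
                            const NumericVector &ty, int K, double p0,
                            double inv2s2) {
  double ll = 0.0;
  int J = tx.size();
  for (int j = 0; j < J; j++) {
    double dx = sx - tx[j], dy = sy - ty[j];
    double p = p0 * std::exp(-(dx * dx + dy * dy) * inv2s2);
    int yij = y(i, j);
    if (yij > 0) ll += yij * std::log(p);
    if (yij < K) ll += (K - yij) * std::log1p(-p);
  }
  return ll;
}

// log Pr(all-zero history | center) -- used for the z update
static inline double ll_zero(double sx, double sy, const NumericVector &tx,
                             const NumericVector &ty, int K, double p0,
                             double inv2s2) {
  double ll = 0.0;
  int J = tx.size();
  for (int j = 0; j < J; j++) {
    double dx = sx - tx[j], dy = sy - ty[j];
    double p = p0 * std::exp(-(dx * dx + dy * dy) * inv2s2);
    ll += K * std::log1p(-p);
  }
  return ll;
}

// [[Rcpp::export]]
List secr_mcmc_cpp(IntegerMatrix y, int n_obs, int K,
                   NumericVector trap_x, NumericVector trap_y,
                   double xmin, double xmax, double ymin, double ymax,
                   IntegerMatrix habitat, double hxmin, double hymin,
                   double hcell,
                   int n_iter, int n_burn, int thin,
                   double p0_tune, double sigma_tune, double s_tune,
                   double sigma_max,
                   double p0_init, double sigma_init) {
  RNGScope scope;
  int M = y.nrow(), J = trap_x.size();
  NumericVector sx(M), sy(M);
  IntegerVector z(M);
  // init: detected individuals at their mean capture location, z = 1;
  // augmented individuals uniform in the (masked) state space, z ~ Bern(.5)
  for (int i = 0; i < M; i++) {
    if (i < n_obs) {
      double wx = 0, wy = 0, w = 0;
      for (int j = 0; j < J; j++) {
        wx += y(i, j) * trap_x[j];
        wy += y(i, j) * trap_y[j];
        w += y(i, j);
      }
      sx[i] = wx / w; sy[i] = wy / w;
      if (!in_habitat(sx[i], sy[i], habitat, hxmin, hymin, hcell,
                      xmin, xmax, ymin, ymax)) {
        // nudge to a habitat cell if the centroid fell off the mask
        for (int tries = 0; tries < 1000; tries++) {
          double px = R::runif(xmin, xmax), py = R::runif(ymin, ymax);
          if (in_habitat(px, py, habitat, hxmin, hymin, hcell,
                         xmin, xmax, ymin, ymax)) {
            sx[i] = px; sy[i] = py; break;
          }
        }
      }
      z[i] = 1;
    } else {
      for (int tries = 0; tries < 10000; tries++) {
        double px = R::runif(xmin, xmax), py = R::runif(ymin, ymax);
        if (in_habitat(px, py, habitat, hxmin, hymin, hcell,
                       xmin, xmax, ymin, ymax)) {
          sx[i] = px; sy[i] = py; break;
        }
      }
      z[i] = (R::unif_rand() < 0.5) ? 1 : 0;
    }
  }
  double p0 = p0_init, sigma = sigma_init, psi = 0.5;

  int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out(n_keep, 4);  // p0, sigma, psi, NSuper
  colnames(out) = CharacterVector::create("p0", "sigma", "psi", "NSuper");
  int keep = 0;
  double acc_p0 = 0, acc_sigma = 0, acc_s = 0, try_s = 0;

  for (int iter = 0; iter < n_iter; iter++) {
    double inv2s2 = 1.0 / (2.0 * sigma * sigma);

    // --- p0 update (MH over all real individuals) ---
    double p0p = p0 + R::norm_rand() * p0_tune;
    if (p0p > 0 && p0p < 1) {
      double d = 0;
      for (int i = 0; i < M; i++) {
        if (!z[i]) continue;
        d += ll_ind(y, i, sx[i], sy[i], trap_x, trap_y, K, p0p, inv2s2) -
             ll_ind(y, i, sx[i], sy[i], trap_x, trap_y, K, p0, inv2s2);
      }
      if (std::log(R::unif_rand()) < d) { p0 = p0p; acc_p0++; }
    }

    // --- sigma update ---
    double sp = sigma + R::norm_rand() * sigma_tune;
    if (sp > 0 && sp < sigma_max) {
      double inv2s2p = 1.0 / (2.0 * sp * sp);
      double d = 0;
      for (int i = 0; i < M; i++) {
        if (!z[i]) continue;
        d += ll_ind(y, i, sx[i], sy[i], trap_x, trap_y, K, p0, inv2s2p) -
             ll_ind(y, i, sx[i], sy[i], trap_x, trap_y, K, p0, inv2s2);
      }
      if (std::log(R::unif_rand()) < d) { sigma = sp; acc_sigma++; }
    }
    inv2s2 = 1.0 / (2.0 * sigma * sigma);

    // --- activity centers ---
    for (int i = 0; i < M; i++) {
      if (!z[i] && i >= n_obs) {
        // flat likelihood: Gibbs draw from the uniform prior
        for (int tries = 0; tries < 100; tries++) {
          double px = R::runif(xmin, xmax), py = R::runif(ymin, ymax);
          if (in_habitat(px, py, habitat, hxmin, hymin, hcell,
                         xmin, xmax, ymin, ymax)) {
            sx[i] = px; sy[i] = py; break;
          }
        }
        continue;
      }
      double px = sx[i] + R::norm_rand() * s_tune;
      double py = sy[i] + R::norm_rand() * s_tune;
      try_s++;
      if (!in_habitat(px, py, habitat, hxmin, hymin, hcell,
                      xmin, xmax, ymin, ymax)) continue;
      double d = ll_ind(y, i, px, py, trap_x, trap_y, K, p0, inv2s2) -
                 ll_ind(y, i, sx[i], sy[i], trap_x, trap_y, K, p0, inv2s2);
      if (std::log(R::unif_rand()) < d) {
        sx[i] = px; sy[i] = py; acc_s++;
      }
    }

    // --- z (augmented, undetected individuals only) ---
    for (int i = n_obs; i < M; i++) {
      double lq = ll_zero(sx[i], sy[i], trap_x, trap_y, K, p0, inv2s2);
      double q = std::exp(lq);
      double pz = psi * q / (psi * q + (1.0 - psi));
      z[i] = (R::unif_rand() < pz) ? 1 : 0;
    }

    // --- psi (Gibbs, Beta(1 + sum z, 1 + M - sum z)) ---
    int nz = 0;
    for (int i = 0; i < M; i++) nz += z[i];
    psi = R::rbeta(1.0 + nz, 1.0 + M - nz);

    if (iter >= n_burn && (iter - n_burn) % thin == 0 && keep < n_keep) {
      out(keep, 0) = p0;
      out(keep, 1) = sigma;
      out(keep, 2) = psi;
      out(keep, 3) = nz;
      keep++;
    }
  }

  return List::create(
    _["samples"] = out,
    _["accept"] = NumericVector::create(
        _["p0"] = acc_p0 / n_iter, _["sigma"] = acc_sigma / n_iter,
        _["s"] = try_s > 0 ? acc_s / try_s : NA_REAL));
}
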