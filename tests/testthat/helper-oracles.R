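# Independent numeric oracles used across the suite.

# Bivariate normal CDF by direct numerical integration of
# Phi2(h,k,rho) = Phi(h)Phi(k) + int_0^rho phi2(h,k;t) dt.
phi2_oracle <- function(h, k, rho) {
  if (rho == 0) return(pnorm(h) * pnorm(k))
  dens <- function(t) {
    exp(-(h^2 - 2 * t * h * k + k^2) / (2 * (1 - t^2))) /
      (2 * pi * sqrt(1 - t^2))
  }
  pnorm(h) * pnorm(k) +
    integrate(Vectorize(dens), 0, rho, rel.tol = 1e-12)$value
}

# Exact cell probabilities of a discretized bivariate normal, via the oracle.
bvn_cell_probs <- function(tau1, tau2, rho) {
  b1 <- c(-Inf, tau1, Inf); b2 <- c(-Inf, tau2, Inf)
  k1 <- length(b1); k2 <- length(b2)
  cdf <- outer(b1, b2, Vectorize(function(a, b) {
    if (is.infinite(a) && a < 0) return(0)
    if (is.infinite(b) && b < 0) return(0)
    if (is.infinite(a)) return(pnorm(b))
    if (is.infinite(b)) return(pnorm(a))
    phi2_oracle(a, b, rho)
  }))
  cdf[-1, -1] - cdf[-k1, -1] - cdf[-1, -k2] + cdf[-k1, -k2]
}

# A quick easy-to-fit simulated panel used by several tests.
easy_panel <- function(n = 2000, seed = 421, ...) {
  args <- list(n_subjects = n, seed = seed, rel_sim_t1 = 0.8,
               rel_trs = 0.7, prop_improved = 0.5, psb = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  simulate_dataset(do.call(sim_config, args))
}
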