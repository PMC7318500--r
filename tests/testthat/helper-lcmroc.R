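# shared fixtures and small oracles for the test suite

# canonical well-separated single-marker world (overlap ~ 0.13)
strong_params <- function() single_marker_params(0.3, 3, 0, 1, 1)

# the spec'd moderately separated world (overlap ~ 0.32)
canonical_params <- function() single_marker_params(0.3, 2, 0, 1, 1)

fast_mcmc <- function(seed = 1L, n_iter = 2000L, n_burnin = 800L,
                      n_chains = 1L) {
  mcmc_settings(n_chains, n_iter, n_burnin, 1L, seed = seed)
}

# brute-force Youden maximizer on a fine grid (independent of the
# quadratic solution used by youden_cutoff)
grid_youden <- function(p, n = 10001L) {
  cc <- seq(min(p$mu_d, p$mu_nd) - 6 * sqrt(max(p$var_d, p$var_nd)),
            max(p$mu_d, p$mu_nd) + 6 * sqrt(max(p$var_d, p$var_nd)),
            length.out = n)
  ss <- se_sp_at_cutoff(p, cc)
  cc[which.max(ss$sensitivity + ss$specificity)]
}

# numeric-integration oracle for the overlap coefficient
integrate_overlap <- function(p) {
  stats::integrate(function(x) {
    pmin(stats::dnorm(x, p$mu_d, sqrt(p$var_d)),
         stats::dnorm(x, p$mu_nd, sqrt(p$var_nd)))
  }, -Inf, Inf, rel.tol = 1e-9)$value
}

# random PD covariance matrix
random_pd <- function(k) {
  a <- matrix(stats::rnorm(k * k), k)
  crossprod(a) + diag(k) * 0.5
}

expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
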