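test_that("prevalence evaluates the logistic link safely", {
  expect_equal(prevalence(c(0, 0, 0), c(1, 30, 25)), 0.5)
  # independent evaluation: exp(0.45)/(1+exp(0.45))
  expect_close(prevalence(c(0.1, 0.02, -0.01), c(1, 30, 25)),
               exp(0.45) / (1 + exp(0.45)), 1e-12)
  expect_equal(prevalence(c(-1e4, 0), c(1, 5)), 0)
  expect_equal(prevalence(c(1e4, 0), c(1, 5)), 1)
  expect_error(prevalence(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("conditional_means applies the disease interactions", {
  expect_equal(conditional_means(matrix(0, 2, 6), c(30, 25), 1), c(0, 0))
  expect_equal(conditional_means(c(1, 0.1, 0, 1, 0, 0), c(30, 25), 1), 5)
  # d = 0 zeroes all disease terms regardless of their coefficients
  b <- matrix(c(1, 0.1, 0.2, 99, 99, 99), 1)
  expect_equal(conditional_means(b, c(2, 3), 0), 1 + 0.2 + 0.6)
  expect_error(conditional_means(b, c(2, 3), 2), "0 or 1")
})

test_that("the joint sampler recovers a K=2 generating model", {
  # well-identified world: standardized disease shifts of 2.5 per marker
  beta <- rbind(m1 = c(0.2, 0.01, 0, 1.25, 0, 0),
                m2 = c(1.5, 0, -0.01, -1.1, 0, 0))
  cfg <- cohort_config(n = 800, alpha = c(qlogis(0.3), 0, 0), beta = beta,
                       sigma0 = diag(c(0.25, 0.2)),
                       sigma1 = diag(c(0.3, 0.25)), seed = 25)
  co <- generate_cohort(cfg)
  fit <- fit_mvn_lcm(co, c("m1", "m2"), c("age", "bmi"),
                     mcmc = fast_mcmc(seed = 6, n_iter = 2500,
                                      n_burnin = 1000),
                     anchor = "m1", anchor_sign = 1)
  m <- draws_matrix(fit)
  truth <- c(alpha_0 = qlogis(0.3), alpha_age = 0, alpha_bmi = 0,
             beta_m1_intercept = 0.2, beta_m1_age = 0.01, beta_m1_bmi = 0,
             beta_m1_d = 1.25, beta_m1_d_age = 0, beta_m1_d_bmi = 0,
             beta_m2_intercept = 1.5, beta_m2_age = 0, beta_m2_bmi = -0.01,
             beta_m2_d = -1.1, beta_m2_d_age = 0, beta_m2_d_bmi = 0,
             `sigma0[1,1]` = 0.25, `sigma0[2,2]` = 0.2,
             `sigma1[1,1]` = 0.3, `sigma1[2,2]` = 0.25)
  for (p in names(truth)) {
    z <- abs(mean(m[, p]) - truth[[p]]) / sd(m[, p])
    expect_lt(z, 3)
  }
  # null covariate coefficients: CrIs cover zero
  for (p in c("alpha_age", "alpha_bmi")) {
    q <- quantile(m[, p], c(0.025, 0.975))
    expect_true(q[1] <= 0 && 0 <= q[2])
  }
  # per-subject probabilities behave like probabilities
  expect_true(all(fit$p_disease >= 0 & fit$p_disease <= 1))
  expect_lt(abs(mean(fit$p_disease) - mean(co$true_d)), 0.1)
  # Metropolis acceptance lands in the healthy band after adaptation
  expect_true(all(fit$meta$alpha_accept >= 0.15 &
                    fit$meta$alpha_accept <= 0.5))
})

test_that("anchor constraint holds in every retained draw", {
  co <- generate_cohort(cohort_config(n = 300, seed = 22))
  fit <- fit_mvn_lcm(co, c("uE3", "bhCG", "AFP"), c("age", "bmi"),
                     mcmc = fast_mcmc(seed = 7, n_iter = 1200,
                                      n_burnin = 500),
                     anchor = "bhCG", anchor_sign = 1)
  m <- draws_matrix(fit)
  ctr <- fit$meta$centers
  effect <- m[, "beta_bhCG_d"] + m[, "beta_bhCG_d_age"] * ctr["age"] +
    m[, "beta_bhCG_d_bmi"] * ctr["bmi"]
  expect_true(all(effect >= 0))
  # every retained covariance draw is positive definite
  for (i in seq(1, nrow(m), by = 37)) {
    for (cl in 0:1) {
      s <- lcmroc:::sigma_from_draw(m[i, ], fit$meta$markers, cl)
      expect_true(all(eigen(s, symmetric = TRUE,
                            only.values = TRUE)$values > 0))
    }
  }
})

test_that("clamped labels reproduce the per-group least-squares fit", {
  co <- generate_cohort(cohort_config(n = 400, seed = 23))
  fit <- fit_mvn_lcm(co, c("uE3", "bhCG"), c("age", "bmi"),
                     mcmc = fast_mcmc(seed = 8, n_iter = 1500,
                                      n_burnin = 600),
                     fix_d = co$true_d)
  m <- draws_matrix(fit)
  z <- cbind(1, co$age, co$bmi, co$true_d, co$true_d * co$age,
             co$true_d * co$bmi)
  terms <- c("intercept", "age", "bmi", "d", "d_age", "d_bmi")
  for (mk in c("uE3", "bhCG")) {
    ols <- qr.solve(z, co[[mk]])
    for (j in seq_along(terms)) {
      col <- paste0("beta_", mk, "_", terms[j])
      mce <- mc_error_batch(m[, col])
      # 3 MC-error units, plus a small absolute floor for the prior pull
      expect_lt(abs(mean(m[, col]) - ols[j]), 3 * mce + 0.02)
    }
  }
})

test_that("K=1 without covariates agrees with the single-marker model", {
  sim <- generate_single_marker(600, strong_params(), seed = 24)
  co <- data.frame(subject_id = seq_along(sim$values), y = sim$values)
  # matched priors: Wishart_1(3, g) on the precision equals
  # Gamma(3/2, 1/(2g)); choose g = 1 so rate = 1/2
  mv <- fit_mvn_lcm(co, "y", character(0),
                    priors = mvn_priors(1, wishart_df = 3,
                                        wishart_scale = matrix(1, 1, 1)),
                    mcmc = fast_mcmc(seed = 9, n_iter = 3000,
                                     n_burnin = 1200))
  sm <- fit_single_marker_lcm(
    sim$values,
    priors = single_marker_priors(prec_shape = 1.5, prec_rate = 0.5),
    mcmc = fast_mcmc(seed = 9, n_iter = 3000, n_burnin = 1200))
  mm <- draws_matrix(mv); ms <- draws_matrix(sm)
  # class means: mu_nd = intercept, mu_d = intercept + d effect
  mu_d_mv <- mm[, "beta_y_intercept"] + mm[, "beta_y_d"]
  agree <- function(a, b) {
    tol <- 3 * (mc_error_batch(a) + mc_error_batch(b))
    expect_lt(abs(mean(a) - mean(b)), tol + 0.02)
  }
  agree(mu_d_mv, ms[, "mu_d"])
  agree(mm[, "beta_y_intercept"], ms[, "mu_nd"])
  agree(mm[, "sigma1[1,1]"], ms[, "var_d"])
  agree(mm[, "sigma0[1,1]"], ms[, "var_nd"])
  # prevalence: compare the implied pi at the (empty) covariate vector
  pi_mv <- plogis(mm[, "alpha_0"])
  agree(pi_mv, ms[, "pi"])
})

test_that("joint fit validates its inputs", {
  co <- generate_cohort(cohort_config(n = 60, seed = 25))
  expect_error(fit_mvn_lcm(co[1:20, ], c("uE3"), c("age", "bmi")),
               "at least 50")
  expect_error(fit_mvn_lcm(co, c("uE3", "nope")), "not in cohort")
  co$flat <- 1
  expect_error(fit_mvn_lcm(co, c("flat")), "constant marker")
})
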