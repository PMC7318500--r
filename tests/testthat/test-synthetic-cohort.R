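test_that("generate_cohort reproduces the stated covariate marginals", {
  co <- generate_cohort(cohort_config(n = 523, seed = 1))
  expect_equal(nrow(co), 523)
  # sample age mean within 3 SE of the target (truncation shifts it < 1 SE)
  expect_lt(abs(mean(co$age) - 28.76), 3 * 5.33 / sqrt(523))
  expect_true(all(co$age >= 20 & co$age <= 40))
  expect_lt(abs(mean(co$bmi) - 24.57), 3 * 3.22 / sqrt(523))
  expect_true(all(is.finite(as.matrix(co[, c("uE3", "bhCG", "AFP")]))))
  expect_true(all(co$true_d %in% 0:1))
})

test_that("marker marginals track the configured mixture moments", {
  cfg <- cohort_config(n = 4000, seed = 2)
  co <- generate_cohort(cfg)
  # analytic mixture mean per subject, averaged over the drawn covariates
  z0 <- cbind(1, co$age, co$bmi, 0, 0, 0)
  z1 <- cbind(1, co$age, co$bmi, 1, co$age, co$bmi)
  pi_i <- plogis(cfg$alpha[1] + cfg$alpha[2] * co$age +
                   cfg$alpha[3] * co$bmi)
  for (j in seq_len(nrow(cfg$beta))) {
    m <- rownames(cfg$beta)[j]
    mu_mix <- mean((1 - pi_i) * (z0 %*% cfg$beta[j, ]) +
                     pi_i * (z1 %*% cfg$beta[j, ]))
    se <- sd(co[[m]]) / sqrt(nrow(co))
    expect_lt(abs(mean(co[[m]]) - mu_mix), 4 * se)
  }
  # default world approximates the study's printed marker moments
  expect_close(colMeans(co[, c("uE3", "bhCG", "AFP")]),
               c(1.06, 1.17, 1.11), 0.06)
})

test_that("disease prevalence follows the logistic model", {
  # saturated logistic: no one diseased
  co0 <- generate_cohort(cohort_config(n = 200, alpha = c(-20, 0, 0),
                                       seed = 3))
  expect_true(all(co0$true_d == 0))
  # constant pi = 0.30
  co3 <- generate_cohort(cohort_config(n = 2000,
                                       alpha = c(qlogis(0.3), 0, 0),
                                       seed = 4))
  expect_lt(abs(mean(co3$true_d) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("edge cases: empty cohort, bad covariance, determinism", {
  empty <- generate_cohort(cohort_config(n = 0))
  expect_equal(nrow(empty), 0)
  expect_true(all(c("subject_id", "age", "bmi", "uE3", "bhCG", "AFP",
                    "true_d") %in% names(empty)))
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)  # not PD
  expect_error(cohort_config(n = 10, sigma0 = bad), "sigma0")
  expect_error(cohort_config(n = 10,
                             beta = matrix(1, 3, 5)), "6 coefficients")
  a <- generate_cohort(cohort_config(n = 100, seed = 99))
  b <- generate_cohort(cohort_config(n = 100, seed = 99))
  expect_identical(a, b)
})

test_that("generate_single_marker honors the mixture and the seed", {
  # degenerate mixture
  all1 <- generate_single_marker(5000, single_marker_params(1, 2, 0, 1, 1),
                                 seed = 5)
  expect_true(all(all1$labels == 1))
  expect_lt(abs(mean(all1$values) - 2), 4 / sqrt(5000))
  # mixture mean identity: E[Y] = pi * mu_d + (1-pi) * mu_nd = 0.6
  mix <- generate_single_marker(1e5, canonical_params(), seed = 6)
  se <- sd(mix$values) / sqrt(1e5)
  expect_lt(abs(mean(mix$values) - 0.6), 3 * se)
  expect_identical(generate_single_marker(50, canonical_params(), seed = 7),
                   generate_single_marker(50, canonical_params(), seed = 7))
  expect_error(generate_single_marker(-1, canonical_params()), "n")
})

test_that("cohort CSV round-trips", {
  co <- generate_cohort(cohort_config(n = 40, seed = 8))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(co, path)
  back <- read_cohort_csv(path)
  expect_equal(attr(back, "markers"), c("uE3", "bhCG", "AFP"))
  expect_equal(back$uE3, co$uE3, tolerance = 1e-12)
  expect_equal(back$true_d, co$true_d)
  expect_error(read_cohort_csv(path, markers = "nope"), "unknown marker")
})
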