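test_that("optimal_combination solves the Fisher-discriminant system", {
  # scalar reduction
  expect_equal(optimal_combination(2, 3, 1.5), 1.5 / 5)
  # identity algebra
  expect_equal(optimal_combination(diag(2), diag(2), c(1, 1)), c(0.5, 0.5))
  # random PD systems against a dense solver
  set.seed(31)
  for (k in c(2, 3, 5)) {
    s0 <- random_pd(k); s1 <- random_pd(k); d <- rnorm(k)
    a <- optimal_combination(s0, s1, d)
    expect_close(a, solve(s0 + s1, d), 1e-10)
    expect_gte(sum(a * d), 0)
  }
  sing <- matrix(0, 2, 2)
  expect_error(optimal_combination(sing, sing, c(1, 1)), "regulariz")
})

test_that("combined_auc matches its closed form and Monte-Carlo oracle", {
  expect_equal(combined_auc(diag(2), diag(2), c(0, 0)), 0.5)
  # frozen value: empirical AUC of the optimal score a'Y over 1e6 MVN
  # pairs with Sigma0 = Sigma1 = I, delta = (1,1) gave 0.841185 (seed 42);
  # closed form pnorm(1) = 0.841345
  expect_close(combined_auc(diag(2), diag(2), c(1, 1)), pnorm(1), 1e-12)
  expect_close(combined_auc(diag(2), diag(2), c(1, 1)), 0.841185, 1e-2)
  # K=1 equals the single-marker AUC
  p <- canonical_params()
  expect_close(combined_auc(p$var_nd, p$var_d, p$mu_d - p$mu_nd),
               single_auc(p), 1e-12)
})

test_that("combined_se_sp endpoints, hand case and curve integration", {
  ends0 <- combined_se_sp(c(1, 1), c(0, 0), c(1, 1), diag(2), diag(2), -Inf)
  expect_equal(c(ends0$sensitivity, ends0$specificity), c(1, 0))
  endsI <- combined_se_sp(c(1, 1), c(0, 0), c(1, 1), diag(2), diag(2), Inf)
  expect_equal(c(endsI$sensitivity, endsI$specificity), c(0, 1))
  # midpoint cutoff with identity covariances: cSe = cSp = pnorm(1/sqrt(2))
  a <- optimal_combination(diag(2), diag(2), c(1, 1))
  cmid <- sum(a * c(1, 1)) / 2
  ss <- combined_se_sp(a, c(0, 0), c(1, 1), diag(2), diag(2), cmid)
  expect_close(ss$sensitivity, pnorm(1 / sqrt(2)), 1e-12)
  expect_close(ss$specificity, pnorm(1 / sqrt(2)), 1e-12)
  # cROC trapezoid area converges to the closed-form cAUC
  set.seed(32)
  s0 <- random_pd(3); s1 <- random_pd(3); d <- rnorm(3, 1)
  aa <- optimal_combination(s0, s1, d)
  cr <- combined_roc(aa, rep(0, 3), d, s0, s1, 4000L)
  expect_close(attr(cr, "auc"), combined_auc(s0, s1, d), 1e-3)
})

test_that("no sampled weight vector beats the optimal combination", {
  set.seed(33)
  s0 <- random_pd(3); s1 <- random_pd(3); d <- rnorm(3, 1)
  best <- combined_auc(s0, s1, d)
  auc_of <- function(b) {
    v <- sqrt(drop(t(b) %*% (s0 + s1) %*% b))
    pnorm(abs(sum(b * d)) / v)
  }
  for (i in 1:200) {
    b <- rnorm(3)
    expect_lte(auc_of(b), best + 1e-9)
  }
  # scale invariance: positive scaling leaves the ROC curve unchanged
  a <- optimal_combination(s0, s1, d)
  r1 <- combined_roc(a, rep(0, 3), d, s0, s1, 200L)
  r2 <- combined_roc(3.7 * a, rep(0, 3), d, s0, s1, 200L)
  expect_close(attr(r1, "auc"), attr(r2, "auc"), 1e-10)
  expect_close(sort(r1$fpr), sort(r2$fpr), 1e-8)
})

test_that("monotone nesting: adding markers never lowers the cAUC", {
  set.seed(34)
  for (rep in 1:5) {
    s0 <- random_pd(3); s1 <- random_pd(3); d <- rnorm(3, 1)
    full <- combined_auc(s0, s1, d)
    for (pair in list(1:2, c(1, 3), 2:3)) {
      pa <- combined_auc(s0[pair, pair], s1[pair, pair], d[pair])
      expect_lte(pa, full + 1e-12)
      for (j in pair) {
        expect_lte(combined_auc(s0[j, j], s1[j, j], d[j]), pa + 1e-12)
      }
    }
  }
})

test_that("evaluate_combinations ranks subsets by posterior-mean cAUC", {
  co <- generate_cohort(cohort_config(n = 400, seed = 41))
  fit <- fit_mvn_lcm(co, c("uE3", "bhCG", "AFP"), c("age", "bmi"),
                     mcmc = fast_mcmc(seed = 10, n_iter = 1500,
                                      n_burnin = 600),
                     anchor = "bhCG", anchor_sign = 1)
  rep <- evaluate_combinations(fit)
  # the triple dominates every pair draw-wise, so it must rank first
  expect_equal(rep$ranking[1], "uE3+bhCG+AFP")
  expect_equal(nrow(rep$table), 4 * 3)
  expect_true(all(rep$table$mean >= 0 & rep$table$mean <= 1))
  expect_true(all(rep$table$cri_low <= rep$table$cri_high))
  # singleton ranking reproduces the single-marker AUC ordering
  single <- evaluate_combinations(fit, subsets = as.list(fit$meta$markers))
  aucs <- vapply(single$details, `[[`, numeric(1), "c_auc")
  expect_equal(names(sort(aucs, decreasing = TRUE)), single$ranking)
  expect_error(evaluate_combinations(fit, subsets = list("nope")),
               "unknown marker")
})

test_that("classify_subjects applies the strict threshold rule", {
  fake <- lcmroc:::new_lcm_draws(
    list(matrix(0, 10, 1, dimnames = list(NULL, "x"))),
    mcmc_settings(1, 20, 10), "mvn",
    p_disease = c(0.7, 0.5, 0.2, 0.5000001))
  cl <- classify_subjects(fake, 0.5)
  expect_equal(cl$labels, c(1L, 0L, 0L, 1L))
  expect_equal(cl$n_positive, 2L)
  expect_error(classify_subjects(fake, 0), "threshold")
  expect_error(classify_subjects(fake, 1), "threshold")
  # well-separated synthetic cohort: classification agrees with truth
  co <- generate_cohort(cohort_config(n = 400, seed = 42))
  fit <- fit_mvn_lcm(co, c("uE3", "bhCG", "AFP"), c("age", "bmi"),
                     mcmc = fast_mcmc(seed = 11, n_iter = 1500,
                                      n_burnin = 600),
                     anchor = "bhCG", anchor_sign = 1)
  cl2 <- classify_subjects(fit)
  expect_gt(mean(cl2$labels == co$true_d), 0.9)
})
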