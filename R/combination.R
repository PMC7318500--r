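#' Optimal linear marker combination
#'
#' The weight vector maximizing the AUC of a linear combination of
#' class-conditionally multivariate-normal markers:
#' `a = (Sigma0 + Sigma1)^-1 delta_x`, where `delta_x = mu(x, 1) -
#' mu(x, 0)` is the covariate-specific mean difference.  Solved as a
#' linear system (no explicit inverse).
#'
#' @param sigma0,sigma1 K x K within-class covariance matrices.
#' @param delta_x K-vector of class mean differences at the reference
#'   covariates.
#' @return K-vector of combination weights, satisfying
#'   `sum(a * delta_x) >= 0`.
#' @export
optimal_combination <- function(sigma0, sigma1, delta_x) {
  if (length(sigma0) == 1L) sigma0 <- matrix(sigma0, 1, 1)
  if (length(sigma1) == 1L) sigma1 <- matrix(sigma1, 1, 1)
  ssum <- sigma0 + sigma1
  ch <- tryCatch(chol_pd(ssum, "sigma0 + sigma1"), error = function(e) {
    stop2(conditionMessage(e),
          " -- consider regularizing the covariance estimates")
  })
  if (length(delta_x) != nrow(ssum)) {
    stop2("`delta_x` length must match the covariance dimension")
  }
  drop(backsolve(ch, backsolve(ch, delta_x, transpose = TRUE)))
}

#' Combined AUC of the optimal linear combination
#'
#' `cAUC = pnorm(sqrt(delta_x' (Sigma0 + Sigma1)^-1 delta_x))`, the AUC of
#' the optimally weighted marker combination at the reference covariates;
#' always in \[0.5, 1\].
#'
#' @inheritParams optimal_combination
#' @return cAUC (single probability).
#' @export
combined_auc <- function(sigma0, sigma1, delta_x) {
  a <- optimal_combination(sigma0, sigma1, delta_x)
  pnorm(sqrt(max(sum(a * delta_x), 0)))
}

#' Combined sensitivity and specificity at a cutoff
#'
#' For the combined score `a'Y` at reference covariates `x`:
#' `cSp = pnorm((c - a'mu(x,0)) / sqrt(a'Sigma0 a))` and
#' `cSe = pnorm((a'mu(x,1) - c) / sqrt(a'Sigma1 a))`.
#'
#' @param a K-vector of combination weights.
#' @param mu_x0,mu_x1 K-vectors of class means at the reference
#'   covariates.
#' @inheritParams optimal_combination
#' @param cutoff cutoff(s) on the combined-score scale (may be `+-Inf`).
#' @return A list with `sensitivity` and `specificity`.
#' @export
combined_se_sp <- function(a, mu_x0, mu_x1, sigma0, sigma1, cutoff) {
  if (length(sigma0) == 1L) sigma0 <- matrix(sigma0, 1, 1)
  if (length(sigma1) == 1L) sigma1 <- matrix(sigma1, 1, 1)
  v0 <- drop(t(a) %*% sigma0 %*% a)
  v1 <- drop(t(a) %*% sigma1 %*% a)
  stopifnot(v0 > 0, v1 > 0)
  m0 <- sum(a * mu_x0); m1 <- sum(a * mu_x1)
  list(sensitivity = pnorm((m1 - cutoff) / sqrt(v1)),
       specificity = pnorm((cutoff - m0) / sqrt(v0)))
}

#' Covariate-adjusted combined ROC curve
#'
#' Evaluates `(1 - cSp, cSe)` for the combined score over an ascending
#' cutoff grid spanning both class score distributions.
#'
#' @inheritParams combined_se_sp
#' @param n_grid number of grid points.
#' @return Data frame with `cutoff`, `fpr`, `tpr`; attribute `auc` holds
#'   the trapezoidal area.
#' @export
combined_roc <- function(a, mu_x0, mu_x1, sigma0, sigma1, n_grid = 2000L) {
  score <- combined_score_params(a, mu_x0, mu_x1, sigma0, sigma1)
  roc_curve(score, n_grid = n_grid)
}

# the combined score a'Y is scalar binormal; reuse the single-marker form
combined_score_params <- function(a, mu_x0, mu_x1, sigma0, sigma1,
                                  pi = 0.5) {
  if (length(sigma0) == 1L) sigma0 <- matrix(sigma0, 1, 1)
  if (length(sigma1) == 1L) sigma1 <- matrix(sigma1, 1, 1)
  single_marker_params(pi = pi,
                       mu_d = sum(a * mu_x1), mu_nd = sum(a * mu_x0),
                       var_d = drop(t(a) %*% sigma1 %*% a),
                       var_nd = drop(t(a) %*% sigma0 %*% a))
}

#' Posterior evaluation and ranking of marker combinations
#'
#' For each requested marker subset, evaluates the optimal-combination
#' accuracy draw-wise over the retained posterior draws of a fitted
#' multivariate latent class model: per draw, the class mean difference at
#' the reference covariates, the optimal weights, cAUC, and cSe/cSp at a
#' fixed cutoff (the Youden cutoff of the combined score at the
#' posterior-mean parameters).  Subsets are ranked by posterior-mean cAUC,
#' ties broken by higher posterior-mean cSe.
#'
#' @param draws an `lcm_draws` object from [fit_mvn_lcm()].
#' @param subsets list of character vectors of marker names; default all
#'   pairs plus the full set (plus singletons when `singletons = TRUE`).
#' @param x_ref reference covariate values (named or in the order of the
#'   fitted covariates); default the cohort covariate means.
#' @param singletons also evaluate each single marker (default FALSE
#'   unless fewer than 2 markers).
#' @return An object of class `combination_report`: a list with `table`
#'   (ranked posterior summaries in long form), `details` (per-subset
#'   weights, cutoff, draws), and `x_ref`.
#' @export
evaluate_combinations <- function(draws, subsets = NULL, x_ref = NULL,
                                  singletons = FALSE) {
  stopifnot(inherits(draws, "lcm_draws"))
  if (draws$model != "mvn") stop2("`draws` must come from fit_mvn_lcm()")
  markers <- draws$meta$markers
  covariates <- draws$meta$covariates
  if (is.null(subsets)) {
    subsets <- list()
    if (singletons || length(markers) < 2L) {
      subsets <- c(subsets, as.list(markers))
    }
    if (length(markers) >= 2L) {
      prs <- utils::combn(markers, 2L, simplify = FALSE)
      subsets <- c(subsets, prs)
      if (length(markers) > 2L) subsets <- c(subsets, list(markers))
    }
  }
  for (ss in subsets) {
    bad <- setdiff(ss, markers)
    if (length(bad)) stop2("subset references unknown marker(s): ",
                           paste(bad, collapse = ", "))
  }
  if (is.null(x_ref)) {
    x_ref <- draws$meta$centers
  } else if (!is.null(names(x_ref)) && length(covariates) > 0) {
    x_ref <- x_ref[covariates]
  }
  if (length(x_ref) != length(covariates)) {
    stop2("`x_ref` must supply one value per fitted covariate")
  }
  m <- draws_matrix(draws)
  nd <- nrow(m)
  mean_draw <- colMeans(m)

  details <- list()
  rows <- list()
  for (ss in subsets) {
    idx <- match(ss, markers)
    auc <- numeric(nd); se <- numeric(nd); sp <- numeric(nd)
    # fixed cutoff from the posterior-mean parameters
    pm <- subset_params(mean_draw, markers, covariates, x_ref, idx)
    a_pm <- optimal_combination(pm$sigma0, pm$sigma1, pm$delta)
    c_star <- youden_cutoff(combined_score_params(a_pm, pm$mu0, pm$mu1,
                                                  pm$sigma0, pm$sigma1))
    for (i in seq_len(nd)) {
      pd <- subset_params(m[i, ], markers, covariates, x_ref, idx)
      a_i <- optimal_combination(pd$sigma0, pd$sigma1, pd$delta)
      auc[i] <- pnorm(sqrt(max(sum(a_i * pd$delta), 0)))
      ssp <- combined_se_sp(a_i, pd$mu0, pd$mu1, pd$sigma0, pd$sigma1,
                            c_star)
      se[i] <- ssp$sensitivity; sp[i] <- ssp$specificity
    }
    label <- paste(ss, collapse = "+")
    stats <- list(cSensitivity = se, cSpecificity = sp, cAUC = auc)
    rows[[label]] <- do.call(rbind, lapply(names(stats), function(nm) {
      s <- posterior_summary(stats[[nm]])
      data.frame(subset = label, statistic = nm, mean = s$mean,
                 median = s$median, sd = s$sd, mc_error = s$mc_error,
                 cri_low = s$cri_low, cri_high = s$cri_high)
    }))
    details[[label]] <- list(markers = ss, a = a_pm, delta_x = pm$delta,
                             c_star = c_star, auc_draws = auc,
                             se_draws = se, sp_draws = sp,
                             c_auc = mean(auc), c_se = mean(se),
                             c_sp = mean(sp))
  }
  mean_auc <- vapply(details, `[[`, numeric(1), "c_auc")
  mean_se <- vapply(details, `[[`, numeric(1), "c_se")
  rank_order <- order(-mean_auc, -mean_se)
  table <- do.call(rbind, rows[rank_order])
  rownames(table) <- NULL
  table$rank <- rep(seq_along(rank_order), each = 3L)
  structure(list(table = table, details = details[rank_order],
                 x_ref = x_ref, ranking = names(details)[rank_order]),
            class = "combination_report")
}

#' @export
print.combination_report <- function(x, ...) {
  cat("<combination_report> ranking by posterior-mean cAUC:\n")
  for (i in seq_along(x$details)) {
    d <- x$details[[i]]
    cat(sprintf("  %d. %-22s cAUC=%.3f cSe=%.3f cSp=%.3f\n",
                i, names(x$details)[i], d$c_auc, d$c_se, d$c_sp))
  }
  invisible(x)
}

# subset parameters (mu0, mu1, delta, sigmas) at x_ref from one draw row
subset_params <- function(draw, markers, covariates, x_ref, idx) {
  beta <- beta_from_draw(draw, markers, covariates)
  mu0 <- conditional_means(beta, x_ref, 0)[idx]
  mu1 <- conditional_means(beta, x_ref, 1)[idx]
  s0 <- sigma_from_draw(draw, markers, 0)[idx, idx, drop = FALSE]
  s1 <- sigma_from_draw(draw, markers, 1)[idx, idx, drop = FALSE]
  list(mu0 = mu0, mu1 = mu1, delta = mu1 - mu0, sigma0 = s0, sigma1 = s1)
}

#' Classify subjects from posterior disease probabilities
#'
#' Assigns label 1 when the per-subject posterior probability of disease
#' exceeds the threshold (strict inequality; a probability exactly equal
#' to the threshold gives label 0).
#'
#' @param draws an `lcm_draws` object fitted with retained per-subject
#'   probabilities (the default).
#' @param threshold probability threshold in (0, 1); default 0.5.
#' @return A list with `labels` (integer 0/1), `probabilities`, `n_positive`,
#'   `fraction_positive`.
#' @export
classify_subjects <- function(draws, threshold = 0.5) {
  stopifnot(inherits(draws, "lcm_draws"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop2("`threshold` must lie strictly inside (0, 1)")
  }
  p <- draws$p_disease
  if (is.null(p)) stop2("fit did not retain per-subject probabilities")
  labels <- as.integer(p > threshold)
  list(labels = labels, probabilities = p,
       n_positive = sum(labels),
       fraction_positive = mean(labels))
}
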