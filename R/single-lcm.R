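#' Priors for the single-marker latent class model
#'
#' Vague conjugate priors: both class means are normal
#' `N(mean_prior_mean, mean_prior_var)`, both precisions are
#' `Gamma(prec_shape, prec_rate)`, and the prevalence has a
#' Beta(`pi_prior[1]`, `pi_prior[2]`) prior (the two-category Dirichlet).
#'
#' @param mean_prior_mean,mean_prior_var normal prior on the class means.
#' @param prec_shape,prec_rate gamma prior on the class precisions.
#' @param pi_prior length-2 positive concentration parameters.
#' @return An object of class `single_marker_priors`.
#' @export
single_marker_priors <- function(mean_prior_mean = 0, mean_prior_var = 1e3,
                                 prec_shape = 1e-3, prec_rate = 1e-3,
                                 pi_prior = c(1, 1)) {
  check_number(mean_prior_mean, "mean_prior_mean")
  check_number(mean_prior_var, "mean_prior_var", lower = 1e-12)
  check_number(prec_shape, "prec_shape", lower = 1e-12)
  check_number(prec_rate, "prec_rate", lower = 1e-12)
  if (length(pi_prior) != 2L || any(pi_prior <= 0)) {
    stop2("`pi_prior` must be two positive concentrations")
  }
  structure(list(mean_prior_mean = mean_prior_mean,
                 mean_prior_var = mean_prior_var,
                 prec_shape = prec_shape, prec_rate = prec_rate,
                 pi_prior = as.numeric(pi_prior)),
            class = "single_marker_priors")
}

#' Fit the single-marker binormal latent class model by Gibbs sampling
#'
#' Two-class normal mixture with latent disease status: labels from their
#' Bernoulli full conditional, class means from normal full conditionals,
#' class precisions from gamma full conditionals, and the prevalence from
#' its Beta full conditional.  Identifiability (`mu_d > mu_nd` on the
#' internal scale) is enforced every iteration by relabeling: a violating
#' draw swaps the two classes and maps the prevalence to its complement,
#' which preserves the stationary distribution restricted to the identified
#' region.
#'
#' Markers that are *lower* in disease (e.g. uE3 in gestational diabetes)
#' are handled by `orientation = "lower"`: the model is fitted on the
#' negated values, and reported class means are mapped back to the original
#' scale with the diseased mean below the non-diseased mean.  ROC, AUC and
#' overlap quantities are invariant to this reflection.
#'
#' @param values numeric vector of marker values (>= 20 finite values with
#'   positive variance).
#' @param priors a [single_marker_priors()].
#' @param mcmc an [mcmc_settings()].
#' @param orientation `"higher"` (diseased mean above non-diseased;
#'   default) or `"lower"`.
#' @param fix_d optional integer 0/1 vector clamping the latent labels to
#'   known values (supervised limit, used for validation); labels are then
#'   never resampled.
#' @return An `lcm_draws` object with monitored parameters `pi`, `mu_d`,
#'   `mu_nd`, `var_d`, `var_nd` (original marker scale) and per-subject
#'   posterior disease probabilities in `$p_disease`.
#' @examples
#' sim <- generate_single_marker(300, single_marker_params(0.3, 2, 0, 1, 1))
#' fit <- fit_single_marker_lcm(sim$values,
#'                              mcmc = mcmc_settings(1, 1000, 500, seed = 1))
#' @export
fit_single_marker_lcm <- function(values,
                                  priors = single_marker_priors(),
                                  mcmc = mcmc_settings(),
                                  orientation = c("higher", "lower"),
                                  fix_d = NULL) {
  orientation <- match.arg(orientation)
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop2("`values` must be numeric and finite (no NA/Inf)")
  }
  n <- length(values)
  if (n < 20L) stop2("need at least 20 observations")
  if (var(values) <= 1e-12) {
    stop2("`values` are (numerically) constant; the mixture is degenerate")
  }
  sign <- if (orientation == "lower") -1 else 1
  y <- sign * values
  if (!is.null(fix_d)) {
    if (length(fix_d) != n || !all(fix_d %in% c(0L, 1L))) {
      stop2("`fix_d` must be a 0/1 vector of length(values)")
    }
    fix_d <- as.integer(fix_d)
  }
  pr <- priors
  keep <- seq.int(mcmc$n_burnin + 1L, mcmc$n_iter, by = mcmc$thin)
  pars <- c("pi", "mu_d", "mu_nd", "var_d", "var_nd")
  chains <- vector("list", mcmc$n_chains)
  p_dis <- numeric(n)
  vy <- var(y); my <- mean(y)
  n_guard <- 0L

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    # deterministic start: split at the median
    d <- if (is.null(fix_d)) as.integer(y > median(y)) else fix_d
    mu <- c(nd = mean(y[d == 0L]), d = mean(y[d == 1L]))
    tau <- c(nd = 1 / max(var(y[d == 0L]), 1e-6),
             d = 1 / max(var(y[d == 1L]), 1e-6))
    pi <- mean(d)
    out <- matrix(NA_real_, length(keep), length(pars),
                  dimnames = list(NULL, pars))
    row <- 0L
    acc_d <- numeric(n)
    for (it in seq_len(mcmc$n_iter)) {
      if (is.null(fix_d)) {
        l1 <- log(pi) + dnorm(y, mu["d"], 1 / sqrt(tau["d"]), log = TRUE)
        l0 <- log1p(-pi) + dnorm(y, mu["nd"], 1 / sqrt(tau["nd"]), log = TRUE)
        d <- as.integer(runif(n) < 1 / (1 + exp(l0 - l1)))
      }
      n1 <- sum(d); n0 <- n - n1
      s1 <- sum(y[d == 1L]); s0 <- sum(y) - s1
      # near-empty classes: the vague priors alone put essentially all
      # mass on astronomically large variances and off-scale means, which
      # makes an emptied class an absorbing state.  Guard by re-drawing
      # that class's parameters from a data-scaled proposal instead
      # (mean ~ N(sample mean, sample var), precision ~ Gamma(1/2, var/2))
      # and counting the event for the warning.
      guard1 <- n1 < 2L; guard0 <- n0 < 2L
      if (guard1 || guard0) n_guard <- n_guard + 1L
      # class means: normal-normal conjugate updates
      if (guard1) {
        mu["d"] <- rnorm(1, my, sqrt(vy))
      } else {
        prec1 <- n1 * tau["d"] + 1 / pr$mean_prior_var
        m1 <- (tau["d"] * s1 + pr$mean_prior_mean / pr$mean_prior_var) /
          prec1
        mu["d"] <- rnorm(1, m1, 1 / sqrt(prec1))
      }
      if (guard0) {
        mu["nd"] <- rnorm(1, my, sqrt(vy))
      } else {
        prec0 <- n0 * tau["nd"] + 1 / pr$mean_prior_var
        m0 <- (tau["nd"] * s0 + pr$mean_prior_mean / pr$mean_prior_var) /
          prec0
        mu["nd"] <- rnorm(1, m0, 1 / sqrt(prec0))
      }
      # precisions: gamma conjugate updates
      ss1 <- sum((y[d == 1L] - mu["d"])^2)
      ss0 <- sum((y[d == 0L] - mu["nd"])^2)
      tau["d"] <- if (guard1) rgamma(1, 0.5, vy / 2) else
        rgamma(1, pr$prec_shape + n1 / 2, pr$prec_rate + ss1 / 2)
      tau["nd"] <- if (guard0) rgamma(1, 0.5, vy / 2) else
        rgamma(1, pr$prec_shape + n0 / 2, pr$prec_rate + ss0 / 2)
      pi <- rbeta(1, pr$pi_prior[1] + n1, pr$pi_prior[2] + n0)
      # identifiability: relabel so the diseased mean is the larger one
      if (mu["d"] < mu["nd"] && is.null(fix_d)) {
        mu <- mu[c(2L, 1L)]; names(mu) <- c("nd", "d")
        tau <- tau[c(2L, 1L)]; names(tau) <- c("nd", "d")
        pi <- 1 - pi
        d <- 1L - d
      }
      if (it > mcmc$n_burnin && (it - mcmc$n_burnin - 1L) %% mcmc$thin == 0L) {
        row <- row + 1L
        out[row, ] <- c(pi, sign * mu["d"], sign * mu["nd"],
                        1 / tau["d"], 1 / tau["nd"])
        acc_d <- acc_d + d
      }
    }
    chains[[ch]] <- out
    p_dis <- p_dis + acc_d / row
  }
  if (n_guard > 0L) {
    warning(sprintf(paste0("a latent class was (nearly) empty in %d ",
                           "iteration(s); its parameters were re-drawn ",
                           "on the data scale"), n_guard), call. = FALSE)
  }
  new_lcm_draws(chains, mcmc, model = "single_marker",
                meta = list(n = n, orientation = orientation,
                            priors = priors,
                            clamped = !is.null(fix_d)),
                p_disease = p_dis / mcmc$n_chains)
}

# single_marker_params from one draw row (internal oriented scale)
params_from_draw <- function(draw, orientation = "higher") {
  single_marker_params(pi = draw[["pi"]],
                       mu_d = draw[["mu_d"]], mu_nd = draw[["mu_nd"]],
                       var_d = draw[["var_d"]], var_nd = draw[["var_nd"]])
}

# oriented (internal) copy of a draw row: diseased mean above
oriented_draw <- function(draw, orientation) {
  s <- if (orientation == "lower") -1 else 1
  single_marker_params(pi = draw[["pi"]],
                       mu_d = s * draw[["mu_d"]], mu_nd = s * draw[["mu_nd"]],
                       var_d = draw[["var_d"]], var_nd = draw[["var_nd"]])
}

#' Posterior accuracy summaries for a single-marker fit
#'
#' Evaluates sensitivity, specificity and AUC draw-wise over the retained
#' posterior draws, so that credible intervals propagate parameter
#' uncertainty.  Sensitivity and specificity are evaluated at a fixed
#' cutoff: by default the Youden-optimal cutoff of the posterior-mean
#' parameters (on the internal oriented scale).  Also reports the overlap
#' diagnostic at the posterior means.
#'
#' @param fit an `lcm_draws` object from [fit_single_marker_lcm()].
#' @param cutoff optional fixed cutoff on the internal oriented scale;
#'   default is the Youden cutoff at the posterior means.
#' @return A list with `summary` (data frame of posterior summaries for
#'   Sensitivity, Specificity, AUC), `cutoff`, `delta` (overlap at the
#'   posterior means), `auc_draws`.
#' @export
marker_accuracy <- function(fit, cutoff = NULL) {
  stopifnot(inherits(fit, "lcm_draws"), fit$model == "single_marker")
  orientation <- fit$meta$orientation
  m <- draws_matrix(fit)
  mean_params <- oriented_draw(colMeans(m), orientation)
  cutoff <- cutoff %||% youden_cutoff(mean_params)
  nd <- nrow(m)
  se <- numeric(nd); sp <- numeric(nd); auc <- numeric(nd)
  for (i in seq_len(nd)) {
    p <- oriented_draw(m[i, ], orientation)
    ss <- se_sp_at_cutoff(p, cutoff)
    se[i] <- ss$sensitivity; sp[i] <- ss$specificity
    auc[i] <- single_auc(p)
  }
  rows <- list(Sensitivity = se, Specificity = sp, AUC = auc)
  su <- do.call(rbind, lapply(names(rows), function(nm) {
    s <- posterior_summary(rows[[nm]])
    data.frame(statistic = nm, mean = s$mean, median = s$median, sd = s$sd,
               mc_error = s$mc_error, cri_low = s$cri_low,
               cri_high = s$cri_high)
  }))
  list(summary = su, cutoff = cutoff,
       delta = overlap_delta(mean_params), auc_draws = auc)
}
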