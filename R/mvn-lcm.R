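#' Logistic disease prevalence
#'
#' `prevalence(alpha, x)` evaluates `exp(alpha'x) / (1 + exp(alpha'x))`
#' overflow-safely; `x` includes the leading intercept 1.
#'
#' @param alpha coefficient vector (intercept first).
#' @param x covariate vector (or matrix with one row per subject) whose
#'   first element/column is the intercept 1.
#' @return Probability (or vector of probabilities).
#' @export
prevalence <- function(alpha, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(alpha)) {
    stop2("dimension mismatch: length(alpha) != ncol(x)")
  }
  drop(plogis(x %*% alpha))
}

#' Class- and covariate-conditional marker means
#'
#' For each marker `k` the mean is
#' `beta0 + beta1*age + beta2*bmi + beta3*d + beta4*(d*age) + beta5*(d*bmi)`
#' (with the covariate list generalizing beyond age/BMI).
#'
#' @param beta K x 6 coefficient matrix (or K x `2*(s+1)` for `s`
#'   covariates), columns ordered (intercept, covariates, d,
#'   d:covariates).
#' @param x numeric covariate vector (e.g. `c(age, bmi)`), without
#'   intercept.
#' @param d disease indicator, 0 or 1.
#' @return K-vector of conditional means.
#' @export
conditional_means <- function(beta, x, d) {
  if (is.null(dim(beta))) beta <- matrix(beta, nrow = 1)
  s <- length(x)
  if (ncol(beta) != 2 * (s + 1)) {
    stop2("`beta` must have 2*(length(x)+1) columns")
  }
  if (!d %in% c(0, 1)) stop2("`d` must be 0 or 1")
  z <- c(1, x, d, d * x)
  drop(beta %*% z)
}

#' Priors for the multivariate latent class model
#'
#' Weakly informative defaults: independent zero-mean normal priors with
#' variance `alpha_prior_var` on the prevalence coefficients and
#' `beta_prior_var` on each regression coefficient, and a
#' Wishart(`wishart_df`, `wishart_scale`) prior on each class precision
#' matrix.  Defaults: `alpha_prior_var = 25` (SD 5 on the log-odds scale;
#' a much larger variance is *not* vague on the probability scale -- it
#' piles prior mass on prevalences near 0 and 1 and invites collapse of a
#' latent class), `beta_prior_var = 1e3`, `wishart_df = K + 2`,
#' `wishart_scale = diag(K)`.
#'
#' @param k number of markers.
#' @param alpha_prior_var,beta_prior_var prior variances (> 0).
#' @param wishart_df degrees of freedom (>= K).
#' @param wishart_scale K x K positive-definite scale matrix.
#' @return An object of class `mvn_priors`.
#' @export
mvn_priors <- function(k, alpha_prior_var = 25, beta_prior_var = 1e3,
                       wishart_df = k + 2, wishart_scale = diag(k)) {
  check_number(alpha_prior_var, "alpha_prior_var", lower = 1e-12)
  check_number(beta_prior_var, "beta_prior_var", lower = 1e-12)
  if (wishart_df < k) stop2("`wishart_df` must be >= number of markers")
  chol_pd(wishart_scale, "wishart_scale")
  structure(list(alpha_prior_var = alpha_prior_var,
                 beta_prior_var = beta_prior_var,
                 wishart_df = wishart_df, wishart_scale = wishart_scale),
            class = "mvn_priors")
}

mvn_logdens <- function(resid, sigma) {
  u <- chol(sigma)
  k <- ncol(sigma)
  q <- rowSums((resid %*% backsolve(u, diag(k)))^2)
  -0.5 * (q + 2 * sum(log(diag(u))) + k * log(2 * pi))
}

#' Fit the covariate-adjusted multivariate-normal latent class model
#'
#' Markers are multivariate normal within each latent disease class with
#' per-marker regression means in the covariates, the disease indicator
#' and disease-by-covariate interactions, class-specific covariance
#' matrices, and a logistic model for the disease prevalence in the
#' covariates.  Estimation is Metropolis-within-Gibbs:
#'
#' * latent labels from their Bernoulli full conditional (logistic prior
#'   times the two MVN likelihoods),
#' * the stacked regression coefficients from their exact multivariate
#'   normal full conditional,
#' * each class precision matrix from its Wishart full conditional,
#' * the prevalence coefficients by adaptive Gaussian random-walk
#'   Metropolis, with the step size tuned during burn-in toward ~30%
#'   acceptance.
#'
#' Covariates are centered internally for sampler stability; all reported
#' draws are mapped back to the original covariate scale.  Label switching
#' is controlled by an anchor marker whose disease effect at the covariate
#' means must have the anchor sign (the anchor defaults to the marker with
#' the strongest two-means separation at initialization); violating draws
#' are relabeled by swapping the classes.
#'
#' @param cohort data frame with the covariate and marker columns (e.g.
#'   from [generate_cohort()] or [read_cohort_csv()]); at least 50 rows.
#' @param markers character vector of marker column names.
#' @param covariates character vector of covariate column names (default
#'   `c("age", "bmi")`; may be empty for a covariate-free model).
#' @param priors an [mvn_priors()]; default `mvn_priors(length(markers))`.
#' @param mcmc an [mcmc_settings()].
#' @param anchor optional anchor marker name; default auto-selected.
#' @param anchor_sign +1 if the anchor marker is higher in disease, -1 if
#'   lower (default +1).  With unlabeled data the direction of "disease"
#'   is a modelling choice; pick an anchor whose direction is known (e.g.
#'   a marker elevated in disease) or flip the sign.
#' @param fix_d optional 0/1 vector clamping the latent labels
#'   (supervised limit, for validation).
#' @return An `lcm_draws` object.  Monitored parameters: `alpha_*`
#'   (prevalence coefficients), `beta_<marker>_<term>` with terms
#'   `intercept`, the covariates, `d`, and `d_<covariate>`, and the lower
#'   triangles `sigma0[i,j]`, `sigma1[i,j]`.  Per-subject posterior
#'   disease probabilities are in `$p_disease`; `$meta` records the
#'   anchor, anchor sign, covariate centers and Metropolis acceptance
#'   rates.
#' @export
fit_mvn_lcm <- function(cohort, markers, covariates = c("age", "bmi"),
                        priors = NULL, mcmc = mcmc_settings(),
                        anchor = NULL, anchor_sign = NULL, fix_d = NULL) {
  cohort <- as.data.frame(cohort)
  n <- nrow(cohort)
  if (n < 50L) stop2("need at least 50 subjects")
  bad <- setdiff(c(markers, covariates), names(cohort))
  if (length(bad)) stop2("column(s) not in cohort: ",
                         paste(bad, collapse = ", "))
  y <- as.matrix(cohort[, markers, drop = FALSE])
  xc <- as.matrix(cohort[, covariates, drop = FALSE])
  if (any(!is.finite(y)) || any(!is.finite(xc))) {
    stop2("markers and covariates must be finite and complete")
  }
  k <- length(markers)
  s <- length(covariates)
  priors <- priors %||% mvn_priors(k)
  if (nrow(priors$wishart_scale) != k) {
    stop2("`priors$wishart_scale` dimension must equal the number of markers")
  }
  if (!is.null(fix_d)) {
    if (length(fix_d) != n || !all(fix_d %in% c(0L, 1L))) {
      stop2("`fix_d` must be a 0/1 vector with one entry per subject")
    }
    fix_d <- as.integer(fix_d)
  }
  centers <- if (s > 0) colMeans(xc) else numeric(0)
  xs <- sweep(xc, 2, centers)            # centered covariates
  xbase <- cbind(1, xs)                  # n x (s+1), intercept + covariates
  if (qr(xbase)$rank < s + 1L) stop2("singular covariate design")
  if (any(apply(y, 2, var) <= 1e-12)) {
    stop2("constant marker column; the mixture is degenerate")
  }
  p <- 2L * (s + 1L)                     # design: (1, x, d, d*x)
  gi <- chol2inv(chol(priors$wishart_scale))  # Wishart scale inverse

  # anchor selection: covariate-free 2-means split per marker judges the
  # strength (and sign) of the bimodal separation
  sep <- vapply(seq_len(k), function(j) {
    km <- suppressWarnings(kmeans(y[, j], centers = range(y[, j])))
    g <- km$cluster == which.max(km$centers)
    (mean(y[g, j]) - mean(y[!g, j])) / sd(y[, j])
  }, numeric(1))
  if (is.null(anchor)) {
    aj <- which.max(abs(sep))
    anchor <- markers[aj]
    anchor_sign <- anchor_sign %||% 1
  } else {
    if (!anchor %in% markers) stop2("`anchor` must be one of the markers")
    aj <- match(anchor, markers)
    anchor_sign <- anchor_sign %||% 1
  }
  if (!anchor_sign %in% c(-1, 1)) stop2("`anchor_sign` must be -1 or +1")

  terms <- c("intercept", covariates, "d",
             if (s > 0) paste0("d_", covariates))
  pars <- c(paste0("alpha_", c("0", covariates)),
            as.vector(t(outer(markers, terms,
                              function(m, t) paste0("beta_", m, "_", t)))),
            sigma_par_names("sigma0", markers),
            sigma_par_names("sigma1", markers))
  keep <- seq.int(mcmc$n_burnin + 1L, mcmc$n_iter, by = mcmc$thin)
  d_row <- s + 2L                        # row of B holding the d coefficient
  base_rows <- seq_len(s + 1L)
  dis_rows <- seq.int(s + 2L, p)
  low <- which(lower.tri(diag(k), diag = TRUE))

  # fixed Metropolis proposal shape from the logistic information bound
  vprop <- chol2inv(chol(crossprod(xbase) / 4 +
                           diag(s + 1L) / priors$alpha_prior_var))
  uprop <- chol(vprop)

  chains <- vector("list", mcmc$n_chains)
  p_dis <- numeric(n)
  acc_rates <- numeric(mcmc$n_chains)
  thin_classes <- 0L

  for (ch in seq_len(mcmc$n_chains)) {
    set.seed(mcmc$seed + ch - 1L)
    # initialization: 2-means split on the anchor marker
    if (is.null(fix_d)) {
      km <- suppressWarnings(kmeans(y[, aj], centers = range(y[, aj])))
      hi_cluster <- which.max(km$centers * anchor_sign)
      d <- as.integer(km$cluster == hi_cluster)
      if (sum(d) < 2L || sum(d) > n - 2L) d <- as.integer(y[, aj] > median(y[, aj]))
    } else d <- fix_d
    bmat <- init_beta(y, xbase, d, p, dis_rows)
    sig <- init_sigma(y, xbase, d, bmat, base_rows, dis_rows, k)
    alpha <- c(stats::qlogis(min(max(mean(d), 0.05), 0.95)), rep(0, s))
    step <- 2.38 / sqrt(s + 1)
    acc <- 0L; acc_n <- 0L

    out <- matrix(NA_real_, length(keep), length(pars),
                  dimnames = list(NULL, pars))
    row <- 0L
    acc_d <- numeric(n)

    for (it in seq_len(mcmc$n_iter)) {
      mu0 <- xbase %*% bmat[base_rows, , drop = FALSE]
      mu1 <- xbase %*% (bmat[base_rows, , drop = FALSE] +
                          bmat[dis_rows, , drop = FALSE])
      ## latent labels
      if (is.null(fix_d)) {
        eta <- drop(xbase %*% alpha)
        l1 <- -log1pexp(-eta) + mvn_logdens(y - mu1, sig[[2]])
        l0 <- -log1pexp(eta) + mvn_logdens(y - mu0, sig[[1]])
        d <- as.integer(runif(n) < 1 / (1 + exp(l0 - l1)))
      }
      i1 <- d == 1L
      n1 <- sum(i1); n0 <- n - n1
      if (n1 < k || n0 < k) thin_classes <- thin_classes + 1L

      ## regression coefficients: exact MVN full conditional for vec(B)
      a0 <- chol2inv(chol(sig[[1]])); a1 <- chol2inv(chol(sig[[2]]))
      x0 <- xbase[!i1, , drop = FALSE]; x1 <- xbase[i1, , drop = FALSE]
      s0q <- crossprod(x0); s1q <- crossprod(x1)
      s0f <- matrix(0, p, p); s0f[base_rows, base_rows] <- s0q
      s1f <- matrix(0, p, p)
      s1f[base_rows, base_rows] <- s1q; s1f[base_rows, dis_rows] <- s1q
      s1f[dis_rows, base_rows] <- s1q; s1f[dis_rows, dis_rows] <- s1q
      prec <- kronecker(a0, s0f) + kronecker(a1, s1f) +
        diag(1 / priors$beta_prior_var, p * k)
      m0 <- crossprod(x0, y[!i1, , drop = FALSE]) %*% a0
      m1 <- crossprod(x1, y[i1, , drop = FALSE]) %*% a1
      mfull <- matrix(0, p, k)
      mfull[base_rows, ] <- m0 + m1
      mfull[dis_rows, ] <- m1
      up <- chol((prec + t(prec)) / 2)
      bmean <- backsolve(up, backsolve(up, as.vector(mfull),
                                       transpose = TRUE))
      bvec <- bmean + backsolve(up, rnorm(p * k))
      bmat <- matrix(bvec, p, k)

      ## class covariance matrices: Wishart full conditionals
      mu0 <- xbase %*% bmat[base_rows, , drop = FALSE]
      mu1 <- xbase %*% (bmat[base_rows, , drop = FALSE] +
                          bmat[dis_rows, , drop = FALSE])
      r0 <- (y - mu0)[!i1, , drop = FALSE]
      r1 <- (y - mu1)[i1, , drop = FALSE]
      sc0 <- chol2inv(chol(gi + crossprod(r0)))
      sc1 <- chol2inv(chol(gi + crossprod(r1)))
      om0 <- rWishart(1, priors$wishart_df + n0, (sc0 + t(sc0)) / 2)[, , 1]
      om1 <- rWishart(1, priors$wishart_df + n1, (sc1 + t(sc1)) / 2)[, , 1]
      sig <- list(chol2inv(chol(om0)), chol2inv(chol(om1)))

      ## prevalence coefficients: adaptive random-walk Metropolis
      prop <- alpha + step * drop(rnorm(s + 1L) %*% uprop)
      lp <- function(a) {
        eta <- drop(xbase %*% a)
        sum(eta[i1]) - sum(log1pexp(eta)) -
          sum(a^2) / (2 * priors$alpha_prior_var)
      }
      if (log(runif(1)) < lp(prop) - lp(alpha)) {
        alpha <- prop
        if (it > mcmc$n_burnin) acc <- acc + 1L
        accepted <- TRUE
      } else accepted <- FALSE
      if (it <= mcmc$n_burnin) {
        step <- exp(log(step) + (as.numeric(accepted) - 0.3) / sqrt(it))
      } else acc_n <- acc_n + 1L

      ## label-switching control via the anchor's disease effect
      if (is.null(fix_d) && anchor_sign * bmat[d_row, aj] < 0) {
        bmat[base_rows, ] <- bmat[base_rows, ] + bmat[dis_rows, ]
        bmat[dis_rows, ] <- -bmat[dis_rows, ]
        sig <- sig[c(2L, 1L)]
        alpha <- -alpha
        d <- 1L - d
      }

      if (it > mcmc$n_burnin && (it - mcmc$n_burnin - 1L) %% mcmc$thin == 0L) {
        row <- row + 1L
        out[row, ] <- c(uncenter_alpha(alpha, centers),
                        as.vector(uncenter_beta(bmat, centers, base_rows,
                                                dis_rows)),
                        sig[[1]][low], sig[[2]][low])
        acc_d <- acc_d + d
      }
    }
    chains[[ch]] <- out
    p_dis <- p_dis + acc_d / row
    acc_rates[ch] <- if (acc_n > 0) acc / acc_n else NA_real_
  }
  if (thin_classes > 0L) {
    warning(sprintf(paste0("one latent class held fewer subjects than ",
                           "markers in %d iteration(s); the Wishart update ",
                           "fell back toward its prior there"), thin_classes),
            call. = FALSE)
  }
  new_lcm_draws(chains, mcmc, model = "mvn",
                meta = list(n = n, markers = markers,
                            covariates = covariates, centers = centers,
                            anchor = anchor, anchor_sign = anchor_sign,
                            priors = priors, alpha_accept = acc_rates,
                            clamped = !is.null(fix_d)),
                p_disease = p_dis / mcmc$n_chains)
}

sigma_par_names <- function(prefix, markers) {
  k <- length(markers)
  idx <- which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  sprintf("%s[%d,%d]", prefix, idx[, 1], idx[, 2])
}

# per-marker ridge least squares given labels, for initialization
init_beta <- function(y, xbase, d, p, dis_rows) {
  z <- cbind(xbase, d * xbase)
  g <- crossprod(z) + diag(1e-6, p)
  matrix(solve(g, crossprod(z, y)), p, ncol(y))
}

init_sigma <- function(y, xbase, d, bmat, base_rows, dis_rows, k) {
  mu0 <- xbase %*% bmat[base_rows, , drop = FALSE]
  mu1 <- xbase %*% (bmat[base_rows, , drop = FALSE] +
                      bmat[dis_rows, , drop = FALSE])
  r <- y - mu0
  r[d == 1L, ] <- (y - mu1)[d == 1L, , drop = FALSE]
  s0 <- cov(r[d == 0L, , drop = FALSE]) + diag(1e-4, k)
  s1 <- cov(r[d == 1L, , drop = FALSE]) + diag(1e-4, k)
  if (any(!is.finite(s0))) s0 <- diag(k)
  if (any(!is.finite(s1))) s1 <- diag(k)
  list(s0, s1)
}

uncenter_alpha <- function(alpha, centers) {
  if (length(centers) == 0) return(alpha)
  c(alpha[1] - sum(alpha[-1] * centers), alpha[-1])
}

uncenter_beta <- function(bmat, centers, base_rows, dis_rows) {
  if (length(centers) == 0) return(bmat)
  s <- length(centers)
  out <- bmat
  out[1, ] <- bmat[1, ] - colSums(bmat[base_rows[-1], , drop = FALSE] *
                                    centers)
  out[dis_rows[1], ] <- bmat[dis_rows[1], ] -
    colSums(bmat[dis_rows[-1], , drop = FALSE] * centers)
  out
}

# extract Sigma draws (d = 0 or 1) from a pooled draw matrix row
sigma_from_draw <- function(draw, markers, class = 0) {
  k <- length(markers)
  nm <- sigma_par_names(paste0("sigma", class), markers)
  m <- matrix(0, k, k)
  m[lower.tri(m, diag = TRUE)] <- draw[nm]
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

# extract the K x p beta matrix from a draw row
beta_from_draw <- function(draw, markers, covariates) {
  terms <- c("intercept", covariates, "d",
             if (length(covariates) > 0) paste0("d_", covariates))
  out <- matrix(NA_real_, length(markers), length(terms),
                dimnames = list(markers, terms))
  for (m in markers) {
    out[m, ] <- draw[paste0("beta_", m, "_", terms)]
  }
  out
}
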