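#' Posterior summary of a scalar chain
#'
#' Mean, median, SD, batch-means Monte Carlo error and the equal-tailed 95%
#' credible interval (2.5 and 97.5 percentiles).  The MC error uses
#' `floor(sqrt(N))` batches; for an (effectively) iid chain it is close to
#' `sd / sqrt(N)`, and it inflates appropriately for autocorrelated chains.
#'
#' @param chain numeric vector of at least 10 draws.
#' @param prob credible mass (default 0.95, equal tails).
#' @return A list with `mean`, `median`, `sd`, `mc_error`, `cri_low`,
#'   `cri_high`.
#' @export
posterior_summary <- function(chain, prob = 0.95) {
  if (!is.numeric(chain) || any(!is.finite(chain))) {
    stop2("`chain` must be numeric and finite")
  }
  if (length(chain) < 10L) stop2("need at least 10 draws")
  a <- (1 - prob) / 2
  ci <- unname(quantile(chain, c(a, 1 - a), type = 7))
  list(mean = mean(chain), median = median(chain), sd = sd(chain),
       mc_error = mc_error_batch(chain), cri_low = ci[1], cri_high = ci[2])
}

#' Batch-means Monte Carlo standard error
#'
#' Splits the chain into `floor(sqrt(N))` consecutive batches and returns
#' `sd(batch means) / sqrt(n_batches)`, the usual estimate of the standard
#' error of the posterior-mean estimate under serial correlation.
#'
#' @param chain numeric draw vector (>= 10 draws).
#' @return The Monte Carlo standard error (single number).
#' @export
mc_error_batch <- function(chain) {
  n <- length(chain)
  if (n < 10L) stop2("need at least 10 draws")
  nb <- floor(sqrt(n))
  bs <- n %/% nb
  used <- nb * bs
  bm <- colMeans(matrix(chain[seq_len(used)], nrow = bs))
  sd(bm) / sqrt(nb)
}

# spectral density at frequency zero via Bartlett-windowed autocovariances
spectrum0_bartlett <- function(x) {
  n <- length(x)
  l <- max(1L, floor(sqrt(n)))
  ac <- acf(x, lag.max = l, type = "covariance", plot = FALSE,
            demean = TRUE)$acf[, 1, 1]
  w <- 1 - seq_len(l) / (l + 1)
  ac[1] + 2 * sum(w * ac[-1])
}

#' Geweke convergence diagnostic
#'
#' Compares the mean of the first `frac_first` fraction of the chain with
#' the mean of the last `frac_last` fraction; the difference is divided by
#' its standard error, with window variances estimated from the spectral
#' density at frequency zero (Bartlett-windowed autocovariances) so that
#' serial correlation is accounted for.  For a stationary converged chain
#' the statistic is approximately standard normal; |z| > 3 flags
#' non-convergence.
#'
#' @param chain numeric draw vector.
#' @param frac_first,frac_last window fractions (defaults 0.1 and 0.5).
#' @return The z statistic (single number).
#' @export
geweke_z <- function(chain, frac_first = 0.1, frac_last = 0.5) {
  if (!is.numeric(chain) || any(!is.finite(chain))) {
    stop2("`chain` must be numeric and finite")
  }
  check_number(frac_first, "frac_first", 1e-6, 1)
  check_number(frac_last, "frac_last", 1e-6, 1)
  if (frac_first + frac_last > 1) {
    stop2("`frac_first` + `frac_last` must not exceed 1")
  }
  n <- length(chain)
  n1 <- floor(frac_first * n); n2 <- floor(frac_last * n)
  if (n1 < 20L || n2 < 20L) {
    stop2("chain too short: both windows need at least 20 draws")
  }
  x1 <- chain[seq_len(n1)]
  x2 <- chain[seq.int(n - n2 + 1L, n)]
  if (var(x1) <= 1e-300 || var(x2) <= 1e-300) {
    stop2("zero-variance window; Geweke statistic undefined")
  }
  v1 <- max(spectrum0_bartlett(x1), 1e-300)
  v2 <- max(spectrum0_bartlett(x2), 1e-300)
  (mean(x1) - mean(x2)) / sqrt(v1 / n1 + v2 / n2)
}

#' Sample autocorrelation function
#'
#' Autocorrelations at lags `0..max_lag`; the lag-0 value is exactly 1.
#'
#' @param chain numeric draw vector with positive variance.
#' @param max_lag largest lag (< length of chain).
#' @return Numeric vector of length `max_lag + 1`, named by lag.
#' @export
autocorrelation <- function(chain, max_lag = 40L) {
  if (!is.numeric(chain) || any(!is.finite(chain))) {
    stop2("`chain` must be numeric and finite")
  }
  if (max_lag >= length(chain)) stop2("`max_lag` must be < chain length")
  if (var(chain) <= 1e-300) stop2("zero-variance chain")
  out <- acf(chain, lag.max = max_lag, plot = FALSE,
             demean = TRUE)$acf[, 1, 1]
  out[1] <- 1
  names(out) <- 0:max_lag
  out
}

#' Convergence diagnostics report for a fit
#'
#' Per-parameter Geweke z and lag-1 autocorrelation (first chain), plus
#' posterior summaries pooled over chains.
#'
#' @param draws an `lcm_draws` object.
#' @return A data frame with one row per monitored parameter and columns
#'   `parameter`, `mean`, `median`, `sd`, `mc_error`, `cri_low`,
#'   `cri_high`, `geweke_z`, `acf_lag1`.
#' @export
diagnostics_report <- function(draws) {
  stopifnot(inherits(draws, "lcm_draws"))
  m <- draws_matrix(draws)
  first <- draws$chains[[1]]
  do.call(rbind, lapply(colnames(m), function(p) {
    s <- posterior_summary(m[, p])
    gz <- tryCatch(geweke_z(first[, p]), error = function(e) NA_real_)
    a1 <- tryCatch(autocorrelation(first[, p], 1L)[2L],
                   error = function(e) NA_real_)
    data.frame(parameter = p, mean = s$mean, median = s$median, sd = s$sd,
               mc_error = s$mc_error, cri_low = s$cri_low,
               cri_high = s$cri_high, geweke_z = gz,
               acf_lag1 = unname(a1))
  }))
}
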