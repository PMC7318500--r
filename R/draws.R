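#' MCMC run settings
#'
#' @param n_chains number of independent chains (>= 1).
#' @param n_iter total iterations per chain.
#' @param n_burnin burn-in iterations discarded per chain (< `n_iter`).
#' @param thin thinning interval (>= 1).
#' @param seed integer seed; chain `j` uses `seed + j - 1`.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_chains = 2L, n_iter = 10000L, n_burnin = 5000L,
                          thin = 1L, seed = 1L) {
  n_chains <- as.integer(n_chains); n_iter <- as.integer(n_iter)
  n_burnin <- as.integer(n_burnin); thin <- as.integer(thin)
  if (n_chains < 1L) stop2("`n_chains` must be >= 1")
  if (thin < 1L) stop2("`thin` must be >= 1")
  if (n_burnin < 0L || n_burnin >= n_iter) {
    stop2("`n_burnin` must satisfy 0 <= n_burnin < n_iter")
  }
  structure(list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                 thin = thin, seed = as.integer(seed)),
            class = "mcmc_settings")
}

new_lcm_draws <- function(chains, settings, model, meta = list(),
                          p_disease = NULL) {
  structure(list(chains = chains, settings = settings, model = model,
                 meta = meta, p_disease = p_disease),
            class = "lcm_draws")
}

#' Pooled draw matrix
#'
#' Row-binds the retained draws of all chains into one matrix
#' (draws x parameters).
#'
#' @param draws an `lcm_draws` object.
#' @return A numeric matrix with one column per monitored parameter.
#' @export
draws_matrix <- function(draws) {
  stopifnot(inherits(draws, "lcm_draws"))
  do.call(rbind, draws$chains)
}

#' @export
print.lcm_draws <- function(x, ...) {
  m <- draws_matrix(x)
  cat(sprintf("<lcm_draws: %s model, %d chain(s) x %d retained draws, %d parameters>\n",
              x$model, length(x$chains), nrow(x$chains[[1]]), ncol(m)))
  su <- t(vapply(colnames(m), function(p) {
    s <- posterior_summary(m[, p])
    c(mean = s$mean, sd = s$sd, `2.5%` = s$cri_low, `97.5%` = s$cri_high)
  }, numeric(4)))
  print(round(su, 4))
  invisible(x)
}

#' Export posterior draws as a long data frame / CSV
#'
#' Long format with columns `chain`, `iteration`, `parameter`, `value`.
#'
#' @param draws an `lcm_draws` object.
#' @param path optional CSV path; when given the data frame is also written.
#' @return The long-format data frame, invisibly when `path` is given.
#' @export
draws_long <- function(draws, path = NULL) {
  stopifnot(inherits(draws, "lcm_draws"))
  pieces <- lapply(seq_along(draws$chains), function(j) {
    m <- draws$chains[[j]]
    data.frame(chain = j,
               iteration = rep(seq_len(nrow(m)), times = ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  })
  out <- do.call(rbind, pieces)
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
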