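#' Single-marker binormal latent class parameters
#'
#' Container for the parameters of the two-class binormal model: prevalence
#' `pi`, class means `mu_d` (diseased) and `mu_nd` (non-diseased), and class
#' variances `var_d`, `var_nd`.  The identifiability convention is
#' `mu_d > mu_nd`; constructors accept any ordering, but model fits always
#' report the oriented parameterization.
#'
#' @param pi prevalence, in \[0, 1\].
#' @param mu_d,mu_nd class means on the marker scale (e.g. MOM).
#' @param var_d,var_nd class variances (> 0).
#' @return An object of class `single_marker_params`.
#' @examples
#' p <- single_marker_params(pi = 0.3, mu_d = 2, mu_nd = 0,
#'                           var_d = 1, var_nd = 1)
#' single_auc(p)
#' @export
single_marker_params <- function(pi, mu_d, mu_nd, var_d, var_nd) {
  check_number(pi, "pi", 0, 1)
  check_number(mu_d, "mu_d")
  check_number(mu_nd, "mu_nd")
  if (!is.numeric(var_d) || length(var_d) != 1L || !is.finite(var_d) ||
      var_d <= 0) {
    stop2("`var_d` must be a positive number")
  }
  if (!is.numeric(var_nd) || length(var_nd) != 1L || !is.finite(var_nd) ||
      var_nd <= 0) {
    stop2("`var_nd` must be a positive number")
  }
  structure(list(pi = pi, mu_d = mu_d, mu_nd = mu_nd,
                 var_d = var_d, var_nd = var_nd),
            class = "single_marker_params")
}

as_single_marker_params <- function(x) {
  if (inherits(x, "single_marker_params")) return(x)
  single_marker_params(pi = x[["pi"]] %||% 0.5, mu_d = x[["mu_d"]],
                       mu_nd = x[["mu_nd"]], var_d = x[["var_d"]],
                       var_nd = x[["var_nd"]])
}

#' Binormal AUC
#'
#' Area under the ROC curve for a marker that is normal within each latent
#' class: `AUC = pnorm((mu_d - mu_nd) / sqrt(var_d + var_nd))`.  Under the
#' orientation `mu_d >= mu_nd` the value lies in \[0.5, 1\].
#'
#' @param params a [single_marker_params()] object (or a list with the same
#'   fields).
#' @return AUC as a single probability.
#' @export
single_auc <- function(params) {
  p <- as_single_marker_params(params)
  pnorm((p$mu_d - p$mu_nd) / sqrt(p$var_d + p$var_nd))
}

#' Sensitivity and specificity at a cutoff
#'
#' For cutoff `c` (test positive when the marker exceeds `c`):
#' sensitivity `= 1 - pnorm((c - mu_d)/sd_d)` and specificity
#' `= pnorm((c - mu_nd)/sd_nd)`.  `c = -Inf` gives (1, 0) and `c = Inf`
#' gives (0, 1).
#'
#' @inheritParams single_auc
#' @param cutoff cutoff(s) on the marker scale; may be a vector and may
#'   contain `-Inf`/`Inf`.
#' @return A list with numeric components `sensitivity` and `specificity`,
#'   each the length of `cutoff`.
#' @export
se_sp_at_cutoff <- function(params, cutoff) {
  p <- as_single_marker_params(params)
  if (!is.numeric(cutoff) || any(is.na(cutoff))) {
    stop2("`cutoff` must be numeric and non-missing")
  }
  list(sensitivity = 1 - pnorm((cutoff - p$mu_d) / sqrt(p$var_d)),
       specificity = pnorm((cutoff - p$mu_nd) / sqrt(p$var_nd)))
}

# cutoff grid spanning both class distributions
cutoff_grid <- function(p, n_grid) {
  s <- sqrt(max(p$var_d, p$var_nd))
  lo <- min(p$mu_d, p$mu_nd) - 8 * s
  hi <- max(p$mu_d, p$mu_nd) + 8 * s
  seq(lo, hi, length.out = n_grid)
}

#' Binormal ROC curve
#'
#' Evaluates `(1 - specificity, sensitivity)` over an ascending cutoff grid
#' spanning both class distributions.  The first row is the (1, 1) corner
#' (cutoff at minus infinity side), the last approaches (0, 0).
#'
#' @inheritParams single_auc
#' @param n_grid number of grid points (>= 2); 2000 or more makes the
#'   trapezoidal area agree with [single_auc()] to about `1e-3`.
#' @return A data frame with columns `cutoff`, `fpr`, `tpr`; attribute
#'   `auc` holds the trapezoidal area.
#' @export
roc_curve <- function(params, n_grid = 2000L) {
  p <- as_single_marker_params(params)
  if (!is.numeric(n_grid) || length(n_grid) != 1L || n_grid < 2) {
    stop2("`n_grid` must be at least 2")
  }
  cc <- cutoff_grid(p, as.integer(n_grid))
  ss <- se_sp_at_cutoff(p, cc)
  out <- data.frame(cutoff = cc, fpr = 1 - ss$specificity,
                    tpr = ss$sensitivity)
  attr(out, "auc") <- trapezoid_area(out$fpr, out$tpr)
  out
}

# area under a (possibly descending-x) piecewise-linear curve
trapezoid_area <- function(x, y) {
  o <- order(x)
  x <- x[o]; y <- y[o]
  sum(diff(x) * (head_(y, -1) + tail_(y, -1)) / 2)
}
head_ <- function(x, n) x[seq_len(length(x) + n)]
tail_ <- function(x, n) x[seq.int(1 - n, length(x))]

# real roots of the normal density intersection equation f_nd(c) = f_d(c)
density_crossings <- function(p) {
  s1 <- sqrt(p$var_d); s0 <- sqrt(p$var_nd)
  a <- 1 / p$var_nd - 1 / p$var_d
  b <- -2 * (p$mu_nd / p$var_nd - p$mu_d / p$var_d)
  cc <- p$mu_nd^2 / p$var_nd - p$mu_d^2 / p$var_d - 2 * log(s1 / s0)
  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12) return(numeric(0))  # identical densities
    return(-cc / b)
  }
  disc <- b^2 - 4 * a * cc
  if (disc < 0) return(numeric(0))
  sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
}

#' Youden-optimal cutoff
#'
#' Cutoff maximizing the Youden index (sensitivity + specificity - 1).  The
#' stationary points satisfy equality of the two class densities, a
#' quadratic in the cutoff; the maximizing root is selected by evaluating
#' the index.  With equal variances this reduces to the midpoint of the
#' class means; a grid search fallback covers degenerate cases.
#'
#' @inheritParams single_auc
#' @return The optimal cutoff (single number).
#' @export
youden_cutoff <- function(params) {
  p <- as_single_marker_params(params)
  if (abs(p$var_d - p$var_nd) < 1e-10 * (p$var_d + p$var_nd)) {
    return((p$mu_d + p$mu_nd) / 2)
  }
  cand <- density_crossings(p)
  cand <- cand[is.finite(cand)]
  if (length(cand) == 0L) {
    cand <- cutoff_grid(p, 10001L)
  }
  j <- function(cc) {
    ss <- se_sp_at_cutoff(p, cc)
    ss$sensitivity + ss$specificity - 1
  }
  cand[which.max(j(cand))]
}

#' Overlap coefficient of the two fitted class distributions
#'
#' The overlap coefficient `OVL = integral of min(f_d, f_nd)` between the
#' diseased and non-diseased normal densities, a diagnostic of practical
#' identifiability of the latent class model.  Values near or above 0.5
#' indicate heavy overlap, where latent class estimation becomes unreliable;
#' below 0.5 separation is considered acceptable.
#'
#' Evaluation is closed-form: the real line is partitioned at the density
#' crossing points and the smaller density is integrated on each piece via
#' the normal CDF.
#'
#' @inheritParams single_auc
#' @param threshold flag boundary; overlap at or above it is flagged
#'   `"poor"`, below it `"acceptable"`.  Default 0.5.
#' @return A list with `delta` (the overlap proportion) and `flag`
#'   (`"acceptable"` or `"poor"`).
#' @export
overlap_delta <- function(params, threshold = 0.5) {
  p <- as_single_marker_params(params)
  cr <- density_crossings(p)
  bounds <- c(-Inf, cr, Inf)
  s1 <- sqrt(p$var_d); s0 <- sqrt(p$var_nd)
  total <- 0
  for (i in seq_len(length(bounds) - 1L)) {
    lo <- bounds[i]; hi <- bounds[i + 1L]
    mid <- if (is.infinite(lo) && is.infinite(hi)) 0 else
      if (is.infinite(lo)) hi - 1 else if (is.infinite(hi)) lo + 1 else
        (lo + hi) / 2
    # log scale: raw densities underflow to a spurious tie far in the tails
    f1 <- dnorm(mid, p$mu_d, s1, log = TRUE)
    f0 <- dnorm(mid, p$mu_nd, s0, log = TRUE)
    if (f1 <= f0) {
      total <- total + (pnorm(hi, p$mu_d, s1) - pnorm(lo, p$mu_d, s1))
    } else {
      total <- total + (pnorm(hi, p$mu_nd, s0) - pnorm(lo, p$mu_nd, s0))
    }
  }
  delta <- min(max(total, 0), 1)
  list(delta = delta,
       flag = if (delta >= threshold) "poor" else "acceptable")
}
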