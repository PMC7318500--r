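#' Kolmogorov-Smirnov normality preflight
#'
#' One-sample KS statistic of the values against a normal distribution
#' with moment-estimated mean and SD.  Because the parameters are
#' estimated from the same data the p-value is conservative; the check is
#' advisory (a warning below 0.05), not a gate, since the latent class
#' model assumes within-class rather than marginal normality.
#'
#' @param values numeric vector (>= 8 observations).
#' @param warn emit a warning when p < 0.05 (default TRUE).
#' @return A list with `statistic` and `p_value`.
#' @export
ks_normality <- function(values, warn = TRUE) {
  if (!is.numeric(values) || any(!is.finite(values))) {
    stop2("`values` must be numeric and finite")
  }
  if (length(values) < 8L) stop2("need at least 8 observations")
  kt <- suppressWarnings(ks.test(values, "pnorm", mean(values), sd(values)))
  if (warn && kt$p.value < 0.05) {
    warning(sprintf("KS normality check: p = %.3g < 0.05; the marginal %s",
                    kt$p.value,
                    "distribution deviates from normal"), call. = FALSE)
  }
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Default pipeline configuration
#'
#' Returns the default configuration list for [run_pipeline()]: a
#' synthetic three-marker cohort (uE3 oriented lower in disease), age and
#' BMI covariates, the bhCG anchor, all pair combinations plus the triple,
#' and classification at threshold 0.5.
#'
#' @param seed integer seed driving every stochastic stage.
#' @param n_iter,n_burnin,n_chains MCMC settings applied to every fit.
#' @return A named configuration list.
#' @export
default_pipeline_config <- function(seed = 1L, n_iter = 10000L,
                                    n_burnin = 5000L, n_chains = 2L) {
  list(
    cohort = list(synthetic = list(n = 523L, seed = seed)),
    markers = c("uE3", "bhCG", "AFP"),
    covariates = c("age", "bmi"),
    orientation = list(uE3 = "lower", bhCG = "higher", AFP = "higher"),
    anchor = "bhCG",
    anchor_sign = 1,
    combinations = TRUE,
    threshold = 0.5,
    x_ref = "mean",
    mcmc = list(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                thin = 1L),
    seed = as.integer(seed)
  )
}

#' Read a pipeline configuration file
#'
#' YAML (when the `yaml` package is available) or JSON; the file mirrors
#' the list accepted by [run_pipeline()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop2("reading YAML configs requires the `yaml` package")
    }
    return(yaml::read_yaml(path))
  }
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the full no-gold-standard accuracy pipeline
#'
#' Executes the complete analysis: read or simulate a cohort; KS normality
#' preflight per marker; single-marker latent class fit per marker with
#' per-marker accuracy summaries and the overlap diagnostic (a
#' "Table 1"-style report); the covariate-adjusted multivariate fit;
#' optimal-combination evaluation over all marker pairs and the full set
#' (a "Table 2"-style report); subject classification with the top-ranked
#' combination model; and convergence diagnostics for every monitored
#' parameter.  All outputs are written as plain CSV/text together with an
#' echo of the configuration and seed.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML/JSON config file.
#' @param out_dir output directory (created if needed); overrides
#'   `config$out_dir`.  `NULL` disables file output.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with elements `cohort`, `ks`, `table1`,
#'   `table2`, `single_fits`, `mvn_fit`, `combos`, `classification`,
#'   `diagnostics`, `converged`, `config`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  base <- default_pipeline_config()
  config <- utils::modifyList(base, config)
  out_dir <- out_dir %||% config$out_dir
  seed <- as.integer(config$seed %||% 1L)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop2(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
    say("stage %-12s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    out
  }
  mc <- config$mcmc
  markers <- config$markers

  ## cohort
  cohort <- stage("cohort", {
    if (!is.null(config$cohort$csv)) {
      read_cohort_csv(config$cohort$csv, markers = markers)
    } else {
      syn <- config$cohort$synthetic %||% list()
      syn$seed <- syn$seed %||% seed
      generate_cohort(do.call(cohort_config, syn))
    }
  })
  markers <- intersect(markers, names(cohort))
  if (length(markers) == 0L) stop2("no configured marker column present")
  covariates <- config$covariates

  ## preflight
  ks <- stage("preflight", {
    out <- lapply(markers, function(m) ks_normality(cohort[[m]]))
    names(out) <- markers
    out
  })

  ## single-marker fits (Table 1)
  single <- stage("single", {
    fits <- list()
    for (j in seq_along(markers)) {
      m <- markers[j]
      ori <- as.list(config$orientation)[[m]] %||% "higher"
      fits[[m]] <- fit_single_marker_lcm(
        cohort[[m]],
        mcmc = mcmc_settings(mc$n_chains, mc$n_iter, mc$n_burnin,
                             mc$thin %||% 1L, seed = seed + 100L + j),
        orientation = ori)
    }
    fits
  })
  acc <- lapply(single, marker_accuracy)
  table1 <- do.call(rbind, lapply(markers, function(m) {
    out <- acc[[m]]$summary
    cbind(marker = m, out, delta = acc[[m]]$delta$delta,
          delta_flag = acc[[m]]$delta$flag)
  }))
  rownames(table1) <- NULL

  ## multivariate fit + combinations (Table 2)
  mvn_fit <- NULL; combos <- NULL; table2 <- NULL; classification <- NULL
  if (isTRUE(config$combinations) && length(markers) >= 2L) {
    mvn_fit <- stage("joint", fit_mvn_lcm(
      cohort, markers, covariates,
      mcmc = mcmc_settings(mc$n_chains, mc$n_iter, mc$n_burnin,
                           mc$thin %||% 1L, seed = seed + 200L),
      anchor = if (!is.null(config$anchor) &&
                   config$anchor %in% markers) config$anchor else NULL,
      anchor_sign = config$anchor_sign))
    x_ref <- config$x_ref
    if (identical(x_ref, "mean")) x_ref <- NULL
    combos <- stage("combine",
                    evaluate_combinations(mvn_fit, x_ref = x_ref))
    table2 <- combos$table
    classification <- stage("classify",
                            classify_subjects(mvn_fit,
                                              config$threshold %||% 0.5))
  }

  ## diagnostics over every monitored parameter
  diag_tabs <- lapply(single, diagnostics_report)
  diagnostics <- do.call(rbind, c(
    lapply(markers, function(m) cbind(model = m, diag_tabs[[m]])),
    if (!is.null(mvn_fit)) list(cbind(model = "joint",
                                      diagnostics_report(mvn_fit)))))
  rownames(diagnostics) <- NULL
  gz <- diagnostics$geweke_z[is.finite(diagnostics$geweke_z)]
  frac_bad <- if (length(gz)) mean(abs(gz) > 3) else 0
  converged <- frac_bad <= 0.2
  if (!converged) {
    warning(sprintf("convergence flag: |Geweke z| > 3 for %.0f%% of %s",
                    100 * frac_bad, "monitored parameters"), call. = FALSE)
  }

  bundle <- list(cohort = cohort, ks = ks, table1 = table1,
                 table2 = table2, single_fits = single, mvn_fit = mvn_fit,
                 combos = combos, classification = classification,
                 diagnostics = diagnostics, converged = converged,
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(bundle, out_dir, acc)
  invisible(bundle)
}

write_pipeline_outputs <- function(bundle, out_dir, acc) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  num <- function(df) {
    # fixed-format numbers so identical runs are byte-identical
    df[] <- lapply(df, function(col)
      if (is.numeric(col)) sprintf("%.10g", col) else col)
    df
  }
  if (is.null(bundle$config$cohort$csv)) {
    write_cohort_csv(bundle$cohort, fp("cohort.csv"))
  }
  write.csv(num(bundle$table1), fp("table1.csv"), row.names = FALSE,
            quote = FALSE)
  if (!is.null(bundle$table2)) {
    write.csv(num(bundle$table2), fp("table2.csv"), row.names = FALSE,
              quote = FALSE)
  }
  write.csv(num(bundle$diagnostics), fp("diagnostics.csv"),
            row.names = FALSE, quote = FALSE)
  for (m in names(bundle$single_fits)) {
    fit <- bundle$single_fits[[m]]
    pm <- oriented_draw(colMeans(draws_matrix(fit)), fit$meta$orientation)
    write.csv(num(roc_curve(pm, 501L)[, c("fpr", "tpr")]),
              fp(sprintf("roc_%s.csv", m)), row.names = FALSE,
              quote = FALSE)
  }
  if (!is.null(bundle$combos)) {
    for (label in names(bundle$combos$details)) {
      d <- bundle$combos$details[[label]]
      mean_draw <- colMeans(draws_matrix(bundle$mvn_fit))
      idx <- match(d$markers, bundle$mvn_fit$meta$markers)
      pd <- subset_params(mean_draw, bundle$mvn_fit$meta$markers,
                          bundle$mvn_fit$meta$covariates,
                          bundle$combos$x_ref, idx)
      cr <- combined_roc(d$a, pd$mu0, pd$mu1, pd$sigma0, pd$sigma1, 501L)
      write.csv(num(cr[, c("fpr", "tpr")]),
                fp(sprintf("croc_%s.csv", gsub("\\+", "_", label))),
                row.names = FALSE, quote = FALSE)
    }
    cl <- bundle$classification
    write.csv(num(data.frame(subject_id = bundle$cohort$subject_id,
                             p_disease = cl$probabilities,
                             label = cl$labels)),
              fp("classification.csv"), row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(bundle$config, fp("config.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  writeLines(pipeline_report_text(bundle), fp("report.txt"))
  invisible(out_dir)
}

pipeline_report_text <- function(bundle) {
  li <- character(0)
  add <- function(...) li <<- c(li, sprintf(...))
  add("no-gold-standard diagnostic accuracy report")
  add("seed: %d   subjects: %d", bundle$config$seed, nrow(bundle$cohort))
  add("")
  add("KS normality preflight (advisory):")
  for (m in names(bundle$ks)) {
    add("  %-6s D = %.4f, p = %.3f%s", m, bundle$ks[[m]]$statistic,
        bundle$ks[[m]]$p_value,
        if (bundle$ks[[m]]$p_value < 0.05) "  [deviates from normal]" else "")
  }
  add("")
  add("single-marker accuracy (posterior mean [95%% CrI]):")
  t1 <- bundle$table1
  for (m in unique(t1$marker)) {
    rows <- t1[t1$marker == m, ]
    add("  %-6s Se %.2f [%.2f-%.2f]  Sp %.2f [%.2f-%.2f]  AUC %.2f [%.2f-%.2f]  delta %.2f (%s)",
        m,
        rows$mean[1], rows$cri_low[1], rows$cri_high[1],
        rows$mean[2], rows$cri_low[2], rows$cri_high[2],
        rows$mean[3], rows$cri_low[3], rows$cri_high[3],
        rows$delta[1], rows$delta_flag[1])
  }
  if (!is.null(bundle$combos)) {
    add("")
    add("combination ranking (posterior-mean cAUC):")
    for (i in seq_along(bundle$combos$details)) {
      d <- bundle$combos$details[[i]]
      add("  %d. %-18s cAUC %.3f  cSe %.3f  cSp %.3f", i,
          names(bundle$combos$details)[i], d$c_auc, d$c_se, d$c_sp)
    }
    cl <- bundle$classification
    add("")
    add("classification at threshold %.2f: %d/%d (%.1f%%) assigned to the diseased class",
        bundle$config$threshold %||% 0.5, cl$n_positive,
        length(cl$labels), 100 * cl$fraction_positive)
  }
  add("")
  add("convergence: %s", if (bundle$converged) "no flag" else
    "FLAG: |Geweke z| > 3 for more than 20% of parameters")
  li
}
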