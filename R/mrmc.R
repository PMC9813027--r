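## The central model fit: random-reader random-case comparison of reading
## modes on the reader-averaged empirical AUC.

#' Compare two reading modes on reader-averaged AUC
#'
#' The primary inference: observed per-reader and reader-averaged empirical
#' AUCs for both modes, their difference (mode B minus mode A), a
#' percentile bootstrap confidence interval and a two-sided bootstrap P
#' value from the patient-clustered two-way bootstrap.
#'
#' @inheritParams two_way_bootstrap
#' @return An object of class `mrmc_comparison`: list with `mode_a`,
#'   `mode_b`, `statistic`, `score_type`, `per_reader_a`, `per_reader_b`,
#'   `mean_a`, `mean_b`, `difference`, `ci_low`, `ci_high`, `p_value`,
#'   `alpha`, `n_effective_resamples`, `n_degenerate_skipped`, `seed`.
#' @seealso [mrmc()] for fitting several comparisons at once,
#'   [compare_binary()] for sensitivity/specificity contrasts.
#' @export
#' @examples
#' ds <- simulate_study(sim_config_small(), seed = 1)
#' compare_modes(ds, "DM", "AICAD_SM", spec = boot_spec(50, 10, seed = 1))
compare_modes <- function(ds, mode_a, mode_b,
                          score_type = c("pom", "birads"),
                          spec = boot_spec(), pool_negatives = FALSE) {
  score_type <- match.arg(score_type)
  bt <- two_way_bootstrap(ds, mode_a, mode_b, statistic = "auc",
                          score_type = score_type, spec = spec,
                          pool_negatives = pool_negatives)
  ci <- percentile_ci(bt$diffs, spec$alpha)
  structure(list(
    mode_a = mode_a, mode_b = mode_b, statistic = "auc",
    score_type = score_type, stratum = NULL,
    per_reader_a = bt$stat_a, per_reader_b = bt$stat_b,
    mean_a = mean(bt$stat_a), mean_b = mean(bt$stat_b),
    difference = mean(bt$stat_b) - mean(bt$stat_a),
    ci_low = unname(ci["low"]), ci_high = unname(ci["high"]),
    p_value = bootstrap_p(bt$diffs),
    alpha = spec$alpha,
    n_effective_resamples = length(bt$diffs),
    n_degenerate_skipped = bt$n_degenerate_skipped,
    seed = spec$seed),
    class = "mrmc_comparison")
}

#' @export
print.mrmc_comparison <- function(x, digits = 3, ...) {
  lab <- if (x$statistic == "auc")
    sprintf("reader-averaged AUC (%s scores)", x$score_type)
  else
    sprintf("%s [stratum %s]", x$statistic, x$stratum)
  cat(sprintf("MRMC comparison: %s vs %s on %s\n", x$mode_a, x$mode_b, lab))
  cat(sprintf("  %s: %.*f   %s: %.*f   difference: %.*f\n",
              x$mode_a, digits, x$mean_a, x$mode_b, digits, x$mean_b,
              digits, x$difference))
  cat(sprintf("  %d%% percentile CI: (%.*f, %.*f)   bootstrap P: %s\n",
              round(100 * (1 - x$alpha)), digits, x$ci_low, digits,
              x$ci_high, format.pval(x$p_value, digits = 2)))
  cat(sprintf("  %d resamples (seed %d); degenerate case resamples redrawn: %d\n",
              x$n_effective_resamples, x$seed, x$n_degenerate_skipped))
  invisible(x)
}

#' Serialize a comparison as JSON
#'
#' @param x an `mrmc_comparison`.
#' @param path optional output file.
#' @return JSON string (invisibly when written to `path`).
#' @export
comparison_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "mrmc_comparison"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Fit a multireader multicase modality analysis
#'
#' The package's central fitting function. For a fully crossed reader
#' study it computes every reader's empirical AUC under every reading
#' mode (for the requested score type) and runs the random-reader
#' random-case bootstrap comparison for each requested mode pair. The
#' default pairs are the two primary sequential contrasts of the study
#' design: 2D alone (DM vs AICAD_SM) and 2D + DBT (DM_DBT vs
#' AICAD_SM_DBT).
#'
#' @param data an [mrmc_study()] object.
#' @param comparisons list of length-2 character vectors `c(mode_a,
#'   mode_b)`; pairs missing from the dataset's modes are an error.
#' @param score_type `"pom"` or `"birads"`.
#' @param spec a [boot_spec()].
#' @param pool_negatives see [pom_score()].
#' @return An object of class `mrmc`: list with `auc` (readers x modes
#'   matrix of per-reader AUCs), `mean_auc` (named vector),
#'   `comparisons` (list of `mrmc_comparison`), `score_type`, `spec`,
#'   `metadata`, and `rocs` (reader-pooled `mrmc_roc` per mode, for
#'   plotting). Methods: `print`, `summary`, `coef` (reader-averaged
#'   AUCs), `plot` (reader-pooled ROC curves).
#' @export
#' @examples
#' ds <- simulate_study(sim_config_small(), seed = 1)
#' fit <- mrmc(ds, spec = boot_spec(50, 10, seed = 1))
#' fit
#' coef(fit)
mrmc <- function(data,
                 comparisons = list(c("DM", "AICAD_SM"),
                                    c("DM_DBT", "AICAD_SM_DBT")),
                 score_type = c("pom", "birads"),
                 spec = boot_spec(), pool_negatives = FALSE) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(data, "mrmc_study"))
  modes <- data$metadata$modes
  for (cp in comparisons) {
    if (length(cp) != 2L || !all(cp %in% modes))
      stop("comparison must be a pair of modes present in the dataset: ",
           paste(cp, collapse = " vs "))
  }
  readers <- data$metadata$readers
  auc <- sapply(modes, function(m)
    reader_auc_table(data, m, score_type, pool_negatives)$auc)
  auc <- matrix(auc, nrow = length(readers),
                dimnames = list(readers, modes))
  rocs <- lapply(modes, function(m) {
    sm <- score_matrix(data, m, score_type, pool_negatives)
    ## reader-pooled overall ROC: all readers' ratings concatenated
    empirical_roc(as.vector(sm$S), rep(sm$labels, ncol(sm$S)))
  })
  names(rocs) <- modes
  cmp <- lapply(comparisons, function(cp)
    compare_modes(data, cp[1], cp[2], score_type, spec, pool_negatives))
  structure(list(auc = auc, mean_auc = colMeans(auc), comparisons = cmp,
                 score_type = score_type, spec = spec,
                 metadata = data$metadata, rocs = rocs),
            class = "mrmc")
}

#' @export
print.mrmc <- function(x, digits = 3, ...) {
  cat(sprintf("MRMC analysis (%s scores): %d readers x %d cases, %d modes\n",
              x$score_type, nrow(x$auc), x$metadata$n_cases, ncol(x$auc)))
  tab <- rbind(x$auc, mean = x$mean_auc)
  print(round(tab, digits))
  cat("\n")
  for (cp in x$comparisons) print(cp, digits = digits)
  invisible(x)
}

#' @export
summary.mrmc <- function(object, ...) {
  structure(list(fit = object), class = "summary.mrmc")
}

#' @export
print.summary.mrmc <- function(x, digits = 3, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("Reader-pooled empirical AUCs:\n")
  print(round(vapply(f$rocs, function(r) r$auc, numeric(1)), digits))
  invisible(x)
}

#' @export
coef.mrmc <- function(object, ...) {
  object$mean_auc
}

#' @export
plot.mrmc <- function(x, modes = colnames(x$auc),
                      col = seq_along(modes), lty = 1, ...) {
  first <- TRUE
  col <- rep_len(col, length(modes))
  lty <- rep_len(lty, length(modes))
  for (i in seq_along(modes)) {
    plot(x$rocs[[modes[i]]], add = !first, col = col[i], lty = lty[i], ...)
    first <- FALSE
  }
  graphics::legend("bottomright",
                   legend = sprintf("%s (AUC %.3f)", modes,
                                    vapply(x$rocs[modes], function(r) r$auc,
                                           numeric(1))),
                   col = col, lty = lty, bty = "n")
  invisible(x)
}
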