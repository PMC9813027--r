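## Report assembly: the study-shaped tables and derived arithmetic.
## Rounding convention: full precision internally; half-up rounding applied
## once, at serialization (3 dp for AUCs, 1 dp for percentages).

#' Round half-up
#'
#' Decimal rounding with ties away from zero (0.8945 -> 0.895 at 3 dp),
#' the serialization rule for every printed table. Base `round()` uses
#' round-half-even and would print 0.894. A small epsilon absorbs binary
#' floating-point representation error of decimal inputs.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
#' @examples
#' round_half_up(0.8945, 3)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Per-reader AUC grid for every mode and score type
#'
#' The per-reader AUC table of a fully crossed study: one row per reader
#' plus an unweighted mean row, one column per score type x mode. The mean
#' row is recomputed from the per-reader values and checked before the
#' object is returned.
#'
#' @param ds an [mrmc_study()] object.
#' @param modes modes to tabulate (default: all in the dataset).
#' @param pool_negatives see [pom_score()].
#' @return An object of class `mrmc_table1`: data frame with a `reader`
#'   column and columns `pom_<mode>`, `birads_<mode>`, rows the readers
#'   plus `"mean"`. Values are full precision; `print` applies 3-dp
#'   half-up rounding.
#' @export
build_table1 <- function(ds, modes = NULL, pool_negatives = FALSE) {
  stopifnot(inherits(ds, "mrmc_study"))
  if (is.null(modes)) modes <- ds$metadata$modes
  readers <- ds$metadata$readers
  cols <- list()
  for (st in c("pom", "birads")) {
    for (m in modes) {
      cols[[paste(st, m, sep = "_")]] <-
        reader_auc_table(ds, m, st, pool_negatives)$auc
    }
  }
  tab <- as.data.frame(cols)
  mean_row <- colMeans(tab)
  stopifnot(all(abs(mean_row - vapply(tab, mean, numeric(1))) < 1e-12))
  tab <- rbind(tab, mean_row)
  out <- cbind(data.frame(reader = c(readers, "mean"),
                          stringsAsFactors = FALSE), tab)
  rownames(out) <- NULL
  structure(out, class = c("mrmc_table1", "data.frame"))
}

#' @export
print.mrmc_table1 <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(v)
    format(round_half_up(v, digits), nsmall = digits))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Sensitivity/specificity grid across strata and modes
#'
#' One row per stratum (overall, density, lesion-type groups), sensitivity
#' and specificity per mode at the BI-RADS >= 4 positivity rule, pooled
#' over readers. Values are proportions; `print` shows percentages at 1
#' decimal (half-up).
#'
#' @param ds an [mrmc_study()] object.
#' @param modes modes to tabulate.
#' @param strata strata to tabulate; see [binary_perf()].
#' @return An object of class `mrmc_table2`: data frame with columns
#'   `stratum`, `n_cases`, then `sens_<mode>` and `spec_<mode>`.
#' @export
build_table2 <- function(ds, modes = NULL,
                         strata = c("overall", "non_dense", "dense",
                                    "soft_tissue", "calcification")) {
  stopifnot(inherits(ds, "mrmc_study"))
  if (is.null(modes)) modes <- ds$metadata$modes
  rows <- lapply(strata, function(s) {
    memb <- stratum_members(ds$truth, s)
    n_cases <- if (s %in% c("overall", .density_levels)) {
      if (s == "overall") nrow(ds$truth) else sum(ds$truth$density == s)
    } else {
      ft <- switch(s, soft_tissue = .soft_tissue_findings,
                   calcification = "calcification",
                   distortion = "distortion")
      sum(ds$truth$finding_type %in% ft)
    }
    out <- list(stratum = s, n_cases = n_cases)
    for (m in modes) {
      bp <- binary_perf(ds, m, s)
      out[[paste0("sens_", m)]] <- bp$sensitivity
      out[[paste0("spec_", m)]] <- bp$specificity
    }
    as.data.frame(out, stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("mrmc_table2", "data.frame"))
}

#' @export
print.mrmc_table2 <- function(x, digits = 1, ...) {
  y <- as.data.frame(x)
  pc <- grepl("^(sens|spec)_", names(y))
  y[pc] <- lapply(y[pc], function(v)
    ifelse(is.na(v), "—",
           format(round_half_up(100 * v, digits), nsmall = digits)))
  print(y, row.names = FALSE)
  invisible(x)
}

#' Per-lesion reader-mean BI-RADS scores
#'
#' For each lesion of the requested finding type and truth class, the
#' arithmetic mean of the readers' forced BI-RADS categories under each
#' requested mode — the per-lesion view used to contrast how two 2D image
#' types render malignant calcifications.
#'
#' @param ds an [mrmc_study()] object.
#' @param finding finding type(s) to include.
#' @param truth_class truth class to include.
#' @param modes modes to tabulate.
#' @return Data frame with `case_id`, `finding_type`, `lesion_size_mm`
#'   and one `mean_birads_<mode>` column per mode.
#' @export
#' @examples
#' ds <- simulate_study(sim_config_small(), seed = 1)
#' mean_birads_per_lesion(ds, modes = c("DM", "AICAD_SM"))
mean_birads_per_lesion <- function(ds, finding = "calcification",
                                   truth_class = "malignant",
                                   modes = c("DM", "AICAD_SM")) {
  stopifnot(inherits(ds, "mrmc_study"))
  keep <- ds$truth$finding_type %in% finding &
    ds$truth$truth %in% truth_class
  out <- ds$truth[keep, c("case_id", "finding_type", "lesion_size_mm")]
  rownames(out) <- NULL
  for (m in modes) {
    sm <- score_matrix(ds, m, "birads")
    out[[paste0("mean_birads_", m)]] <-
      rowMeans(sm$S)[match(out$case_id, sm$case_ids)]
  }
  out
}

#' Dose arithmetic for a combined 2D + DBT examination
#'
#' Given per-view mean glandular doses for the 2D mammogram and the DBT
#' acquisition: the combined dose, the combined-to-2D ratio, and the
#' fraction of the combined dose attributable to the 2D image — the dose
#' saved when a synthesized mammogram replaces the 2D acquisition.
#'
#' @param dm_dose 2D mammogram dose (mGy), positive.
#' @param dbt_dose DBT dose (mGy), positive.
#' @return An object of class `dose_metrics`: list with `combined`,
#'   `ratio_combined_to_dm` and `sm_dbt_fraction` (a proportion), full
#'   precision; `print` shows the conventional 1-dp ratio and 0-dp
#'   percentage.
#' @export
#' @examples
#' derived_dose_metrics(1.12, 1.62)
derived_dose_metrics <- function(dm_dose, dbt_dose) {
  if (!is.numeric(dm_dose) || !is.numeric(dbt_dose) ||
      dm_dose <= 0 || dbt_dose <= 0)
    stop("doses must be positive numbers")
  combined <- dm_dose + dbt_dose
  structure(list(combined = combined,
                 ratio_combined_to_dm = combined / dm_dose,
                 sm_dbt_fraction = dm_dose / combined),
            class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf("Combined 2D + DBT dose: %.2f mGy (%.1f x the 2D dose); replacing the 2D acquisition saves %.0f%% of the combined dose\n",
              x$combined, round_half_up(x$ratio_combined_to_dm, 1),
              round_half_up(100 * x$sm_dbt_fraction, 0)))
  invisible(x)
}

#' Assemble a full study report
#'
#' Runs the whole pipeline on a fully crossed study: the per-reader AUC
#' grid, the stratified sensitivity/specificity grid, the per-lesion
#' calcification view, and the requested bootstrap mode comparisons.
#'
#' @param ds an [mrmc_study()] object.
#' @param comparisons list of mode pairs for [compare_modes()].
#' @param score_type score scale for the comparisons.
#' @param spec a [boot_spec()].
#' @return An object of class `mrmc_report`: list with `table1`,
#'   `table2`, `table3`, `comparisons`, `provenance`.
#' @export
study_report <- function(ds,
                         comparisons = list(c("DM", "AICAD_SM"),
                                            c("DM_DBT", "AICAD_SM_DBT")),
                         score_type = c("pom", "birads"),
                         spec = boot_spec()) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(ds, "mrmc_study"))
  cmp <- lapply(comparisons, function(cp)
    compare_modes(ds, cp[1], cp[2], score_type, spec))
  structure(list(
    table1 = build_table1(ds),
    table2 = build_table2(ds),
    table3 = mean_birads_per_lesion(ds),
    comparisons = cmp,
    provenance = list(metadata = ds$metadata,
                      boot_spec = unclass(spec),
                      score_type = score_type,
                      package_version =
                        as.character(utils::packageVersion("mrmcboot")))),
    class = "mrmc_report")
}

#' @export
print.mrmc_report <- function(x, ...) {
  cat("== Per-reader AUCs ==\n")
  print(x$table1)
  cat("\n== Sensitivity / specificity by stratum (%) ==\n")
  print(x$table2)
  cat("\n== Reader-mean BI-RADS, malignant calcification lesions ==\n")
  print(x$table3, row.names = FALSE)
  cat("\n== Modality comparisons ==\n")
  for (cp in x$comparisons) print(cp)
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `table1.csv`, `table2.csv`, `table3.csv` (rounded at the
#' serialization rule: 3-dp AUCs, 1-dp percentages, 2-dp mean BI-RADS),
#' `comparisons.json` (full precision) and `report.txt` (the printed
#' report).
#'
#' @param report an `mrmc_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the output paths.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mrmc_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  t1 <- as.data.frame(report$table1)
  num <- vapply(t1, is.numeric, logical(1))
  t1[num] <- lapply(t1[num], round_half_up, digits = 3)
  utils::write.csv(t1, file.path(dir, "table1.csv"), row.names = FALSE)
  t2 <- as.data.frame(report$table2)
  pc <- grepl("^(sens|spec)_", names(t2))
  t2[pc] <- lapply(t2[pc], function(v) round_half_up(100 * v, 1))
  utils::write.csv(t2, file.path(dir, "table2.csv"), row.names = FALSE,
                   na = "")
  t3 <- report$table3
  mb <- grepl("^mean_birads_", names(t3))
  t3[mb] <- lapply(t3[mb], round_half_up, digits = 2)
  utils::write.csv(t3, file.path(dir, "table3.csv"), row.names = FALSE,
                   na = "")
  cmp <- lapply(report$comparisons, unclass)
  writeLines(jsonlite::toJSON(list(comparisons = cmp,
                                   provenance = report$provenance),
                              auto_unbox = TRUE, pretty = TRUE,
                              digits = NA, null = "null"),
             file.path(dir, "comparisons.json"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(file.path(dir, c("table1.csv", "table2.csv", "table3.csv",
                             "comparisons.json", "report.txt")))
}
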