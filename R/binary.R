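## Sensitivity / specificity at the BI-RADS 4-5 positivity rule.
##
## The reference standard dichotomizes assessments as positive (BI-RADS
## 4-5) vs negative (BI-RADS 1-3); truth is binary (malignant vs
## benign-biopsy + normal-negative). Performance is pooled over readers
## (total counts); with a fully crossed design this coincides with the
## reader average.

.stratum_levels <- c("overall", "non_dense", "dense", "soft_tissue",
                     "calcification", "distortion")
.soft_tissue_findings <- c("mass", "mass_calc", "focal_asymmetry")

#' Dichotomize a BI-RADS assessment
#'
#' Positive iff BI-RADS >= 4 (categories 4-5); BI-RADS 1-3 are negative.
#'
#' @param bi_rads integer vector of BI-RADS categories.
#' @return Logical vector, `TRUE` = positive.
#' @export
#' @examples
#' classify_positive(c(1, 3, 4, 5))
classify_positive <- function(bi_rads) {
  bi_rads >= 4
}

## Internal: denominator case sets for a stratum.
##   sens_ids — malignant cases of the stratum (sensitivity denominator);
##   spec_ids — non-malignant denominator. Density strata and "overall"
##   use all non-malignant breasts; lesion-type strata use only the benign
##   lesions of that type group (finding type is a lesion attribute, so
##   normal-negative breasts do not enter).
stratum_members <- function(truth, stratum) {
  stratum <- match.arg(stratum, .stratum_levels)
  mal <- truth$truth == "malignant"
  if (stratum == "overall") {
    keep <- rep(TRUE, nrow(truth))
    spec_keep <- !mal
  } else if (stratum %in% .density_levels) {
    keep <- truth$density == stratum
    spec_keep <- keep & !mal
  } else {
    ft <- switch(stratum,
                 soft_tissue = .soft_tissue_findings,
                 calcification = "calcification",
                 distortion = "distortion")
    keep <- truth$finding_type %in% ft
    spec_keep <- keep & truth$truth == "benign_biopsy"
  }
  list(sens_ids = truth$case_id[keep & mal],
       spec_ids = truth$case_id[spec_keep])
}

#' Sensitivity and specificity in a case stratum
#'
#' Counts are pooled over readers: `tp + fn` equals the number of
#' malignant breasts in the stratum times the number of readers.
#' Strata: `"overall"`, the density values `"non_dense"`/`"dense"`, the
#' lesion-type groups `"soft_tissue"` (mass, mass with calcifications,
#' focal asymmetry) and `"calcification"`, and `"distortion"` (reported
#' descriptively, outside the two named lesion groups). For lesion-type
#' strata the specificity denominator is the benign lesions of that group
#' only; for `"overall"` and the density strata it is all non-malignant
#' breasts.
#'
#' An empty denominator yields `NA` for that metric together with a
#' `sensitivity_defined` / `specificity_defined` flag — never a silent
#' `NaN`.
#'
#' @param ds an [mrmc_study()] object, fully crossed for `mode`.
#' @param mode reading mode.
#' @param stratum one of the strata above.
#' @return An object of class `binary_perf`: list with `stratum`, `mode`,
#'   counts `tp`, `fn`, `tn`, `fp`, `sensitivity`, `specificity` and the
#'   two `_defined` flags.
#' @export
#' @examples
#' ds <- simulate_study(sim_config_small(), seed = 1)
#' binary_perf(ds, "DM", "overall")
binary_perf <- function(ds, mode, stratum = "overall") {
  stopifnot(inherits(ds, "mrmc_study"))
  stratum <- match.arg(stratum, .stratum_levels)
  sm <- score_matrix(ds, mode, "birads")
  memb <- stratum_members(ds$truth, stratum)
  pos <- sm$S >= 4
  sens_rows <- sm$case_ids %in% memb$sens_ids
  spec_rows <- sm$case_ids %in% memb$spec_ids
  tp <- sum(pos[sens_rows, , drop = FALSE])
  fn <- sum(!pos[sens_rows, , drop = FALSE])
  fp <- sum(pos[spec_rows, , drop = FALSE])
  tn <- sum(!pos[spec_rows, , drop = FALSE])
  structure(list(
    stratum = stratum, mode = mode,
    tp = tp, fn = fn, tn = tn, fp = fp,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    sensitivity_defined = (tp + fn) > 0,
    specificity_defined = (tn + fp) > 0),
    class = "binary_perf")
}

#' @export
print.binary_perf <- function(x, ...) {
  fmt <- function(v, def) if (def) sprintf("%.1f%%", 100 * v) else "undefined"
  cat(sprintf("Binary performance [%s, %s]: sensitivity %s (tp %d / fn %d), specificity %s (tn %d / fp %d)\n",
              x$mode, x$stratum,
              fmt(x$sensitivity, x$sensitivity_defined), x$tp, x$fn,
              fmt(x$specificity, x$specificity_defined), x$tn, x$fp))
  invisible(x)
}

#' Paired bootstrap comparison of sensitivity or specificity
#'
#' Contrasts two reading modes on a proportion metric with the same
#' patient-clustered two-way bootstrap used for AUC comparisons
#' ([two_way_bootstrap()] with the proportion statistic): percentile CI
#' and two-sided bootstrap P for the reader-averaged difference
#' (mode B minus mode A).
#'
#' @inheritParams two_way_bootstrap
#' @param metric `"sensitivity"` or `"specificity"`.
#' @return An object of class `mrmc_comparison` (see [compare_modes()]),
#'   with the observed pooled proportions as the mode summaries.
#' @export
compare_binary <- function(ds, mode_a, mode_b,
                           metric = c("sensitivity", "specificity"),
                           stratum = "overall", spec = boot_spec()) {
  metric <- match.arg(metric)
  bt <- two_way_bootstrap(ds, mode_a, mode_b, statistic = metric,
                          stratum = stratum, spec = spec)
  ci <- percentile_ci(bt$diffs, spec$alpha)
  structure(list(
    mode_a = mode_a, mode_b = mode_b, statistic = metric,
    score_type = NULL, stratum = stratum,
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
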