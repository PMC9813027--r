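## Random-reader random-case inference via a two-way bootstrap.
##
## Cases are resampled as patient clusters (both breasts of a resampled
## patient enter with all their ratings) and, nested within each case
## resample, reader identities are resampled with replacement. The paired
## statistic difference (mode B minus mode A) is evaluated on the SAME
## resampled cases and readers for both modes, so shared case/reader
## variation cancels exactly as in the paired study design.

#' Bootstrap specification
#'
#' @param n_case_resamples number of case (patient-cluster) resamples;
#'   the reference analysis uses 1000.
#' @param n_reader_resamples number of reader resamples nested within each
#'   case resample; the reference analysis uses 100 (total 100,000).
#' @param cluster `"patient"` (default; both breasts of a patient are
#'   resampled together, reflecting within-patient correlation) or
#'   `"breast"` (each breast its own cluster, for sensitivity analysis).
#' @param seed master RNG seed; a single sequential stream drawn from this
#'   seed makes every result reproducible.
#' @param alpha two-sided confidence level complement (default 0.05 for a
#'   95% percentile interval).
#' @param max_redraws bound on redraws of degenerate case resamples
#'   (resamples on which the statistic is undefined, e.g. single-class).
#' @return An object of class `boot_spec`.
#' @export
boot_spec <- function(n_case_resamples = 1000L, n_reader_resamples = 100L,
                      cluster = c("patient", "breast"), seed = 1L,
                      alpha = 0.05, max_redraws = 1000L) {
  cluster <- match.arg(cluster)
  stopifnot(n_case_resamples >= 1, n_reader_resamples >= 1,
            alpha > 0, alpha < 1, max_redraws >= 1)
  structure(list(n_case_resamples = as.integer(n_case_resamples),
                 n_reader_resamples = as.integer(n_reader_resamples),
                 cluster = cluster, seed = as.integer(seed),
                 alpha = alpha, max_redraws = as.integer(max_redraws)),
            class = "boot_spec")
}

#' @export
print.boot_spec <- function(x, ...) {
  cat(sprintf("Two-way bootstrap spec: %d case resamples x %d reader resamples = %d total; cluster = %s; alpha = %g; seed = %d\n",
              x$n_case_resamples, x$n_reader_resamples,
              x$n_case_resamples * x$n_reader_resamples,
              x$cluster, x$alpha, x$seed))
  invisible(x)
}

## Internal: draw one case resample as a vector of case row indices.
## cl_mat-free design: cl_list maps cluster -> case indices; every drawn
## cluster contributes all of its cases.
resample_clusters <- function(cl_list) {
  k <- length(cl_list)
  unlist(cl_list[sample.int(k, k, replace = TRUE)], use.names = FALSE)
}

## Internal: per-reader statistic matrices for the bootstrap.
## For "auc": S_a/S_b are score matrices and labels is the truth vector.
## For proportions: C_a/C_b are 0/1 "metric success" matrices and
## `eligible` restricts to the stratum's denominator cases.
boot_prep <- function(ds, mode_a, mode_b, statistic, score_type,
                      stratum, pool_negatives) {
  if (statistic == "auc") {
    pa <- score_matrix(ds, mode_a, score_type, pool_negatives)
    pb <- score_matrix(ds, mode_b, score_type, pool_negatives)
    list(type = "auc", A = pa$S, B = pb$S, labels = pa$labels,
         eligible = NULL, patient = pa$patient, readers = pa$readers)
  } else {
    pa <- score_matrix(ds, mode_a, "birads")
    pb <- score_matrix(ds, mode_b, "birads")
    memb <- stratum_members(ds$truth, stratum)
    ids <- if (statistic == "sensitivity") memb$sens_ids else memb$spec_ids
    if (length(ids) == 0L)
      stop("statistic '", statistic, "' undefined: stratum '", stratum,
           "' has an empty denominator")
    eligible <- ds$truth$case_id %in% ids
    pos_a <- pa$S >= 4          # classify positive at BI-RADS >= 4
    pos_b <- pb$S >= 4
    if (statistic == "sensitivity") {
      A <- pos_a * 1; B <- pos_b * 1
    } else {
      A <- (!pos_a) * 1; B <- (!pos_b) * 1
    }
    list(type = "prop", A = A, B = B, labels = NULL,
         eligible = eligible, patient = pa$patient, readers = pa$readers)
  }
}

## Per-reader statistic on a case resample; returns length-R vectors for
## both modes or NULL if the resample is degenerate.
boot_stat <- function(prep, idx) {
  R <- length(prep$readers)
  if (prep$type == "auc") {
    lab <- prep$labels[idx]
    if (all(lab == 1L) || all(lab == 0L)) return(NULL)
    a <- vapply(seq_len(R), function(r) auc_mw(prep$A[idx, r], lab),
                numeric(1))
    b <- vapply(seq_len(R), function(r) auc_mw(prep$B[idx, r], lab),
                numeric(1))
  } else {
    ide <- idx[prep$eligible[idx]]
    if (length(ide) == 0L) return(NULL)
    a <- colMeans(prep$A[ide, , drop = FALSE])
    b <- colMeans(prep$B[ide, , drop = FALSE])
  }
  list(a = a, b = b)
}

#' Two-way (cases x readers) clustered bootstrap of a paired statistic
#'
#' For each of `n_case_resamples` draws, patient clusters are resampled
#' with replacement (a drawn patient contributes both breasts and all
#' their ratings); nested within, `n_reader_resamples` reader resamples
#' are drawn with replacement, a duplicated reader contributing its
#' statistic multiply to the reader average. The reader-averaged statistic
#' difference (mode B minus mode A) is computed on identical case and
#' reader draws for both modes. Degenerate case resamples (statistic
#' undefined, e.g. a single truth class) are redrawn and counted.
#'
#' @param ds an [mrmc_study()] object, fully crossed for both modes.
#' @param mode_a,mode_b the two reading modes to contrast.
#' @param statistic `"auc"` (reader-averaged empirical AUC),
#'   `"sensitivity"` or `"specificity"` (reader-averaged proportion at the
#'   BI-RADS >= 4 positivity rule).
#' @param score_type score scale for `statistic = "auc"`; see
#'   [pom_score()] and [birads_score()].
#' @param stratum case stratum for the proportion statistics; see
#'   [binary_perf()].
#' @param spec a [boot_spec()].
#' @param pool_negatives see [pom_score()].
#' @return An object of class `mrmc_boot`: list with `diffs` (vector of
#'   `n_case_resamples * n_reader_resamples` bootstrap differences),
#'   `stat_a`, `stat_b` (observed per-reader statistics), `n_degenerate_skipped`,
#'   and the `spec`.
#' @export
two_way_bootstrap <- function(ds, mode_a, mode_b,
                              statistic = c("auc", "sensitivity",
                                            "specificity"),
                              score_type = c("pom", "birads"),
                              stratum = "overall",
                              spec = boot_spec(),
                              pool_negatives = FALSE) {
  statistic <- match.arg(statistic)
  score_type <- match.arg(score_type)
  stopifnot(inherits(spec, "boot_spec"))
  prep <- boot_prep(ds, mode_a, mode_b, statistic, score_type, stratum,
                    pool_negatives)
  n <- nrow(prep$A)
  R <- length(prep$readers)
  cl_key <- if (spec$cluster == "patient") prep$patient else seq_len(n)
  cl_list <- split(seq_len(n), cl_key)

  obs <- boot_stat(prep, seq_len(n))
  if (is.null(obs))
    stop("statistic undefined on the observed dataset")

  B1 <- spec$n_case_resamples
  B2 <- spec$n_reader_resamples
  diffs <- numeric(B1 * B2)
  n_degenerate <- 0L
  set.seed(spec$seed)
  for (b in seq_len(B1)) {
    st <- NULL
    tries <- 0L
    while (is.null(st)) {
      idx <- resample_clusters(cl_list)
      st <- boot_stat(prep, idx)
      if (is.null(st)) {
        n_degenerate <- n_degenerate + 1L
        tries <- tries + 1L
        if (tries > spec$max_redraws)
          stop("exceeded max_redraws (", spec$max_redraws,
               ") degenerate case resamples")
      }
    }
    d <- st$b - st$a
    W <- matrix(sample.int(R, B2 * R, replace = TRUE), B2, R)
    diffs[((b - 1L) * B2 + 1L):(b * B2)] <-
      rowMeans(matrix(d[W], B2, R))
  }
  structure(list(diffs = diffs, stat_a = obs$a, stat_b = obs$b,
                 n_degenerate_skipped = n_degenerate, spec = spec,
                 statistic = statistic, mode_a = mode_a, mode_b = mode_b),
            class = "mrmc_boot")
}

#' Percentile confidence interval
#'
#' Nearest-rank empirical quantiles of the bootstrap distribution: with
#' `B` sorted values, the interval is the `ceiling(alpha/2 * B)`-th and
#' `ceiling((1 - alpha/2) * B)`-th order statistics (ranks clamped to
#' `[1, B]`). With `alpha = 0.1` and `B = 100` this is the 5th and 95th
#' order statistic.
#'
#' @param boot_diffs numeric vector of bootstrap statistic values.
#' @param alpha two-sided level complement (default 0.05).
#' @return Numeric `c(low, high)`.
#' @export
percentile_ci <- function(boot_diffs, alpha = 0.05) {
  stopifnot(length(boot_diffs) >= 1, alpha > 0, alpha < 1)
  s <- sort(boot_diffs)
  B <- length(s)
  lo <- min(max(1L, ceiling(alpha / 2 * B)), B)
  hi <- min(max(1L, ceiling((1 - alpha / 2) * B)), B)
  c(low = s[lo], high = s[hi])
}

#' Two-sided bootstrap percentile P value
#'
#' `p = 2 * min((#\{d <= 0\} + 1) / (B + 1), (#\{d >= 0\} + 1) / (B + 1))`,
#' capped at 1. The +1 correction keeps the P value strictly positive
#' (smallest attainable value `2 / (B + 1)`).
#'
#' @param boot_diffs numeric vector of bootstrap differences.
#' @return A number in (0, 1].
#' @export
bootstrap_p <- function(boot_diffs) {
  stopifnot(length(boot_diffs) >= 1)
  B <- length(boot_diffs)
  p <- 2 * min(sum(boot_diffs <= 0) + 1, sum(boot_diffs >= 0) + 1) / (B + 1)
  min(1, p)
}
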