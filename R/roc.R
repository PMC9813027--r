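## Empirical ROC analysis.
##
## Scores are oriented so that larger = more suspicious. Two score types:
##   pom    — the POM rating (0-100) for BI-RADS >= 3, with BI-RADS 1 and 2
##            mapped below every POM value (reference encoding -2, -1);
##   birads — the forced BI-RADS category itself (1-5).
## The empirical ROC sweeps distinct score thresholds (positive when
## score >= threshold); AUC is the trapezoidal area, identical to the
## tie-corrected Mann-Whitney pair statistic.

#' POM-based common-scale score
#'
#' The elicitation protocol records a POM (0-100) only for BI-RADS >= 3, so
#' the POM-based ROC needs a completed scale: BI-RADS 1 maps to -2 and
#' BI-RADS 2 to -1, placing non-elicited cases below every POM value while
#' preserving the 1 < 2 ordering. Any strictly order-preserving encoding
#' yields the same empirical ROC; this one is the package's reference.
#' `pool_negatives = TRUE` collapses BI-RADS 1 and 2 to a single value (-1)
#' for sensitivity analysis.
#'
#' @param bi_rads integer vector of BI-RADS categories (1-5).
#' @param pom integer vector of POM ratings, `NA` where not elicited.
#' @param pool_negatives collapse BI-RADS 1 and 2 to one tie group?
#' @return Numeric score vector; an error if a BI-RADS >= 3 rating lacks a
#'   POM.
#' @export
#' @examples
#' pom_score(c(1, 2, 3, 4), c(NA, NA, 0, 65))
pom_score <- function(bi_rads, pom, pool_negatives = FALSE) {
  stopifnot(length(bi_rads) == length(pom))
  if (any(bi_rads >= 3 & is.na(pom)))
    stop("BI-RADS >= 3 rating without a POM value")
  low <- if (pool_negatives) c(-1, -1) else c(-2, -1)
  ifelse(bi_rads <= 2, low[bi_rads], as.numeric(pom))
}

#' Forced BI-RADS ordinal score
#'
#' The secondary analysis scale: the BI-RADS category itself as an ordinal
#' score (1-5), giving an empirical ROC with at most 4 interior operating
#' points.
#'
#' @param bi_rads integer vector of BI-RADS categories.
#' @return Numeric score vector.
#' @export
birads_score <- function(bi_rads) {
  as.numeric(bi_rads)
}

## Fast tie-corrected Mann-Whitney AUC (midranks); the bootstrap hot path.
auc_mw <- function(scores, labels) {
  np <- sum(labels)
  nn <- length(labels) - np
  if (np == 0L || nn == 0L)
    stop("AUC undefined: scores contain a single truth class")
  r <- rank(scores)
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Computes operating points over the distinct score thresholds (a case is
#' called positive when its score is `>=` the threshold) and the
#' trapezoidal AUC, which equals the tie-corrected pair-comparison
#' statistic `(#\{pos > neg\} + 0.5 #\{pos = neg\}) / (n_pos * n_neg)`.
#' Ties receive half credit and are never broken randomly.
#'
#' @param scores numeric scores, larger = more suspicious.
#' @param labels binary labels (1 = malignant); at least one of each class.
#' @param case_ids optional identifiers, stored for bookkeeping.
#' @return An object of class `mrmc_roc`: list with `points` (data frame
#'   `threshold`, `fpr`, `tpr`, including (0,0) and (1,1)), `auc`, `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' r <- empirical_roc(c(0.9, 0.7, 0.8, 0.3), c(1, 1, 0, 0))
#' r$auc
empirical_roc <- function(scores, labels, case_ids = NULL) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)), !anyNA(scores))
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  if (n_pos == 0L || n_neg == 0L)
    stop("empirical ROC undefined: need at least one positive and one negative")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  ends <- c(which(diff(s) != 0), length(s))   # last index of each tie block
  tp <- cumsum(y)[ends]
  fp <- cumsum(1L - y)[ends]
  pts <- data.frame(threshold = c(Inf, s[ends]),
                    fpr = c(0, fp / n_neg),
                    tpr = c(0, tp / n_pos))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 case_ids = case_ids),
            class = "mrmc_roc")
}

#' @export
print.mrmc_roc <- function(x, digits = 3, ...) {
  cat(sprintf("Empirical ROC: AUC = %s (%d positives, %d negatives, %d operating points)\n",
              format(round(x$auc, digits)), x$n_pos, x$n_neg,
              nrow(x$points)))
  invisible(x)
}

#' @export
plot.mrmc_roc <- function(x, add = FALSE, diag = TRUE, ...) {
  if (!add) {
    graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                   xlab = "False-positive fraction",
                   ylab = "True-positive fraction",
                   xlim = c(0, 1), ylim = c(0, 1), ...)
    if (diag) graphics::abline(0, 1, lty = 3, col = "grey60")
  } else {
    graphics::lines(x$points$fpr, x$points$tpr, ...)
  }
  invisible(x)
}

#' Export ROC operating points as CSV
#'
#' @param roc an `mrmc_roc` object.
#' @param path output CSV path (columns `threshold`, `fpr`, `tpr`).
#' @return Invisibly, `path`.
#' @export
write_roc_points <- function(roc, path) {
  stopifnot(inherits(roc, "mrmc_roc"))
  utils::write.csv(roc$points, path, row.names = FALSE)
  invisible(path)
}

## Internal: per-reader score matrix for one mode, aligned to the truth
## table's case order. Errors if the mode is not fully crossed.
score_matrix <- function(ds, mode, score_type = c("pom", "birads"),
                         pool_negatives = FALSE) {
  score_type <- match.arg(score_type)
  stopifnot(inherits(ds, "mrmc_study"))
  if (!(mode %in% ds$metadata$modes))
    stop("mode '", mode, "' not present in dataset")
  rt <- ds$ratings[ds$ratings$mode == mode, , drop = FALSE]
  readers <- ds$metadata$readers
  cases <- ds$truth$case_id
  n <- length(cases)
  S <- matrix(NA_real_, n, length(readers),
              dimnames = list(cases, readers))
  ri <- match(rt$reader_id, readers)
  ci <- match(rt$case_id, cases)
  if (anyNA(ci)) stop("rating refers to case_id absent from truth table")
  sc <- switch(score_type,
               pom = pom_score(rt$bi_rads, rt$pom, pool_negatives),
               birads = birads_score(rt$bi_rads))
  S[cbind(ci, ri)] <- sc
  if (anyNA(S))
    stop("mode '", mode, "' is not fully crossed: missing ratings ",
         "(run validate_completeness())")
  list(S = S, labels = as.integer(ds$truth$truth == "malignant"),
       case_ids = cases, patient = ds$truth$patient_id,
       readers = readers)
}

#' Per-reader AUCs and their mean for one mode
#'
#' Computes the empirical AUC of every reader for one reading mode and
#' score type, plus the unweighted arithmetic mean across readers (the
#' reader-averaged AUC that the modality comparisons act on). Values are
#' full precision; rounding happens only at the reporting layer.
#'
#' @param ds an [mrmc_study()] object, fully crossed for `mode`.
#' @param mode reading mode, e.g. `"DM"`.
#' @param score_type `"pom"` or `"birads"`.
#' @param pool_negatives see [pom_score()].
#' @return List with `auc` (named per-reader vector) and `mean`.
#' @export
#' @examples
#' ds <- simulate_study(sim_config_small(), seed = 1)
#' reader_auc_table(ds, "DM", "pom")
reader_auc_table <- function(ds, mode, score_type = c("pom", "birads"),
                             pool_negatives = FALSE) {
  score_type <- match.arg(score_type)
  sm <- score_matrix(ds, mode, score_type, pool_negatives)
  auc <- vapply(seq_along(sm$readers),
                function(r) empirical_roc(sm$S[, r], sm$labels)$auc,
                numeric(1))
  names(auc) <- sm$readers
  list(auc = auc, mean = mean(auc))
}
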