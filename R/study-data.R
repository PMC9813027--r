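## Study container and CSV interchange.
##
## Two flat tables describe a reader study:
##   truth:   one row per breast (case) with the reference standard;
##   ratings: one row per breast x reader x reading mode with the forced
##            BI-RADS score and, when BI-RADS >= 3, the POM rating.
## The container is deliberately plain (data frames in a classed list) so
## that every analysis function can be exercised on hand-built fixtures.

#' Assemble a reader-study dataset
#'
#' Bundles a case-truth table and a long-format rating table into an
#' `mrmc_study` object, the input to every analysis function in the package.
#'
#' @param truth data frame with columns `case_id`, `patient_id`, `side`,
#'   `truth`, `density`, `finding_type`, and optionally `lesion_size_mm`
#'   and `histology`. `truth` takes values `malignant`, `benign_biopsy`,
#'   `normal_negative`; see [read_truth()] for the accepted vocabulary.
#' @param ratings data frame with columns `case_id`, `reader_id`, `mode`,
#'   `session`, `bi_rads` (integer 1-5) and `pom` (integer 0-100, `NA`
#'   when BI-RADS is 1-2).
#' @param provenance `"real"` or `"synthetic"`.
#' @param seed generator seed when `provenance = "synthetic"`, else `NULL`.
#'
#' @return An object of class `mrmc_study`: a list with elements `truth`,
#'   `ratings` and `metadata` (`n_cases`, `n_readers`, `readers`, `modes`,
#'   `provenance`, `seed`).
#' @seealso [read_study()], [simulate_study()], [validate_completeness()]
#' @export
#' @examples
#' ds <- simulate_study(sim_config_small(), seed = 1)
#' ds
mrmc_study <- function(truth, ratings, provenance = c("real", "synthetic"),
                       seed = NULL) {
  provenance <- match.arg(provenance)
  truth <- as.data.frame(truth)
  ratings <- as.data.frame(ratings)
  for (col in setdiff(.truth_cols, names(truth))) {
    if (col %in% c("lesion_size_mm", "histology")) {
      truth[[col]] <- if (col == "histology") NA_character_ else NA_real_
    } else {
      stop("truth table is missing required column '", col, "'")
    }
  }
  missing_rc <- setdiff(.rating_cols, names(ratings))
  if (length(missing_rc))
    stop("rating table is missing required column(s): ",
         paste(missing_rc, collapse = ", "))
  truth <- truth[, .truth_cols]
  ratings <- ratings[, .rating_cols]
  if (anyDuplicated(truth$case_id))
    stop("duplicate case_id in truth table")
  key <- paste(ratings$case_id, ratings$reader_id, ratings$mode)
  if (anyDuplicated(key))
    stop("duplicate (case_id, reader_id, mode) triple in rating table")
  readers <- sort(unique(ratings$reader_id))
  modes <- unique(ratings$mode)
  modes <- c(intersect(.modes, modes), setdiff(modes, .modes))
  structure(
    list(truth = truth, ratings = ratings,
         metadata = list(n_cases = nrow(truth),
                         n_readers = length(readers),
                         readers = readers,
                         modes = modes,
                         provenance = provenance,
                         seed = seed)),
    class = "mrmc_study")
}

#' @export
print.mrmc_study <- function(x, ...) {
  md <- x$metadata
  tab <- table(factor(x$truth$truth, levels = .truth_levels))
  cat("MRMC reader study (", md$provenance, ")\n", sep = "")
  cat(sprintf("  %d breasts in %d patients: %d malignant, %d benign (biopsy), %d normal/negative\n",
              md$n_cases, length(unique(x$truth$patient_id)),
              tab[["malignant"]], tab[["benign_biopsy"]],
              tab[["normal_negative"]]))
  cat(sprintf("  %d readers x %d modes (%s); %d ratings\n",
              md$n_readers, length(md$modes),
              paste(md$modes, collapse = ", "), nrow(x$ratings)))
  if (!is.null(md$seed)) cat("  seed:", md$seed, "\n")
  invisible(x)
}

## lower-snake canonicalization of hand-edited categorical values
.normalize_cat <- function(x, levels, field, row_offset = 0L) {
  y <- tolower(trimws(as.character(x)))
  y <- gsub("[ \\-]+", "_", y)
  bad <- which(!(y %in% levels) & !(is.na(y) | y == ""))
  if (length(bad)) {
    stop(sprintf("row %d: field '%s': unknown value '%s' (expected one of %s)",
                 bad[1] + row_offset, field, x[bad[1]],
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  y[y == ""] <- NA_character_
  y
}

.numeric_or_na <- function(x) {
  y <- suppressWarnings(as.numeric(ifelse(trimws(as.character(x)) == "",
                                          NA, x)))
  y
}

#' Read a case-truth table from CSV
#'
#' Parses the per-breast reference-standard table. Categorical fields are
#' case-insensitive on input (`"Malignant"`, `"non-dense"` are accepted) and
#' canonicalized to lower snake case. Header row is mandatory; columns are
#' `case_id, patient_id, side, truth, density, finding_type, lesion_size_mm,
#' histology` (the last two optional).
#'
#' Row-level validation: unknown categorical values, duplicated `case_id`,
#' a `normal_negative` case carrying a finding type other than `none`, or a
#' lesion size attached to a case without a finding all raise an error that
#' names the offending row and field.
#'
#' @param path path to a CSV file.
#' @return A data frame of validated case-truth rows in canonical column
#'   order.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                        colClasses = "character")
  req <- c("case_id", "patient_id", "side", "truth", "density",
           "finding_type")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("truth CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  ## row_offset 1 accounts for the header line in user-facing row numbers
  df$side <- .normalize_cat(df$side, .side_levels, "side", 1L)
  df$truth <- .normalize_cat(df$truth, .truth_levels, "truth", 1L)
  df$density <- .normalize_cat(df$density, .density_levels, "density", 1L)
  df$finding_type <- .normalize_cat(df$finding_type, .finding_levels,
                                    "finding_type", 1L)
  if (anyNA(df$truth) || anyNA(df$density) || anyNA(df$finding_type) ||
      anyNA(df$side)) {
    bad <- which(is.na(df$truth) | is.na(df$density) |
                   is.na(df$finding_type) | is.na(df$side))[1]
    stop(sprintf("row %d: empty required categorical field", bad + 1L))
  }
  if (anyDuplicated(df$case_id)) {
    dup <- df$case_id[duplicated(df$case_id)][1]
    stop("duplicate case_id in truth table: '", dup, "'")
  }
  df$lesion_size_mm <- if ("lesion_size_mm" %in% names(df))
    .numeric_or_na(df$lesion_size_mm) else NA_real_
  df$histology <- if ("histology" %in% names(df)) {
    h <- trimws(df$histology); h[h == ""] <- NA_character_; h
  } else NA_character_
  bad <- which(df$truth == "normal_negative" & df$finding_type != "none")
  if (length(bad))
    stop(sprintf("row %d: normal_negative case must have finding_type 'none'",
                 bad[1] + 1L))
  bad <- which(!is.na(df$lesion_size_mm) & df$finding_type == "none")
  if (length(bad))
    stop(sprintf("row %d: lesion_size_mm given but finding_type is 'none'",
                 bad[1] + 1L))
  bad <- which(!is.na(df$lesion_size_mm) & df$lesion_size_mm <= 0)
  if (length(bad))
    stop(sprintf("row %d: lesion_size_mm must be positive", bad[1] + 1L))
  df[, .truth_cols]
}

#' Read a long-format rating table from CSV
#'
#' Parses one row per breast x reader x reading mode. `bi_rads` must be an
#' integer 1-5. `pom` must be present (0-100) whenever `bi_rads >= 3` —
#' the conditional-elicitation protocol — and is encoded as an empty field
#' (never 0) when absent. A POM attached to a BI-RADS 1-2 rating is a
#' protocol violation handled per `pom_violation`.
#'
#' @param path path to a CSV file with header `case_id, reader_id, mode,
#'   session, bi_rads, pom` (`session` optional; derived from `mode` when
#'   absent).
#' @param pom_violation `"warn"` (default) or `"error"`: treatment of a POM
#'   value accompanying a BI-RADS 1-2 rating.
#' @return A data frame of validated rating rows.
#' @export
read_ratings <- function(path, pom_violation = c("warn", "error")) {
  pom_violation <- match.arg(pom_violation)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                        colClasses = "character")
  req <- c("case_id", "reader_id", "mode", "bi_rads")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("rating CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  mode_in <- toupper(trimws(df$mode))
  bad <- which(!(mode_in %in% .modes))
  if (length(bad))
    stop(sprintf("row %d: field 'mode': unknown value '%s' (expected one of %s)",
                 bad[1] + 1L, df$mode[bad[1]], paste(.modes, collapse = ", ")))
  df$mode <- mode_in
  br <- .numeric_or_na(df$bi_rads)
  bad <- which(is.na(br) | br != round(br) | br < 1 | br > 5)
  if (length(bad))
    stop(sprintf("row %d: field 'bi_rads': value '%s' is not an integer in 1..5",
                 bad[1] + 1L, df$bi_rads[bad[1]]))
  df$bi_rads <- as.integer(br)
  pom <- if ("pom" %in% names(df)) .numeric_or_na(df$pom) else NA_real_
  bad <- which(!is.na(pom) & (pom != round(pom) | pom < 0 | pom > 100))
  if (length(bad))
    stop(sprintf("row %d: field 'pom': value '%s' is not an integer in 0..100",
                 bad[1] + 1L, df$pom[bad[1]]))
  df$pom <- as.integer(round(pom))
  bad <- which(df$bi_rads >= 3 & is.na(df$pom))
  if (length(bad))
    stop(sprintf("row %d: bi_rads %d requires a POM rating (protocol: POM elicited for BI-RADS >= 3)",
                 bad[1] + 1L, df$bi_rads[bad[1]]))
  bad <- which(df$bi_rads <= 2 & !is.na(df$pom))
  if (length(bad)) {
    msg <- sprintf("row %d: POM present for bi_rads %d (protocol elicits POM only for BI-RADS >= 3)",
                   bad[1] + 1L, df$bi_rads[bad[1]])
    if (pom_violation == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  derived <- unname(.mode_session[df$mode])
  if ("session" %in% names(df) && any(trimws(df$session) != "")) {
    ses <- .numeric_or_na(df$session)
    bad <- which(!is.na(ses) & ses != derived)
    if (length(bad))
      stop(sprintf("row %d: session %s inconsistent with mode %s (expected %d)",
                   bad[1] + 1L, df$session[bad[1]], df$mode[bad[1]],
                   derived[bad[1]]))
  }
  df$session <- derived
  key <- paste(df$case_id, df$reader_id, df$mode)
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop(sprintf("duplicate rating for (case %s, reader %s, mode %s)",
                 df$case_id[d], df$reader_id[d], df$mode[d]))
  }
  df[, .rating_cols]
}

#' Read a full study from its two CSV files
#'
#' @param truth_path,ratings_path CSV paths for [read_truth()] and
#'   [read_ratings()].
#' @param provenance,seed passed to [mrmc_study()].
#' @inheritParams read_ratings
#' @return An [mrmc_study()] object.
#' @export
read_study <- function(truth_path, ratings_path,
                       provenance = c("real", "synthetic"), seed = NULL,
                       pom_violation = c("warn", "error")) {
  mrmc_study(read_truth(truth_path),
             read_ratings(ratings_path, pom_violation),
             provenance = match.arg(provenance), seed = seed)
}

#' Write a study to CSV
#'
#' Writes `truth.csv` and `ratings.csv` in the canonical dialect (UTF-8,
#' comma-separated, header row, lower-snake categoricals, absent POM as an
#' empty field). A written study read back with [read_study()] reproduces
#' the original field for field.
#'
#' @param ds an [mrmc_study()] object.
#' @param dir output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_study <- function(ds, dir) {
  stopifnot(inherits(ds, "mrmc_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- file.path(dir, "truth.csv")
  rp <- file.path(dir, "ratings.csv")
  utils::write.csv(ds$truth, tp, row.names = FALSE, na = "")
  utils::write.csv(ds$ratings, rp, row.names = FALSE, na = "")
  invisible(c(truth = tp, ratings = rp))
}
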