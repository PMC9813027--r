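## Dataset completeness validation.
##
## A complete fully crossed study has one rating per (case, reader, mode)
## and therefore n_cases x n_readers x 2 session reports (each session
## report carries the 2D rating and the +DBT rating for one breast).

#' Validate completeness of a reader study
#'
#' Checks that the rating table covers the full cases x readers x modes
#' grid: lists missing triples, duplicated triples, orphan ratings (ratings
#' whose `case_id` is absent from the truth table), and counts complete
#' session reports (a case x reader x session pair with both of that
#' session's mode ratings present).
#'
#' @param ds an [mrmc_study()] object.
#' @param modes modes expected in the grid; defaults to the modes present
#'   in the dataset's metadata.
#' @param readers readers expected in the grid; defaults to those observed.
#' @return An object of class `mrmc_validation`: a list with `n_cases`,
#'   `n_readers`, `n_modes`, `n_expected`, `n_ratings`, `missing` (data
#'   frame of absent triples), `duplicates`, `orphans`, `n_session_reports`
#'   and logical `complete`. Findings are reported, never raised as errors.
#' @seealso [validation_json()]
#' @export
#' @examples
#' ds <- simulate_study(sim_config_small(), seed = 1)
#' validate_completeness(ds)
validate_completeness <- function(ds, modes = NULL, readers = NULL) {
  stopifnot(inherits(ds, "mrmc_study"))
  if (is.null(modes)) modes <- ds$metadata$modes
  if (is.null(readers)) readers <- ds$metadata$readers
  cases <- ds$truth$case_id
  rt <- ds$ratings

  expected <- expand.grid(case_id = cases, reader_id = readers,
                          mode = modes, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  ekey <- paste(expected$case_id, expected$reader_id, expected$mode,
                sep = "\r")
  okey <- paste(rt$case_id, rt$reader_id, rt$mode, sep = "\r")

  missing <- expected[!(ekey %in% okey), , drop = FALSE]
  rownames(missing) <- NULL
  dup <- rt[duplicated(okey), c("case_id", "reader_id", "mode"),
            drop = FALSE]
  rownames(dup) <- NULL
  orphans <- rt[!(rt$case_id %in% cases),
                c("case_id", "reader_id", "mode"), drop = FALSE]
  rownames(orphans) <- NULL

  ## session report = (case, reader, session) with every mode of that
  ## session rated
  n_session_reports <- 0L
  for (s in sort(unique(.mode_session[modes]))) {
    ms <- modes[.mode_session[modes] == s]
    in_grid <- rt$mode %in% ms & rt$case_id %in% cases
    pair <- paste(rt$case_id[in_grid], rt$reader_id[in_grid], sep = "\r")
    cnt <- table(pair)
    n_session_reports <- n_session_reports + sum(cnt == length(ms))
  }

  structure(
    list(n_cases = length(cases), n_readers = length(readers),
         n_modes = length(modes),
         n_expected = length(cases) * length(readers) * length(modes),
         n_ratings = nrow(rt),
         missing = missing, duplicates = dup, orphans = orphans,
         n_session_reports = as.integer(n_session_reports),
         complete = nrow(missing) == 0L && nrow(dup) == 0L &&
           nrow(orphans) == 0L),
    class = "mrmc_validation")
}

#' @export
print.mrmc_validation <- function(x, ...) {
  cat("MRMC study completeness report\n")
  cat(sprintf("  expected ratings: %d (%d cases x %d readers x %d modes)\n",
              x$n_expected, x$n_cases, x$n_readers, x$n_modes))
  cat(sprintf("  observed ratings: %d; complete session reports: %d\n",
              x$n_ratings, x$n_session_reports))
  cat(sprintf("  missing triples: %d; duplicates: %d; orphan ratings: %d\n",
              nrow(x$missing), nrow(x$duplicates), nrow(x$orphans)))
  cat(if (x$complete) "  dataset is COMPLETE\n" else "  dataset is INCOMPLETE\n")
  if (nrow(x$missing)) {
    cat("  first missing triples:\n")
    print(utils::head(x$missing, 5))
  }
  invisible(x)
}

#' Serialize a validation report as JSON
#'
#' @param v an object from [validate_completeness()].
#' @param path optional file path; when given the JSON is written there.
#' @return JSON string (invisibly when written to `path`).
#' @export
validation_json <- function(v, path = NULL) {
  stopifnot(inherits(v, "mrmc_validation"))
  js <- jsonlite::toJSON(unclass(v), dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
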