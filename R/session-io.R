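#' Read and write writing sessions
#'
#' One file holds one session. Two dialects are supported:
#' * `csv` — header `t_ms,x_px,y_px,phase`, one event per row; the subject
#'   id is taken from the file name (without extension) unless supplied;
#' * `json` — an object with `subject_id`, `screen` (`w`, `h`),
#'   `task_char_count`, `time_limit` and an `events` array.
#'
#' Timestamps are stored as integer milliseconds, so valid sessions
#' round-trip bit-identically through write/read.
#'
#' @param path File path.
#' @param dialect `"csv"`, `"json"`, or `"auto"` (by file extension).
#' @param subject_id Overrides the subject id (csv only; defaults to the
#'   file name).
#' @param ... Screen geometry / task constants forwarded to
#'   [writing_session()] when the dialect cannot carry them (csv).
#' @return [read_session()] returns a validated [writing_session()];
#'   [write_session()] returns `path` invisibly.
#' @examples
#' s <- simulate_session(group = "HC", seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_session(s, f)
#' identical(read_session(f, subject_id = s$subject_id)$events, s$events)
#' @export
read_session <- function(path, dialect = c("auto", "csv", "json"),
                         subject_id = NULL, ...) {
  dialect <- resolve_dialect(match.arg(dialect), path)
  if (!file.exists(path)) {
    abort(paste0("session file not found: ", path),
          class = "graphomarker_io_error")
  }
  if (dialect == "csv") {
    ev <- utils::read.csv(path, colClasses = c(
      t_ms = "integer", x_px = "numeric", y_px = "numeric",
      phase = "character"
    ))
    id <- subject_id %||% tools::file_path_sans_ext(basename(path))
    writing_session(ev, subject_id = id, ...)
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    for (k in c("subject_id", "screen", "events")) {
      if (is.null(obj[[k]])) {
        abort(paste0("session JSON lacks required key: ", k),
              class = "graphomarker_io_error")
      }
    }
    ev <- as_tibble(obj$events)
    if (nrow(ev) > 0) ev$t_ms <- as.integer(ev$t_ms)
    writing_session(
      ev,
      subject_id = obj$subject_id,
      screen_w = obj$screen$w, screen_h = obj$screen$h,
      task_char_count = obj$task_char_count %||% 10,
      time_limit = obj$time_limit %||% 180
    )
  }
}

#' @rdname read_session
#' @param session A [writing_session()].
#' @export
write_session <- function(session, path, dialect = c("auto", "csv", "json")) {
  stopifnot(inherits(session, "writing_session"))
  dialect <- resolve_dialect(match.arg(dialect), path)
  if (dialect == "csv") {
    utils::write.csv(session$events, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(
      subject_id = session$subject_id,
      screen = list(w = session$screen_w, h = session$screen_h),
      task_char_count = session$task_char_count,
      time_limit = session$time_limit,
      events = session$events
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

resolve_dialect <- function(dialect, path) {
  if (dialect != "auto") return(dialect)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json" else "csv"
}

#' Read and write cohort feature tables
#'
#' A cohort table has one row per subject: `subject_id`, `group`
#' (`MCI`/`HC`), the demographics (`age`, `sex`, `education`, `mmse`,
#' `moca`) and the 21 biomarker columns `IPSDB_1..10`, `EFDB_1..11`.
#' Unknown columns are preserved but ignored by the statistics. Validation
#' rejects duplicated subject ids, a non two-level group column, and
#' negative values in biomarker columns.
#'
#' @param path CSV file path.
#' @return [read_cohort()] returns a validated tibble;
#'   [write_cohort()] returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cohort file not found: ", path),
          class = "graphomarker_io_error")
  }
  validate_cohort(as_tibble(utils::read.csv(path)))
}

#' @rdname read_cohort
#' @param cohort A cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_cohort
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (!"group" %in% names(cohort)) {
    abort("cohort table lacks a 'group' column",
          class = "graphomarker_schema_error")
  }
  if (!"subject_id" %in% names(cohort)) {
    abort("cohort table lacks a 'subject_id' column",
          class = "graphomarker_schema_error")
  }
  dup <- cohort$subject_id[duplicated(cohort$subject_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicated subject_id: ", paste(unique(dup), collapse = ", ")),
          class = "graphomarker_schema_error")
  }
  lev <- unique(as.character(cohort$group))
  if (!setequal(lev, c("MCI", "HC"))) {
    abort(paste0("group column must have exactly the levels MCI and HC, got: ",
                 paste(lev, collapse = ", ")),
          class = "graphomarker_schema_error")
  }
  cohort$group <- factor(cohort$group, levels = c("HC", "MCI"))
  present <- intersect(BIOMARKER_NAMES, names(cohort))
  for (m in present) {
    if (!is.numeric(cohort[[m]])) {
      abort(paste0("biomarker column not numeric: ", m),
            class = "graphomarker_schema_error")
    }
    if (any(cohort[[m]] < 0, na.rm = TRUE)) {
      abort(paste0("negative values in biomarker column: ", m),
            class = "graphomarker_schema_error")
    }
  }
  cohort
}

#' Extract biomarkers for a whole cohort of sessions
#'
#' Maps [extract_biomarkers()] over a list of sessions (or a directory of
#' session files) and joins the result onto per-subject metadata, yielding
#' the cohort feature table consumed by the statistics layer.
#'
#' @param sessions A list of [writing_session()] objects, or a directory
#'   path containing one session file per subject.
#' @param metadata Optional tibble keyed by `subject_id` (group,
#'   demographics) to join onto the features.
#' @param min_pause_ms Passed to [extract_biomarkers()].
#' @param drop_invalid Drop sessions flagged invalid (time limit exceeded)
#'   before extraction, mirroring the paradigm's exclusion rule
#'   (default TRUE; a message reports how many were dropped).
#' @return Cohort tibble: metadata columns followed by the 21 biomarkers.
#' @export
extract_cohort <- function(sessions, metadata = NULL, min_pause_ms = 50,
                           drop_invalid = TRUE) {
  if (is.character(sessions) && length(sessions) == 1) {
    files <- list.files(sessions, pattern = "\\.(csv|json)$",
                        full.names = TRUE)
    files <- files[!basename(files) %in% c("metadata.csv", "manifest.json")]
    if (length(files) == 0) {
      abort(paste0("no session files found in ", sessions),
            class = "graphomarker_io_error")
    }
    sessions <- lapply(files, read_session)
  }
  invalid <- vapply(sessions, function(s) !s$valid, logical(1))
  if (drop_invalid && any(invalid)) {
    inform(sprintf("dropping %d invalid session(s) (time limit exceeded)",
                   sum(invalid)))
    sessions <- sessions[!invalid]
  }
  feats <- purrr::map_dfr(sessions, extract_biomarkers,
                          min_pause_ms = min_pause_ms)
  if (!is.null(metadata)) {
    feats <- dplyr::left_join(metadata, feats, by = "subject_id")
  }
  feats
}
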