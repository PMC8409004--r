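#' Construct a test segmentation
#'
#' A segmentation maps stretches of a recording (seconds from recording start,
#' half-open intervals `[start_s, end_s)`) to named neuropsychological tests.
#' Intervals must be non-overlapping; gaps (un-annotated time) are allowed.
#'
#' @param df data frame with columns `test_name`, `start_s`, `end_s`.
#' @return A `segmentation`: the validated data frame sorted by `start_s`.
#' @export
segmentation <- function(df) {
  req <- c("test_name", "start_s", "end_s")
  if (!all(req %in% names(df))) {
    stop("segmentation needs columns: ", paste(req, collapse = ", "))
  }
  df <- df[req]
  df$test_name <- as.character(df$test_name)
  df$start_s <- suppressWarnings(as.numeric(df$start_s))
  df$end_s <- suppressWarnings(as.numeric(df$end_s))
  if (anyNA(df$start_s) || anyNA(df$end_s)) stop("non-numeric interval bounds")
  bad <- which(!(df$start_s >= 0 & df$start_s < df$end_s))
  if (length(bad)) {
    stop("invalid intervals (need 0 <= start_s < end_s) at rows: ",
         paste(bad, collapse = ", "))
  }
  df <- df[order(df$start_s), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) > 1L) {
    ov <- which(df$start_s[-1L] < df$end_s[-nrow(df)])
    if (length(ov)) {
      stop("overlapping intervals at sorted rows: ",
           paste(paste(ov, ov + 1L, sep = "-"), collapse = ", "))
    }
  }
  class(df) <- c("segmentation", "data.frame")
  df
}

#' Read / write a test segmentation TSV
#'
#' The on-disk dialect is a tab-separated file with header
#' `test_name  start_s  end_s`; times are seconds from recording start.
#'
#' @param path file path.
#' @return [read_segmentation()]: a validated [segmentation()].
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) stop("segmentation file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  segmentation(df)
}

#' @rdname read_segmentation
#' @param seg a [segmentation()].
#' @export
write_segmentation <- function(seg, path) {
  utils::write.table(as.data.frame(seg), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Valid cognitive status codes
#' @export
STATUS_LEVELS <- c("NC", "MCI", "DE")

#' Read diagnosis timelines
#'
#' A timeline CSV has columns `participant_id, diagnosis_date, status` with
#' ISO-8601 dates and status codes `NC` (normal cognition), `MCI` (mild
#' cognitive impairment) or `DE` (dementia). One timeline is returned per
#' participant, entries sorted by date; duplicate (participant, date) pairs
#' are rejected.
#'
#' @param path CSV file path.
#' @return Named list of data frames (`diagnosis_date` as `Date`, `status`),
#'   one per participant; empty list for an empty file.
#' @export
read_timelines <- function(path) {
  if (!file.exists(path)) stop("timeline file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) return(structure(list(), names = character()))
  timelines_from_frame(df)
}

#' Build per-participant timelines from a long data frame
#' @param df data frame with `participant_id`, `diagnosis_date`, `status`.
#' @return Named list of per-participant timeline data frames.
#' @export
timelines_from_frame <- function(df) {
  req <- c("participant_id", "diagnosis_date", "status")
  if (!all(req %in% names(df))) {
    stop("timelines need columns: ", paste(req, collapse = ", "))
  }
  bad <- setdiff(unique(df$status), STATUS_LEVELS)
  if (length(bad)) {
    stop("unknown cognitive status token(s): ", paste(bad, collapse = ", "),
         " (expected NC, MCI or DE)")
  }
  dates <- as.Date(df$diagnosis_date)
  if (anyNA(dates)) stop("unparseable diagnosis_date (expected ISO-8601)")
  df$diagnosis_date <- dates
  if (anyDuplicated(df[c("participant_id", "diagnosis_date")])) {
    stop("duplicate (participant_id, diagnosis_date) entries")
  }
  out <- split(df[c("diagnosis_date", "status")], df$participant_id)
  lapply(out, function(tl) {
    tl <- tl[order(tl$diagnosis_date), , drop = FALSE]
    rownames(tl) <- NULL
    tl
  })
}

#' @rdname read_timelines
#' @param timelines named list of timeline data frames.
#' @export
write_timelines <- function(timelines, path) {
  rows <- do.call(rbind, lapply(names(timelines), function(pid) {
    tl <- timelines[[pid]]
    data.frame(participant_id = pid,
               diagnosis_date = as.character(tl$diagnosis_date),
               status = tl$status, stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    rows <- data.frame(participant_id = character(), diagnosis_date = character(),
                       status = character())
  }
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' The manifest CSV lists one recording per row:
#' `recording_id, participant_id, recording_date, audio_path, duration_s`.
#'
#' @param path CSV file path.
#' @return A data frame with `recording_date` parsed as `Date`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("recording_id", "participant_id", "recording_date", "audio_path")
  if (!all(req %in% names(df))) {
    stop("manifest needs columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(df$recording_id)) stop("duplicate recording_id in manifest")
  df$recording_date <- as.Date(df$recording_date)
  df
}

#' @rdname read_manifest
#' @param manifest manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  m <- manifest
  m$recording_date <- as.character(m$recording_date)
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a metrics report as JSON
#' @param report a named list (e.g. from [summarize_metrics()]).
#' @param path output path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
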