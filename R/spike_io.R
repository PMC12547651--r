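#' Build a multi-well MEA recording session from a spike table
#'
#' An `mea_session` bundles a tidy spike table (one row per sorted spike)
#' with the recording layout: a baseline window and a treatment window that
#' share their boundary, the treatment time. All windows are half-open
#' `[t0, t1)`, so a spike exactly at treatment time belongs to the treatment
#' period and no spike is counted twice.
#'
#' @param spikes A data frame with columns `well_id` (character), `unit_id`
#'   (character, unique within well), `timestamp_s` (numeric seconds,
#'   non-negative). Timestamps need not arrive sorted; they are sorted per
#'   unit. Duplicate timestamps within a unit are an error (each spike is one
#'   threshold crossing).
#' @param condition `"treated"` or `"untreated"`.
#' @param baseline_window Numeric length-2, `[t0, t1)` in seconds.
#' @param treatment_window Numeric length-2, `[t1, t2)` in seconds; must start
#'   where the baseline window ends.
#'
#' @return An object of class `mea_session`: a list with elements `spikes`
#'   (tibble), `condition`, `baseline_window`, `treatment_window`.
#' @export
#' @examples
#' sp <- tibble::tibble(
#'   well_id = "A", unit_id = c("u1", "u1", "u2"),
#'   timestamp_s = c(10, 12.5, 3)
#' )
#' mea_session(sp, "treated", c(0, 300), c(300, 600))
mea_session <- function(spikes, condition = c("treated", "untreated"),
                        baseline_window = c(0, 300),
                        treatment_window = c(300, 600)) {
  condition <- match.arg(condition)
  required <- c("well_id", "unit_id", "timestamp_s")
  missing_cols <- setdiff(required, names(spikes))
  if (length(missing_cols) > 0) {
    stop("spike table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_window(baseline_window, "baseline_window")
  check_window(treatment_window, "treatment_window")
  if (!isTRUE(all.equal(baseline_window[2], treatment_window[1]))) {
    stop("baseline_window must end exactly where treatment_window begins",
         call. = FALSE)
  }
  spikes <- tibble::as_tibble(spikes)[required]
  spikes$well_id <- as.character(spikes$well_id)
  spikes$unit_id <- as.character(spikes$unit_id)
  spikes$timestamp_s <- as.numeric(spikes$timestamp_s)
  if (anyNA(spikes$timestamp_s)) {
    stop("non-numeric timestamp in spike table", call. = FALSE)
  }
  if (any(spikes$timestamp_s < 0)) {
    stop("negative timestamp in spike table", call. = FALSE)
  }
  out_of_range <- spikes$timestamp_s < baseline_window[1] |
    spikes$timestamp_s >= treatment_window[2]
  if (any(out_of_range)) {
    stop("timestamp outside recording interval [",
         baseline_window[1], ", ", treatment_window[2], ") at row(s) ",
         paste(head(which(out_of_range), 5), collapse = ", "), call. = FALSE)
  }
  spikes <- dplyr::arrange(spikes, .data$well_id, .data$unit_id,
                           .data$timestamp_s)
  dup <- spikes |>
    dplyr::group_by(.data$well_id, .data$unit_id) |>
    dplyr::summarise(dup = anyDuplicated(.data$timestamp_s) > 0,
                     .groups = "drop")
  if (any(dup$dup)) {
    bad <- dup[dup$dup, ]
    stop("duplicate timestamps within unit(s): ",
         paste(paste(bad$well_id, bad$unit_id, sep = "/"), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(spikes = spikes, condition = condition,
         baseline_window = as.numeric(baseline_window),
         treatment_window = as.numeric(treatment_window)),
    class = "mea_session"
  )
}

check_window <- function(w, name) {
  if (!is.numeric(w) || length(w) != 2 || !all(is.finite(w)) || w[2] <= w[1]) {
    stop(name, " must be a numeric [start, end) pair with end > start",
         call. = FALSE)
  }
  invisible(w)
}

#' @export
print.mea_session <- function(x, ...) {
  n_units <- nrow(dplyr::distinct(x$spikes, .data$well_id, .data$unit_id))
  cat("<mea_session> ", x$condition, "\n",
      "  baseline  [", x$baseline_window[1], ", ", x$baseline_window[2], ") s\n",
      "  treatment [", x$treatment_window[1], ", ", x$treatment_window[2], ") s\n",
      "  ", length(unique(x$spikes$well_id)), " well(s), ", n_units,
      " unit(s), ", nrow(x$spikes), " spikes\n", sep = "")
  invisible(x)
}

#' List the units of a session
#'
#' @param session An [mea_session()].
#' @return A tibble with one row per (well_id, unit_id).
#' @export
session_units <- function(session) {
  stopifnot(inherits(session, "mea_session"))
  dplyr::distinct(session$spikes, .data$well_id, .data$unit_id)
}

#' Read a spike-time table from CSV
#'
#' The interchange format is a comma-delimited file with a mandatory header
#' `well_id,unit_id,timestamp_s`, one row per sorted spike, timestamps in
#' seconds. Rows whose timestamp falls outside the recording interval
#' `[t0, t2)` are an error in `"strict"` mode (the default) or are dropped
#' with a warning in `"drop"` mode; rows are never dropped silently.
#'
#' @inheritParams mea_session
#' @param path Path to the CSV file.
#' @param out_of_window `"strict"` (error) or `"drop"` (drop and warn).
#' @return An [mea_session()].
#' @export
read_spike_table <- function(path, condition = c("treated", "untreated"),
                             baseline_window = c(0, 300),
                             treatment_window = c(300, 600),
                             out_of_window = c("strict", "drop")) {
  condition <- match.arg(condition)
  out_of_window <- match.arg(out_of_window)
  spikes <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_character()))
  required <- c("well_id", "unit_id", "timestamp_s")
  missing_cols <- setdiff(required, names(spikes))
  if (length(missing_cols) > 0) {
    stop("'", path, "' is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ts <- suppressWarnings(as.numeric(spikes$timestamp_s))
  bad <- which(is.na(ts) & !is.na(spikes$timestamp_s) |
                 is.na(spikes$timestamp_s))
  if (length(bad) > 0) {
    stop("non-numeric timestamp at data row(s) ",
         paste(head(bad, 5), collapse = ", "), " of '", path, "'",
         call. = FALSE)
  }
  spikes$timestamp_s <- ts
  if (nrow(spikes) == 0) {
    warning("'", path, "' contains a valid header but no spikes",
            call. = FALSE)
  }
  outside <- ts < baseline_window[1] | ts >= treatment_window[2]
  if (any(outside)) {
    if (out_of_window == "strict") {
      stop("timestamp outside recording interval at data row(s) ",
           paste(head(which(outside), 5), collapse = ", "), " of '", path,
           "'", call. = FALSE)
    }
    warning("dropping ", sum(outside),
            " spike(s) outside the recording interval", call. = FALSE)
    spikes <- spikes[!outside, , drop = FALSE]
  }
  mea_session(spikes, condition, baseline_window, treatment_window)
}

#' Write a session's spike table to CSV
#'
#' @param session An [mea_session()] or a data frame with the spike-table
#'   columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spike_table <- function(session, path) {
  spikes <- if (inherits(session, "mea_session")) session$spikes else
    tibble::as_tibble(session)
  readr::write_csv(spikes[c("well_id", "unit_id", "timestamp_s")], path)
  invisible(path)
}

#' Read and write per-unit label tables
#'
#' Labels are stored as CSV with columns
#' `well_id,unit_id,delta_mfr_hz,kde_density,label`. The round trip
#' write-then-read is the identity (floats to full double precision).
#'
#' @param labels A data frame with the five label columns (as produced by
#'   [label_units()]).
#' @param path File path.
#' @return `write_labels()` returns `path` invisibly; `read_labels()` returns
#'   a tibble.
#' @export
write_labels <- function(labels, path) {
  required <- c("well_id", "unit_id", "delta_mfr_hz", "kde_density", "label")
  missing_cols <- setdiff(required, names(labels))
  if (length(missing_cols) > 0) {
    stop("label table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(tibble::as_tibble(labels)[required], path)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
    well_id = readr::col_character(),
    unit_id = readr::col_character(),
    delta_mfr_hz = readr::col_double(),
    kde_density = readr::col_double(),
    label = readr::col_character()
  ))
}

#' Read and write baseline feature tables
#'
#' Features are stored as CSV with columns
#' `well_id,unit_id,mfr_hz,isicv,sync_median,sync_skewness` and an optional
#' `label` column. On read-back, a table without a label column gets an
#' explicit `label = "unlabeled"` marker rather than a silent default.
#'
#' @param features A data frame with the feature columns (as produced by
#'   [build_feature_table()]).
#' @param path File path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns a tibble that always carries a `label` column.
#' @export
write_features <- function(features, path) {
  required <- c("well_id", "unit_id", "mfr_hz", "isicv", "sync_median",
                "sync_skewness")
  missing_cols <- setdiff(required, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  keep <- c(required, intersect("label", names(features)))
  readr::write_csv(tibble::as_tibble(features)[keep], path)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()
                         ))
  for (col in c("mfr_hz", "isicv", "sync_median", "sync_skewness")) {
    if (col %in% names(out)) out[[col]] <- as.numeric(out[[col]])
  }
  if (!"label" %in% names(out)) {
    out$label <- "unlabeled"
  }
  out
}

#' Read and write classifier metric documents
#'
#' Metrics (accuracy, per-class F1, AUC, ROC points, feature importances,
#' confidence-retention curve, ...) are stored as a single JSON document so
#' that the full evaluation report re-parses to identical values.
#'
#' @param metrics A named list (e.g. a tidied [evaluate_holdout()] report).
#' @param path File path.
#' @return `write_metrics()` returns `path` invisibly; `read_metrics()`
#'   returns a named list.
#' @export
write_metrics <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_metrics
#' @export
read_metrics <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
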