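#' Mean firing rate over a window
#'
#' @param timestamps Numeric spike times (seconds) of one unit.
#' @param window Half-open `[start, end)` interval in seconds.
#' @return Spikes per second (Hz).
#' @export
mean_firing_rate <- function(timestamps, window) {
  check_window(window, "window")
  sum(timestamps >= window[1] & timestamps < window[2]) /
    (window[2] - window[1])
}

#' Inter-spike-interval coefficient of variation
#'
#' Sample SD (n-1 denominator by default) of consecutive inter-spike
#' intervals divided by the mean interval: 0 for clock-like firing, about 1
#' for Poisson firing, above 1 for bursty/irregular firing. Undefined with
#' fewer than 3 spikes (2 intervals) in the window; such units are returned
#' as `NA` and flagged for exclusion by [build_feature_table()] rather than
#' imputed.
#'
#' @param timestamps Numeric spike times (seconds) of one unit.
#' @param window Half-open `[start, end)` interval in seconds.
#' @param sd_denominator `"sample"` (n-1, default) or `"population"` (n).
#' @return Dimensionless CV, or `NA_real_` when undefined.
#' @export
isi_cv <- function(timestamps, window,
                   sd_denominator = c("sample", "population")) {
  sd_denominator <- match.arg(sd_denominator)
  ts <- sort(timestamps[timestamps >= window[1] & timestamps < window[2]])
  if (length(ts) < 3) return(NA_real_)
  isis <- diff(ts)
  m <- mean(isis)
  if (m == 0) return(NA_real_)
  s <- sd(isis)
  if (sd_denominator == "population") {
    n <- length(isis)
    s <- s * sqrt((n - 1) / n)
  }
  s / m
}

#' Adaptive-coincidence spike synchronization of a train pair
#'
#' The bounded `[0, 1]` SPIKE-synchronization measure: for each spike, the
#' coincidence window `tau` is half the minimum of the four adjacent
#' inter-spike intervals (the spike's own preceding/following ISI and its
#' nearest counterpart's preceding/following ISI); the spike counts as
#' coincident iff its nearest counterpart spike lies strictly within `tau`.
#' The measure is the mean coincidence indicator over all spikes of both
#' trains, so identical trains score 1 and trains without near-coincident
#' spikes score 0.
#'
#' At the train boundaries the distance to the window edge is used as the
#' surrogate ISI (auxiliary-spike convention), so single-spike trains are
#' well defined.
#'
#' @param a,b Numeric spike times of the two units (seconds).
#' @param window Half-open `[start, end)` interval; spikes outside are
#'   ignored.
#' @return Synchronization in `[0, 1]`, or `NA_real_` if either train has no
#'   spike in the window (the pair is then excluded from aggregation).
#' @export
spike_synchronization <- function(a, b, window) {
  check_window(window, "window")
  a <- sort(a[a >= window[1] & a < window[2]])
  b <- sort(b[b >= window[1] & b < window[2]])
  if (length(a) == 0 || length(b) == 0) return(NA_real_)
  ca <- sync_coincidences(a, b, window[1], window[2])
  cb <- sync_coincidences(b, a, window[1], window[2])
  (sum(ca) + sum(cb)) / (length(a) + length(b))
}

# Coincidence indicators for each spike of x against counterpart train y.
# Edge ISIs use the distance to the window boundary as surrogate.
sync_coincidences <- function(x, y, w0, w1) {
  nx <- length(x)
  ny <- length(y)
  prev_x <- c(x[1] - w0, diff(x))
  next_x <- c(diff(x), w1 - x[nx])
  prev_y <- c(y[1] - w0, diff(y))
  next_y <- c(diff(y), w1 - y[ny])
  pos <- findInterval(x, y)
  d_left <- ifelse(pos >= 1, x - y[pmax(pos, 1L)], Inf)
  d_right <- ifelse(pos < ny, y[pmin(pos + 1L, ny)] - x, Inf)
  j <- ifelse(d_left <= d_right, pmax(pos, 1L), pmin(pos + 1L, ny))
  d <- pmin(d_left, d_right)
  tau <- 0.5 * pmin(prev_x, next_x, prev_y[j], next_y[j])
  d < tau
}

#' Adjusted Fisher-Pearson skewness (G1)
#'
#' `G1 = sqrt(n(n-1))/(n-2) * m3 / m2^(3/2)` with central moments `m2`,
#' `m3`. Zero-variance samples return 0 by convention (a degenerate,
#' perfectly symmetric distribution); fewer than 3 values return `NA`.
#'
#' @param x Numeric sample.
#' @return Dimensionless skewness.
#' @export
skewness_g1 <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) return(NA_real_)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  m3 <- mean((x - m)^3)
  sqrt(n * (n - 1)) / (n - 2) * m3 / m2^1.5
}

#' Median and skewness of a unit's pairwise synchrony values
#'
#' Summarises the relationship of one unit to the rest of its well: the
#' median and [skewness_g1()] of its pairwise [spike_synchronization()]
#' values against every other unit in the same well that has at least one
#' spike in the window. Pairs never cross wells. With fewer than 3 valid
#' pairs the features are undefined (`NA`) and the unit is flagged for
#' exclusion downstream.
#'
#' @param unit_spikes Numeric spike times of the focal unit.
#' @param others List of numeric spike-time vectors (co-resident units).
#' @param window Half-open `[start, end)` interval.
#' @return A list with `sync_median` and `sync_skewness`.
#' @export
pairwise_synchrony_stats <- function(unit_spikes, others, window) {
  vals <- purrr::map_dbl(others, spike_synchronization, b = unit_spikes,
                         window = window)
  vals <- vals[!is.na(vals)]
  if (length(vals) < 3) {
    return(list(sync_median = NA_real_, sync_skewness = NA_real_))
  }
  list(sync_median = median(vals), sync_skewness = skewness_g1(vals))
}

# All pairwise synchronies within one well; returns a symmetric matrix with
# NA diagonal. Each pair is computed once.
well_sync_matrix <- function(trains, window) {
  n <- length(trains)
  m <- matrix(NA_real_, n, n)
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- spike_synchronization(trains[[i]], trains[[j]], window)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}

#' Baseline phenotype feature table for a session
#'
#' Computes the four-feature functional phenotype of every unit from the
#' entire baseline period (never from the 30-s response bins): mean firing
#' rate (`mfr_hz`), ISI coefficient of variation (`isicv`), and the median
#' and skewness of the unit's pairwise spike-synchronization values against
#' its well mates (`sync_median`, `sync_skewness`). Units whose features are
#' undefined (fewer than 3 spikes, or fewer than 3 valid within-well pairs)
#' are excluded from the table — never imputed — and listed with reasons in
#' the `exclusions` attribute.
#'
#' @param session An [mea_session()].
#' @param labels Optional label table (from [label_units()] or
#'   [read_labels()]); joined on `(well_id, unit_id)`. Retained units
#'   missing from `labels` are an error.
#' @return A tibble with columns `well_id`, `unit_id`, `mfr_hz`, `isicv`,
#'   `sync_median`, `sync_skewness` and, when `labels` is given, `label`.
#'   Attribute `exclusions`: tibble (`well_id`, `unit_id`, `reason`).
#' @export
build_feature_table <- function(session, labels = NULL) {
  stopifnot(inherits(session, "mea_session"))
  window <- session$baseline_window
  by_unit <- session$spikes |>
    dplyr::filter(.data$timestamp_s >= window[1],
                  .data$timestamp_s < window[2]) |>
    dplyr::group_by(.data$well_id, .data$unit_id) |>
    dplyr::summarise(spikes = list(.data$timestamp_s), .groups = "drop")
  # units with no baseline spike at all still exist in the session
  all_units <- session_units(session)
  silent <- dplyr::anti_join(all_units, by_unit, by = c("well_id", "unit_id"))

  rows <- list()
  excl <- list(
    dplyr::mutate(silent, reason = "no baseline spikes")
  )
  for (w in unique(by_unit$well_id)) {
    wu <- by_unit[by_unit$well_id == w, ]
    trains <- wu$spikes
    sync_m <- well_sync_matrix(trains, window)
    for (i in seq_len(nrow(wu))) {
      cv <- isi_cv(trains[[i]], window)
      vals <- sync_m[i, ]
      vals <- vals[!is.na(vals)]
      reasons <- character(0)
      if (is.na(cv)) reasons <- c(reasons, "insufficient ISIs")
      if (length(vals) < 3) reasons <- c(reasons, "insufficient valid pairs")
      if (length(reasons) > 0) {
        excl[[length(excl) + 1]] <- tibble::tibble(
          well_id = w, unit_id = wu$unit_id[i],
          reason = paste(reasons, collapse = "; "))
        next
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        well_id = w, unit_id = wu$unit_id[i],
        mfr_hz = mean_firing_rate(trains[[i]], window),
        isicv = cv,
        sync_median = median(vals),
        sync_skewness = skewness_g1(vals))
    }
  }
  features <- dplyr::bind_rows(rows)
  exclusions <- dplyr::bind_rows(excl)
  if (nrow(features) > 0) {
    features <- dplyr::arrange(features, .data$well_id, .data$unit_id)
  }
  if (!is.null(labels)) {
    lab <- tibble::as_tibble(labels)[c("well_id", "unit_id", "label")]
    features <- dplyr::left_join(features, lab, by = c("well_id", "unit_id"))
    unmatched <- features[is.na(features$label), c("well_id", "unit_id")]
    if (nrow(unmatched) > 0) {
      stop("no label for unit(s): ",
           paste(paste(unmatched$well_id, unmatched$unit_id, sep = "/"),
                 collapse = ", "), call. = FALSE)
    }
  }
  attr(features, "exclusions") <- exclusions
  features
}
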