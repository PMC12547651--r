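#' Bin spike counts over a window
#'
#' Counts spikes in consecutive full bins of `bin_width` seconds starting at
#' the window start. A trailing partial bin is dropped (never rescaled), so
#' max-count comparisons always run over equal-width bins.
#'
#' @param timestamps Numeric spike times (seconds) of one unit.
#' @param window Half-open `[start, end)` interval in seconds.
#' @param bin_width Bin width in seconds (default 30).
#' @return An object of class `binned_counts`: list with integer `counts`
#'   (one per full bin, temporal order), `bin_width`, `window`.
#' @export
#' @examples
#' bin_counts(c(10, 12, 40, 41, 42), c(0, 90), 30)$counts # 2 3 0
bin_counts <- function(timestamps, window, bin_width = 30) {
  check_window(window, "window")
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  n_bins <- floor((window[2] - window[1]) / bin_width)
  if (n_bins < 1) {
    stop("window shorter than one bin (", bin_width, " s)", call. = FALSE)
  }
  ts <- timestamps[timestamps >= window[1] &
                     timestamps < window[1] + n_bins * bin_width]
  idx <- floor((ts - window[1]) / bin_width) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(counts = as.integer(counts), bin_width = bin_width,
                 window = as.numeric(window)),
            class = "binned_counts")
}

#' Most-active bin and its mean firing rate
#'
#' Returns the mean firing rate (max count / bin width, Hz) of the bin with
#' the greatest spike count, with ties broken in favour of the earliest bin.
#' Bin indices are 1-based, following R convention.
#'
#' @param binned A [bin_counts()] result.
#' @return A list with `mfr_hz` and `bin` (1-based index of the max bin).
#' @export
max_bin_mfr <- function(binned) {
  stopifnot(inherits(binned, "binned_counts"))
  if (length(binned$counts) < 1) stop("no bins", call. = FALSE)
  i <- which.max(binned$counts) # which.max takes the earliest tie
  list(mfr_hz = binned$counts[i] / binned$bin_width, bin = i)
}

#' Max-bin absolute change in mean firing rate for one unit
#'
#' The response metric: the MFR of the most-active treatment bin minus the
#' MFR of the most-active baseline bin (absolute difference in Hz, sign
#' preserved — agonist responders are expected positive, silenced units
#' negative).
#'
#' @param timestamps Numeric spike times (seconds) of one unit.
#' @param baseline_window,treatment_window Half-open `[start, end)` windows.
#' @param bin_width Bin width in seconds (default 30).
#' @return A list with `delta_mfr_hz`, `baseline_max_bin`,
#'   `treatment_max_bin` (1-based).
#' @export
response_delta <- function(timestamps, baseline_window, treatment_window,
                           bin_width = 30) {
  b <- max_bin_mfr(bin_counts(timestamps, baseline_window, bin_width))
  t <- max_bin_mfr(bin_counts(timestamps, treatment_window, bin_width))
  list(delta_mfr_hz = t$mfr_hz - b$mfr_hz,
       baseline_max_bin = b$bin, treatment_max_bin = t$bin)
}

#' Per-unit response deltas for a whole session
#'
#' @param session An [mea_session()].
#' @param bin_width Bin width in seconds (default 30).
#' @return A tibble with one row per unit: `well_id`, `unit_id`,
#'   `delta_mfr_hz`, `baseline_max_bin`, `treatment_max_bin`.
#' @export
response_deltas <- function(session, bin_width = 30) {
  stopifnot(inherits(session, "mea_session"))
  session$spikes |>
    dplyr::group_by(.data$well_id, .data$unit_id) |>
    dplyr::summarise(
      res = list(response_delta(.data$timestamp_s, session$baseline_window,
                                session$treatment_window, bin_width)),
      .groups = "drop"
    ) |>
    tidyr::unnest_wider("res")
}

#' Silverman rule-of-thumb bandwidth
#'
#' The robust rule `h = 0.9 * min(SD, IQR/1.349) * n^(-1/5)`. When the IQR
#' is zero but the SD is not (heavily tied quartiles), the SD alone is used;
#' zero spread overall (all samples equal) is an error — the bandwidth is
#' undefined and callers must not silently substitute one.
#'
#' @param x Numeric sample (n >= 2).
#' @return Bandwidth `h > 0`.
#' @export
silverman_bandwidth <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("need at least 2 samples for a bandwidth", call. = FALSE)
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    stop("zero sample spread: Silverman bandwidth undefined", call. = FALSE)
  }
  iqr <- as.numeric(quantile(x, 0.75, names = FALSE) -
                      quantile(x, 0.25, names = FALSE))
  spread <- if (iqr > 0) min(s, iqr / 1.349) else s
  0.9 * spread * n^(-1 / 5)
}

#' Fit a Gaussian kernel density model on a reference sample
#'
#' The model is the plain Gaussian-kernel density estimator
#' `f(x) = (1/(n h)) * sum_i K((x - x_i)/h)` over the reference samples
#' (the untreated pseudo-treatment deltas), with `h` from
#' [silverman_bandwidth()] unless supplied.
#'
#' @param reference Numeric reference sample (n >= 2 for an automatic
#'   bandwidth; a single reference point is allowed when `bandwidth` is
#'   supplied).
#' @param bandwidth Optional bandwidth override (> 0).
#' @return An object of class `density_model`: list with `samples`, `h`, `n`.
#' @export
fit_kde <- function(reference, bandwidth = NULL) {
  reference <- as.numeric(reference)
  if (length(reference) < 1) {
    stop("need at least 1 reference sample", call. = FALSE)
  }
  if (length(reference) < 2 && is.null(bandwidth)) {
    stop("need at least 2 reference samples for an automatic bandwidth",
         call. = FALSE)
  }
  h <- bandwidth %||% silverman_bandwidth(reference)
  if (h <= 0) stop("bandwidth must be > 0", call. = FALSE)
  structure(list(samples = reference, h = h, n = length(reference)),
            class = "density_model")
}

#' @export
print.density_model <- function(x, ...) {
  cat("<density_model> Gaussian kernel, n =", x$n, ", h =",
      format(x$h, digits = 6), "\n")
  invisible(x)
}

#' Evaluate a fitted kernel density model
#'
#' @param x Numeric vector of evaluation points.
#' @param model A [fit_kde()] model.
#' @return Numeric densities, same length as `x`.
#' @export
kde_density <- function(x, model) {
  stopifnot(inherits(model, "density_model"))
  x <- as.numeric(x)
  # column-blocked evaluation keeps memory bounded for large x
  out <- numeric(length(x))
  block <- 2048L
  for (start in seq(1L, length(x), by = block)) {
    idx <- start:min(start + block - 1L, length(x))
    z <- outer(x[idx], model$samples, "-") / model$h
    out[idx] <- rowSums(dnorm(z)) / (model$n * model$h)
  }
  out
}

#' Label presumptive nociceptors by density under the untreated null
#'
#' The unsupervised labeling rule: (1) fit the kernel density model on the
#' untreated pseudo-treatment deltas; (2) score every treated unit's delta
#' under that model; (3) score every untreated unit under the same model;
#' (4) take the `percentile_threshold`-th percentile (linear interpolation)
#' of the untreated density scores as the cutoff; (5) a treated unit is
#' labeled `"nociceptor"` iff its density falls strictly below the cutoff
#' and — when `require_positive_delta` is on (the default, since the
#' stimulus is an agonist) — its delta is positive. The density criterion
#' alone is two-sided; switching the flag off gives the literal
#' low-density-tail rule.
#'
#' @param treated_deltas Tibble from [response_deltas()] (needs
#'   `well_id`, `unit_id`, `delta_mfr_hz`) or a bare numeric vector.
#' @param untreated_deltas Same, for the untreated condition (pooled across
#'   wells; n >= 2).
#' @param percentile_threshold Percent in (0, 100); default 10.
#' @param require_positive_delta Require `delta_mfr_hz > 0` for a nociceptor
#'   label (default `TRUE`).
#' @return A tibble with one row per treated unit: `well_id`, `unit_id`,
#'   `delta_mfr_hz`, `kde_density`, `label` (`"nociceptor"` /
#'   `"non-nociceptor"`). Attributes: `density_model`, `density_threshold`,
#'   `untreated_densities`, `config`.
#' @export
label_units <- function(treated_deltas, untreated_deltas,
                        percentile_threshold = 10,
                        require_positive_delta = TRUE) {
  if (percentile_threshold <= 0 || percentile_threshold >= 100) {
    stop("percentile_threshold must lie in (0, 100)", call. = FALSE)
  }
  treated <- as_delta_table(treated_deltas, "treated")
  untreated <- as_delta_table(untreated_deltas, "untreated")
  if (nrow(treated) == 0) stop("empty treated set", call. = FALSE)

  model <- fit_kde(untreated$delta_mfr_hz)
  dens_treated <- kde_density(treated$delta_mfr_hz, model)
  dens_untreated <- kde_density(untreated$delta_mfr_hz, model)
  threshold <- as.numeric(quantile(dens_untreated,
                                   percentile_threshold / 100,
                                   names = FALSE, type = 7))
  is_noci <- dens_treated < threshold
  if (require_positive_delta) {
    is_noci <- is_noci & treated$delta_mfr_hz > 0
  }
  out <- tibble::tibble(
    well_id = treated$well_id,
    unit_id = treated$unit_id,
    delta_mfr_hz = treated$delta_mfr_hz,
    kde_density = dens_treated,
    label = ifelse(is_noci, "nociceptor", "non-nociceptor")
  )
  attr(out, "density_model") <- model
  attr(out, "density_threshold") <- threshold
  attr(out, "untreated_densities") <- dens_untreated
  attr(out, "config") <- list(percentile_threshold = percentile_threshold,
                              require_positive_delta = require_positive_delta)
  class(out) <- c("noci_labels", class(out))
  out
}

as_delta_table <- function(x, what) {
  if (is.numeric(x) && is.null(dim(x))) {
    return(tibble::tibble(well_id = NA_character_,
                          unit_id = sprintf("%s_%d", what, seq_along(x)),
                          delta_mfr_hz = as.numeric(x)))
  }
  x <- tibble::as_tibble(x)
  if (!"delta_mfr_hz" %in% names(x)) {
    stop(what, " deltas need a delta_mfr_hz column", call. = FALSE)
  }
  if (!"well_id" %in% names(x)) x$well_id <- NA_character_
  if (!"unit_id" %in% names(x)) {
    x$unit_id <- sprintf("%s_%d", what, seq_len(nrow(x)))
  }
  x[c("well_id", "unit_id", "delta_mfr_hz")]
}
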