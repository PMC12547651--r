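#' Configuration for the synthetic MEA study generator
#'
#' The generator emulates a multi-well sensory-neuron culture: each sorted
#' unit fires as a gamma-renewal process whose rate and regularity depend on
#' its (hidden) subtype, within-well synchrony is planted by letting units
#' copy spikes from a shared well-wide mother process, and in treated
#' sessions the responder subpopulation multiplies its firing rate by
#' `response_gain` from the treatment time onward (after a short per-unit
#' latency emulating droplet diffusion).
#'
#' Subtype structure at the defaults reproduces the qualitative contrasts the
#' labeling-and-classification workflow assumes: responders have higher
#' baseline mean firing rate (log-normal rate distributions), higher ISI
#' coefficient of variation (gamma shape < 1), and higher median pairwise
#' synchrony (dense mother-process participation), while non-responders
#' participate in the mother process only sparsely, which makes their
#' pairwise-synchrony distributions right-skewed.
#'
#' @param n_wells_treated,n_wells_untreated Number of wells per condition.
#' @param units_per_well Either a single count or an inclusive `c(min, max)`
#'   range sampled uniformly per well. The default range (26-62, mean 44)
#'   makes a 14-well condition total roughly 620 units, the scale of a
#'   full-plate screening run.
#' @param responder_fraction Probability that a unit is a responder
#'   (independent Bernoulli per unit). Default 0.3682, a typical
#'   TRPV1-positive prevalence for these cultures.
#' @param baseline_rate_meanlog,baseline_rate_sdlog Named length-2 vectors
#'   (`nonresponder`, `responder`): log-normal parameters of the per-unit
#'   baseline firing rate in Hz.
#' @param isi_shape Named length-2 vector: gamma renewal shape k per subtype
#'   (`k < 1` gives irregular firing, ISICV `= 1/sqrt(k) > 1`). A per-unit
#'   log-normal jitter (`isi_shape_jitter_sdlog`) spreads individual units
#'   around the subtype value.
#' @param isi_shape_jitter_sdlog SD of the log-normal per-unit jitter on k.
#' @param response_gain Multiplicative post-treatment rate factor for
#'   responders (> 0; 1 means no effect).
#' @param response_latency_jitter Responder onset delay is uniform in
#'   `[0, response_latency_jitter]` seconds after treatment time.
#' @param mother_rate Rate (Hz) of the shared per-well Poisson mother
#'   process.
#' @param sync_copy_beta Named list of `c(shape1, shape2)` Beta parameters
#'   per subtype for the per-unit mother-spike copy probability `p_sync`.
#'   Responders draw from a dense, symmetric Beta; non-responders from a
#'   right-skewed Beta concentrated near zero with an occasional high value.
#' @param sync_jitter_sd Gaussian SD (seconds) of the jitter applied to
#'   copied mother spikes.
#' @param baseline_duration,treatment_duration Window lengths in seconds.
#' @param seed Master seed; fixing it fixes every generated session exactly.
#'
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(n_wells_treated = 14,
                         n_wells_untreated = 14,
                         units_per_well = c(26, 62),
                         responder_fraction = 0.3682,
                         baseline_rate_meanlog = c(nonresponder = log(0.6),
                                                   responder = log(2.0)),
                         baseline_rate_sdlog = c(nonresponder = 0.5,
                                                 responder = 0.5),
                         isi_shape = c(nonresponder = 0.9,
                                       responder = 0.4),
                         isi_shape_jitter_sdlog = 0.15,
                         response_gain = 4,
                         response_latency_jitter = 10,
                         mother_rate = 1.5,
                         sync_copy_beta = list(nonresponder = c(0.4, 2.3),
                                               responder = c(6, 2)),
                         sync_jitter_sd = 0.0015,
                         baseline_duration = 300,
                         treatment_duration = 300,
                         seed = 1L) {
  cfg <- list(
    n_wells_treated = as.integer(n_wells_treated),
    n_wells_untreated = as.integer(n_wells_untreated),
    units_per_well = as.integer(units_per_well),
    responder_fraction = responder_fraction,
    baseline_rate_meanlog = baseline_rate_meanlog,
    baseline_rate_sdlog = baseline_rate_sdlog,
    isi_shape = isi_shape,
    isi_shape_jitter_sdlog = isi_shape_jitter_sdlog,
    response_gain = response_gain,
    response_latency_jitter = response_latency_jitter,
    mother_rate = mother_rate,
    sync_copy_beta = sync_copy_beta,
    sync_jitter_sd = sync_jitter_sd,
    baseline_duration = baseline_duration,
    treatment_duration = treatment_duration,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$responder_fraction < 0 || cfg$responder_fraction > 1) {
    stop("responder_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$response_gain <= 0) stop("response_gain must be > 0", call. = FALSE)
  if (cfg$baseline_duration <= 0 || cfg$treatment_duration <= 0) {
    stop("durations must be > 0", call. = FALSE)
  }
  if (any(cfg$units_per_well < 1) || length(cfg$units_per_well) > 2) {
    stop("units_per_well must be a positive count or c(min, max) range",
         call. = FALSE)
  }
  if (cfg$n_wells_treated < 0 || cfg$n_wells_untreated < 0) {
    stop("well counts must be non-negative", call. = FALSE)
  }
  for (nm in c("baseline_rate_meanlog", "baseline_rate_sdlog", "isi_shape")) {
    v <- cfg[[nm]]
    if (length(v) != 2 || !all(c("nonresponder", "responder") %in% names(v))) {
      stop(nm, " must be a named length-2 vector (nonresponder, responder)",
           call. = FALSE)
    }
  }
  if (any(cfg$isi_shape <= 0)) stop("isi_shape must be > 0", call. = FALSE)
  if (cfg$mother_rate < 0) stop("mother_rate must be >= 0", call. = FALSE)
  invisible(cfg)
}

# Ordinary gamma renewal train on [t_start, t_end): ISIs ~ Gamma(k, rate = k * r)
# so mean ISI = 1/r and ISI CV = 1/sqrt(k).
gen_gamma_train <- function(rate, shape, t_start, t_end) {
  dur <- t_end - t_start
  if (rate <= 0 || dur <= 0) return(numeric(0))
  times <- numeric(0)
  t <- t_start
  # draw in chunks; expected count + slack keeps the loop to ~1 iteration
  repeat {
    n_draw <- max(16L, ceiling((t_end - t) * rate * 1.5 + 6 * sqrt((t_end - t) * rate + 1)))
    isis <- rgamma(n_draw, shape = shape, rate = shape * rate)
    new_t <- t + cumsum(isis)
    times <- c(times, new_t[new_t < t_end])
    t <- new_t[length(new_t)]
    if (t >= t_end) break
  }
  times
}

# One unit's spike train over the whole recording. The independent renewal
# component carries the subtype rate minus the expected mother contribution,
# so the unit's total rate stays close to its drawn baseline rate.
gen_unit_train <- function(rate, shape, p_sync, mother, jitter_sd,
                           t0, t1, t2, gain = 1, onset = t1) {
  mother_part <- p_sync * attr(mother, "rate")
  own_rate <- max(rate - mother_part, 0.05 * rate)
  if (gain == 1) {
    own <- gen_gamma_train(own_rate, shape, t0, t2)
  } else {
    # the unit's TOTAL rate multiplies by the gain; the mother contribution
    # is unchanged by treatment, so the renewal component absorbs the rest
    own_post <- max(rate * gain - mother_part, 0.05 * rate * gain)
    own <- c(gen_gamma_train(own_rate, shape, t0, onset),
             gen_gamma_train(own_post, shape, onset, t2))
  }
  copied <- numeric(0)
  if (p_sync > 0 && length(mother) > 0) {
    take <- runif(length(mother)) < p_sync
    copied <- mother[take] + rnorm(sum(take), 0, jitter_sd)
  }
  spk <- sort(c(own, copied))
  spk <- spk[spk >= t0 & spk < t2]
  spk[!duplicated(spk)]
}

#' Generate one synthetic recording session with ground truth
#'
#' Builds an [mea_session()] for one condition together with the per-unit
#' ground truth. In `"treated"` sessions, ground-truth responders multiply
#' their firing rate by `response_gain` from treatment time (plus a uniform
#' onset latency) onward; `"untreated"` sessions have no rate change anywhere
#' and every unit's ground-truth label is non-responder (subtype phenotypes
#' are still drawn, since the untreated culture is just as heterogeneous).
#'
#' @param config A [synth_config()].
#' @param condition `"treated"` or `"untreated"`.
#' @param well_prefix Prefix for generated well ids (defaults to "T"/"U" by
#'   condition).
#' @return A list with elements `session` (an [mea_session()]) and `truth`
#'   (tibble: `well_id`, `unit_id`, `phenotype`, `truth_responder`).
#' @export
generate_session <- function(config, condition = c("treated", "untreated"),
                             well_prefix = NULL) {
  stopifnot(inherits(config, "synth_config"))
  condition <- match.arg(condition)
  validate_synth_config(config)
  n_wells <- if (condition == "treated") config$n_wells_treated else
    config$n_wells_untreated
  if (n_wells < 1) stop("no wells requested for condition ", condition,
                        call. = FALSE)
  prefix <- well_prefix %||% if (condition == "treated") "T" else "U"
  set.seed(derive_seed(config$seed, if (condition == "treated") 1L else 2L))

  t0 <- 0
  t1 <- config$baseline_duration
  t2 <- t1 + config$treatment_duration
  upw <- config$units_per_well
  subtype_names <- c("nonresponder", "responder")

  well_data <- purrr::map(seq_len(n_wells), function(w) {
    well_id <- sprintf("%s%02d", prefix, w)
    n_units <- if (length(upw) == 1) upw else
      sample(seq(upw[1], upw[2]), 1)
    mother <- sort(runif(rpois(1, config$mother_rate * (t2 - t0)), t0, t2))
    attr(mother, "rate") <- config$mother_rate
    units <- purrr::map(seq_len(n_units), function(u) {
      is_resp <- runif(1) < config$responder_fraction
      st <- subtype_names[is_resp + 1L]
      rate <- rlnorm(1, config$baseline_rate_meanlog[[st]],
                     config$baseline_rate_sdlog[[st]])
      shape <- config$isi_shape[[st]] *
        rlnorm(1, 0, config$isi_shape_jitter_sdlog)
      b <- config$sync_copy_beta[[st]]
      p_sync <- rbeta(1, b[1], b[2])
      responds <- is_resp && condition == "treated"
      onset <- t1 + runif(1, 0, config$response_latency_jitter)
      spk <- gen_unit_train(rate, shape, p_sync, mother,
                            config$sync_jitter_sd, t0, t1, t2,
                            gain = if (responds) config$response_gain else 1,
                            onset = onset)
      list(unit_id = sprintf("u%03d", u), phenotype = st,
           truth_responder = responds, spikes = spk)
    })
    list(well_id = well_id, units = units)
  })

  spikes <- purrr::map_dfr(well_data, function(w) {
    purrr::map_dfr(w$units, function(u) {
      if (length(u$spikes) == 0) return(NULL)
      tibble::tibble(well_id = w$well_id, unit_id = u$unit_id,
                     timestamp_s = u$spikes)
    })
  })
  truth <- purrr::map_dfr(well_data, function(w) {
    purrr::map_dfr(w$units, function(u) {
      tibble::tibble(well_id = w$well_id, unit_id = u$unit_id,
                     phenotype = u$phenotype,
                     truth_responder = u$truth_responder)
    })
  })
  session <- mea_session(spikes, condition, c(t0, t1), c(t1, t2))
  list(session = session, truth = truth)
}

#' Generate a full synthetic study (treated + untreated conditions)
#'
#' Generates one treated and one untreated session from the same
#' configuration and, optionally, writes them in the package's interchange
#' formats: `treated.csv`, `untreated.csv` (spike tables) and `truth.csv`
#' (per-unit ground truth with condition column).
#'
#' @param config A [synth_config()].
#' @param out_dir Optional output directory; created if missing.
#' @return A list with `treated`, `untreated` (each an [mea_session()]) and
#'   `truth` (tibble with `condition`, `well_id`, `unit_id`, `phenotype`,
#'   `truth_responder`).
#' @export
generate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  tr <- generate_session(config, "treated")
  un <- generate_session(config, "untreated")
  truth <- dplyr::bind_rows(
    dplyr::mutate(tr$truth, condition = "treated", .before = 1),
    dplyr::mutate(un$truth, condition = "untreated", .before = 1)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_spike_table(tr$session, file.path(out_dir, "treated.csv"))
    write_spike_table(un$session, file.path(out_dir, "untreated.csv"))
    readr::write_csv(truth, file.path(out_dir, "truth.csv"))
  }
  list(treated = tr$session, untreated = un$session, truth = truth)
}
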