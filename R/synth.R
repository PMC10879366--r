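#' Configuration for the synthetic anesthesia-transition cohort
#'
#' Defines a cohort of simulated 4-channel EEG recordings (Fp1, Fp2, P3, P4
#' at 250 Hz), each containing an awake baseline, an induction transition at
#' loss of responsiveness (LoR), a maintained anesthetized segment, and an
#' emergence transition at return of responsiveness (RoR). Awake activity is
#' an irregular fast oscillation (AR(2) resonance near `awake_peak_hz`);
#' anesthetized activity is a larger-amplitude, more regular slow oscillation
#' (resonance near `anesth_peak_hz`). Parietal channels receive a lagged copy
#' of the mean frontal signal whose gain interpolates between
#' `awake_coupling` and `anesth_coupling`, so directed frontal-to-parietal
#' information transfer is stronger while awake.
#'
#' @param n_patients Number of recordings in the cohort.
#' @param duration_s Recording duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param lor_time_s,ror_time_s Event times in seconds. When `NULL` (the
#'   default) they are drawn per patient, LoR uniformly in \[60, 120\] s and
#'   RoR uniformly in \[`duration_s` - 120, `duration_s` - 60\] s.
#' @param transition_width_s Logistic scale of the state transitions, seconds.
#' @param awake_peak_hz,anesth_peak_hz Spectral peak of the awake and
#'   anesthetized AR(2) processes, Hz.
#' @param awake_coupling,anesth_coupling Frontal-to-parietal coupling gain in
#'   each state; must lie in \[0, 1).
#' @param coupling_lag_samples Coupling lag in input samples (10 at 250 Hz
#'   equals 40 ms).
#' @param noise_sd Innovation standard deviation of the awake AR(2) process;
#'   the anesthetized process uses three times this value.
#' @param seed Master seed; per-patient seeds are `seed + patient index`.
#'
#' @return A `simulation_config` list.
#' @seealso [generate_recording()], [generate_cohort()]
#' @export
simulation_config <- function(n_patients = 20,
                              duration_s = 300,
                              fs = 250,
                              lor_time_s = NULL,
                              ror_time_s = NULL,
                              transition_width_s = 10,
                              awake_peak_hz = 10,
                              anesth_peak_hz = 1.5,
                              awake_coupling = 0.4,
                              anesth_coupling = 0.05,
                              coupling_lag_samples = 10,
                              noise_sd = 1,
                              seed = 1L) {
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      duration_s = duration_s,
      fs = fs,
      lor_time_s = lor_time_s,
      ror_time_s = ror_time_s,
      transition_width_s = transition_width_s,
      awake_peak_hz = awake_peak_hz,
      anesth_peak_hz = anesth_peak_hz,
      awake_coupling = awake_coupling,
      anesth_coupling = anesth_coupling,
      coupling_lag_samples = as.integer(coupling_lag_samples),
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.finite(cfg$fs) || cfg$fs <= 0) {
    stop("invalid simulation config: fs must be > 0", call. = FALSE)
  }
  if (cfg$n_patients < 1) {
    stop("invalid simulation config: n_patients must be >= 1", call. = FALSE)
  }
  if (!is.finite(cfg$transition_width_s) || cfg$transition_width_s <= 0) {
    stop("invalid simulation config: transition_width_s must be > 0",
         call. = FALSE)
  }
  for (fld in c("awake_coupling", "anesth_coupling")) {
    g <- cfg[[fld]]
    if (g < 0 || g >= 1) {
      stop(sprintf("invalid simulation config: %s must lie in [0, 1)", fld),
           call. = FALSE)
    }
  }
  if (!is.null(cfg$lor_time_s) && !is.null(cfg$ror_time_s)) {
    if (!(0 < cfg$lor_time_s && cfg$lor_time_s < cfg$ror_time_s &&
          cfg$ror_time_s < cfg$duration_s)) {
      stop("invalid simulation config: need 0 < lor_time_s < ror_time_s < duration_s",
           call. = FALSE)
    }
  }
  if (is.null(cfg$lor_time_s) && cfg$duration_s < 181) {
    stop("invalid simulation config: duration_s too short for randomized LoR/RoR draws",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf("  %d patient(s), %.0f s at %g Hz, master seed %d\n",
              x$n_patients, x$duration_s, x$fs, x$seed))
  cat(sprintf("  peaks: awake %g Hz / anesth %g Hz; coupling %g -> %g (lag %d samples)\n",
              x$awake_peak_hz, x$anesth_peak_hz,
              x$awake_coupling, x$anesth_coupling, x$coupling_lag_samples))
  invisible(x)
}

# Stationary AR(2) with complex poles r * exp(+-i * 2*pi*f_peak/fs).
# A burn-in of 2000 samples is discarded so the series starts in its
# stationary regime.
ar2_series <- function(n, f_peak_hz, fs, r, innov_sd) {
  theta <- 2 * pi * f_peak_hz / fs
  a <- c(2 * r * cos(theta), -r^2)
  burn <- 2000L
  e <- stats::rnorm(n + burn, sd = innov_sd)
  x <- stats::filter(e, a, method = "recursive")
  as.numeric(x)[(burn + 1L):(burn + n)]
}

# Responsiveness weight: 1 while awake, ~0 while anesthetized.
responsiveness_weight <- function(t, lor_s, ror_s, width_s) {
  1 - stats::plogis((t - lor_s) / width_s) * stats::plogis((ror_s - t) / width_s)
}

#' Generate one synthetic anesthesia-transition recording
#'
#' Each channel is `w(t) * awake + (1 - w(t)) * anesthetized` plus white
#' measurement noise at 5% of the awake signal's standard deviation, where
#' `w(t)` is a product-of-logistics weight that falls from 1 to 0 around LoR
#' and returns to 1 around RoR. Parietal channels additionally receive the
#' lagged mean frontal signal scaled by the state-dependent coupling gain.
#' Output is fully deterministic given `(config, patient_seed)`.
#'
#' @param config A [simulation_config()].
#' @param patient_seed Integer seed for this recording.
#' @param patient_id Identifier; defaults to `"P<seed>"`.
#'
#' @return A list with `recording` (tibble: `time_s`, `Fp1`, `Fp2`, `P3`,
#'   `P4`; sample `i` is timestamped `(i - 1) / fs`) and `events` (one-row
#'   tibble: `patient_id`, `lor_s`, `ror_s`).
#' @export
generate_recording <- function(config, patient_seed,
                               patient_id = paste0("P", patient_seed)) {
  validate_simulation_config(config)
  withr::with_seed(as.integer(patient_seed), {
    lor <- config$lor_time_s %||% stats::runif(1, 60, 120)
    ror <- config$ror_time_s %||%
      stats::runif(1, config$duration_s - 120, config$duration_s - 60)
    n <- round(config$duration_s * config$fs)
    t <- (seq_len(n) - 1) / config$fs
    w <- responsiveness_weight(t, lor, ror, config$transition_width_s)

    chans <- c("Fp1", "Fp2", "P3", "P4")
    awake <- lapply(chans, function(ch) {
      ar2_series(n, config$awake_peak_hz, config$fs, 0.95, config$noise_sd)
    })
    anesth <- lapply(chans, function(ch) {
      ar2_series(n, config$anesth_peak_hz, config$fs, 0.98, 3 * config$noise_sd)
    })
    names(awake) <- names(anesth) <- chans

    y <- lapply(chans, function(ch) w * awake[[ch]] + (1 - w) * anesth[[ch]])
    names(y) <- chans

    # state-dependent directed frontal -> parietal input, lagged by L samples
    g <- w * config$awake_coupling + (1 - w) * config$anesth_coupling
    L <- config$coupling_lag_samples
    frontal_mean <- (y$Fp1 + y$Fp2) / 2
    lagged <- c(rep(0, L), frontal_mean[seq_len(n - L)])
    y$P3 <- y$P3 + g * lagged
    y$P4 <- y$P4 + g * lagged

    awake_sd <- mean(vapply(awake, stats::sd, numeric(1)))
    y <- lapply(y, function(v) v + stats::rnorm(n, sd = 0.05 * awake_sd))

    list(
      recording = tibble::tibble(time_s = t, !!!y),
      events = tibble::tibble(patient_id = patient_id, lor_s = lor, ror_s = ror)
    )
  })
}

#' Generate a synthetic cohort
#'
#' Per-patient seeds are derived as `config$seed + patient index`, so the
#' whole cohort (signals and event times) is reproducible from the master
#' seed alone.
#'
#' @param config A [simulation_config()].
#' @return A tibble with one row per patient: `patient_id`, `lor_s`, `ror_s`
#'   and a `recording` list-column of channel tibbles.
#' @export
generate_cohort <- function(config) {
  validate_simulation_config(config)
  purrr::map_dfr(seq_len(config$n_patients), function(i) {
    res <- generate_recording(config, config$seed + i,
                              patient_id = sprintf("P%02d", i))
    tibble::tibble(
      patient_id = res$events$patient_id,
      lor_s = res$events$lor_s,
      ror_s = res$events$ror_s,
      recording = list(res$recording)
    )
  })
}

#' Event annotations of a cohort
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return The `patient_id`, `lor_s`, `ror_s` columns.
#' @export
cohort_events <- function(cohort) {
  dplyr::select(cohort, "patient_id", "lor_s", "ror_s")
}
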