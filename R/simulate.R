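# Synthetic herd generator. Activity is modelled as an amplitude-modulated
# noise envelope: the pipeline consumes only magnitude statistics, so only the
# envelope's spectral content matters, not literal gait. The envelope for
# animal i is
#   lambda_i(t) = rest + a_i * ramp_i(t) * welfare(t) * (1 + sin(2*pi*t/86400 + phi_i)) / 2
# with a per-animal acclimatisation ramp over the first weeks of life, a
# herd-shared welfare curve (optionally with an abrupt dip), near-common phase
# (shared zeitgebers), staggered births, collar-off gaps and battery-end
# truncation. Two output modes: "epoch" (envelope sampled directly at epoch
# resolution; fast, used for herd-scale work) and "raw" (12.5 Hz triaxial
# samples around a slowly wandering gravity vector; exercises the full
# pre-processing chain).

#' Build a herd welfare curve
#'
#' A function of calendar time into `[0, 1]`: a base level with an optional
#' abrupt dip (linear fall over `fall_days`, hold at `base - depth` for
#' `duration_days`, linear recovery over `recover_days`).
#'
#' @param dip_start Dip onset (time, POSIXct/Date/ISO string), or `NULL` for a
#'   constant curve.
#' @param depth Dip depth in `[0, 1]` (default 0.6).
#' @param duration_days Hold duration in days (default 3).
#' @param base Baseline level (default 1).
#' @param fall_days,recover_days Ramp lengths in days (defaults 0.5 and 4).
#' @return A vectorised function `f(t_seconds) -> [0, 1]`, with attribute
#'   `dip_interval` (onset, end-of-recovery) when a dip is present.
#' @export
make_welfare_curve <- function(dip_start = NULL, depth = 0.6, duration_days = 3,
                               base = 1, fall_days = 0.5, recover_days = 4) {
  stopifnot(base >= 0, base <= 1, depth >= 0, depth <= 1)
  if (is.null(dip_start)) {
    f <- function(t) rep(base, length(t))
    return(f)
  }
  s <- as_utc_time(dip_start)
  fall <- fall_days * 86400; hold <- duration_days * 86400; rec <- recover_days * 86400
  f <- function(t) {
    w <- rep(base, length(t))
    d <- t - s
    i <- d >= 0 & d < fall
    w[i] <- base - depth * d[i] / fall
    i <- d >= fall & d < fall + hold
    w[i] <- base - depth
    i <- d >= fall + hold & d < fall + hold + rec
    w[i] <- base - depth * (1 - (d[i] - fall - hold) / rec)
    pmin(pmax(w, 0), 1)
  }
  attr(f, "dip_interval") <- c(s, s + fall + hold + rec)
  f
}

#' Simulation configuration for a synthetic herd
#'
#' Defaults emulate the study herd: 24 spring-born dairy calves in four birth
#' cohorts (5 born 2 Mar, 4 born 14 Mar, 4 born 21 Mar, 11 born 5 Apr 2019),
#' each logged ~60 days from collar-on (1--5 days after birth) at 12.5 Hz, a
#' 14-day acclimatisation ramp, a shared welfare dip starting 2 May, and 5
#' animals with long collar-off gaps (the ones the exclusion rule should
#' remove).
#'
#' @param n_animals Herd size (default 24).
#' @param birth_dates Birth timestamps, recycled/truncated to `n_animals`;
#'   default = the four staggered cohorts above.
#' @param days_logged Logging span per animal in days, from collar-on
#'   (default 60); scalar or per-animal.
#' @param rate Raw sampling rate in Hz (default 12.5).
#' @param epoch_len Epoch length in seconds for epoch-mode output (default 60).
#' @param rest_level Resting envelope level in g (default 0.05).
#' @param circadian_amplitude Base diurnal envelope amplitude `a` in g
#'   (default 0.3); scalar or per-animal. Per-animal amplitudes get a
#'   `amplitude_jitter` relative spread unless given explicitly.
#' @param amplitude_jitter Relative uniform jitter on `a` (default 0.3).
#' @param acclimatisation_days Ramp length in days from birth (default 14).
#' @param welfare_curve Herd-shared function of time into `[0, 1]`; default
#'   [make_welfare_curve()] with a depth-0.6, 3-day dip starting 2 May 2019.
#' @param epoch_noise_sigma Epoch-mode observation noise s.d. in g
#'   (default 0.10).
#' @param noise_sigma Raw-mode sensor noise s.d. in g (default 0.02).
#' @param phase_jitter_sd S.d. of per-animal diurnal phase jitter in radians
#'   (default 0.2; herds synchronise to shared zeitgebers).
#' @param gap_schedule Optional list (per animal) of 2-column matrices of
#'   collar-off intervals (start, end seconds); overrides the generated gaps.
#' @param n_gap_animals Number of animals given heavy generated collar-off
#'   gaps (default 5).
#' @param gap_frac Fraction of a heavy-gap animal's span removed (default
#'   0.35, spread over several intervals).
#' @param collar_on_delay_days Range of days between birth and collar-on
#'   (default `c(1, 5)`).
#' @param start_snap Grid (seconds) collar-on times are snapped to (default
#'   900, the trace step) so per-animal window anchors align across the herd.
#' @param seed Run seed (default 1); every animal derives its own stream seed
#'   from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_animals = 24,
                       birth_dates = NULL,
                       days_logged = 60,
                       rate = 12.5,
                       epoch_len = 60,
                       rest_level = 0.05,
                       circadian_amplitude = 0.3,
                       amplitude_jitter = 0.3,
                       acclimatisation_days = 14,
                       welfare_curve = NULL,
                       epoch_noise_sigma = 0.10,
                       noise_sigma = 0.02,
                       phase_jitter_sd = 0.2,
                       gap_schedule = NULL,
                       n_gap_animals = 5,
                       gap_frac = 0.35,
                       collar_on_delay_days = c(1, 5),
                       start_snap = 900,
                       seed = 1) {
  if (is.null(birth_dates)) {
    cohorts <- c(rep("2019-03-02", 5), rep("2019-03-14", 4),
                 rep("2019-03-21", 4), rep("2019-04-05", 11))
    birth_dates <- rep_len(cohorts, n_animals)
  }
  birth_dates <- vapply(rep_len(as.list(birth_dates), n_animals),
                        as_utc_time, numeric(1))
  if (is.null(welfare_curve))
    welfare_curve <- make_welfare_curve("2019-05-02")
  stopifnot(n_animals >= 1, all(days_logged > 0), rate > 0, epoch_len > 0,
            rest_level >= 0, all(circadian_amplitude >= 0),
            acclimatisation_days >= 0, is.function(welfare_curve))
  structure(list(
    n_animals = n_animals, birth_dates = birth_dates,
    days_logged = rep_len(days_logged, n_animals), rate = rate,
    epoch_len = epoch_len, rest_level = rest_level,
    circadian_amplitude = rep_len(circadian_amplitude, n_animals),
    amplitude_jitter = amplitude_jitter,
    acclimatisation_days = acclimatisation_days,
    welfare_curve = welfare_curve,
    epoch_noise_sigma = epoch_noise_sigma, noise_sigma = noise_sigma,
    phase_jitter_sd = phase_jitter_sd,
    gap_schedule = gap_schedule, n_gap_animals = n_gap_animals,
    gap_frac = gap_frac, collar_on_delay_days = collar_on_delay_days,
    start_snap = start_snap, seed = seed), class = "sim_config")
}

# Per-animal deterministic draws (amplitude factor, phase, collar delay,
# gaps). Everything below depends only on (config$seed, animal_index).
#' @keywords internal
.animal_params <- function(config, i) {
  set.seed(derive_seed(config$seed, i))
  amp_given <- length(unique(config$circadian_amplitude)) > 1
  jit <- if (amp_given) 1 else stats::runif(1, 1 - config$amplitude_jitter,
                                            1 + config$amplitude_jitter)
  a <- config$circadian_amplitude[i] * jit
  phi <- stats::rnorm(1, 0, config$phase_jitter_sd)
  delay <- stats::runif(1, config$collar_on_delay_days[1],
                        config$collar_on_delay_days[2]) * 86400
  birth <- config$birth_dates[i]
  # snap collar-on to the trace step grid so per-animal anchors align by
  # date and time across the herd
  start <- round((birth + delay) / config$start_snap) * config$start_snap
  end <- start + config$days_logged[i] * 86400
  gaps <- NULL
  if (!is.null(config$gap_schedule)) {
    gaps <- config$gap_schedule[[i]]
  } else if (config$n_gap_animals > 0) {
    gap_ids <- round(seq(1, config$n_animals,
                         length.out = min(config$n_gap_animals, config$n_animals)))
    if (i %in% gap_ids) {
      # three disjoint collar-off intervals totalling gap_frac of the span,
      # spread across it so the trace-level damage is unambiguous
      k <- 3L
      span <- end - start
      len <- config$gap_frac * span / k
      anchors <- (c(0.12, 0.42, 0.72) + stats::runif(k, -0.03, 0.03)) * span
      gaps <- cbind(start + anchors, start + anchors + len)
    }
  }
  list(a = a, phi = phi, birth = birth, start = start, end = end, gaps = gaps)
}

#' @keywords internal
.envelope <- function(t, config, pars) {
  ramp <- if (config$acclimatisation_days > 0)
    pmin(1, pmax(0, (t - pars$birth) / (config$acclimatisation_days * 86400)))
  else rep(1, length(t))
  w <- config$welfare_curve(t)
  diurnal <- (1 + sin(2 * pi * t / 86400 + pars$phi)) / 2
  config$rest_level + pars$a * ramp * w * diurnal
}

#' @keywords internal
.in_gap <- function(t, gaps) {
  if (is.null(gaps) || !nrow(gaps)) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (g in seq_len(nrow(gaps))) out <- out | (t >= gaps[g, 1] & t < gaps[g, 2])
  out
}

#' Simulate one animal
#'
#' Deterministic under `(config$seed, animal_index)`. In `"epoch"` mode the
#' activity envelope is sampled directly on the epoch grid with Gaussian
#' observation noise (collar-off epochs flagged missing); in `"raw"` mode
#' 12.5 Hz triaxial samples are emitted as a slowly wandering gravity unit
#' vector plus zero-mean burst noise whose per-axis s.d. is the envelope, plus
#' sensor noise (collar-off samples are timestamp holes).
#'
#' @param config A [sim_config()].
#' @param animal_index Index in `1:n_animals`.
#' @param mode `"epoch"` or `"raw"`.
#' @return A list: `data` (an `epoch_series` or [triaxial_stream()]),
#'   `truth` (amplitude, phase, birth, span, gap intervals, dip interval,
#'   envelope function) and `animal_id`.
#' @export
simulate_animal <- function(config, animal_index, mode = c("epoch", "raw")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "sim_config"),
            animal_index >= 1, animal_index <= config$n_animals)
  pars <- .animal_params(config, animal_index)
  id <- sprintf("calf%03d", animal_index)
  set.seed(derive_seed(config$seed, animal_index) %% 2147480000L + 101L)
  if (mode == "epoch") {
    t <- seq(pars$start, pars$end - config$epoch_len, by = config$epoch_len)
    lam <- .envelope(t, config, pars)
    value <- pmax(0, lam + stats::rnorm(length(t), 0, config$epoch_noise_sigma))
    missing <- .in_gap(t, pars$gaps)
    value[missing] <- NA_real_
    df <- tibble::tibble(epoch_start = t, value = value, missing = missing)
    data <- structure(df, class = c("epoch_series", class(tibble::tibble())),
                      animal_id = id, epoch_len = config$epoch_len)
  } else {
    t <- seq(pars$start, pars$end, by = 1 / config$rate)
    keep <- !.in_gap(t, pars$gaps)
    t <- t[keep]
    lam <- .envelope(t, config, pars)
    # gravity unit vector with slow orientation wander (periods of hours)
    th <- 0.4 * sin(2 * pi * t / (3.1 * 3600) + stats::runif(1, 0, 2 * pi)) + 0.8
    ps <- 2 * pi * t / (5.7 * 3600) + stats::runif(1, 0, 2 * pi)
    gx <- sin(th) * cos(ps); gy <- sin(th) * sin(ps); gz <- cos(th)
    n <- length(t)
    noise <- function() stats::rnorm(n, 0, 1) * lam + stats::rnorm(n, 0, config$noise_sigma)
    clamp <- function(v) pmin(pmax(v, -8), 8)
    data <- triaxial_stream(t, clamp(gx + noise()), clamp(gy + noise()),
                            clamp(gz + noise()),
                            animal_id = id, nominal_rate = config$rate)
  }
  truth <- list(animal_id = id, amplitude = pars$a, phase = pars$phi,
                birth = pars$birth, start = pars$start, end = pars$end,
                gaps = pars$gaps,
                dip_interval = attr(config$welfare_curve, "dip_interval"),
                envelope = function(t) .envelope(t, config, pars))
  list(animal_id = id, data = data, truth = truth)
}

#' Simulate a whole herd
#'
#' Runs [simulate_animal()] for every index with independent phases and noise
#' but the shared welfare curve, and builds a manifest.
#'
#' @param config A [sim_config()].
#' @param mode `"epoch"` or `"raw"` (see [simulate_animal()]).
#' @return A list: `animals` (per-animal lists), `manifest` (tibble
#'   `animal_id`, `birth_date`, `start`, `end`, `amplitude`, `has_gaps`) and
#'   `config`.
#' @export
simulate_herd <- function(config, mode = c("epoch", "raw")) {
  mode <- match.arg(mode)
  animals <- lapply(seq_len(config$n_animals), function(i)
    simulate_animal(config, i, mode = mode))
  manifest <- tibble::tibble(
    animal_id = vapply(animals, `[[`, character(1), "animal_id"),
    birth_date = vapply(animals, function(a) a$truth$birth, numeric(1)),
    start = vapply(animals, function(a) a$truth$start, numeric(1)),
    end = vapply(animals, function(a) a$truth$end, numeric(1)),
    amplitude = vapply(animals, function(a) a$truth$amplitude, numeric(1)),
    has_gaps = vapply(animals, function(a) !is.null(a$truth$gaps), logical(1)))
  list(animals = animals, manifest = manifest, config = config)
}

#' Write a raw stream in the triaxial CSV dialect
#'
#' The same `timestamp,x,y,z` dialect [read_triaxial_csv()] reads.
#'
#' @param stream A [triaxial_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_triaxial_csv <- function(stream, path) {
  readr::write_csv(tibble::tibble(timestamp = stream$time, x = stream$x,
                                  y = stream$y, z = stream$z), path)
  invisible(path)
}
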