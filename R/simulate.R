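# Synthetic physiology generators. All randomness is drawn from streams
# derived deterministically from config$seed (one fixed offset per
# generator), so identical seed + config give bit-identical outputs while
# ABP, ICP and ventilator noise remain mutually independent.

.seed_offset <- c(abp = 11L, icp = 23L, vent = 37L, cohort = 53L,
                  gases = 71L)

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

# band-limited unit-variance Gaussian process via FFT masking
band_limited_noise <- function(n, fs, band) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  freqs <- (seq_len(n) - 1L) * fs / n
  freqs <- pmin(freqs, fs - freqs)           # two-sided
  W[freqs < band[1L] | freqs > band[2L]] <- 0 + 0i
  s <- Re(stats::fft(W, inverse = TRUE)) / n
  sdev <- stats::sd(s)
  if (sdev == 0) rep(0, n) else s / sdev
}

# brick-wall FFT low-pass (used to extract the slow-wave component)
lowpass_fft <- function(x, fs, cutoff) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1L) * fs / n
  freqs <- pmin(freqs, fs - freqs)
  X[freqs > cutoff] <- 0 + 0i
  Re(stats::fft(X, inverse = TRUE)) / n
}

#' Simulate an arterial blood pressure waveform
#'
#' ABP = baseline + vasogenic slow-wave component (band-limited in
#' `slow_wave_band`) + cardiac pulsation at the heart rate (with a small
#' second harmonic) + ventilator-frequency modulation + white noise.
#' Deterministic given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param duration record length in seconds (> 0).
#' @param start_time start of the record in seconds.
#' @return an `"ABP"` [waveform()].
#' @export
simulate_abp <- function(config, duration, start_time = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  fs <- config$sampling_rate
  n <- round(duration * fs)
  t <- start_time + (seq_len(n) - 1L) / fs
  slow <- slow_wave_component(config, n, fs,
                              seed = config$seed + .seed_offset[["abp"]])
  f_hr <- config$heart_rate / 60
  f_rr <- config$respiratory_rate / 60
  pulse <- config$pulse_amplitude_abp *
    (sin(2 * pi * f_hr * t) + 0.3 * sin(4 * pi * f_hr * t))
  resp <- config$resp_amplitude_abp * sin(2 * pi * f_rr * t)
  noise <- if (config$noise_sd$abp > 0)
    with_seed(config$seed + .seed_offset[["abp"]] + 1L,
              stats::rnorm(n, 0, config$noise_sd$abp)) else 0
  waveform(config$baseline_abp + slow + pulse + resp + noise, fs, "ABP",
           start_time)
}

slow_wave_component <- function(config, n, fs, seed) {
  if (config$slow_wave_amplitude == 0) return(rep(0, n))
  if (config$slow_wave_mode == "sinusoid") {
    f0 <- sqrt(prod(config$slow_wave_band))   # geometric band center
    t <- (seq_len(n) - 1L) / fs
    config$slow_wave_amplitude * sin(2 * pi * f0 * t)
  } else {
    # match the RMS of a sinusoid with the configured amplitude
    with_seed(seed,
              band_limited_noise(n, fs, config$slow_wave_band)) *
      config$slow_wave_amplitude / sqrt(2)
  }
}

#' Simulate an intracranial pressure waveform coupled to ABP
#'
#' `ICP(t) = baseline_icp + g * S(t) + beta * (PEEP(t) - 5) + pulse +
#' respiratory modulation + noise`, where `S(t)` is the slow (< 0.05 Hz)
#' component of the supplied ABP record, `g` the signed vasoreactivity
#' gain and `beta` the PEEP-to-ICP slope. PEEP steps settle exponentially
#' with `config$peep_settle_tau`. The cardiac pulse amplitude follows the
#' exponential craniospinal pressure-volume surrogate
#' `AMP(t) = a0 * exp(k * (meanICP(t) - knee))`, clipped below at `a0`,
#' so pulse amplitude grows once mean ICP exceeds the knee.
#'
#' @param abp the ABP [waveform()] the record couples to; must cover the
#'   protocol span.
#' @param config a [sim_config()].
#' @param protocol a [protocol_design()] (or `NULL` for constant PEEP 5).
#' @return an `"ICP"` [waveform()] aligned with `abp`.
#' @export
simulate_icp <- function(abp, config, protocol = NULL) {
  stopifnot(inherits(abp, "waveform"), inherits(config, "sim_config"))
  fs <- abp$fs
  n <- length(abp$values)
  t <- wf_time(abp)
  if (!is.null(protocol)) {
    sp <- protocol_span(protocol)
    if (sp[1L] < abp$start_time - 1e-9 || sp[2L] > wf_end_time(abp) + 1e-9)
      stop("protocol lies outside the ABP record span", call. = FALSE)
  }
  S <- lowpass_fft(abp$values - mean(abp$values), fs, 0.05)
  peep <- if (is.null(protocol)) rep(5, n)
          else peep_at(protocol, t, config$peep_settle_tau)
  mean_icp <- config$baseline_icp + config$vasoreactivity_gain * S +
    config$peep_icp_slope * (peep - 5)
  a0 <- config$pulse_amplitude_icp
  amp <- pmax(a0, a0 * exp(config$pv_exponent *
                             (mean_icp - config$pv_knee_icp)))
  f_hr <- config$heart_rate / 60
  f_rr <- config$respiratory_rate / 60
  pulse <- amp * sin(2 * pi * f_hr * t)
  resp <- config$resp_amplitude_icp * sin(2 * pi * f_rr * t)
  noise <- if (config$noise_sd$icp > 0)
    with_seed(config$seed + .seed_offset[["icp"]],
              stats::rnorm(n, 0, config$noise_sd$icp)) else 0
  waveform(mean_icp + pulse + resp + noise, fs, "ICP", abp$start_time)
}

#' Simulate ventilator waveforms with embedded occlusion maneuvers
#'
#' Volume-controlled breath shapes (constant inspiratory flow, 20%
#' end-inspiratory pause, passive exponential expiration, I:E 1:2) for
#' airway pressure, esophageal pressure and flow over a protocol. At each
#' PEEP period one 5-s end-inspiratory and one 5-s end-expiratory
#' zero-flow hold are embedded; by construction the plateau pressures
#' satisfy `Pawei = PEEP + VT * (El + Ecw)` and
#' `Pesei - Pesee = VT * Ecw`, and pressure excursions during holds obey
#' `dPes/dPaw = pes_to_paw_ratio` (a 1-Hz cardiac-scale oscillation is
#' superimposed on both channels during holds so the Baydur ratio is
#' measurable).
#'
#' @param config a [sim_config()].
#' @param protocol a [protocol_design()].
#' @return list with `"PAW"`, `"PES"` (cmH2O) and `"FLOW"` (L/s)
#'   [waveform()]s plus `holds`, a data.frame of ground-truth hold windows
#'   (`period` row index, `kind`, `start`, `end`).
#' @export
simulate_ventilator <- function(config, protocol) {
  stopifnot(inherits(config, "sim_config"),
            inherits(protocol, "protocol_design"))
  fs <- config$sampling_rate
  span <- protocol_span(protocol)
  n <- round((span[2L] - span[1L]) * fs)
  t <- span[1L] + (seq_len(n) - 1L) / fs
  Tc <- 60 / config$respiratory_rate
  Ti <- Tc / 3                               # I:E = 1:2
  Tflow <- 0.8 * Ti                          # 20% inspiratory pause
  Te <- Tc - Ti
  tau_e <- Te / 4
  VT <- config$tidal_volume
  Ecw <- config$chest_wall_elastance
  El <- config$lung_elastance
  Ers <- Ecw + El
  R <- config$airway_resistance
  Qi <- if (Tflow > 0) VT / Tflow else 0

  phase <- (t - span[1L]) %% Tc
  flow <- numeric(n)
  vol <- numeric(n)
  insp <- phase < Tflow
  pause <- phase >= Tflow & phase < Ti
  expi <- phase >= Ti
  flow[insp] <- Qi
  vol[insp] <- Qi * phase[insp]
  vol[pause] <- VT
  te <- phase[expi] - Ti
  vol[expi] <- VT * exp(-te / tau_e)
  flow[expi] <- -VT / tau_e * exp(-te / tau_e)

  peep <- peep_at(protocol, t, config$peep_settle_tau)
  paw <- peep + Ers * vol + R * flow
  pes <- config$pes_baseline +
    config$peep_pes_transmission * (peep - 5) + Ecw * vol

  # schedule one end-inspiratory and one end-expiratory hold per period,
  # snapped to breath phase so the hold starts at a settled state and
  # lasts a whole number of cycles (>= 5 s), so ventilation resumes
  # phase-continuously when the hold releases
  hold_dur <- ceiling(5 / Tc) * Tc
  holds <- do.call(rbind, lapply(seq_len(nrow(protocol)), function(i) {
    p0 <- protocol$start[i]
    dur <- protocol$duration[i]
    ei_nom <- p0 + 0.55 * dur
    ee_nom <- p0 + 0.75 * dur
    k_ei <- ceiling((ei_nom - span[1L] - Ti) / Tc)
    ei_start <- span[1L] + k_ei * Tc + Ti     # end of an insp. pause
    k_ee <- ceiling((ee_nom - span[1L]) / Tc)
    ee_start <- span[1L] + k_ee * Tc          # end of an expiration
    data.frame(period = i,
               kind = c("end_inspiratory", "end_expiratory"),
               start = c(ei_start, ee_start),
               end = c(ei_start, ee_start) + hold_dur)
  }))

  settle_tau <- 0.3
  for (i in seq_len(nrow(holds))) {
    idx <- which(t >= holds$start[i] & t < holds$end[i])
    if (length(idx) == 0L) next
    tr <- t[idx] - holds$start[i]
    pk <- peep_at(protocol, holds$start[i], 0)
    wig <- sin(2 * pi * 1 * tr)               # 1 Hz cardiac-scale wiggle
    flow[idx] <- 0
    if (holds$kind[i] == "end_inspiratory") {
      plat <- pk + Ers * VT
      peak <- plat + R * Qi
      paw[idx] <- plat + (peak - plat) * exp(-tr / settle_tau) + 0.5 * wig
      pes[idx] <- config$pes_baseline +
        config$peep_pes_transmission * (pk - 5) + Ecw * VT +
        config$pes_to_paw_ratio * 0.5 * wig
    } else {
      paw[idx] <- pk + 0.5 * wig              # full exhalation: V = 0
      pes[idx] <- config$pes_baseline +
        config$peep_pes_transmission * (pk - 5) +
        config$pes_to_paw_ratio * 0.5 * wig
    }
  }

  add_noise <- function(x, sd, off) {
    if (sd > 0) x + with_seed(config$seed + .seed_offset[["vent"]] + off,
                              stats::rnorm(n, 0, sd)) else x
  }
  list(paw = waveform(add_noise(paw, config$noise_sd$paw, 0L), fs, "PAW",
                      span[1L]),
       pes = waveform(add_noise(pes, config$noise_sd$pes, 1L), fs, "PES",
                      span[1L]),
       flow = waveform(add_noise(flow, config$noise_sd$flow, 2L), fs,
                       "FLOW", span[1L]),
       holds = holds)
}

#' Inject spike and dropout artifacts into a waveform
#'
#' Spikes force whole 10-s-aligned segments to an implausible absolute
#' level (outside the validity interval for the channel under the default
#' spec); dropouts mark segments invalid. Returns both the corrupted
#' waveform and the ground-truth artifact windows so cleaning rules can be
#' scored exactly. Deterministic given `seed`.
#'
#' @param x a [waveform()].
#' @param spec an [artifact_spec()].
#' @param seed integer seed for event placement.
#' @return list(`waveform`, `windows`) where `windows` is a data.frame
#'   with `kind` ("spike"/"dropout"), `start`, `end`, `level` (NA for
#'   dropouts).
#' @export
inject_artifacts <- function(x, spec, seed = 1L) {
  stopifnot(inherits(x, "waveform"), inherits(spec, "artifact_spec"))
  dur_h <- length(x$values) / x$fs / 3600
  empty <- data.frame(kind = character(0), start = numeric(0),
                      end = numeric(0), level = numeric(0))
  if (spec$spike_rate == 0 && spec$dropout_rate == 0)
    return(list(waveform = x, windows = empty))
  out <- with_seed(seed, {
    n_spike <- stats::rpois(1L, spec$spike_rate * dur_h)
    n_drop <- stats::rpois(1L, spec$dropout_rate * dur_h)
    # candidate slots on the 10-s grid, wide enough for the longest event
    slot_len <- max(spec$spike_duration, spec$dropout_duration)
    n_slots <- floor(length(x$values) / x$fs / slot_len)
    n_ev <- min(n_spike + n_drop, n_slots)
    n_spike <- min(n_spike, n_ev)
    n_drop <- n_ev - n_spike
    slots <- if (n_ev > 0) sort(sample.int(n_slots, n_ev)) else integer(0)
    kinds <- sample(rep(c("spike", "dropout"), c(n_spike, n_drop)))
    lv <- numeric(n_ev)
    win <- empty
    for (j in seq_len(n_ev)) {
      s0 <- x$start_time + (slots[j] - 1L) * slot_len
      if (kinds[j] == "spike") {
        d <- spec$spike_duration
        pos <- stats::runif(1L) < spec$spike_sign_prob
        lv[j] <- if (pos) stats::runif(1L, spec$spike_high[1L],
                                       spec$spike_high[2L])
                 else stats::runif(1L, spec$spike_low[1L],
                                   spec$spike_low[2L])
      } else {
        d <- spec$dropout_duration
        lv[j] <- NA_real_
      }
      win <- rbind(win, data.frame(kind = kinds[j], start = s0,
                                   end = s0 + d, level = lv[j]))
    }
    win
  })
  tt <- wf_time(x)
  for (j in seq_len(nrow(out))) {
    idx <- tt >= out$start[j] & tt < out$end[j]
    if (out$kind[j] == "spike") x$values[idx] <- out$level[j]
    else x$valid[idx] <- FALSE
  }
  list(waveform = x, windows = out)
}

#' Simulate per-period blood gases and brain oxygen tension
#'
#' Arterial gases per protocol period: PaO2 rises with PEEP (recruitment),
#' PaCO2 is held near-stable by protocolized ventilator adjustment, and
#' the brain-tissue oxygen trend is an affine function of PaO2 plus noise
#' (no sensor biophysics). FiO2 is fixed at 0.40.
#'
#' @param protocol a [protocol_design()].
#' @param config a [sim_config()].
#' @param pao2_base,pao2_peep_slope mmHg and mmHg/cmH2O above PEEP 5.
#' @param paco2_mean,paco2_sd mmHg.
#' @param pbo2_slope,pbo2_intercept,pbo2_sd PbO2 = intercept +
#'   slope * PaO2 + noise.
#' @return data.frame with one row per period: `PaO2`, `PaCO2`, `pH`,
#'   `FiO2`, `PF` (PaO2/FiO2), `PbO2`.
#' @export
simulate_blood_gases <- function(protocol, config, pao2_base = 150,
                                 pao2_peep_slope = 8, paco2_mean = 48,
                                 paco2_sd = 1.5, pbo2_slope = 0.15,
                                 pbo2_intercept = 1, pbo2_sd = 2) {
  n <- nrow(protocol)
  noise_on <- config$noise_sd$abp > 0    # noise-free mode zeroes all SDs
  with_seed(config$seed + .seed_offset[["gases"]], {
    pao2 <- pao2_base + pao2_peep_slope * (protocol$peep - 5) +
      if (noise_on) stats::rnorm(n, 0, 12) else 0
    paco2 <- paco2_mean + if (noise_on) stats::rnorm(n, 0, paco2_sd) else 0
    pbo2 <- pbo2_intercept + pbo2_slope * pao2 +
      if (noise_on) stats::rnorm(n, 0, pbo2_sd) else 0
    data.frame(PaO2 = pao2, PaCO2 = paco2,
               pH = 7.4 - 0.008 * (paco2 - 40), FiO2 = 0.4,
               PF = pao2 / 0.4, PbO2 = pbo2)
  })
}

#' Generate a synthetic crossover cohort with known ground truth
#'
#' Balanced allocation of position sequences (half prone-first, half
#' supine-first), per-animal parameter draws around the configured means,
#' and per-animal ABP/ICP (optionally ventilator) waveforms over the full
#' two-block protocol. The returned truth table holds every animal's drawn
#' vasoreactivity gain `g` and PEEP slope `beta`, the targets downstream
#' recovery checks are scored against.
#'
#' @param n_animals even number of animals (default 12).
#' @param config a [sim_config()] of cohort-mean parameters.
#' @param seed cohort seed (per-animal seeds are derived from it).
#' @param step_minutes PEEP-step duration passed to [protocol_design()].
#' @param channels subset of `c("abp", "icp", "vent")` to simulate.
#' @param variation named list of between-animal SDs:
#'   `g`, `beta`, `baseline_icp`, `baseline_abp` (defaults 0.1, 0.05,
#'   2 mmHg, 5 mmHg; all forced to 0 when `config` is noise-free).
#' @return list of class `"sim_cohort"`: `animals` (per animal: `protocol`,
#'   `waves`, `gases`, `config`), `truth` (data.frame of drawn
#'   parameters), `config`, `seed`.
#' @export
generate_cohort <- function(n_animals = 12, config = sim_config(),
                            seed = 1L, step_minutes = 20,
                            channels = c("abp", "icp"),
                            variation = list()) {
  stopifnot(n_animals >= 2, n_animals %% 2 == 0)
  channels <- match.arg(channels, c("abp", "icp", "vent"),
                        several.ok = TRUE)
  noise_on <- config$noise_sd$abp > 0 || config$slow_wave_amplitude > 0
  vdef <- list(g = 0.1, beta = 0.05, baseline_icp = 2, baseline_abp = 5)
  if (!noise_on) vdef <- list(g = 0, beta = 0, baseline_icp = 0,
                              baseline_abp = 0)
  vdef[names(variation)] <- variation
  seqs <- with_seed(seed + .seed_offset[["cohort"]],
                    sample(rep(c("prone_first", "supine_first"),
                               each = n_animals / 2)))
  draws <- with_seed(seed + .seed_offset[["cohort"]] + 1L, data.frame(
    animal_id = sprintf("A%02d", seq_len(n_animals)),
    sequence = seqs,
    g = stats::rnorm(n_animals, config$vasoreactivity_gain, vdef$g),
    beta = stats::rnorm(n_animals, config$peep_icp_slope, vdef$beta),
    baseline_icp = stats::rnorm(n_animals, config$baseline_icp,
                                vdef$baseline_icp),
    baseline_abp = stats::rnorm(n_animals, config$baseline_abp,
                                vdef$baseline_abp)))
  animals <- lapply(seq_len(n_animals), function(i) {
    cfg <- config
    cfg$seed <- seed * 1000L + i
    cfg$vasoreactivity_gain <- draws$g[i]
    cfg$peep_icp_slope <- draws$beta[i]
    cfg$baseline_icp <- draws$baseline_icp[i]
    cfg$baseline_abp <- draws$baseline_abp[i]
    prot <- protocol_design(draws$animal_id[i], draws$sequence[i],
                            step_minutes = step_minutes)
    span <- protocol_span(prot)
    waves <- list()
    if ("abp" %in% channels || "icp" %in% channels)
      waves$abp <- simulate_abp(cfg, span[2L] - span[1L], span[1L])
    if ("icp" %in% channels)
      waves$icp <- simulate_icp(waves$abp, cfg, prot)
    if ("vent" %in% channels) {
      vent <- simulate_ventilator(cfg, prot)
      waves$paw <- vent$paw; waves$pes <- vent$pes; waves$flow <- vent$flow
      waves$holds <- vent$holds
    }
    list(animal_id = draws$animal_id[i], protocol = prot, waves = waves,
         gases = simulate_blood_gases(prot, cfg), config = cfg)
  })
  structure(list(animals = animals, truth = draws, config = config,
                 seed = seed),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d animals (%d prone-first), seed %d\n",
              nrow(x$truth), sum(x$truth$sequence == "prone_first"),
              x$seed))
  invisible(x)
}

#' Simulate a per-period summary table directly (trend-level shortcut)
#'
#' Generates the `PeriodSummary` table a full waveform pipeline run would
#' produce, directly from the period-mean model
#' `ICP = baseline_animal + position_effect + beta * (PEEP - 5) + effects +
#' noise`. This is the fast generator used for statistical calibration
#' studies (type-I error, power), where hundreds of replicate cohorts are
#' needed and the waveform stages are not under test. Sequence, period
#' (block-order) and carryover effects act on post-baseline periods only,
#' so they survive baseline differencing.
#'
#' @param n_animals even number of animals.
#' @param beta PEEP-to-ICP slope, mmHg/cmH2O above 5.
#' @param sd_animal,sd_position,sd_resid between-animal, between-block and
#'   residual SDs (mmHg).
#' @param sequence_effect mmHg added to post-baseline periods of
#'   supine-first animals (0 under the null).
#' @param period_effect mmHg added to post-baseline periods of the second
#'   position block.
#' @param carryover mmHg added to post-baseline periods of the second
#'   block of prone-first animals only (differential carryover).
#' @param position_effect mmHg added in the supine position.
#' @param position_beta_diff extra PEEP slope (mmHg/cmH2O) in the supine
#'   position, for simulating a PEEP-by-position interaction.
#' @param covariate_effect modulation of `beta` per unit of the standard
#'   normal animal-level covariate `cov` (mmHg/cmH2O per SD).
#' @param baseline_icp cohort-mean baseline ICP, mmHg.
#' @param seed integer seed.
#' @return data.frame with one row per animal x position x PEEP level:
#'   `animal_id`, `sequence`, `position`, `block`, `period_index`, `peep`,
#'   `ICP`, `cov`.
#' @export
simulate_summary_cohort <- function(n_animals = 12, beta = 0.35,
                                    sd_animal = 3, sd_position = 1,
                                    sd_resid = 1, sequence_effect = 0,
                                    period_effect = 0, carryover = 0,
                                    position_effect = 0,
                                    position_beta_diff = 0,
                                    covariate_effect = 0,
                                    baseline_icp = 9, seed = 1L) {
  stopifnot(n_animals %% 2 == 0)
  with_seed(seed, {
    seqs <- sample(rep(c("prone_first", "supine_first"),
                       each = n_animals / 2))
    base <- stats::rnorm(n_animals, baseline_icp, sd_animal)
    cov <- stats::rnorm(n_animals)
    rows <- do.call(rbind, lapply(seq_len(n_animals), function(i) {
      prot <- protocol_design(sprintf("A%02d", i), seqs[i],
                              step_minutes = 1)
      b_pos <- stats::rnorm(2, 0, sd_position)
      bi <- beta + covariate_effect * cov[i] +
        position_beta_diff * (prot$position == "supine")
      post <- prot$peep > 5
      icp <- base[i] + b_pos[prot$block] + bi * (prot$peep - 5) +
        position_effect * (prot$position == "supine") +
        sequence_effect * (seqs[i] == "supine_first") * post +
        period_effect * (prot$block == 2) * post +
        carryover * (seqs[i] == "prone_first") * (prot$block == 2) * post +
        stats::rnorm(nrow(prot), 0, sd_resid)
      cbind(prot[, c("animal_id", "sequence", "position", "block",
                     "period_index", "peep")],
            ICP = icp, cov = cov[i])
    }))
    rownames(rows) <- NULL
    rows
  })
}
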