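#' Simulation configuration
#'
#' Ground-truth parameters of the synthetic physiology generator. Defaults
#' describe an anesthetized ~25 kg pig with lavage-injured lungs on
#' volume-controlled ventilation: mean ABP 91 mmHg, baseline ICP 9 mmHg,
#' respiratory rate 35/min, tidal volume 0.19 L, chest-wall elastance
#' 17 and lung elastance 65 cmH2O/L. Time is in seconds; vascular and
#' intracranial pressures in mmHg; airway and esophageal pressures in
#' cmH2O; flow in L/s.
#'
#' The two parameters the downstream pipeline is designed to recover are
#' `vasoreactivity_gain` (g) - the signed coupling of ICP to the slow-wave
#' (0.005-0.05 Hz) component of ABP, positive for passive transmission
#' (impaired autoregulation, PRx > 0), negative for active
#' counter-regulation (PRx < 0) - and `peep_icp_slope` (beta, mmHg per
#' cmH2O of PEEP above 5), the linear PEEP-to-ICP coupling.
#'
#' @param seed integer seed; every generator derives its random stream
#'   deterministically from it.
#' @param sampling_rate waveform sampling rate in Hz (>= 50).
#' @param heart_rate beats/min.
#' @param respiratory_rate breaths/min.
#' @param tidal_volume L.
#' @param slow_wave_band Hz interval of vasogenic slow waves, within
#'   (0, 0.1).
#' @param slow_wave_amplitude mmHg; amplitude of the ABP slow-wave
#'   component (sinusoid amplitude in `"sinusoid"` mode; matched RMS in
#'   `"stochastic"` mode).
#' @param slow_wave_mode `"stochastic"` (band-limited Gaussian process,
#'   realistic PRx variance) or `"sinusoid"` (single tone at the geometric
#'   band center, for closed-form checks).
#' @param vasoreactivity_gain dimensionless signed gain g.
#' @param peep_icp_slope beta, mmHg per cmH2O of PEEP above 5.
#' @param baseline_icp,baseline_abp mmHg.
#' @param pulse_amplitude_abp mmHg; cardiac pulsation amplitude of ABP.
#' @param pulse_amplitude_icp mmHg; ICP cardiac pulsation amplitude floor
#'   `a0` of the exponential craniospinal pressure-volume surrogate
#'   `AMP = a0 * exp(pv_exponent * (meanICP - pv_knee_icp))`, clipped below
#'   at `a0`.
#' @param pv_knee_icp mmHg; knee of the pressure-volume surrogate.
#' @param pv_exponent per-mmHg exponent of the surrogate.
#' @param resp_amplitude_abp,resp_amplitude_icp mmHg; ventilator-frequency
#'   modulation amplitudes.
#' @param chest_wall_elastance,lung_elastance cmH2O/L (> 0).
#' @param pes_to_paw_ratio true Baydur ratio reproduced during occlusions.
#' @param airway_resistance cmH2O/(L/s).
#' @param pes_baseline cmH2O; esophageal pressure at end-expiration,
#'   PEEP 5.
#' @param peep_pes_transmission fraction of PEEP above 5 transmitted to
#'   esophageal pressure.
#' @param peep_settle_tau s; time constant of the exponential settling
#'   after each PEEP step change (0 = instantaneous steps).
#' @param noise_sd named per-channel white-noise SDs
#'   (`abp`, `icp` in mmHg; `paw`, `pes` in cmH2O; `flow` in L/s).
#' @param artifact_spec an [artifact_spec()] (rates default to zero).
#' @param noise_free logical; if `TRUE`, zeroes all noise SDs and the
#'   slow-wave amplitude, disables artifacts, and sets
#'   `peep_settle_tau = 0`, giving records on which constructed identities
#'   hold exactly.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       sampling_rate = 50,
                       heart_rate = 100,
                       respiratory_rate = 35,
                       tidal_volume = 0.19,
                       slow_wave_band = c(0.005, 0.05),
                       slow_wave_amplitude = 3,
                       slow_wave_mode = c("stochastic", "sinusoid"),
                       vasoreactivity_gain = 0.3,
                       peep_icp_slope = 0.35,
                       baseline_icp = 9,
                       baseline_abp = 91,
                       pulse_amplitude_abp = 15,
                       pulse_amplitude_icp = 1,
                       pv_knee_icp = 15,
                       pv_exponent = 0.12,
                       resp_amplitude_abp = 3,
                       resp_amplitude_icp = 0.5,
                       chest_wall_elastance = 17,
                       lung_elastance = 65,
                       pes_to_paw_ratio = 1.0,
                       airway_resistance = 10,
                       pes_baseline = 5,
                       peep_pes_transmission = 0.25,
                       peep_settle_tau = 7.5,
                       noise_sd = list(abp = 1.5, icp = 0.3, paw = 0.05,
                                       pes = 0.05, flow = 0.005),
                       artifact_spec = NULL,
                       noise_free = FALSE) {
  slow_wave_mode <- match.arg(slow_wave_mode)
  cfg <- as.list(environment())
  cfg$artifact_spec <- artifact_spec %||% peepicp::artifact_spec()
  if (noise_free) {
    # deterministic mode: all stochastic and oscillatory components off,
    # instantaneous PEEP steps, so constructed identities hold exactly
    cfg$noise_sd <- list(abp = 0, icp = 0, paw = 0, pes = 0, flow = 0)
    cfg$slow_wave_amplitude <- 0
    cfg$pulse_amplitude_abp <- 0
    cfg$pulse_amplitude_icp <- 0
    cfg$resp_amplitude_abp <- 0
    cfg$resp_amplitude_icp <- 0
    cfg$peep_settle_tau <- 0
    cfg$artifact_spec <- peepicp::artifact_spec()
  }
  if (cfg$sampling_rate < 50)
    stop("sampling_rate must be >= 50 Hz", call. = FALSE)
  if (cfg$slow_wave_band[1L] <= 0 || cfg$slow_wave_band[2L] >= 0.1 ||
      diff(cfg$slow_wave_band) <= 0)
    stop("slow_wave_band must be an interval within (0, 0.1) Hz",
         call. = FALSE)
  if (cfg$chest_wall_elastance <= 0 || cfg$lung_elastance <= 0)
    stop("elastances must be positive", call. = FALSE)
  if (abs(cfg$heart_rate - cfg$respiratory_rate) < 5)
    stop("heart and respiratory rates must occupy distinct spectral bands",
         call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> fs=%g Hz, HR=%g/min, RR=%g/min, VT=%g L\n",
    "  g=%+.2f, beta=%.2f mmHg/cmH2O, ICP0=%g, ABP0=%g mmHg\n",
    "  Ecw=%g, El=%g cmH2O/L, Baydur ratio=%g, slow waves: %s\n"),
    x$sampling_rate, x$heart_rate, x$respiratory_rate, x$tidal_volume,
    x$vasoreactivity_gain, x$peep_icp_slope, x$baseline_icp,
    x$baseline_abp, x$chest_wall_elastance, x$lung_elastance,
    x$pes_to_paw_ratio, x$slow_wave_mode))
  invisible(x)
}

#' Artifact injection specification
#'
#' Rates and magnitudes of the two artifact families the cleaning rules
#' must catch: spikes (segments forced to an implausible absolute level)
#' and dropouts (segments marked invalid, emulating sensor disconnection).
#' Artifact windows are aligned to the 10-s coarse-graining grid and have
#' durations in whole 10-s multiples, so ground-truth bookkeeping maps
#' one-to-one onto trend windows.
#'
#' @param spike_rate,dropout_rate expected events per hour.
#' @param spike_duration,dropout_duration s, multiples of 10.
#' @param spike_high,spike_low ranges (in channel units) from which the
#'   level of positive / negative spikes is drawn; for ICP the defaults
#'   land outside the \[-10, 60\] mmHg validity interval.
#' @param spike_sign_prob probability a spike is positive.
#' @return a list of class `"artifact_spec"`.
#' @export
artifact_spec <- function(spike_rate = 0, dropout_rate = 0,
                          spike_duration = 10, dropout_duration = 20,
                          spike_high = c(65, 120),
                          spike_low = c(-40, -15),
                          spike_sign_prob = 0.5) {
  if (spike_duration %% 10 != 0 || dropout_duration %% 10 != 0)
    stop("artifact durations must be multiples of 10 s", call. = FALSE)
  structure(as.list(environment()), class = "artifact_spec")
}

#' Protocol design for one animal
#'
#' The randomized crossover PEEP-titration schedule: two position blocks
#' (prone and supine, order set by `sequence`), each stepping PEEP through
#' 5, 10, 15 and 20 cmH2O in that order, each level held for
#' `step_minutes` (nominally 20; scale down for fast tests).
#'
#' @param animal_id identifier.
#' @param sequence `"prone_first"` or `"supine_first"`.
#' @param step_minutes duration of each PEEP level in minutes.
#' @param start start time of the first period in seconds.
#' @return a data.frame of class `"protocol_design"` with one row per
#'   period: `animal_id`, `sequence`, `position`, `block` (1 or 2),
#'   `period_index` (1-4 within block), `peep`, `start`, `duration`.
#' @export
protocol_design <- function(animal_id = "A1",
                            sequence = c("prone_first", "supine_first"),
                            step_minutes = 20, start = 0) {
  sequence <- match.arg(sequence)
  positions <- if (sequence == "prone_first") c("prone", "supine")
               else c("supine", "prone")
  peeps <- c(5, 10, 15, 20)
  dur <- step_minutes * 60
  rows <- expand.grid(period_index = seq_along(peeps), block = 1:2)
  d <- data.frame(
    animal_id = animal_id, sequence = sequence,
    position = positions[rows$block], block = rows$block,
    period_index = rows$period_index, peep = peeps[rows$period_index],
    duration = dur)
  d$start <- start + (seq_len(nrow(d)) - 1L) * dur
  d <- d[, c("animal_id", "sequence", "position", "block", "period_index",
             "peep", "start", "duration")]
  class(d) <- c("protocol_design", "data.frame")
  d
}

protocol_span <- function(protocol) {
  c(min(protocol$start), max(protocol$start + protocol$duration))
}

#' PEEP level as a function of time
#'
#' Piecewise-constant set PEEP from a protocol, optionally smoothed with
#' the first-order exponential settling applied at step changes.
#'
#' @param protocol a [protocol_design()].
#' @param time numeric vector of times in seconds.
#' @param settle_tau settling time constant in seconds (0 = steps).
#' @return numeric vector of PEEP (cmH2O) at `time`.
#' @export
peep_at <- function(protocol, time, settle_tau = 0) {
  idx <- findInterval(time, protocol$start)
  p <- protocol$peep[pmax(1L, idx)]
  p[idx < 1L] <- protocol$peep[1L]
  if (settle_tau > 0 && length(time) > 1L) {
    dt <- time[2L] - time[1L]
    a <- 1 - exp(-dt / settle_tau)
    p <- as.numeric(stats::filter(a * p, 1 - a, method = "recursive",
                                  init = p[1L]))
  }
  p
}
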