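# Esophageal-balloon respiratory mechanics: occlusion detection, plateau
# extraction, balloon validation, and the derived per-period quantities.

wf_slice <- function(x, start, end) {
  # half-sample guard keeps float jitter on window bounds from pulling
  # in the neighbouring sample
  eps <- 0.5 / x$fs
  tt <- wf_time(x)
  x$values[tt >= start - eps & tt < end - eps & x$valid]
}

#' Detect zero-flow occlusion maneuvers
#'
#' Finds maximal intervals where `|flow| < zero_flow_threshold` (strict)
#' for at least `min_duration` seconds and classifies each as
#' end-inspiratory (airway plateau elevated above the local pressure
#' context, i.e. the hold trapped the tidal volume) or end-expiratory
#' (plateau near PEEP). Normal inspiratory pauses are far shorter than
#' `min_duration` and are not detected.
#'
#' @param flow,paw aligned [waveform()]s (L/s and cmH2O).
#' @param zero_flow_threshold L/s (default 0.02).
#' @param min_duration minimum zero-flow duration in seconds (default 3;
#'   nominal holds are 5 s).
#' @return data.frame with one row per maneuver: `kind`
#'   (`"end_inspiratory"` / `"end_expiratory"`), `start`, `end`,
#'   `paw_plateau` (mean of the final 2 s). Empty when nothing qualifies.
#' @export
detect_occlusions <- function(flow, paw, zero_flow_threshold = 0.02,
                              min_duration = 3) {
  stopifnot(inherits(flow, "waveform"), inherits(paw, "waveform"))
  if (length(flow) != length(paw) ||
      abs(flow$start_time - paw$start_time) > 1e-9)
    stop("flow and paw must be aligned", call. = FALSE)
  empty <- data.frame(kind = character(0), start = numeric(0),
                      end = numeric(0), paw_plateau = numeric(0))
  zero <- abs(flow$values) < zero_flow_threshold & flow$valid
  if (!any(zero)) return(empty)
  r <- rle(zero)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_duration * flow$fs
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]
  tt <- wf_time(flow)
  out <- lapply(seq_along(starts), function(j) {
    t0 <- tt[starts[j]]
    t1 <- tt[ends[j]] + 1 / flow$fs
    plateau <- mean(wf_slice(paw, t1 - 2, t1))
    ctx <- wf_slice(paw, max(paw$start_time, t0 - 30),
                    min(wf_end_time(paw), t1 + 30))
    kind <- if (plateau > stats::median(ctx)) "end_inspiratory"
            else "end_expiratory"
    data.frame(kind = kind, start = t0, end = t1, paw_plateau = plateau)
  })
  do.call(rbind, out)
}

#' Plateau pressure of an occlusion
#'
#' Mean pressure over the final 2 s of a zero-flow hold. With 5-s holds
#' the tail is settled (post-occlusion stress relaxation has a sub-second
#' time constant), so this estimates the static recoil pressure.
#'
#' @param x a pressure [waveform()].
#' @param occlusion one row of the data.frame from [detect_occlusions()]
#'   (or any list with `start` and `end`).
#' @return mean pressure over `[end - 2, end)` in channel units.
#' @export
plateau_pressure <- function(x, occlusion) {
  stopifnot(inherits(x, "waveform"))
  if (occlusion$end - occlusion$start < 2)
    stop("occlusion window shorter than 2 s", call. = FALSE)
  mean(wf_slice(x, occlusion$end - 2, occlusion$end))
}

#' Baydur validation of esophageal balloon position
#'
#' Ratio of esophageal to airway pressure excursions during an occlusion,
#' computed over the settled tail of the hold (default last 3 s, avoiding
#' the initial plateau relaxation). A correctly placed balloon transmits
#' pleural swings faithfully: the position is flagged valid iff
#' `0.8 <= dPes/dPaw <= 1.2`.
#'
#' @param paw,pes aligned pressure [waveform()]s (cmH2O).
#' @param occlusion one row from [detect_occlusions()].
#' @param tail seconds of the window tail used (default 3).
#' @return list(`ratio`, `valid`).
#' @export
baydur_check <- function(paw, pes, occlusion, tail = 3) {
  t0 <- occlusion$end - tail
  dpaw <- diff(range(wf_slice(paw, t0, occlusion$end)))
  dpes <- diff(range(wf_slice(pes, t0, occlusion$end)))
  if (dpaw == 0)
    stop("zero airway pressure excursion: Baydur ratio undefined",
         call. = FALSE)
  ratio <- dpes / dpaw
  list(ratio = ratio, valid = ratio >= 0.8 && ratio <= 1.2)
}

#' Mechanical power of ventilation (simplified volume-control formula)
#'
#' `MP = 0.098 * RR * VT * (Ppeak - (Pplat - PEEPtot) / 2)` in J/min,
#' with VT in litres and pressures in cmH2O (0.098 converts
#' cmH2O·L/min to J/min). Lung power is obtained by substituting
#' transpulmonary pressures for the airway pressures.
#'
#' @param vt tidal volume, L.
#' @param rr respiratory rate, breaths/min.
#' @param ppeak peak pressure, cmH2O.
#' @param pplat plateau pressure, cmH2O.
#' @param peep_tot total end-expiratory pressure, cmH2O.
#' @return power in J/min.
#' @export
mechanical_power <- function(vt, rr, ppeak, pplat, peep_tot) {
  0.098 * rr * vt * (ppeak - (pplat - peep_tot) / 2)
}

#' Derive per-period respiratory mechanics from occlusion pressures
#'
#' Computes the full set of derived quantities from the four occlusion
#' pressures, the synchronous peak pressures, tidal volume and rate:
#' \describe{
#'   \item{elastances}{`Ers = (Pawei - PEEPtot)/VT`,
#'     `Ecw = (Pesei - Pesee)/VT`, `El = Ers - Ecw` (additive partition,
#'     exact by construction).}
#'   \item{transpulmonary pressures}{`TPPei = Pawei - Pesei`,
#'     `TPPee = Pawee - Pesee`, `TPPelast = Pawei * El / Ers`.}
#'   \item{pressures}{`DP = Pawei - PEEPtot`,
#'     `Ppeakl = Ppeakrs - Ppeakcw` (synchronous-peak convention),
#'     `PEEPtot = Pawee` measured at the end-expiratory occlusion, which
#'     captures intrinsic PEEP.}
#'   \item{power}{`MPrs` from [mechanical_power()] on airway pressures;
#'     lung power with `Ppeakl`, `TPPei`, `TPPee` substituted, split into
#'     dependent/non-dependent parts by `mp_partition`.}
#' }
#' A non-positive `Ers` marks the record invalid (`valid = FALSE`) rather
#' than raising an error.
#'
#' @param pawei,pawee end-inspiratory / end-expiratory occlusion airway
#'   pressures, cmH2O (`pawee` is PEEPtot).
#' @param pesei,pesee corresponding esophageal pressures, cmH2O.
#' @param ppeak_paw,ppeak_pes peak airway and (same-breath) esophageal
#'   pressures, cmH2O.
#' @param vt tidal volume, L (> 0).
#' @param rr respiratory rate, breaths/min.
#' @param mp_partition fraction of lung power assigned to the dependent
#'   lung (default 0.5).
#' @return one-row data.frame of class `"period_mechanics"` with columns
#'   `Pawei`, `Pawee`, `Pesei`, `Pesee`, `PEEPtot`, `Ppeakrs`, `Ppeakcw`,
#'   `Ppeakl`, `TPPei`, `TPPee`, `TPPelast`, `Ers`, `Ecw`, `El`, `DP`,
#'   `VT`, `RR`, `MPrs`, `MPl_dep`, `MPl_nondep`, `valid`.
#' @export
derive_mechanics <- function(pawei, pawee, pesei, pesee, ppeak_paw,
                             ppeak_pes, vt, rr, mp_partition = 0.5) {
  if (vt <= 0) stop("tidal volume must be positive", call. = FALSE)
  peep_tot <- pawee
  ers <- (pawei - peep_tot) / vt
  ecw <- (pesei - pesee) / vt
  el <- ers - ecw
  tppei <- pawei - pesei
  tppee <- pawee - pesee
  tppelast <- if (!is.na(ers) && ers > 0) pawei * el / ers else NA_real_
  ppeakl <- ppeak_paw - ppeak_pes
  mprs <- mechanical_power(vt, rr, ppeak_paw, pawei, peep_tot)
  mpl <- mechanical_power(vt, rr, ppeakl, tppei, tppee)
  out <- data.frame(
    Pawei = pawei, Pawee = pawee, Pesei = pesei, Pesee = pesee,
    PEEPtot = peep_tot, Ppeakrs = ppeak_paw, Ppeakcw = ppeak_pes,
    Ppeakl = ppeakl, TPPei = tppei, TPPee = tppee, TPPelast = tppelast,
    Ers = ers, Ecw = ecw, El = el, DP = pawei - peep_tot,
    VT = vt, RR = rr, MPrs = mprs,
    MPl_dep = mp_partition * mpl, MPl_nondep = (1 - mp_partition) * mpl,
    valid = ers > 0)
  class(out) <- c("period_mechanics", "data.frame")
  out
}

#' Per-period mechanics from ventilator waveforms
#'
#' Runs the full mechanics chain for every protocol period: detect the
#' end-inspiratory and end-expiratory holds, extract plateau pressures
#' from airway and esophageal channels, validate balloon position on the
#' end-expiratory hold (Baydur), take the synchronous peak pressures, and
#' derive all quantities via [derive_mechanics()]. Periods lacking one of
#' the two holds yield a row of NAs with `valid = FALSE`.
#'
#' @param paw,pes,flow aligned [waveform()]s.
#' @param protocol a [protocol_design()].
#' @param vt,rr tidal volume (L) and rate (breaths/min); scalars or
#'   per-period vectors.
#' @param zero_flow_threshold passed to [detect_occlusions()].
#' @param mp_partition passed to [derive_mechanics()].
#' @return data.frame, one row per protocol period, the
#'   [derive_mechanics()] columns plus `animal_id`, `position`, `block`,
#'   `period_index`, `peep`, `baydur_ratio`, `baydur_valid`.
#' @export
period_mechanics <- function(paw, pes, flow, protocol, vt, rr,
                             zero_flow_threshold = 0.02,
                             mp_partition = 0.5) {
  occ <- detect_occlusions(flow, paw, zero_flow_threshold)
  vt <- rep_len(vt, nrow(protocol))
  rr <- rep_len(rr, nrow(protocol))
  rows <- lapply(seq_len(nrow(protocol)), function(i) {
    p0 <- protocol$start[i]
    p1 <- p0 + protocol$duration[i]
    keys <- protocol[i, c("animal_id", "position", "block",
                          "period_index", "peep")]
    oi <- occ[occ$start >= p0 & occ$end <= p1, ]
    ei <- oi[oi$kind == "end_inspiratory", ]
    ee <- oi[oi$kind == "end_expiratory", ]
    if (nrow(ei) < 1L || nrow(ee) < 1L) {
      na <- derive_mechanics(NA_real_, NA_real_, NA_real_, NA_real_,
                             NA_real_, NA_real_, vt[i], rr[i],
                             mp_partition)
      na$valid <- FALSE
      return(cbind(keys, na, baydur_ratio = NA_real_,
                   baydur_valid = NA))
    }
    ei <- ei[1L, ]; ee <- ee[1L, ]
    pawei <- plateau_pressure(paw, ei)
    pawee <- plateau_pressure(paw, ee)
    pesei <- plateau_pressure(pes, ei)
    pesee <- plateau_pressure(pes, ee)
    # synchronous peaks: Pes max taken within the breath containing the
    # Paw maximum (one cycle back from the peak sample)
    tt <- wf_time(paw)
    in_period <- tt >= p0 & tt < p1 & paw$valid
    pk_idx <- which(in_period)[which.max(paw$values[in_period])]
    t_pk <- tt[pk_idx]
    cyc <- 60 / rr[i]
    ppeak_paw <- max(paw$values[in_period])
    ppeak_pes <- max(wf_slice(pes, t_pk - cyc, t_pk + 1 / paw$fs))
    bay <- baydur_check(paw, pes, ee)
    mech <- derive_mechanics(pawei, pawee, pesei, pesee, ppeak_paw,
                             ppeak_pes, vt[i], rr[i], mp_partition)
    cbind(keys, mech, baydur_ratio = bay$ratio, baydur_valid = bay$valid)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
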