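# Period-level aggregation: map trend/index/mechanics streams onto
# protocol periods and build the summary table the statistics operate on.

series_mean <- function(s, start, end) {
  v <- s$value[s$time > start & s$time <= end]
  list(mean = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE),
       frac_missing = if (length(v) == 0L) 1 else mean(is.na(v)))
}

#' Summarize trends and indices over protocol periods
#'
#' One row per protocol period holding the mean of each supplied variable
#' over the period window (missing values excluded; the fraction missing
#' is recorded per variable as `<name>_missing`). The first
#' `settle_minutes` after each PEEP change are excluded as a settling
#' washout. Reactivity indices passed via `indices` are additionally
#' summarized on the Fisher scale as `<name>_fisher`, the scale used for
#' statistical analysis.
#'
#' @param protocol a [protocol_design()].
#' @param trends named list of [trend_series()] (e.g. `ICP`, `ABP`,
#'   `CPP`, `AMP`).
#' @param indices named list of [index_series()] (e.g. `PRx`, `RAP`).
#' @param mechanics optional [period_mechanics()] table to join by period.
#' @param gases optional per-period blood-gas data.frame (row-aligned with
#'   the protocol) to join.
#' @param settle_minutes settling exclusion after each PEEP change
#'   (default 2; set 0 to keep the full window).
#' @return a data.frame, one row per animal x position x PEEP level.
#' @export
summarize_periods <- function(protocol, trends = list(), indices = list(),
                              mechanics = NULL, gases = NULL,
                              settle_minutes = 2) {
  stopifnot(inherits(protocol, "protocol_design"))
  settle <- settle_minutes * 60
  if (any(settle >= protocol$duration))
    stop("settling exclusion swallows entire periods", call. = FALSE)
  rows <- lapply(seq_len(nrow(protocol)), function(i) {
    p0 <- protocol$start[i] + settle
    p1 <- protocol$start[i] + protocol$duration[i]
    out <- protocol[i, c("animal_id", "sequence", "position", "block",
                         "period_index", "peep")]
    for (nm in names(trends)) {
      m <- series_mean(trends[[nm]], p0, p1)
      out[[nm]] <- m$mean
      out[[paste0(nm, "_missing")]] <- m$frac_missing
    }
    for (nm in names(indices)) {
      m <- series_mean(indices[[nm]], p0, p1)
      out[[nm]] <- m$mean
      mf <- series_mean(fisher_transform(indices[[nm]]), p0, p1)
      out[[paste0(nm, "_fisher")]] <- mf$mean
      out[[paste0(nm, "_missing")]] <- m$frac_missing
    }
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(mechanics)) {
    keep <- setdiff(names(mechanics),
                    c("animal_id", "sequence", "position", "block",
                      "period_index", "peep"))
    out <- cbind(out, mechanics[, keep, drop = FALSE])
  }
  if (!is.null(gases)) {
    stopifnot(nrow(gases) == nrow(out))
    out <- cbind(out, gases)
  }
  rownames(out) <- NULL
  out
}

#' Changes from the same-position PEEP-5 baseline
#'
#' For each animal and position block, subtracts the PEEP-5 value from the
#' values at PEEP 10, 15 and 20. Baseline rows are excluded from the
#' output (their delta is identically zero); a missing baseline makes all
#' deltas for that block missing.
#'
#' @param summaries a [summarize_periods()] table.
#' @param vars character vector of summary columns to difference.
#' @return data.frame with key columns and one `d_<var>` column per input
#'   variable.
#' @export
delta_from_baseline <- function(summaries, vars = "ICP") {
  stopifnot(all(vars %in% names(summaries)))
  key <- interaction(summaries$animal_id, summaries$block, drop = TRUE)
  parts <- lapply(split(summaries, key), function(s) {
    b <- s[s$peep == 5, ]
    d <- s[s$peep > 5, c("animal_id", "sequence", "position", "block",
                         "period_index", "peep")]
    for (v in vars) {
      base <- if (nrow(b) == 1L) b[[v]] else NA_real_
      d[[paste0("d_", v)]] <- s[[v]][s$peep > 5] - base
    }
    d
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$animal_id, out$block, out$peep), ]
  rownames(out) <- NULL
  out
}

#' Brain-tissue to arterial oxygen tension ratio
#'
#' `PbO2 / PaO2`, dimensionless; adjusts brain oxygen tension for systemic
#' oxygenation. Missing when either input is missing; `PaO2 = 0` is an
#' error.
#'
#' @param pbo2,pao2 numeric vectors, same units (mmHg).
#' @return numeric vector of ratios.
#' @export
pbo2_ratio <- function(pbo2, pao2) {
  if (any(!is.na(pao2) & pao2 == 0))
    stop("PaO2 must be nonzero", call. = FALSE)
  pbo2 / pao2
}

#' Run the waveform pipeline for one animal
#'
#' Convenience chain from raw channels to a per-period summary row set:
#' coarse-grain ABP and ICP, apply the threshold validity rules, derive
#' CPP, AMP, PRx and RAP, (optionally) compute occlusion mechanics, and
#' aggregate over the protocol periods.
#'
#' @param waves named list with `abp` and `icp` [waveform()]s, optionally
#'   `paw`, `pes`, `flow` for mechanics.
#' @param protocol a [protocol_design()].
#' @param rules a [validity_rules()] list.
#' @param gases optional per-period blood-gas table.
#' @param vt,rr tidal volume and rate for mechanics (defaults taken from
#'   nothing; required when ventilator channels are supplied).
#' @param settle_minutes passed to [summarize_periods()].
#' @param min_pairs minimum pairs per correlation window.
#' @param exclusions optional manual exclusion windows applied to ABP and
#'   ICP before processing.
#' @return the [summarize_periods()] table for this animal.
#' @export
process_animal <- function(waves, protocol, rules = validity_rules(),
                           gases = NULL, vt = NULL, rr = NULL,
                           settle_minutes = 2, min_pairs = 15,
                           exclusions = NULL) {
  abp <- waves$abp
  icp <- waves$icp
  if (!is.null(exclusions)) {
    abp <- apply_manual_exclusions(abp, exclusions)
    icp <- apply_manual_exclusions(icp, exclusions)
  }
  abp_t <- coarse_grain(abp, variable = "ABP")
  icp_t <- threshold_filter(coarse_grain(icp, variable = "ICP"), rules)
  cpp_t <- threshold_filter(cpp_trend(abp_t, icp_t), rules)
  amp_t <- pulse_amplitude(icp)
  trends <- list(ABP = abp_t, ICP = icp_t, CPP = cpp_t, AMP = amp_t)
  indices <- list(PRx = prx(abp_t, icp_t, min_pairs = min_pairs),
                  RAP = rap(amp_t, icp_t, min_pairs = min_pairs))
  mech <- NULL
  if (!is.null(waves$paw) && !is.null(waves$flow)) {
    stopifnot(!is.null(vt), !is.null(rr))
    mech <- period_mechanics(waves$paw, waves$pes, waves$flow, protocol,
                             vt, rr)
  }
  summarize_periods(protocol, trends, indices, mech, gases,
                    settle_minutes)
}

#' Per-period summaries for a whole simulated cohort
#'
#' Applies [process_animal()] to every animal of a [generate_cohort()]
#' result and stacks the rows.
#'
#' @param cohort a `"sim_cohort"`.
#' @param ... passed to [process_animal()].
#' @return one stacked summary data.frame.
#' @export
cohort_summaries <- function(cohort, ...) {
  stopifnot(inherits(cohort, "sim_cohort"))
  out <- do.call(rbind, lapply(cohort$animals, function(a) {
    args <- list(waves = a$waves, protocol = a$protocol, gases = a$gases,
                 ...)
    if (!is.null(a$waves$paw) && is.null(args$vt)) {
      args$vt <- a$config$tidal_volume
      args$rr <- a$config$respiratory_rate
    }
    do.call(process_animal, args)
  }))
  rownames(out) <- NULL
  out
}

#' Normality-routed descriptive summary (Table-1 style)
#'
#' For each requested variable, reports `mean (SD)` when the Shapiro-Wilk
#' test does not reject normality at `alpha`, otherwise `median (IQR)`,
#' mirroring standard physiological-study descriptive tables.
#'
#' @param summaries a summary data.frame.
#' @param vars columns to describe.
#' @param by optional grouping column (e.g. `"position"`).
#' @param alpha Shapiro-Wilk significance level (default 0.05).
#' @return data.frame with `variable`, group, `n`, `descriptor`, `text`.
#' @export
describe_variables <- function(summaries, vars, by = NULL, alpha = 0.05) {
  groups <- if (is.null(by)) list(all = summaries)
            else split(summaries, summaries[[by]])
  rows <- list()
  for (g in names(groups)) {
    for (v in vars) {
      x <- groups[[g]][[v]]
      x <- x[!is.na(x)]
      r <- normality_route(x, alpha)
      txt <- if (r$route == "parametric")
        sprintf("%.3g ± %.2g", mean(x), stats::sd(x))
      else sprintf("%.3g (%.3g-%.3g)", stats::median(x),
                   stats::quantile(x, 0.25), stats::quantile(x, 0.75))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, group = g, n = length(x),
        descriptor = if (r$route == "parametric") "mean (SD)"
                     else "median (IQR)",
        text = txt)
    }
  }
  do.call(rbind, rows)
}
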