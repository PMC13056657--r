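# Crossover statistical analysis: normality routing, baseline position
# comparison, crossover assumption checks, PEEP x position ANOVA with
# Welch/Kruskal fallbacks, and baseline-covariate models of the ICP
# response. Mixed models are fitted by REML via lme4, with Satterthwaite
# F/t tests from lmerTest for fixed effects.

test_result <- function(effect, estimate = NA_real_,
                        statistic = NA_real_, df = NA_real_,
                        p = NA_real_, method = NA_character_,
                        shapiro_p = NA_real_, levene_p = NA_real_,
                        bartlett_p = NA_real_, note = NA_character_) {
  structure(data.frame(effect = effect, estimate = estimate,
                       statistic = statistic, df = df, p = p,
                       method = method, shapiro_p = shapiro_p,
                       levene_p = levene_p, bartlett_p = bartlett_p,
                       note = note),
            class = c("test_result", "data.frame"))
}

#' @export
print.test_result <- function(x, ...) {
  print.data.frame(x[, colSums(!is.na(x)) > 0 | names(x) == "p"],
                   row.names = FALSE, digits = 4)
  invisible(x)
}

shapiro_p_safe <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

#' Route a sample to parametric or rank-based treatment
#'
#' Shapiro-Wilk at `alpha`: non-rejection routes to mean +/- SD
#' descriptives and parametric tests, rejection to median (IQR) and rank
#' tests. Degenerate samples (n < 3 or zero variance), where the test is
#' undefined, take the conservative rank route.
#'
#' @param values numeric sample.
#' @param alpha significance level (default 0.05).
#' @return list with `route` (`"parametric"`/`"rank"`), `shapiro_p`,
#'   `center`, `spread`, `descriptor`.
#' @export
normality_route <- function(values, alpha = 0.05) {
  x <- values[!is.na(values)]
  p <- shapiro_p_safe(x)
  if (!is.na(p) && p >= alpha) {
    list(route = "parametric", shapiro_p = p, center = mean(x),
         spread = stats::sd(x), descriptor = "mean (SD)")
  } else {
    list(route = "rank", shapiro_p = p, center = stats::median(x),
         spread = stats::IQR(x), descriptor = "median (IQR)")
  }
}

#' Compare baseline values between positions
#'
#' Two-sample comparison of a baseline variable between prone-first and
#' supine-first groups (or any two groups): a two-sample t test when both
#' samples pass the Shapiro-Wilk normality screen, a Mann-Whitney U test
#' otherwise (exact when sample sizes permit and there are no ties).
#' Levene and Bartlett variance diagnostics are recorded alongside.
#'
#' @param x,y numeric samples for the two groups.
#' @param effect label for the result row.
#' @param alpha normality screening level.
#' @return a one-row `test_result` data.frame.
#' @export
baseline_compare <- function(x, y, effect = "group", alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  px <- shapiro_p_safe(x); py <- shapiro_p_safe(y)
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  v <- c(x, y)
  lev <- tryCatch(car::leveneTest(v ~ g)[1L, "Pr(>F)"],
                  error = function(e) NA_real_)
  bar <- tryCatch(stats::bartlett.test(v ~ g)$p.value,
                  error = function(e) NA_real_)
  parametric <- !is.na(px) && !is.na(py) && px >= alpha && py >= alpha
  if (parametric) {
    tt <- stats::t.test(x, y)
    test_result(effect, estimate = mean(x) - mean(y),
                statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value, method = "t",
                shapiro_p = min(px, py), levene_p = lev, bartlett_p = bar)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    test_result(effect, estimate = stats::median(x) - stats::median(y),
                statistic = unname(wt$statistic), p = wt$p.value,
                method = "mann-whitney",
                shapiro_p = suppressWarnings(min(px, py, na.rm = TRUE)),
                levene_p = lev, bartlett_p = bar)
  }
}

delta_response <- function(summaries, variable) {
  d <- delta_from_baseline(summaries, vars = variable)
  d$resp <- d[[paste0("d_", variable)]]
  d$animal_id <- factor(d$animal_id)
  d$sequence <- factor(d$sequence)
  d$position <- factor(d$position)
  d$peep_f <- factor(d$peep)
  d$period <- factor(d$block)      # position-block order: 1st vs 2nd
  d$posblock <- interaction(d$animal_id, d$block, drop = TRUE)
  d
}

#' Test the crossover design assumptions
#'
#' Fits the linear mixed-effects model
#' `delta ~ PEEP + sequence + period + sequence:PEEP + (1 | animal) +
#' (1 | animal:position)` by REML to the baseline-differenced response and
#' reports Satterthwaite F tests (type II) for the sequence effect, the
#' period effect (first vs second position block) and the carryover term
#' (sequence-by-PEEP interaction). Any term with `p < alpha` flags a
#' violation of the crossover assumptions. Non-convergence or a
#' degenerate response is reported in the result rows, never silently
#' worked around.
#'
#' @param summaries a [summarize_periods()] (or
#'   [simulate_summary_cohort()]) table.
#' @param variable summary column to analyze (`"ICP"`, or
#'   `"PRx_fisher"` for the Fisher-scale reactivity index).
#' @param alpha violation threshold (default 0.05).
#' @return a `test_result` data.frame with rows `sequence`, `period`,
#'   `carryover` and a logical `violation` column.
#' @export
crossover_assumptions <- function(summaries, variable = "ICP",
                                  alpha = 0.05) {
  d <- delta_response(summaries, variable)
  if (all(is.na(d$resp)) || stats::sd(d$resp, na.rm = TRUE) == 0) {
    out <- test_result(c("sequence", "period", "carryover"),
                       method = "lmm (degenerate)",
                       note = "zero-variance response; model not fitted")
    out$violation <- NA
    return(out)
  }
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      resp ~ peep_f + sequence + period + sequence:peep_f +
        (1 | animal_id) + (1 | posblock),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- test_result(c("sequence", "period", "carryover"),
                       method = "lmm (non-convergent)",
                       note = conditionMessage(fit))
    out$violation <- NA
    return(out)
  }
  a <- stats::anova(fit, type = 2)
  row_of <- function(term) {
    i <- match(term, rownames(a))
    test_result(term, statistic = a[i, "F value"],
                df = a[i, "DenDF"], p = a[i, "Pr(>F)"],
                method = "lmm satterthwaite F")
  }
  out <- rbind(row_of("sequence"), row_of("period"),
               row_of("peep_f:sequence"))
  out$effect <- c("sequence", "period", "carryover")
  out$violation <- !is.na(out$p) & out$p < alpha
  class(out) <- c("test_result", "data.frame")
  out
}

#' PEEP-by-position ANOVA with pooling and fallbacks
#'
#' Stage one: two-way ANOVA of the baseline-differenced response on PEEP
#' level, body position and their interaction. If the interaction is not
#' significant at `alpha`, positions are pooled and the PEEP effect is
#' re-tested with a repeated-measures ANOVA using animal as the
#' within-subject unit (positions averaged within animal by default, or
#' kept as replicates with `pooling = "replicates"`). Assumption checks
#' route the pooled test: Shapiro-Wilk rejection sends it to
#' Kruskal-Wallis, Levene rejection (with normality retained) to Welch's
#' ANOVA; the route taken is recorded in `method`.
#'
#' @param summaries a period-summary table.
#' @param variable summary column to analyze.
#' @param alpha significance level for routing and the interaction gate.
#' @param pooling `"average"` (one value per animal and PEEP level) or
#'   `"replicates"` (both positions enter as repeated observations).
#' @return a `test_result` data.frame with rows `peep:position`
#'   (interaction), `position`, `peep` (two-way) and, when pooled,
#'   `peep (pooled)`.
#' @export
peep_position_anova <- function(summaries, variable = "ICP",
                                alpha = 0.05,
                                pooling = c("average", "replicates")) {
  pooling <- match.arg(pooling)
  d <- delta_response(summaries, variable)
  d <- d[!is.na(d$resp), ]
  if (nrow(d) == 0L || stats::sd(d$resp) == 0) {
    # constant response carries no evidence of any effect
    out <- test_result(c("peep:position", "position", "peep",
                         "peep (pooled)"), p = 1,
                       method = "degenerate (constant response)")
    class(out) <- c("test_result", "data.frame")
    return(out)
  }
  aov2 <- stats::aov(resp ~ peep_f * position, data = d)
  tab <- summary(aov2)[[1L]]
  p_of <- function(nm) {
    i <- match(nm, trimws(rownames(tab)))
    c(tab[i, "F value"], tab[i, "Pr(>F)"], tab[i, "Df"])
  }
  int <- p_of("peep_f:position")
  pos <- p_of("position")
  pp <- p_of("peep_f")
  out <- rbind(
    test_result("peep:position", statistic = int[1L], df = int[3L],
                p = int[2L], method = "two-way anova"),
    test_result("position", statistic = pos[1L], df = pos[3L],
                p = pos[2L], method = "two-way anova"),
    test_result("peep", statistic = pp[1L], df = pp[3L], p = pp[2L],
                method = "two-way anova"))
  if (!is.na(int[2L]) && int[2L] < alpha) {
    class(out) <- c("test_result", "data.frame")
    return(out)
  }
  # pool positions
  pooled <- if (pooling == "average")
    stats::aggregate(resp ~ animal_id + peep_f, data = d, FUN = mean)
  else d[, c("animal_id", "peep_f", "resp")]
  sh <- shapiro_p_safe(stats::residuals(
    stats::lm(resp ~ peep_f, data = pooled)))
  lev <- tryCatch(car::leveneTest(resp ~ peep_f,
                                  data = pooled)[1L, "Pr(>F)"],
                  error = function(e) NA_real_)
  bar <- tryCatch(stats::bartlett.test(resp ~ peep_f,
                                       data = pooled)$p.value,
                  error = function(e) NA_real_)
  if (!is.na(sh) && sh < alpha) {
    kw <- stats::kruskal.test(resp ~ peep_f, data = pooled)
    pooled_row <- test_result("peep (pooled)",
                              statistic = unname(kw$statistic),
                              df = unname(kw$parameter), p = kw$p.value,
                              method = "kruskal-wallis", shapiro_p = sh,
                              levene_p = lev, bartlett_p = bar)
  } else if (!is.na(lev) && lev < alpha) {
    wa <- stats::oneway.test(resp ~ peep_f, data = pooled,
                             var.equal = FALSE)
    pooled_row <- test_result("peep (pooled)",
                              statistic = unname(wa$statistic),
                              df = unname(wa$parameter[2L]),
                              p = wa$p.value, method = "welch anova",
                              shapiro_p = sh, levene_p = lev,
                              bartlett_p = bar)
  } else {
    rm_fit <- stats::aov(resp ~ peep_f + Error(animal_id), data = pooled)
    tab2 <- summary(rm_fit)[["Error: Within"]][[1L]]
    i <- match("peep_f", trimws(rownames(tab2)))
    pooled_row <- test_result("peep (pooled)",
                              statistic = tab2[i, "F value"],
                              df = tab2[i, "Df"],
                              p = tab2[i, "Pr(>F)"],
                              method = "repeated-measures anova",
                              shapiro_p = sh, levene_p = lev,
                              bartlett_p = bar)
  }
  out <- rbind(out, pooled_row)
  class(out) <- c("test_result", "data.frame")
  out
}

#' Baseline-covariate modulation of the ICP response
#'
#' Linear mixed-effects model of the baseline-differenced response on the
#' PEEP increment, a baseline covariate, and their interaction, with
#' animal and position-within-animal random intercepts:
#' `delta ~ peep_c * covariate_c + (1 | animal) + (1 | animal:position)`.
#' The quantity of interest is the interaction slope - how much the
#' PEEP-response (mmHg per cmH2O) changes per unit of the baseline
#' covariate - with its Satterthwaite t test. Covariates are screened one
#' at a time with no multiplicity correction (the covariate list is
#' specified a priori). A covariate with no between-subject variance is
#' reported as non-identifiable.
#'
#' @param summaries a period-summary table containing the response and
#'   covariate columns.
#' @param covariate name of the covariate column; its baseline value is
#'   taken from the same-position PEEP-5 row.
#' @param variable response column (default `"ICP"`).
#' @return a one-row `test_result`: `estimate` is the modulation slope.
#' @export
baseline_predictor_model <- function(summaries, covariate,
                                     variable = "ICP") {
  stopifnot(covariate %in% names(summaries))
  d <- delta_response(summaries, variable)
  base <- summaries[summaries$peep == 5,
                    c("animal_id", "block", covariate)]
  names(base)[3L] <- "covariate"
  d <- merge(d, base, by = c("animal_id", "block"))
  d <- d[!is.na(d$resp) & !is.na(d$covariate), ]
  if (nrow(d) == 0L || stats::sd(d$covariate) == 0)
    return(test_result(paste0("peep:", covariate),
                       method = "lmm (non-identifiable)",
                       note = "covariate constant across subjects"))
  d$peep_c <- d$peep - 5
  d$cov_c <- d$covariate - mean(d$covariate)
  fit <- tryCatch(
    suppressMessages(lmerTest::lmer(
      resp ~ peep_c * cov_c + (1 | animal_id) + (1 | posblock),
      data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore"))),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(test_result(paste0("peep:", covariate),
                       method = "lmm (non-convergent)",
                       note = conditionMessage(fit)))
  ct <- stats::coef(summary(fit))
  i <- match("peep_c:cov_c", rownames(ct))
  test_result(paste0("peep:", covariate), estimate = ct[i, "Estimate"],
              statistic = ct[i, "t value"], df = ct[i, "df"],
              p = ct[i, "Pr(>|t|)"], method = "lmm satterthwaite t")
}

#' Estimate the PEEP-to-ICP slope from period summaries
#'
#' Mixed-effects estimate of the linear PEEP coupling (mmHg per cmH2O of
#' PEEP above 5): `response ~ (PEEP - 5) + (1 | animal) +
#' (1 | animal:position)`, REML. On degenerate (noise-free) data where the
#' random-effect and residual variances vanish, the fit falls back to
#' ordinary least squares, which returns the same fixed-effect slope.
#'
#' @param summaries a period-summary table.
#' @param variable response column (default `"ICP"`).
#' @return named list: `slope` (mmHg/cmH2O), `se`, `method`.
#' @export
estimate_peep_slope <- function(summaries, variable = "ICP") {
  d <- summaries[!is.na(summaries[[variable]]), ]
  d$resp <- d[[variable]]
  d$peep_c <- d$peep - 5
  d$animal_id <- factor(d$animal_id)
  d$posblock <- interaction(d$animal_id, d$block, drop = TRUE)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(lme4::lmer(
      resp ~ peep_c + (1 | animal_id) + (1 | posblock), data = d,
      REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) e)
  if (inherits(fit, "error")) {
    ols <- stats::lm(resp ~ peep_c, data = d)
    return(list(slope = unname(stats::coef(ols)["peep_c"]),
                se = unname(sqrt(diag(stats::vcov(ols)))["peep_c"]),
                method = "ols (degenerate mixed model)"))
  }
  fe <- lme4::fixef(fit)
  se <- tryCatch(
    suppressWarnings(unname(sqrt(diag(as.matrix(
      stats::vcov(fit))))[2L])),
    error = function(e) NA_real_)   # exactly-degenerate fits
  list(slope = unname(fe["peep_c"]), se = se, method = "lmm")
}
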