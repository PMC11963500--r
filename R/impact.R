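# Cause-and-intervention impact model.
#
# Single-intervention arithmetic (the printed LiST-style formulas):
#   estimated MMR = MMR * (1 - cause share * coverage change
#                              * efficacy * affected fraction)
#   lives saved   = live births * MMR/1e5 * cause share * coverage change
#                              * efficacy * affected fraction
#
# Several interventions acting on the same cause combine multiplicatively
# on residual deaths: residual_c = D_c * prod_i (1 - e_ic), with
# e_ic = coverage change * efficacy * affected fraction. Per-intervention
# attribution rescales the independent savings D_c * e_ic proportionally
# so they sum exactly to the cause's total deaths averted; the rule is
# order-independent and reduces to the printed formulas for a single
# intervention.
#
# Background (non-intervention) MMR is held at its 2020 value in the
# scenario projections; only the sensitivity mode moves it along the
# 2015-2020 APC.

.check_fraction <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  x
}

#' Estimated MMR after scaling up one intervention
#'
#' Direct evaluation of the single-intervention impact formula.
#'
#' @param mmr Baseline MMR (per 100,000 live births), positive.
#' @param cause_share Fraction of maternal deaths from the target cause.
#' @param coverage_change Coverage change vs baseline, a fraction.
#' @param efficacy Proportional cause-specific mortality reduction.
#' @param affected_fraction Share of cause deaths the intervention can
#'   act on.
#' @return Estimated MMR.
#' @export
#' @examples
#' single_intervention_mmr(200, 0.2, 0.5, 0.8, 1.0)  # 184
single_intervention_mmr <- function(mmr, cause_share, coverage_change,
                                    efficacy, affected_fraction) {
  if (!is.numeric(mmr) || any(mmr <= 0)) stop("mmr must be > 0", call. = FALSE)
  .check_fraction(cause_share, "cause_share")
  .check_fraction(coverage_change, "coverage_change")
  .check_fraction(efficacy, "efficacy")
  .check_fraction(affected_fraction, "affected_fraction")
  mmr * (1 - cause_share * coverage_change * efficacy * affected_fraction)
}

#' Additional maternal lives saved by one intervention
#'
#' Direct evaluation of the lives-saved formula; `mmr` is per 100,000
#' live births.
#'
#' @inheritParams single_intervention_mmr
#' @param live_births Annual live births, positive.
#' @return Deaths averted per year.
#' @export
#' @examples
#' single_intervention_lives_saved(100000, 200, 0.2, 0.5, 0.8, 1.0)  # 16
single_intervention_lives_saved <- function(live_births, mmr, cause_share,
                                            coverage_change, efficacy,
                                            affected_fraction) {
  if (!is.numeric(live_births) || any(live_births <= 0)) {
    stop("live_births must be > 0", call. = FALSE)
  }
  if (!is.numeric(mmr) || any(mmr <= 0)) stop("mmr must be > 0", call. = FALSE)
  .check_fraction(cause_share, "cause_share")
  .check_fraction(coverage_change, "coverage_change")
  .check_fraction(efficacy, "efficacy")
  .check_fraction(affected_fraction, "affected_fraction")
  live_births * (mmr / 1e5) * cause_share * coverage_change * efficacy *
    affected_fraction
}

#' Apply an intervention registry to one country's cause-specific deaths
#'
#' For each cause, residual deaths follow the multiplicative cascade
#' `D_c * prod_i (1 - e_ic)`; the deaths averted are attributed to
#' interventions by rescaling their independent savings `D_c * e_ic`
#' proportionally so they sum to the cause total. The result does not
#' depend on registry order.
#'
#' @param country A [country_record()].
#' @param registry List of [intervention()] objects.
#' @param coverage_changes Named numeric vector of coverage changes per
#'   intervention id (fractions).
#' @return List with `residual_deaths` (named by cause),
#'   `lives_saved` (named by intervention id), `baseline_deaths` (named
#'   by cause).
#' @export
apply_interventions <- function(country, registry, coverage_changes) {
  stopifnot(inherits(country, "country_record"))
  causes <- maternal_causes()
  total_deaths <- country$live_births * country$mmr_2020 / 1e5
  d_c <- stats::setNames(as.numeric(country$causes) * total_deaths, causes)

  ids <- vapply(registry, `[[`, "", "id")
  missing <- setdiff(ids, names(coverage_changes))
  if (length(missing)) {
    stop("no coverage change supplied for intervention(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # e[i, c]: per-intervention, per-cause effect size.
  e <- matrix(0, nrow = length(registry), ncol = length(causes),
              dimnames = list(ids, causes))
  for (iv in registry) {
    dc <- .check_fraction(coverage_changes[[iv$id]],
                          paste0("coverage change for ", iv$id))
    for (cause in names(iv$targets)) {
      if (!cause %in% causes) stop("unknown cause: ", cause, call. = FALSE)
      t <- iv$targets[[cause]]
      e[iv$id, cause] <- dc * t$efficacy * t$affected_fraction
    }
  }

  residual <- d_c * apply(1 - e, 2, prod)
  averted_c <- d_c - residual
  independent <- sweep(e, 2, d_c, `*`)          # D_c * e_ic
  col_ind <- colSums(independent)
  scale <- ifelse(col_ind > 0, averted_c / col_ind, 0)
  attributed <- sweep(independent, 2, scale, `*`)
  lives_saved <- rowSums(attributed)

  list(residual_deaths = residual, lives_saved = lives_saved,
       baseline_deaths = d_c)
}

#' 80% uncertainty interval from a standard error
#'
#' `mmr +/- z * se` with `z` the standard-normal 90th percentile
#' (about 1.2816), giving the 10th and 90th percentiles under a normal
#' approximation; the lower bound is floored at a small positive value.
#'
#' @param mmr Point estimate.
#' @param se Standard error, non-negative.
#' @return Length-2 numeric `(lower, upper)`.
#' @export
#' @examples
#' ui_from_se(200, 39.02)
ui_from_se <- function(mmr, se) {
  if (se < 0) stop("se must be >= 0", call. = FALSE)
  z <- stats::qnorm(0.9)
  c(max(mmr - z * se, 1e-6), mmr + z * se)
}

#' Propagate a baseline 80% UI to an estimated MMR
#'
#' Both bounds are scaled by the ratio `estimated_mmr / baseline_mmr`
#' (multiplicative propagation), so the relative width of the interval is
#' preserved.
#'
#' @param baseline_mmr Baseline MMR, positive.
#' @param baseline_ui Length-2 `(lower, upper)` bracketing the baseline.
#' @param estimated_mmr Projected MMR.
#' @return Length-2 numeric `(lower, upper)`.
#' @export
propagate_ui <- function(baseline_mmr, baseline_ui, estimated_mmr) {
  if (baseline_mmr <= 0) stop("baseline mmr must be > 0", call. = FALSE)
  stopifnot(length(baseline_ui) == 2L,
            baseline_ui[1] <= baseline_mmr, baseline_mmr <= baseline_ui[2])
  baseline_ui * (estimated_mmr / baseline_mmr)
}

#' MMR projected along the 2015-2020 trend (sensitivity analysis)
#'
#' Extrapolates the 2020 MMR forward at a constant annual percent change:
#' `mmr_2020 * (1 + apc/100)^(year - 2020)`. Used for the current-trend
#' comparator in which coverage stays at baseline and the MMR follows its
#' recent trajectory.
#'
#' @param mmr_2020 MMR in 2020, positive.
#' @param apc_2015_2020 APC over 2015-2020 in percent; must exceed -100.
#' @param year Projection year, at least 2020.
#' @return Projected MMR.
#' @export
#' @examples
#' sensitivity_project(200, -3, 2030)  # 200 * 0.97^10
sensitivity_project <- function(mmr_2020, apc_2015_2020, year) {
  stopifnot(mmr_2020 > 0, apc_2015_2020 > -100, year >= 2020)
  mmr_2020 * (1 + apc_2015_2020 / 100)^(year - 2020)
}

#' Project one country under one scenario
#'
#' Builds each intervention's coverage change at `year`, applies the
#' multi-intervention cascade, converts residual deaths back to an MMR,
#' propagates the 80% UI multiplicatively and computes the percent
#' reduction versus the no-scale-up scenario (whose MMR equals the 2020
#' baseline, since background MMR is held constant).
#'
#' @param country A [country_record()].
#' @param scenario An [scenario()] object.
#' @param registry Intervention registry.
#' @param year Projection year (default 2030).
#' @param lives_saved_mode `"annual"` (deaths averted in `year`, default)
#'   or `"cumulative"` (summed over every year after the baseline through
#'   `year`).
#' @return An object of class `"mmr_projection"`: list with `iso3`,
#'   `scenario_id`, `year`, `mmr` (point, `ui` lower/upper),
#'   `residual_deaths` by cause, `lives_saved` by intervention,
#'   `pct_reduction_vs_s0`.
#' @export
project <- function(country, scenario, registry, year = 2030,
                    lives_saved_mode = c("annual", "cumulative")) {
  lives_saved_mode <- match.arg(lives_saved_mode)
  stopifnot(inherits(country, "country_record"),
            inherits(scenario, "mmr_scenario"))
  ids <- vapply(registry, `[[`, "", "id")
  missing_cov <- setdiff(ids, names(country$coverage))
  if (length(missing_cov)) {
    stop(country$iso3, ": no baseline coverage for intervention(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  }

  changes_at <- function(yr) {
    vapply(ids, function(id) {
      traj <- coverage_trajectory(country$coverage[[id]], scenario,
                                  years = scenario$baseline_year:yr)
      coverage_change(traj, yr)
    }, numeric(1))
  }

  res <- apply_interventions(country, registry, changes_at(year))
  lives_saved <- res$lives_saved
  if (lives_saved_mode == "cumulative") {
    yrs <- seq(scenario$baseline_year + 1L, year)
    lives_saved <- Reduce(`+`, lapply(yrs, function(yr) {
      apply_interventions(country, registry, changes_at(yr))$lives_saved
    }))
  }

  est_mmr <- sum(res$residual_deaths) / country$live_births * 1e5
  ui <- propagate_ui(country$mmr_2020, country$mmr_ui_2020, est_mmr)
  structure(list(iso3 = country$iso3, scenario_id = scenario$id,
                 year = year, mmr = est_mmr, ui = ui,
                 residual_deaths = res$residual_deaths,
                 lives_saved = lives_saved,
                 baseline_deaths = res$baseline_deaths,
                 live_births = country$live_births,
                 region = country$region,
                 income_group = country$income_group,
                 lives_saved_mode = lives_saved_mode,
                 pct_reduction_vs_s0 =
                   (country$mmr_2020 - est_mmr) / country$mmr_2020 * 100),
            class = "mmr_projection")
}

#' @export
print.mmr_projection <- function(x, ...) {
  cat(sprintf(
    "%s, scenario %d, %d: MMR %.2f (80%% UI %.2f-%.2f), %.1f lives saved/yr, -%.2f%% vs no scale-up\n",
    x$iso3, x$scenario_id, x$year, x$mmr, x$ui[1], x$ui[2],
    sum(x$lives_saved), x$pct_reduction_vs_s0))
  invisible(x)
}

#' Project a whole panel across scenarios
#'
#' @param records Named list of [country_record()] objects.
#' @param scenarios List of [scenario()] objects (default: the four
#'   built-ins).
#' @param registry Intervention registry.
#' @param year Projection year (default 2030).
#' @param lives_saved_mode Passed to [project()].
#' @return List with `projections` (data frame: iso3, scenario, year,
#'   mmr, ui_low, ui_high, pct_reduction_vs_s0) and `lives_saved` (data
#'   frame: iso3, scenario, intervention_id, lives_saved), plus the raw
#'   [project()] results in `results`.
#' @export
project_panel <- function(records, scenarios = builtin_scenarios(),
                          registry = default_intervention_registry(),
                          year = 2030, lives_saved_mode = "annual") {
  results <- list()
  for (sc in scenarios) {
    for (rec in records) {
      results[[length(results) + 1L]] <-
        project(rec, sc, registry, year, lives_saved_mode)
    }
  }
  projections <- do.call(rbind, lapply(results, function(p) {
    data.frame(iso3 = p$iso3, scenario = p$scenario_id, year = p$year,
               mmr = p$mmr, ui_low = p$ui[1], ui_high = p$ui[2],
               pct_reduction_vs_s0 = p$pct_reduction_vs_s0,
               row.names = NULL)
  }))
  lives <- do.call(rbind, lapply(results, function(p) {
    data.frame(iso3 = p$iso3, scenario = p$scenario_id,
               intervention_id = names(p$lives_saved),
               lives_saved = as.numeric(p$lives_saved), row.names = NULL)
  }))
  list(projections = projections, lives_saved = lives, results = results)
}

#' Aggregate projections to regional, income-group or world level
#'
#' Group MMR is births-weighted: total residual deaths over total live
#' births, times 100,000. Lives saved are summed. Percent reduction is
#' recomputed from the aggregated MMRs against the group's no-scale-up
#' (baseline) MMR.
#'
#' @param results List of `"mmr_projection"` objects (e.g.
#'   `project_panel(...)$results`), all for the same year.
#' @param grouping `"region"`, `"income"` or `"world"`.
#' @return Data frame with columns `group`, `scenario`, `mmr`, `ui_low`,
#'   `ui_high`, `lives_saved`, `baseline_mmr`, `pct_reduction_vs_s0`.
#' @export
aggregate_projections <- function(results,
                                  grouping = c("region", "income", "world")) {
  grouping <- match.arg(grouping)
  if (length(results) == 0L) stop("empty result set", call. = FALSE)
  key <- vapply(results, function(p) {
    switch(grouping, region = p$region, income = p$income_group,
           world = "world")
  }, "")
  sc <- vapply(results, `[[`, 0L, "scenario_id")
  out <- list()
  for (g in unique(key)) {
    for (s in sort(unique(sc))) {
      sel <- results[key == g & sc == s]
      if (length(sel) == 0L) next
      births <- sum(vapply(sel, `[[`, 0, "live_births"))
      deaths <- sum(vapply(sel, function(p) sum(p$residual_deaths), 0))
      base_deaths <- sum(vapply(sel, function(p) sum(p$baseline_deaths), 0))
      ui <- rowSums(vapply(sel, function(p) {
        p$ui * p$live_births / 1e5
      }, numeric(2))) / births * 1e5
      base_mmr <- base_deaths / births * 1e5
      mmr <- deaths / births * 1e5
      out[[length(out) + 1L]] <- data.frame(
        group = g, scenario = s, mmr = mmr, ui_low = ui[1], ui_high = ui[2],
        lives_saved = sum(vapply(sel, function(p) sum(p$lives_saved), 0)),
        baseline_mmr = base_mmr,
        pct_reduction_vs_s0 = (base_mmr - mmr) / base_mmr * 100,
        row.names = NULL)
    }
  }
  do.call(rbind, out)
}
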