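# Seeded synthetic country-panel generator.
#
# Emulates the statistical structure of the WHO MMR estimates, GBD cause
# shares and LiST coverage inputs the projection model consumes: 126
# countries over 6 WHO regions x 3 income groups, piecewise log-linear MMR
# trends 2000-2020 with 0-2 breakpoints, Dirichlet cause shares with the
# fixed hemorrhage decomposition, uniform baseline coverage, and a
# relative standard error on the 2020 MMR. No attempt is made to match
# any real country; values are synthetic.
#
# Reproducibility: each country draws from its own substream whose seed is
# a deterministic function of (seed, index), so a record is identical no
# matter in which order, or alongside which others, it is generated.

.default_allocation <- function() {
  # Region x income allocation, 126 countries total; counts chosen to
  # resemble the World Bank / WHO LMIC composition.
  data.frame(
    region = rep(c("AFR", "AMR", "SEAR", "EUR", "EMR", "WPR"),
                 times = c(3, 3, 3, 2, 3, 3)),
    income_group = c("low", "lower-middle", "upper-middle",
                     "low", "lower-middle", "upper-middle",
                     "low", "lower-middle", "upper-middle",
                     "lower-middle", "upper-middle",
                     "low", "lower-middle", "upper-middle",
                     "low", "lower-middle", "upper-middle"),
    n = c(23, 18, 5,  1, 5, 11,  1, 7, 2,  5, 12,  4, 7, 5,  1, 12, 7),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic panel generator
#'
#' @param n_countries Number of countries (default 126).
#' @param allocation Data frame with columns `region`, `income_group`, `n`
#'   giving the region-by-income composition; recycled proportionally when
#'   `n_countries` differs from `sum(n)`.
#' @param mmr_range_2020 Named list of length-2 ranges for the 2020 MMR
#'   (per 100,000 live births) by income group.
#' @param years Observation years (default 2000:2020).
#' @param max_breakpoints Maximum number of trend breakpoints per country
#'   (default 2).
#' @param breakpoint_probs Probabilities of 0, 1, ..., `max_breakpoints`
#'   breakpoints.
#' @param apc_range Range of segment annual percent changes, in percent
#'   (default c(-8, 3)).
#' @param min_apc_gap Minimum absolute APC difference (percentage points)
#'   between adjacent segments, so breakpoints are identifiable.
#' @param min_segment_years Minimum segment length in years (default 6).
#' @param noise_sd Observation noise standard deviation on the natural-log
#'   MMR scale (default 0.01).
#' @param cause_alpha Dirichlet concentration over the six aggregate
#'   causes (hemorrhage as one component, later decomposed with the fixed
#'   24/3/73 split).
#' @param coverage_range Range of baseline intervention coverage
#'   (default c(0.2, 0.9)).
#' @param rel_se_2020 Relative standard error of the 2020 MMR
#'   (default 0.08).
#' @param births_range Range of annual live births per country.
#' @param seed Integer random seed.
#' @return An object of class `"panel_config"`.
#' @export
panel_config <- function(n_countries = 126L,
                         allocation = .default_allocation(),
                         mmr_range_2020 = list("low" = c(300, 700),
                                               "lower-middle" = c(70, 400),
                                               "upper-middle" = c(10, 170)),
                         years = 2000:2020,
                         max_breakpoints = 2L,
                         breakpoint_probs = c(0.35, 0.40, 0.25),
                         apc_range = c(-8, 3),
                         min_apc_gap = 2,
                         min_segment_years = 6L,
                         noise_sd = 0.01,
                         cause_alpha = c(hemorrhage = 3.7,
                                         hypertensive_disorders = 3.0,
                                         sepsis = 1.8, abortion = 1.6,
                                         other_direct = 4.4, indirect = 5.5),
                         coverage_range = c(0.2, 0.9),
                         rel_se_2020 = 0.08,
                         births_range = c(2e4, 5e6),
                         seed = 1L) {
  stopifnot(n_countries >= 1L,
            all(c("region", "income_group", "n") %in% names(allocation)),
            all(allocation$region %in% who_regions()),
            all(allocation$income_group %in% income_groups()),
            length(years) >= 7L,
            max_breakpoints >= 0L,
            length(breakpoint_probs) == max_breakpoints + 1L,
            diff(apc_range) >= 0, min_apc_gap >= 0,
            min_segment_years >= 2L, noise_sd >= 0,
            all(cause_alpha > 0), diff(coverage_range) >= 0,
            coverage_range[1] >= 0, coverage_range[2] <= 1,
            rel_se_2020 >= 0, diff(births_range) >= 0, births_range[1] > 0)
  for (rg in mmr_range_2020) stopifnot(length(rg) == 2L, rg[1] > 0, diff(rg) >= 0)
  structure(list(n_countries = as.integer(n_countries),
                 allocation = allocation, mmr_range_2020 = mmr_range_2020,
                 years = as.integer(years),
                 max_breakpoints = as.integer(max_breakpoints),
                 breakpoint_probs = breakpoint_probs,
                 apc_range = apc_range, min_apc_gap = min_apc_gap,
                 min_segment_years = as.integer(min_segment_years),
                 noise_sd = noise_sd, cause_alpha = cause_alpha,
                 coverage_range = coverage_range, rel_se_2020 = rel_se_2020,
                 births_range = births_range, seed = as.integer(seed)),
            class = "panel_config")
}

# Deterministic per-country substream seed below 2^31.
.country_seed <- function(seed, index) {
  as.integer((as.numeric(seed) %% 2147483629 * 48271 +
                as.numeric(index) * 2654435761) %% 2147483629)
}

# Expand the allocation table to one (region, income) pair per index.
.expand_allocation <- function(config) {
  alloc <- config$allocation
  reps <- rep(seq_len(nrow(alloc)), times = alloc$n)
  if (length(reps) != config$n_countries) {
    # Rescale proportionally, then pad/trim cycling through rows so any
    # n_countries gets a full assignment.
    target <- round(alloc$n / sum(alloc$n) * config$n_countries)
    reps <- rep(seq_len(nrow(alloc)), times = target)
    while (length(reps) < config$n_countries) {
      reps <- c(reps, seq_len(nrow(alloc)))
    }
    reps <- reps[seq_len(config$n_countries)]
    reps <- sort(reps)
  }
  alloc[reps, c("region", "income_group"), drop = FALSE]
}

.synthetic_iso3 <- function(index) {
  # Synthetic three-letter codes X{AA..ZZ}; no collision below 677.
  first <- (index - 1L) %/% 26L
  second <- (index - 1L) %% 26L
  paste0("X", LETTERS[first + 1L], LETTERS[second + 1L])
}

# Draw breakpoint years and segment APCs honoring minimum segment length
# and minimum adjacent-APC separation.
.draw_trend <- function(config) {
  years <- config$years
  n_bp <- sample.int(config$max_breakpoints + 1L, 1L,
                     prob = config$breakpoint_probs) - 1L
  span <- range(years)
  bps <- integer(0)
  if (n_bp > 0L) {
    lo <- span[1] + config$min_segment_years
    hi <- span[2] - config$min_segment_years
    candidates <- years[years >= lo & years <= hi]
    ok <- FALSE
    for (attempt in seq_len(50L)) {
      if (length(candidates) < n_bp) break
      bps <- sort(sample(candidates, n_bp))
      if (n_bp == 1L || all(diff(bps) >= config$min_segment_years)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) bps <- integer(0)
  }
  n_seg <- length(bps) + 1L
  apcs <- numeric(n_seg)
  apcs[1] <- stats::runif(1, config$apc_range[1], config$apc_range[2])
  if (n_seg > 1L) {
    for (s in 2:n_seg) {
      repeat {
        a <- stats::runif(1, config$apc_range[1], config$apc_range[2])
        if (abs(a - apcs[s - 1L]) >= config$min_apc_gap) break
      }
      apcs[s] <- a
    }
  }
  list(breakpoints = bps, apcs = apcs)
}

# Piecewise log-linear mean anchored so the final year equals log(anchor).
.piecewise_log_mmr <- function(years, breakpoints, apcs, anchor) {
  slopes <- log(1 + apcs / 100)
  t0 <- years[1]
  base <- slopes[1] * (years - t0)
  if (length(breakpoints)) {
    for (j in seq_along(breakpoints)) {
      delta <- slopes[j + 1L] - slopes[j]
      base <- base + delta * pmax(years - breakpoints[j], 0)
    }
  }
  base + (log(anchor) - base[length(base)])
}

#' Generate one synthetic country record
#'
#' Draws one country from its own (seed, index)-derived substream. The
#' hidden ground truth (true breakpoint years and segment APCs) is
#' returned alongside the record for parameter-recovery testing.
#'
#' @param config A [panel_config()].
#' @param index Country index (1-based).
#' @param registry Intervention registry supplying the coverage ids
#'   (default: the bundled fourteen-intervention registry).
#' @return List with elements `record` (a [country_record()]) and `truth`
#'   (list with `iso3`, `breakpoints`, `apcs`).
#' @export
generate_country <- function(config, index,
                             registry = default_intervention_registry()) {
  stopifnot(inherits(config, "panel_config"),
            index >= 1L, index <= config$n_countries)
  assign_tab <- .expand_allocation(config)
  region <- assign_tab$region[index]
  income <- assign_tab$income_group[index]
  iso3 <- .synthetic_iso3(index)

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(.country_seed(config$seed, index))

  mmr_rg <- config$mmr_range_2020[[income]]
  mmr_2020_true <- stats::runif(1, mmr_rg[1], mmr_rg[2])
  trend <- .draw_trend(config)
  log_mu <- .piecewise_log_mmr(config$years, trend$breakpoints, trend$apcs,
                               mmr_2020_true)
  log_obs <- log_mu + stats::rnorm(length(config$years), 0, config$noise_sd)
  mmr <- exp(log_obs)

  mmr_2020 <- mmr[length(mmr)]
  se_2020 <- config$rel_se_2020 * mmr_2020
  se <- rep(NA_real_, length(config$years))
  se[length(se)] <- se_2020
  ui <- ui_from_se(mmr_2020, se_2020)

  # Six aggregate causes via Dirichlet (normalized gammas), then the fixed
  # hemorrhage decomposition.
  g <- stats::rgamma(length(config$cause_alpha), shape = config$cause_alpha)
  agg <- g / sum(g)
  names(agg) <- names(config$cause_alpha)
  shares <- c(decompose_hemorrhage(agg[["hemorrhage"]]),
              agg[setdiff(names(agg), "hemorrhage")])

  coverage <- stats::runif(length(registry), config$coverage_range[1],
                           config$coverage_range[2])
  names(coverage) <- vapply(registry, `[[`, "", "id")

  births <- round(exp(stats::runif(1, log(config$births_range[1]),
                                   log(config$births_range[2]))))

  rec <- country_record(
    iso3 = iso3, region = region, income_group = income,
    live_births = births,
    series = mmr_series(iso3, config$years, mmr, se),
    causes = cause_profile(shares),
    coverage = coverage,
    mmr_ui_2020 = ui)
  list(record = rec,
       truth = list(iso3 = iso3, breakpoints = trend$breakpoints,
                    apcs = trend$apcs))
}

#' Generate a synthetic country panel
#'
#' Applies [generate_country()] across all indices. Because each country
#' uses an index-derived substream, the resulting multiset of records does
#' not depend on generation order.
#'
#' @inheritParams generate_country
#' @return List with elements `records` (named list of
#'   [country_record()]) and `truth` (data frame with `iso3`,
#'   `breakpoints` as a ";"-separated string, `apcs` likewise).
#' @export
#' @examples
#' panel <- generate_panel(panel_config(n_countries = 4, seed = 7))
#' names(panel$records)
generate_panel <- function(config = panel_config(),
                           registry = default_intervention_registry()) {
  out <- lapply(seq_len(config$n_countries), generate_country,
                config = config, registry = registry)
  records <- lapply(out, `[[`, "record")
  names(records) <- vapply(records, `[[`, "", "iso3")
  truth <- do.call(rbind, lapply(out, function(o) {
    data.frame(iso3 = o$truth$iso3,
               breakpoints = paste(o$truth$breakpoints, collapse = ";"),
               apcs = paste(sprintf("%.6f", o$truth$apcs), collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  list(records = records, truth = truth)
}
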