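# Coverage scale-up scenarios.
#
# Four built-in scenarios over the 2024 baseline to the 2030 horizon:
#   S0 no scale-up             coverage held at baseline
#   S1 modest scale-up         +2 percentage points per year, capped at 100%
#   S2 substantial scale-up    +5 percentage points per year, capped at 100%
#   S3 universal coverage      linear ramp to 95% coverage by 2030
#
# "Increased by 2%/5% per year" is interpreted as absolute percentage
# points per year (the reading consistent with a hard cap at 100%); the
# relative-growth reading is available via `increment_type = "relative"`.

#' Coverage scenario
#'
#' @param id Integer identifier.
#' @param kind One of `"constant"`, `"annual_increment"`,
#'   `"endpoint_target"`.
#' @param increment Annual coverage increment for `"annual_increment"`:
#'   a fraction per year (0.02 means +2 percentage points/year under
#'   `increment_type = "percentage_point"`, or +2% relative growth under
#'   `"relative"`).
#' @param cap Maximum coverage (default 1).
#' @param endpoint Target coverage for `"endpoint_target"` (in \[0, 1\]).
#' @param endpoint_year Year the endpoint is reached (default 2030).
#' @param baseline_year Baseline year (default 2024).
#' @param horizon_year Projection horizon (default 2030).
#' @param increment_type `"percentage_point"` (default) or `"relative"`.
#' @param label Human-readable label.
#' @return An object of class `"mmr_scenario"`.
#' @export
scenario <- function(id, kind = c("constant", "annual_increment",
                                  "endpoint_target"),
                     increment = 0, cap = 1, endpoint = NA_real_,
                     endpoint_year = 2030L, baseline_year = 2024L,
                     horizon_year = 2030L,
                     increment_type = c("percentage_point", "relative"),
                     label = NULL) {
  kind <- match.arg(kind)
  increment_type <- match.arg(increment_type)
  stopifnot(increment >= 0, cap >= 0, cap <= 1,
            baseline_year < horizon_year)
  if (kind == "endpoint_target") {
    stopifnot(!is.na(endpoint), endpoint >= 0, endpoint <= 1,
              endpoint_year > baseline_year)
  }
  structure(list(id = as.integer(id), kind = kind, increment = increment,
                 cap = cap, endpoint = endpoint,
                 endpoint_year = as.integer(endpoint_year),
                 baseline_year = as.integer(baseline_year),
                 horizon_year = as.integer(horizon_year),
                 increment_type = increment_type,
                 label = if (is.null(label)) paste0("scenario ", id) else label),
            class = "mmr_scenario")
}

#' @export
print.mmr_scenario <- function(x, ...) {
  desc <- switch(x$kind,
    constant = "coverage constant at baseline",
    annual_increment = sprintf("+%.0f %s/year, capped at %.0f%%",
                               x$increment * 100,
                               if (x$increment_type == "percentage_point")
                                 "pp" else "% relative",
                               x$cap * 100),
    endpoint_target = sprintf("ramp to %.0f%% coverage by %d",
                              x$endpoint * 100, x$endpoint_year))
  cat(sprintf("Scenario %d (%s): %s\n", x$id, x$label, desc))
  invisible(x)
}

#' The four built-in coverage scale-up scenarios
#'
#' @return Named list of four [scenario()] objects with ids 0-3: no
#'   scale-up, modest (+2 pp/year), substantial (+5 pp/year), universal
#'   (95% coverage by 2030).
#' @export
#' @examples
#' builtin_scenarios()
builtin_scenarios <- function() {
  list(
    s0 = scenario(0L, "constant", label = "no scale-up"),
    s1 = scenario(1L, "annual_increment", increment = 0.02,
                  label = "modest scale-up"),
    s2 = scenario(2L, "annual_increment", increment = 0.05,
                  label = "substantial scale-up"),
    s3 = scenario(3L, "endpoint_target", endpoint = 0.95,
                  label = "universal coverage"))
}

#' Coverage trajectory for one intervention under a scenario
#'
#' Returns the scenario's coverage path from the baseline year to the
#' horizon. Trajectories never decrease coverage: the endpoint-target rule
#' ramps to `max(baseline, endpoint)`, and increments are floored at the
#' baseline value.
#'
#' @param baseline_coverage Baseline-year coverage, a fraction in
#'   \[0, 1\].
#' @param scenario An [scenario()] object.
#' @param years Years to evaluate (default baseline:horizon).
#' @return Named numeric vector of coverage per year, values in \[0, 1\],
#'   non-decreasing.
#' @export
#' @examples
#' s <- builtin_scenarios()
#' coverage_trajectory(0.40, s$s3)[["2030"]]  # 0.95
coverage_trajectory <- function(baseline_coverage, scenario,
                                years = scenario$baseline_year:scenario$horizon_year) {
  if (!is.numeric(baseline_coverage) || length(baseline_coverage) != 1L ||
      is.na(baseline_coverage) || baseline_coverage < 0 ||
      baseline_coverage > 1) {
    stop("baseline coverage must be a single fraction in [0, 1]",
         call. = FALSE)
  }
  stopifnot(inherits(scenario, "mmr_scenario"))
  dt <- years - scenario$baseline_year
  if (any(dt < 0)) {
    stop("trajectory years must not precede the baseline year",
         call. = FALSE)
  }
  cov <- switch(scenario$kind,
    constant = rep(baseline_coverage, length(years)),
    annual_increment = {
      if (scenario$increment_type == "percentage_point") {
        pmin(baseline_coverage + scenario$increment * dt, scenario$cap)
      } else {
        pmin(baseline_coverage * (1 + scenario$increment)^dt, scenario$cap)
      }
    },
    endpoint_target = {
      target <- max(baseline_coverage, scenario$endpoint)
      span <- scenario$endpoint_year - scenario$baseline_year
      frac <- pmin(dt / span, 1)
      baseline_coverage + (target - baseline_coverage) * frac
    })
  cov <- pmax(cov, baseline_coverage)  # scale *up*: never below baseline
  stats::setNames(pmin(pmax(cov, 0), 1), years)
}

#' Coverage change relative to baseline
#'
#' `coverage(year) - coverage(baseline)`; the "intervention coverage
#' change" factor of the impact model. Non-negative for the built-in
#' scenarios.
#'
#' @param trajectory Output of [coverage_trajectory()] (named by year).
#' @param year Year to evaluate; must be in the trajectory.
#' @return Coverage change, a fraction.
#' @export
coverage_change <- function(trajectory, year) {
  yrs <- as.integer(names(trajectory))
  if (!year %in% yrs) {
    stop(sprintf("year %s outside the trajectory (%d-%d)", year,
                 min(yrs), max(yrs)), call. = FALSE)
  }
  unname(trajectory[[as.character(year)]] - trajectory[[1L]])
}

#' Read scenario overrides from JSON
#'
#' Accepts a JSON array of objects with the fields of [scenario()].
#'
#' @param path Path to a JSON file.
#' @return Named list of [scenario()] objects.
#' @export
read_scenarios <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  out <- lapply(raw, function(e) {
    do.call(scenario, e[intersect(names(e), names(formals(scenario)))])
  })
  names(out) <- paste0("s", vapply(out, `[[`, 0L, "id"))
  out
}
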