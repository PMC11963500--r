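# Country-panel domain types and the four-file CSV interchange format.
#
# A panel directory holds:
#   countries.csv   iso3, region, income_group, live_births,
#                   mmr_ui_low_2020, mmr_ui_high_2020
#   mmr_series.csv  iso3, year, mmr, se        (long; se empty except 2020)
#   causes.csv      iso3, cause, share         (long)
#   coverage.csv    iso3, intervention_id, coverage_2024 (long)
#
# All shares, coverages, efficacies are fractions in [0, 1] internally;
# percent appears only at reporting boundaries.

.who_regions <- c("AFR", "AMR", "SEAR", "EUR", "EMR", "WPR")
.income_groups <- c("low", "lower-middle", "upper-middle")

#' WHO regions and income groups used by the panel
#' @return Character vector of the six WHO region codes (`who_regions()`)
#'   or the three World Bank income groups (`income_groups()`).
#' @export
who_regions <- function() .who_regions

#' @rdname who_regions
#' @export
income_groups <- function() .income_groups

#' MMR time series for one country
#'
#' @param iso3 Country identifier (three characters).
#' @param years Integer calendar years, strictly increasing.
#' @param mmr Maternal deaths per 100,000 live births; all positive.
#' @param se Optional standard error per year (`NA` allowed); non-negative
#'   where present.
#' @return An object of class `"mmr_series"`.
#' @export
mmr_series <- function(iso3, years, mmr, se = NULL) {
  years <- as.integer(years)
  mmr <- as.numeric(mmr)
  if (length(years) != length(mmr) || length(years) == 0L) {
    stop("years and mmr must be non-empty and of equal length", call. = FALSE)
  }
  if (anyNA(years) || any(diff(years) <= 0L)) {
    stop(sprintf("series '%s': years must be strictly increasing", iso3),
         call. = FALSE)
  }
  if (anyNA(mmr) || any(mmr <= 0)) {
    stop(sprintf("series '%s': all MMR values must be > 0", iso3),
         call. = FALSE)
  }
  if (is.null(se)) se <- rep(NA_real_, length(years))
  se <- as.numeric(se)
  if (length(se) != length(years) || any(se < 0, na.rm = TRUE)) {
    stop(sprintf("series '%s': standard errors must be >= 0", iso3),
         call. = FALSE)
  }
  structure(list(iso3 = iso3, years = years, mmr = mmr, se = se),
            class = "mmr_series")
}

#' @export
print.mmr_series <- function(x, ...) {
  cat(sprintf("MMR series for %s, %d-%d (%d observations)\n",
              x$iso3, min(x$years), max(x$years), length(x$years)))
  invisible(x)
}

#' One country's record in the panel
#'
#' Bundles identifiers, the MMR series, the cause-of-death profile, annual
#' live births, baseline (2024) intervention coverage and the 80% UI of
#' the 2020 MMR into a validated record.
#'
#' @param iso3 Three-character country code.
#' @param region One of the six WHO regions ([who_regions()]).
#' @param income_group One of `"low"`, `"lower-middle"`, `"upper-middle"`.
#' @param live_births Annual live births, a positive count.
#' @param series An [mmr_series()] containing the year 2020.
#' @param causes A [cause_profile()].
#' @param coverage Named numeric vector: baseline-year coverage per
#'   intervention id, each in \[0, 1\].
#' @param mmr_ui_2020 Length-2 numeric `(lower, upper)` 80% UI bracketing
#'   the 2020 MMR point estimate.
#' @return An object of class `"country_record"`.
#' @export
country_record <- function(iso3, region, income_group, live_births,
                           series, causes, coverage, mmr_ui_2020) {
  if (!is.character(iso3) || length(iso3) != 1L || nchar(iso3) != 3L) {
    stop("iso3 must be a three-character code, got ", deparse(iso3),
         call. = FALSE)
  }
  if (!region %in% .who_regions) {
    stop(sprintf("%s: region must be one of %s", iso3,
                 paste(.who_regions, collapse = ", ")), call. = FALSE)
  }
  if (!income_group %in% .income_groups) {
    stop(sprintf("%s: income_group must be one of %s", iso3,
                 paste(.income_groups, collapse = ", ")), call. = FALSE)
  }
  live_births <- as.numeric(live_births)
  if (length(live_births) != 1L || is.na(live_births) || live_births <= 0) {
    stop(sprintf("%s: live_births must be positive", iso3), call. = FALSE)
  }
  if (!inherits(series, "mmr_series")) series <- do.call(mmr_series, series)
  if (!inherits(causes, "cause_profile")) causes <- cause_profile(causes)
  coverage <- unlist(coverage)
  if (is.null(names(coverage)) || !all(nzchar(names(coverage)))) {
    stop(sprintf("%s: coverage must be named by intervention id", iso3),
         call. = FALSE)
  }
  if (anyNA(coverage) || any(coverage < 0) || any(coverage > 1)) {
    stop(sprintf("%s: coverage values must lie in [0, 1]", iso3),
         call. = FALSE)
  }
  if (!2020L %in% series$years) {
    stop(sprintf("%s: MMR series must contain the year 2020", iso3),
         call. = FALSE)
  }
  point <- series$mmr[series$years == 2020L]
  mmr_ui_2020 <- as.numeric(mmr_ui_2020)
  if (length(mmr_ui_2020) != 2L || anyNA(mmr_ui_2020) ||
      mmr_ui_2020[1] > point || point > mmr_ui_2020[2]) {
    stop(sprintf("%s: 2020 UI must satisfy lower <= point <= upper", iso3),
         call. = FALSE)
  }
  structure(list(iso3 = iso3, region = region, income_group = income_group,
                 live_births = live_births, series = series, causes = causes,
                 coverage = coverage, mmr_2020 = point,
                 mmr_ui_2020 = mmr_ui_2020),
            class = "country_record")
}

#' @export
print.country_record <- function(x, ...) {
  cat(sprintf("Country %s (%s, %s income): MMR 2020 = %.1f (80%% UI %.1f-%.1f), %s live births\n",
              x$iso3, x$region, x$income_group, x$mmr_2020,
              x$mmr_ui_2020[1], x$mmr_ui_2020[2],
              format(x$live_births, big.mark = ",")))
  invisible(x)
}

.require_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read a country panel from a directory of CSV files
#'
#' Reads `countries.csv`, `mmr_series.csv`, `causes.csv` and
#' `coverage.csv` from `path` and assembles validated
#' [country_record()] objects. Any invariant violation (cause shares not
#' summing to 1, negative values, UI not bracketing the point estimate)
#' is an error identifying the offending country and rows.
#'
#' @param path Directory containing the four CSV files.
#' @return Named list of [country_record()] objects.
#' @export
read_panel <- function(path) {
  files <- file.path(path, c("countries.csv", "mmr_series.csv",
                             "causes.csv", "coverage.csv"))
  for (f in files) {
    if (!file.exists(f)) stop("panel file not found: ", f, call. = FALSE)
  }
  countries <- utils::read.csv(files[1], stringsAsFactors = FALSE)
  series <- utils::read.csv(files[2], stringsAsFactors = FALSE)
  causes <- utils::read.csv(files[3], stringsAsFactors = FALSE)
  coverage <- utils::read.csv(files[4], stringsAsFactors = FALSE)

  .require_columns(countries, c("iso3", "region", "income_group",
                                "live_births", "mmr_ui_low_2020",
                                "mmr_ui_high_2020"), "countries.csv")
  .require_columns(series, c("iso3", "year", "mmr", "se"), "mmr_series.csv")
  .require_columns(causes, c("iso3", "cause", "share"), "causes.csv")
  .require_columns(coverage, c("iso3", "intervention_id", "coverage_2024"),
                   "coverage.csv")

  records <- lapply(seq_len(nrow(countries)), function(i) {
    row <- countries[i, ]
    s <- series[series$iso3 == row$iso3, , drop = FALSE]
    if (nrow(s) == 0L) {
      stop(sprintf("countries.csv row %d (%s): no rows in mmr_series.csv",
                   i, row$iso3), call. = FALSE)
    }
    s <- s[order(s$year), , drop = FALSE]
    cs <- causes[causes$iso3 == row$iso3, , drop = FALSE]
    share <- stats::setNames(cs$share, cs$cause)
    prof <- tryCatch(cause_profile(share), error = function(e) {
      stop(sprintf("causes.csv rows for %s (file rows %s): %s", row$iso3,
                   paste(which(causes$iso3 == row$iso3), collapse = ","),
                   conditionMessage(e)), call. = FALSE)
    })
    cv <- coverage[coverage$iso3 == row$iso3, , drop = FALSE]
    country_record(
      iso3 = row$iso3, region = row$region, income_group = row$income_group,
      live_births = row$live_births,
      series = mmr_series(row$iso3, s$year, s$mmr, s$se),
      causes = prof,
      coverage = stats::setNames(cv$coverage_2024, cv$intervention_id),
      mmr_ui_2020 = c(row$mmr_ui_low_2020, row$mmr_ui_high_2020))
  })
  names(records) <- countries$iso3
  records
}

#' Write a country panel to a directory of CSV files
#'
#' Inverse of [read_panel()]: emits the four interchange CSVs. A written
#' panel always re-reads to a field-for-field identical panel.
#'
#' @param records Named list of [country_record()] objects.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_panel <- function(records, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  countries <- do.call(rbind, lapply(records, function(r) {
    data.frame(iso3 = r$iso3, region = r$region,
               income_group = r$income_group, live_births = r$live_births,
               mmr_ui_low_2020 = r$mmr_ui_2020[1],
               mmr_ui_high_2020 = r$mmr_ui_2020[2])
  }))
  series <- do.call(rbind, lapply(records, function(r) {
    data.frame(iso3 = r$iso3, year = r$series$years, mmr = r$series$mmr,
               se = r$series$se)
  }))
  causes <- do.call(rbind, lapply(records, function(r) {
    data.frame(iso3 = r$iso3, cause = names(r$causes),
               share = as.numeric(r$causes))
  }))
  coverage <- do.call(rbind, lapply(records, function(r) {
    data.frame(iso3 = r$iso3, intervention_id = names(r$coverage),
               coverage_2024 = as.numeric(r$coverage))
  }))
  utils::write.csv(countries, file.path(path, "countries.csv"),
                   row.names = FALSE)
  utils::write.csv(series, file.path(path, "mmr_series.csv"),
                   row.names = FALSE)
  utils::write.csv(causes, file.path(path, "causes.csv"), row.names = FALSE)
  utils::write.csv(coverage, file.path(path, "coverage.csv"),
                   row.names = FALSE)
  invisible(path)
}
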