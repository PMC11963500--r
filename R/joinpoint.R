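# Joinpoint regression on log-MMR.
#
# Model: ln MMR(t) = a + b1*t + sum_j d_j * (t - tau_j)+  + eps,
# a continuous piecewise-linear ("joinpoint") fit whose breakpoints tau_j
# are selected by exhaustive search over observed years. Segment slopes
# are cumulative sums of (b1, d_j); APC = (exp(slope) - 1) * 100.
#
# Breakpoint-count selection is a forward sequential likelihood-ratio
# test on the Gaussian log-scale likelihood with a Bonferroni correction
# over candidate placements: k+1 breakpoints are accepted over k only if
# the profile deviance gain n*log(RSS_k/RSS_{k+1}) of the best placement
# exceeds qchisq(1 - alpha/m_{k+1}, df = 2), m being the number of
# admissible placements searched. This controls the probability of
# selecting any spurious joinpoint at about alpha, which plain BIC does
# not: maximizing the likelihood over every placement inflates the gain
# an extra knot can show, and BIC-family penalties routinely admit
# spurious joinpoints on 21-point annual series. Breakpoints are
# constrained to observed years with at least `min_segment` observations
# in every closed segment (the breakpoint year counts for both adjoining
# segments). A perfect fit's RSS is floored at a tiny constant so that
# nested perfect fits show no deviance gain and parsimony decides.

.series_frame <- function(series, year_range = NULL) {
  if (inherits(series, "mmr_series")) {
    df <- data.frame(year = series$years, mmr = series$mmr)
  } else if (is.data.frame(series)) {
    stopifnot(all(c("year", "mmr") %in% names(series)))
    df <- series[, c("year", "mmr")]
  } else {
    stop("series must be an mmr_series or a data frame with year and mmr",
         call. = FALSE)
  }
  if (!is.null(year_range)) {
    df <- df[df$year >= year_range[1] & df$year <= year_range[2], ,
             drop = FALSE]
  }
  if (any(df$mmr <= 0)) stop("all MMR values must be > 0", call. = FALSE)
  df[order(df$year), , drop = FALSE]
}

#' Fit a single log-linear segment and its APC
#'
#' Least-squares fit of `ln(MMR)` on calendar year over a window; the
#' annual percent change is `(exp(slope) - 1) * 100`.
#'
#' @param series An [mmr_series()] or data frame with columns `year`,
#'   `mmr`.
#' @param year_range Optional length-2 window `(first, last)`; defaults to
#'   the whole series.
#' @return List with `slope` (per-year change in ln MMR), `intercept`,
#'   `apc` (percent), `n` (observations used).
#' @export
#' @examples
#' s <- data.frame(year = 2000:2020, mmr = 100 * 0.97^(0:20))
#' fit_segment(s)$apc   # -3
fit_segment <- function(series, year_range = NULL) {
  df <- .series_frame(series, year_range)
  if (nrow(df) < 2L) {
    stop("fit_segment needs at least 2 observations in the window",
         call. = FALSE)
  }
  y <- log(df$mmr)
  t <- df$year
  slope <- stats::cov(t, y) / stats::var(t)
  intercept <- mean(y) - slope * mean(t)
  list(slope = slope, intercept = intercept,
       apc = (exp(slope) - 1) * 100, n = nrow(df))
}

# Hinge design matrix for breakpoints bps at years t.
.hinge_design <- function(t, bps) {
  X <- cbind(1, t)
  for (b in bps) X <- cbind(X, pmax(t - b, 0))
  X
}

# RSS floor: perfect fits tie, then parsimony picks fewer breakpoints.
.rss_floor <- 1e-12

.fit_bps <- function(t, y, bps) {
  X <- .hinge_design(t, bps)
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  list(coef = fit$coefficients, rss = rss)
}

# All admissible breakpoint sets of size k: breakpoints at observed years,
# every closed segment containing >= min_segment observations.
.admissible_sets <- function(years, k, min_segment) {
  n <- length(years)
  if (k == 0L) return(list(integer(0)))
  # Candidate positions by index: segment [start..bp] and [bp..end] counts
  # include the breakpoint itself.
  idx <- seq_len(n)
  cand <- idx[idx >= min_segment & idx <= n - min_segment + 1L]
  if (length(cand) < k) return(list())
  combos <- utils::combn(cand, k, simplify = FALSE)
  keep <- vapply(combos, function(cb) {
    all(diff(c(1L, cb, n)) >= min_segment - 1L)
  }, logical(1))
  lapply(combos[keep], function(cb) years[cb])
}

#' Joinpoint regression of an MMR series
#'
#' Fits continuous piecewise-linear models of `ln(MMR)` on year for every
#' admissible placement of 0 to `max_breakpoints` breakpoints at observed
#' years. Within each breakpoint count the placement minimizing the
#' residual sum of squares is retained; the count is then chosen by a
#' forward sequential likelihood-ratio test: `k + 1` breakpoints are
#' accepted over `k` only when the deviance gain
#' `n * log(RSS_k / RSS_(k+1))` of the best placement exceeds the
#' Bonferroni-corrected chi-squared threshold
#' `qchisq(1 - alpha / m, df = 2)`, `m` being the number of placements
#' searched at `k + 1`. The correction accounts for the search over
#' placements and keeps the probability of selecting a spurious joinpoint
#' near `alpha`. Deterministic for fixed input.
#'
#' @param series An [mmr_series()] or data frame with columns `year`,
#'   `mmr`; needs at least 7 observations.
#' @param max_breakpoints Maximum breakpoints to consider (default 3).
#' @param min_segment Minimum observations per segment, counting the
#'   breakpoint year in both adjoining segments (default 3).
#' @param alpha Size of each sequential likelihood-ratio test
#'   (default 0.05).
#' @return An object of class `"joinpoint"` with components
#'   `breakpoints`, `segments` (data frame: `start`, `end`, `slope`,
#'   `apc`), `aapc` (over the full range), `coefficients`, `rss`,
#'   `selection` (per-count table: best RSS, deviance gain, threshold,
#'   number of placements), `too_short` (TRUE when no breakpoint
#'   placement was admissible), plus the data.
#' @export
#' @examples
#' yrs <- 2000:2020
#' mmr <- exp(log(300) + log(0.95) * (yrs - 2000) +
#'            (log(0.99) - log(0.95)) * pmax(yrs - 2010, 0))
#' fit <- fit_joinpoint(data.frame(year = yrs, mmr = mmr))
#' fit$breakpoints  # 2010
fit_joinpoint <- function(series, max_breakpoints = 3L, min_segment = 3L,
                          alpha = 0.05) {
  df <- .series_frame(series)
  n <- nrow(df)
  if (n < 7L) {
    stop("fit_joinpoint needs at least 7 observations", call. = FALSE)
  }
  t <- df$year
  y <- log(df$mmr)

  # Best placement and RSS for every breakpoint count.
  per_k <- list()
  for (k in 0:max_breakpoints) {
    sets <- .admissible_sets(t, k, min_segment)
    if (length(sets) == 0L) break
    k_best <- NULL
    for (bps in sets) {
      f <- .fit_bps(t, y, bps)
      if (is.null(k_best) || f$rss < k_best$rss - 1e-15) {
        k_best <- c(f, list(bps = bps))
      }
    }
    per_k[[k + 1L]] <- c(k_best, list(m = length(sets)))
  }
  any_admissible_bp <- length(per_k) > 1L

  # Sequence of LR tests of k versus k_max breakpoints (testing against
  # the largest model avoids the stepwise blind spot where two
  # opposite-direction slope changes cancel in a single-knot step).
  # The smallest k not rejected is selected. Thresholds are chi-squared
  # with 2 df per extra joinpoint, Bonferroni-corrected for the number of
  # placements searched at k_max and for the number of tests in the
  # sequence.
  rss_eff <- vapply(per_k, function(f) max(f$rss, .rss_floor), 0)
  kmax <- length(per_k) - 1L
  n_tests <- max(kmax, 1L)
  sel_k <- kmax
  gains <- thresholds <- rep(NA_real_, length(per_k))
  if (kmax > 0L) {
    m_max <- per_k[[kmax + 1L]]$m
    for (k in 0:(kmax - 1L)) {
      gain <- n * log(rss_eff[k + 1L] / rss_eff[kmax + 1L])
      thr <- stats::qchisq(1 - alpha / (n_tests * m_max),
                           df = 2L * (kmax - k))
      gains[k + 1L] <- gain
      thresholds[k + 1L] <- thr
      if (gain <= thr) {
        sel_k <- k
        break
      }
    }
  } else {
    sel_k <- 0L
  }
  selection <- data.frame(
    breakpoints = seq_along(per_k) - 1L,
    rss = vapply(per_k, `[[`, 0, "rss"),
    placements = vapply(per_k, `[[`, 0L, "m"),
    deviance_gain = gains, threshold = thresholds,
    selected = seq_along(per_k) - 1L == sel_k)

  best <- per_k[[sel_k + 1L]]
  bps <- best$bps
  slopes <- cumsum(best$coef[-1])
  starts <- c(t[1], bps)
  ends <- c(bps, t[n])
  segments <- data.frame(start = starts, end = ends, slope = slopes,
                         apc = (exp(slopes) - 1) * 100, row.names = NULL)

  fit <- structure(list(breakpoints = bps, segments = segments,
                        coefficients = best$coef, rss = best$rss,
                        selection = selection,
                        too_short = !any_admissible_bp,
                        years = t, mmr = df$mmr, logmmr = y,
                        max_breakpoints = max_breakpoints,
                        min_segment = min_segment),
                   class = "joinpoint")
  fit$aapc <- aapc(fit, range(t))
  if (fit$too_short && max_breakpoints > 0L) {
    warning("series too short for any breakpoint; returning the ",
            "0-breakpoint fit", call. = FALSE)
  }
  fit
}

#' Average annual percent change over a year range
#'
#' The segment-length-weighted geometric average of the fitted segment
#' slopes: `AAPC = (exp(sum(w_s * slope_s) / sum(w_s)) - 1) * 100`, where
#' `w_s` is the number of years of segment `s` inside the range.
#'
#' @param fit A `"joinpoint"` object from [fit_joinpoint()].
#' @param year_range Length-2 numeric `(first, last)` within the fitted
#'   range.
#' @return AAPC in percent.
#' @export
aapc <- function(fit, year_range = range(fit$years)) {
  stopifnot(inherits(fit, "joinpoint"), length(year_range) == 2L)
  lo <- max(year_range[1], min(fit$years))
  hi <- min(year_range[2], max(fit$years))
  w <- pmax(0, pmin(fit$segments$end, hi) - pmax(fit$segments$start, lo))
  if (sum(w) <= 0) {
    stop("year_range does not overlap the fitted range", call. = FALSE)
  }
  mean_slope <- sum(w * fit$segments$slope) / sum(w)
  (exp(mean_slope) - 1) * 100
}

#' Classify a country's MMR trend as increasing, stalled or declining
#'
#' Single-segment log-linear fits are made over the post-pivot window
#' (default 2015-2020) and the pre-pivot window (series start to pivot),
#' regardless of where the selected joinpoints fall, so the fixed pivot
#' is always honored. The trend is `"increasing"` when the post-pivot APC
#' is positive; `"stalled"` when it is non-positive but strictly less
#' negative than the pre-pivot average decline; `"declining"` otherwise.
#'
#' @param fit A `"joinpoint"` object (carries its data).
#' @param pivot_year Pivot year (default 2015).
#' @param end_year Last year of the post-pivot window (default 2020).
#' @return One of `"increasing"`, `"stalled"`, `"declining"`, with the two
#'   window APCs attached as attributes `apc_post` and `apc_pre`.
#' @export
classify_trend <- function(fit, pivot_year = 2015, end_year = 2020) {
  stopifnot(inherits(fit, "joinpoint"))
  df <- data.frame(year = fit$years, mmr = fit$mmr)
  post <- fit_segment(df, c(pivot_year, end_year))$apc
  pre <- fit_segment(df, c(min(fit$years), pivot_year))$apc
  cls <- if (post > 0) {
    "increasing"
  } else if (post > pre) {
    "stalled"
  } else {
    "declining"
  }
  structure(cls, apc_post = post, apc_pre = pre)
}

#' @export
print.joinpoint <- function(x, digits = 3, ...) {
  cat(sprintf("Joinpoint fit: %d observations %d-%d, %d breakpoint(s)",
              length(x$years), min(x$years), max(x$years),
              length(x$breakpoints)))
  if (length(x$breakpoints)) {
    cat(" at ", paste(x$breakpoints, collapse = ", "), sep = "")
  }
  cat("\nSegments (APC in %):\n")
  print(round(x$segments, digits))
  cat(sprintf("AAPC %d-%d: %.2f%%\n", min(x$years), max(x$years), x$aapc))
  invisible(x)
}

#' @export
summary.joinpoint <- function(object, ...) {
  cls <- classify_trend(object)
  structure(list(fit = object, classification = cls),
            class = "summary.joinpoint")
}

#' @export
print.summary.joinpoint <- function(x, ...) {
  print(x$fit)
  cat("Breakpoint-count selection (sequential LR tests):\n")
  print(round(x$fit$selection, 3))
  cat(sprintf("Trend since 2015: %s (APC post %.2f%%, pre %.2f%%)\n",
              unclass(x$classification),
              attr(x$classification, "apc_post"),
              attr(x$classification, "apc_pre")))
  invisible(x)
}

#' @export
coef.joinpoint <- function(object, ...) {
  cf <- object$coefficients
  names(cf) <- c("(Intercept)", "year",
                 if (length(object$breakpoints))
                   paste0("hinge_", object$breakpoints))
  cf
}

#' Predicted MMR from a joinpoint fit
#'
#' @param object A `"joinpoint"` fit.
#' @param years Years to predict at (default: the fitted years).
#' @param ... Unused.
#' @return Numeric vector of predicted MMR (back-transformed from the log
#'   scale).
#' @export
predict.joinpoint <- function(object, years = object$years, ...) {
  X <- .hinge_design(years, object$breakpoints)
  exp(drop(X %*% object$coefficients))
}

#' @export
fitted.joinpoint <- function(object, ...) predict(object)

#' @export
residuals.joinpoint <- function(object, ...) {
  object$logmmr - log(predict(object))
}

#' @export
plot.joinpoint <- function(x, ...) {
  graphics::plot(x$years, x$mmr, log = "y", xlab = "Year",
                 ylab = "MMR (per 100,000 live births)",
                 pch = 16, ...)
  yy <- seq(min(x$years), max(x$years), by = 0.1)
  graphics::lines(yy, predict(x, yy), col = "firebrick", lwd = 2)
  if (length(x$breakpoints)) {
    graphics::abline(v = x$breakpoints, lty = 3, col = "grey40")
  }
  invisible(x)
}
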