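# Shared fixture builders for the test suite. Everything is constructed
# in code; no data files.

# A valid cause profile with a given aggregate hemorrhage share.
make_profile <- function(hem = 0.27, hyp = 0.16, sep = 0.09, abo = 0.08,
                         oth = 0.15) {
  ind <- 1 - hem - hyp - sep - abo - oth
  cause_profile(c(decompose_hemorrhage(hem),
                  hypertensive_disorders = hyp, sepsis = sep,
                  abortion = abo, other_direct = oth, indirect = ind))
}

# A noiseless piecewise log-linear MMR data frame.
make_series_df <- function(years = 2000:2020, apcs = -3, breakpoints = NULL,
                           mmr0 = 300) {
  slopes <- log(1 + apcs / 100)
  lv <- log(mmr0) + slopes[1] * (years - years[1])
  if (length(breakpoints)) {
    for (j in seq_along(breakpoints)) {
      lv <- lv + (slopes[j + 1] - slopes[j]) * pmax(years - breakpoints[j], 0)
    }
  }
  data.frame(year = years, mmr = exp(lv))
}

# A fully specified small country record.
make_record <- function(iso3 = "XTA", region = "AFR",
                        income_group = "lower-middle",
                        live_births = 100000, mmr_2020 = 200,
                        coverage_ids = names(default_intervention_registry()),
                        coverage = 0.4, apcs = -3, breakpoints = NULL) {
  df <- make_series_df(apcs = apcs, breakpoints = breakpoints)
  df$mmr <- df$mmr * mmr_2020 / df$mmr[nrow(df)]  # anchor 2020 at mmr_2020
  se <- rep(NA_real_, nrow(df))
  se[nrow(df)] <- 0.08 * mmr_2020
  country_record(
    iso3 = iso3, region = region, income_group = income_group,
    live_births = live_births,
    series = mmr_series(iso3, df$year, df$mmr, se),
    causes = make_profile(),
    coverage = stats::setNames(rep(coverage, length(coverage_ids)),
                               coverage_ids),
    mmr_ui_2020 = ui_from_se(mmr_2020, se[nrow(df)]))
}

# Independent brute-force joinpoint oracle: enumerates admissible
# placements from scratch, fits each with lm() on an explicitly built
# hinge data frame, and applies the same k-vs-kmax LR decision rule.
oracle_joinpoint <- function(years, mmr, max_bp = 3, min_seg = 3,
                             alpha = 0.05) {
  n <- length(years)
  y <- log(mmr)
  admissible <- function(k) {
    if (k == 0) return(list(integer(0)))
    pos <- years[seq_len(n) >= min_seg & seq_len(n) <= n - min_seg + 1]
    if (length(pos) < k) return(list())
    cb <- utils::combn(pos, k, simplify = FALSE)
    Filter(function(b) {
      segs <- cbind(c(years[1], b), c(b, years[n]))
      counts <- apply(segs, 1, function(s) sum(years >= s[1] & years <= s[2]))
      all(counts >= min_seg)
    }, cb)
  }
  fit1 <- function(bps) {
    dat <- data.frame(y = y, t = years)
    form <- "y ~ t"
    for (j in seq_along(bps)) {
      dat[[paste0("h", j)]] <- pmax(years - bps[j], 0)
      form <- paste0(form, " + h", j)
    }
    sum(stats::resid(stats::lm(stats::as.formula(form), dat))^2)
  }
  per_k <- list()
  for (k in 0:max_bp) {
    sets <- admissible(k)
    if (!length(sets)) break
    rss <- vapply(sets, fit1, 0)
    i <- which.min(rss)
    per_k[[k + 1]] <- list(bps = sets[[i]], rss = rss[i], m = length(sets))
  }
  kmax <- length(per_k) - 1
  rss_eff <- vapply(per_k, function(f) max(f$rss, 1e-12), 0)
  sel <- kmax
  if (kmax > 0) {
    for (k in 0:(kmax - 1)) {
      gain <- n * log(rss_eff[k + 1] / rss_eff[kmax + 1])
      thr <- stats::qchisq(1 - alpha / (kmax * per_k[[kmax + 1]]$m),
                           df = 2 * (kmax - k))
      if (gain <= thr) {
        sel <- k
        break
      }
    }
  }
  per_k[[sel + 1]]
}
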