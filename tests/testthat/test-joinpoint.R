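test_that("fit_segment matches a closed-form least-squares oracle", {
  # exact log-linear series: APC recovered exactly
  s <- make_series_df(apcs = -3)
  expect_equal(fit_segment(s)$apc, -3, tolerance = 1e-9)

  const <- data.frame(year = 2000:2020, mmr = rep(150, 21))
  expect_equal(fit_segment(const)$apc, 0, tolerance = 1e-12)

  # noisy series against an independently coded normal-equations slope
  set.seed(31)
  for (i in 1:10) {
    t <- 2000:2020
    y <- log(200) - 0.02 * (t - 2000) + rnorm(21, 0, 0.05)
    df <- data.frame(year = t, mmr = exp(y))
    n <- length(t)
    slope_oracle <- (n * sum(t * y) - sum(t) * sum(y)) /
      (n * sum(t^2) - sum(t)^2)
    f <- fit_segment(df)
    expect_equal(f$slope, slope_oracle, tolerance = 1e-9)
    expect_equal(f$apc, (exp(slope_oracle) - 1) * 100, tolerance = 1e-9)
  }

  expect_error(fit_segment(s, c(2020, 2020.5)), "at least 2")
})

test_that("noiseless breakpoint structures are recovered exactly", {
  f1 <- fit_joinpoint(make_series_df(apcs = c(-5, -1), breakpoints = 2010))
  expect_equal(f1$breakpoints, 2010)
  expect_equal(f1$segments$apc, c(-5, -1), tolerance = 1e-6)

  f0 <- fit_joinpoint(make_series_df(apcs = -4))
  expect_length(f0$breakpoints, 0)
  expect_equal(f0$segments$apc, -4, tolerance = 1e-9)

  f2 <- fit_joinpoint(make_series_df(apcs = c(-6, -1, -4),
                                     breakpoints = c(2007, 2014)))
  expect_equal(f2$breakpoints, c(2007, 2014))
  expect_equal(f2$segments$apc, c(-6, -1, -4), tolerance = 1e-6)
})

test_that("selected fit agrees with a brute-force enumeration oracle", {
  set.seed(77)
  cases <- list(
    list(apcs = c(-5, -1), bps = 2010, noise = 0.004),
    list(apcs = -3, bps = NULL, noise = 0.004),
    list(apcs = c(-2, 2), bps = 2012, noise = 0.006),
    list(apcs = c(2, -4, 0), bps = c(2006, 2013), noise = 0.004))
  for (cs in cases) {
    for (rep in 1:3) {
      df <- make_series_df(apcs = cs$apcs, breakpoints = cs$bps)
      df$mmr <- df$mmr * exp(rnorm(21, 0, cs$noise))
      fit <- fit_joinpoint(df)
      oracle <- oracle_joinpoint(df$year, df$mmr)
      expect_equal(as.numeric(fit$breakpoints), as.numeric(oracle$bps))
      expect_equal(fit$rss, oracle$rss, tolerance = 1e-8)
    }
  }
})

test_that("best RSS is non-increasing in the number of breakpoints", {
  set.seed(19)
  for (i in 1:5) {
    df <- make_series_df(apcs = c(-4, -1), breakpoints = 2011)
    df$mmr <- df$mmr * exp(rnorm(21, 0, 0.02))
    sel <- fit_joinpoint(df)$selection
    expect_true(all(diff(sel$rss) <= 1e-10))
  }
})

test_that("fit is invariant to rescaling MMR by a positive constant", {
  set.seed(23)
  df <- make_series_df(apcs = c(-5, 0), breakpoints = 2009)
  df$mmr <- df$mmr * exp(rnorm(21, 0, 0.01))
  f1 <- fit_joinpoint(df)
  df2 <- df
  df2$mmr <- df2$mmr * 37.5
  f2 <- fit_joinpoint(df2)
  expect_equal(f1$breakpoints, f2$breakpoints)
  expect_equal(f1$segments$apc, f2$segments$apc, tolerance = 1e-8)
})

test_that("AAPC is the length-weighted geometric mean of segment APCs", {
  # two equal 10-year segments at -2% and -4%
  f <- fit_joinpoint(make_series_df(apcs = c(-2, -4), breakpoints = 2010))
  expect_equal(aapc(f, c(2000, 2020)),
               (exp((log(0.98) + log(0.96)) / 2) - 1) * 100,
               tolerance = 1e-6)

  # 15-year flat + 5-year -4% segment
  f2 <- fit_joinpoint(make_series_df(apcs = c(0, -4), breakpoints = 2015))
  expect_equal(aapc(f2, c(2000, 2020)),
               (exp(5 * log(0.96) / 20) - 1) * 100, tolerance = 1e-6)

  # single segment: AAPC equals the APC
  f3 <- fit_joinpoint(make_series_df(apcs = -3))
  expect_equal(aapc(f3, c(2000, 2020)), f3$segments$apc, tolerance = 1e-9)

  # AAPC bounded by the extreme segment APCs
  set.seed(3)
  for (i in 1:10) {
    ap <- runif(2, -8, 3)
    ap[2] <- ap[1] + sign(ap[2] - ap[1]) * max(abs(ap[2] - ap[1]), 2)
    fi <- fit_joinpoint(make_series_df(apcs = ap,
                                       breakpoints = sample(2006:2014, 1)))
    a <- aapc(fi, c(2000, 2020))
    expect_gte(a, min(fi$segments$apc) - 1e-9)
    expect_lte(a, max(fi$segments$apc) + 1e-9)
  }

  expect_error(aapc(f, c(2050, 2060)), "overlap")
})

test_that("trend classification follows the fixed 2015 pivot", {
  # post-2015 increase (regional pattern with a positive recent APC)
  inc <- fit_joinpoint(make_series_df(apcs = c(-3, 1.93),
                                      breakpoints = 2015))
  expect_equal(classify_trend(inc), "increasing", ignore_attr = TRUE)

  # slower post-2015 decline than before: stalled
  st <- fit_joinpoint(make_series_df(apcs = c(-5.31, -4.48, -3.97),
                                     breakpoints = c(2010, 2015)))
  cls <- classify_trend(st)
  expect_equal(cls, "stalled", ignore_attr = TRUE)
  expect_lt(attr(cls, "apc_post"), 0)
  expect_gt(attr(cls, "apc_post"), attr(cls, "apc_pre"))

  # faster post-2015 decline: declining
  de <- fit_joinpoint(make_series_df(apcs = c(-2, -4), breakpoints = 2015))
  expect_equal(classify_trend(de), "declining", ignore_attr = TRUE)
})

test_that("joinpoint object supports the standard model methods", {
  df <- make_series_df(apcs = c(-5, -1), breakpoints = 2010)
  fit <- fit_joinpoint(df)
  expect_length(coef(fit), 3)
  expect_equal(predict(fit), df$mmr, tolerance = 1e-6)
  expect_equal(fitted(fit), predict(fit))
  expect_lt(max(abs(residuals(fit))), 1e-8)
  expect_output(print(fit), "breakpoint")
  expect_output(print(summary(fit)), "selection")

  expect_error(fit_joinpoint(df[1:5, ]), "at least 7")
})
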