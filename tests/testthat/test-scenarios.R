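test_that("the four built-in scenarios match their definitions", {
  s <- builtin_scenarios()
  expect_length(s, 4)
  expect_equal(vapply(s, `[[`, 0L, "id"), c(s0 = 0L, s1 = 1L, s2 = 2L,
                                            s3 = 3L))
  expect_equal(s$s0$kind, "constant")
  expect_equal(s$s1$kind, "annual_increment")
  expect_equal(s$s1$increment, 0.02)
  expect_equal(s$s2$increment, 0.05)
  expect_equal(s$s1$cap, 1.0)
  expect_equal(s$s2$cap, 1.0)
  expect_equal(s$s3$kind, "endpoint_target")
  expect_equal(s$s3$endpoint, 0.95)
  expect_equal(s$s3$endpoint_year, 2030L)
  expect_equal(s$s0$baseline_year, 2024L)
})

test_that("coverage trajectories follow the scenario rules", {
  s <- builtin_scenarios()
  # no scale-up: constant at baseline
  expect_equal(unname(coverage_trajectory(0.37, s$s0)), rep(0.37, 7))
  # universal coverage: any baseline below 95% reaches exactly 0.95 in 2030
  expect_equal(coverage_trajectory(0.40, s$s3)[["2030"]], 0.95)
  # +2 pp/year from 0.90 hits the 100% cap before 2030
  tr <- coverage_trajectory(0.90, s$s1)
  expect_equal(tr[["2030"]], 1.00)
  expect_equal(tr[["2029"]], 1.00)
  expect_equal(tr[["2028"]], 0.98)
  # +5 pp/year from 0.40 reaches 0.70 by 2030
  expect_equal(coverage_trajectory(0.40, s$s2)[["2030"]], 0.70)
  # baseline already above the endpoint: never scaled down
  expect_equal(unname(coverage_trajectory(0.96, s$s3)), rep(0.96, 7))

  expect_error(coverage_trajectory(1.2, s$s1), "\\[0, 1\\]")
})

test_that("coverage change is the difference from baseline", {
  s <- builtin_scenarios()
  expect_equal(coverage_change(coverage_trajectory(0.5, s$s0), 2030), 0)
  expect_equal(coverage_change(coverage_trajectory(0.40, s$s1), 2030), 0.12)
  expect_equal(coverage_change(coverage_trajectory(0.96, s$s3), 2030), 0)
  expect_equal(coverage_change(coverage_trajectory(0.40, s$s3), 2027),
               (0.95 - 0.40) * 3 / 6)  # midpoint of the linear ramp
  expect_error(coverage_change(coverage_trajectory(0.4, s$s1), 2035),
               "outside")
})

test_that("scenario ordering and monotonicity hold for any baseline", {
  s <- builtin_scenarios()
  for (b in seq(0, 1, by = 0.05)) {
    trajs <- lapply(s, function(sc) coverage_trajectory(b, sc))
    for (tr in trajs) {
      expect_true(all(diff(tr) >= -1e-12))     # non-decreasing in year
      expect_true(all(tr >= b - 1e-12 & tr <= 1 + 1e-12))
    }
    for (yr in 2024:2030) {
      ch <- vapply(trajs, coverage_change, 0, year = yr)
      expect_lte(ch[["s0"]], ch[["s1"]] + 1e-12)
      expect_lte(ch[["s1"]], ch[["s2"]] + 1e-12)
      expect_gte(ch[["s3"]], ch[["s0"]] - 1e-12)
    }
  }
})

test_that("relative-growth reading is available behind the config switch", {
  rel <- scenario(9L, "annual_increment", increment = 0.02,
                  increment_type = "relative")
  tr <- coverage_trajectory(0.50, rel)
  expect_equal(tr[["2030"]], 0.50 * 1.02^6, tolerance = 1e-12)
})

test_that("scenario JSON overrides round-trip", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('[{"id": 5, "kind": "annual_increment", "increment": 0.03,
               "label": "custom"}]', path)
  sc <- read_scenarios(path)
  expect_length(sc, 1)
  expect_equal(sc$s5$increment, 0.03)
  expect_equal(coverage_trajectory(0.2, sc$s5)[["2030"]], 0.38)
})
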