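test_that("the single-intervention formulas evaluate literally", {
  expect_equal(single_intervention_mmr(200, 0.2, 0.5, 0.8, 1.0), 184.0)
  expect_equal(single_intervention_mmr(200, 0.2, 0, 0.8, 1.0), 200)
  expect_equal(single_intervention_mmr(200, 0.2, 1, 1, 1), 160.0)

  expect_equal(
    single_intervention_lives_saved(100000, 200, 0.2, 0.5, 0.8, 1.0), 16.0)
  expect_equal(
    single_intervention_lives_saved(100000, 200, 0.2, 0, 0.8, 1.0), 0)

  expect_error(single_intervention_mmr(200, 1.2, 0.5, 0.8, 1), "\\[0, 1\\]")
  expect_error(single_intervention_mmr(-5, 0.2, 0.5, 0.8, 1), "> 0")
})

test_that("lives saved and estimated MMR are algebraically linked", {
  set.seed(41)
  for (i in 1:200) {
    lb <- runif(1, 1e4, 5e6)
    mmr <- runif(1, 5, 800)
    x <- runif(4)
    saved <- single_intervention_lives_saved(lb, mmr, x[1], x[2], x[3], x[4])
    est <- single_intervention_mmr(mmr, x[1], x[2], x[3], x[4])
    expect_equal(saved, (mmr - est) * lb / 1e5, tolerance = 1e-9)
  }
})

test_that("multi-intervention cascade matches the worked two-intervention case", {
  # cause deaths 40; effect sizes 0.4 and 0.25
  # residual 40*0.6*0.75 = 18; averted 22; independent 16 and 10
  # rescaled by 22/26
  rec <- make_record(live_births = 1e5, mmr_2020 = 200)
  reg <- list(
    intervention("i1", "childbirth",
                 list(postpartum_hemorrhage = list(efficacy = 0.8,
                                                   affected_fraction = 1))),
    intervention("i2", "childbirth",
                 list(postpartum_hemorrhage = list(efficacy = 0.5,
                                                   affected_fraction = 1))))
  # coverage changes 0.5 give e = 0.4 and 0.25
  pph_share <- as.numeric(rec$causes["postpartum_hemorrhage"])
  d_pph <- rec$live_births * rec$mmr_2020 / 1e5 * pph_share
  out <- apply_interventions(rec, reg, c(i1 = 0.5, i2 = 0.5))
  expect_equal(out$residual_deaths[["postpartum_hemorrhage"]],
               d_pph * 0.6 * 0.75, tolerance = 1e-9)
  averted <- d_pph - d_pph * 0.6 * 0.75
  expect_equal(unname(out$lives_saved[c("i1", "i2")]),
               c(d_pph * 0.4, d_pph * 0.25) * averted /
                 (d_pph * 0.4 + d_pph * 0.25),
               tolerance = 1e-9)
  # the printed worked numbers, scaled to cause deaths of 40
  scale <- 40 / d_pph
  expect_equal(out$residual_deaths[["postpartum_hemorrhage"]] * scale, 18)
  expect_equal(unname(out$lives_saved[c("i1", "i2")]) * scale,
               c(13.538462, 8.461538), tolerance = 1e-6)
})

test_that("one intervention reduces to the printed formulas and order never matters", {
  rec <- make_record()
  reg <- default_intervention_registry()
  ut <- reg["uterotonics_pph"]
  ch <- c(uterotonics_pph = 0.3)
  out <- apply_interventions(rec, ut, ch)
  t <- ut[[1]]$targets$postpartum_hemorrhage
  share <- as.numeric(rec$causes["postpartum_hemorrhage"])
  expect_equal(sum(out$lives_saved),
               single_intervention_lives_saved(
                 rec$live_births, rec$mmr_2020, share, 0.3,
                 t$efficacy, t$affected_fraction),
               tolerance = 1e-9)
  est <- sum(out$residual_deaths) / rec$live_births * 1e5
  expect_equal(est,
               single_intervention_mmr(rec$mmr_2020, share, 0.3,
                                       t$efficacy, t$affected_fraction),
               tolerance = 1e-9)

  # permuting the registry leaves the outputs unchanged
  set.seed(8)
  ch_all <- stats::setNames(runif(length(reg), 0, 0.5), names(reg))
  a <- apply_interventions(rec, reg, ch_all)
  perm <- sample(length(reg))
  b <- apply_interventions(rec, reg[perm], ch_all)
  expect_equal(a$residual_deaths, b$residual_deaths, tolerance = 1e-12)
  expect_equal(a$lives_saved[names(reg)], b$lives_saved[names(reg)],
               tolerance = 1e-12)
})

test_that("projection conserves deaths and honors the scenario rules", {
  rec <- make_record()
  reg <- default_intervention_registry()
  s <- builtin_scenarios()

  p0 <- project(rec, s$s0, reg)
  expect_equal(p0$mmr, rec$mmr_2020, tolerance = 1e-9)
  expect_equal(sum(p0$lives_saved), 0, tolerance = 1e-12)
  expect_equal(p0$ui, rec$mmr_ui_2020, tolerance = 1e-9)

  # every coverage already at/above the endpoint: S3 equals S0
  rec95 <- make_record(coverage = 0.96)
  expect_equal(project(rec95, s$s3, reg)$mmr,
               project(rec95, s$s0, reg)$mmr, tolerance = 1e-12)

  for (sc in s) {
    p <- project(rec, sc, reg)
    expect_equal(sum(p$residual_deaths) + sum(p$lives_saved),
                 sum(p$baseline_deaths), tolerance = 1e-6)
    expect_true(all(p$lives_saved >= 0))
    expect_lte(p$mmr, rec$mmr_2020 + 1e-9)
    expect_gt(p$mmr, 0)
    expect_lte(p$ui[1], p$mmr)
    expect_gte(p$ui[2], p$mmr)
  }

  # cumulative mode sums annual savings over 2025..2030 (more than annual)
  pc <- project(rec, s$s2, reg, lives_saved_mode = "cumulative")
  pa <- project(rec, s$s2, reg, lives_saved_mode = "annual")
  expect_gt(sum(pc$lives_saved), sum(pa$lives_saved))
})

test_that("estimated MMR is monotone across scenarios on a synthetic panel", {
  panel <- generate_panel(panel_config(n_countries = 30, seed = 17))
  reg <- default_intervention_registry()
  s <- builtin_scenarios()
  for (rec in panel$records) {
    mmrs <- vapply(s, function(sc) project(rec, sc, reg)$mmr, 0)
    expect_lte(mmrs[["s3"]], mmrs[["s2"]] + 1e-9)
    expect_lte(mmrs[["s2"]], mmrs[["s1"]] + 1e-9)
    expect_lte(mmrs[["s1"]], mmrs[["s0"]] + 1e-9)
  }
})

test_that("uncertainty intervals are built and propagated multiplicatively", {
  expect_equal(ui_from_se(200, 0), c(200, 200))
  ui <- ui_from_se(200, 39.02)
  expect_equal(ui, c(149.99, 250.01), tolerance = 1e-4)

  expect_equal(propagate_ui(200, c(150, 260), 100), c(75, 130))
  expect_equal(propagate_ui(200, c(150, 260), 200), c(150, 260))
  expect_equal(propagate_ui(200, c(200, 200), 120), c(120, 120))
  # relative width preserved
  set.seed(6)
  for (i in 1:20) {
    base <- runif(1, 50, 500)
    w <- runif(2, 0, 0.4)
    ui0 <- c(base * (1 - w[1]), base * (1 + w[2]))
    est <- base * runif(1, 0.3, 1)
    ui1 <- propagate_ui(base, ui0, est)
    expect_equal(ui1[2] / ui1[1], ui0[2] / ui0[1], tolerance = 1e-9)
  }
  expect_error(propagate_ui(0, c(0, 1), 1), "> 0")
})

test_that("ui_from_se achieves approximately 80% coverage", {
  set.seed(99)
  mmr <- 200
  se <- 30
  ui <- ui_from_se(mmr, se)
  draws <- mmr + se * rnorm(1000)
  cover <- mean(draws >= ui[1] & draws <= ui[2])
  expect_gt(cover, 0.77)
  expect_lt(cover, 0.83)
})

test_that("sensitivity projection compounds the APC from 2020", {
  expect_equal(sensitivity_project(200, 0, 2030), 200)
  expect_equal(sensitivity_project(200, -3, 2030), 200 * 0.97^10,
               tolerance = 1e-12)
  # closed form equals iterated one-year multiplication
  m <- 137
  for (yr in 2021:2030) m <- m * (1 - 0.021)
  expect_equal(sensitivity_project(137, -2.1, 2030), m, tolerance = 1e-9)
})

test_that("aggregation is births-weighted and degenerates correctly", {
  reg <- default_intervention_registry()
  s <- builtin_scenarios()
  a <- make_record(iso3 = "XTA", live_births = 50000, mmr_2020 = 100)
  b <- make_record(iso3 = "XTB", live_births = 50000, mmr_2020 = 300)
  res <- project_panel(list(XTA = a, XTB = b), s["s0"], reg)$results
  agg <- aggregate_projections(res, "world")
  expect_equal(agg$mmr, 200)

  c1 <- make_record(iso3 = "XTC", live_births = 10000, mmr_2020 = 100)
  c2 <- make_record(iso3 = "XTD", live_births = 90000, mmr_2020 = 300)
  res2 <- project_panel(list(XTC = c1, XTD = c2), s["s0"], reg)$results
  expect_equal(aggregate_projections(res2, "world")$mmr, 280)

  res3 <- project_panel(list(XTA = a), s, reg)$results
  agg3 <- aggregate_projections(res3, "region")
  expect_equal(agg3$mmr[agg3$scenario == 0], a$mmr_2020, tolerance = 1e-9)

  # aggregate of identical countries equals any member's result
  twin <- project_panel(list(XTA = a, XTB = modifyList(a, list(iso3 = "XTB"))),
                        s["s2"], reg)$results
  aggt <- aggregate_projections(twin, "world")
  expect_equal(aggt$mmr, twin[[1]]$mmr, tolerance = 1e-9)

  expect_error(aggregate_projections(list(), "world"), "empty")
})
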