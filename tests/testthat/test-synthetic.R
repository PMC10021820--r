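test_that("generators are pure functions of (scenario, seed)", {
  sc <- tiny_scenario()
  expect_identical(generate_ledger(sc, 7), generate_ledger(sc, 7))
  expect_identical(generate_dom_logs(sc, 7), generate_dom_logs(sc, 7))
  expect_identical(generate_population_and_survey(sc, 7),
                   generate_population_and_survey(sc, 7))
  # different seeds move the seeded parts
  expect_false(identical(generate_ledger(sc, 7)$amount,
                         generate_ledger(sc, 8)$amount))
  # byte-identical files for the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_cost_ledger(generate_ledger(sc, 7), p1)
  write_cost_ledger(generate_ledger(sc, 7), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("generated inputs pass schema and ledger validation", {
  sc <- tiny_scenario()
  led <- generate_ledger(sc, 3)
  rep <- validate_ledger(led)
  expect_equal(nrow(rep$errors), 0L)
  expect_equal(nrow(rep$warnings), 0L)
  logs <- generate_dom_logs(sc, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(logs$dom, path, row.names = FALSE)
  expect_silent(read_dom_log(path))
  utils::write.csv(logs$staffing, path, row.names = FALSE)
  roster <- read_staffing(path, sc$constants)
  expect_true(all(roster$monthly_salary_usd > 0))
})

test_that("stochastic observation volumes respect the 10-20 patients-per-site design", {
  sc <- tiny_scenario(balanced_dom = FALSE, time_cv = 0.4)
  logs <- generate_dom_logs(sc, 13)
  n_sites <- length(unique(logs$dom$site))
  expect_equal(n_sites, 8)             # 2 districts x (2 urban + 2 rural)
  per_site <- table(logs$dom$site)
  expect_true(all(per_site >= 10 & per_site <= 20))
  expect_true(nrow(logs$dom) >= 80 && nrow(logs$dom) <= 160)
  # degenerate times: the mean task time is exactly the configured value
  scd <- tiny_scenario()
  logsd <- generate_dom_logs(scd, 13)
  mu <- scd$time_scale_minutes * scd$personnel_totals /
    sum(scd$personnel_totals)
  expect_equal(mean_task_time(logsd$dom, "physician", "MI_STROKE"),
               unname(mu[["MI_STROKE"]]), tolerance = 1e-12)
})

test_that("closed-form expectations compose the stated costing rules", {
  # single fixed national item with one protocol: per-capita = C/62/eligible
  sc <- tiny_scenario()
  exp <- expected_outputs(sc)
  expect_equal(unname(exp$cells[, "consultancy"]), rep(100, 5))
  expect_equal(exp$grand_total,
               sum(sc$supply_totals, sc$personnel_totals,
                   sc$equipment_totals, sc$nonspecific), tolerance = 1e-9)
  expect_equal(sum(exp$shares$category), 100, tolerance = 1e-9)
  expect_equal(exp$coverage, 0.40)
  # zero variable costs: per-capita is independent of covered population
  scz <- tiny_scenario()
  scz$supply_totals[] <- 0
  scz$personnel_totals[] <- 1e-12  # keep protocols active
  scz$shared_supply_usd <- 0
  ez <- expected_outputs(scz)
  scz2 <- scz
  scz2$denominators$covered_population <-
    ceiling(scz$denominators$covered_population / 3)
  ez2 <- expected_outputs(scz2)
  expect_equal(ez$program_total_without, ez2$program_total_without,
               tolerance = 1e-9)
})

test_that("full pipeline recovers the closed-form ground truth on degenerate data", {
  sc <- tiny_scenario()   # time_cv = 0, balanced design
  led <- generate_ledger(sc, 5)
  logs <- generate_dom_logs(sc, 5)
  staffing <- logs$staffing
  staffing$monthly_salary_usd <-
    staffing$monthly_salary / sc$constants$exchange_rate_irr_per_usd
  fit <- pen_costing(led, logs$dom, staffing, sc$denominators,
                     constants = sc$constants)
  exp <- expected_outputs(sc)
  expect_equal(fit$breakdown$cells, exp$cells, tolerance = 1e-6)
  expect_equal(fit$report$per_capita, exp$per_capita, tolerance = 1e-6)
  expect_equal(fit$report$program_total_without,
               exp$program_total_without, tolerance = 1e-6)
})

test_that("usage extremes propagate to the coverage estimator", {
  sc1 <- tiny_scenario(usage_prob = 1.0)
  f1 <- generate_population_and_survey(sc1, 2)
  rec1 <- draw_sample(f1, survey_design("A", 6000, 4000, seed = 2))
  expect_equal(estimate_coverage(rec1)$coverage_pct, 100)
  sc0 <- tiny_scenario(usage_prob = 0.0)
  f0 <- generate_population_and_survey(sc0, 2)
  rec0 <- draw_sample(f0, survey_design("A", 6000, 4000, seed = 2))
  expect_equal(estimate_coverage(rec0)$coverage_pct, 0)
})
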