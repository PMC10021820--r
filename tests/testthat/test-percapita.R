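test_that("per-capita division uses the right denominator and guards zeros", {
  expect_equal(per_capita_fixed(4291.00, 42910), 0.1000, tolerance = 1e-4)
  expect_equal(per_capita_fixed(0, 1000), 0)
  expect_equal(round(per_capita_fixed(1482.814, 49427), 2), 0.03)
  expect_error(per_capita_fixed(100, 0), "eligible population")

  expect_equal(per_capita_variable(1000, 500), 2)
  expect_equal(per_capita_variable(0, 500), 0)
  expect_equal(round(per_capita_variable(102859.24, 44145), 2), 2.33)
  expect_equal(per_capita_variable(0, 0), 0)   # no cost, nobody covered
  expect_error(per_capita_variable(10, 0), "zero covered")
})

test_that("protocol totals include or exclude the introduction component by flag", {
  zero <- setNames(rep(0, 9), pen_categories())
  expect_equal(protocol_total(zero, TRUE), 0)
  expect_equal(protocol_total(zero, FALSE), 0)
  intro_only <- zero; intro_only["introduction"] <- 0.09
  expect_equal(protocol_total(intro_only, FALSE), 0)
  expect_equal(protocol_total(intro_only, TRUE), 0.09)
  # direct-summation oracle: full row sums to 12.298; the introduction
  # component is 0.09, so the without-introduction total is 12.208
  row <- setNames(c(2.33, 9.47, 0.16, 0.10, 0.008, 0.07, 0.09, 0.03, 0.04),
                  pen_categories())
  expect_equal(protocol_total(row, FALSE), 12.208, tolerance = 1e-9)
  expect_equal(protocol_total(row, TRUE), 12.298, tolerance = 1e-9)
  expect_error(protocol_total(row[-1], TRUE), "incomplete")
})

test_that("report assembly divides fixed by eligible, variable by covered", {
  cn <- pen_constants()
  items <- annualize_ledger(make_ledger(
    ledger_row("S", amount = 50, currency = "USD", observed_over_months = 12,
               protocols = "MI_STROKE"),
    ledger_row("C", kind = "consultancy", category = "capital",
               protocols = "MI_STROKE", amount = 100, currency = "USD",
               observed_over_months = NA)
  ), cn)
  bk <- build_breakdown(items, constants = cn)
  den <- data.frame(district = "A", protocol = "MI_STROKE",
                    eligible_population = 100, covered_population = 50)
  rep <- build_report(bk, den)
  expect_equal(rep$per_capita["MI_STROKE", "supply"], 1)      # 50 / 50
  expect_equal(rep$per_capita["MI_STROKE", "consultancy"], 1) # 100 / 100
  expect_equal(rep$totals$total_without_introduction[1], 2)
  expect_equal(rep$program_total_without, 2)

  # a protocol with nonzero cost but no denominators is a configuration error
  den_wrong <- data.frame(district = "A", protocol = "CRC",
                          eligible_population = 100, covered_population = 50)
  expect_error(build_report(bk, den_wrong), "no denominators")
  expect_error(build_report(bk, data.frame(district = "A",
                                           protocol = "MI_STROKE",
                                           eligible_population = 100,
                                           covered_population = 200)),
               "cannot exceed")
})

test_that("per-capita values are homogeneous of degree -1 in denominators", {
  sc <- tiny_scenario()
  bk <- local({
    cells <- matrix(0, 5, 9, dimnames = list(pen_protocols(),
                                             pen_categories()))
    cells[, "supply"] <- sc$supply_totals
    cells[, "consultancy"] <- 100
    bkk <- list(cells = cells, column_totals = colSums(cells),
                grand_total = sum(cells),
                cost_class = setNames(ifelse(pen_categories() %in%
                                               c("supply", "personnel"),
                                             "variable", "fixed"),
                                      pen_categories()))
    class(bkk) <- "pen_breakdown"
    bkk
  })
  den <- sc$denominators
  base <- build_report(bk, den)
  for (k in c(2, 5)) {
    scaled <- den
    scaled$eligible_population <- k * scaled$eligible_population
    scaled$covered_population <- k * scaled$covered_population
    rep_k <- build_report(bk, scaled)
    expect_equal(rep_k$per_capita, base$per_capita / k, tolerance = 1e-9)
    expect_equal(rep_k$program_total_without,
                 base$program_total_without / k, tolerance = 1e-9)
  }
})

test_that("with/without introduction totals differ by the introduction component", {
  sc <- pen_scenario_published()
  exp <- expected_outputs(sc)
  gap <- exp$protocol_totals_with - exp$protocol_totals_without
  expect_equal(unname(gap), unname(exp$per_capita[, "introduction"]),
               tolerance = 1e-9)
  expect_equal(exp$program_total_with - exp$program_total_without,
               sum(exp$per_capita[, "introduction"]), tolerance = 0.02)
})

test_that("consistency checks pass on a coherent report and flag a perturbed cell", {
  sc <- tiny_scenario()
  led <- generate_ledger(sc, seed = 2)
  logs <- generate_dom_logs(sc, seed = 2)
  staffing <- logs$staffing
  staffing$monthly_salary_usd <- staffing$monthly_salary / 36440
  fit <- pen_costing(led, logs$dom, staffing, sc$denominators,
                     constants = sc$constants)
  expect_true(all(fit$checks$pass))

  broken <- fit$report
  broken$per_capita["CRC", "supply"] <- broken$per_capita["CRC", "supply"] * 2
  chk <- consistency_checks(broken, fit$breakdown)
  bad <- chk[!chk$pass, ]
  expect_true(nrow(bad) >= 1)
  expect_true(any(grepl("CRC:supply", bad$target)))
})
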