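test_that("supplies and personnel are variable; everything else is fixed", {
  expect_equal(classify_fixed_variable("supply"), "variable")
  expect_equal(classify_fixed_variable("personnel"), "variable")
  expect_equal(classify_fixed_variable("equipment"), "fixed")
  expect_equal(classify_fixed_variable("customization"), "fixed")
  expect_equal(classify_fixed_variable("introduction"), "fixed")
  expect_error(classify_fixed_variable("lab_analysis"), "unrecognized")
})

test_that("equal splits conserve the total exactly", {
  s <- split_nonspecific(21455.02, pen_protocols())
  expect_equal(unname(s), rep(4291.004, 5), tolerance = 1e-9)
  expect_equal(sum(split_nonspecific(7414.07)), 7414.07)
  expect_equal(unname(split_nonspecific(0)), rep(0, 5))
  expect_error(split_nonspecific(10, character(0)), "non-empty")

  g <- split_shared_item(300, c("MI_STROKE", "FEMALE_CANCER"))
  expect_equal(unname(g), c(150, 150))
  expect_equal(unname(split_shared_item(42, "CRC")), 42)
  three <- split_shared_item(100, c("MI_STROKE", "CRC", "NCD_RISK"))
  expect_equal(sum(three), 100, tolerance = 1e-12)
  expect_error(split_shared_item(10, character(0)), "at least one")
  expect_error(split_shared_item(10, "DENTAL"), "unknown protocol")
})

test_that("breakdown assembly places specific, shared and non-specific items", {
  cn <- pen_constants()
  items <- annualize_ledger(make_ledger(
    ledger_row("S-CRC", amount = 100, currency = "USD", protocols = "CRC"),
    ledger_row("S-SH", amount = 300, currency = "USD",
               protocols = "MI_STROKE;FEMALE_CANCER"),
    ledger_row("CONS", kind = "consultancy", category = "capital",
               level = "national", district = "NATIONAL",
               protocols = "NONSPECIFIC", amount = 62 * 21455.02,
               currency = "USD", observed_over_months = NA)
  ), cn)
  bk <- build_breakdown(items, constants = cn)
  expect_equal(bk$cells["CRC", "supply"], 100)
  expect_equal(bk$cells["MI_STROKE", "supply"], 150)
  expect_equal(bk$cells["FEMALE_CANCER", "supply"], 150)
  expect_equal(unname(bk$cells[, "consultancy"]), rep(4291.004, 5),
               tolerance = 1e-9)
  expect_equal(bk$grand_total, sum(items$annual_cost_usd), tolerance = 1e-9)

  empty <- build_breakdown(items[0, ], constants = cn)
  expect_true(all(empty$cells == 0))
  expect_equal(empty$grand_total, 0)

  # untagged equipment: non-specific with a warning
  ue <- annualize_ledger(make_ledger(
    ledger_row("E-UT", kind = "equipment", category = "capital",
               amount = 500, currency = "USD", units_purchased = 1,
               unit_cost = 500, useful_life_years = 1,
               observed_over_months = NA, protocols = "NONSPECIFIC")
  ), cn)
  ue$protocols <- ""
  expect_warning(bue <- build_breakdown(ue, constants = cn),
                 "no protocol tag")
  expect_equal(sum(bue$cells[, "equipment"]), ue$annual_cost_usd,
               tolerance = 1e-9)
})

test_that("allocation conserves cost for random ledgers and permutes with labels", {
  cn <- pen_constants()
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(3:12, 1)
    rows <- lapply(seq_len(n), function(i) {
      tags <- if (runif(1) < 0.3) "NONSPECIFIC" else
        paste(sample(pen_protocols(), sample(1:3, 1)), collapse = ";")
      kind <- sample(c("supply", "consultancy", "supervision"), 1)
      ledger_row(paste0("I", i), kind = kind,
                 category = if (kind == "supply") "recurrent" else
                   sample(c("capital", "recurrent"), 1),
                 level = "district", protocols = tags,
                 amount = runif(1, 0, 1e5), currency = "USD",
                 observed_over_months = if (kind == "supply") 13 else NA)
    })
    items <- annualize_ledger(do.call(make_ledger, rows), cn)
    bk <- build_breakdown(items, constants = cn)
    expect_equal(sum(bk$cells), sum(items$annual_cost_usd),
                 tolerance = 1e-6)
    expect_equal(unname(bk$column_totals), unname(colSums(bk$cells)),
                 tolerance = 1e-9)
  }

  # permuting protocol labels permutes cells identically
  items <- annualize_ledger(make_ledger(
    ledger_row("A", amount = 120, currency = "USD", protocols = "CRC"),
    ledger_row("B", amount = 80, currency = "USD", protocols = "NCD_RISK")
  ), cn)
  bk1 <- build_breakdown(items, constants = cn)
  swapped <- items
  swapped$protocols <- c("NCD_RISK", "CRC")
  bk2 <- build_breakdown(swapped, constants = cn)
  expect_equal(bk1$cells["CRC", "supply"], bk2$cells["NCD_RISK", "supply"])
  expect_equal(bk1$cells["NCD_RISK", "supply"], bk2$cells["CRC", "supply"])
})

test_that("category shares sum to 100 and follow the printed-cell arithmetic", {
  cn <- pen_constants()
  items <- annualize_ledger(make_ledger(
    ledger_row("S", amount = 300, currency = "USD", observed_over_months = 12),
    ledger_row("C", kind = "consultancy", category = "capital",
               protocols = "NONSPECIFIC", amount = 100, currency = "USD",
               observed_over_months = NA)
  ), cn)
  bk <- build_breakdown(items, constants = cn)
  sh <- category_shares(bk)
  expect_equal(sum(sh$category), 100, tolerance = 1e-9)
  expect_equal(sh$category[["supply"]], 75)
  expect_equal(sh$within["MI_STROKE", "supply"], 100)
  expect_true(all(is.na(sh$within[, "equipment"])))  # empty column

  zero <- build_breakdown(items[0, ], constants = cn)
  expect_error(category_shares(zero), "grand total")
})
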