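test_that("annualization factor matches the discounted-annuity sum oracle", {
  # oracle: a(L, r) = sum_{t=1..L} (1+r)^(-t), direct summation
  expect_equal(annualization_factor(1, 0.10), 1 / 1.1, tolerance = 1e-9)
  expect_equal(annualization_factor(5, 0.10), 3.790786769, tolerance = 1e-8)
  expect_equal(annualization_factor(7, 0), 7)
  for (L in c(1, 2, 3, 5, 8, 13, 20)) {
    for (r in c(0.01, 0.03, 0.05, 0.10, 0.15, 0.30)) {
      expect_equal(annualization_factor(L, r), sum((1 + r)^-(1:L)),
                   tolerance = 1e-9)
    }
  }
  expect_error(annualization_factor(0, 0.1), "useful life")
  expect_error(annualization_factor(5, -0.1), "discount rate")
})

test_that("annualization factor is monotone in life and rate, continuous at r = 0", {
  Ls <- seq(1, 30, by = 0.5)
  f <- annualization_factor(Ls, 0.10)
  expect_true(all(diff(f) > 0))              # increasing in L
  rs <- seq(0.01, 0.5, by = 0.01)
  g <- annualization_factor(5, rs)
  expect_true(all(diff(g) < 0))              # decreasing in r
  expect_equal(annualization_factor(7, 1e-10), 7, tolerance = 1e-6)
})

test_that("equipment annualization satisfies the present-value identity", {
  expect_equal(annual_equipment_cost(2, 1000, 5, 0.10), 527.5949616,
               tolerance = 1e-7)
  expect_equal(annual_equipment_cost(3, 500, 3, 0.10), 603.1722054,
               tolerance = 1e-7)
  expect_equal(annual_equipment_cost(0, 1000, 5, 0.10), 0)
  # annual cost x annuity factor recovers the purchase price
  set.seed(42)
  for (i in 1:20) {
    u <- sample(1:10, 1); c <- runif(1, 10, 5000)
    L <- runif(1, 0.5, 15); r <- runif(1, 0, 0.3)
    a <- annual_equipment_cost(u, c, L, r)
    expect_equal(a * annualization_factor(L, r), u * c, tolerance = 1e-9)
  }
})

test_that("supply, apportionment and cyclic rules follow the stated arithmetic", {
  expect_equal(annualize_supply(1200, 12), 1200)
  expect_equal(annualize_supply(826.70, 13), 763.1076923, tolerance = 1e-9)
  expect_equal(annualize_supply(0, 13), 0)
  expect_error(annualize_supply(100, 0), "positive number of months")

  expect_equal(apportion_national(62000, 62), 1000)
  expect_equal(apportion_national(0, 62), 0)
  expect_equal(apportion_national(123456.78, 62), 1991.238387,
               tolerance = 1e-8)
  expect_error(apportion_national(100, 62, level = "district"),
               "national-level")
  # conservation: shares times the number of universities restore the input
  expect_equal(apportion_national(98765.4321, 62) * 62, 98765.4321,
               tolerance = 1e-9)

  expect_equal(annualize_cyclic(1000, 5), 200)
  expect_equal(annualize_cyclic(0, 5), 0)
  expect_error(annualize_cyclic(100, 0), "cycle length")
  # national retraining composes cycle division with apportionment:
  # 1979.39 x 62 at national level -> /62 -> /5 -> 395.878/year
  expect_equal(annualize_cyclic(apportion_national(1979.39 * 62, 62), 5),
               395.878, tolerance = 1e-9)
})

test_that("ledger annualization dispatches by kind and level", {
  cn <- pen_constants()
  items <- annualize_ledger(small_ledger(), cn)
  expect_s3_class(items, "pen_annualized")
  a <- setNames(items$annual_cost_usd, items$item_id)
  expect_equal(a[["S1"]], 1200)
  expect_equal(a[["S2"]], 763.1076923, tolerance = 1e-9)
  expect_equal(a[["E1"]], 527.5949616, tolerance = 1e-7)
  expect_equal(a[["C1"]], 1000)              # national /62
  expect_equal(a[["R1"]], 1000)              # national /62 then /5

  # a national consultancy item of 62 x 21455.02 lands at 21455.02
  nat <- make_ledger(ledger_row("CN", kind = "consultancy",
                                category = "capital", level = "national",
                                district = "NATIONAL",
                                protocols = "NONSPECIFIC",
                                amount = 62 * 21455.02, currency = "USD",
                                observed_over_months = NA))
  expect_equal(annualize_ledger(nat, cn)$annual_cost_usd, 21455.02,
               tolerance = 1e-9)

  expect_equal(nrow(annualize_ledger(small_ledger()[0, ], cn)), 0L)
  irr <- small_ledger(); irr$currency <- "IRR"
  expect_error(annualize_ledger(irr, cn), "converted to USD")
  pers <- make_ledger(ledger_row("P1", kind = "personnel",
                                 amount = 10, currency = "USD",
                                 observed_over_months = NA))
  expect_error(annualize_ledger(pers, cn), "task-time")
})

test_that("annualization is linear in ledger amounts", {
  cn <- pen_constants()
  led <- small_ledger()
  base <- annualize_ledger(led, cn)$annual_cost_usd
  for (k in c(0.5, 2, 10)) {
    scaled <- led
    scaled$amount <- scaled$amount * k
    scaled$unit_cost <- scaled$unit_cost * k
    expect_equal(annualize_ledger(scaled, cn)$annual_cost_usd, k * base,
                 tolerance = 1e-9)
  }
})
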