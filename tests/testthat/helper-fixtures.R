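# In-code fixtures shared across the suite.

# One valid ledger row with overridable fields.
ledger_row <- function(item_id = "X1", name = "item", district = "D1",
                       level = "district", category = "recurrent",
                       kind = "supply", protocols = "MI_STROKE",
                       amount = 1000, currency = "IRR",
                       units_purchased = NA, unit_cost = NA,
                       useful_life_years = NA, observed_over_months = 12) {
  data.frame(item_id = item_id, name = name, district = district,
             level = level, category = category, kind = kind,
             protocols = protocols, amount = amount, currency = currency,
             units_purchased = units_purchased, unit_cost = unit_cost,
             useful_life_years = useful_life_years,
             observed_over_months = observed_over_months,
             stringsAsFactors = FALSE)
}

make_ledger <- function(...) as_pen_ledger(rbind(...))

# A small valid mixed ledger (USD, so it can be annualized directly).
small_ledger <- function() {
  make_ledger(
    ledger_row("S1", kind = "supply", amount = 1200, currency = "USD",
               observed_over_months = 12),
    ledger_row("S2", kind = "supply", amount = 826.70, currency = "USD",
               observed_over_months = 13, protocols = "CRC"),
    ledger_row("E1", kind = "equipment", category = "capital",
               amount = 2000, currency = "USD", units_purchased = 2,
               unit_cost = 1000, useful_life_years = 5,
               observed_over_months = NA),
    ledger_row("C1", kind = "consultancy", category = "capital",
               level = "national", district = "NATIONAL",
               protocols = "NONSPECIFIC", amount = 62000, currency = "USD",
               observed_over_months = NA),
    ledger_row("R1", kind = "retraining", category = "recurrent",
               level = "national", district = "NATIONAL",
               protocols = "NONSPECIFIC", amount = 310000, currency = "USD",
               observed_over_months = NA)
  )
}

# Tiny DOM log: one observation per role x protocol with given minutes.
balanced_dom_log <- function(minutes_by_protocol) {
  g <- expand.grid(role = c("physician", "midwife", "chw"),
                   protocol = names(minutes_by_protocol),
                   stringsAsFactors = FALSE)
  data.frame(district = "D1", site = "D1-urban-S1", stratum = "urban",
             role = g$role, visit_date = "2016-06-15",
             protocol = g$protocol,
             minutes_per_service = minutes_by_protocol[g$protocol],
             stringsAsFactors = FALSE)
}

# A small non-calibrated scenario for generator tests (fast frames).
tiny_scenario <- function(...) {
  pen_scenario(
    districts = list(A = list(urban_pop = 6000, rural_pop = 4000),
                     B = list(urban_pop = 7000, rural_pop = 3000)),
    supply_totals = c(MI_STROKE = 1200, RESPIRATORY = 600, CRC = 500,
                      FEMALE_CANCER = 900, NCD_RISK = 300),
    personnel_totals = c(MI_STROKE = 5000, RESPIRATORY = 1000, CRC = 2000,
                         FEMALE_CANCER = 4000, NCD_RISK = 6000),
    equipment_totals = c(MI_STROKE = 400, RESPIRATORY = 150, CRC = 0,
                         FEMALE_CANCER = 0, NCD_RISK = 0),
    nonspecific = c(consultancy = 500, retraining = 100,
                    supervision_recurrent = 300, introduction = 450,
                    customization = 120, supervision_capital = 200),
    denominators = data.frame(
      district = rep(c("A", "B"), each = 5),
      protocol = rep(pen_protocols(), 2),
      eligible_population = rep(c(2000, 2500, 1500, 1800, 3000), 2),
      covered_population = rep(c(800, 1000, 600, 700, 1200), 2)
    ),
    shared_supply_usd = 200,
    ...
  )
}
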