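# Annualization of capital and recurrent expenditure: capital recovery
# factor for equipment, 12/months scaling for supplies, cycle division
# for retraining, and national-to-district apportionment.

#' Annualization factor (present value of an annuity)
#'
#' The factor that converts an equipment purchase price into an
#' equivalent constant annual cost over its useful life at a discount
#' rate r: \deqn{a(L, r) = \frac{(1+r)^L - 1}{r (1+r)^L}}
#' i.e. the present value of a 1-per-year annuity over L years; the
#' annual cost is price / a(L, r), which equals price times the capital
#' recovery factor. At r = 0 the factor is L (straight-line
#' depreciation), the continuity limit.
#'
#' @param useful_life_years Useful life L in years (> 0, real).
#' @param discount_rate Annual discount rate r (>= 0).
#' @return The annuity factor (vectorized over both arguments).
#' @examples
#' annualization_factor(5, 0.10) # 3.790787
#' @export
annualization_factor <- function(useful_life_years, discount_rate) {
  if (any(useful_life_years <= 0)) stop("useful life must be > 0")
  if (any(discount_rate < 0)) stop("discount rate must be >= 0")
  L <- useful_life_years
  r <- discount_rate
  # expm1/log1p form: numerically stable as r -> 0, where the naive
  # ((1+r)^L - 1) / (r (1+r)^L) cancels catastrophically
  ifelse(r == 0, L,
         expm1(L * log1p(r)) / (r * exp(L * log1p(r))))
}

#' Annual cost of equipment
#'
#' Purchase cost (units times current unit cost) divided by the
#' annualization factor for the item's useful life and the discount rate.
#'
#' @param units_purchased Number of units bought (>= 0).
#' @param unit_cost Current unit cost (>= 0).
#' @param useful_life_years Useful life in years (> 0).
#' @param discount_rate Annual discount rate (>= 0).
#' @return Annual cost, same currency as `unit_cost`.
#' @examples
#' annual_equipment_cost(2, 1000, 5, 0.10) # 527.59
#' @export
annual_equipment_cost <- function(units_purchased, unit_cost,
                                  useful_life_years, discount_rate) {
  stopifnot(all(units_purchased >= 0), all(unit_cost >= 0))
  units_purchased * unit_cost /
    annualization_factor(useful_life_years, discount_rate)
}

#' Annual cost of supplies
#'
#' Scales supply expenditure observed over the pilot window to a yearly
#' rate: total cost divided by the observation duration in months, times
#' twelve.
#'
#' @param total_cost Total supply expenditure over the window (>= 0).
#' @param observed_over_months Duration of the observation window in
#'   months (> 0).
#' @param months_per_year Months per year (default 12).
#' @return Annual cost.
#' @export
annualize_supply <- function(total_cost, observed_over_months,
                             months_per_year = 12) {
  if (any(observed_over_months <= 0)) {
    stop("observation window must be a positive number of months")
  }
  total_cost / observed_over_months * months_per_year
}

#' Apportion a national expenditure across universities
#'
#' National-level (ministry) expenditure benefits every medical
#' university equally, so each district's share is the cost divided by
#' the number of universities. Only national-level items are apportioned;
#' applying the operation to a district-level item is an error.
#'
#' @param cost National-level cost (vectorized).
#' @param n_universities Number of universities (>= 1).
#' @param level Item level; must be `"national"`.
#' @return The per-university (per-district) share.
#' @export
apportion_national <- function(cost, n_universities, level = "national") {
  stopifnot(n_universities >= 1)
  if (any(level != "national")) {
    stop("apportion_national applies only to national-level items")
  }
  cost / n_universities
}

#' Annualize a cyclically repeated expenditure
#'
#' Expenditure repeated on a fixed revision cycle (retraining-material
#' design, production, translation, printing) contributes its total
#' divided by the cycle length each year. National retraining items are
#' additionally apportioned across universities (compose with
#' [apportion_national()]).
#'
#' @param cost Total expenditure per cycle.
#' @param cycle_years Cycle length in years (>= 1).
#' @return Annual cost.
#' @export
annualize_cyclic <- function(cost, cycle_years) {
  if (any(cycle_years < 1)) stop("cycle length must be >= 1 year")
  cost / cycle_years
}

# Report category for a ledger row. "meeting" folds by its
# capital/recurrent tag: capital meetings belong with the initial
# meetings/workshops/consultancy family, recurrent meetings with annual
# meetings/supervision. "supervision" keeps separate capital and
# recurrent columns, as in the published breakdown.
report_category <- function(kind, category) {
  switch(kind,
    equipment = "equipment",
    supply = "supply",
    personnel = "personnel",
    consultancy = "consultancy",
    retraining = "retraining",
    introduction = "introduction",
    customization = "customization",
    supervision = if (category == "capital") "supervision_capital"
                  else "supervision_recurrent",
    meeting = if (category == "capital") "consultancy"
              else "supervision_recurrent",
    stop("no report category for kind '", kind, "'")
  )
}

#' Annualize a validated cost ledger
#'
#' Dispatches every ledger item to its annualization rule:
#' \itemize{
#'   \item equipment: [annual_equipment_cost()] (capital recovery factor);
#'   \item supply: [annualize_supply()] (scale the pilot window to a year);
#'   \item retraining: [annualize_cyclic()] over the revision cycle;
#'   \item all national-level items: additionally [apportion_national()];
#'   \item district-level recurrent non-supply items and district one-off
#'     items (e.g. program introduction): pass through as annual amounts.
#' }
#' Personnel costs are computed from task-time observations by
#' [personnel_cost_by_protocol()], never from the ledger; a `personnel`
#' ledger row is a configuration error.
#'
#' @param ledger A validated `pen_ledger` with every row in USD (see
#'   [convert_ledger()]).
#' @param constants A [pen_constants()] object.
#' @return A data.frame of class `pen_annualized` with columns
#'   `item_id`, `kind`, `category` (capital/recurrent), `report_category`,
#'   `cost_class` (fixed/variable), `protocols`, `annual_cost_usd`.
#' @export
annualize_ledger <- function(ledger, constants = pen_constants()) {
  if (nrow(ledger) > 0 && any(ledger$currency != "USD")) {
    stop("ledger must be converted to USD before annualization")
  }
  if (any(ledger$kind == "personnel")) {
    stop("personnel costs are derived from task-time observations, ",
         "not ledger rows; remove kind='personnel' items")
  }
  n <- nrow(ledger)
  annual <- numeric(n)
  rcat <- character(n)
  for (i in seq_len(n)) {
    it <- ledger[i, ]
    base <- switch(it$kind,
      equipment = annual_equipment_cost(
        it$units_purchased, it$unit_cost,
        it$useful_life_years, constants$discount_rate),
      supply = annualize_supply(
        it$amount, it$observed_over_months, constants$months_per_year),
      retraining = annualize_cyclic(
        it$amount, constants$retraining_cycle_years),
      it$amount  # consultancy/supervision/introduction/customization/meeting
    )
    if (it$level == "national") {
      base <- apportion_national(base, constants$n_universities)
    }
    annual[i] <- base
    rcat[i] <- report_category(it$kind, it$category)
  }
  out <- data.frame(
    item_id = ledger$item_id,
    kind = ledger$kind,
    category = ledger$category,
    report_category = rcat,
    cost_class = vapply(ledger$kind, classify_fixed_variable, character(1),
                        USE.NAMES = FALSE),
    protocols = ledger$protocols,
    annual_cost_usd = annual,
    stringsAsFactors = FALSE
  )
  class(out) <- c("pen_annualized", "data.frame")
  out
}
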