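#' Service protocols of the program
#'
#' The five service protocols of the IraPEN package: integrated
#' prevention of myocardial infarction and stroke, respiratory-disease
#' screening, colorectal-cancer screening, female-cancer (breast and
#' cervical) screening, and the NCD risk-factor survey.
#'
#' @return Character vector of the five protocol identifiers, in report
#'   order.
#' @export
pen_protocols <- function() {
  c("MI_STROKE", "RESPIRATORY", "CRC", "FEMALE_CANCER", "NCD_RISK")
}

#' Cost-report categories
#'
#' The nine cost categories of the annual cost breakdown: supply and
#' personnel (variable), equipment, consultancy, retraining, recurrent
#' supervision, introduction, customization, and capital supervision
#' (fixed).
#'
#' @return Character vector of category identifiers, in report order.
#' @export
pen_categories <- function() {
  c("supply", "personnel", "equipment", "consultancy", "retraining",
    "supervision_recurrent", "introduction", "customization",
    "supervision_capital")
}

# Ledger item kinds accepted by the reader. Laboratory-analysis costs are
# deliberately not representable: they are excluded from the incremental
# cost of the program.
pen_kinds <- function() {
  c("equipment", "supply", "personnel", "consultancy", "retraining",
    "supervision", "introduction", "customization", "meeting")
}

pen_roles <- function() c("physician", "midwife", "chw")

#' Program constants
#'
#' Bundle of the program-level constants every pipeline stage consumes:
#' the discount rate used by the capital recovery factor, the number of
#' medical universities national expenditure is apportioned across, the
#' retraining revision cycle, the pilot duration, the official exchange
#' rate, and the survey design sizes.
#'
#' @param discount_rate Annual discount rate used to annualize equipment
#'   (fraction per year; default 0.10).
#' @param n_universities Number of Universities of Medical Sciences that
#'   national-level expenditure is divided across (default 62).
#' @param retraining_cycle_years Revision cycle of retraining material in
#'   years (default 5).
#' @param months_per_year Months per year (12; exposed for completeness).
#' @param pilot_duration_months Duration of the pilot phase in months,
#'   used to scale supply expenditure to an annual cost (default 13:
#'   February 2016 through March 2017 inclusive).
#' @param exchange_rate_irr_per_usd Official exchange rate in Iranian
#'   rials per US dollar (default 36440).
#' @param n_protocols Number of service protocols (5).
#' @param families_per_cluster Families sampled per survey cluster (10).
#' @param clusters_per_district Survey clusters per district (25).
#' @param workday_minutes Provider working minutes per day used by the
#'   personnel worktime fraction (default 480, an 8-hour day).
#'
#' @return An object of class `pen_constants` (a validated list). The
#'   derived field `families_per_district` equals
#'   `clusters_per_district * families_per_cluster`.
#' @examples
#' pen_constants(discount_rate = 0.03)
#' @export
pen_constants <- function(discount_rate = 0.10,
                          n_universities = 62,
                          retraining_cycle_years = 5,
                          months_per_year = 12,
                          pilot_duration_months = 13,
                          exchange_rate_irr_per_usd = 36440,
                          n_protocols = 5,
                          families_per_cluster = 10,
                          clusters_per_district = 25,
                          workday_minutes = 480) {
  x <- list(
    discount_rate = discount_rate,
    n_universities = n_universities,
    retraining_cycle_years = retraining_cycle_years,
    months_per_year = months_per_year,
    pilot_duration_months = pilot_duration_months,
    exchange_rate_irr_per_usd = exchange_rate_irr_per_usd,
    n_protocols = n_protocols,
    families_per_cluster = families_per_cluster,
    clusters_per_district = clusters_per_district,
    workday_minutes = workday_minutes
  )
  stopifnot(
    discount_rate >= 0,
    n_universities >= 1, retraining_cycle_years >= 1,
    months_per_year >= 1, n_protocols >= 1,
    families_per_cluster >= 1, clusters_per_district >= 1,
    pilot_duration_months > 0,
    exchange_rate_irr_per_usd > 0,
    workday_minutes > 0
  )
  x$families_per_district <- clusters_per_district * families_per_cluster
  class(x) <- "pen_constants"
  x
}

#' Read program constants from a YAML configuration file
#'
#' Reads the `constants:` block of a run-configuration YAML file and
#' overrides the corresponding [pen_constants()] defaults. Unknown keys
#' are an error.
#'
#' @param path Path to a YAML file with a top-level `constants:` mapping.
#' @return A `pen_constants` object.
#' @export
pen_constants_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  block <- if (!is.null(cfg$constants)) cfg$constants else cfg
  if (is.null(block)) block <- list()
  known <- names(formals(pen_constants))
  bad <- setdiff(names(block), known)
  if (length(bad) > 0) {
    stop("unknown constants field(s): ", paste(bad, collapse = ", "))
  }
  do.call(pen_constants, block)
}

#' @export
print.pen_constants <- function(x, ...) {
  cat("Program constants:\n")
  for (nm in setdiff(names(x), "families_per_district")) {
    cat(sprintf("  %-26s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
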