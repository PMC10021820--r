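# The central fit: run the whole incremental-costing pipeline on a cost
# ledger, task-time log, staffing roster, and population denominators,
# returning one classed object with the annual breakdown, cost shares,
# and per-capita report.

#' Fit the incremental-costing pipeline
#'
#' Runs the full bottom-up costing procedure: validates the ledger
#' (refusing to run on errors), converts every amount to US dollars at
#' the official rate, annualizes capital and recurrent expenditure
#' (capital recovery factor for equipment, pilot-window scaling for
#' supplies, cycle division for retraining, university apportionment for
#' national items), computes annual personnel cost per protocol from the
#' task-time observations and roster, assembles the protocol x category
#' cost breakdown with equal splitting of shared and non-specific items,
#' and converts it to per-capita costs (fixed over eligible, variable
#' over covered populations).
#'
#' @param ledger A `pen_ledger` or path to a ledger CSV.
#' @param dom DOM observation data.frame or path to a DOM log CSV; `NULL`
#'   to skip personnel costing.
#' @param staffing Staffing roster data.frame (with `monthly_salary_usd`)
#'   or path to a staffing CSV; required when `dom` is given.
#' @param denominators `pen_denominators` data.frame or path to a
#'   denominators CSV; `NULL` to skip the per-capita report.
#' @param constants A [pen_constants()] object.
#' @param mode Denominator mode, see [build_report()].
#' @return An object of class `pen_costing`: list with `validation`,
#'   `annualized`, `personnel`, `breakdown`, `shares`, `report`,
#'   `checks`, `constants`.
#' @examples
#' sc <- pen_scenario_published()
#' led <- generate_ledger(sc, seed = 1)
#' logs <- generate_dom_logs(sc, seed = 1)
#' staffing <- logs$staffing
#' staffing$monthly_salary_usd <- staffing$monthly_salary / 36440
#' fit <- pen_costing(led, logs$dom, staffing, sc$denominators,
#'                    constants = sc$constants)
#' fit
#' @export
pen_costing <- function(ledger, dom = NULL, staffing = NULL,
                        denominators = NULL,
                        constants = pen_constants(),
                        mode = c("protocol_denominators",
                                 "program_denominators")) {
  mode <- match.arg(mode)
  if (is.character(ledger)) ledger <- read_cost_ledger(ledger, constants)
  val <- validate_ledger(ledger)
  if (nrow(val$errors) > 0) {
    stop("ledger validation failed with ", nrow(val$errors),
         " error(s); see validate_ledger()")
  }
  ledger <- convert_ledger(ledger, constants$exchange_rate_irr_per_usd)
  items <- annualize_ledger(ledger, constants)

  personnel <- NULL
  if (!is.null(dom)) {
    if (is.character(dom)) dom <- read_dom_log(dom)
    if (is.null(staffing)) stop("staffing roster required with a DOM log")
    if (is.character(staffing)) staffing <- read_staffing(staffing, constants)
    personnel <- personnel_cost_by_protocol(dom, staffing, constants)
  }
  breakdown <- build_breakdown(
    items,
    personnel_by_protocol = if (!is.null(personnel)) personnel$by_protocol,
    constants = constants
  )
  shares <- category_shares(breakdown)

  report <- NULL; checks <- NULL
  if (!is.null(denominators)) {
    if (is.character(denominators)) denominators <- read_denominators(denominators)
    report <- build_report(breakdown, denominators, mode)
    checks <- consistency_checks(report, breakdown)
  }
  out <- list(validation = val, annualized = items, personnel = personnel,
              breakdown = breakdown, shares = shares, report = report,
              checks = checks, constants = constants)
  class(out) <- "pen_costing"
  out
}

#' @export
print.pen_costing <- function(x, ...) {
  cat("Incremental-costing fit\n")
  cat(sprintf("  %d ledger items annualized; grand total %.2f USD/year\n",
              nrow(x$annualized), x$breakdown$grand_total))
  top <- sort(x$shares$category, decreasing = TRUE)[1:2]
  cat(sprintf("  largest cost categories: %s (%.2f%%), %s (%.2f%%)\n",
              names(top)[1], top[1], names(top)[2], top[2]))
  if (!is.null(x$report)) {
    cat(sprintf("  program total per user: %.2f USD (%.2f with introduction)\n",
                x$report$program_total_without, x$report$program_total_with))
  }
  invisible(x)
}

#' @export
summary.pen_costing <- function(object, ...) {
  structure(list(fit = object), class = "summary.pen_costing")
}

#' @export
print.summary.pen_costing <- function(x, ...) {
  f <- x$fit
  print(f$breakdown)
  cat("\nCategory shares of total cost (%):\n")
  print(round(f$shares$category, 2))
  if (!is.null(f$report)) {
    cat("\n")
    print(f$report)
  }
  if (!is.null(f$checks)) {
    cat("\n")
    print(f$checks)
  }
  invisible(x)
}

#' Extract per-user protocol totals from a costing fit
#'
#' @param object A `pen_costing` fit with a per-capita report.
#' @param ... Unused.
#' @return Named vector of per-protocol per-user totals (without the
#'   introduction component); `NULL` when no denominators were supplied.
#' @export
coef.pen_costing <- function(object, ...) {
  if (is.null(object$report)) return(NULL)
  stats::setNames(object$report$totals$total_without_introduction,
                  object$report$totals$protocol)
}

#' Plot the annual cost breakdown
#'
#' Stacked barplot of annual cost per protocol, coloured by cost
#' category.
#'
#' @param x A `pen_costing` fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.pen_costing <- function(x, ...) {
  m <- t(x$breakdown$cells)
  graphics::barplot(m, legend.text = rownames(m),
                    ylab = "Annual cost (USD/year)",
                    args.legend = list(x = "topright", cex = 0.7),
                    las = 2, ...)
  invisible(x)
}

#' Write the machine-readable run summary
#'
#' Writes `summary.json`: program totals, category shares, and
#' consistency-check results for a costing fit.
#'
#' @param fit A `pen_costing` fit.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(fit, path) {
  out <- list(
    grand_total_usd = fit$breakdown$grand_total,
    category_totals = as.list(fit$breakdown$column_totals),
    category_shares_pct = as.list(fit$shares$category)
  )
  if (!is.null(fit$report)) {
    out$program_total_without_introduction <- fit$report$program_total_without
    out$program_total_with_introduction <- fit$report$program_total_with
    out$protocol_totals_without_introduction <- as.list(
      stats::setNames(fit$report$totals$total_without_introduction,
                      fit$report$totals$protocol))
  }
  if (!is.null(fit$checks)) {
    out$checks_passed <- sum(fit$checks$pass)
    out$checks_total <- nrow(fit$checks)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
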