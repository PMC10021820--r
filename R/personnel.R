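# Personnel costing from direct-observation task-time logs: per-visit
# task times by role, worktime fractions, annual salary cost, and the
# attribution of each role's cost across service protocols.

dom_columns <- function() {
  c("district", "site", "stratum", "role", "visit_date", "protocol",
    "minutes_per_service")
}

staffing_columns <- function() {
  c("district", "stratum", "role", "headcount", "monthly_salary",
    "currency", "visits_per_day", "workday_minutes")
}

#' Read a direct-observation task-time log
#'
#' Direct Observation Method (DOM) logs record the minutes an on-site
#' observer timed for each service delivery, by provider role and
#' protocol. Schema:
#' `district,site,stratum,role,visit_date,protocol,minutes_per_service`.
#'
#' @param path Path to the DOM log CSV.
#' @return A data.frame of observations.
#' @export
read_dom_log <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(dom_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("DOM log missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  check_dom(x)
  x
}

check_dom <- function(x) {
  if (nrow(x) == 0) return(invisible(x))
  bad_role <- setdiff(unique(x$role), pen_roles())
  if (length(bad_role) > 0) {
    stop("unknown provider role(s): ", paste(bad_role, collapse = ", "))
  }
  bad_prot <- setdiff(unique(x$protocol), pen_protocols())
  if (length(bad_prot) > 0) {
    stop("unknown protocol(s) in DOM log: ",
         paste(bad_prot, collapse = ", "))
  }
  if (any(x$minutes_per_service <= 0)) {
    stop("minutes_per_service must be > 0")
  }
  invisible(x)
}

#' Read a staffing roster
#'
#' One row per district, stratum and provider role: headcount, monthly
#' salary (IRR or USD), average daily visits, and working minutes per
#' day. Salaries are converted to USD on read.
#'
#' @param path Path to the staffing CSV, schema
#'   `district,stratum,role,headcount,monthly_salary,currency,`
#'   `visits_per_day,workday_minutes`.
#' @param constants A [pen_constants()] object (exchange rate).
#' @return A data.frame with `monthly_salary_usd` in place of the raw
#'   salary/currency pair.
#' @export
read_staffing <- function(path, constants = pen_constants()) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(staffing_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("staffing roster missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  stopifnot(all(x$headcount >= 0), all(x$workday_minutes > 0))
  irr <- x$currency == "IRR"
  x$monthly_salary_usd <- x$monthly_salary
  x$monthly_salary_usd[irr] <-
    convert_currency(x$monthly_salary[irr], constants$exchange_rate_irr_per_usd)
  x$monthly_salary <- NULL
  x$currency <- NULL
  x
}

#' Mean per-visit task time
#'
#' Arithmetic mean of observed minutes per service for one provider
#' role, over all protocols (`protocol = "ALL"`) or one protocol.
#'
#' @param observations DOM observation data.frame.
#' @param role Provider role (`"physician"`, `"midwife"`, `"chw"`).
#' @param protocol A protocol identifier or `"ALL"`.
#' @return Mean minutes per visit.
#' @export
mean_task_time <- function(observations, role, protocol = "ALL") {
  sel <- observations$role == role
  if (!identical(protocol, "ALL")) {
    sel <- sel & observations$protocol == protocol
  }
  if (!any(sel)) {
    stop("no task-time observations for role '", role, "', protocol '",
         protocol, "'")
  }
  mean(observations$minutes_per_service[sel])
}

#' Fraction of the working day spent on program services
#'
#' Mean minutes per visit times daily visits, as a fraction of the
#' working day. Values above 1 indicate noisy timesheets (over-allocated
#' providers) and are clamped to 1 with a warning rather than treated as
#' an invalid state.
#'
#' @param mean_minutes_per_visit Mean task time (minutes).
#' @param visits_per_day Average daily program visits per provider.
#' @param workday_minutes Working minutes per day (> 0).
#' @return A fraction in [0, 1].
#' @export
worktime_fraction <- function(mean_minutes_per_visit, visits_per_day,
                              workday_minutes) {
  if (any(workday_minutes <= 0)) stop("workday_minutes must be > 0")
  f <- mean_minutes_per_visit * visits_per_day / workday_minutes
  if (any(f > 1)) {
    warning("worktime fraction exceeds 1 (over-allocated provider); ",
            "clamping to 1")
    f <- pmin(f, 1)
  }
  f
}

#' Annual salary cost attributable to the program
#'
#' The program's share of a provider group's salary bill: worktime
#' fraction times monthly salary times 12 months times headcount.
#'
#' @param fraction Worktime fraction in [0, 1].
#' @param monthly_salary_usd Average monthly salary (USD).
#' @param headcount Number of providers in the group.
#' @return Annual cost (USD/year).
#' @export
annual_personnel_cost <- function(fraction, monthly_salary_usd, headcount) {
  stopifnot(all(fraction >= 0), all(monthly_salary_usd >= 0),
            all(headcount >= 0))
  fraction * monthly_salary_usd * 12 * headcount
}

#' Annual personnel cost attributed to each protocol
#'
#' For each provider role, the annual program-attributable salary cost is
#' computed per staffing row (worktime fraction from the role's mean task
#' time and the row's visit volume, times salary, times 12, times
#' headcount) and summed. Each role's total is then attributed across
#' protocols proportionally to that role's total observed
#' service-minutes per protocol, so protocol personnel totals conserve
#' the all-protocol personnel total.
#'
#' @param observations DOM observation data.frame.
#' @param staffing Staffing roster (from [read_staffing()] or with a
#'   `monthly_salary_usd` column).
#' @param constants A [pen_constants()] object.
#' @return A list with `by_protocol` (named numeric vector over the five
#'   protocols, USD/year), `by_role` (role x protocol matrix), and
#'   `role_totals`.
#' @export
personnel_cost_by_protocol <- function(observations, staffing,
                                       constants = pen_constants()) {
  check_dom(observations)
  protos <- pen_protocols()
  roles <- intersect(pen_roles(), unique(staffing$role))
  by_role <- matrix(0, nrow = length(roles), ncol = length(protos),
                    dimnames = list(roles, protos))
  role_totals <- stats::setNames(numeric(length(roles)), roles)
  for (role in roles) {
    rows <- staffing[staffing$role == role & staffing$headcount > 0, ]
    if (nrow(rows) == 0) next
    m <- mean_task_time(observations, role)
    total <- 0
    for (j in seq_len(nrow(rows))) {
      wd <- rows$workday_minutes[j]
      if (is.na(wd)) wd <- constants$workday_minutes
      f <- worktime_fraction(m, rows$visits_per_day[j], wd)
      total <- total + annual_personnel_cost(f, rows$monthly_salary_usd[j],
                                             rows$headcount[j])
    }
    role_totals[role] <- total
    obs <- observations[observations$role == role, ]
    if (nrow(obs) == 0 && total > 0) {
      stop("no task-time observations for role '", role,
           "' with nonzero staffing cost")
    }
    mins <- vapply(protos, function(p) {
      sum(obs$minutes_per_service[obs$protocol == p])
    }, numeric(1))
    if (sum(mins) > 0) {
      by_role[role, ] <- total * mins / sum(mins)
    }
  }
  list(
    by_protocol = colSums(by_role),
    by_role = by_role,
    role_totals = role_totals
  )
}
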