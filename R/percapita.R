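# Per-capita incremental cost: fixed costs over the eligible
# population, variable costs over the covered population, protocol and
# program totals with and without the one-off introduction cost.

#' Population denominators
#'
#' Per (district, protocol) eligible and covered population counts.
#' Fixed costs are divided by the eligible population; variable costs by
#' the covered population.
#'
#' @param x A data.frame with columns
#'   `district, protocol, eligible_population, covered_population`.
#' @return The validated data.frame, classed `pen_denominators`.
#' @export
as_pen_denominators <- function(x) {
  need <- c("district", "protocol", "eligible_population",
            "covered_population")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("denominators missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- setdiff(unique(x$protocol), pen_protocols())
  if (length(bad) > 0) stop("unknown protocol(s): ", paste(bad, collapse = ", "))
  stopifnot(all(x$eligible_population > 0),
            all(x$covered_population >= 0))
  if (any(x$covered_population > x$eligible_population)) {
    stop("covered population cannot exceed eligible population")
  }
  class(x) <- c("pen_denominators", "data.frame")
  x
}

#' Read population denominators from CSV
#'
#' Schema: `district,protocol,eligible_population,covered_population`.
#'
#' @param path Path to the CSV.
#' @return A `pen_denominators` data.frame.
#' @export
read_denominators <- function(path) {
  as_pen_denominators(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Per-capita fixed cost
#'
#' Fixed costs do not vary with coverage, so they are spread over the
#' whole eligible population.
#'
#' @param annual_cost Annual fixed cost (USD/year).
#' @param eligible_population Eligible individuals (> 0).
#' @return USD per eligible person per year.
#' @export
per_capita_fixed <- function(annual_cost, eligible_population) {
  if (any(eligible_population <= 0)) {
    stop("eligible population must be > 0")
  }
  annual_cost / eligible_population
}

#' Per-capita variable cost
#'
#' Variable costs scale with service use, so they are spread over the
#' population actually covered by the program.
#'
#' @param annual_cost Annual variable cost (USD/year).
#' @param covered_population Covered individuals; must be > 0 whenever
#'   the cost is positive (a positive cost with nobody covered has no
#'   defined per-user cost).
#' @return USD per covered user per year.
#' @export
per_capita_variable <- function(annual_cost, covered_population) {
  if (any(annual_cost > 0 & covered_population <= 0)) {
    stop("positive variable cost with zero covered population")
  }
  ifelse(covered_population > 0, annual_cost / covered_population, 0)
}

#' Per-protocol total per-capita cost
#'
#' Sum of a protocol's per-capita components; the one-off introduction
#' component is included or excluded by flag, since introduction costs
#' apply only to the first year of implementation.
#'
#' @param row Named numeric vector of per-capita values over the nine
#'   report categories.
#' @param include_introduction Include the introduction component?
#' @return USD per capita.
#' @export
protocol_total <- function(row, include_introduction = TRUE) {
  cats <- pen_categories()
  missing_cats <- setdiff(cats, names(row))
  if (length(missing_cats) > 0) {
    stop("incomplete per-capita row; missing: ",
         paste(missing_cats, collapse = ", "))
  }
  use <- if (include_introduction) cats else setdiff(cats, "introduction")
  sum(row[use])
}

#' Build the per-capita cost report
#'
#' Applies [per_capita_fixed()] / [per_capita_variable()] cell-wise to
#' the annual cost breakdown: variable categories (supply, personnel)
#' are divided by the covered population, fixed categories by the
#' eligible population. Two denominator modes:
#' \describe{
#'   \item{protocol_denominators}{each protocol uses its own eligible and
#'     covered counts (summed over districts) — the default, since
#'     protocols target different demographics;}
#'   \item{program_denominators}{a single program-wide pair (the maximum
#'     eligible and covered count over protocols per district, summed) is
#'     applied to every protocol.}
#' }
#'
#' @param breakdown A `pen_breakdown`.
#' @param denominators A `pen_denominators` data.frame.
#' @param mode Denominator mode (see above).
#' @return Object of class `pen_report`: list with `per_capita`
#'   (protocol x category matrix), `totals` (data.frame of per-protocol
#'   totals with and without introduction), `program_total_without`,
#'   `program_total_with`, `denominators_used`.
#' @export
build_report <- function(breakdown, denominators,
                         mode = c("protocol_denominators",
                                  "program_denominators")) {
  mode <- match.arg(mode)
  denominators <- as_pen_denominators(as.data.frame(denominators))
  protos <- pen_protocols()
  cats <- pen_categories()

  eligible <- stats::setNames(numeric(length(protos)), protos)
  covered <- stats::setNames(numeric(length(protos)), protos)
  if (mode == "protocol_denominators") {
    for (p in protos) {
      d <- denominators[denominators$protocol == p, ]
      if (nrow(d) == 0) {
        if (any(breakdown$cells[p, ] > 0)) {
          stop("no denominators for protocol ", p, " with nonzero cost")
        }
        eligible[p] <- NA_real_; covered[p] <- NA_real_
      } else {
        eligible[p] <- sum(d$eligible_population)
        covered[p] <- sum(d$covered_population)
      }
    }
  } else {
    agg_e <- tapply(denominators$eligible_population, denominators$district, max)
    agg_c <- tapply(denominators$covered_population, denominators$district, max)
    eligible[] <- sum(agg_e)
    covered[] <- sum(agg_c)
  }

  pc <- matrix(0, nrow = length(protos), ncol = length(cats),
               dimnames = list(protos, cats))
  for (p in protos) {
    if (is.na(eligible[p])) next
    for (cc in cats) {
      cost <- breakdown$cells[p, cc]
      pc[p, cc] <- if (breakdown$cost_class[[cc]] == "variable") {
        per_capita_variable(cost, covered[p])
      } else {
        per_capita_fixed(cost, eligible[p])
      }
    }
  }
  tot_wo <- apply(pc, 1, protocol_total, include_introduction = FALSE)
  tot_wi <- apply(pc, 1, protocol_total, include_introduction = TRUE)
  out <- list(
    per_capita = pc,
    totals = data.frame(
      protocol = protos,
      total_without_introduction = tot_wo,
      total_with_introduction = tot_wi,
      row.names = NULL, stringsAsFactors = FALSE
    ),
    program_total_without = sum(tot_wo),
    program_total_with = sum(tot_wi),
    denominators_used = data.frame(
      protocol = protos, eligible = eligible, covered = covered,
      row.names = NULL, stringsAsFactors = FALSE
    ),
    mode = mode
  )
  class(out) <- "pen_report"
  out
}

#' @export
print.pen_report <- function(x, digits = 2, ...) {
  cat("Per-capita annual incremental cost (USD)\n")
  cat("  fixed components per eligible person; variable per covered user\n\n")
  m <- cbind(round(x$per_capita, digits),
             `total (w/o intro)` = round(x$totals$total_without_introduction,
                                         digits),
             `total (w/ intro)` = round(x$totals$total_with_introduction,
                                        digits))
  print(m)
  cat(sprintf("\nProgram total per user: %.2f (without introduction), %.2f (with)\n",
              x$program_total_without, x$program_total_with))
  invisible(x)
}

#' Internal consistency checks on a per-capita report
#'
#' Verifies, without throwing, that
#' (a) each protocol's with/without-introduction difference equals its
#' per-capita introduction component, (b) the program totals equal the
#' sums of the protocol totals, and (c) each per-capita cell times its
#' denominator recovers the breakdown cell to 0.5%.
#'
#' @param report A `pen_report`.
#' @param breakdown The `pen_breakdown` it was built from.
#' @return Data.frame of class `pen_checks` with columns `check`,
#'   `target`, `pass`.
#' @export
consistency_checks <- function(report, breakdown) {
  rows <- list()
  add <- function(check, target, pass) rows[[length(rows) + 1L]] <<-
    data.frame(check = check, target = target, pass = pass)

  for (p in rownames(report$per_capita)) {
    d <- report$totals$total_with_introduction[report$totals$protocol == p] -
      report$totals$total_without_introduction[report$totals$protocol == p]
    add("introduction_difference", p,
        abs(d - report$per_capita[p, "introduction"]) <= 0.01)
  }
  add("program_total_without", "program",
      abs(report$program_total_without -
            sum(report$totals$total_without_introduction)) <= 1e-9)
  add("program_total_with", "program",
      abs(report$program_total_with -
            sum(report$totals$total_with_introduction)) <= 1e-9)
  den <- report$denominators_used
  for (p in rownames(report$per_capita)) {
    e <- den$eligible[den$protocol == p]
    cv <- den$covered[den$protocol == p]
    if (is.na(e)) next
    for (cc in colnames(report$per_capita)) {
      n <- if (breakdown$cost_class[[cc]] == "variable") cv else e
      back <- report$per_capita[p, cc] * n
      ref <- breakdown$cells[p, cc]
      ok <- if (ref == 0) back == 0 else abs(back - ref) / ref <= 0.005
      add("cell_recovery", paste(p, cc, sep = ":"), ok)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pen_checks", "data.frame")
  out
}

#' @export
print.pen_checks <- function(x, ...) {
  n_fail <- sum(!x$pass)
  cat(sprintf("Consistency checks: %d of %d passed\n",
              nrow(x) - n_fail, nrow(x)))
  if (n_fail > 0) print(as.data.frame(x[!x$pass, ]), row.names = FALSE)
  invisible(x)
}

#' Write the per-capita report to CSV
#'
#' Protocol rows by per-capita category columns plus the two total
#' columns, 2-decimal fixed point, with a program-total row.
#'
#' @param report A `pen_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  m <- as.data.frame(round(report$per_capita, 2))
  m <- cbind(protocol = rownames(report$per_capita), m,
             total_without_introduction =
               round(report$totals$total_without_introduction, 2),
             total_with_introduction =
               round(report$totals$total_with_introduction, 2))
  tot <- c(protocol = "Total", as.list(round(colSums(report$per_capita), 2)),
           total_without_introduction = round(report$program_total_without, 2),
           total_with_introduction = round(report$program_total_with, 2))
  out <- rbind(m, as.data.frame(tot))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
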