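# Fixed/variable classification, equal-split apportionment of shared and
# non-specific costs, and assembly of the protocol x category annual
# cost breakdown.

#' Classify an item kind as fixed or variable
#'
#' Supplies and personnel scale with program coverage and are variable;
#' every other cost category is fixed.
#'
#' @param kind A ledger item kind (see [read_cost_ledger()]).
#' @return `"fixed"` or `"variable"`.
#' @export
classify_fixed_variable <- function(kind) {
  if (!kind %in% pen_kinds()) stop("unrecognized kind: ", kind)
  if (kind %in% c("supply", "personnel")) "variable" else "fixed"
}

#' Split a non-specific cost equally across protocols
#'
#' Overhead not attributable to any single service (program
#' introduction, supervision, customization, consultancy) is apportioned
#' to each protocol equally. The split conserves the total exactly; no
#' rounding happens at this stage.
#'
#' @param cost Amount to split.
#' @param protocols Character vector of protocol identifiers (non-empty).
#' @return Named numeric vector, one equal share per protocol.
#' @examples
#' split_nonspecific(21455.02, pen_protocols()) # 4291.004 each
#' @export
split_nonspecific <- function(cost, protocols = pen_protocols()) {
  if (length(protocols) == 0) stop("protocol list must be non-empty")
  stats::setNames(rep(cost / length(protocols), length(protocols)),
                  protocols)
}

#' Split a shared item across the protocols that use it
#'
#' Supplies and equipment used in multiple protocols (e.g. disposable
#' gloves) are divided equally between those protocols only — not across
#' all five.
#'
#' @param cost Amount to split.
#' @param using_protocols Protocols that use the item (non-empty subset
#'   of the five).
#' @return Named numeric vector over `using_protocols`, summing to
#'   `cost`.
#' @export
split_shared_item <- function(cost, using_protocols) {
  if (length(using_protocols) == 0) {
    stop("shared item must be tagged with at least one protocol")
  }
  bad <- setdiff(using_protocols, pen_protocols())
  if (length(bad) > 0) stop("unknown protocol(s): ", paste(bad, collapse = ", "))
  split_nonspecific(cost, using_protocols)
}

#' Assemble the protocol x category annual cost breakdown
#'
#' Places every annualized item into the 5-protocol x 9-category matrix:
#' protocol-specific items land in their protocol's cell; items tagged
#' with several protocols are split equally between those protocols
#' ([split_shared_item()]); `NONSPECIFIC` items are split equally across
#' all five ([split_nonspecific()]). The personnel column comes from
#' [personnel_cost_by_protocol()]. Untagged equipment is treated as
#' non-specific with a warning.
#'
#' @param items A `pen_annualized` data.frame (from [annualize_ledger()]).
#' @param personnel_by_protocol Named numeric vector of annual personnel
#'   cost per protocol (the `by_protocol` element of
#'   [personnel_cost_by_protocol()]), or `NULL` for none.
#' @param constants A [pen_constants()] object.
#' @return An object of class `pen_breakdown`: list with `cells`
#'   (protocol x category matrix, USD/year), `column_totals`,
#'   `grand_total`, and `cost_class` (fixed/variable per category).
#' @export
build_breakdown <- function(items, personnel_by_protocol = NULL,
                            constants = pen_constants()) {
  protos <- pen_protocols()
  cats <- pen_categories()
  cells <- matrix(0, nrow = length(protos), ncol = length(cats),
                  dimnames = list(protos, cats))
  for (i in seq_len(nrow(items))) {
    it <- items[i, ]
    if (it$report_category == "personnel") next
    tags <- split_protocols(it$protocols)
    if (identical(tags, "NONSPECIFIC")) {
      share <- split_nonspecific(it$annual_cost_usd, protos)
    } else if (length(tags) == 0 || all(!nzchar(tags))) {
      if (it$kind == "equipment") {
        warning("equipment item '", it$item_id,
                "' has no protocol tag; treating as non-specific")
        share <- split_nonspecific(it$annual_cost_usd, protos)
      } else {
        stop("item '", it$item_id,
             "' has no protocol tag and is not marked NONSPECIFIC")
      }
    } else {
      share <- split_shared_item(it$annual_cost_usd, tags)
    }
    cells[names(share), it$report_category] <-
      cells[names(share), it$report_category] + share
  }
  if (!is.null(personnel_by_protocol)) {
    cells[names(personnel_by_protocol), "personnel"] <-
      cells[names(personnel_by_protocol), "personnel"] + personnel_by_protocol
  }
  column_totals <- colSums(cells)
  out <- list(
    cells = cells,
    column_totals = column_totals,
    grand_total = sum(column_totals),
    cost_class = stats::setNames(
      ifelse(cats %in% c("supply", "personnel"), "variable", "fixed"), cats)
  )
  class(out) <- "pen_breakdown"
  out
}

#' Category and within-category cost shares
#'
#' Each category's percentage of the grand total, and — within the
#' supply, personnel and equipment columns — each protocol's percentage
#' of the column total. Shares are computed on unrounded cells.
#'
#' @param breakdown A `pen_breakdown`.
#' @return List with `category` (named vector, percent of grand total)
#'   and `within` (protocol x {supply, personnel, equipment} matrix of
#'   within-column percentages; a zero column yields `NA`).
#' @export
category_shares <- function(breakdown) {
  if (breakdown$grand_total <= 0) {
    stop("grand total must be positive to compute shares")
  }
  cat_share <- 100 * breakdown$column_totals / breakdown$grand_total
  wcats <- c("supply", "personnel", "equipment")
  within <- sapply(wcats, function(cc) {
    tot <- breakdown$column_totals[[cc]]
    if (tot > 0) 100 * breakdown$cells[, cc] / tot else
      rep(NA_real_, nrow(breakdown$cells))
  })
  rownames(within) <- rownames(breakdown$cells)
  list(category = cat_share, within = within)
}

#' @export
print.pen_breakdown <- function(x, digits = 2, ...) {
  cat("Annual incremental cost breakdown (USD/year)\n\n")
  m <- rbind(x$cells, Total = x$column_totals)
  print(round(m, digits))
  cat(sprintf("\nGrand total: %.2f USD/year\n", x$grand_total))
  invisible(x)
}

#' Write the annual cost breakdown to CSV
#'
#' Mirrors the published summary-table layout: protocol rows by nine
#' category columns, a totals row, and category-share and
#' within-category share columns, at 2-decimal fixed point.
#'
#' @param breakdown A `pen_breakdown`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_breakdown_csv <- function(breakdown, path) {
  sh <- category_shares(breakdown)
  m <- as.data.frame(round(breakdown$cells, 2))
  m <- cbind(protocol = rownames(breakdown$cells),
             m,
             supply_share_pct = round(sh$within[, "supply"], 2),
             personnel_share_pct = round(sh$within[, "personnel"], 2),
             equipment_share_pct = round(sh$within[, "equipment"], 2))
  tot <- c(protocol = "Total",
           as.list(round(breakdown$column_totals, 2)),
           supply_share_pct = NA, personnel_share_pct = NA,
           equipment_share_pct = NA)
  shr <- c(protocol = "Category share (%)",
           as.list(round(sh$category, 2)),
           supply_share_pct = NA, personnel_share_pct = NA,
           equipment_share_pct = NA)
  out <- rbind(m, as.data.frame(tot), as.data.frame(shr))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
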