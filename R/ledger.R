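# Item-level cost ledger: reading, validation, currency conversion.
#
# A ledger is a data.frame with one row per expenditure item, held in its
# source currency until convert_ledger() stamps every row to USD. All
# downstream arithmetic is in USD.

ledger_columns <- function() {
  c("item_id", "name", "district", "level", "category", "kind",
    "protocols", "amount", "currency", "units_purchased", "unit_cost",
    "useful_life_years", "observed_over_months")
}

#' Read an item-level cost ledger from CSV
#'
#' Reads a UTF-8, comma-separated cost ledger with the schema
#' `item_id,name,district,level,category,kind,protocols,amount,currency,`
#' `units_purchased,unit_cost,useful_life_years,observed_over_months`.
#' The `protocols` field is a semicolon-joined list of protocol
#' identifiers or the literal `NONSPECIFIC`. When `amount` is missing but
#' `units_purchased` and `unit_cost` are both present, the amount is
#' filled as their product.
#'
#' @param path Path to the ledger CSV.
#' @param constants A [pen_constants()] object (schema-level checks only;
#'   no conversion happens here).
#' @return A data.frame of class `pen_ledger`, one row per cost item.
#' @seealso [validate_ledger()], [convert_ledger()]
#' @export
read_cost_ledger <- function(path, constants = pen_constants()) {
  if (!file.exists(path)) stop("ledger file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  missing_cols <- setdiff(ledger_columns(), names(x))
  if (length(missing_cols) > 0) {
    stop("ledger is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  x <- x[ledger_columns()]
  for (col in c("amount", "units_purchased", "unit_cost",
                "useful_life_years", "observed_over_months")) {
    x[[col]] <- suppressWarnings(as.numeric(x[[col]]))
  }
  as_pen_ledger(x)
}

#' Construct a ledger from a data.frame
#'
#' Validates schema-level constraints (known kinds, known protocol tags,
#' non-negative amounts, recognized level/category/currency values) and
#' stamps the `pen_ledger` class. Invariant-level checks that should be
#' collected rather than thrown live in [validate_ledger()].
#'
#' @param x A data.frame with the ledger columns (see
#'   [read_cost_ledger()]).
#' @return The same data, classed `pen_ledger`.
#' @export
as_pen_ledger <- function(x) {
  if (nrow(x) > 0) {
    if (is.na(nchar(paste(x$item_id, collapse = ""))))
      stop("item_id must be non-missing")
    bad_kind <- setdiff(unique(x$kind), pen_kinds())
    if (length(bad_kind) > 0) {
      stop("unknown item kind(s): ", paste(bad_kind, collapse = ", "))
    }
    bad_level <- setdiff(unique(x$level), c("national", "district"))
    if (length(bad_level) > 0) {
      stop("level must be 'national' or 'district', got: ",
           paste(bad_level, collapse = ", "))
    }
    bad_cat <- setdiff(unique(x$category), c("capital", "recurrent"))
    if (length(bad_cat) > 0) {
      stop("category must be 'capital' or 'recurrent', got: ",
           paste(bad_cat, collapse = ", "))
    }
    bad_cur <- setdiff(unique(x$currency), c("IRR", "USD"))
    if (length(bad_cur) > 0) {
      stop("currency must be 'IRR' or 'USD', got: ",
           paste(bad_cur, collapse = ", "))
    }
    tags <- unique(unlist(strsplit(x$protocols, ";", fixed = TRUE)))
    bad_tag <- setdiff(tags, c(pen_protocols(), "NONSPECIFIC"))
    if (length(bad_tag) > 0) {
      stop("unknown protocol tag(s): ", paste(bad_tag, collapse = ", "))
    }
    fill <- is.na(x$amount) & !is.na(x$units_purchased) & !is.na(x$unit_cost)
    x$amount[fill] <- x$units_purchased[fill] * x$unit_cost[fill]
    if (anyNA(x$amount)) stop("amount missing and not derivable for item(s): ",
                              paste(x$item_id[is.na(x$amount)], collapse = ", "))
    if (any(x$amount < 0)) {
      stop("negative amount for item(s): ",
           paste(x$item_id[x$amount < 0], collapse = ", "))
    }
  }
  class(x) <- c("pen_ledger", "data.frame")
  x
}

#' Write a cost ledger to CSV
#'
#' Inverse of [read_cost_ledger()]: a written ledger reads back
#' field-for-field identical (up to column order).
#'
#' @param ledger A `pen_ledger`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cost_ledger <- function(ledger, path) {
  utils::write.csv(as.data.frame(ledger)[ledger_columns()], path,
                   row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Validate a cost ledger
#'
#' Collects every item-level invariant breach into a validation report
#' rather than throwing: equipment items need a positive useful life and
#' a non-negative unit count; supply items need a positive observation
#' window; amounts must be non-negative and, where both a unit count and
#' a unit cost are given, agree with their product to within 0.5 currency
#' units. A duplicated `item_id` is a warning. The pipeline refuses to
#' run while the report carries errors.
#'
#' @param ledger A `pen_ledger`.
#' @return An object of class `pen_validation`: a list with data.frames
#'   `errors` and `warnings`, each with columns `item_id`, `message`.
#' @export
validate_ledger <- function(ledger) {
  err <- list(); wrn <- list()
  add_err <- function(id, msg) err[[length(err) + 1L]] <<-
    data.frame(item_id = id, message = msg)
  add_wrn <- function(id, msg) wrn[[length(wrn) + 1L]] <<-
    data.frame(item_id = id, message = msg)

  for (i in seq_len(nrow(ledger))) {
    it <- ledger[i, ]
    if (it$kind == "equipment") {
      if (is.na(it$useful_life_years) || it$useful_life_years <= 0)
        add_err(it$item_id, "equipment item requires useful_life_years > 0")
      if (!is.na(it$units_purchased) && it$units_purchased < 0)
        add_err(it$item_id, "units_purchased must be >= 0")
    }
    if (it$kind == "supply" &&
        (is.na(it$observed_over_months) || it$observed_over_months <= 0))
      add_err(it$item_id, "supply item requires observed_over_months > 0")
    if (is.na(it$amount) || it$amount < 0)
      add_err(it$item_id, "amount must be >= 0")
    if (!is.na(it$units_purchased) && !is.na(it$unit_cost) &&
        !is.na(it$amount) &&
        abs(it$amount - it$units_purchased * it$unit_cost) > 0.5)
      add_err(it$item_id,
              "amount differs from units_purchased * unit_cost by > 0.5")
    if (!nzchar(it$protocols))
      add_err(it$item_id, "protocols must be a tag list or NONSPECIFIC")
  }
  dup <- unique(ledger$item_id[duplicated(ledger$item_id)])
  for (d in dup) add_wrn(d, "duplicated item_id")

  empty <- data.frame(item_id = character(), message = character())
  out <- list(
    errors = if (length(err)) do.call(rbind, err) else empty,
    warnings = if (length(wrn)) do.call(rbind, wrn) else empty
  )
  class(out) <- "pen_validation"
  out
}

#' @export
print.pen_validation <- function(x, ...) {
  cat(sprintf("Ledger validation: %d error(s), %d warning(s)\n",
              nrow(x$errors), nrow(x$warnings)))
  if (nrow(x$errors)) print(x$errors, row.names = FALSE)
  if (nrow(x$warnings)) print(x$warnings, row.names = FALSE)
  invisible(x)
}

#' Convert an amount from rials to US dollars
#'
#' Division by the official exchange rate. Guarded by the currency tag so
#' a value is never converted twice.
#'
#' @param amount Amount in IRR (vectorized).
#' @param rate Exchange rate in IRR per USD (> 0).
#' @param currency Currency tag of `amount`; converting a value already
#'   tagged `"USD"` is an error.
#' @return Amount in USD.
#' @examples
#' convert_currency(36440, 36440) # 1
#' @export
convert_currency <- function(amount, rate, currency = "IRR") {
  if (!all(rate > 0)) stop("exchange rate must be > 0")
  if (any(currency == "USD")) {
    stop("value is already in USD; refusing to convert twice")
  }
  amount / rate
}

#' Convert every ledger row to US dollars
#'
#' Applies [convert_currency()] to the `amount` and `unit_cost` of each
#' IRR-tagged row and re-tags it `USD`; rows already in USD pass through
#' unchanged. Done once, immediately after reading, so that all
#' downstream arithmetic is in dollars.
#'
#' @param ledger A `pen_ledger`.
#' @param rate Exchange rate in IRR per USD.
#' @return The ledger with all rows tagged `USD`.
#' @export
convert_ledger <- function(ledger, rate) {
  irr <- ledger$currency == "IRR"
  ledger$amount[irr] <- convert_currency(ledger$amount[irr], rate)
  has_uc <- irr & !is.na(ledger$unit_cost)
  ledger$unit_cost[has_uc] <- convert_currency(ledger$unit_cost[has_uc], rate)
  ledger$currency[irr] <- "USD"
  ledger
}

# Split a semicolon-joined protocol tag into a character vector;
# NONSPECIFIC maps to character(0) with attribute handled by callers.
split_protocols <- function(tag) {
  if (identical(tag, "NONSPECIFIC")) return("NONSPECIFIC")
  strsplit(tag, ";", fixed = TRUE)[[1]]
}
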