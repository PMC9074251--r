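#' Construct a cost table for the recovery economics
#'
#' Investment line items are one-off amounts in million USD; utility line
#' items are annual amounts in million USD per year. The defaults for
#' payout time (5 years) and operating hours (8000 h/yr) are the usual
#' assumptions for continuous chemical plant evaluation.
#'
#' @param investment_items Named numeric vector, million USD.
#' @param utility_items Named numeric vector, million USD/yr.
#' @param payout_years Investment payout time in years (> 0).
#' @param hours_per_year Operating hours per year, in (0, 8784].
#' @return An object of class `cost_table`.
#' @export
cost_table <- function(investment_items = numeric(0),
                       utility_items = numeric(0),
                       payout_years = 5, hours_per_year = 8000) {
  investment_items <- unlist(investment_items)
  utility_items <- unlist(utility_items)
  if (any(investment_items < 0) || any(utility_items < 0))
    stop("cost amounts must be non-negative")
  if (payout_years <= 0) stop("payout_years must be positive")
  if (hours_per_year <= 0 || hours_per_year > 8784)
    stop("hours_per_year must lie in (0, 8784]")
  structure(list(investment_items = investment_items,
                 utility_items = utility_items,
                 payout_years = payout_years,
                 hours_per_year = hours_per_year),
            class = "cost_table")
}

#' @export
print.cost_table <- function(x, ...) {
  tot <- cost_totals(x)
  cat("Cost table (million USD):\n")
  cat(sprintf("  investment total: %.3f M$ (%d items)\n",
              tot$total_investment, length(x$investment_items)))
  cat(sprintf("  utilities total:  %.3f M$/yr (%d items)\n",
              tot$total_utility, length(x$utility_items)))
  cat(sprintf("  payout %g yr, %g h/yr\n", x$payout_years, x$hours_per_year))
  invisible(x)
}

#' Investment and utility totals
#'
#' @param table A [cost_table()].
#' @return List with `total_investment` (million USD) and `total_utility`
#'   (million USD/yr), the exact sums of the line items.
#' @export
cost_totals <- function(table) {
  stopifnot(inherits(table, "cost_table"))
  list(total_investment = sum(table$investment_items),
       total_utility = sum(table$utility_items))
}

#' Annualized unit recovery cost
#'
#' Straight-line annualization of the investment over the payout time plus
#' annual utilities, divided by the annual product mass:
#' \deqn{c = \frac{I/t_{payout} + U}{\dot m \cdot h_{yr}}}
#' with I and U in (million) USD and \eqn{\dot m} the product rate in
#' kg/h. An optional discount rate replaces the straight-line factor
#' \eqn{1/t} by the capital-recovery factor
#' \eqn{r / (1 - (1+r)^{-t})}.
#'
#' @param table A [cost_table()].
#' @param product_rate Product mass rate in kg/h (> 0).
#' @param discount_rate Optional annual interest rate (e.g. 0.08); default
#'   `NULL` (no discounting, plain payout-time annualization).
#' @return Unit cost in USD per kg of product. The value rounded to cents
#'   is attached as attribute `"cents"`.
#' @export
unit_recovery_cost <- function(table, product_rate, discount_rate = NULL) {
  stopifnot(inherits(table, "cost_table"))
  if (product_rate <= 0) stop("product_rate must be positive (kg/h)")
  tot <- cost_totals(table)
  annual_capital <- if (is.null(discount_rate)) {
    tot$total_investment / table$payout_years
  } else {
    r <- discount_rate
    tot$total_investment * r / (1 - (1 + r)^(-table$payout_years))
  }
  annual_usd <- (annual_capital + tot$total_utility) * 1e6
  cost <- annual_usd / (product_rate * table$hours_per_year)
  attr(cost, "cents") <- round(cost, 2)
  cost
}
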