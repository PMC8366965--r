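#' Discount factor for a real-dollar cash flow
#'
#' Deflates a cash flow occurring at the end of year `year` to year-0 present
#' value at a constant real annual discount rate: `(1 + rate)^(-year)`.
#'
#' @param rate Real annual discount rate as a fraction (e.g. `0.07`).
#'   Must exceed -1.
#' @param year Non-negative integer year index; year 0 is the construction
#'   date and is undiscounted. Vectorised.
#' @return Dimensionless discount factor(s) in `(0, 1]` for positive rates.
#' @examples
#' discount_factor(0.07, 10)
#' discount_factor(0.07, 0:5)
#' @export
discount_factor <- function(rate, year) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate > -1)
  if (!is.numeric(year) || any(year < 0) || any(year != floor(year))) {
    stop("`year` must contain non-negative integers", call. = FALSE)
  }
  (1 + rate)^(-year)
}

#' Annuity factor (present value of $1 per year)
#'
#' Present value of a level end-of-year stream of $1 per year for `n_years`
#' years at rate `rate`: `(1 - (1 + rate)^(-n)) / rate`. At `rate = 0` the
#' limiting value `n_years` is returned.
#'
#' @param rate Real annual discount rate as a fraction; non-negative.
#' @param n_years Positive integer number of years.
#' @return Dimensionless annuity factor.
#' @examples
#' annuity_factor(0.07, 50)
#' @export
annuity_factor <- function(rate, n_years) {
  stopifnot(is.numeric(rate), length(rate) == 1L, rate >= 0)
  stopifnot(is.numeric(n_years), length(n_years) == 1L,
            n_years >= 1, n_years == floor(n_years))
  if (rate == 0) return(as.numeric(n_years))
  (1 - (1 + rate)^(-n_years)) / rate
}

#' Recurring cash-flow event
#'
#' A fixed real-dollar amount falling due at each of a set of year indices,
#' e.g. a $3,000 desilting every ten years over a 50-year period.
#'
#' @param amount Non-negative real-dollar amount per occurrence.
#' @param years Strictly increasing positive integer year indices.
#' @param label Optional description.
#' @return An object of class `recurring_event`.
#' @examples
#' recurring_event(3000, seq(10, 50, by = 10), "desilting, poor dam")
#' @export
recurring_event <- function(amount, years, label = "") {
  stopifnot(is.numeric(amount), length(amount) == 1L, amount >= 0)
  stopifnot(is.numeric(years), all(years >= 1), all(years == floor(years)),
            !is.unsorted(years, strictly = TRUE))
  structure(list(amount = amount, years = as.integer(years), label = label),
            class = "recurring_event")
}

#' Present value of a recurring event stream
#'
#' Sums `amount * discount_factor(rate, year)` over the event's occurrence
#' years.
#'
#' @param event A [recurring_event()], or a numeric amount (in which case
#'   `years` must be supplied).
#' @param rate Real annual discount rate.
#' @param years Occurrence years when `event` is given as a bare amount.
#' @return Present value in the same (real) dollars as `amount`.
#' @examples
#' pv_recurring(recurring_event(3000, seq(10, 50, 10)), rate = 0.07)
#' pv_recurring(3000, rate = 0.07, years = c(20, 40, 60))
#' @export
pv_recurring <- function(event, rate, years = NULL) {
  if (!inherits(event, "recurring_event")) {
    if (is.null(years)) stop("supply `years` when `event` is an amount", call. = FALSE)
    event <- recurring_event(event, years)
  }
  if (length(event$years) == 0L) {
    warning("empty occurrence list; present value is 0")
    return(0)
  }
  sum(event$amount * discount_factor(rate, event$years))
}

#' Equivalent annual value of a present value
#'
#' The level end-of-year annual amount whose `n_years`-year annuity has
#' present value `pv`. Used to put cost streams with different cycle lengths
#' on a comparable per-year footing.
#'
#' @param pv Present value in real dollars.
#' @param rate Real annual discount rate.
#' @param n_years Annuitisation period in years.
#' @return Real dollars per year.
#' @examples
#' equivalent_annual_value(2997, 0.07, 50)
#' @export
equivalent_annual_value <- function(pv, rate, n_years) {
  pv / annuity_factor(rate, n_years)
}

#' Present value of a level annuity
#'
#' Inverse of [equivalent_annual_value()]: `annual_amount` received at the
#' end of each of `n_years` years, discounted at `rate`.
#'
#' @param annual_amount Real dollars per year.
#' @param rate Real annual discount rate.
#' @param n_years Number of years.
#' @return Present value in real dollars.
#' @examples
#' pv_of_annuity(144, 0.07, 50)
#' @export
pv_of_annuity <- function(annual_amount, rate, n_years) {
  annual_amount * annuity_factor(rate, n_years)
}

#' @export
print.recurring_event <- function(x, ...) {
  cat(sprintf("<recurring_event> $%.2f at years %s%s\n", x$amount,
              paste(x$years, collapse = ", "),
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  invisible(x)
}
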