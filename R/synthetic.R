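#' Generate a synthetic annual price history
#'
#' Emulates the kind of real-dollar annual liveweight price series the
#' return-volatility parameter was estimated from: a multiplicative random
#' walk with zero-mean normal log returns. The first year carries the
#' initial price exactly.
#'
#' @param n_years Series length (>= 2).
#' @param init Initial price, AUD/kg.
#' @param sigma Standard deviation of annual log returns (>= 0).
#' @param start_year First calendar year label.
#' @param seed Optional integer RNG seed.
#' @return A data frame with columns `year` and `price`, with the seed (if
#'   any) recorded in attribute `"seed"`.
#' @examples
#' generate_price_history(17, init = 3.03, sigma = 0.14, seed = 1)
#' @export
generate_price_history <- function(n_years, init = 3.03, sigma = 0.14,
                                   start_year = 2003, seed = NULL) {
  stopifnot(n_years >= 2, init > 0)
  if (!is.numeric(sigma) || sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- stats::rnorm(n_years - 1, 0, sigma)
  prices <- init * exp(cumsum(c(0, r)))
  structure(data.frame(year = seq(start_year, length.out = n_years),
                       price = prices),
            seed = seed)
}

#' Estimate the log-return standard deviation of a price series
#'
#' The volatility input of the price model: the standard deviation of the
#' first differences of log prices. The sample (n-1) denominator is the
#' default; the population (n) denominator is available since published
#' estimates do not always state the convention.
#'
#' @param history A data frame with a `price` column (as returned by
#'   [generate_price_history()]) or a numeric price vector.
#' @param denominator `"n-1"` (sample, default) or `"n"` (population).
#' @return Estimated standard deviation of annual log returns.
#' @examples
#' h <- generate_price_history(1000, sigma = 0.14, seed = 1)
#' estimate_log_return_sd(h)
#' @export
estimate_log_return_sd <- function(history, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  prices <- if (is.data.frame(history)) history$price else history
  stopifnot(is.numeric(prices), all(prices > 0))
  if (length(prices) < 3L) {
    stop("need at least 3 price observations to estimate a return sd",
         call. = FALSE)
  }
  r <- diff(log(prices))
  s <- stats::sd(r)
  if (denominator == "n") s <- s * sqrt((length(r) - 1) / length(r))
  s
}

#' Generate a synthetic farm population
#'
#' Emulates farm-level microdata that the published per-farm averages
#' summarise (the underlying survey records are not public): each synthetic
#' farm draws a survey year uniformly and scatters that year's averages
#' with multiplicative lognormal noise. A farm-level size factor is shared
#' across cattle sold, herd and area so that large farms are large in every
#' dimension and stocking rates stay near the survey values; a smaller
#' idiosyncratic component keeps the columns from being perfectly
#' proportional.
#'
#' @param region `"NSW"` or `"Victoria"`.
#' @param n_farms Number of synthetic farms (>= 1).
#' @param dispersion Relative standard deviation of the total multiplicative
#'   noise (>= 0); 0 reproduces the year averages exactly.
#' @param seed Optional integer RNG seed.
#' @param params A `dam_params` object.
#' @param years Financial years sampled.
#' @return A data frame with columns `farm`, `region`, `financial_year`,
#'   `cattle_sold`, `herd_size`, `area_ha`, `stocking_rate`, `n_dams`; the
#'   seed (if any) is recorded in attribute `"seed"`.
#' @examples
#' pop <- generate_farm_population("NSW", 100, dispersion = 0.2, seed = 1)
#' mean(pop$area_ha)
#' @export
generate_farm_population <- function(region, n_farms, dispersion = 0.2,
                                     seed = NULL, params = dam_params(),
                                     years = c("2015", "2016", "2017", "2018")) {
  stopifnot(n_farms >= 1, dispersion >= 0)
  region <- match_region(region, params)
  if (!is.null(seed)) set.seed(seed)
  scen <- sample_year_scenario(n_farms, region, params, years)

  # Shared size factor carries most of the variance (correlating herd, area
  # and sales); per-column factors add the rest. meanlog offsets keep every
  # noise term mean-1 so population means converge to the survey averages.
  shared_sd <- dispersion * sqrt(0.8)
  idio_sd <- dispersion * sqrt(0.2)
  lognoise <- function(sdlog, n) {
    if (sdlog == 0) rep(1, n) else stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  size <- lognoise(shared_sd, n_farms)
  sold <- scen$cattle_sold * size * lognoise(idio_sd, n_farms)
  herd <- scen$herd_size * size * lognoise(idio_sd, n_farms)
  area <- scen$area_ha * size * lognoise(idio_sd, n_farms)

  structure(data.frame(farm = seq_len(n_farms), region = region,
                       financial_year = scen$financial_year,
                       cattle_sold = sold, herd_size = herd, area_ha = area,
                       stocking_rate = herd / area,
                       n_dams = area / params$dams$ha_per_dam,
                       row.names = NULL),
            seed = seed)
}
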