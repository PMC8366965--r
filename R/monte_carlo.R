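#' Monte Carlo simulation configuration
#'
#' Collects every stochastic-model setting: replicate count, horizon, the
#' uniform weight-gain bounds, the price random-walk parameters, the year
#' scenarios sampled, and the RNG seed. Defaults come from the parameter
#' fixtures: 100,000 replicates, gain ~ Uniform(0, 0.23) persistent per
#' farm, log-return sd 0.14 from an initial Victorian price of $3.03/kg
#' (NSW = Victoria + $0.16), and the four financial years 2015-2018 equally
#' likely.
#'
#' @param params A `dam_params` object.
#' @param n_replicates Number of simulated farms.
#' @param seed Integer RNG seed, or `NULL` to use the session RNG state.
#' @param gain_bounds Length-2 numeric, uniform bounds on the persistent
#'   additional weight-gain fraction.
#' @param price_sigma Standard deviation of the zero-mean normal log real
#'   returns driving the price random walk.
#' @param price_init Initial Victorian price, AUD/kg.
#' @param nsw_price_offset Constant added to the Victorian price path to
#'   obtain the NSW path, AUD/kg.
#' @param horizon_years Simulation horizon.
#' @param scenario_years Character vector of financial-year labels sampled
#'   uniformly (jointly: cattle sold, herd and area all come from the drawn
#'   year). Use `"mean"` to pin every replicate to the mean farm.
#' @return An object of class `simulation_config`.
#' @examples
#' simulation_config(n_replicates = 1000, seed = 42)
#' @export
simulation_config <- function(params = dam_params(),
                              n_replicates = params$simulation$n_replicates,
                              seed = NULL,
                              gain_bounds = c(params$simulation$gain_lower,
                                              params$simulation$gain_upper),
                              price_sigma = params$simulation$price_sigma,
                              price_init = params$simulation$price_init_vic,
                              nsw_price_offset = params$simulation$nsw_price_offset,
                              horizon_years = params$discount$horizon_years,
                              scenario_years = c("2015", "2016", "2017", "2018")) {
  stopifnot(n_replicates >= 1, length(gain_bounds) == 2L,
            gain_bounds[1] <= gain_bounds[2], price_sigma >= 0,
            price_init > 0, horizon_years >= 1)
  structure(list(n_replicates = as.integer(n_replicates), seed = seed,
                 gain_bounds = as.numeric(gain_bounds),
                 price_sigma = price_sigma, price_init = price_init,
                 nsw_price_offset = nsw_price_offset,
                 horizon_years = as.integer(horizon_years),
                 scenario_years = as.character(scenario_years)),
            class = "simulation_config")
}

#' Draw persistent weight-gain fractions
#'
#' One uniform draw per simulated farm; the drawn gain persists for the
#' farm's whole simulated life, representing permanent idiosyncratic
#' differences between farms rather than year-to-year variability.
#'
#' @param n Number of draws.
#' @param bounds Length-2 numeric lower/upper bounds.
#' @return Numeric vector of gain fractions.
#' @export
draw_weight_gain <- function(n, bounds = c(0, 0.23)) {
  stopifnot(length(bounds) == 2L, bounds[1] <= bounds[2])
  if (bounds[1] == bounds[2]) return(rep(bounds[1], n))
  stats::runif(n, bounds[1], bounds[2])
}

#' Simulate lognormal random-walk price paths
#'
#' `Price_t = Price_(t-1) * exp(r_t)` with `r_t ~ Normal(0, sigma^2)`
#' independent across years and replicates. Zero-mean log returns make the
#' median path constant at the initial price while the mean path drifts up.
#'
#' @param n Number of paths.
#' @param init Initial price, AUD/kg (the year-0 price; the first simulated
#'   year already carries one return).
#' @param sigma Standard deviation of the log returns.
#' @param horizon Number of years.
#' @return A `horizon x n` numeric matrix of prices, one column per path.
#' @export
simulate_price_paths <- function(n, init, sigma, horizon) {
  stopifnot(init > 0, sigma >= 0, horizon >= 1, n >= 1)
  r <- matrix(stats::rnorm(n * horizon, mean = 0, sd = sigma), nrow = horizon)
  if (horizon > 1) {
    for (t in 2:horizon) r[t, ] <- r[t - 1, ] + r[t, ]
  }
  init * exp(r)
}

#' NSW price path from a Victorian path
#'
#' NSW prices track Victorian prices almost perfectly; the NSW path is the
#' Victorian path plus a constant per-kilogram offset, giving perfect
#' correlation by construction.
#'
#' @param vic_path Numeric vector or matrix of Victorian prices.
#' @param offset AUD/kg added elementwise.
#' @return Object of the same shape as `vic_path`.
#' @export
nsw_price_path <- function(vic_path, offset = 0.16) {
  stopifnot(is.numeric(vic_path), all(vic_path > 0))
  vic_path + offset
}

#' Sample year scenarios for simulated farms
#'
#' Each simulated farm draws one of the survey financial years uniformly,
#' and takes cattle sold, herd size and area operated jointly from that
#' year's row, preserving their correlation.
#'
#' @param n Number of draws.
#' @param region `"NSW"` or `"Victoria"`.
#' @param params A `dam_params` object.
#' @param years Financial-year labels to sample from (equally likely).
#' @return A data frame of `n` rows with columns `financial_year`,
#'   `cattle_sold`, `herd_size`, `area_ha`.
#' @export
sample_year_scenario <- function(n, region, params = dam_params(),
                                 years = c("2015", "2016", "2017", "2018")) {
  region <- match_region(region, params)
  stats <- params$farm_stats[params$farm_stats$region == region &
                             params$farm_stats$financial_year %in% years, ]
  if (nrow(stats) != length(years)) {
    stop("farm statistics missing for some of: ", paste(years, collapse = ", "),
         call. = FALSE)
  }
  idx <- if (nrow(stats) == 1L) rep(1L, n) else sample.int(nrow(stats), n, replace = TRUE)
  stats[idx, c("financial_year", "cattle_sold", "herd_size", "area_ha")]
}

#' Simulate per-farm outcomes
#'
#' Runs the full uncertainty model for one region and returns one row per
#' simulated farm. Per replicate: a persistent weight-gain fraction, a
#' jointly sampled year scenario, and a 50-year price path; the annual
#' weight-gain benefit `gain x base weight x price_t x cattle sold` is
#' discounted year by year, while the fertiliser and desilting savings and
#' the per-dam costs follow the deterministic constructions.
#'
#' RNG draw order (given the seed): all gain draws, then all scenario
#' draws, then the return matrix; identical seed and configuration give
#' bit-identical results.
#'
#' @param region `"NSW"` or `"Victoria"`.
#' @param config A [simulation_config()].
#' @param params A `dam_params` object.
#' @return A data frame with columns `replicate`, `gain`, `financial_year`,
#'   `cattle_sold`, `herd_size`, `area_ha`, `n_dams`, `pv_benefits`,
#'   `pv_costs`, `npv`, `bcr`.
#' @export
simulate_farms <- function(region, config = simulation_config(params),
                           params = dam_params()) {
  stopifnot(inherits(config, "simulation_config"))
  region <- match_region(region, params)
  if (!is.null(config$seed)) set.seed(config$seed)

  n <- config$n_replicates
  horizon <- config$horizon_years
  rate <- params$discount$rate

  gain <- draw_weight_gain(n, config$gain_bounds)
  scen <- sample_year_scenario(n, region, params, config$scenario_years)
  vic <- simulate_price_paths(n, config$price_init, config$price_sigma, horizon)
  price <- if (region == "NSW") nsw_price_path(vic, config$nsw_price_offset) else vic

  df <- discount_factor(rate, seq_len(horizon))
  pv_price <- colSums(price * df)  # discounted price-weighted annuity, per path

  n_dams <- scen$area_ha / params$dams$ha_per_dam
  pv_gain <- gain * params$benefits$base_sale_weight_kg * scen$cattle_sold * pv_price
  pv_fert <- scen$herd_size / 100 * params$benefits$fertiliser_per_100head_year *
    annuity_factor(rate, horizon)
  pv_desilt <- n_dams * desilt_saving_per_dam(params)
  benefits <- pv_gain + pv_fert + pv_desilt
  costs <- n_dams * per_dam_costs(params)$total

  data.frame(replicate = seq_len(n), gain = gain,
             financial_year = scen$financial_year,
             cattle_sold = scen$cattle_sold, herd_size = scen$herd_size,
             area_ha = scen$area_ha, n_dams = n_dams,
             pv_benefits = benefits, pv_costs = costs,
             npv = benefits - costs, bcr = benefits / costs,
             row.names = NULL)
}

#' Run the Monte Carlo simulation and summarise it
#'
#' Simulates `config$n_replicates` hypothetical farms and reports NPV and
#' BCR percentiles together with the probability that present-value
#' benefits exceed present-value costs.
#'
#' @inheritParams simulate_farms
#' @param percentiles Percentile levels to report (percent).
#' @return An object of class `simulation_summary`: `region`,
#'   `npv_percentiles`, `bcr_percentiles`, `prob_benefit_exceeds_cost`,
#'   `n_replicates`, `seed`, `config`, and the per-replicate data in
#'   `draws` (dropped when `keep_draws = FALSE`).
#' @param keep_draws Keep the per-replicate data frame in the result.
#' @examples
#' run_simulation("Victoria", simulation_config(n_replicates = 500, seed = 7))
#' @export
run_simulation <- function(region, config = simulation_config(params),
                           params = dam_params(),
                           percentiles = c(25, 50, 75), keep_draws = FALSE) {
  draws <- simulate_farms(region, config, params)
  probs <- percentiles / 100
  out <- list(region = match_region(region, params),
              npv_percentiles = stats::quantile(draws$npv, probs),
              bcr_percentiles = stats::quantile(draws$bcr, probs),
              prob_benefit_exceeds_cost = mean(draws$pv_benefits > draws$pv_costs),
              n_replicates = config$n_replicates,
              seed = config$seed,
              config = config)
  if (keep_draws) out$draws <- draws
  structure(out, class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("<simulation_summary> %s, %s replicates%s\n", x$region,
              format(x$n_replicates, big.mark = ","),
              if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")") else ""))
  cat("  NPV ($'000): ",
      paste(sprintf("%s=%.0f", names(x$npv_percentiles), x$npv_percentiles / 1000),
            collapse = "  "), "\n")
  cat("  BCR:         ",
      paste(sprintf("%s=%.2f", names(x$bcr_percentiles), x$bcr_percentiles),
            collapse = "  "), "\n")
  cat(sprintf("  P(benefits > costs): %.1f%%\n", 100 * x$prob_benefit_exceeds_cost))
  invisible(x)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0("<simulation_config> n=%s, horizon=%d yr, gain~U(%.2f, %.2f), ",
                     "price sd=%.2f from $%.2f (+$%.2f NSW), years {%s}\n"),
              format(x$n_replicates, big.mark = ","), x$horizon_years,
              x$gain_bounds[1], x$gain_bounds[2], x$price_sigma, x$price_init,
              x$nsw_price_offset, paste(x$scenario_years, collapse = ",")))
  invisible(x)
}
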