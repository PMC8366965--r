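#' Render a deterministic breakdown as a benefit-cost table
#'
#' One row per benefit and cost item with the published row labels, the
#' full-precision present value, and the value rounded to thousands as the
#' tables print it.
#'
#' @param x A `cba_breakdown` from [run_deterministic()].
#' @return A data frame with columns `item`, `pv` (AUD), `pv_000`
#'   (rounded $'000; the BCR row carries the ratio in both columns).
#' @examples
#' render_table3(run_deterministic("Victoria"))
#' @export
render_table3 <- function(x) {
  stopifnot(inherits(x, "cba_breakdown"))
  items <- c("Value of additional weight gain",
             "Fertiliser saving",
             "Saving due to reduced frequency of desilting dams",
             "Present Value ($2019) of benefits",
             "Construction of dam fence",
             "Construction of hardened watering point",
             "Planting vegetation",
             "Dam fence maintenance",
             "Hardened watering point maintenance",
             "Present Value ($2019) of costs",
             "Net Present Value ($2019)",
             "Benefit Cost Ratio")
  pv <- c(x$benefits$pv_weight_gain, x$benefits$pv_fertiliser,
          x$benefits$pv_desilt_saving, x$benefits$total,
          x$costs$pv_fence, x$costs$pv_watering, x$costs$pv_vegetation,
          x$costs$pv_fence_maint, x$costs$pv_watering_maint, x$costs$total,
          x$npv, x$bcr)
  pv_000 <- c(round(pv[1:11] / 1000), round(x$bcr, 1))
  data.frame(item = items, pv = pv, pv_000 = pv_000)
}

#' Render a simulation summary as a percentile table
#'
#' @param x A `simulation_summary` from [run_simulation()].
#' @return A data frame with columns `quantity`, `statistic`, `value`
#'   (full precision) and `printed` (NPVs in rounded $'000, BCRs to two
#'   decimals, the exceedance probability as a percentage).
#' @export
render_table4 <- function(x) {
  stopifnot(inherits(x, "simulation_summary"))
  npv <- x$npv_percentiles
  bcr <- x$bcr_percentiles
  data.frame(
    quantity = c(rep("Net Present Value ($000s)", length(npv)),
                 rep("Benefit Cost Ratio", length(bcr)),
                 "Probability Benefit > Costs"),
    statistic = c(names(npv), names(bcr), "probability"),
    value = c(unname(npv), unname(bcr), x$prob_benefit_exceeds_cost),
    printed = c(round(unname(npv) / 1000), round(unname(bcr), 2),
                round(100 * x$prob_benefit_exceeds_cost, 1)))
}

#' Break-even sensitivity report
#'
#' The break-even additional weight gain for a region, recomputed over a
#' grid of discount rates and price multipliers.
#'
#' @param region `"NSW"` or `"Victoria"`.
#' @param params A `dam_params` object.
#' @param rates Discount-rate grid.
#' @param price_factors Multipliers applied to the region's liveweight
#'   price.
#' @return A data frame with columns `region`, `rate`, `price_factor`,
#'   `price_per_kg`, `break_even_gain` (fraction) and `break_even_pct`
#'   (percent, one decimal).
#' @examples
#' break_even_report("NSW", rates = 0.07, price_factors = 1)
#' @export
break_even_report <- function(region, params = dam_params(),
                              rates = c(0.03, 0.07, 0.10),
                              price_factors = c(0.9, 1.0, 1.1)) {
  region <- match_region(region, params)
  base_price <- params$regions[[region]]$price_per_kg
  grid <- expand.grid(rate = rates, price_factor = price_factors)
  grid$region <- region
  grid$price_per_kg <- base_price * grid$price_factor
  grid$break_even_gain <- mapply(function(r, pf) {
    p <- dam_params(overrides = list(discount = list(rate = r)))
    p$regions[[region]]$price_per_kg <- base_price * pf
    break_even_gain(region, p)
  }, grid$rate, grid$price_factor)
  grid$break_even_pct <- round(100 * grid$break_even_gain, 1)
  grid[, c("region", "rate", "price_factor", "price_per_kg",
           "break_even_gain", "break_even_pct")]
}

#' Run manifest
#'
#' Snapshot of the command, resolved parameters, seed and software version
#' attached to every emitted report so a report can be reproduced from the
#' manifest alone.
#'
#' @param command Character description of the invocation.
#' @param params A `dam_params` object.
#' @param seed RNG seed used, or `NULL`.
#' @param extra Named list of additional resolved settings.
#' @return A named list.
#' @export
run_manifest <- function(command, params = dam_params(), seed = NULL,
                         extra = list()) {
  p <- unclass(params)
  p$weight_gain_studies <- NULL
  p$farm_stats <- NULL
  c(list(command = command,
         package = "damcba",
         version = as.character(utils::packageVersion("damcba")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         seed = seed),
    extra,
    list(parameters = p))
}

#' Write a report table as CSV and JSON
#'
#' The CSV holds the table; the JSON holds the same numbers plus the
#' manifest.
#'
#' @param table A data frame.
#' @param out Output path prefix; `<out>.csv` and `<out>.json` are written.
#' @param manifest A [run_manifest()] list.
#' @return Character vector of the two paths, invisibly.
#' @export
write_report <- function(table, out, manifest) {
  csv <- paste0(out, ".csv")
  js <- paste0(out, ".json")
  utils::write.csv(table, csv, row.names = FALSE)
  jsonlite::write_json(list(manifest = manifest, table = table), js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}

# --- command-line interface -------------------------------------------------

parse_cli_args <- function(args) {
  if (length(args) == 0L) return(list(command = NULL, opts = list()))
  command <- args[[1]]
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[[i + 1L]]
      i <- i + 2L
    }
  }
  list(command = command, opts = opts)
}

cli_params <- function(opts) {
  overrides <- list()
  if (!is.null(opts$rate)) overrides$discount$rate <- as.numeric(opts$rate)
  if (!is.null(opts$horizon)) overrides$discount$horizon_years <- as.integer(opts$horizon)
  if (!is.null(opts$gain)) overrides$benefits$weight_gain_fraction <- as.numeric(opts$gain)
  dam_params(path = opts$config, overrides = overrides)
}

#' Command-line entry point
#'
#' Subcommands: `deterministic` (per-farm benefit-cost table),
#' `simulate` (Monte Carlo percentile table), `breakeven` (break-even
#' sensitivity grid) and `fixtures` (dump the packaged input tables).
#' Shared flags: `--region nsw|vic`, `--out <prefix>`, `--config <yaml>`,
#' `--rate`, `--horizon`, `--gain`; `simulate` adds `--n` and `--seed`.
#' Designed to be wrapped by the installed `damcba` Rscript.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status: 0 success, 1 validation error, 2 runtime
#'   error.
#' @examples
#' out <- file.path(tempdir(), "det_nsw")
#' cli_main(c("deterministic", "--region", "nsw", "--out", out))
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parse_cli_args(args), error = function(e) e)
  if (inherits(parsed, "error")) {
    message("damcba: ", conditionMessage(parsed))
    return(1L)
  }
  cmd <- parsed$command
  opts <- parsed$opts
  known <- c("region", "out", "config", "rate", "horizon", "gain", "n", "seed",
             "replicates-out")
  if (is.null(cmd) || !cmd %in% c("deterministic", "simulate", "breakeven", "fixtures")) {
    message("usage: damcba {deterministic|simulate|breakeven|fixtures} [--flags]")
    return(1L)
  }
  if (length(bad <- setdiff(names(opts), known))) {
    message("damcba: unknown option(s) ", paste0("--", bad, collapse = ", "),
            "; valid: ", paste0("--", known, collapse = ", "))
    return(1L)
  }
  status <- tryCatch({
    params <- cli_params(opts)
    out <- opts$out %||% file.path(tempdir(), paste0("damcba_", cmd))
    if (cmd == "fixtures") {
      utils::write.csv(weight_gain_studies(),
                       paste0(out, "_weight_gain.csv"), row.names = FALSE)
      utils::write.csv(farm_year_stats(),
                       paste0(out, "_farm_stats.csv"), row.names = FALSE)
      message("damcba: fixtures written to ", out, "_*.csv")
      return(0L)
    }
    region <- match_region(opts$region %||% "NSW", params)
    manifest_extra <- list(region = region)
    if (cmd == "deterministic") {
      message("damcba: deterministic analysis, region ", region,
              ", rate ", params$discount$rate,
              ", horizon ", params$discount$horizon_years, " yr")
      tab <- render_table3(run_deterministic(region, params))
      write_report(tab, out, run_manifest(paste(c(cmd, args[-1]), collapse = " "),
                                          params, NULL, manifest_extra))
    } else if (cmd == "simulate") {
      n <- as.integer(opts$n %||% params$simulation$n_replicates)
      if (n > 5e7) stop("replicate cap exceeded (5e7)", call. = FALSE)
      seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
      cfg <- simulation_config(params, n_replicates = n, seed = seed)
      message("damcba: simulating ", n, " farms, region ", region,
              if (!is.null(seed)) paste0(", seed ", seed))
      sim <- run_simulation(region, cfg, params,
                            keep_draws = !is.null(opts[["replicates-out"]]))
      tab <- render_table4(sim)
      write_report(tab, out, run_manifest(paste(c(cmd, args[-1]), collapse = " "),
                                          params, seed, manifest_extra))
      if (!is.null(opts[["replicates-out"]])) {
        utils::write.csv(sim$draws, opts[["replicates-out"]], row.names = FALSE)
      }
    } else { # breakeven
      tab <- break_even_report(region, params)
      write_report(tab, out, run_manifest(paste(c(cmd, args[-1]), collapse = " "),
                                          params, NULL, manifest_extra))
    }
    message("damcba: wrote ", out, ".csv and ", out, ".json")
    0L
  }, error = function(e) {
    message("damcba: error: ", conditionMessage(e))
    validation <- grepl("unknown region|invalid parameter|parameter file|must",
                        conditionMessage(e))
    if (validation) 1L else 2L
  })
  status
}

`%||%` <- function(a, b) if (is.null(a)) b else a
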