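test_that("weight-gain draws follow the uniform study-range distribution", {
  set.seed(401)
  n <- 1e5
  g <- draw_weight_gain(n, c(0, 0.23))
  se_mean <- 0.23 / sqrt(12) / sqrt(n)
  expect_equal(mean(g), 0.115, tolerance = 3 * se_mean / 0.115)
  tail_p <- (0.23 - 0.065) / 0.23
  se_tail <- sqrt(tail_p * (1 - tail_p) / n)
  expect_equal(mean(g > 0.065), tail_p, tolerance = 3 * se_tail / tail_p)
  expect_true(all(g >= 0 & g <= 0.23))
  expect_identical(draw_weight_gain(5, c(0.11, 0.11)), rep(0.11, 5))
})

test_that("price paths have random-walk variance and zero-median log returns", {
  set.seed(402)
  paths <- simulate_price_paths(4000, init = 3.03, sigma = 0.14, horizon = 50)
  expect_equal(dim(paths), c(50, 4000))
  lr50 <- log(paths[50, ] / 3.03)
  expect_equal(sd(lr50), 0.14 * sqrt(50), tolerance = 0.05)
  expect_equal(median(paths[50, ]), 3.03, tolerance = 0.05)
  expect_true(all(paths > 0))
  flat <- simulate_price_paths(3, init = 3.03, sigma = 0, horizon = 10)
  expect_true(all(flat == 3.03))
})

test_that("the NSW path is the Victorian path plus a constant offset", {
  vic <- simulate_price_paths(2, init = 3.03, sigma = 0, horizon = 5)
  expect_true(all(nsw_price_path(vic) == 3.19))
  set.seed(403)
  v1 <- simulate_price_paths(1, 3.03, 0.14, 30)[, 1]
  n1 <- nsw_price_path(v1, 0.16)
  expect_equal(unique(round(n1 - v1, 12)), 0.16)
  expect_equal(cor(v1, n1), 1)
})

test_that("year scenarios are sampled jointly and uniformly", {
  set.seed(404)
  scen <- sample_year_scenario(2e4, "NSW", p)
  stats <- p$farm_stats[p$farm_stats$region == "NSW" &
                          p$farm_stats$financial_year != "mean", ]
  # joint sampling: every drawn row is one of the four published rows intact
  key <- paste(scen$cattle_sold, scen$herd_size, scen$area_ha)
  expect_true(all(key %in% paste(stats$cattle_sold, stats$herd_size, stats$area_ha)))
  r2016 <- scen[scen$financial_year == "2016", ][1, ]
  expect_equal(c(r2016$cattle_sold, r2016$herd_size, r2016$area_ha),
               c(222, 282, 1705))
  freq <- table(scen$financial_year) / nrow(scen)
  expect_true(all(abs(freq - 0.25) < 3 * sqrt(0.25 * 0.75 / nrow(scen))))
  single <- sample_year_scenario(50, "Victoria", p, years = "2017")
  expect_true(all(single$financial_year == "2017"))
})

test_that("a degenerate simulation collapses to the deterministic analysis", {
  for (region in c("NSW", "Victoria")) {
    cfg <- simulation_config(p, n_replicates = 8, seed = 405,
                             gain_bounds = c(0.11, 0.11), price_sigma = 0,
                             scenario_years = "mean")
    draws <- simulate_farms(region, cfg, p)
    det <- run_deterministic(region, p)
    expect_equal(draws$npv, rep(det$npv, 8), tolerance = 1e-10)
    expect_equal(draws$bcr, rep(det$bcr, 8), tolerance = 1e-10)
    expect_equal(draws$pv_benefits, rep(det$benefits$total, 8), tolerance = 1e-10)
  }
})

test_that("simulated NPV decomposes affinely in the gain fraction", {
  base_cfg <- function(g) simulation_config(p, n_replicates = 1, seed = 406,
                                            gain_bounds = c(g, g), price_sigma = 0,
                                            scenario_years = "mean")
  det <- run_deterministic("NSW", p)
  npv_at <- function(g) simulate_farms("NSW", base_cfg(g), p)$npv
  # gain 0: only the non-gain benefits remain
  expect_equal(npv_at(0),
               det$benefits$pv_fertiliser + det$benefits$pv_desilt_saving -
                 det$costs$total, tolerance = 1e-10)
  # gain 0.23: deterministic NPV plus the proportional weight-gain increment
  expect_equal(npv_at(0.23),
               det$npv + (0.23 - 0.11) / 0.11 * det$benefits$pv_weight_gain,
               tolerance = 1e-10)
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- simulation_config(p, n_replicates = 500, seed = 407)
  a <- run_simulation("NSW", cfg, p, keep_draws = TRUE)
  b <- run_simulation("NSW", cfg, p, keep_draws = TRUE)
  expect_identical(a$draws, b$draws)
  expect_identical(a$npv_percentiles, b$npv_percentiles)
  cfg2 <- simulation_config(p, n_replicates = 500, seed = 408)
  expect_false(identical(run_simulation("NSW", cfg2, p)$npv_percentiles,
                         a$npv_percentiles))
})

test_that("single-replicate summaries equal that farm at every percentile", {
  cfg <- simulation_config(p, n_replicates = 1, seed = 409)
  s <- run_simulation("Victoria", cfg, p, keep_draws = TRUE)
  expect_true(all(s$npv_percentiles == s$draws$npv))
  expect_true(all(s$bcr_percentiles == s$draws$bcr))
  expect_true(s$prob_benefit_exceeds_cost %in% c(0, 1))
})

test_that("BCR exceeds one exactly when NPV is positive, replicate by replicate", {
  cfg <- simulation_config(p, n_replicates = 5000, seed = 410)
  draws <- simulate_farms("NSW", cfg, p)
  expect_identical(draws$bcr > 1, draws$npv > 0)
})

test_that("exceedance probabilities sit in their analytic anchor bands", {
  # anchor: P(gain above scenario break-even) averaged over year scenarios,
  # perturbed only slightly by price noise
  for (region in c("NSW", "Victoria")) {
    cfg <- simulation_config(p, n_replicates = 2e4, seed = 411)
    prob <- run_simulation(region, cfg, p)$prob_benefit_exceeds_cost
    band <- if (region == "NSW") c(0.68, 0.74) else c(0.89, 0.93)
    expect_gt(prob, band[1])
    expect_lt(prob, band[2])
  }
})
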