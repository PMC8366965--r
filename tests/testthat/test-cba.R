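test_that("per-dam cost components agree with a finance-core oracle", {
  rate <- p$discount$rate
  pd <- per_dam_costs(p)
  expect_equal(pd$fence_capex, 5475)
  expect_equal(pd$watering_capex, 3048)
  expect_equal(pd$vegetation, 374.30)
  expect_equal(pd$fence_maint_pv, brute_pv(350, seq(10, 50, 10), rate))
  watering_oracle <- pv_of_annuity(
    equivalent_annual_value(brute_pv(500, seq(10, 60, 10), rate) +
                              brute_pv(400, seq(15, 60, 15), rate), rate, 60),
    rate, 50)
  expect_equal(pd$watering_maint_pv, watering_oracle)
  expect_equal(pd$total,
               5475 + 3048 + 374.30 + pd$fence_maint_pv + pd$watering_maint_pv)
  # a single-dam farm costs exactly the per-dam schedule (~ $9,967)
  one_dam <- farm_scenario("NSW", 10, 10, 40, p)
  expect_equal(farm_costs(one_dam, p)$total, pd$total)
  expect_equal(pd$total, 9967, tolerance = 1 / 9967)
})

test_that("benefit components reproduce their direct-product oracles", {
  a50 <- brute_annuity(p$discount$rate, 50)
  expect_equal(pv_fertiliser_saving(100, p), 1047 * a50)
  nsw <- mean_scenario("NSW", p)
  expect_equal(pv_weight_gain_benefit(nsw, p),
               0.11 * 400 * 3.19 * 217 * a50)
  expect_equal(pv_weight_gain_benefit(nsw, p, gain_fraction = 0), 0)
  expect_equal(pv_desilt_saving(0, p), 0)
  expect_equal(desilt_saving_per_dam(p), 1986, tolerance = 1 / 1986)
})

test_that("the per-farm table reproduces the published cells at printed rounding", {
  for (region in c("NSW", "Victoria")) {
    ours <- table3_cells(region)
    printed <- printed_table3[[region]]
    money <- setdiff(names(printed), "bcr")
    expect_true(all(abs(round(ours[money] / 1000) - printed[money]) <= 1),
                label = paste(region, "money cells within $1k of print"))
    expect_equal(unname(ours["bcr"]), unname(printed["bcr"]), tolerance = 0.05 / printed["bcr"])
  }
})

test_that("NPV and BCR satisfy their defining identities", {
  x <- run_deterministic("NSW", p)
  expect_equal(x$npv, x$benefits$total - x$costs$total)
  expect_equal(x$bcr, x$benefits$total / x$costs$total)
  expect_equal(x$benefits$total,
               x$benefits$pv_weight_gain + x$benefits$pv_fertiliser +
                 x$benefits$pv_desilt_saving)
  expect_true((x$bcr > 1) == (x$npv > 0))
  # all benefit channels switched off: NPV = -costs, BCR = 0
  zeroed <- dam_params(overrides = list(
    benefits = list(weight_gain_fraction = 0, fertiliser_per_100head_year = 1e-9),
    desilting = list(cost_per_event = 0)))
  z <- run_deterministic("NSW", zeroed)
  expect_equal(z$npv, -z$costs$total, tolerance = 1e-6)
  expect_equal(z$bcr, 0, tolerance = 1e-6)
})

test_that("benefits are affine in the gain fraction", {
  g <- c(0, 0.05, 0.11, 0.23)
  nsw <- mean_scenario("NSW", p)
  b <- vapply(g, function(gi) farm_benefits(nsw, p, gi)$total, numeric(1))
  slopes <- diff(b) / diff(g)
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-6)
  expect_equal(b[1], farm_benefits(nsw, p, 0.11)$total -
                 0.11 * slopes[1], tolerance = 1e-8)
})

test_that("NPV moves monotonically with prices, sales and per-dam costs", {
  base <- run_deterministic("NSW", p)
  dearer <- dam_params()
  dearer$regions$NSW$price_per_kg <- 3.50
  expect_gt(run_deterministic("NSW", dearer)$npv, base$npv)
  more_sold <- mean_scenario("NSW", p)
  more_sold$cattle_sold <- more_sold$cattle_sold + 50
  expect_gt(run_deterministic("NSW", p, scenario = more_sold)$npv, base$npv)
  pricier_fence <- dam_params(overrides = list(costs = list(fence_materials = 5000)))
  expect_lt(run_deterministic("NSW", pricier_fence)$npv, base$npv)
})

test_that("doubling area doubles costs and desilting but not herd-driven benefits", {
  s1 <- mean_scenario("NSW", p)
  s2 <- farm_scenario("NSW", s1$cattle_sold, s1$herd_size, 2 * s1$area_ha, p)
  x1 <- run_deterministic("NSW", p, scenario = s1)
  x2 <- run_deterministic("NSW", p, scenario = s2)
  expect_equal(x2$costs$total, 2 * x1$costs$total)
  expect_equal(x2$benefits$pv_desilt_saving, 2 * x1$benefits$pv_desilt_saving)
  expect_equal(x2$benefits$pv_weight_gain, x1$benefits$pv_weight_gain)
  expect_equal(x2$benefits$pv_fertiliser, x1$benefits$pv_fertiliser)
})

test_that("closed-form break-even agrees with a root-finding oracle and the print", {
  for (region in c("NSW", "Victoria")) {
    g_closed <- break_even_gain(region, p)
    npv_at <- function(g) run_deterministic(region, p, gain_fraction = g)$npv
    g_root <- stats::uniroot(npv_at, c(0, 0.5), tol = 1e-12)$root
    expect_equal(g_closed, g_root, tolerance = 1e-8)
    expect_lt(abs(npv_at(g_closed)), 1)  # plugging back in balances to < $1
  }
  expect_equal(100 * break_even_gain("NSW", p), 6.5, tolerance = 0.15 / 6.5)
  expect_equal(100 * break_even_gain("Victoria", p), 1.8, tolerance = 0.15 / 1.8)
  # costs fully covered by non-gain benefits: break-even is zero
  cheap <- dam_params(overrides = list(costs = list(
    fence_materials = 0, fence_labour = 0, watering_gravel = 0,
    watering_spreading = 0, watering_extra_fence = 0, watering_submersible = 0,
    vegetation_trees_shrubs = 0, vegetation_grasses = 0, vegetation_labour = 0,
    fence_maint = list(amount = 0, every_years = 10),
    watering_maint = list(list(amount = 0, every_years = 10),
                          list(amount = 0, every_years = 15)))))
  expect_message(g0 <- break_even_gain("Victoria", cheap), "0")
  expect_identical(g0, 0)
})

test_that("sector aggregation scales per-farm NPV by farm counts", {
  nsw <- sector_npv(run_deterministic("NSW", p)$npv, 492)
  vic <- sector_npv(run_deterministic("Victoria", p)$npv, 1889)
  expect_equal(nsw / 1e6, 85, tolerance = 2 / 85)
  expect_equal(vic / 1e6, 519, tolerance = 2 / 519)
  expect_equal((nsw + vic) / 1e6, 604, tolerance = 2 / 604)
  expect_error(sector_npv(1, 0))
})
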