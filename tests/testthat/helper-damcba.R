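# Shared fixtures: load the packaged defaults once per test file.
p <- dam_params()

# Independent brute-force present-value oracle: sum of year-by-year
# discount factors, no annuity algebra.
brute_pv <- function(amount, years, rate) {
  sum(amount / (1 + rate)^years)
}
brute_annuity <- function(rate, n) brute_pv(1, seq_len(n), rate)

# Printed per-farm benefit-cost table ($'000; BCR as ratio), used by the
# reproduction tests.
printed_table3 <- list(
  NSW = c(weight_gain = 420, fertiliser = 50, desilt = 74, benefits = 544,
          fence = 204, watering = 114, vegetation = 14, fence_maint = 13,
          watering_maint = 27, costs = 372, npv = 172, bcr = 1.5),
  Victoria = c(weight_gain = 326, fertiliser = 59, desilt = 28, benefits = 413,
               fence = 76, watering = 42, vegetation = 5, fence_maint = 5,
               watering_maint = 10, costs = 138, npv = 275, bcr = 3.0))

table3_cells <- function(region, params = p) {
  x <- run_deterministic(region, params)
  c(weight_gain = x$benefits$pv_weight_gain, fertiliser = x$benefits$pv_fertiliser,
    desilt = x$benefits$pv_desilt_saving, benefits = x$benefits$total,
    fence = x$costs$pv_fence, watering = x$costs$pv_watering,
    vegetation = x$costs$pv_vegetation, fence_maint = x$costs$pv_fence_maint,
    watering_maint = x$costs$pv_watering_maint, costs = x$costs$total,
    npv = x$npv, bcr = x$bcr)
}
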