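test_that("annual failure rates convert to per-cycle hazards exactly", {
  expect_equal(afr_to_cycle_hazard(0, 1), 0)
  h <- afr_to_cycle_hazard(0.05, 1)
  expect_equal((1 - h)^2, 0.95)
  expect_equal(h, 1 - sqrt(0.95))
  # a period of one cycle: the hazard is the cumulative failure itself
  expect_equal(afr_to_cycle_hazard(0.1, 0.5), 0.05)

  # identity (1 - h)^(2y) = 1 - a*y over random valid inputs
  set.seed(7)
  a <- runif(200, 0, 0.5)
  y <- runif(200, 0.1, 1.9)
  keep <- a * y < 1
  h <- afr_to_cycle_hazard(a[keep], y[keep])
  expect_lt(max(abs((1 - h)^(2 * y[keep]) - (1 - a[keep] * y[keep]))), 1e-12)

  expect_error(afr_to_cycle_hazard(0.6, 2), "100%")
  expect_error(afr_to_cycle_hazard(0.1, 0), "'y'")
})

test_that("default parameters reproduce the published fee schedule and probabilities", {
  p <- table1_pair$pulpotomy
  r <- table1_pair$root_canal
  expect_equal(p$cost_rct, 1109.31)
  expect_equal(p$cost_pulpotomy, 210.50)
  expect_equal(p$cost_direct_restoration, 294.82)
  expect_equal(p$cost_crown, 1095.76)
  expect_equal(p$cost_nsretx, 1246.06)
  expect_equal(p$cost_sretx, 961.87)
  expect_equal(p$cost_extraction, 189.83)
  expect_equal(c(p$p_success_y1, r$p_success_y1), c(0.96, 0.99))
  expect_equal(c(p$p_success_followup, r$p_success_followup), c(0.95, 0.97))
  expect_equal(c(p$p_complication_followup, r$p_complication_followup),
               c(0.05, 0.03))
  expect_equal(p$p_rct_after_failed_pulpotomy, 0.875)
  expect_equal(p$p_extraction_after_failed_pulpotomy, 0.125)
  expect_equal(c(p$p_nsretx_after_failed_rct, p$p_sretx_after_failed_rct,
                 p$p_extraction_after_failed_rct), c(0.1, 0.15, 0.75))
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$start_age, 18)

  expect_error(strategy_parameters("pulpotomy", p_success_y1 = 1.3), "\\[0, 1\\]")
  expect_error(strategy_parameters("pulpotomy", cost_crown = -5), ">= 0")
  expect_error(strategy_parameters("pulpotomy",
                                   p_rct_after_failed_pulpotomy = 0.8),
               "sum to 1")
  expect_error(strategy_parameters("root_canal",
                                   p_nsretx_after_failed_rct = 0.2),
               "sum to 1")
})

test_that("cycle 0 charges the initial intervention plus restoration and crown", {
  run_p <- run_cohort(build_dental_model(table1_pair$pulpotomy, LT), 0.03)
  expect_equal(run_p$trace$disc_cost[1], 210.50 + 294.82 + 1095.76)
  run_r <- run_cohort(build_dental_model(table1_pair$root_canal, LT), 0.03)
  expect_equal(run_r$trace$disc_cost[1], 1109.31 + 294.82 + 1095.76)
})

test_that("with no failures and no deaths the cohort stays healthy forever", {
  nofail <- dental_parameters(
    pulpotomy = list(p_success_y1 = 1, p_success_followup = 1,
                     p_complication_followup = 0),
    root_canal = list(p_success_y1 = 1, p_success_followup = 1,
                      p_complication_followup = 0))
  lt0 <- no_death_life_table()
  for (arm in names(nofail)) {
    m <- build_dental_model(nofail[[arm]], lt0)
    run <- run_cohort(m, discount_rate = 0.03)
    init <- if (arm == "pulpotomy") 210.50 else 1109.31
    expect_equal(run$result$cost, init + 294.82 + 1095.76)
    # discounted annuity of half-year retention credits over the horizon
    expect_equal(run$result$effect, annuity_sum(0.03, m$n_cycles))
  }
})

test_that("effect rises and cost falls as success probabilities improve", {
  eff_cost <- function(fu) {
    p <- strategy_parameters("pulpotomy", p_success_followup = fu,
                             p_complication_followup = 1 - fu)
    r <- run_cohort(build_dental_model(p, LT), 0.03)$result
    c(r$effect, r$cost)
  }
  lo <- eff_cost(0.90); mid <- eff_cost(0.95); hi <- eff_cost(0.99)
  expect_true(lo[1] < mid[1] && mid[1] < hi[1])
  expect_true(lo[2] >= mid[2] && mid[2] >= hi[2])
})

test_that("root canal treatment yields more retention than pulpotomy at base case", {
  bc <- run_base_case(table1_pair, LT)
  eff <- bc$results$effect[match(c("pulpotomy", "root_canal"),
                                 bc$results$strategy)]
  expect_gt(eff[2], eff[1])
  # and pulpotomy is the cheaper reference strategy
  expect_identical(bc$icer$strategy[1], "pulpotomy")
  expect_identical(bc$icer$status[1], "reference")
})

test_that("arms with identical hazards and extraction-only failure are symmetric", {
  pair <- dental_parameters(
    pulpotomy = list(p_success_y1 = 0.97, p_success_followup = 0.96,
                     p_complication_followup = 0.04,
                     p_rct_after_failed_pulpotomy = 0,
                     p_extraction_after_failed_pulpotomy = 1),
    root_canal = list(p_success_y1 = 0.97, p_success_followup = 0.96,
                      p_complication_followup = 0.04,
                      p_nsretx_after_failed_rct = 0,
                      p_sretx_after_failed_rct = 0,
                      p_extraction_after_failed_rct = 1))
  bc <- run_base_case(pair, LT)
  expect_equal(bc$results$effect[1], bc$results$effect[2], tolerance = 1e-9)
})

test_that("salvage restoration policy affects cost only, in the expected order", {
  eff_cost <- function(policy) {
    p <- strategy_parameters("pulpotomy", salvage_restoration = policy)
    r <- run_cohort(build_dental_model(p, LT), 0.03)$result
    c(r$effect, r$cost)
  }
  none <- eff_cost("none"); comp <- eff_cost("composite"); full <- eff_cost("full")
  expect_equal(none[1], comp[1])
  expect_equal(comp[1], full[1])
  expect_true(none[2] < comp[2] && comp[2] < full[2])
})

test_that("crediting all in-mouth states raises retention above healthy-only", {
  for (arm in names(table1_pair)) {
    e_h <- run_cohort(build_dental_model(table1_pair[[arm]], LT), 0.03)$result$effect
    e_m <- run_cohort(build_dental_model(table1_pair[[arm]], LT,
                                         effect_states = "tooth_in_mouth"),
                      0.03)$result$effect
    expect_gt(e_m, e_h)
  }
})
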