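test_that("discount factors follow (1+r)^(-k*cycle_length)", {
  expect_identical(discount_factor(0.03, 0, 0.5), 1)
  expect_equal(discount_factor(0.03, 2, 0.5), 1 / 1.03)
  expect_equal(discount_factor(0, 0:50, 0.5), rep(1, 51))
  expect_error(discount_factor(-0.01, 1, 0.5), ">= 0")
})

test_that("degenerate one-state cohort reproduces the closed-form annuity", {
  m <- annuity_model(cycle_cost = 10, horizon = 10)
  r0 <- run_cohort(m, discount_rate = 0)
  expect_equal(r0$result$effect, 10)
  expect_equal(r0$result$cost, 20 * 10)

  r3 <- run_cohort(m, discount_rate = 0.03)
  expect_equal(r3$result$effect, annuity_sum(0.03, 20))
  expect_equal(r3$result$cost, annuity_sum(0.03, 20, amount = 10))
})

test_that("occupancy traces conserve mass and stay within [0, 1]", {
  models <- c(lapply(c(101, 202, 303), random_small_model),
              lapply(table1_pair, build_dental_model, life_table = LT))
  for (m in models) {
    occ <- run_cohort(m, discount_rate = 0.03)$occupancy
    expect_lt(max(abs(rowSums(occ) - 1)), 1e-12)
    expect_true(all(occ >= 0 & occ <= 1 + 1e-12))
  }
})

test_that("invalid transition probabilities fail loudly, naming the state", {
  states <- list(health_state("a"), health_state("z", absorbing = TRUE))
  over <- cohort_model(states,
                       list(transition("a", "z", 0.7), transition("a", "a", 0.7)),
                       "a", start_age = 0, horizon_age = 2)
  expect_error(run_cohort(over), "sum to")
  expect_error(run_cohort(over), "'a'")

  neg_resid <- cohort_model(states,
                            list(transition("a", "z", 0.7),
                                 transition("a", "a", 0.6),
                                 transition("a", "z")),
                            "a", start_age = 0, horizon_age = 2)
  expect_error(run_cohort(neg_resid), "more than one residual|negative residual")

  expect_error(transition("a", "z", 1.2), "\\[0, 1\\]")
  fn_bad <- cohort_model(states,
                         list(transition("a", "z", function(cycle, age) 1.5),
                              transition("a", "a")),
                         "a", start_age = 0, horizon_age = 2)
  expect_error(run_cohort(fn_bad), "outside \\[0, 1\\]")
})

test_that("a transient state must have outgoing transitions at every cycle", {
  states <- list(health_state("a"), health_state("z", absorbing = TRUE))
  m <- cohort_model(states,
                    list(transition("a", "z", 0.5, from_cycle = 0, to_cycle = 0),
                         transition("a", "a", from_cycle = 0, to_cycle = 0)),
                    "a", start_age = 0, horizon_age = 2)
  expect_error(run_cohort(m), "no outgoing transitions at cycle 1")
})

test_that("higher discount rates shrink effect and never raise cost", {
  m <- build_dental_model(table1_pair$pulpotomy, LT)
  runs <- lapply(c(0, 0.03, 0.06), function(r) run_cohort(m, r)$result)
  effs <- vapply(runs, `[[`, 0, "effect")
  costs <- vapply(runs, `[[`, 0, "cost")
  expect_true(all(diff(effs) < 0))
  expect_true(all(diff(costs) <= 0))
})

test_that("effect accrual stops once the cohort is fully absorbed", {
  # certain failure each cycle: everyone reaches the tooth-less sink fast
  states <- list(health_state("on", tooth_present = TRUE),
                 health_state("off", absorbing = TRUE))
  m <- cohort_model(states, list(transition("on", "off", 1)),
                    "on", start_age = 0, horizon_age = 20)
  run <- run_cohort(m, discount_rate = 0)
  expect_equal(unname(run$occupancy[2, "off"]), 1)
  expect_true(all(run$trace$disc_effect[-1] == 0))
  expect_equal(run$result$effect, 0.5)
})

test_that("entry costs are charged to arriving mass at the arrival-cycle discount", {
  states <- list(health_state("a"),
                 health_state("b", absorbing = TRUE, entry_cost = 100))
  m <- cohort_model(states, list(transition("a", "b", 0.25),
                                 transition("a", "a")),
                    "a", start_age = 0, horizon_age = 1)
  run <- run_cohort(m, discount_rate = 0.04)
  # arrivals into b: 0.25 at cycle 1 (cycle-2 arrivals fall beyond the horizon)
  expect_equal(run$result$cost, 0.25 * 100 * 1.04^-0.5)
})

test_that("cycle-windowed rules reproduce the equivalent tunnel construction", {
  h1 <- 0.2; h2 <- 0.05
  windowed <- cohort_model(
    list(health_state("h", tooth_present = TRUE),
         health_state("f", absorbing = TRUE)),
    list(transition("h", "f", h1, from_cycle = 0, to_cycle = 1),
         transition("h", "f", h2, from_cycle = 2),
         transition("h", "h")),
    "h", start_age = 0, horizon_age = 15)
  tunnel <- cohort_model(
    list(health_state("y1a", tooth_present = TRUE),
         health_state("y1b", tooth_present = TRUE),
         health_state("fu", tooth_present = TRUE),
         health_state("f", absorbing = TRUE)),
    list(transition("y1a", "f", h1), transition("y1a", "y1b"),
         transition("y1b", "f", h1), transition("y1b", "fu"),
         transition("fu", "f", h2), transition("fu", "fu")),
    "y1a", start_age = 0, horizon_age = 15)
  rw <- run_cohort(windowed, 0.03)
  rt <- run_cohort(tunnel, 0.03)
  expect_equal(rw$result$effect, rt$result$effect, tolerance = 1e-12)
  expect_equal(rw$result$cost, rt$result$cost, tolerance = 1e-12)
})

test_that("half-cycle correction averages start- and end-of-cycle occupancy", {
  states <- list(health_state("on", tooth_present = TRUE),
                 health_state("off", absorbing = TRUE))
  m <- cohort_model(states, list(transition("on", "off", 0.5),
                                 transition("on", "on")),
                    "on", start_age = 0, horizon_age = 1)
  full <- run_cohort(m, 0)$result$effect      # 0.5*(1 + 0.5)
  half <- run_cohort(m, 0, half_cycle = TRUE)$result$effect
  expect_equal(full, 0.75)
  expect_equal(half, 0.5 * ((1 + 0.5) / 2 + (0.5 + 0.25) / 2))
  dm <- build_dental_model(table1_pair$root_canal, LT)
  expect_lt(run_cohort(dm, 0.03, half_cycle = TRUE)$result$effect,
            run_cohort(dm, 0.03)$result$effect)
})

test_that("microsimulation agrees with the cohort engine", {
  # deterministic chain: exact equality for any n
  chain <- cohort_model(
    list(health_state("a", tooth_present = TRUE, entry_cost = 10),
         health_state("b", cycle_cost = 5, entry_cost = 20),
         health_state("z", absorbing = TRUE, entry_cost = 30)),
    list(transition("a", "b", 1), transition("b", "z", 1)),
    "a", start_age = 0, horizon_age = 3)
  co <- run_cohort(chain, 0.03)$result
  ms <- run_microsim(chain, 0.03, n = 5, seed = 1)
  expect_equal(ms$result$cost, co$cost)
  expect_equal(ms$result$effect, co$effect)

  # degenerate absorbing start: identical for any n
  m1 <- annuity_model()
  expect_equal(run_microsim(m1, 0.03, n = 3, seed = 1)$result,
               run_cohort(m1, 0.03)$result)

  # stochastic models: within 3 standard errors at moderate n
  for (seed in c(101, 202)) {
    m <- random_small_model(seed)
    co <- run_cohort(m, 0.03)$result
    ms <- run_microsim(m, 0.03, n = 20000, seed = seed + 1)
    expect_lt(abs(ms$result$cost - co$cost), 3 * ms$se_cost + 1e-9)
    expect_lt(abs(ms$result$effect - co$effect), 3 * ms$se_effect + 1e-9)
  }
})

test_that("model assembly rejects inconsistent structures", {
  s <- list(health_state("a"), health_state("z", absorbing = TRUE))
  expect_error(cohort_model(s, list(transition("z", "a", 0.5)), "a",
                            start_age = 0, horizon_age = 1), "absorbing")
  expect_error(cohort_model(s, list(transition("a", "q", 0.5)), "a",
                            start_age = 0, horizon_age = 1), "undeclared")
  expect_error(cohort_model(s, list(), "missing", start_age = 0,
                            horizon_age = 1), "start_state")
  expect_error(cohort_model(s, list(), "a", start_age = 10, horizon_age = 5),
               "horizon_age")
  expect_error(health_state("a", cycle_cost = -1), ">= 0")
})
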