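# Shared fixtures, built in code.

# life table with constant annual death probability q (closes out at 110)
const_life_table <- function(q, max_age = 110) {
  life_table(0:max_age, c(rep(q, max_age), 1))
}

no_death_life_table <- function(max_age = 110) const_life_table(0, max_age)

# the calibrated synthetic background-mortality table used throughout
LT <- calibrate_gompertz(60.6, 18)$life_table

# single absorbing tooth-bearing state: the degenerate annuity model
annuity_model <- function(cycle_cost = 10, horizon = 10, start_age = 0) {
  cohort_model(
    states = list(health_state("alive", absorbing = TRUE,
                               tooth_present = TRUE, cycle_cost = cycle_cost)),
    transitions = list(),
    start_state = "alive", start_age = start_age,
    horizon_age = start_age + horizon)
}

# closed-form discounted annuity of half-year payments of size `amount`
annuity_sum <- function(rate, n_cycles, amount = 0.5) {
  sum(amount * (1 + rate)^(-0.5 * (0:(n_cycles - 1))))
}

# random small valid model: 3 transient states, 1 absorbing tooth-less sink,
# random outgoing probabilities with a residual self-loop
random_small_model <- function(seed, horizon = 6) {
  set.seed(seed)
  nm <- c("a", "b", "c", "sink")
  states <- list(
    health_state("a", tooth_present = TRUE, cycle_cost = runif(1, 0, 50),
                 entry_cost = runif(1, 0, 100)),
    health_state("b", tooth_present = runif(1) > 0.5,
                 cycle_cost = runif(1, 0, 50), entry_cost = runif(1, 0, 100)),
    health_state("c", tooth_present = runif(1) > 0.5,
                 cycle_cost = runif(1, 0, 50)),
    health_state("sink", absorbing = TRUE, entry_cost = runif(1, 0, 100))
  )
  rules <- list()
  for (s in nm[1:3]) {
    targets <- sample(setdiff(nm, s), 2)
    p <- runif(2, 0, 0.3)
    rules <- c(rules,
               list(transition(s, targets[1], p[1]),
                    transition(s, targets[2], p[2]),
                    transition(s, s)))  # residual self-loop
  }
  cohort_model(states, rules, start_state = "a", start_age = 0,
               horizon_age = horizon)
}

table1_pair <- dental_parameters()
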