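# Generic discrete-time Markov cohort engine: states, transition rules with
# cycle windows and a residual-complement convention, age-dependent background
# mortality as a competing risk, and discounted cost / tooth-life-year rewards.

#' Define a health state
#'
#' A health state carries its reward structure: a per-cycle cost while the
#' state is occupied, a one-time cost charged when cohort mass first arrives
#' in the state, and a flag saying whether the tooth is still in the mouth
#' (tooth-life-years accrue only while `tooth_present` states are occupied).
#'
#' @param name State identifier (non-empty string, unique within a model).
#' @param absorbing Logical; an absorbing state has no outgoing transitions
#'   other than staying put.
#' @param tooth_present Logical; does occupancy of this state accrue
#'   tooth-life-years?
#' @param cycle_cost Cost (USD) accrued per cycle of occupancy. Must be >= 0.
#' @param entry_cost One-time cost (USD) charged when mass enters the state
#'   (including initial occupancy at cycle 0). Must be >= 0.
#' @return An object of class `health_state`.
#' @examples
#' health_state("healthy", tooth_present = TRUE)
#' health_state("extracted", absorbing = TRUE, entry_cost = 189.83)
#' @export
health_state <- function(name, absorbing = FALSE, tooth_present = FALSE,
                         cycle_cost = 0, entry_cost = 0) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("'name' must be a non-empty string")
  if (!is.numeric(cycle_cost) || cycle_cost < 0)
    stop(sprintf("cycle_cost of state '%s' must be >= 0", name))
  if (!is.numeric(entry_cost) || entry_cost < 0)
    stop(sprintf("entry_cost of state '%s' must be >= 0", name))
  structure(list(name = name, absorbing = isTRUE(absorbing),
                 tooth_present = isTRUE(tooth_present),
                 cycle_cost = as.numeric(cycle_cost),
                 entry_cost = as.numeric(entry_cost)),
            class = "health_state")
}

#' Define a transition rule
#'
#' Each chance node declares explicit probabilities for all but (at most) one
#' outgoing edge; a rule created with `prob = NULL` is the *residual* edge and
#' receives one minus the sum of the other active edges from the same state
#' (the "#" convention of decision-tree software). A negative residual is a
#' hard error at resolution time.
#'
#' @param from,to State names.
#' @param prob Either `NULL` (residual edge), a single probability in
#'   \[0, 1\], or a function `f(cycle, age)` returning per-cycle
#'   probabilities (vectorised over its arguments).
#' @param from_cycle,to_cycle Cycle-index window (0-based, inclusive) in which
#'   the rule is active; defaults cover all cycles. Windows support
#'   first-year versus follow-up probability regimes.
#' @return An object of class `markov_transition`.
#' @examples
#' transition("healthy", "failed", 0.05)
#' transition("healthy", "healthy")  # residual self-loop
#' @export
transition <- function(from, to, prob = NULL, from_cycle = 0L, to_cycle = Inf) {
  if (!is.character(from) || !is.character(to))
    stop("'from' and 'to' must be state names")
  if (!is.null(prob) && !is.function(prob)) {
    if (!is.numeric(prob) || length(prob) != 1L || is.na(prob) ||
        prob < 0 || prob > 1)
      stop(sprintf("transition %s -> %s: 'prob' must be in [0, 1]", from, to))
  }
  if (from_cycle < 0 || to_cycle < from_cycle)
    stop(sprintf("transition %s -> %s: invalid cycle window", from, to))
  structure(list(from = from, to = to, prob = prob,
                 from_cycle = from_cycle, to_cycle = to_cycle),
            class = "markov_transition")
}

#' Assemble a Markov cohort model
#'
#' Background mortality is supplied as a per-cycle death probability function
#' of age and is applied first each cycle as a competing risk: the declared
#' tooth-level transition probabilities (which then sum to one per state) are
#' rescaled over the surviving fraction, keeping them interpretable as
#' conditional on surviving the cycle. Absorbing states are left untouched by
#' mortality (they carry no rewards in practice, so tracking vital status
#' inside them has no economic consequence).
#'
#' @param states List of [health_state()] objects (unique names).
#' @param transitions List of [transition()] rules between declared states.
#'   Absorbing states must not have outgoing rules.
#' @param start_state Name of the state holding the whole cohort at cycle 0.
#' @param start_age Age (years) of the cohort at cycle 0.
#' @param cycle_length Cycle length in years (default 0.5, i.e. 6 months).
#' @param horizon_age Age (years) at which the simulation stops.
#' @param death_prob Optional function `f(age)` returning the per-cycle death
#'   probability at a given age (vectorised). Requires `death_state`.
#' @param death_state Name of the absorbing state receiving background deaths.
#' @param name Strategy label attached to results.
#' @return An object of class `cohort_model`.
#' @seealso [run_cohort()], [run_microsim()]
#' @export
cohort_model <- function(states, transitions, start_state,
                         start_age = 18, cycle_length = 0.5,
                         horizon_age = 110,
                         death_prob = NULL, death_state = NULL,
                         name = "strategy") {
  if (!length(states) || !all(vapply(states, inherits, TRUE, "health_state")))
    stop("'states' must be a non-empty list of health_state objects")
  nm <- vapply(states, `[[`, "", "name")
  if (anyDuplicated(nm))
    stop(sprintf("duplicate state name '%s'", nm[duplicated(nm)][1]))
  st <- data.frame(
    name = nm,
    absorbing = vapply(states, `[[`, TRUE, "absorbing"),
    tooth_present = vapply(states, `[[`, TRUE, "tooth_present"),
    cycle_cost = vapply(states, `[[`, 0, "cycle_cost"),
    entry_cost = vapply(states, `[[`, 0, "entry_cost"),
    stringsAsFactors = FALSE
  )
  if (!all(vapply(transitions, inherits, TRUE, "markov_transition")))
    stop("'transitions' must be a list of transition() rules")
  tr_from <- vapply(transitions, `[[`, "", "from")
  tr_to <- vapply(transitions, `[[`, "", "to")
  unknown <- setdiff(c(tr_from, tr_to), nm)
  if (length(unknown))
    stop(sprintf("transition references undeclared state '%s'", unknown[1]))
  bad <- tr_from %in% nm[st$absorbing] & tr_from != tr_to
  if (any(bad))
    stop(sprintf("absorbing state '%s' cannot have outgoing transitions",
                 tr_from[bad][1]))
  if (!start_state %in% nm) stop(sprintf("start_state '%s' not declared", start_state))
  if (horizon_age <= start_age) stop("horizon_age must exceed start_age")
  if (cycle_length <= 0) stop("cycle_length must be positive")
  if (is.null(death_prob) != is.null(death_state))
    stop("'death_prob' and 'death_state' must be supplied together")
  if (!is.null(death_state)) {
    if (!death_state %in% nm) stop(sprintf("death_state '%s' not declared", death_state))
    if (!st$absorbing[match(death_state, nm)]) stop("death_state must be absorbing")
    if (!is.function(death_prob)) stop("'death_prob' must be a function of age")
  }
  structure(list(
    state_table = st,
    transitions = transitions,
    tr_from = match(tr_from, nm),
    tr_to = match(tr_to, nm),
    start_idx = match(start_state, nm),
    start_age = start_age,
    cycle_length = cycle_length,
    horizon_age = horizon_age,
    n_cycles = as.integer(ceiling((horizon_age - start_age) / cycle_length - 1e-9)),
    death_prob = death_prob,
    death_state_idx = if (is.null(death_state)) NULL else match(death_state, nm),
    name = name
  ), class = "cohort_model")
}

# Resolve every rule to realised per-cycle probabilities and return the
# n x n x K transition-probability array (row-stochastic at every cycle).
resolve_probabilities <- function(model) {
  st <- model$state_table
  n <- nrow(st)
  K <- model$n_cycles
  ages <- model$start_age + (0:(K - 1)) * model$cycle_length
  if (is.null(model$death_prob)) {
    d <- rep(0, K)
  } else {
    d <- model$death_prob(ages)
    if (length(d) == 1L) d <- rep(d, K)
    if (length(d) != K || anyNA(d) || any(d < 0 | d > 1))
      stop("death_prob must return per-cycle probabilities in [0, 1]")
  }
  m <- length(model$transitions)
  from <- model$tr_from
  to <- model$tr_to
  E <- matrix(0, K, max(m, 1L))
  act <- matrix(FALSE, K, max(m, 1L))
  S <- matrix(0, K, n)      # explicit outgoing probability sums
  nres <- matrix(0L, K, n)  # number of active residual rules
  cyc0 <- 0:(K - 1)
  for (j in seq_len(m)) {
    r <- model$transitions[[j]]
    w <- which(cyc0 >= r$from_cycle & cyc0 <= r$to_cycle)
    if (!length(w)) next
    act[w, j] <- TRUE
    if (is.null(r$prob)) {
      nres[w, from[j]] <- nres[w, from[j]] + 1L
      next
    }
    p <- if (is.function(r$prob)) {
      pv <- r$prob(cycle = cyc0[w], age = ages[w])
      if (length(pv) == 1L) rep(pv, length(w)) else pv
    } else {
      rep(r$prob, length(w))
    }
    if (length(p) != length(w) || anyNA(p) || any(p < 0 | p > 1)) {
      bad <- w[which(is.na(p) | p < 0 | p > 1)][1]
      stop(sprintf(
        "transition '%s' -> '%s': probability outside [0, 1] at cycle %d",
        st$name[from[j]], st$name[to[j]],
        if (is.na(bad)) -1L else bad - 1L))
    }
    E[w, j] <- p
    S[w, from[j]] <- S[w, from[j]] + p
  }
  if (any(nres > 1L)) {
    bad <- which(nres > 1L, arr.ind = TRUE)[1, ]
    stop(sprintf("state '%s' has more than one residual rule at cycle %d",
                 st$name[bad[2]], bad[1] - 1L))
  }
  for (j in seq_len(m)) {
    if (!is.null(model$transitions[[j]]$prob)) next
    w <- which(act[, j])
    resid <- 1 - S[w, from[j]]
    if (any(resid < -1e-9)) {
      bad <- w[which(resid < -1e-9)[1]]
      stop(sprintf(
        "negative residual probability (%.6g) for state '%s' at cycle %d",
        min(resid), st$name[from[j]], bad - 1L))
    }
    E[w, j] <- pmax(resid, 0)
  }
  for (s in seq_len(n)) {
    if (st$absorbing[s]) next
    own <- which(from == s)
    has_rule <- if (length(own)) rowSums(act[, own, drop = FALSE]) > 0 else rep(FALSE, K)
    none <- which(!has_rule)
    if (length(none))
      stop(sprintf("state '%s' has no outgoing transitions at cycle %d",
                   st$name[s], none[1] - 1L))
    check <- which(nres[, s] == 0L & abs(S[, s] - 1) > 1e-9)
    if (length(check))
      stop(sprintf(
        "outgoing probabilities from state '%s' sum to %.12g (not 1) at cycle %d",
        st$name[s], S[check[1], s], check[1] - 1L))
  }
  # competing-risk rescaling: death first, tooth-level transitions conditional
  # on surviving the cycle
  if (m) E <- E * (1 - d)
  P <- array(0, dim = c(n, n, K))
  for (j in seq_len(m)) {
    w <- which(act[, j])
    if (!length(w)) next
    idx <- cbind(from[j], to[j], w)
    P[idx] <- P[idx] + E[w, j]
  }
  ks <- seq_len(K)
  for (s in which(st$absorbing)) P[cbind(s, s, ks)] <- 1
  if (!is.null(model$death_state_idx)) {
    ds <- model$death_state_idx
    for (s in which(!st$absorbing)) {
      idx <- cbind(s, ds, ks)
      P[idx] <- P[idx] + d
    }
  }
  list(P = P, death = d, ages = ages)
}

#' Per-cycle discount factor
#'
#' @param rate Annual discount rate (fraction, >= 0).
#' @param cycle_index Cycle index (0-based); vectorised.
#' @param cycle_length Cycle length in years.
#' @return `(1 + rate)^(-(cycle_index * cycle_length))`.
#' @examples
#' discount_factor(0.03, 2, 0.5)  # one year out: 1 / 1.03
#' @export
discount_factor <- function(rate, cycle_index, cycle_length) {
  if (any(rate < 0)) stop("'rate' must be >= 0")
  (1 + rate)^(-(cycle_index * cycle_length))
}

#' Run the cohort simulation
#'
#' Propagates state-occupancy fractions cycle by cycle to the horizon and
#' accumulates discounted cost and discounted tooth-life-years. State
#' membership is evaluated at cycle start; rewards accrue for the full cycle
#' at the start-of-cycle discount factor (no half-cycle correction by
#' default). Entry costs are charged to arriving mass at the discount factor
#' of the arrival cycle.
#'
#' @param model A [cohort_model()].
#' @param discount_rate Annual discount rate applied to both cost and
#'   effectiveness (default 0.03).
#' @param half_cycle Logical; if `TRUE`, occupancy rewards (cycle costs and
#'   tooth-life-years, not entry costs) are computed on the average of the
#'   start- and end-of-cycle occupancy.
#' @return A list of class `cohort_run` with elements `trace` (data frame:
#'   cycle, age, one occupancy column per state, `disc_cost`, `disc_effect`),
#'   `result` (data frame: strategy, cost, effect) and `occupancy` (the full
#'   (K+1) x n occupancy matrix including the horizon row).
#' @examples
#' m <- cohort_model(
#'   states = list(health_state("alive", absorbing = TRUE,
#'                              tooth_present = TRUE, cycle_cost = 10)),
#'   transitions = list(), start_state = "alive",
#'   start_age = 0, horizon_age = 10)
#' run_cohort(m, discount_rate = 0)$result  # effect 10 years, cost 200
#' @export
run_cohort <- function(model, discount_rate = 0.03, half_cycle = FALSE) {
  if (!inherits(model, "cohort_model")) stop("'model' must be a cohort_model")
  if (discount_rate < 0) stop("'discount_rate' must be >= 0")
  rp <- resolve_probabilities(model)
  P <- rp$P
  st <- model$state_table
  n <- nrow(st)
  K <- model$n_cycles
  occ <- matrix(0, K + 1, n, dimnames = list(NULL, st$name))
  occ[1, model$start_idx] <- 1
  for (k in seq_len(K)) occ[k + 1, ] <- occ[k, ] %*% P[, , k]
  # per-cycle self-retention probabilities, for inflow accounting
  diag_idx <- cbind(rep(seq_len(n), K), rep(seq_len(n), K), rep(seq_len(K), each = n))
  Pdiag <- matrix(P[diag_idx], K, n, byrow = TRUE)
  inflow <- matrix(0, K, n)
  inflow[1, ] <- occ[1, ]
  if (K > 1)
    inflow[2:K, ] <- pmax(occ[2:K, , drop = FALSE] -
                            occ[1:(K - 1), , drop = FALSE] *
                            Pdiag[1:(K - 1), , drop = FALSE], 0)
  dfs <- discount_factor(discount_rate, 0:(K - 1), model$cycle_length)
  occ_rew <- occ[1:K, , drop = FALSE]
  if (half_cycle)
    occ_rew <- (occ_rew + occ[2:(K + 1), , drop = FALSE]) / 2
  cyc_cost <- drop(occ_rew %*% st$cycle_cost + inflow %*% st$entry_cost) * dfs
  cyc_eff <- model$cycle_length * drop(occ_rew %*% as.numeric(st$tooth_present)) * dfs
  trace <- data.frame(cycle = 0:(K - 1), age = rp$ages,
                      occ[1:K, , drop = FALSE],
                      disc_cost = cyc_cost, disc_effect = cyc_eff,
                      check.names = FALSE)
  result <- data.frame(strategy = model$name,
                       cost = sum(cyc_cost), effect = sum(cyc_eff),
                       stringsAsFactors = FALSE)
  structure(list(trace = trace, result = result, occupancy = occ),
            class = "cohort_run")
}

#' Individual-level microsimulation of the same model
#'
#' Samples individual trajectories through the transition structure resolved
#' exactly as in [run_cohort()] and returns mean discounted cost and effect
#' with their standard errors. Intended as an independent Monte Carlo
#' cross-check of the cohort recursion, not as a production path.
#'
#' @param model A [cohort_model()].
#' @param discount_rate Annual discount rate.
#' @param n Number of simulated individuals (>= 1).
#' @param seed Optional integer seed.
#' @return List with `result` (data frame: strategy, cost, effect — the
#'   sample means), `se_cost`, `se_effect`, `n`, and the per-individual
#'   vectors `cost` and `effect`.
#' @export
run_microsim <- function(model, discount_rate = 0.03, n = 1000L, seed = NULL) {
  if (!inherits(model, "cohort_model")) stop("'model' must be a cohort_model")
  if (n < 1) stop("'n' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rp <- resolve_probabilities(model)
  P <- rp$P
  st <- model$state_table
  ns <- nrow(st)
  K <- model$n_cycles
  cl <- model$cycle_length
  cum <- array(0, dim = dim(P))
  for (k in seq_len(K)) cum[, , k] <- t(apply(P[, , k, drop = FALSE], 1, cumsum))
  dfs <- discount_factor(discount_rate, 0:K, cl)
  tail_df <- rev(cumsum(rev(dfs[1:K])))  # tail_df[k] = sum of dfs for cycles k-1 .. K-1
  tooth <- as.numeric(st$tooth_present)
  ccost <- st$cycle_cost
  ecost <- st$entry_cost
  absorbing <- st$absorbing
  s0 <- model$start_idx
  cost <- rep(ecost[s0], n)
  eff <- numeric(n)
  state <- rep.int(s0, n)
  if (absorbing[s0]) {
    cost <- cost + ccost[s0] * tail_df[1]
    eff <- eff + cl * tooth[s0] * tail_df[1]
    active <- integer(0)
  } else {
    active <- seq_len(n)
  }
  for (k in seq_len(K)) {
    if (!length(active)) break
    stk <- state[active]
    cost[active] <- cost[active] + ccost[stk] * dfs[k]
    eff[active] <- eff[active] + cl * tooth[stk] * dfs[k]
    u <- runif(length(active))
    new <- integer(length(active))
    for (s in unique(stk)) {
      idx <- which(stk == s)
      new[idx] <- findInterval(u[idx], cum[s, , k]) + 1L
    }
    new[new > ns] <- ns  # u == 1 boundary guard
    if (k < K) {
      moved <- new != stk
      if (any(moved))
        cost[active[moved]] <- cost[active[moved]] +
          ecost[new[moved]] * dfs[k + 1]
      absd <- absorbing[new]
      if (any(absd)) {
        ia <- active[absd]
        sa <- new[absd]
        cost[ia] <- cost[ia] + ccost[sa] * tail_df[k + 1]
        eff[ia] <- eff[ia] + cl * tooth[sa] * tail_df[k + 1]
      }
      state[active] <- new
      active <- active[!absd]
    } else {
      state[active] <- new
    }
  }
  list(result = data.frame(strategy = model$name,
                           cost = mean(cost), effect = mean(eff),
                           stringsAsFactors = FALSE),
       se_cost = sd(cost) / sqrt(n),
       se_effect = sd(eff) / sqrt(n),
       n = n, cost = cost, effect = eff)
}

#' Write a cohort trace to CSV
#'
#' Columns: cycle, age, one occupancy column per state, `disc_cost`,
#' `disc_effect`.
#'
#' @param run A `cohort_run` object from [run_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(run, path) {
  if (!inherits(run, "cohort_run")) stop("'run' must be a cohort_run")
  write.csv(run$trace, path, row.names = FALSE)
  invisible(path)
}
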