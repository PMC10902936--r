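# Parameter-uncertainty analyses: Monte Carlo probabilistic sensitivity
# analysis (Gamma-distributed costs, Beta-distributed success probabilities,
# draws restricted to each distribution's own 5-95 percentile band) and
# deterministic one-way (tornado) sensitivity analysis.

#' Probabilistic sensitivity analysis specification
#'
#' @param iterations Number of Monte Carlo iterations (default 10,000).
#' @param seed Integer seed fixing the draw stream.
#' @param cost_sd_fraction Standard deviation of each sampled cost as a
#'   fraction of its mean (Gamma distributions; default 0.10).
#' @param prob_sd Absolute standard deviation of each sampled success
#'   probability (Beta distributions; default 0.02).
#' @param percentile_bounds Draws outside this percentile band of their own
#'   distribution are rejected and redrawn (default `c(0.05, 0.95)`).
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(iterations = 10000L, seed = 1L,
                     cost_sd_fraction = 0.10, prob_sd = 0.02,
                     percentile_bounds = c(0.05, 0.95)) {
  if (iterations < 1) stop("'iterations' must be >= 1")
  if (cost_sd_fraction < 0 || prob_sd < 0)
    stop("standard deviations must be >= 0")
  if (length(percentile_bounds) != 2L ||
      any(percentile_bounds <= 0) || any(percentile_bounds >= 1) ||
      percentile_bounds[1] >= percentile_bounds[2])
    stop("'percentile_bounds' must be ordered and inside (0, 1)")
  structure(list(iterations = as.integer(iterations), seed = seed,
                 cost_sd_fraction = cost_sd_fraction, prob_sd = prob_sd,
                 percentile_bounds = percentile_bounds),
            class = "psa_spec")
}

# rejection sampling against the distribution's own percentile band
rtrunc <- function(n, rfun, qfun, bounds) {
  lo <- qfun(bounds[1])
  hi <- qfun(bounds[2])
  x <- rfun(n)
  repeat {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) return(x)
    x[bad] <- rfun(length(bad))
  }
}

rtrunc_gamma <- function(n, mean, sd_fraction, bounds) {
  if (sd_fraction == 0 || mean == 0) return(rep(mean, n))
  shape <- 1 / sd_fraction^2          # moment matching: sd = sd_fraction * mean
  rate <- shape / mean
  rtrunc(n, function(k) rgamma(k, shape, rate),
         function(p) qgamma(p, shape, rate), bounds)
}

rtrunc_beta <- function(n, mean, sd, bounds, parameter = "probability") {
  if (sd == 0) return(rep(mean, n))
  nu <- mean * (1 - mean) / sd^2 - 1  # moment matching
  if (!is.finite(nu) || nu <= 0)
    stop(sprintf(
      "Beta moment matching infeasible for '%s' (mean %.4g, sd %.4g)",
      parameter, mean, sd))
  a <- mean * nu
  b <- (1 - mean) * nu
  rtrunc(n, function(k) rbeta(k, a, b),
         function(p) qbeta(p, a, b), bounds)
}

#' Sample perturbed parameter draws for the PSA
#'
#' Costs are drawn once per iteration from Gamma distributions (mean = base
#' value, SD = `cost_sd_fraction` times the mean) and shared between the two
#' arms, matching a common fee schedule. First-year and follow-up success
#' probabilities of each arm are drawn from moment-matched Beta distributions
#' (SD = `prob_sd`); follow-up complication probabilities are set to the
#' complement of the drawn success probability so each chance node still sums
#' to 1, and the secondary-RCT profile in the pulpotomy arm shares the root
#' canal arm's follow-up draw. All draws are restricted to the 5-95
#' percentile band of their own distribution by rejection sampling. Uses the
#' current RNG state; seed management belongs to the caller (see
#' [run_psa()]).
#'
#' @param base_pair Base-case parameters from [dental_parameters()].
#' @param spec A [psa_spec()].
#' @param n Number of draws (default `spec$iterations`).
#' @return Data frame of class `psa_draws`, one row per iteration.
#' @export
sample_parameters <- function(base_pair, spec, n = spec$iterations) {
  if (!inherits(spec, "psa_spec")) stop("'spec' must be a psa_spec")
  bp <- base_pair$pulpotomy
  br <- base_pair$root_canal
  b <- spec$percentile_bounds
  costs <- c("cost_rct", "cost_pulpotomy", "cost_direct_restoration",
             "cost_crown", "cost_nsretx", "cost_sretx", "cost_extraction")
  draws <- list()
  for (nm in costs)
    draws[[nm]] <- rtrunc_gamma(n, bp[[nm]], spec$cost_sd_fraction, b)
  draws$pulpotomy_p_success_y1 <-
    rtrunc_beta(n, bp$p_success_y1, spec$prob_sd, b, "pulpotomy p_success_y1")
  draws$pulpotomy_p_success_followup <-
    rtrunc_beta(n, bp$p_success_followup, spec$prob_sd, b,
                "pulpotomy p_success_followup")
  draws$root_canal_p_success_y1 <-
    rtrunc_beta(n, br$p_success_y1, spec$prob_sd, b, "root_canal p_success_y1")
  draws$root_canal_p_success_followup <-
    rtrunc_beta(n, br$p_success_followup, spec$prob_sd, b,
                "root_canal p_success_followup")
  out <- as.data.frame(draws)
  out <- cbind(iteration = seq_len(n), out)
  class(out) <- c("psa_draws", "data.frame")
  out
}

# materialise the parameter pair for one PSA iteration
apply_draw <- function(base_pair, draws, i) {
  d <- draws[i, ]
  shared <- list(cost_rct = d$cost_rct, cost_pulpotomy = d$cost_pulpotomy,
                 cost_direct_restoration = d$cost_direct_restoration,
                 cost_crown = d$cost_crown, cost_nsretx = d$cost_nsretx,
                 cost_sretx = d$cost_sretx, cost_extraction = d$cost_extraction)
  mod <- function(base, y1, fu, sec) {
    args <- utils::modifyList(unclass(base), c(shared, list(
      p_success_y1 = y1, p_success_followup = fu,
      p_complication_followup = 1 - fu,
      p_complication_secondary_rct = sec)))
    do.call(strategy_parameters, args)
  }
  list(
    pulpotomy = mod(base_pair$pulpotomy, d$pulpotomy_p_success_y1,
                    d$pulpotomy_p_success_followup,
                    1 - d$root_canal_p_success_followup),
    root_canal = mod(base_pair$root_canal, d$root_canal_p_success_y1,
                     d$root_canal_p_success_followup,
                     1 - d$root_canal_p_success_followup)
  )
}

#' Run the probabilistic sensitivity analysis
#'
#' One parameter draw per iteration is applied to both arms (costs paired
#' across arms), both cohort models are rebuilt and run, and the discounted
#' totals recorded. Fully reproducible given `spec$seed`.
#'
#' @param base_pair Base-case parameters from [dental_parameters()].
#' @param life_table A [life_table()].
#' @param spec A [psa_spec()].
#' @param horizon_age,half_cycle Passed to the cohort runs.
#' @return A list of class `psa_result`: `results` (data frame `iteration`,
#'   `strategy`, `cost`, `effect`), `incremental` (per-iteration `d_cost`,
#'   `d_effect`, root canal minus pulpotomy), `draws`, and `summary` with
#'   mean incremental cost/effect, the ICER of means, the mean of
#'   per-iteration ICERs, and central 95% intervals of the incremental cloud.
#' @export
run_psa <- function(base_pair, life_table, spec = psa_spec(),
                    horizon_age = 110, half_cycle = FALSE) {
  if (!inherits(spec, "psa_spec")) stop("'spec' must be a psa_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$iterations
  draws <- sample_parameters(base_pair, spec, n)
  cost <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("pulpotomy", "root_canal")))
  effect <- cost
  for (i in seq_len(n)) {
    pair <- tryCatch(apply_draw(base_pair, draws, i),
                     error = function(e)
                       stop(sprintf("PSA iteration %d: %s", i, conditionMessage(e))))
    for (arm in c("pulpotomy", "root_canal")) {
      r <- tryCatch(
        run_cohort(build_dental_model(pair[[arm]], life_table, horizon_age),
                   discount_rate = pair[[arm]]$discount_rate,
                   half_cycle = half_cycle),
        error = function(e)
          stop(sprintf("PSA iteration %d (%s): %s", i, arm, conditionMessage(e))))
      cost[i, arm] <- r$result$cost
      effect[i, arm] <- r$result$effect
    }
  }
  results <- data.frame(
    iteration = rep(seq_len(n), 2L),
    strategy = rep(c("pulpotomy", "root_canal"), each = n),
    cost = c(cost[, 1], cost[, 2]),
    effect = c(effect[, 1], effect[, 2]),
    stringsAsFactors = FALSE)
  inc <- data.frame(iteration = seq_len(n),
                    d_cost = cost[, 2] - cost[, 1],
                    d_effect = effect[, 2] - effect[, 1])
  ratio <- inc$d_cost / inc$d_effect
  summary <- list(
    mean_d_cost = mean(inc$d_cost),
    mean_d_effect = mean(inc$d_effect),
    icer_of_means = mean(inc$d_cost) / mean(inc$d_effect),
    mean_icer = mean(ratio[is.finite(ratio)]),
    ci_d_cost = quantile(inc$d_cost, c(0.025, 0.975), names = FALSE),
    ci_d_effect = quantile(inc$d_effect, c(0.025, 0.975), names = FALSE),
    prop_north_east = mean(inc$d_cost > 0 & inc$d_effect > 0))
  structure(list(results = results, incremental = inc, draws = draws,
                 summary = summary, spec = spec),
            class = "psa_result")
}

#' One-way (tornado) deterministic sensitivity analysis
#'
#' Each parameter is varied to its low and high value while all others stay
#' at base case; the base-case ICER (root canal treatment versus pulpotomy)
#' is recomputed at each end. By default the seven procedure costs and the
#' two follow-up complication probabilities are varied by +/-20% of their
#' base value (probabilities clipped to \[0, 1\]).
#'
#' @param base_pair Base-case parameters from [dental_parameters()].
#' @param life_table A [life_table()].
#' @param ranges Optional named list `list(parameter = c(low, high))`
#'   overriding the default ranges; names must be the cost fields or
#'   `p_complication_pulpotomy` / `p_complication_rct`.
#' @param range_fraction Half-width of the default relative range (0.2 =
#'   +/-20%).
#' @param horizon_age,half_cycle Passed to the cohort runs.
#' @return Data frame of class `tornado` sorted by descending ICER spread,
#'   with columns `parameter`, `low_value`, `high_value`, `icer_at_low`,
#'   `icer_at_high`, `spread`; the base-case ICER is in
#'   `attr(, "base_icer")`.
#' @export
tornado <- function(base_pair, life_table, ranges = NULL,
                    range_fraction = 0.2, horizon_age = 110,
                    half_cycle = FALSE) {
  costs <- c("cost_rct", "cost_pulpotomy", "cost_direct_restoration",
             "cost_crown", "cost_nsretx", "cost_sretx", "cost_extraction")
  pars <- c(costs, "p_complication_pulpotomy", "p_complication_rct")
  base_value <- function(nm) {
    switch(nm,
           p_complication_pulpotomy = base_pair$pulpotomy$p_complication_followup,
           p_complication_rct = base_pair$root_canal$p_complication_followup,
           base_pair$pulpotomy[[nm]])
  }
  default_range <- function(nm) {
    v <- base_value(nm)
    r <- c(v * (1 - range_fraction), v * (1 + range_fraction))
    if (startsWith(nm, "p_")) r <- pmin(pmax(r, 0), 1)
    r
  }
  if (is.null(ranges)) {
    ranges <- lapply(pars, default_range)
    names(ranges) <- pars
  } else {
    unknown <- setdiff(names(ranges), pars)
    if (length(unknown))
      stop(sprintf("unknown tornado parameter '%s'", unknown[1]))
  }
  set_param <- function(nm, value) {
    pp <- unclass(base_pair$pulpotomy)
    rr <- unclass(base_pair$root_canal)
    if (nm == "p_complication_pulpotomy") {
      pp$p_complication_followup <- value
      pp$p_success_followup <- 1 - value
    } else if (nm == "p_complication_rct") {
      rr$p_complication_followup <- value
      rr$p_success_followup <- 1 - value
      pp$p_complication_secondary_rct <- value
      rr$p_complication_secondary_rct <- value
    } else {
      pp[[nm]] <- value
      rr[[nm]] <- value
    }
    list(pulpotomy = do.call(strategy_parameters, pp),
         root_canal = do.call(strategy_parameters, rr))
  }
  icer_at <- function(pair) {
    bc <- run_base_case(pair, life_table, horizon_age, half_cycle)
    d_e <- diff(bc$results$effect[match(c("pulpotomy", "root_canal"),
                                        bc$results$strategy)])
    d_c <- diff(bc$results$cost[match(c("pulpotomy", "root_canal"),
                                      bc$results$strategy)])
    if (d_e == 0) Inf else d_c / d_e
  }
  rows <- lapply(names(ranges), function(nm) {
    r <- ranges[[nm]]
    v <- base_value(nm)
    if (r[1] > v + 1e-12 || r[2] < v - 1e-12)
      stop(sprintf("tornado range for '%s' must bracket the base value", nm))
    data.frame(parameter = nm, low_value = r[1], high_value = r[2],
               icer_at_low = icer_at(set_param(nm, r[1])),
               icer_at_high = icer_at(set_param(nm, r[2])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spread <- abs(out$icer_at_high - out$icer_at_low)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- icer_at(base_pair)
  class(out) <- c("tornado", "data.frame")
  out
}
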