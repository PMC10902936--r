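# The dental state-transition model: a mature permanent tooth with
# irreversible pulpitis in an 18-year-old, treated at time zero by either
# pulpotomy or root canal treatment (RCT), followed over the lifetime in
# 6-month cycles. Costs are ADA 2020 survey fees indexed by CDT code;
# effectiveness is tooth-life-years (years the tooth stays in the mouth).

#' Convert an annual failure rate to a per-6-month-cycle hazard
#'
#' A mean annual failure rate `a` reported over a follow-up period of `y`
#' years is spread uniformly over the 2y half-year cycles of that period,
#' assuming a constant hazard: `h = 1 - (1 - a * y)^(1 / (2 * y))`, so that
#' `(1 - h)^(2y) = 1 - a * y` exactly.
#'
#' @param a Mean annual failure rate (fraction per year); vectorised.
#' @param y Period length in years (> 0). `a * y` must be < 1.
#' @return Per-cycle failure probability.
#' @examples
#' afr_to_cycle_hazard(0.05, 1)   # 1 - 0.95^0.5
#' afr_to_cycle_hazard(0.1, 0.5)  # one-cycle period: h = a * y = 0.05
#' @export
afr_to_cycle_hazard <- function(a, y) {
  if (any(y <= 0)) stop("'y' must be > 0")
  if (any(a < 0)) stop("'a' must be >= 0")
  if (any(a * y >= 1))
    stop("a * y >= 1: cumulative failure over the period reaches 100%")
  1 - (1 - a * y)^(1 / (2 * y))
}

#' Parameters for one treatment arm
#'
#' Defaults are the base-case inputs: ADA 2020 fee-survey costs by CDT code
#' and literature-derived success/complication probabilities. Success
#' probabilities left `NULL` take the arm-specific defaults (pulpotomy:
#' 0.96 first year, 0.95 follow-up; root canal treatment: 0.99 first year,
#' 0.97 follow-up), with complication probabilities defaulting to their
#' complements (0.05 / 0.03).
#'
#' @param strategy `"pulpotomy"` or `"root_canal"` — the initial
#'   intervention of the arm.
#' @param cost_rct Root canal treatment fee, CDT D3330 (USD).
#' @param cost_pulpotomy Pulpotomy fee, CDT D3220 (USD).
#' @param cost_direct_restoration Direct composite restoration, CDT D2393 (USD).
#' @param cost_crown Porcelain-fused-to-metal crown, CDT D2751 (USD).
#' @param cost_nsretx Nonsurgical retreatment, CDT D3348 (USD).
#' @param cost_sretx Surgical retreatment, CDT D3425 (USD).
#' @param cost_extraction Extraction, CDT D7140 (USD).
#' @param cost_symptomatic_visit Per-cycle cost of symptomatic management in
#'   a diseased (failed-treatment) state; no fee is listed for it, so the
#'   default is 0 (configurable).
#' @param p_success_y1 First-year success probability of the arm's initial
#'   intervention.
#' @param p_success_followup Annual success probability in follow-up years.
#' @param p_complication_followup Annual complication probability in
#'   follow-up years (drives the follow-up failure hazard).
#' @param p_rct_after_failed_pulpotomy,p_extraction_after_failed_pulpotomy
#'   Branch probabilities after a failed pulpotomy (must sum to 1).
#' @param p_nsretx_after_failed_rct,p_sretx_after_failed_rct,p_extraction_after_failed_rct
#'   Branch probabilities after a failed root canal treatment (must sum to 1).
#' @param p_complication_secondary_rct Annual complication probability
#'   governing the secondary RCT placed after a failed pulpotomy and the
#'   post-retreatment states (the RCT follow-up profile).
#' @param salvage_restoration How the secondary RCT placed after a failed
#'   pulpotomy is restored: `"composite"` (default; the RCT is performed
#'   through the existing crown and the access cavity is sealed with a
#'   direct composite restoration, so D3330 + D2393 are charged),
#'   `"none"` (procedure fee only) or `"full"` (direct restoration plus a
#'   new crown are re-charged).
#' @param discount_rate Annual discount rate applied to cost and effect.
#' @param start_age Cohort age at treatment (years).
#' @return An object of class `strategy_parameters`.
#' @export
strategy_parameters <- function(strategy = c("pulpotomy", "root_canal"),
                                cost_rct = 1109.31,
                                cost_pulpotomy = 210.50,
                                cost_direct_restoration = 294.82,
                                cost_crown = 1095.76,
                                cost_nsretx = 1246.06,
                                cost_sretx = 961.87,
                                cost_extraction = 189.83,
                                cost_symptomatic_visit = 0,
                                p_success_y1 = NULL,
                                p_success_followup = NULL,
                                p_complication_followup = NULL,
                                p_rct_after_failed_pulpotomy = 0.875,
                                p_extraction_after_failed_pulpotomy = 0.125,
                                p_nsretx_after_failed_rct = 0.1,
                                p_sretx_after_failed_rct = 0.15,
                                p_extraction_after_failed_rct = 0.75,
                                p_complication_secondary_rct = 0.03,
                                salvage_restoration = c("composite", "none", "full"),
                                discount_rate = 0.03,
                                start_age = 18) {
  strategy <- match.arg(strategy)
  salvage_restoration <- match.arg(salvage_restoration)
  if (is.null(p_success_y1))
    p_success_y1 <- if (strategy == "pulpotomy") 0.96 else 0.99
  if (is.null(p_success_followup))
    p_success_followup <- if (strategy == "pulpotomy") 0.95 else 0.97
  if (is.null(p_complication_followup))
    p_complication_followup <- 1 - p_success_followup
  p <- list(strategy = strategy,
            cost_rct = cost_rct, cost_pulpotomy = cost_pulpotomy,
            cost_direct_restoration = cost_direct_restoration,
            cost_crown = cost_crown, cost_nsretx = cost_nsretx,
            cost_sretx = cost_sretx, cost_extraction = cost_extraction,
            cost_symptomatic_visit = cost_symptomatic_visit,
            p_success_y1 = p_success_y1,
            p_success_followup = p_success_followup,
            p_complication_followup = p_complication_followup,
            p_rct_after_failed_pulpotomy = p_rct_after_failed_pulpotomy,
            p_extraction_after_failed_pulpotomy = p_extraction_after_failed_pulpotomy,
            p_nsretx_after_failed_rct = p_nsretx_after_failed_rct,
            p_sretx_after_failed_rct = p_sretx_after_failed_rct,
            p_extraction_after_failed_rct = p_extraction_after_failed_rct,
            p_complication_secondary_rct = p_complication_secondary_rct,
            salvage_restoration = salvage_restoration,
            discount_rate = discount_rate, start_age = start_age)
  costs <- grep("^cost_", names(p), value = TRUE)
  for (nm in costs)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || p[[nm]] < 0)
      stop(sprintf("'%s' must be a single cost >= 0", nm))
  probs <- grep("^p_", names(p), value = TRUE)
  for (nm in probs)
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L ||
        is.na(p[[nm]]) || p[[nm]] < 0 || p[[nm]] > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", nm))
  if (abs(p$p_rct_after_failed_pulpotomy +
          p$p_extraction_after_failed_pulpotomy - 1) > 1e-9)
    stop("failed-pulpotomy branch probabilities must sum to 1")
  if (abs(p$p_nsretx_after_failed_rct + p$p_sretx_after_failed_rct +
          p$p_extraction_after_failed_rct - 1) > 1e-9)
    stop("failed-RCT branch probabilities must sum to 1")
  if (discount_rate < 0) stop("'discount_rate' must be >= 0")
  structure(p, class = "strategy_parameters")
}

#' Base-case parameters for both arms
#'
#' @param pulpotomy,root_canal Named lists of arm-specific overrides passed
#'   to [strategy_parameters()].
#' @param ... Shared overrides (costs, discount rate, start age) applied to
#'   both arms.
#' @return List with elements `pulpotomy` and `root_canal`.
#' @examples
#' pars <- dental_parameters()
#' pars$pulpotomy$p_success_y1
#' @export
dental_parameters <- function(pulpotomy = list(), root_canal = list(), ...) {
  shared <- list(...)
  list(
    pulpotomy = do.call(strategy_parameters,
                        c(list(strategy = "pulpotomy"), shared, pulpotomy)),
    root_canal = do.call(strategy_parameters,
                         c(list(strategy = "root_canal"), shared, root_canal))
  )
}

#' Build the cohort model for one treatment arm
#'
#' The cohort enters the first-year healthy state at cycle 0, when the
#' initial intervention (pulpotomy or RCT) plus direct restoration plus crown
#' is charged as an entry cost. The first year is a two-cycle tunnel with a
#' per-cycle hazard from the first-year failure rate `1 - p_success_y1`;
#' follow-up years use the complication rate. A failed state persists exactly
#' one cycle (accruing the symptomatic-visit cost) before the follow-up
#' treatment branch: a failed pulpotomy goes to a secondary (salvage) RCT —
#' restored per `salvage_restoration` and adopting the RCT follow-up hazard —
#' or to extraction; a failed RCT goes to nonsurgical retreatment, surgical
#' retreatment, or extraction. Failure after a retreatment leads to
#' extraction. Background mortality applies from every living state as a
#' competing risk.
#'
#' Effectiveness accrual: by default (`effect_states = "healthy"`) the
#' tooth-life-year reward is attached to the arm's healthy states only — the
#' first-year tunnel and the follow-up healthy state — so time spent in a
#' diseased (failed) state or under salvage treatment contributes cost but
#' no retention credit. `effect_states = "tooth_in_mouth"` instead credits
#' every cycle in which the tooth is physically present (all states except
#' extraction and death).
#'
#' @param params A [strategy_parameters()] object.
#' @param life_table A [life_table()] supplying background mortality.
#' @param horizon_age Age at which the simulation stops (default 110, by
#'   which the life table has closed out).
#' @param effect_states Which states accrue tooth-life-years: `"healthy"`
#'   (default) or `"tooth_in_mouth"`.
#' @return A [cohort_model()] ready for [run_cohort()].
#' @export
build_dental_model <- function(params, life_table, horizon_age = 110,
                               effect_states = c("healthy", "tooth_in_mouth")) {
  effect_states <- match.arg(effect_states)
  if (!inherits(params, "strategy_parameters"))
    stop("'params' must be strategy_parameters")
  if (!inherits(life_table, "life_table"))
    stop("'life_table' must be a life_table")
  h1 <- afr_to_cycle_hazard(1 - params$p_success_y1, 1)
  hf <- afr_to_cycle_hazard(params$p_complication_followup, 1)
  hs <- afr_to_cycle_hazard(params$p_complication_secondary_rct, 1)
  restoration <- params$cost_direct_restoration + params$cost_crown
  initial <- if (params$strategy == "pulpotomy")
    params$cost_pulpotomy + restoration else params$cost_rct + restoration
  salvage_cost <- params$cost_rct + switch(params$salvage_restoration,
    composite = params$cost_direct_restoration,
    none = 0,
    full = restoration)
  sym <- params$cost_symptomatic_visit
  inm <- effect_states == "tooth_in_mouth"  # credit non-healthy living states?

  common_states <- list(
    health_state("failed_rct", tooth_present = inm, cycle_cost = sym),
    health_state("post_nsretx", tooth_present = inm,
                 entry_cost = params$cost_nsretx),
    health_state("post_sretx", tooth_present = inm,
                 entry_cost = params$cost_sretx),
    health_state("extracted", absorbing = TRUE,
                 entry_cost = params$cost_extraction),
    health_state("dead", absorbing = TRUE)
  )
  # failed-RCT chance node; extraction is the residual ("#") edge
  post_hazard <- if (params$strategy == "pulpotomy") hs else hf
  common_rules <- list(
    transition("failed_rct", "post_nsretx", params$p_nsretx_after_failed_rct),
    transition("failed_rct", "post_sretx", params$p_sretx_after_failed_rct),
    transition("failed_rct", "extracted"),
    transition("post_nsretx", "extracted", post_hazard),
    transition("post_nsretx", "post_nsretx"),
    transition("post_sretx", "extracted", post_hazard),
    transition("post_sretx", "post_sretx")
  )

  if (params$strategy == "pulpotomy") {
    states <- c(list(
      health_state("healthy_y1a", tooth_present = TRUE, entry_cost = initial),
      health_state("healthy_y1b", tooth_present = TRUE),
      health_state("healthy_fu", tooth_present = TRUE),
      health_state("failed_pulpotomy", tooth_present = inm, cycle_cost = sym),
      health_state("secondary_rct", tooth_present = inm,
                   entry_cost = salvage_cost)
    ), common_states)
    rules <- c(list(
      transition("healthy_y1a", "failed_pulpotomy", h1),
      transition("healthy_y1a", "healthy_y1b"),
      transition("healthy_y1b", "failed_pulpotomy", h1),
      transition("healthy_y1b", "healthy_fu"),
      transition("healthy_fu", "failed_pulpotomy", hf),
      transition("healthy_fu", "healthy_fu"),
      transition("failed_pulpotomy", "secondary_rct",
                 params$p_rct_after_failed_pulpotomy),
      transition("failed_pulpotomy", "extracted"),
      transition("secondary_rct", "failed_rct", hs),
      transition("secondary_rct", "secondary_rct")
    ), common_rules)
  } else {
    states <- c(list(
      health_state("healthy_y1a", tooth_present = TRUE, entry_cost = initial),
      health_state("healthy_y1b", tooth_present = TRUE),
      health_state("healthy_fu", tooth_present = TRUE)
    ), common_states)
    rules <- c(list(
      transition("healthy_y1a", "failed_rct", h1),
      transition("healthy_y1a", "healthy_y1b"),
      transition("healthy_y1b", "failed_rct", h1),
      transition("healthy_y1b", "healthy_fu"),
      transition("healthy_fu", "failed_rct", hf),
      transition("healthy_fu", "healthy_fu")
    ), common_rules)
  }

  cohort_model(states, rules, start_state = "healthy_y1a",
               start_age = params$start_age, cycle_length = 0.5,
               horizon_age = horizon_age,
               death_prob = function(age) cycle_death_prob(life_table, age),
               death_state = "dead",
               name = params$strategy)
}

#' Run the base case for both arms
#'
#' Builds and runs both cohort models at the supplied parameters and returns
#' the discounted totals together with the incremental cost-effectiveness
#' ranking.
#'
#' @param params_pair List with `pulpotomy` and `root_canal`
#'   [strategy_parameters()] (see [dental_parameters()]).
#' @param life_table A [life_table()].
#' @param horizon_age Simulation stop age.
#' @param half_cycle Passed to [run_cohort()].
#' @param effect_states Passed to [build_dental_model()].
#' @return List with `runs` (named `cohort_run`s), `results` (two-row data
#'   frame: strategy, cost, effect) and `icer` (the [icer_ranking()] table).
#' @examples
#' \donttest{
#' lt <- calibrate_gompertz(60.6, 18)$life_table
#' bc <- run_base_case(dental_parameters(), lt)
#' bc$icer
#' }
#' @export
run_base_case <- function(params_pair, life_table, horizon_age = 110,
                          half_cycle = FALSE,
                          effect_states = c("healthy", "tooth_in_mouth")) {
  runs <- lapply(params_pair, function(p) {
    run_cohort(build_dental_model(p, life_table, horizon_age, effect_states),
               discount_rate = p$discount_rate, half_cycle = half_cycle)
  })
  results <- do.call(rbind, lapply(runs, `[[`, "result"))
  rownames(results) <- NULL
  list(runs = runs, results = results, icer = icer_ranking(results))
}
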