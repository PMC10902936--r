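# Incremental cost-effectiveness machinery: ICER ranking with strict and
# extended dominance, net monetary benefit, and cost-effectiveness
# acceptability curves from probabilistic sensitivity analysis output.

#' Incremental cost-effectiveness ranking
#'
#' Strategies are ordered by ascending cost. A strategy is *dominated* when
#' another is no more expensive and no less effective (with at least one
#' strict inequality); it is *extended dominated* when its ICER against the
#' previous non-dominated strategy exceeds that of the next more effective
#' option. ICERs are computed between successive non-dominated strategies.
#'
#' @param results Data frame with columns `strategy`, `cost`, `effect`
#'   (e.g. rbind of `run_cohort()` results). At least two rows; strategy
#'   names must be unique.
#' @return A data frame of class `icer_table` ordered by ascending cost with
#'   columns `strategy`, `cost`, `effect`, `incr_cost`, `incr_effect`,
#'   `icer` (USD per tooth-life-year; `Inf` when the incremental effect is
#'   zero) and `status` (`reference`, `nondominated`, `dominated`,
#'   `extended dominated`).
#' @examples
#' icer_ranking(data.frame(strategy = c("pulpotomy", "root_canal"),
#'                         cost = c(2469.38, 2780.59),
#'                         effect = c(15.07, 16.15)))
#' @export
icer_ranking <- function(results) {
  req <- c("strategy", "cost", "effect")
  if (!is.data.frame(results) || !all(req %in% names(results)))
    stop("'results' must be a data frame with strategy, cost, effect")
  if (nrow(results) < 2) stop("need at least two strategies")
  if (anyDuplicated(results$strategy))
    stop(sprintf("duplicate strategy name '%s'",
                 results$strategy[duplicated(results$strategy)][1]))
  df <- results[order(results$cost, results$effect, results$strategy), req]
  rownames(df) <- NULL
  n <- nrow(df)
  status <- rep("nondominated", n)
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    dom <- df$cost[others] <= df$cost[i] & df$effect[others] >= df$effect[i] &
      (df$cost[others] < df$cost[i] | df$effect[others] > df$effect[i])
    if (any(dom)) status[i] <- "dominated"
  }
  # extended dominance among the remaining strategies
  repeat {
    keep <- which(status == "nondominated")
    if (length(keep) < 3) break
    de <- diff(df$effect[keep])
    dc <- diff(df$cost[keep])
    icers <- ifelse(de == 0, Inf, dc / de)
    worse <- which(utils::head(icers, -1) > utils::tail(icers, -1))
    if (!length(worse)) break
    status[keep[worse[1] + 1]] <- "extended dominated"
  }
  keep <- which(status == "nondominated")
  df$incr_cost <- NA_real_
  df$incr_effect <- NA_real_
  df$icer <- NA_real_
  if (length(keep)) {
    status[keep[1]] <- "reference"
    if (length(keep) > 1) {
      prev <- keep[-length(keep)]
      cur <- keep[-1]
      df$incr_cost[cur] <- df$cost[cur] - df$cost[prev]
      df$incr_effect[cur] <- df$effect[cur] - df$effect[prev]
      df$icer[cur] <- ifelse(df$incr_effect[cur] == 0, Inf,
                             df$incr_cost[cur] / df$incr_effect[cur])
    }
  }
  df$status <- status
  class(df) <- c("icer_table", "data.frame")
  df
}

#' @export
print.icer_table <- function(x, ...) {
  y <- as.data.frame(x)
  for (nm in c("cost", "effect", "incr_cost", "incr_effect", "icer"))
    y[[nm]] <- round(y[[nm]], 2)
  print(y, ...)
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * effect - cost`. The strategy with the highest NMB at a given
#' willingness-to-pay is the cost-effective choice; for two strategies where
#' one costs more and yields more effect, the costlier one wins exactly when
#' `wtp` exceeds their ICER.
#'
#' @param cost Discounted cost (USD); vectorised.
#' @param effect Discounted effect (tooth-life-years); vectorised.
#' @param wtp Willingness-to-pay (USD per tooth-life-year, >= 0).
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(cost, effect, wtp) {
  if (any(wtp < 0)) stop("'wtp' must be >= 0")
  wtp * effect - cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that a strategy is
#' cost-effective is the fraction of (paired) PSA iterations in which its net
#' monetary benefit is strictly greatest. Exact NMB ties are awarded to the
#' strategy with the lower cost in that iteration (then alphabetically), so
#' probabilities across strategies sum to 1 at every grid point.
#'
#' @param psa_results Data frame with columns `iteration`, `strategy`,
#'   `cost`, `effect`: one row per strategy per iteration (equal iteration
#'   counts per strategy). Typically `run_psa()$results`.
#' @param wtp_grid Willingness-to-pay grid (USD per tooth-life-year);
#'   default 0 to 1000 in steps of 25.
#' @return Data frame of class `ceac_curve` with columns `wtp`, `strategy`,
#'   `probability`.
#' @export
ceac <- function(psa_results, wtp_grid = seq(0, 1000, by = 25)) {
  req <- c("iteration", "strategy", "cost", "effect")
  if (!is.data.frame(psa_results) || !all(req %in% names(psa_results)) ||
      !nrow(psa_results))
    stop("'psa_results' must be a non-empty data frame with iteration, strategy, cost, effect")
  strategies <- sort(unique(psa_results$strategy))
  S <- length(strategies)
  counts <- table(psa_results$strategy)
  if (length(unique(counts)) != 1L)
    stop("each strategy must have the same number of iterations")
  ord <- order(match(psa_results$strategy, strategies), psa_results$iteration)
  I <- as.integer(counts[1])
  C <- matrix(psa_results$cost[ord], I, S)
  E <- matrix(psa_results$effect[ord], I, S)
  out <- vector("list", length(wtp_grid))
  for (w in seq_along(wtp_grid)) {
    nmb <- net_monetary_benefit(C, E, wtp_grid[w])
    best <- rep(1L, I)
    bn <- nmb[, 1]
    bc <- C[, 1]
    if (S > 1) for (s in 2:S) {
      take <- nmb[, s] > bn | (nmb[, s] == bn & C[, s] < bc)
      best[take] <- s
      bn[take] <- nmb[take, s]
      bc[take] <- C[take, s]
    }
    out[[w]] <- data.frame(wtp = wtp_grid[w], strategy = strategies,
                           probability = tabulate(best, S) / I,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("ceac_curve", "data.frame")
  res
}
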