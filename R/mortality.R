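# Background mortality: annual life tables, conversion to 6-month-cycle death
# probabilities, remaining life expectancy, and a Gompertz-Makeham synthetic
# life table calibrated to a target remaining life expectancy (a stand-in for
# a national vital-statistics table, so the analysis runs self-contained).

#' Construct a life table
#'
#' @param age Contiguous ascending integer ages (e.g. 0:110).
#' @param qx Annual death probability per age, in \[0, 1\]; the final age must
#'   have `qx = 1` so the table closes out.
#' @return An object of class `life_table`.
#' @export
life_table <- function(age, qx) {
  if (length(age) != length(qx) || !length(age))
    stop("'age' and 'qx' must be non-empty vectors of equal length")
  if (any(age != round(age)) || any(diff(age) != 1))
    stop("'age' must be contiguous ascending integers")
  if (anyNA(qx) || any(qx < 0 | qx > 1))
    stop("'qx' must be probabilities in [0, 1]")
  if (qx[length(qx)] != 1)
    stop("the final age of a life table must have qx = 1")
  structure(list(age = as.integer(age), qx = as.numeric(qx)),
            class = "life_table")
}

# annual qx lookup by completed age; beyond the table -> certain death
qx_at <- function(table, age) {
  a <- floor(age)
  if (any(a < table$age[1]))
    stop(sprintf("age %g below life-table range", min(a)))
  idx <- a - table$age[1] + 1L
  out <- rep(1, length(a))
  inside <- idx <= length(table$qx)
  out[inside] <- table$qx[idx[inside]]
  out
}

#' Per-cycle (6-month) death probability at a given age
#'
#' Converts the annual probability `qx` at the completed age to a half-year
#' probability assuming a constant hazard within the year:
#' `1 - (1 - qx)^(1/2)`. Ages beyond the table end are treated as certain
#' death.
#'
#' @param table A [life_table()].
#' @param age Age in years (vectorised).
#' @return Per-cycle death probabilities.
#' @examples
#' lt <- life_table(0:1, c(0.01, 1))
#' cycle_death_prob(lt, 0)  # 1 - 0.99^0.5
#' @export
cycle_death_prob <- function(table, age) {
  if (!inherits(table, "life_table")) stop("'table' must be a life_table")
  1 - (1 - qx_at(table, age))^0.5
}

#' Remaining life expectancy at an exact age
#'
#' Computed in half-year steps as the sum over cycles of the probability of
#' surviving through that cycle, times the half-year interval:
#' `sum_k 0.5 * prod_{j<k} (1 - h_j)` with `h_j` the per-cycle death
#' probability. Under this convention an individual is credited only with
#' completed half-year intervals, so a table with `qx = 1` everywhere gives a
#' remaining life expectancy of exactly 0. Undiscounted.
#'
#' @param table A [life_table()].
#' @param age Exact age in years.
#' @return Remaining life expectancy in years.
#' @export
remaining_life_expectancy <- function(table, age) {
  if (!inherits(table, "life_table")) stop("'table' must be a life_table")
  max_age <- table$age[length(table$age)]
  K <- max(2L * (max_age + 1L - floor(age)), 1L)
  h <- cycle_death_prob(table, age + 0.5 * (0:(K - 1)))
  0.5 * sum(cumprod(1 - h))
}

#' Gompertz-Makeham life table
#'
#' Annual death probabilities from the hazard
#' `mu(x) = makeham + alpha * exp(beta * x)`:
#' `qx = 1 - exp(-integral of mu over [x, x + 1])`.
#'
#' @param alpha Baseline senescent hazard (per year, > 0).
#' @param beta Age slope (per year, > 0).
#' @param makeham Age-independent background hazard (per year, >= 0).
#' @param max_age Final table age; `qx` is forced to 1 there.
#' @return A [life_table()] over ages `0:max_age`.
#' @export
gompertz_life_table <- function(alpha, beta, makeham = 0, max_age = 110) {
  if (alpha <= 0 || beta <= 0 || makeham < 0)
    stop("require alpha > 0, beta > 0, makeham >= 0")
  x <- 0:max_age
  H <- makeham + (alpha / beta) * exp(beta * x) * expm1(beta)
  qx <- -expm1(-H)
  qx[length(qx)] <- 1
  life_table(x, qx)
}

#' Calibrate a synthetic life table to a target remaining life expectancy
#'
#' One-dimensional deterministic solve on the Gompertz baseline hazard
#' `alpha` (with `beta` and `makeham` held at documented defaults) so that
#' [remaining_life_expectancy()] at `at_age` hits `target_le`. Used to
#' emulate population background mortality when no vital-statistics table is
#' supplied.
#'
#' @param target_le Target remaining life expectancy (years) at `at_age`.
#' @param at_age Anchor age in years.
#' @param beta,makeham Fixed Gompertz-Makeham shape parameters. The default
#'   `beta` corresponds to an adult mortality doubling time of about 8 years.
#' @param max_age Final table age.
#' @param tol Maximum acceptable |achieved - target| in years.
#' @return List with `alpha`, `beta`, `makeham`, `achieved_le` and
#'   `life_table`.
#' @examples
#' cal <- calibrate_gompertz(60.6, 18)
#' remaining_life_expectancy(cal$life_table, 18)
#' @export
calibrate_gompertz <- function(target_le, at_age, beta = 0.087,
                               makeham = 5e-4, max_age = 110, tol = 0.05) {
  if (target_le <= 0 || target_le >= max_age - at_age)
    stop(sprintf("target_le must be in (0, %g)", max_age - at_age))
  f <- function(log_alpha) {
    lt <- gompertz_life_table(exp(log_alpha), beta, makeham, max_age)
    remaining_life_expectancy(lt, at_age) - target_le
  }
  lo <- log(1e-10); hi <- log(1)
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0)
    stop(sprintf(paste0(
      "calibration root not bracketed for target_le = %g at age %g ",
      "(residual %.3g at alpha = %.3g, %.3g at alpha = %.3g); ",
      "adjust beta or makeham"), target_le, at_age, flo, exp(lo), fhi, exp(hi)))
  root <- uniroot(f, c(lo, hi), tol = 1e-12)
  alpha <- exp(root$root)
  lt <- gompertz_life_table(alpha, beta, makeham, max_age)
  achieved <- remaining_life_expectancy(lt, at_age)
  if (abs(achieved - target_le) > tol)
    stop(sprintf("calibration achieved %.4f years (target %.4f, tol %.3g)",
                 achieved, target_le, tol))
  list(alpha = alpha, beta = beta, makeham = makeham,
       achieved_le = achieved, life_table = lt)
}

#' Read / write a life table as CSV
#'
#' Format: header `age,qx`, one row per integer age.
#'
#' @param path File path.
#' @return A [life_table()] (for the reader); `path` invisibly (writer).
#' @export
read_life_table <- function(path) {
  df <- read.csv(path)
  if (!all(c("age", "qx") %in% names(df)))
    stop("life-table CSV must have columns 'age' and 'qx'")
  life_table(df$age, df$qx)
}

#' @rdname read_life_table
#' @param table A [life_table()] to serialise.
#' @export
write_life_table <- function(table, path) {
  if (!inherits(table, "life_table")) stop("'table' must be a life_table")
  write.csv(data.frame(age = table$age, qx = table$qx), path, row.names = FALSE)
  invisible(path)
}
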