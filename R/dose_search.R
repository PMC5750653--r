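#' Titration dose grid
#'
#' The candidate doses (IU per kg of the chosen weight metric) scanned
#' during titration: a coarse 2 IU/kg step from 10 to 100 IU/kg, a
#' 10 IU/kg step from 100 to 210 IU/kg, refined to 0.1 IU/kg between 20
#' and 30 IU/kg where the optima of interest fall.
#'
#' @param coarse_range,coarse_step Lower segment (default 10-100 by 2).
#' @param wide_range,wide_step Upper segment (default 100-210 by 10).
#' @param fine_range,fine_step Refinement window (default 20-30 by 0.1);
#'   set `fine_step = NULL` to disable.
#' @return Sorted numeric vector of unique candidate doses.
#' @export
dose_grid <- function(coarse_range = c(10, 100), coarse_step = 2,
                      wide_range = c(100, 210), wide_step = 10,
                      fine_range = c(20, 30), fine_step = 0.1) {
  if (coarse_step <= 0 || wide_step <= 0 ||
      (!is.null(fine_step) && fine_step <= 0))
    stop("grid steps must be positive")
  if (coarse_range[2] != wide_range[1])
    stop("grid segments must be contiguous")
  g <- c(seq(coarse_range[1], coarse_range[2], by = coarse_step),
         seq(wide_range[1], wide_range[2], by = wide_step))
  if (!is.null(fine_step))
    g <- c(g, seq(fine_range[1], fine_range[2], by = fine_step))
  sort(unique(round(g, 8)))
}

# leftmost index of grid for which ok(grid[i]) is TRUE, assuming
# monotonicity of ok; NA if none
.bisect_leftmost <- function(grid, ok) {
  lo <- 1L
  hi <- length(grid)
  if (!ok(grid[hi])) return(NA_integer_)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (ok(grid[mid])) hi <- mid else lo <- mid + 1L
  }
  hi
}

.optimal_result <- function(schedule, metric, baseline, criterion, grid,
                            crit_doses, m, doses_per_week_base, base_dose = NULL) {
  safe_at <- function(d) mean(crit_doses <= d)
  new_result <- function(idx, ratios = NULL) {
    achieved <- !is.na(idx)
    dose <- if (achieved) grid[idx] else NA_real_
    cons <- if (!achieved) NA_real_
      else if (schedule == "mwf_friday")
        mean((2 * base_dose + dose) * m)
      else mean(doses_per_week_base * dose * m)
    structure(list(
      schedule = schedule, metric = metric, baseline = baseline,
      criterion = criterion, achieved = achieved,
      optimal_dose_per_kg = dose,
      safe_ratio_at_optimum = if (achieved) safe_at(dose) else safe_at(grid[length(grid)]),
      mean_weekly_consumption = cons,
      base_dose_per_kg = base_dose,
      curve = if (!is.null(ratios))
        data.frame(dose_per_kg = grid, safe_ratio = ratios),
      critical_doses = crit_doses, n = length(crit_doses)
    ), class = "optimal_dose")
  }
  list(scan = function() {
    ratios <- vapply(grid, safe_at, numeric(1))
    new_result(which(ratios >= criterion)[1], ratios)
  }, bisect = function() {
    new_result(.bisect_leftmost(grid, function(d) safe_at(d) >= criterion))
  })
}

#' Per-IU steady-state weekly trough of each subject
#'
#' The minimum, over the analysis week, of each subject's activity
#' response to a schedule of 1 IU boluses (IU/dL per IU administered).
#' By linearity the weekly trough of any dose D per administration is
#' baseline + D x unit trough, which makes dose titration a closed-form
#' per-subject computation; [find_optimal_dose()] accepts the result via
#' its `unit_trough` argument to avoid recomputing it across metrics.
#'
#' @param pk_params Per-subject PK parameters (data.frame with `cl`, `q`,
#'   `v1`, `v2`).
#' @param schedule `"q48h"` or `"mwf"` (uniform doses).
#' @param run_in_weeks,dt_h Simulation bookkeeping, as in
#'   [dosing_regimen()].
#' @return Numeric vector, one per subject: weekly trough per IU per
#'   administration.
#' @export
unit_trough <- function(pk_params, schedule = c("q48h", "mwf"),
                        run_in_weeks = 4, dt_h = 0.2) {
  schedule <- match.arg(schedule)
  .unit_weekly_trough(pk_params, schedule, run_in_weeks, dt_h)
}

.unit_weekly_trough <- function(pk_params, schedule, run_in_weeks, dt_h) {
  mac <- macro_constants(pk_params)
  times <- .analysis_times(run_in_weeks, dt_h)
  ev <- .schedule_times(schedule, run_in_weeks)
  S <- .unit_response(mac, if (schedule == "q48h") ev$all else c(ev$mw, ev$fri),
                      times)
  .col_mins(S)
}

#' Minimal dose meeting the population trough-safety criterion
#'
#' Titrates the per-kg dose of a weight metric over a grid and returns the
#' lowest dose at which at least `criterion` of the cohort keeps its
#' steady-state weekly trough at or above 1 IU/dL. Because trough levels
#' are exactly linear in dose, each subject has a closed-form critical
#' dose; the scan evaluates the exact safe ratio at every grid dose, and
#' an optional binary search (`method = "bisect"`) exploits monotonicity
#' and must return the same optimum.
#'
#' @param population Population data.frame; rows align with `pk_params`.
#' @param pk_params Per-subject PK parameters.
#' @param metric Weight metric dosed per kg of (`"TBW"`, `"LBW"`, `"IBW"`,
#'   `"ABW25"`, `"ABW40"`).
#' @param schedule `"q48h"` or `"mwf"` (for `"mwf"` the same per-kg dose
#'   is given at every administration, Friday included).
#' @param baseline Endogenous baseline, IU/dL.
#' @param grid Candidate doses from [dose_grid()].
#' @param criterion Required fraction of subjects with Cmin >= 1 IU/dL
#'   (default 0.95).
#' @param method `"scan"` (default; also returns the full safety curve)
#'   or `"bisect"`.
#' @param run_in_weeks,dt_h Simulation bookkeeping, as in
#'   [dosing_regimen()].
#' @param unit_trough Optional precomputed per-subject per-IU weekly
#'   trough from [unit_trough()] for the same subjects and schedule.
#' @return An object of class `optimal_dose`: `achieved` (logical;
#'   FALSE means the criterion is unreachable at the grid maximum and
#'   `optimal_dose_per_kg` is NA), `optimal_dose_per_kg`,
#'   `safe_ratio_at_optimum`, `mean_weekly_consumption` (IU/person/week),
#'   per-subject `critical_doses`, and for `method = "scan"` the
#'   dose-response `curve`.
#' @export
find_optimal_dose <- function(population, pk_params, metric = "TBW",
                              schedule = c("q48h", "mwf"), baseline = 0.5,
                              grid = dose_grid(), criterion = 0.95,
                              method = c("scan", "bisect"),
                              run_in_weeks = 4, dt_h = 0.2,
                              unit_trough = NULL) {
  schedule <- match.arg(schedule)
  method <- match.arg(method)
  metric <- match.arg(metric, names(.metric_column))
  if (criterion < 0 || criterion > 1) stop("'criterion' must be in [0, 1]")
  m <- .metric_values(population, metric)
  smin <- unit_trough %||%
    .unit_weekly_trough(pk_params, schedule, run_in_weeks, dt_h)
  if (length(smin) != length(m))
    stop("'unit_trough' must have one value per subject")
  # trough(d) = baseline + d * m * smin, so the subject is safe iff
  # d >= (1 - baseline) / (m * smin)
  crit_doses <- (1 - baseline) / (m * smin)
  dpw <- if (schedule == "q48h") 3.5 else 3
  .optimal_result(schedule, metric, baseline, criterion, grid, crit_doses,
                  m, dpw)[[method]]()
}

#' Minimal Friday dose on a Monday-Wednesday-Friday schedule
#'
#' With the Monday and Wednesday doses fixed (typically at the q48h
#' optimum for the metric), escalates the Friday dose until the required
#' fraction of the cohort keeps its weekly trough, including the 72 h
#' weekend gap, at or above 1 IU/dL. The per-subject critical Friday dose
#' is obtained in closed form from linearity of the profile in the Friday
#' amount.
#'
#' @inheritParams find_optimal_dose
#' @param base_dose_per_kg Monday/Wednesday dose, IU per kg of `metric`.
#' @return An `optimal_dose` object; `optimal_dose_per_kg` is the Friday
#'   dose and `base_dose_per_kg` records the fixed Monday/Wednesday dose.
#' @export
find_optimal_friday_dose <- function(population, pk_params, metric = "TBW",
                                     baseline = 0.5, base_dose_per_kg,
                                     grid = dose_grid(), criterion = 0.95,
                                     method = c("scan", "bisect"),
                                     run_in_weeks = 4, dt_h = 0.2) {
  method <- match.arg(method)
  metric <- match.arg(metric, names(.metric_column))
  stopifnot(base_dose_per_kg >= 0)
  m <- .metric_values(population, metric)
  mac <- macro_constants(pk_params)
  times <- .analysis_times(run_in_weeks, dt_h)
  ev <- .schedule_times("mwf", run_in_weeks)
  nt <- length(times)
  S_mw <- .unit_response(mac, ev$mw, times)
  S_fr <- .unit_response(mac, ev$fri, times)
  # level(t) = baseline + base_amt * S_mw + f * m * S_fr; safe iff for all t
  # f >= ((1 - baseline) - base_amt * S_mw) / (m * S_fr)
  deficit <- (1 - baseline) - S_mw * rep(base_dose_per_kg * m, each = nt)
  crit <- apply(deficit / (S_fr * rep(m, each = nt)), 2, max)
  crit <- pmax(crit, 0)
  .optimal_result("mwf_friday", metric, baseline, criterion, grid, crit,
                  m, NA, base_dose = base_dose_per_kg)[[method]]()
}

#' @export
print.optimal_dose <- function(x, ...) {
  what <- switch(x$schedule,
                 q48h = "q48h dose",
                 mwf = "mwf uniform dose",
                 mwf_friday = sprintf("Friday dose (Mon/Wed fixed at %g IU/kg)",
                                      x$base_dose_per_kg))
  cat(sprintf("Dose titration: %s per kg %s, baseline %g IU/dL, criterion %g\n",
              what, x$metric, x$baseline, x$criterion))
  if (x$achieved) {
    cat(sprintf("  optimal dose:      %.1f IU/kg (safe ratio %.3f, n = %d)\n",
                x$optimal_dose_per_kg, x$safe_ratio_at_optimum, x$n))
    cat(sprintf("  mean consumption:  %.0f IU/person/week\n",
                x$mean_weekly_consumption))
  } else {
    cat(sprintf("  criterion not achievable on the grid (safe ratio %.3f at grid maximum)\n",
                x$safe_ratio_at_optimum))
  }
  invisible(x)
}

#' Plot the safety-versus-dose curve of a titration
#'
#' @param x An `optimal_dose` fitted with `method = "scan"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.optimal_dose <- function(x, ...) {
  if (is.null(x$curve))
    stop("no safety curve stored; rerun with method = \"scan\"")
  graphics::plot(x$curve$dose_per_kg, 100 * x$curve$safe_ratio, type = "s",
                 xlab = sprintf("dose (IU per kg %s)", x$metric),
                 ylab = "subjects with Cmin >= 1 IU/dL (%)", ...)
  graphics::abline(h = 100 * x$criterion, lty = 2)
  if (x$achieved) graphics::abline(v = x$optimal_dose_per_kg, lty = 3)
  invisible(x)
}
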