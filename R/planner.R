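# Outcome surfaces over the (conversion %, capacity %) plane, level curves,
# and inverse planning: what capacity increase hits a target outcome.
#
# MC-mean objectives reuse one fixed draw set across all candidate
# strategies (common random numbers), so each objective is a smooth,
# strictly monotone function of the capacity fraction and root finding is
# well posed.

# evaluates (tc_days, deaths) for one strategy cell in either mode;
# draws is the CRN set (mc-mean mode only)
.cell_outcomes <- function(params, p, c, ratio, mode, draws) {
  Te <- total_surplus(params, strategy(capacity_increase = c,
                                       conversion_fraction = p,
                                       ratio = ratio,
                                       allow_above_cap = TRUE))
  if (Te <= 0) {
    # non-clearing cell: sentinel rather than an error, so grids render the
    # full domain; deaths marker is the one-year zero-surplus mortality
    return(c(tc = Inf,
             deaths = deaths_by_time(params$W0_mean, params$mu_mean, 1)))
  }
  if (identical(mode, "point")) {
    tc <- clearance_time(params$W0_mean, params$mu_mean, Te)
    c(tc = tc * params$days_per_year,
      deaths = deaths_at_clearance(params$W0_mean, Te, tc))
  } else {
    out <- .mc_outcomes(draws, Te, params$days_per_year)
    c(tc = mean(out$tc_days), deaths = mean(out$deaths))
  }
}

.planner_draws <- function(params, mode, n, seed, draws) {
  if (identical(mode, "point")) return(NULL)
  draws %||% draw_parameters(params, n = n, seed = seed)
}

#' Outcome grid over conversion and capacity fractions
#'
#' Evaluates clearance time and waiting-list deaths for every combination
#' of a conversion-fraction axis and a capacity-increase axis, either at
#' the point-estimate parameters (`mode = "point"`) or as Monte-Carlo means
#' under common random numbers (`mode = "mc-mean"`, the default
#' presentation for planning heatmaps). Cells with zero surplus (p = 0,
#' c = 0) carry `Inf` clearance time and the one-year zero-surplus death
#' count as a non-clearing marker.
#'
#' @inheritParams mc_summary
#' @param p_axis Conversion fractions (columns of the outcome matrices).
#' @param c_axis Capacity-increase fractions (rows).
#' @param ratio A [conversion_ratio()].
#' @param mode `"mc-mean"` or `"point"`.
#' @return An object of class `strategy_grid`: `p_axis`, `c_axis`,
#'   matrices `tc_days` and `deaths` (rows = `c_axis`, columns =
#'   `p_axis`), `mode`, `n`, `seed`. Use [as.data.frame()] for the long
#'   format (p, c, tc_days, deaths).
#' @examples
#' g <- compute_grid(population_params(), p_axis = c(0, 0.25, 0.5),
#'                   c_axis = c(0, 0.25, 0.5), mode = "point")
#' as.data.frame(g)
#' @export
compute_grid <- function(params, p_axis, c_axis,
                         ratio = conversion_ratio(),
                         mode = c("mc-mean", "point"),
                         n = 10000, seed = 20220616, draws = NULL) {
  stopifnot(inherits(params, "population_params"),
            inherits(ratio, "conversion_ratio"),
            is.numeric(p_axis), is.numeric(c_axis))
  mode <- match.arg(mode)
  if (any(p_axis < 0) || any(c_axis < 0))
    stop("axes must be nonnegative fractions", call. = FALSE)
  draws <- .planner_draws(params, mode, n, seed, draws)
  tc <- deaths <- matrix(NA_real_, nrow = length(c_axis),
                         ncol = length(p_axis),
                         dimnames = list(format(c_axis), format(p_axis)))
  for (i in seq_along(c_axis)) {
    for (j in seq_along(p_axis)) {
      o <- .cell_outcomes(params, p_axis[j], c_axis[i], ratio, mode, draws)
      tc[i, j] <- o[["tc"]]
      deaths[i, j] <- o[["deaths"]]
    }
  }
  structure(list(p_axis = p_axis, c_axis = c_axis,
                 tc_days = tc, deaths = deaths, mode = mode,
                 n = if (mode == "mc-mean") nrow(draws) else NA_integer_,
                 seed = if (mode == "mc-mean") seed else NA_integer_),
            class = "strategy_grid")
}

#' @export
as.data.frame.strategy_grid <- function(x, ...) {
  idx <- expand.grid(ci = seq_along(x$c_axis), pj = seq_along(x$p_axis))
  data.frame(p = x$p_axis[idx$pj], c = x$c_axis[idx$ci],
             tc_days = x$tc_days[cbind(idx$ci, idx$pj)],
             deaths = x$deaths[cbind(idx$ci, idx$pj)])
}

#' @export
print.strategy_grid <- function(x, ...) {
  cat(sprintf("Strategy grid (%s mode): %d conversion x %d capacity cells\n",
              x$mode, length(x$p_axis), length(x$c_axis)))
  cat(sprintf("  clearance time range: %.0f-%.0f days\n",
              min(x$tc_days), max(x$tc_days[is.finite(x$tc_days)])))
  cat(sprintf("  deaths range        : %.0f-%.0f persons\n",
              min(x$deaths), max(x$deaths)))
  invisible(x)
}

# shared inverse solver: finds the capacity fraction where `objective(c)`
# crosses target; objective is strictly decreasing in c
.invert_capacity <- function(objective, target, c_max, what) {
  lo <- objective(1e-9)
  hi <- objective(c_max)
  if (target > lo || target < hi)
    stop(sprintf(
      "%s target %g outside the attainable range [%g, %g] for c in [0, %g]",
      what, target, hi, lo, c_max), call. = FALSE)
  stats::uniroot(function(c) objective(c) - target,
                 lower = 1e-9, upper = c_max, tol = 1e-8)$root
}

#' Capacity increase needed to hit a target death count
#'
#' Inverse planning: given a conversion fraction `p`, finds the general
#' capacity-increase fraction `c` at which the predicted waiting-list
#' deaths equal `target_deaths`. In `mc-mean` mode the objective is the
#' Monte-Carlo mean under common random numbers, making it strictly
#' monotone in `c`; root finding is by Brent's method to well below the
#' 0.5-person tolerance on the objective.
#'
#' @inheritParams compute_grid
#' @param target_deaths Target mean deaths, persons.
#' @param p Conversion fraction held fixed.
#' @param c_max Upper end of the search bracket for `c`.
#' @return The capacity fraction `c` (e.g. 0.25 for +25%).
#' @examples
#' \donttest{
#' find_capacity_for_deaths(population_params(), 1000, p = 0.5)  # ~0.087
#' }
#' @export
find_capacity_for_deaths <- function(params, target_deaths, p = 0,
                                     ratio = conversion_ratio(),
                                     mode = c("mc-mean", "point"),
                                     n = 10000, seed = 20220616,
                                     c_max = 2, draws = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "population_params"))
  draws <- .planner_draws(params, mode, n, seed, draws)
  obj <- function(c)
    .cell_outcomes(params, p, c, ratio, mode, draws)[["deaths"]]
  .invert_capacity(obj, target_deaths, c_max, "deaths")
}

#' Capacity increase needed to hit a target clearance time
#'
#' As [find_capacity_for_deaths()] with mean clearance time (days) as the
#' objective.
#'
#' @inheritParams find_capacity_for_deaths
#' @param target_days Target mean clearance time, days.
#' @return The capacity fraction `c`.
#' @export
find_capacity_for_time <- function(params, target_days, p = 0,
                                   ratio = conversion_ratio(),
                                   mode = c("mc-mean", "point"),
                                   n = 10000, seed = 20220616,
                                   c_max = 2, draws = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "population_params"))
  draws <- .planner_draws(params, mode, n, seed, draws)
  obj <- function(c)
    .cell_outcomes(params, p, c, ratio, mode, draws)[["tc"]]
  .invert_capacity(obj, target_days, c_max, "clearance-time")
}

#' Extract an isocline of constant outcome
#'
#' Level curve in the (conversion fraction, capacity increase) plane along
#' which the chosen outcome is constant: for each conversion fraction on
#' `p_axis` where the level is attainable within `[0, c_max]`, the
#' matching capacity fraction is found by the inverse solvers
#' (per-column root finding). Along a contour the required capacity
#' decreases as conversion increases.
#'
#' @inheritParams find_capacity_for_deaths
#' @param level Outcome level: days for `outcome = "time"`, persons for
#'   `outcome = "deaths"`.
#' @param outcome `"time"` or `"deaths"`.
#' @param p_axis Conversion fractions at which to solve.
#' @return An object of class `isocline`: `level`, `outcome`, and a
#'   data.frame `points` with columns `p`, `c` (ordered by `p`).
#' @examples
#' \donttest{
#' extract_isocline(population_params(), level = 1000, outcome = "deaths",
#'                  p_axis = seq(0, 0.5, by = 0.25))
#' }
#' @export
extract_isocline <- function(params, level, outcome = c("time", "deaths"),
                             p_axis = seq(0, 0.5, by = 0.05),
                             ratio = conversion_ratio(),
                             mode = c("mc-mean", "point"),
                             n = 10000, seed = 20220616,
                             c_max = 2, draws = NULL) {
  outcome <- match.arg(outcome)
  mode <- match.arg(mode)
  stopifnot(inherits(params, "population_params"))
  draws <- .planner_draws(params, mode, n, seed, draws)
  solver <- if (outcome == "deaths") find_capacity_for_deaths
            else find_capacity_for_time
  pts <- lapply(sort(p_axis), function(p) {
    c_at <- tryCatch(
      solver(params, level, p = p, ratio = ratio, mode = mode,
             c_max = c_max, draws = draws),
      error = function(e) NA_real_)
    data.frame(p = p, c = c_at)
  })
  pts <- do.call(rbind, pts)
  pts <- pts[!is.na(pts$c), , drop = FALSE]
  if (nrow(pts) == 0)
    stop("level unattainable anywhere on the conversion axis", call. = FALSE)
  rownames(pts) <- NULL
  structure(list(level = level, outcome = outcome, points = pts),
            class = "isocline")
}

#' @export
print.isocline <- function(x, ...) {
  unit <- if (x$outcome == "time") "days" else "deaths"
  cat(sprintf("Isocline at %g %s (%d points)\n", x$level, unit,
              nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}
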