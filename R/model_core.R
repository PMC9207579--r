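# Closed-form solutions of the excess-list balance dW/dt = -mu*W - Te:
# the list shrinks only through death (hazard mu) and surplus treatment (Te).

# series branch threshold: below this |mu| the log form loses precision and
# the mu -> 0 limit tc = W0/Te is used; both branches agree to ~1e-10 here
.MU_EPS <- 1e-8

#' Time to clear the excess backlog
#'
#' Closed-form clearance time of the waiting list
#' \deqn{t_c = \frac{\ln(1 + W_0 \mu / T_e)}{\mu},}
#' the first time the excess list, shrinking through mortality at hazard
#' \eqn{\mu} and surplus treatment at rate \eqn{T_e}, reaches zero.
#' Evaluated via `log1p` for numerical stability; for \eqn{|\mu|} below
#' `1e-8` the analytic limit \eqn{W_0/T_e} is returned, so the function is
#' continuous in \eqn{\mu} through zero.
#'
#' @param W0 Excess backlog, persons (vectorised, recycled).
#' @param mu Mortality hazard, 1/year.
#' @param Te Surplus treatment capacity, procedures/year. Must be positive:
#'   with no surplus the backlog never clears (see [deaths_by_time()] for
#'   the zero-capacity system).
#' @return Clearance time in years.
#' @seealso [deaths_at_clearance()], [waitlist_trajectory()]
#' @examples
#' p <- population_params()
#' clearance_time(p$W0_mean, p$mu_mean, p$rS0 + p$rT0) * 365  # days, doubled capacity
#' @export
clearance_time <- function(W0, mu, Te) {
  n <- max(length(W0), length(mu), length(Te))
  W0 <- rep_len(as.numeric(W0), n)
  mu <- rep_len(as.numeric(mu), n)
  Te <- rep_len(as.numeric(Te), n)
  if (any(W0 < 0)) stop("W0 must be nonnegative", call. = FALSE)
  if (any(Te <= 0))
    stop("Te must be positive: without surplus capacity the backlog cannot ",
         "clear by treatment", call. = FALSE)
  x <- W0 * mu / Te
  if (any(1 + x <= 0))
    stop("non-clearing regime: 1 + W0*mu/Te must be positive", call. = FALSE)
  tiny <- abs(mu) < .MU_EPS
  tc <- numeric(n)
  tc[!tiny] <- log1p(x[!tiny]) / mu[!tiny]
  tc[tiny] <- W0[tiny] / Te[tiny]
  tc
}

#' Deaths on the excess waiting list at clearance
#'
#' Waiting-list mortality accumulated by the time the backlog clears,
#' \eqn{m(t_c) = W_0 - T_e t_c}: whoever was not treated by the surplus
#' capacity died waiting. `tc` must be the clearance time computed from the
#' same parameters; small negative results from floating-point cancellation
#' are clipped to zero, but a violation beyond tolerance signals
#' inconsistent inputs and is an error, not a clamp.
#'
#' @inheritParams clearance_time
#' @param tc Clearance time in years, from [clearance_time()].
#' @param tol Relative tolerance (on the scale of `W0`) within which
#'   out-of-range results are clipped.
#' @return Deaths before treatment, persons.
#' @export
deaths_at_clearance <- function(W0, Te, tc, tol = 1e-9) {
  n <- max(length(W0), length(Te), length(tc))
  W0 <- rep_len(as.numeric(W0), n)
  Te <- rep_len(as.numeric(Te), n)
  tc <- rep_len(as.numeric(tc), n)
  m <- W0 - Te * tc
  slack <- tol * pmax(W0, 1)
  if (any(m < -slack | m > W0 + slack))
    stop("inconsistent inputs: W0 - Te*tc outside [0, W0] beyond tolerance; ",
         "tc must come from clearance_time() with the same parameters",
         call. = FALSE)
  pmin(pmax(m, 0), W0)
}

#' Deaths on the excess list by a given time (zero-surplus form)
#'
#' Cumulative mortality of the untreated excess backlog after time `t` when
#' no surplus capacity exists: \eqn{W_0 (1 - e^{-\mu t})}. This is the
#' zero-capacity special case of the trajectory; under the point-estimate
#' parameters it exceeds 1500 deaths within the first year. Monotone
#' increasing in both `t` and `mu`, approaching `W0` as `t` grows.
#'
#' @inheritParams clearance_time
#' @param t Time since the start of the recovery period, years (vectorised).
#' @return Cumulative deaths, persons.
#' @examples
#' deaths_by_time(4989, 0.36, 1)  # first-year deaths with no extra capacity
#' @export
deaths_by_time <- function(W0, mu, t) {
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  if (any(W0 < 0)) stop("W0 must be nonnegative", call. = FALSE)
  W0 * (-expm1(-mu * t))
}

#' Waiting-list trajectory under constant surplus capacity
#'
#' Evaluates the solution of the excess-list balance
#' \eqn{dW/dt = -\mu W - T_e} on a time grid:
#' \eqn{W(t) = (W_0 + T_e/\mu) e^{-\mu t} - T_e/\mu}, truncated at zero once
#' the backlog clears. Cumulative treated is \eqn{T_e \min(t, t_c)};
#' cumulative deaths is the balance \eqn{W_0 - W(t) - T_e \min(t, t_c)}.
#' `Te = 0` is allowed (pure exponential decay; the list never clears).
#'
#' @inheritParams clearance_time
#' @param Te Surplus capacity, procedures/year; zero allowed here.
#' @param t_grid Nonnegative, nondecreasing times in years.
#' @return A data.frame with columns `time` (years), `waiting`,
#'   `cum_deaths`, `cum_treated` (persons). The three compartments sum to
#'   `W0` at every time before clearance.
#' @export
waitlist_trajectory <- function(W0, mu, Te, t_grid) {
  stopifnot(length(W0) == 1L, length(mu) == 1L, length(Te) == 1L)
  if (any(t_grid < 0)) stop("t_grid must be nonnegative", call. = FALSE)
  if (is.unsorted(t_grid)) stop("t_grid must be nondecreasing", call. = FALSE)
  if (Te < 0) stop("Te must be nonnegative", call. = FALSE)
  t <- as.numeric(t_grid)
  tc <- if (Te > 0) clearance_time(W0, mu, Te) else Inf
  if (abs(mu) < .MU_EPS) {
    waiting <- pmax(W0 - Te * t, 0)
  } else {
    waiting <- pmax((W0 + Te / mu) * exp(-mu * t) - Te / mu, 0)
  }
  waiting[t >= tc] <- 0
  cum_treated <- Te * pmin(t, tc)
  cum_deaths <- pmax(W0 - waiting - cum_treated, 0)
  data.frame(time = t, waiting = waiting,
             cum_deaths = cum_deaths, cum_treated = cum_treated)
}

#' Point-estimate outcomes for a strategy
#'
#' Convenience wrapper: computes the surplus capacity of a strategy via
#' [total_surplus()] and evaluates the closed forms at the point-estimate
#' parameters, returning surplus, clearance time in days, deaths and treated
#' count.
#'
#' @param params A [population_params()] object.
#' @param strategy A [strategy()] object.
#' @return An object of class `clearance_result`: a list with
#'   `Te_per_year`, `Te_per_day`, `tc_days`, `deaths`, `treated`.
#' @examples
#' clearance_point(population_params(), strategy(capacity_increase = 0.2))
#' @export
clearance_point <- function(params, strategy) {
  stopifnot(inherits(params, "population_params"),
            inherits(strategy, "backlog_strategy"))
  Te <- total_surplus(params, strategy)
  if (Te <= 0)
    stop("strategy yields no surplus capacity: backlog cannot clear; use ",
         "deaths_by_time() for the zero-surplus system", call. = FALSE)
  tc <- clearance_time(params$W0_mean, params$mu_mean, Te)
  deaths <- deaths_at_clearance(params$W0_mean, Te, tc)
  structure(
    list(Te_per_year = Te,
         Te_per_day = per_day(Te, params),
         tc_days = tc * params$days_per_year,
         deaths = deaths,
         treated = params$W0_mean - deaths),
    class = "clearance_result"
  )
}

#' @export
print.clearance_result <- function(x, ...) {
  cat("Point-estimate backlog clearance\n")
  cat(sprintf("  surplus capacity : %.1f procedures/year (%.3f/day)\n",
              x$Te_per_year, x$Te_per_day))
  cat(sprintf("  clearance time   : %.0f days\n", x$tc_days))
  cat(sprintf("  deaths waiting   : %.0f persons\n", x$deaths))
  cat(sprintf("  treated from backlog: %.0f persons\n", x$treated))
  invisible(x)
}
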