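# Monte-Carlo propagation of parameter uncertainty. The backlog size and
# mortality hazard are drawn independently from normal distributions whose
# standard deviations are recovered from the published 95% CIs; outcome
# summaries are means plus the 2.5/97.5 percentile reference range.

#' Normal parameter distribution recovered from a 95% CI
#'
#' The standard deviation is the CI half-width divided by the normal 97.5%
#' quantile (`qnorm(0.975)` = 1.959964...). A lower truncation `floor`
#' keeps draws in the model's domain; draws below it are resampled
#' (truncated normal via rejection).
#'
#' @param mean Distribution mean.
#' @param ci Length-2 numeric 95% CI (lower, upper).
#' @param floor Lower truncation bound; must not sit above `mean + 5*sd`
#'   or rejection sampling would stall.
#' @return An object of class `param_distribution` with `mean`, `sd`,
#'   `floor`.
#' @examples
#' param_distribution(4989, c(4020, 5959), floor = 0)  # sd ~ 494.65
#' @export
param_distribution <- function(mean, ci, floor = 0) {
  stopifnot(is.numeric(mean), length(mean) == 1L,
            is.numeric(ci), length(ci) == 2L, ci[1] <= ci[2],
            is.numeric(floor), length(floor) == 1L)
  sd <- (ci[2] - ci[1]) / (2 * stats::qnorm(0.975))
  # sd = 0 (degenerate CI) is allowed: all draws collapse to the mean
  if (floor > mean + 5 * sd)
    stop("floor lies above mean + 5*sd: rejection sampling would stall",
         call. = FALSE)
  structure(list(mean = mean, sd = sd, floor = floor),
            class = "param_distribution")
}

# one truncated-normal vector via rejection resampling; sd = 0 degenerates
# to the constant mean (floor permitting)
.rtruncnorm <- function(n, dist) {
  if (dist$sd == 0) return(rep(max(dist$mean, dist$floor), n))
  x <- stats::rnorm(n, dist$mean, dist$sd)
  bad <- x < dist$floor
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), dist$mean, dist$sd)
    bad <- x < dist$floor
  }
  x
}

#' Draw (W0, mu) parameter pairs
#'
#' Independent i.i.d. draws of the excess backlog size and the mortality
#' hazard from their stated normal distributions, truncated below at
#' `W0_floor` (default 0) and `mu_floor` (default 1e-4/year, where the
#' clearance closed form is still well defined) by rejection resampling.
#' Reproducible for a fixed seed.
#'
#' @param params A [population_params()] object.
#' @param n Number of draws.
#' @param seed RNG seed. The default, 20220616, is an arbitrary fixed
#'   integer; pass any seed.
#' @param mu_floor Lower truncation for the hazard, 1/year.
#' @param W0_floor Lower truncation for the backlog size, persons.
#' @return A data.frame with columns `W0` and `mu`, one row per draw.
#' @export
draw_parameters <- function(params, n = 10000, seed = 20220616,
                            mu_floor = 1e-4, W0_floor = 0) {
  stopifnot(inherits(params, "population_params"), n >= 1)
  dW <- param_distribution(params$W0_mean, params$W0_ci, floor = W0_floor)
  dm <- param_distribution(params$mu_mean, params$mu_ci, floor = mu_floor)
  if (!is.null(seed)) set.seed(seed)
  out <- data.frame(W0 = .rtruncnorm(n, dW), mu = .rtruncnorm(n, dm))
  attr(out, "seed") <- seed
  out
}

# per-draw outcomes for a given surplus; reused by the planner with common
# random numbers (one draw set across all candidate strategies)
.mc_outcomes <- function(draws, Te, days_per_year = 365) {
  tc <- clearance_time(draws$W0, draws$mu, Te)
  list(tc_days = tc * days_per_year,
       deaths = deaths_at_clearance(draws$W0, Te, tc))
}

#' Monte-Carlo summary of a strategy's outcomes
#'
#' Propagates the parameter uncertainty through the closed-form model:
#' draws `n` (W0, mu) pairs, computes per-draw clearance time and deaths
#' for the strategy's surplus capacity, and summarises each outcome by its
#' mean and empirical 2.5/97.5 percentiles (the 95% reference range).
#' Percentiles use linear interpolation between order statistics
#' (`quantile` type 7), so ranges are reproducible bit-for-bit given the
#' seed.
#'
#' @inheritParams draw_parameters
#' @param strategy A [strategy()] object with positive total surplus.
#' @param draws Optional precomputed draw set from [draw_parameters()]
#'   (common random numbers); when supplied, `n` and `seed` are taken from
#'   it and the RNG is untouched.
#' @return An object of class `mc_summary`: `n`, `seed`, `Te_per_year`,
#'   and mean/2.5/97.5-percentile fields for clearance time in days
#'   (`tc_mean`, `tc_p2_5`, `tc_p97_5`) and deaths (`deaths_mean`,
#'   `deaths_p2_5`, `deaths_p97_5`).
#' @examples
#' mc_summary(population_params(), strategy(capacity_increase = 0.2),
#'            n = 2000, seed = 1)
#' @export
mc_summary <- function(params, strategy, n = 10000, seed = 20220616,
                       mu_floor = 1e-4, W0_floor = 0, draws = NULL) {
  stopifnot(inherits(params, "population_params"),
            inherits(strategy, "backlog_strategy"))
  Te <- total_surplus(params, strategy)
  if (Te <= 0)
    stop("strategy yields no surplus capacity; Monte-Carlo summary ",
         "requires a clearing system", call. = FALSE)
  if (is.null(draws)) {
    draws <- draw_parameters(params, n = n, seed = seed,
                             mu_floor = mu_floor, W0_floor = W0_floor)
  } else {
    n <- nrow(draws)
    seed <- attr(draws, "seed") %||% NA_integer_
  }
  out <- .mc_outcomes(draws, Te, params$days_per_year)
  qt <- stats::quantile(out$tc_days, c(0.025, 0.975), names = FALSE)
  qd <- stats::quantile(out$deaths, c(0.025, 0.975), names = FALSE)
  structure(
    list(n = n, seed = seed, Te_per_year = Te,
         tc_mean = mean(out$tc_days), tc_p2_5 = qt[1], tc_p97_5 = qt[2],
         deaths_mean = mean(out$deaths),
         deaths_p2_5 = qd[1], deaths_p97_5 = qd[2]),
    class = "mc_summary"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf("Monte-Carlo summary (n = %d draws)\n", x$n))
  cat(sprintf("  surplus capacity : %.1f procedures/year\n", x$Te_per_year))
  cat(sprintf("  clearance time   : %.0f (%.0f-%.0f) days\n",
              x$tc_mean, x$tc_p2_5, x$tc_p97_5))
  cat(sprintf("  deaths waiting   : %.0f (%.0f-%.0f) persons\n",
              x$deaths_mean, x$deaths_p2_5, x$deaths_p97_5))
  invisible(x)
}

#' @export
as.data.frame.mc_summary <- function(x, ...) {
  data.frame(n = x$n, seed = x$seed, Te_per_year = x$Te_per_year,
             tc_mean = x$tc_mean, tc_p2_5 = x$tc_p2_5,
             tc_p97_5 = x$tc_p97_5, deaths_mean = x$deaths_mean,
             deaths_p2_5 = x$deaths_p2_5, deaths_p97_5 = x$deaths_p97_5)
}
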