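#' Epidemiological constants of the waiting-list system
#'
#' Bundles the population-level inputs of the backlog model: the size of the
#' excess waiting list accumulated during the pandemic, the annual mortality
#' hazard of untreated severe aortic stenosis, and the prepandemic SAVR and
#' TAVI throughputs from which surplus capacity is built. Defaults are the
#' NHS England estimates: an excess backlog of 4989 patients (95% CI
#' 4020--5959) as of November 2020, a 36% annual mortality hazard (95% CI
#' 12%--60%), and 2018/19 throughput of 7830 SAVR and 5197 TAVI procedures.
#'
#' The steady-state inflow of new patients `inflow_f` is carried for
#' completeness only: under the assumption that baseline capacity continues
#' to absorb incident cases, it cancels out of the excess-backlog dynamics.
#'
#' @param W0_mean Excess backlog size, persons.
#' @param W0_ci Length-2 numeric, 95% CI bounds (lower, upper) for `W0_mean`.
#' @param mu_mean Annual mortality hazard of untreated patients, 1/year.
#' @param mu_ci Length-2 numeric, 95% CI bounds for `mu_mean`.
#' @param rS0 Baseline SAVR throughput, procedures/year.
#' @param rT0 Baseline TAVI throughput, procedures/year.
#' @param inflow_f Steady-state arrival rate of new patients, patients/year.
#'   Defaults to `rS0 + rT0` (steady state: arrivals equal baseline
#'   throughput).
#' @param days_per_year Day-count convention; fixed at 365.
#'
#' @return An object of class `population_params`.
#' @examples
#' population_params()
#' @export
population_params <- function(W0_mean = 4989,
                              W0_ci = c(4020, 5959),
                              mu_mean = 0.36,
                              mu_ci = c(0.12, 0.60),
                              rS0 = 7830,
                              rT0 = 5197,
                              inflow_f = rS0 + rT0,
                              days_per_year = 365) {
  stopifnot(
    is.numeric(W0_mean), length(W0_mean) == 1L, W0_mean > 0,
    is.numeric(W0_ci), length(W0_ci) == 2L,
    is.numeric(mu_mean), length(mu_mean) == 1L,
    is.numeric(mu_ci), length(mu_ci) == 2L,
    is.numeric(rS0), length(rS0) == 1L,
    is.numeric(rT0), length(rT0) == 1L
  )
  if (!(W0_ci[1] < W0_mean && W0_mean < W0_ci[2]))
    stop("W0 CI must satisfy lower < mean < upper", call. = FALSE)
  if (!(mu_ci[1] < mu_mean && mu_mean < mu_ci[2]))
    stop("mu CI must satisfy lower < mean < upper", call. = FALSE)
  if (!(mu_mean > 0 && mu_mean < 1))
    stop("mu_mean must lie in (0, 1) per year", call. = FALSE)
  if (rS0 <= 0 || rT0 <= 0)
    stop("baseline throughputs rS0 and rT0 must be positive", call. = FALSE)
  if (!identical(as.numeric(days_per_year), 365))
    stop("days_per_year is fixed at 365 by the model's day-count convention",
         call. = FALSE)
  structure(
    list(
      W0_mean = as.numeric(W0_mean), W0_ci = as.numeric(W0_ci),
      mu_mean = as.numeric(mu_mean), mu_ci = as.numeric(mu_ci),
      rS0 = as.numeric(rS0), rT0 = as.numeric(rT0),
      inflow_f = as.numeric(inflow_f),
      days_per_year = 365
    ),
    class = "population_params"
  )
}

#' @export
print.population_params <- function(x, ...) {
  cat("Waiting-list population parameters\n")
  cat(sprintf("  excess backlog W0 : %.0f (95%% CI %.0f-%.0f) persons\n",
              x$W0_mean, x$W0_ci[1], x$W0_ci[2]))
  cat(sprintf("  mortality hazard  : %.2f (95%% CI %.2f-%.2f) / year\n",
              x$mu_mean, x$mu_ci[1], x$mu_ci[2]))
  cat(sprintf("  baseline SAVR     : %.0f procedures/year\n", x$rS0))
  cat(sprintf("  baseline TAVI     : %.0f procedures/year\n", x$rT0))
  invisible(x)
}
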