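# Independent brute-force checks of the closed forms: a daily-step Euler
# integrator of the same flow balance, and a patient-level stochastic queue.
# Both are deliberately simple step-by-step loops so they share no code
# path with the analytic solutions they validate.

#' Deterministic Euler integration of the waiting-list balance
#'
#' Integrates `dW/dt = -(mu/365) W - Te/365` (time in days) with explicit
#' Euler steps, accumulating deaths as `(mu/365) * W * step` per step.
#' Clearance is the first crossing of `W <= 0`, located by linear
#' interpolation inside the final step. First-order convergent: halving the
#' step halves the error against the closed forms.
#'
#' @param params A [population_params()] object (supplies W0, mu and the
#'   day-count convention); alternatively pass `W0` and `mu` explicitly.
#' @param Te Surplus capacity, procedures/year.
#' @param step_days Euler step, days.
#' @param horizon_days Integration horizon; if the list has not cleared by
#'   then, the result is flagged `cleared = FALSE` with partial tallies.
#' @param W0,mu Scalar overrides of the point-estimate parameters.
#' @return A list: `tc_days` (NA if not cleared), `deaths`, `treated`,
#'   `cleared`, and a `trajectory` data.frame sampled at whole days
#'   (`day`, `waiting`, `cum_deaths`, `cum_treated`).
#' @examples
#' sim <- simulate_deterministic(population_params(), Te = 13027,
#'                               step_days = 0.1)
#' sim$tc_days  # ~131, matching the closed form
#' @export
simulate_deterministic <- function(params = population_params(), Te,
                                   step_days = 0.01, horizon_days = 3650,
                                   W0 = params$W0_mean, mu = params$mu_mean) {
  stopifnot(step_days > 0, horizon_days >= step_days, Te >= 0, W0 >= 0)
  h <- step_days
  mu_d <- mu / 365
  Te_d <- Te / 365
  n_steps <- ceiling(horizon_days / h)
  W <- W0
  deaths <- 0
  treated <- 0
  tc <- NA_real_
  # sample the trajectory at (roughly) whole days to keep output small
  rec_every <- max(1L, round(1 / h))
  rec_day <- numeric(0); rec_W <- numeric(0)
  rec_d <- numeric(0); rec_t <- numeric(0)
  for (k in seq_len(n_steps)) {
    dD <- mu_d * W * h
    dT <- Te_d * h
    W_next <- W - dD - dT
    if (W_next <= 0) {
      # linear interpolation to the crossing inside this step
      frac <- W / (dD + dT)
      tc <- (k - 1) * h + frac * h
      deaths <- deaths + dD * frac
      treated <- treated + dT * frac
      W <- 0
      break
    }
    deaths <- deaths + dD
    treated <- treated + dT
    W <- W_next
    if (k %% rec_every == 0L) {
      rec_day <- c(rec_day, k * h); rec_W <- c(rec_W, W)
      rec_d <- c(rec_d, deaths); rec_t <- c(rec_t, treated)
    }
  }
  list(tc_days = tc, deaths = deaths, treated = treated,
       cleared = !is.na(tc),
       trajectory = data.frame(day = c(0, rec_day),
                               waiting = c(W0, rec_W),
                               cum_deaths = c(0, rec_d),
                               cum_treated = c(0, rec_t)))
}

#' Patient-level stochastic queue simulation
#'
#' Simulates the excess list day by day with integer patients: each waiting
#' patient dies within a day with probability `1 - exp(-mu/365)` (deaths
#' applied first), then the day's accumulated fractional treatment slots
#' are spent on `floor(slots)` patients (unspent fractions carry over, so
#' annualised capacity is not wasted on rounding). Replicate means of
#' clearance time and deaths converge to the deterministic values.
#'
#' @inheritParams simulate_deterministic
#' @param n_reps Number of independent replicates.
#' @param seed RNG seed.
#' @return A list: `replicates` data.frame (`tc_days`, `deaths`,
#'   `treated`, `cleared`, with `treated + deaths + waiting = W0` exactly
#'   per replicate), and `means` (mean `tc_days` over cleared replicates,
#'   mean `deaths`).
#' @examples
#' simulate_stochastic(Te = 2605.4, n_reps = 20, seed = 1)$means
#' @export
simulate_stochastic <- function(params = population_params(), Te,
                                n_reps = 200, horizon_days = 3650,
                                seed = 20220616,
                                W0 = params$W0_mean, mu = params$mu_mean) {
  stopifnot(n_reps >= 1, horizon_days >= 1, Te >= 0)
  if (!is.null(seed)) set.seed(seed)
  W0 <- round(W0)
  p_die <- -expm1(-mu / 365)
  slots_per_day <- Te / 365
  W <- rep(W0, n_reps)
  deaths <- integer(n_reps)
  treated <- integer(n_reps)
  acc <- numeric(n_reps)   # fractional slot carry-over, per replicate
  tc <- rep(NA_real_, n_reps)
  for (day in seq_len(horizon_days)) {
    active <- W > 0
    if (!any(active)) break
    d <- integer(n_reps)
    d[active] <- stats::rbinom(sum(active), W[active], p_die)
    W <- W - d
    deaths <- deaths + d
    acc[active] <- acc[active] + slots_per_day
    s <- pmin(floor(acc), W)
    s[!active] <- 0L
    W <- W - s
    treated <- treated + s
    acc <- acc - s
    done <- active & W == 0
    tc[done] <- day
  }
  reps <- data.frame(tc_days = tc, deaths = deaths, treated = treated,
                     waiting = W, cleared = !is.na(tc))
  list(replicates = reps,
       means = c(tc_days = mean(tc, na.rm = TRUE), deaths = mean(deaths)))
}
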