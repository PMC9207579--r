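# Intervention arithmetic: how capacity increases and SAVR->TAVI conversion
# translate into surplus procedures per year.

#' Procedure time-equivalence ratio for SAVR-to-TAVI conversion
#'
#' In the operating time of `savr_slots` surgical valve replacements
#' (each roughly 2--4 h), `tavi_slots` transcatheter implantations
#' (roughly 1--2 h each) can be performed. The default 2:3 is the base
#' assumption; sensitivity ratios 3:4, 2:4 and 3:5 are also used, 2:4 being
#' the highest considered plausible in the short term. A conversion only
#' creates surplus when `tavi_slots > savr_slots`.
#'
#' @param savr_slots SAVR procedures per time block (`a`), at least 1.
#' @param tavi_slots TAVI procedures in the same block (`b`), must exceed
#'   `savr_slots`.
#' @return An object of class `conversion_ratio`. Slot counts are kept as
#'   integers; the surplus factor `b/a - 1` is formed only at evaluation so
#'   the ratio stays exact.
#' @examples
#' conversion_ratio(2, 3)
#' conversion_ratio(2, 4)  # highest sensitivity ratio
#' @export
conversion_ratio <- function(savr_slots = 2, tavi_slots = 3) {
  stopifnot(is.numeric(savr_slots), length(savr_slots) == 1L,
            is.numeric(tavi_slots), length(tavi_slots) == 1L)
  if (savr_slots < 1 || savr_slots != round(savr_slots) ||
      tavi_slots != round(tavi_slots))
    stop("slot counts must be whole numbers with savr_slots >= 1",
         call. = FALSE)
  if (tavi_slots <= savr_slots)
    stop("no surplus: tavi_slots must exceed savr_slots", call. = FALSE)
  structure(list(savr_slots = as.integer(savr_slots),
                 tavi_slots = as.integer(tavi_slots)),
            class = "conversion_ratio")
}

#' @export
print.conversion_ratio <- function(x, ...) {
  cat(sprintf("SAVR:TAVI time-equivalence ratio %d:%d (surplus factor %s)\n",
              x$savr_slots, x$tavi_slots,
              format(x$tavi_slots / x$savr_slots - 1)))
  invisible(x)
}

#' An intervention strategy
#'
#' A strategy combines a general capacity increase (extra lists, more
#' procedures per list) with the conversion of a fraction of SAVR cases to
#' the faster TAVI procedure. Short-term clinical constraints cap both the
#' conversion fraction and the general increase at 50%; exceeding a cap
#' raises a warning unless `allow_above_cap = TRUE` (scenarios exploring a
#' doubled capacity need `capacity_increase = 1`).
#'
#' @param capacity_increase Fraction `c >= 0` of throughput added by
#'   general measures (0.2 means +20%).
#' @param conversion_fraction Fraction `p` in `[0, 1]` of SAVR cases
#'   converted to TAVI.
#' @param ratio A [conversion_ratio()].
#' @param allow_above_cap Suppress the 50% soft-cap warning.
#' @return An object of class `backlog_strategy`.
#' @examples
#' strategy(capacity_increase = 0.2, conversion_fraction = 0.4)
#' @export
strategy <- function(capacity_increase = 0,
                     conversion_fraction = 0,
                     ratio = conversion_ratio(),
                     allow_above_cap = FALSE) {
  stopifnot(is.numeric(capacity_increase), length(capacity_increase) == 1L,
            is.numeric(conversion_fraction), length(conversion_fraction) == 1L,
            inherits(ratio, "conversion_ratio"))
  if (capacity_increase < 0)
    stop("capacity_increase must be nonnegative", call. = FALSE)
  if (conversion_fraction < 0 || conversion_fraction > 1)
    stop("conversion_fraction must lie in [0, 1]", call. = FALSE)
  if (!allow_above_cap &&
      (capacity_increase > 0.5 || conversion_fraction > 0.5))
    warning("strategy exceeds the 50% short-term caps on capacity increase ",
            "or conversion; pass allow_above_cap = TRUE to silence",
            call. = FALSE)
  structure(list(capacity_increase = as.numeric(capacity_increase),
                 conversion_fraction = as.numeric(conversion_fraction),
                 ratio = ratio),
            class = "backlog_strategy")
}

#' @export
print.backlog_strategy <- function(x, ...) {
  cat(sprintf(
    "Strategy: %.0f%% capacity increase, %.0f%% SAVR->TAVI conversion at %d:%d\n",
    100 * x$capacity_increase, 100 * x$conversion_fraction,
    x$ratio$savr_slots, x$ratio$tavi_slots))
  invisible(x)
}

#' Surplus capacity created by SAVR-to-TAVI conversion
#'
#' Converting a fraction `p` of the baseline SAVR caseload to TAVI frees
#' operating time: each converted case still occupies one treatment, but at
#' ratio `a:b` every `a` converted SAVR slots now host `b` TAVI cases, so
#' the surplus is `p * rS0 * (b/a - 1)` procedures per year.
#'
#' @param params A [population_params()] object.
#' @param p Conversion fraction in `[0, 1]`.
#' @param ratio A [conversion_ratio()].
#' @return Surplus capacity, procedures/year.
#' @examples
#' conversion_surplus(population_params(), 0.5, conversion_ratio(2, 3))
#' @export
conversion_surplus <- function(params, p, ratio = conversion_ratio()) {
  stopifnot(inherits(params, "population_params"),
            inherits(ratio, "conversion_ratio"))
  if (any(p < 0 | p > 1))
    stop("conversion fraction p must lie in [0, 1]", call. = FALSE)
  p * params$rS0 * (ratio$tavi_slots / ratio$savr_slots - 1)
}

#' Total surplus capacity of a strategy
#'
#' Combines conversion surplus and general capacity increase. The general
#' increase applies to the post-conversion throughput ("at that mix"):
#' `Te = conv + c * (rS0 + rT0 + conv)` where
#' `conv = conversion_surplus(p, ratio)`. Extra lists added after converting
#' cases run at the converted case mix, so the two levers interact
#' positively.
#'
#' @inheritParams conversion_surplus
#' @param strategy A [strategy()] object.
#' @return Surplus capacity `Te`, procedures/year.
#' @examples
#' p <- population_params()
#' total_surplus(p, strategy(capacity_increase = 0.05))  # 651.35/yr = 1.785/day
#' @export
total_surplus <- function(params, strategy) {
  stopifnot(inherits(params, "population_params"),
            inherits(strategy, "backlog_strategy"))
  conv <- conversion_surplus(params, strategy$conversion_fraction,
                             strategy$ratio)
  conv + strategy$capacity_increase * (params$rS0 + params$rT0 + conv)
}

#' Convert an annual surplus to procedures per day
#'
#' @param Te_per_year Surplus capacity, procedures/year.
#' @param params A [population_params()] object (supplies the 365-day
#'   convention).
#' @return Procedures per day.
#' @examples
#' per_day(651.35, population_params())  # 1.785
#' @export
per_day <- function(Te_per_year, params = population_params()) {
  stopifnot(inherits(params, "population_params"))
  Te_per_year / params$days_per_year
}
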