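# Scenario configuration files (JSON or YAML), batch runs and fixture
# generation. A scenario carries three blocks -- population, strategy, mc --
# any of which may be partial; missing fields are filled from the published
# point estimates so an empty file is the baseline scenario.

.POP_FIELDS <- c("W0_mean", "W0_ci", "mu_mean", "mu_ci", "rS0", "rT0",
                 "inflow_f", "days_per_year")
.STRAT_FIELDS <- c("capacity_increase", "conversion_fraction", "ratio",
                   "allow_above_cap")
.MC_FIELDS <- c("n", "seed", "mu_floor", "W0_floor")

.reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown %s field(s): %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

# "2:3" or list(savr_slots, tavi_slots) -> conversion_ratio
.parse_ratio <- function(r) {
  if (inherits(r, "conversion_ratio")) return(r)
  if (is.character(r) && length(r) == 1L) {
    parts <- as.numeric(strsplit(r, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2L || anyNA(parts))
      stop("ratio string must look like \"2:3\"", call. = FALSE)
    return(conversion_ratio(parts[1], parts[2]))
  }
  if (is.list(r))
    return(conversion_ratio(r$savr_slots %||% 2, r$tavi_slots %||% 3))
  stop("unparseable conversion ratio", call. = FALSE)
}

#' Load a scenario configuration
#'
#' Reads a JSON (`.json`) or YAML (`.yaml`/`.yml`) scenario file with
#' optional blocks `population`, `strategy` and `mc` plus an `id`. Missing
#' fields default to the published point estimates (W0 4989 with CI
#' 4020--5959, mu 0.36 with CI 0.12--0.60, rS0 7830, rT0 5197, ratio 2:3,
#' n = 10000), so an empty object is the baseline scenario. Unknown keys
#' are rejected with the offending name.
#'
#' @param path Path to the scenario file.
#' @return An object of class `scenario_config`: `id`, `population`
#'   ([population_params()]), `strategy` ([strategy()]), `mc` (list with
#'   `n`, `seed`, `mu_floor`, `W0_floor`).
#' @seealso [save_scenario()], [run_scenarios()], [generate_fixtures()]
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop("no such scenario file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(raw)) raw <- list()
  scenario_config(
    id = raw$id %||% sub("\\.[^.]+$", "", basename(path)),
    population = raw$population %||% list(),
    strategy = raw$strategy %||% list(),
    mc = raw$mc %||% list(),
    .extra = setdiff(names(raw), c("id", "population", "strategy", "mc"))
  )
}

#' Build a validated scenario configuration in code
#'
#' @param id Scenario identifier.
#' @param population,strategy,mc Partial lists of overrides; see
#'   [load_scenario()] for the fields and defaults.
#' @param .extra Internal: unknown top-level keys to report.
#' @return A `scenario_config` object.
#' @export
scenario_config <- function(id = "scenario", population = list(),
                            strategy = list(), mc = list(),
                            .extra = character(0)) {
  if (length(.extra))
    stop("unknown top-level field(s): ", paste(.extra, collapse = ", "),
         call. = FALSE)
  .reject_unknown(population, .POP_FIELDS, "population")
  .reject_unknown(strategy, .STRAT_FIELDS, "strategy")
  .reject_unknown(mc, .MC_FIELDS, "mc")
  pop <- population_params(
    W0_mean = population$W0_mean %||% 4989,
    W0_ci = unlist(population$W0_ci) %||% c(4020, 5959),
    mu_mean = population$mu_mean %||% 0.36,
    mu_ci = unlist(population$mu_ci) %||% c(0.12, 0.60),
    rS0 = population$rS0 %||% 7830,
    rT0 = population$rT0 %||% 5197,
    inflow_f = population$inflow_f %||%
      ((population$rS0 %||% 7830) + (population$rT0 %||% 5197)),
    days_per_year = population$days_per_year %||% 365
  )
  strat <- asbacklog::strategy(
    capacity_increase = strategy$capacity_increase %||% 0,
    conversion_fraction = strategy$conversion_fraction %||% 0,
    ratio = .parse_ratio(strategy$ratio %||% "2:3"),
    allow_above_cap = isTRUE(strategy$allow_above_cap)
  )
  mc_block <- list(n = as.integer(mc$n %||% 10000L),
                   seed = as.integer(mc$seed %||% 20220616L),
                   mu_floor = mc$mu_floor %||% 1e-4,
                   W0_floor = mc$W0_floor %||% 0)
  if (mc_block$n < 1L) stop("mc$n must be at least 1", call. = FALSE)
  structure(list(id = as.character(id), population = pop,
                 strategy = strat, mc = mc_block),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("Scenario \"%s\"\n", x$id))
  print(x$strategy)
  cat(sprintf("  MC: n = %d, seed = %d\n", x$mc$n, x$mc$seed))
  invisible(x)
}

# scenario_config -> plain nested list (for serialization)
.scenario_as_list <- function(cfg) {
  p <- cfg$population
  s <- cfg$strategy
  list(
    id = cfg$id,
    population = list(W0_mean = p$W0_mean, W0_ci = p$W0_ci,
                      mu_mean = p$mu_mean, mu_ci = p$mu_ci,
                      rS0 = p$rS0, rT0 = p$rT0, inflow_f = p$inflow_f,
                      days_per_year = p$days_per_year),
    strategy = list(capacity_increase = s$capacity_increase,
                    conversion_fraction = s$conversion_fraction,
                    ratio = sprintf("%d:%d", s$ratio$savr_slots,
                                    s$ratio$tavi_slots),
                    allow_above_cap = s$capacity_increase > 0.5 ||
                      s$conversion_fraction > 0.5),
    mc = cfg$mc
  )
}

#' Write a scenario configuration to disk
#'
#' Serialises a `scenario_config` as JSON or YAML (by file extension).
#' Files round-trip: `load_scenario(save_scenario(cfg, path))` rebuilds an
#' identical configuration.
#'
#' @param cfg A `scenario_config`.
#' @param path Output path ending in `.json`, `.yaml` or `.yml`.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(cfg, path) {
  stopifnot(inherits(cfg, "scenario_config"))
  x <- .scenario_as_list(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Run a batch of scenarios
#'
#' Evaluates each scenario's point-estimate outcomes and (optionally) its
#' Monte-Carlo summary, one row per scenario. A scenario that fails
#' validation or evaluation is recorded in the `error` column and the
#' batch continues. Deterministic given the per-scenario seeds.
#'
#' @param configs A list of `scenario_config` objects and/or file paths.
#' @param mode `"mc"` (point estimates plus Monte-Carlo columns) or
#'   `"point"` (point estimates only).
#' @return A data.frame with columns `id`, `Te_per_year`, `Te_per_day`,
#'   `tc_point_days`, `deaths_point`, and in `"mc"` mode also `n`, `seed`,
#'   `tc_mean`, `tc_p2_5`, `tc_p97_5`, `deaths_mean`, `deaths_p2_5`,
#'   `deaths_p97_5`; plus `error` (NA on success).
#' @export
run_scenarios <- function(configs, mode = c("mc", "point")) {
  mode <- match.arg(mode)
  if (inherits(configs, "scenario_config")) configs <- list(configs)
  rows <- lapply(configs, function(cfg) {
    tryCatch({
      if (is.character(cfg)) cfg <- load_scenario(cfg)
      stopifnot(inherits(cfg, "scenario_config"))
      Te <- total_surplus(cfg$population, cfg$strategy)
      row <- data.frame(id = cfg$id, Te_per_year = Te,
                        Te_per_day = per_day(Te, cfg$population))
      if (Te > 0) {
        pt <- clearance_point(cfg$population, cfg$strategy)
        row$tc_point_days <- pt$tc_days
        row$deaths_point <- pt$deaths
      } else {
        row$tc_point_days <- Inf
        row$deaths_point <- deaths_by_time(cfg$population$W0_mean,
                                           cfg$population$mu_mean, 1)
      }
      if (mode == "mc") {
        if (Te > 0) {
          s <- mc_summary(cfg$population, cfg$strategy, n = cfg$mc$n,
                          seed = cfg$mc$seed, mu_floor = cfg$mc$mu_floor,
                          W0_floor = cfg$mc$W0_floor)
          row <- cbind(row, as.data.frame(s)[, -3])  # Te already present
        } else {
          row <- cbind(row, data.frame(
            n = cfg$mc$n, seed = cfg$mc$seed, tc_mean = Inf,
            tc_p2_5 = Inf, tc_p97_5 = Inf, deaths_mean = row$deaths_point,
            deaths_p2_5 = NA_real_, deaths_p97_5 = NA_real_))
        }
      }
      row$error <- NA_character_
      row
    }, error = function(e) {
      id <- if (is.character(cfg)) basename(cfg)
            else tryCatch(cfg$id, error = function(...) "<invalid>")
      out <- data.frame(id = id, Te_per_year = NA_real_,
                        Te_per_day = NA_real_, tc_point_days = NA_real_,
                        deaths_point = NA_real_)
      if (mode == "mc")
        out <- cbind(out, data.frame(n = NA_integer_, seed = NA_integer_,
                                     tc_mean = NA_real_, tc_p2_5 = NA_real_,
                                     tc_p97_5 = NA_real_,
                                     deaths_mean = NA_real_,
                                     deaths_p2_5 = NA_real_,
                                     deaths_p97_5 = NA_real_))
      out$error <- conditionMessage(e)
      out
    })
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Write the canonical scenario fixtures
#'
#' Emits the headline scenarios as JSON configs -- +5%, +20% and +100%
#' general capacity, 30% and 50% conversion at ratio 2:3, 50% conversion
#' at 2:4, the combined 40% conversion + 20% capacity strategy, and the
#' zero-surplus baseline -- plus `n_random` randomized strategies (within
#' the 50% caps) for property testing.
#'
#' @param outdir Output directory (created if absent).
#' @param n_random Number of additional randomized scenario files.
#' @param seed Seed for the randomized strategies.
#' @return Character vector of the files written, invisibly.
#' @export
generate_fixtures <- function(outdir, n_random = 4, seed = 20220616) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  canon <- list(
    capacity_05 = list(strategy = list(capacity_increase = 0.05)),
    capacity_20 = list(strategy = list(capacity_increase = 0.20)),
    capacity_100 = list(strategy = list(capacity_increase = 1.0,
                                        allow_above_cap = TRUE)),
    conversion_30 = list(strategy = list(conversion_fraction = 0.30)),
    conversion_50 = list(strategy = list(conversion_fraction = 0.50)),
    conversion_50_ratio_2_4 = list(strategy = list(
      conversion_fraction = 0.50, ratio = "2:4")),
    combined_40_20 = list(strategy = list(conversion_fraction = 0.40,
                                          capacity_increase = 0.20)),
    zero_surplus = list(strategy = list())
  )
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(n_random)) {
    canon[[sprintf("random_%02d", i)]] <- list(strategy = list(
      capacity_increase = round(stats::runif(1, 0, 0.5), 3),
      conversion_fraction = round(stats::runif(1, 0, 0.5), 3)))
  }
  paths <- character(0)
  for (nm in names(canon)) {
    cfg <- scenario_config(id = nm, strategy = canon[[nm]]$strategy)
    paths <- c(paths, save_scenario(cfg, file.path(outdir,
                                                   paste0(nm, ".json"))))
  }
  invisible(paths)
}
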