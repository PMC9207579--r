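# Shared fixtures: published point estimates and a few named strategies.
default_params <- function() population_params()

published_scenarios <- function() {
  list(
    capacity_05 = strategy(capacity_increase = 0.05),
    capacity_20 = strategy(capacity_increase = 0.20),
    capacity_100 = strategy(capacity_increase = 1.0, allow_above_cap = TRUE),
    conversion_30 = strategy(conversion_fraction = 0.30),
    conversion_50 = strategy(conversion_fraction = 0.50),
    conversion_50_24 = strategy(conversion_fraction = 0.50,
                                ratio = conversion_ratio(2, 4)),
    combined_40_20 = strategy(conversion_fraction = 0.40,
                              capacity_increase = 0.20)
  )
}

# tolerance used for comparisons with published Monte-Carlo means:
# +/-1% or +/-5 units, whichever is larger
mc_tol <- function(x) pmax(0.01 * abs(x), 5)
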