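# Shared fixture builders: everything is generated in code, no stored data.

# A small, fully valid trait table with hand-picked values.
tiny_trait_table <- function() {
  tibble::tibble(
    species_id = c("sp1", "sp2", "sp3"),
    fecundity = c(1, 5, 9),
    adult_lifetime = c(5, 30, 60),
    voltinism = c(0.5, 1, 3),
    larval_growth_rate = c(16, 100, 186),
    ripe_egg_load = c(1, 4, 9),
    ovigeny_index = c(0, 0.5, 1),
    female_maturation = c(1, 4, 8),
    overwintering_stage = c(0, 3, 7),
    life_cycle_flexibility = c(0, 1, 0),
    flight_period = c(3, 10, 32),
    thermal_tolerance = c(1, 5, 9),
    adult_habitat_range = c(1, 4, 7),
    larval_dietary_breadth = c(1, 2, 4),
    myrmecophily = c(0, 3, 9),
    female_precision = c(1, 5, 9),
    laying_strategy = c(0, 1, 1),
    mate_location = c(1, 4, 7),
    wing_length = c(11, 20, 37.5)
  )
}

# The recovery fixture used across selection and validation tests:
# 2 strong linear terms among 10 candidate traits, n species, chosen noise.
recovery_candidates <- function() {
  c("voltinism", "ovigeny_index", "fecundity", "flight_period",
    "adult_lifetime", "myrmecophily", "mate_location", "thermal_tolerance",
    "ripe_egg_load", "female_precision")
}

recovery_true_model <- function(noise_sd = 0.25,
                                element = "mean_distance",
                                coefficients = c(1, -1)) {
  true_model(
    element,
    model_terms(linear = c("voltinism", "ovigeny_index")),
    coefficients = coefficients,
    intercept = 0,
    noise_sd = noise_sd
  )
}

recovery_dataset <- function(n = 29, noise_sd = 0.25, seed = 1,
                             element = "mean_distance") {
  traits <- simulate_trait_table(n, seed = seed)
  model <- recovery_true_model(noise_sd = noise_sd, element = element)
  disp <- simulate_responses(traits, model, seed = seed + 1000L)
  syndrome_data(traits, disp, element, candidates = recovery_candidates())
}
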