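# Small in-code fixtures shared across test files.

# three-line sandwich recipe used by the printed worked example
sandwich_db <- function() {
  tibble::tibble(
    dish_id = "ham_vegetable_sandwich_black_bread",
    food_group = c("red_meat_pork", "vegetables", "whole_grains"),
    proportion = c(0.20, 0.10, 0.50),
    gated = FALSE
  )
}

# gated cereal: whole-grain share suppressed, added sugars kept
cereal_db <- function() {
  tibble::tibble(
    dish_id = "sweet_cereal",
    food_group = c("whole_grains", "added_sugars"),
    proportion = c(0.60, 0.25),
    gated = c(TRUE, FALSE)
  )
}

# a two-country toy intake table with known strata
toy_intake <- function() {
  g <- phd_food_groups()
  base <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:10),
    country = rep(c("AA", "BB"), each = 5),
    sex = rep(c("women", "men"), 5),
    age_band = rep(c("18-44", "45-64"), each = 5),
    education = "lower",
    energy_kcal = 2500
  )
  for (gr in g) base[[gr]] <- 50
  base
}

# margins covering exactly the strata present in toy_intake()
toy_population <- function() {
  dplyr::distinct(toy_intake(), country, sex, age_band) |>
    dplyr::mutate(population_count = 1000)
}

# a diet at every group's target
target_diet <- function(targets = phd_targets()) {
  stats::setNames(
    targets$target[match(phd_food_groups(), targets$food_group)],
    phd_food_groups()
  )
}
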