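#' Configuration for the synthetic multi-country dietary survey
#'
#' Defines the generating conditions for a synthetic cohort emulating the
#' structure of harmonised European 24-hour-recall surveys: nine countries
#' with national population sizes and recall-day counts, per-food-group
#' European mean intakes (g/d at 2500 kcal) with between-country dispersion,
#' right-skewed (log-normal) individual variation, demographic composition,
#' additive demographic effects on adherence-relevant food groups (women
#' above men, older above younger, higher education above lower), an energy
#' distribution with a misreporter fraction outside the plausibility bounds,
#' and a share of intake delivered as composite-dish records so the recipe
#' engine is exercised end to end.
#'
#' Central values are calibrated to the pooled European means and SDs of the
#' food groups (e.g. vegetables 189.6 +/- 24.6 g/d, fruits 177.1 +/- 47.7
#' g/d); the SDs parameterise between-country spread of country means. The
#' demographic mix is 56.1% women, age shares 39.8/35.7/24.5% and education
#' shares 59.3/40.7%; the misreporter fraction defaults to 1.6%. Education
#' is unavailable ("missing") in the two countries mirroring surveys without
#' it.
#'
#' @param n_per_country Participants per country (default 500).
#' @param country_spread Multiplier on the between-country coefficient of
#'   variation; 0 collapses all country means onto the European means.
#' @param within_cv Within-country individual log-normal coefficient of
#'   variation (default 0.6); 0 gives every participant the group mean.
#' @param misreporter_fraction Share of participants whose energy is drawn
#'   outside their sex-specific plausibility bounds.
#' @param dish_fraction Share of participants with part of their intake
#'   expressed as composite-dish records.
#' @return A list of class `phd_sim_config`.
#' @export
phd_sim_config <- function(n_per_country = 500, country_spread = 1,
                           within_cv = 0.6, misreporter_fraction = 0.016,
                           dish_fraction = 0.25) {
  stopifnot(n_per_country >= 1, country_spread >= 0, within_cv >= 0,
            misreporter_fraction >= 0, misreporter_fraction < 1,
            dish_fraction >= 0, dish_fraction <= 1)
  countries <- tibble::tribble(
    ~country, ~population_count, ~recall_days, ~has_education,
    "EE",   1050000, 2, TRUE,
    "FI",   4400000, 2, FALSE,
    "FR",  52000000, 3, TRUE,
    "HU",   7900000, 2, TRUE,
    "NL",  14100000, 2, TRUE,
    "PT",   8600000, 2, TRUE,
    "ES",  38800000, 2, TRUE,
    "CH",   7100000, 2, TRUE,
    "UK",  53000000, 4, FALSE
  )
  countries$n <- as.integer(n_per_country)
  group_means <- c(
    whole_grains = 31.5, vegetables = 189.6, fruits = 177.1, tubers = 66.2,
    legumes = 27.5, nuts = 5.2, unsaturated_oils = 14.0, dairy = 263.8,
    red_meat_beef_lamb = 40.4, red_meat_pork = 42.0, poultry = 49.9,
    eggs = 22.8, fish = 38.6, saturated_fats = 28.2, added_sugars = 54.6
  )
  group_sds <- c(
    whole_grains = 19.5, vegetables = 24.6, fruits = 47.7, tubers = 13.6,
    legumes = 12.8, nuts = 3.2, unsaturated_oils = 7.4, dairy = 85.6,
    red_meat_beef_lamb = 10.5 * 40.4 / 82.5, red_meat_pork = 10.5 * 42.0 / 82.5,
    poultry = 17.8, eggs = 7.0, fish = 17.4, saturated_fats = 9.3,
    added_sugars = 9.5
  )
  effects <- list(
    men = c(red_meat_beef_lamb = 15, red_meat_pork = 15, added_sugars = 12,
            saturated_fats = 6, vegetables = -40, fruits = -40,
            whole_grains = -8, legumes = -6, nuts = -2),
    age_45_64 = c(vegetables = 15, fruits = 25, fish = 6,
                  red_meat_beef_lamb = -2, red_meat_pork = -3,
                  added_sugars = -6),
    age_65_plus = c(vegetables = 25, fruits = 50, fish = 10, whole_grains = 4,
                    red_meat_beef_lamb = -4, red_meat_pork = -6,
                    added_sugars = -10),
    higher_edu = c(vegetables = 20, fruits = 20, nuts = 1.5, whole_grains = 5,
                   red_meat_beef_lamb = -4, red_meat_pork = -6,
                   added_sugars = -6)
  )
  structure(list(
    countries = countries,
    group_means = group_means,
    group_cvs = group_sds / group_means,
    within_cv = within_cv,
    country_spread = country_spread,
    p_women = 0.561,
    age_shares = c("18-44" = 0.398, "45-64" = 0.357, ">=65" = 0.245),
    edu_shares = c(lower = 0.593, higher = 0.407),
    pop_p_women = 0.52,
    pop_age_shares = c("18-44" = 0.45, "45-64" = 0.33, ">=65" = 0.22),
    effects = effects,
    energy = list(women = c(mean = 1900, sd = 350),
                  men = c(mean = 2400, sd = 450)),
    misreporter_fraction = misreporter_fraction,
    dish_fraction = dish_fraction,
    dish_id = "ham_vegetable_sandwich_black_bread",
    dish_route_fraction = 0.5
  ), class = "phd_sim_config")
}

#' Expected ELD-I contrasts implied by a generator configuration
#'
#' Because the ELD-I component is exactly linear in intake, an additive
#' shift `d_g` on the mean intake of group `g` shifts the expected ELD-I
#' total by `sum_g dir_g * d_g / target_g`. This converts the configured
#' demographic effects into the regression contrasts the cohort analytics
#' should recover.
#'
#' @param config A [phd_sim_config()].
#' @param targets Target table (default [phd_targets()]).
#' @return Named numeric vector of expected ELD-I point differences versus
#'   the reference class (women, 18-44, lower education).
#' @export
expected_eldi_contrasts <- function(config, targets = phd_targets()) {
  vapply(config$effects, function(shift) {
    # fold the red-meat sub-group shifts into the total scored by ELD-I
    rm_shift <- sum(shift[c("red_meat_beef_lamb", "red_meat_pork")], na.rm = TRUE)
    shift <- shift[setdiff(names(shift), c("red_meat_beef_lamb", "red_meat_pork"))]
    if (rm_shift != 0) shift <- c(shift, red_meat = rm_shift)
    sum(vapply(names(shift), function(g) {
      row <- target_row(targets, g)
      dir <- if (row$direction == "encouraged") 1 else -1
      dir * shift[[g]] / row$target
    }, numeric(1)))
  }, numeric(1))
}

# internal: truncated-normal draws via inverse CDF (deterministic given RNG)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n)
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

#' Generate a synthetic multi-country dietary survey
#'
#' Draws a full survey dataset under a [phd_sim_config()]: country means are
#' drawn log-normally around the configured European means with the
#' configured between-country spread (mean-preserving); individual
#' standardised intakes are log-normal around the country mean plus the
#' participant's additive demographic shifts; energy is truncated-normal
#' inside the sex-specific plausibility bounds for plausible reporters and
#' forced outside them for misreporters; raw intakes are the standardised
#' intakes rescaled to the participant's energy. For a configured fraction
#' of participants, part of the raw intake is re-expressed as daily
#' composite-dish records (subtracting the dish allocation from the direct
#' intakes), so disaggregating and recombining reproduces the drawn intake
#' exactly.
#'
#' Identical seeds produce identical surveys.
#'
#' @param config A [phd_sim_config()].
#' @param seed Integer seed controlling all randomness.
#' @param recipes Recipe database used for dish routing; default the
#'   packaged demo database.
#' @return List of class `phd_survey`: `intake` (per-participant direct
#'   intakes, raw g/d, with demographics and energy), `dishes` (per-day dish
#'   records), `population` (age-sex margins per country), `truth` (the
#'   generating parameters: drawn country means, configured effects and the
#'   analytically expected ELD-I contrasts).
#' @export
generate_survey <- function(config = phd_sim_config(), seed = 1L,
                            recipes = phdiet_demo_recipes()) {
  stopifnot(inherits(config, "phd_sim_config"))
  set.seed(seed)
  groups <- phd_food_groups()
  M <- config$group_means[groups]
  if (any(M <= 0)) stop("configured group means must be positive", call. = FALSE)
  cv_between <- config$country_spread * config$group_cvs[groups]
  n_country <- nrow(config$countries)

  # country-level means, mean-preserving log-normal spread
  sg <- sqrt(log(1 + cv_between^2))
  z <- matrix(stats::rnorm(n_country * length(groups)), nrow = n_country)
  cm <- matrix(rep(M, each = n_country), nrow = n_country) *
    exp(sweep(z, 2, sg, `*`) - matrix(rep(sg^2 / 2, each = n_country),
                                      nrow = n_country))
  dimnames(cm) <- list(config$countries$country, groups)

  sigma_w <- sqrt(log(1 + config$within_cv^2))
  parts <- vector("list", n_country)
  for (ci in seq_len(n_country)) {
    crow <- config$countries[ci, ]
    n <- crow$n
    sex <- ifelse(stats::runif(n) < config$p_women, "women", "men")
    age <- sample(names(config$age_shares), n, replace = TRUE,
                  prob = config$age_shares)
    edu <- if (crow$has_education) {
      sample(names(config$edu_shares), n, replace = TRUE,
             prob = config$edu_shares)
    } else {
      rep("missing", n)
    }
    # additive demographic shifts per group
    shift <- matrix(0, nrow = n, ncol = length(groups),
                    dimnames = list(NULL, groups))
    apply_shift <- function(shift, who, eff) {
      for (g in names(eff)) shift[who, g] <- shift[who, g] + eff[[g]]
      shift
    }
    shift <- apply_shift(shift, sex == "men", config$effects$men)
    shift <- apply_shift(shift, age == "45-64", config$effects$age_45_64)
    shift <- apply_shift(shift, age == ">=65", config$effects$age_65_plus)
    shift <- apply_shift(shift, edu == "higher", config$effects$higher_edu)
    mu <- pmax(sweep(shift, 2, cm[ci, ], `+`),
               matrix(rep(0.05 * cm[ci, ], each = n), nrow = n))
    x_std <- if (sigma_w > 0) {
      matrix(stats::rlnorm(n * length(groups),
                           meanlog = log(mu) - sigma_w^2 / 2,
                           sdlog = sigma_w), nrow = n)
    } else {
      mu
    }
    colnames(x_std) <- groups

    b <- energy_bounds()
    lo <- ifelse(sex == "men", b$men[1], b$women[1])
    hi <- ifelse(sex == "men", b$men[2], b$women[2])
    emean <- ifelse(sex == "men", config$energy$men["mean"],
                    config$energy$women["mean"])
    esd <- ifelse(sex == "men", config$energy$men["sd"],
                  config$energy$women["sd"])
    energy <- rtruncnorm(n, emean, esd, lo, hi)
    mis <- stats::runif(n) < config$misreporter_fraction
    side_low <- stats::runif(n) < 0.5
    e_low <- stats::runif(n, 200, lo - 1)
    e_high <- stats::runif(n, hi + 1, hi + 1500)
    energy[mis & side_low] <- e_low[mis & side_low]
    energy[mis & !side_low] <- e_high[mis & !side_low]

    x_raw <- x_std * energy / 2500

    tab <- tibble::tibble(
      participant_id = sprintf("%s-%04d", crow$country, seq_len(n)),
      country = crow$country, sex = sex, age_band = age, education = edu,
      energy_kcal = energy, n_days = crow$recall_days,
      misreporter = mis
    )
    parts[[ci]] <- dplyr::bind_cols(tab, tibble::as_tibble(x_raw))
  }
  intake <- dplyr::bind_rows(parts)

  # dish routing: move part of some participants' intake into dish records
  lines <- recipes[recipes$dish_id == config$dish_id & !recipes$gated, ]
  if (nrow(lines) == 0) stop("routing dish absent from recipe database", call. = FALSE)
  routed <- stats::runif(nrow(intake)) < config$dish_fraction
  xmat <- as.matrix(intake[, lines$food_group, drop = FALSE])
  q <- config$dish_route_fraction *
    apply(sweep(xmat, 2, lines$proportion, `/`), 1, min)
  q[!routed] <- 0
  alloc <- q %o% stats::setNames(lines$proportion, lines$food_group)
  for (g in lines$food_group) {
    intake[[g]] <- intake[[g]] - alloc[, g]
  }
  dish_rows <- which(routed & q > 0)
  nd <- intake$n_days[dish_rows]
  dishes <- tibble::tibble(
    participant_id = rep(intake$participant_id[dish_rows], times = nd),
    day = as.integer(sequence(nd)),
    dish_id = if (length(dish_rows) > 0) config$dish_id else character(0),
    grams = rep(q[dish_rows], times = nd)
  )

  population <- tidyr::expand_grid(
    country = config$countries$country,
    sex = c("women", "men"),
    age_band = names(config$pop_age_shares)
  )
  population$population_count <- {
    pc <- config$countries$population_count[
      match(population$country, config$countries$country)]
    psex <- ifelse(population$sex == "women", config$pop_p_women,
                   1 - config$pop_p_women)
    page <- config$pop_age_shares[population$age_band]
    round(pc * psex * page)
  }

  truth <- list(
    seed = seed,
    n_per_country = config$countries$n[1],
    country_spread = config$country_spread,
    within_cv = config$within_cv,
    misreporter_fraction = config$misreporter_fraction,
    dish_fraction = config$dish_fraction,
    group_means = as.list(M),
    country_means = as.data.frame(cm),
    effects = lapply(config$effects, as.list),
    expected_eldi_contrasts = as.list(expected_eldi_contrasts(config))
  )
  structure(list(intake = intake, dishes = dishes, population = population,
                 truth = truth),
            class = "phd_survey")
}

#' Write a synthetic survey to disk
#'
#' Emits `intake.csv`, `dishes.csv`, `population.csv` and `truth.json` into
#' a directory. Identical surveys produce byte-identical files.
#'
#' @param survey A `phd_survey` from [generate_survey()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(survey, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  phd_write_csv(survey$intake, file.path(dir, "intake.csv"))
  phd_write_csv(survey$dishes, file.path(dir, "dishes.csv"))
  phd_write_csv(survey$population, file.path(dir, "population.csv"))
  jsonlite::write_json(survey$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Worked-example fixtures
#'
#' Deterministic fixtures used throughout the documentation and tests: the
#' 200 g ham-and-vegetable sandwich dish record (20% red meat, 10%
#' vegetables, 50% whole grains), a fully compliant diet (every group at its
#' full-compliance intake: WISH 130, ELI 42, ELD-I 0), a worst-case diet
#' (encouraged foods at zero, limited foods beyond their zero-score
#' breakpoints), and two red-meat deviation diets (81.4 and 143.8 g/d of
#' total red meat with every other group at target).
#'
#' @param targets Target table (default [phd_targets()]).
#' @return List: `sandwich_record`, `compliant_diet`, `worst_diet`,
#'   `red_meat_low_diet`, `red_meat_high_diet` (named intake vectors over
#'   the stored food groups, g/d at 2500 kcal).
#' @export
generate_worked_examples <- function(targets = phd_targets()) {
  at_target <- stats::setNames(
    targets$target[match(phd_food_groups(), targets$food_group)],
    phd_food_groups()
  )
  worst <- stats::setNames(numeric(length(phd_food_groups())), phd_food_groups())
  worst[c("red_meat_beef_lamb", "red_meat_pork")] <- 60 # total 120 > 112
  worst["saturated_fats"] <- 50
  worst["added_sugars"] <- 130
  worst["tubers"] <- 210
  worst["poultry"] <- 120
  worst["eggs"] <- 60
  worst["dairy"] <- 1100
  rm_diet <- function(total) {
    d <- at_target
    d[c("red_meat_beef_lamb", "red_meat_pork")] <- total / 2
    d
  }
  list(
    sandwich_record = tibble::tibble(
      participant_id = "example", day = 1L,
      dish_id = "ham_vegetable_sandwich_black_bread", grams = 200
    ),
    compliant_diet = at_target,
    worst_diet = worst,
    red_meat_low_diet = rm_diet(81.4),
    red_meat_high_diet = rm_diet(143.8)
  )
}

#' Packaged demo recipe database
#'
#' A small standardised recipe database (15 dishes) shipped with the
#' package, including the ham-and-vegetable sandwich worked example and
#' dishes with gated encouraged-food allocations (e.g. sweetened whole-grain
#' cereal credited only to added sugars).
#'
#' @return Recipe tibble (see [read_recipe_db()]).
#' @export
phdiet_demo_recipes <- function() {
  read_recipe_db(system.file("extdata", "recipes_demo.csv", package = "phdiet",
                             mustWork = TRUE))
}
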