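#' Standardise intakes to grams per 2500 kcal
#'
#' Scales each food-group intake by `2500 / energy_kcal`, expressing diets at
#' the PHD's 2500 kcal reference so that intakes are comparable across
#' participants with different energy intakes. Idempotent on data already at
#' 2500 kcal.
#'
#' @param intakes Named numeric vector (or data frame of food-group columns)
#'   of raw intakes in g/d.
#' @param energy_kcal Daily energy intake(s), kcal/d, strictly positive.
#'   Recycled against data-frame rows.
#' @return Intakes rescaled to g per 2500 kcal, same shape as `intakes`.
#' @export
#' @examples
#' standardize_energy(c(vegetables = 100), 2000) # 125 g
standardize_energy <- function(intakes, energy_kcal) {
  if (any(!is.finite(energy_kcal) | energy_kcal <= 0)) {
    stop("energy_kcal must be finite and > 0", call. = FALSE)
  }
  if (is.data.frame(intakes)) {
    return(intakes * (2500 / energy_kcal))
  }
  intakes * (2500 / energy_kcal)
}

#' Energy misreporting bounds
#'
#' Sex-specific plausibility bounds on reported daily energy: 800-4200 kcal
#' for men, 600-3500 kcal for women. Exclusion is stated with strict
#' inequalities, so boundary values are retained.
#'
#' @return Named list `men = c(lo, hi)`, `women = c(lo, hi)` (kcal/d).
#' @export
energy_bounds <- function() {
  list(men = c(800, 4200), women = c(600, 3500))
}

#' Exclude extreme energy reporters
#'
#' Splits a participant table into plausible reporters and excluded extreme
#' reporters using [energy_bounds()] applied to each participant's mean daily
#' energy. Boundary values are kept.
#'
#' @param participants Tibble with at least `sex` (`"women"`/`"men"`) and
#'   `energy_kcal` columns.
#' @return List with `kept` and `excluded` tibbles (excluded rows retain all
#'   columns so ids can be logged).
#' @export
exclude_extreme_energy <- function(participants) {
  stopifnot(all(c("sex", "energy_kcal") %in% names(participants)))
  if (!all(participants$sex %in% c("women", "men"))) {
    stop("sex must be 'women' or 'men' for every participant", call. = FALSE)
  }
  b <- energy_bounds()
  lo <- ifelse(participants$sex == "men", b$men[1], b$women[1])
  hi <- ifelse(participants$sex == "men", b$men[2], b$women[2])
  keep <- participants$energy_kcal >= lo & participants$energy_kcal <= hi
  list(kept = participants[keep, , drop = FALSE],
       excluded = participants[!keep, , drop = FALSE])
}

#' Post-stratification weights against population margins
#'
#' Assigns each participant a weight proportional to the under- or
#' over-representation of their sex-by-age stratum relative to national
#' population margins, rescaled so weights sum to the country's sample size.
#' Within the country, the weighted sex-age distribution then matches the
#' population distribution exactly. Weighting uses age and sex only (not
#' education).
#'
#' @param participants Tibble for one country with `sex` and `age_band`
#'   columns.
#' @param margins Tibble with `sex`, `age_band`, `population_count` for the
#'   same country. Strata present in the margins but absent from the sample
#'   are dropped from the margins with a warning (their weight is undefined);
#'   a sampled stratum with zero population count is an error.
#' @return `participants` with a `weight` column appended.
#' @export
poststratification_weights <- function(participants, margins) {
  stopifnot(all(c("sex", "age_band") %in% names(participants)),
            all(c("sex", "age_band", "population_count") %in% names(margins)))
  n <- nrow(participants)
  if (n == 0) stop("no participants to weight", call. = FALSE)
  samp_key <- paste(participants$sex, participants$age_band, sep = "\r")
  marg_key <- paste(margins$sex, margins$age_band, sep = "\r")
  if (anyDuplicated(marg_key)) stop("duplicate strata in margins", call. = FALSE)
  missing_marg <- setdiff(unique(samp_key), marg_key)
  if (length(missing_marg) > 0) {
    stop("sampled stratum absent from population margins: ",
         paste(gsub("\r", "/", missing_marg), collapse = ", "), call. = FALSE)
  }
  empty <- !(marg_key %in% samp_key)
  if (any(empty)) {
    warning("stratum present in population but not sampled; dropped from margins: ",
            paste(gsub("\r", "/", marg_key[empty]), collapse = ", "),
            call. = FALSE)
    margins <- margins[!empty, , drop = FALSE]
    marg_key <- marg_key[!empty]
  }
  if (any(margins$population_count <= 0)) {
    stop("sampled stratum has non-positive population count", call. = FALSE)
  }
  pop_share <- margins$population_count / sum(margins$population_count)
  samp_share <- as.numeric(table(samp_key)[marg_key]) / n
  w_stratum <- stats::setNames(pop_share / samp_share, marg_key)
  w <- as.numeric(w_stratum[samp_key])
  participants$weight <- w * n / sum(w)
  participants
}

#' Population-weighted pooled mean across countries
#'
#' Pools per-country weighted means so each country contributes in
#' proportion to its national population: `pooled = sum_c p_c * mean_c` with
#' `p_c` the population share among included countries. The result is a
#' convex combination of the country means.
#'
#' @param country_means Tibble with a `country` column and one numeric column
#'   per pooled quantity (e.g. food-group means).
#' @param country_populations Named numeric vector (or tibble with `country`,
#'   `population_count`) of national population sizes.
#' @return One-row tibble of pooled values over the numeric columns.
#' @export
pooled_european_mean <- function(country_means, country_populations) {
  if (is.data.frame(country_populations)) {
    country_populations <- stats::setNames(
      country_populations$population_count, country_populations$country)
  }
  pops <- country_populations[country_means$country]
  if (any(is.na(pops))) {
    stop("population missing for country: ",
         paste(country_means$country[is.na(pops)], collapse = ", "),
         call. = FALSE)
  }
  if (sum(pops) <= 0) stop("country populations sum to zero", call. = FALSE)
  p <- pops / sum(pops)
  num <- vapply(country_means[setdiff(names(country_means), "country")],
                function(x) sum(p * x), numeric(1))
  tibble::as_tibble(as.list(num))
}

#' Harmonise a raw intake table into the analysis-ready dataset
#'
#' Applies, in order: exclusion of extreme energy reporters, energy
#' standardisation to g per 2500 kcal (appending `<group>_std` columns), and
#' per-country post-stratification weights from age-sex population margins.
#' The two first steps commute (exclusion depends only on raw energy).
#'
#' @param intake Tibble with `participant_id`, `country`, `sex`, `age_band`,
#'   `education`, `energy_kcal` and one raw g/d column per food group.
#' @param population Tibble with `country`, `sex`, `age_band`,
#'   `population_count`.
#' @return List: `participants` (kept rows with `_std` columns and `weight`),
#'   `excluded` (dropped rows), `n_input`, `n_kept`, `n_excluded`.
#' @export
harmonize_intake <- function(intake, population) {
  groups <- intersect(phd_food_groups(), names(intake))
  if (length(groups) == 0) stop("no food-group columns in intake table", call. = FALSE)
  split_rows <- exclude_extreme_energy(intake)
  kept <- split_rows$kept
  std <- standardize_energy(kept[groups], kept$energy_kcal)
  names(std) <- paste0(groups, "_std")
  kept <- dplyr::bind_cols(kept, std)
  kept <- dplyr::bind_rows(lapply(split(kept, kept$country), function(d) {
    m <- population[population$country == d$country[1], , drop = FALSE]
    poststratification_weights(d, m)
  }))
  list(participants = tibble::as_tibble(kept),
       excluded = tibble::as_tibble(split_rows$excluded),
       n_input = nrow(intake), n_kept = nrow(kept),
       n_excluded = nrow(split_rows$excluded))
}

#' Weighted mean and spread helpers
#'
#' `weighted_mean()` is the weighted arithmetic mean; `weighted_sd()` the
#' weighted standard deviation with a small-sample correction
#' (`sum w (x - m)^2 / (sum w - 1)`, appropriate for weights normalised to
#' the sample size); `weighted_se()` the standard error of the weighted mean
#' (`sqrt(sum w^2 (x - m)^2) / sum w`).
#'
#' @param x Numeric vector.
#' @param w Non-negative weights, same length.
#' @return A single number.
#' @name weighted_moments
#' @export
weighted_mean <- function(x, w) sum(w * x) / sum(w)

#' @rdname weighted_moments
#' @export
weighted_sd <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(sum(w * (x - m)^2) / (sum(w) - 1))
}

#' @rdname weighted_moments
#' @export
weighted_se <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(sum((w * (x - m))^2)) / sum(w)
}
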