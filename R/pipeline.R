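#' Combine dish records with direct intakes
#'
#' Disaggregates a survey's composite-dish records through the recipe
#' database, averages them over each participant's recall days, and adds
#' the result to the direct food-group columns, yielding the full raw
#' intake table the harmonisation stage expects.
#'
#' @param survey A `phd_survey` from [generate_survey()], or any list with
#'   `intake` and `dishes` elements of the same shape.
#' @param recipes Recipe tibble.
#' @param lenient Passed to [disaggregate_dishes()].
#' @return The `intake` tibble with dish-derived grams folded into the
#'   food-group columns.
#' @export
combine_survey_intake <- function(survey, recipes = phdiet_demo_recipes(),
                                  lenient = FALSE) {
  intake <- survey$intake
  dishes <- survey$dishes
  if (is.null(dishes) || nrow(dishes) == 0) return(intake)
  dish_means <- aggregate_participant_days(dishes, recipes, lenient = lenient)
  idx <- match(intake$participant_id, dish_means$participant_id)
  for (g in phd_food_groups()) {
    add <- dish_means[[g]][idx]
    add[is.na(add)] <- 0
    intake[[g]] <- intake[[g]] + add
  }
  intake
}

#' Cohort analytics report
#'
#' Runs the comparative statistics over a scored, harmonised cohort:
#' per-country deviations from the population-weighted pooled mean with
#' intercept-only significance tests (for each standardised food-group
#' intake and each index total), DerSimonian-Laird heterogeneity across
#' countries, general dominance analysis of index components, per-country
#' demographic regressions with eta-squared effect sizes, and between-index
#' concordance (pooled and per country).
#'
#' @param scored Output of [score_cohort()].
#' @param harmonized Output of [harmonize_intake()].
#' @param population Population margins tibble (`country`,
#'   `population_count` summed over strata).
#' @param weighted_concordance Use survey weights in the concordance
#'   correlations (quintile assignment itself is rank-based, unweighted).
#' @param dominance Set `FALSE` to skip the dominance stage (the most
#'   expensive one).
#' @param dominance_seed Seed for sampled dominance mode (only used above 16
#'   predictors).
#' @return List of tibbles: `deviations`, `heterogeneity`, `dominance`,
#'   `regression`, `eta_squared`, `concordance`.
#' @export
analyze_cohort <- function(scored, harmonized, population,
                           weighted_concordance = FALSE, dominance = TRUE,
                           dominance_seed = 1L) {
  parts <- harmonized$participants
  scores <- scored$scores
  country_pop <- dplyr::summarise(population,
                                  population_count = sum(.data$population_count),
                                  .by = "country")
  std_cols <- paste0(phd_food_groups(), "_std")
  value_cols <- c(stats::setNames(std_cols, phd_food_groups()),
                  wish = "wish_total", eli = "eli_total", eldi = "eldi_total")
  dat <- dplyr::left_join(
    parts[, c("participant_id", "country", "weight", std_cols)],
    scores[, c("participant_id", "wish_total", "eli_total", "eldi_total")],
    by = "participant_id"
  )

  country_means <- dplyr::summarise(
    dat,
    dplyr::across(dplyr::all_of(unname(value_cols)),
                  ~ weighted_mean(.x, weight)),
    .by = "country"
  )
  pooled <- pooled_european_mean(country_means, country_pop)

  deviations <- dplyr::bind_rows(lapply(names(value_cols), function(v) {
    col <- value_cols[[v]]
    dplyr::bind_rows(lapply(split(dat, dat$country), function(d) {
      country_deviation(d[[col]], d$weight, pooled[[col]], d$country[1])
    })) |> dplyr::mutate(variable = v, .before = 1)
  }))

  heterogeneity <- dplyr::bind_rows(lapply(names(value_cols), function(v) {
    col <- value_cols[[v]]
    per <- dplyr::summarise(dat,
                            est = weighted_mean(.data[[col]], .data$weight),
                            se = weighted_se(.data[[col]], .data$weight),
                            .by = "country")
    random_effects_heterogeneity(per$est, per$se) |>
      dplyr::mutate(variable = v, .before = 1)
  }))

  dom_tbl <- tibble::tibble(index = character(), predictor = character(),
                            dominance = numeric(), rank = integer(),
                            r2_full = numeric(), dropped = character())
  if (dominance) {
    comp_sets <- list(wish = paste0("wish_", wish_groups()),
                      eli = paste0("eli_", eli_groups()),
                      eldi = paste0("eldi_", eldi_groups()))
    dom_tbl <- dplyr::bind_rows(lapply(names(comp_sets), function(ix) {
      X <- as.matrix(scores[, comp_sets[[ix]]])
      keep <- apply(X, 2, stats::sd) > 0
      res <- general_dominance(scores[[paste0(ix, "_total")]],
                               X[, keep, drop = FALSE],
                               weights = scores$weight, seed = dominance_seed)
      res$weights |>
        dplyr::mutate(index = ix, r2_full = res$r2_full,
                      dropped = paste(colnames(X)[!keep], collapse = ";"),
                      .before = 1)
    }))
  }

  reg_parts <- lapply(split(seq_len(nrow(scores)), scores$country), function(i) {
    demo <- parts[match(scores$participant_id[i], parts$participant_id),
                  c("age_band", "sex", "education")]
    lapply(c(wish = "wish_total", eli = "eli_total", eldi = "eldi_total"),
           function(col) {
             demographic_regression(scores[[col]][i], demo, scores$weight[i])
           })
  })
  regression <- dplyr::bind_rows(lapply(names(reg_parts), function(cty) {
    dplyr::bind_rows(lapply(names(reg_parts[[cty]]), function(ix) {
      reg_parts[[cty]][[ix]]$coefficients |>
        dplyr::mutate(country = cty, index = ix, .before = 1)
    }))
  }))
  eta_squared <- dplyr::bind_rows(lapply(names(reg_parts), function(cty) {
    dplyr::bind_rows(lapply(names(reg_parts[[cty]]), function(ix) {
      reg_parts[[cty]][[ix]]$eta_squared |>
        dplyr::mutate(country = cty, index = ix, .before = 1)
    }))
  }))

  conc_of <- function(d) {
    cc <- index_concordance(
      d[, c("wish_total", "eli_total", "eldi_total")],
      weights = if (weighted_concordance) d$weight else NULL
    )
    pairs <- utils::combn(c("wish_total", "eli_total", "eldi_total"), 2)
    dplyr::bind_rows(apply(pairs, 2, function(pr) {
      tibble::tibble(index_a = pr[1], index_b = pr[2],
                     r = cc$correlation[pr[1], pr[2]],
                     r_weighted = cc$correlation_weighted[pr[1], pr[2]],
                     quintile_agreement_pct = cc$quintile_agreement[pr[1], pr[2]])
    }))
  }
  concordance <- dplyr::bind_rows(
    dplyr::mutate(conc_of(scores), stratum = "pooled", .before = 1),
    dplyr::bind_rows(lapply(split(scores, scores$country), conc_of),
                     .id = "stratum")
  )

  list(deviations = deviations, heterogeneity = heterogeneity,
       dominance = dom_tbl, regression = regression,
       eta_squared = eta_squared, concordance = concordance)
}

#' Run the full PHD adherence pipeline
#'
#' Orchestrates simulate -> disaggregate -> harmonize -> score -> analyze on
#' a synthetic survey and writes every intermediate and final table to
#' `out_dir`, together with a `manifest.json` recording the package version,
#' seed, per-stage row counts (including energy exclusions) and MD5
#' checksums of every written file. Re-running with the same seed and
#' configuration reproduces every file byte for byte.
#'
#' @param out_dir Output directory.
#' @param config Generator configuration ([phd_sim_config()]).
#' @param seed Integer seed for all randomness.
#' @param recipes Recipe database.
#' @param targets Target table.
#' @param countries Optional character vector restricting the analysis to a
#'   subset of countries (a sensitivity-style filter); the manifest records
#'   it.
#' @param lenient Lenient mode for unknown dishes.
#' @param weighted_concordance Passed to [analyze_cohort()].
#' @param dominance Passed to [analyze_cohort()].
#' @return Invisibly, a list with the in-memory `survey`, `harmonized`,
#'   `scored`, `report` and `manifest`.
#' @export
run_phd_pipeline <- function(out_dir, config = phd_sim_config(), seed = 1L,
                             recipes = phdiet_demo_recipes(),
                             targets = phd_targets(), countries = NULL,
                             lenient = FALSE, weighted_concordance = FALSE,
                             dominance = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  survey <- generate_survey(config, seed = seed, recipes = recipes)
  write_survey(survey, out_dir)

  combined <- combine_survey_intake(survey, recipes, lenient = lenient)
  if (!is.null(countries)) {
    combined <- combined[combined$country %in% countries, , drop = FALSE]
  }
  population <- survey$population
  if (!is.null(countries)) {
    population <- population[population$country %in% countries, , drop = FALSE]
  }
  phd_write_csv(combined, file.path(out_dir, "combined_intake.csv"))

  harmonized <- harmonize_intake(combined, population)
  phd_write_csv(harmonized$participants, file.path(out_dir, "harmonized.csv"))
  phd_write_csv(harmonized$excluded, file.path(out_dir, "excluded.csv"))

  country_pop <- dplyr::summarise(population,
                                  population_count = sum(.data$population_count),
                                  .by = "country")
  scored <- score_cohort(harmonized$participants, targets,
                         country_populations = country_pop)
  phd_write_csv(scored$scores, file.path(out_dir, "scores.csv"))
  phd_write_csv(scored$index_summary, file.path(out_dir, "index_summary.csv"))
  phd_write_csv(scored$component_summary,
                   file.path(out_dir, "component_summary.csv"))

  report <- analyze_cohort(scored, harmonized, population,
                           weighted_concordance = weighted_concordance,
                           dominance = dominance, dominance_seed = seed)
  for (nm in names(report)) {
    phd_write_csv(report[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }

  files <- sort(list.files(out_dir, pattern = "\\.(csv|json)$"))
  files <- setdiff(files, "manifest.json")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(
    package = "phdiet",
    version = as.character(utils::packageVersion("phdiet")),
    seed = seed,
    country_filter = if (is.null(countries)) "none" else countries,
    rows = list(
      generated = nrow(survey$intake),
      dish_records = nrow(survey$dishes),
      harmonize_input = harmonized$n_input,
      harmonize_kept = harmonized$n_kept,
      harmonize_excluded = harmonized$n_excluded,
      scored = nrow(scored$scores)
    ),
    checksums = as.list(stats::setNames(unname(sums), files))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(survey = survey, harmonized = harmonized, scored = scored,
                 report = report, manifest = manifest))
}
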