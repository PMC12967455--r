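#' Food-group compliance with the PHD target
#'
#' Compliance is `100 * intake / target` (%): 100% is full adherence, values
#' above 100% mean consumption above the target, below 100% consumption
#' below it. Linear in intake.
#'
#' @param intake Intake in g/d (vectorised), non-negative.
#' @param target PHD target in g/d, strictly positive.
#' @return Compliance percentage(s).
#' @export
#' @examples
#' compliance_pct(143.8, 28) # 513.57%
compliance_pct <- function(intake, target) {
  if (any(target <= 0)) stop("target must be > 0", call. = FALSE)
  if (any(intake < 0)) stop("intake must be >= 0", call. = FALSE)
  100 * intake / target
}

# internal: piecewise-linear WISH curve, vectorised over intake
wish_curve_score <- function(intake, curve, bp) {
  switch(curve,
    ramp_up = 10 * pmin(intake / bp[1], 1),
    ramp_down = {
      lo <- bp[1]; hi <- bp[2]
      ifelse(intake <= lo, 10, pmax(10 * (hi - intake) / (hi - lo), 0))
    },
    plateau_range = {
      a <- bp[1]; lo <- bp[2]; hi <- bp[3]; b <- bp[4]
      s <- numeric(length(intake))
      s[intake >= lo & intake <= hi] <- 10
      rise <- intake > a & intake < lo
      if (lo > a) s[rise] <- 10 * (intake[rise] - a) / (lo - a)
      fall <- intake > hi & intake < b
      if (b > hi) s[fall] <- 10 * (b - intake[fall]) / (b - hi)
      if (lo == a) s[intake <= lo] <- 10
      s
    },
    stop("unknown wish_curve '", curve, "'", call. = FALSE)
  )
}

#' WISH component score for one food group
#'
#' Scores intake 0 (non-compliance) to 10 (full compliance) along the
#' group's piecewise-linear curve: `ramp_up` rises linearly from 0 at zero
#' intake to 10 at the full-compliance breakpoint and plateaus; `ramp_down`
#' holds 10 up to the lower breakpoint then falls linearly to 0 at the upper
#' one; `plateau_range` is 10 inside the recommended range with linear
#' flanks. Output is clamped to [0, 10].
#'
#' @param intake Intake in g/d (vectorised), non-negative.
#' @param row One-row target table slice carrying `wish_curve` and
#'   `wish_breakpoints`.
#' @return Score(s) in [0, 10].
#' @export
score_wish_component <- function(intake, row) {
  if (any(intake < 0)) stop("intake must be >= 0", call. = FALSE)
  if (is.na(row$wish_curve)) {
    stop("group '", row$food_group, "' has no WISH curve", call. = FALSE)
  }
  bp <- parse_breakpoints(row$wish_breakpoints)
  pmin(pmax(wish_curve_score(intake, row$wish_curve, bp), 0), 10)
}

#' ELI component score for one food group
#'
#' Grades intake 0 (non-compliance) to 3 (high compliance) over the group's
#' three band cut-points. For emphasised foods higher intake bands score
#' higher; for limited foods lower intake bands score higher. An intake
#' exactly on a cut-point is assigned to the higher-adherence side.
#'
#' @param intake Intake in g/d (vectorised), non-negative.
#' @param row One-row target table slice carrying `eli_direction` and
#'   `eli_bands`.
#' @return Integer score(s) in {0, 1, 2, 3}.
#' @export
score_eli_component <- function(intake, row) {
  if (any(intake < 0)) stop("intake must be >= 0", call. = FALSE)
  if (is.na(row$eli_bands) || is.na(row$eli_direction)) {
    stop("group '", row$food_group, "' has no ELI bands", call. = FALSE)
  }
  cuts <- parse_breakpoints(row$eli_bands)
  if (row$eli_direction == "emphasised") {
    (intake >= cuts[1]) + (intake >= cuts[2]) + (intake >= cuts[3])
  } else {
    3L - ((intake > cuts[1]) + (intake > cuts[2]) + (intake > cuts[3]))
  }
}

#' ELD-I component score for one food group
#'
#' Signed relative deviation from the PHD target:
#' `dir * (intake - target) / target`, with `dir = +1` for encouraged and
#' `-1` for limited foods. Zero at target; positive when an encouraged food
#' exceeds its target or a limited food stays below it; unbounded and exactly
#' linear in intake with slope `dir / target`.
#'
#' @param intake Intake in g/d (vectorised), non-negative; expected already
#'   standardised to 2500 kcal.
#' @param row One-row target table slice carrying `target` and `direction`.
#' @return Signed score(s).
#' @export
#' @examples
#' tab <- phd_targets()
#' score_eldi_component(81.4, tab[tab$food_group == "red_meat", ]) # -1.91
score_eldi_component <- function(intake, row) {
  if (any(row$target <= 0)) stop("target must be > 0", call. = FALSE)
  if (any(intake < 0)) stop("intake must be >= 0", call. = FALSE)
  dir <- if (row$direction == "encouraged") 1 else -1
  dir * (intake - row$target) / row$target
}

# internal: pull intakes for a group set from a named vector, deriving the
# red-meat total; errors name the missing group
intakes_for <- function(intakes, groups) {
  if ("red_meat" %in% groups && !("red_meat" %in% names(intakes))) {
    intakes <- add_red_meat_total(intakes)
  }
  miss <- setdiff(groups, names(intakes))
  if (length(miss) > 0) {
    stop("intake missing for food group(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  intakes[groups]
}

# internal: generic per-diet index scorer
score_index <- function(intakes, targets, groups, component_fn) {
  x <- intakes_for(intakes, groups)
  comp <- vapply(groups, function(g) {
    component_fn(x[[g]], target_row(targets, g))
  }, numeric(1))
  list(components = comp, total = sum(comp))
}

#' Score a diet on the three PHD indices
#'
#' `score_wish()` sums 13 components of 0-10 (total 0-130), `score_eli()`
#' sums 14 graded components of 0-3 (total 0-42), and `score_eldi()` sums 14
#' signed relative deviations (unbounded total, 0 for a diet exactly at
#' every target). Red meat is scored as a total by WISH and ELD-I and as
#' separate beef/lamb and pork components by ELI; the total is derived from
#' the sub-groups when absent from `intakes`.
#'
#' @param intakes Named numeric vector of intakes (g/d at 2500 kcal) over
#'   the food-group codes.
#' @param targets Target table, default [phd_targets()].
#' @return List with `components` (named numeric vector) and `total`.
#' @name score_indices
#' @export
score_wish <- function(intakes, targets = phd_targets()) {
  score_index(intakes, targets, wish_groups(), score_wish_component)
}

#' @rdname score_indices
#' @export
score_eli <- function(intakes, targets = phd_targets()) {
  score_index(intakes, targets, eli_groups(), score_eli_component)
}

#' @rdname score_indices
#' @export
score_eldi <- function(intakes, targets = phd_targets()) {
  score_index(intakes, targets, eldi_groups(), score_eldi_component)
}

#' Score every participant in a harmonised dataset
#'
#' Computes, per participant, food-group compliance (%) and the WISH, ELI
#' and ELD-I components and totals from the energy-standardised intake
#' columns (`<group>_std`), plus survey-weighted per-country summaries.
#' Component contributions are weighted means of per-participant component
#' scores (not scores of mean intakes).
#'
#' @param participants Harmonised tibble (as from [harmonize_intake()]) with
#'   `participant_id`, `country`, `weight` and `<group>_std` columns.
#' @param targets Target table.
#' @param country_populations Optional named vector (or tibble with
#'   `country`, `population_count`); when given, population-weighted pooled
#'   ("Europe") rows are appended to the summaries.
#' @return List: `scores` (wide per-participant tibble with `compliance_*`,
#'   `wish_*`, `wish_total`, `eli_*`, `eli_total`, `eldi_*`, `eldi_total`),
#'   `index_summary` (country x index weighted mean/SD), and
#'   `component_summary` (country x index x food group weighted mean
#'   component score).
#' @export
score_cohort <- function(participants, targets = phd_targets(),
                         country_populations = NULL) {
  if (nrow(participants) == 0) stop("empty dataset", call. = FALSE)
  std_groups <- paste0(phd_food_groups(), "_std")
  miss <- setdiff(std_groups, names(participants))
  if (length(miss) > 0) {
    stop("harmonised dataset missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  intk <- participants[std_groups]
  names(intk) <- phd_food_groups()
  intk <- add_red_meat_total(intk)

  out <- participants[, intersect(c("participant_id", "country", "weight"),
                                  names(participants))]
  for (g in eldi_groups()) {
    out[[paste0("compliance_", g)]] <-
      compliance_pct(intk[[g]], target_row(targets, g)$target)
  }
  for (g in wish_groups()) {
    out[[paste0("wish_", g)]] <- score_wish_component(intk[[g]], target_row(targets, g))
  }
  out$wish_total <- rowSums(out[paste0("wish_", wish_groups())])
  for (g in eli_groups()) {
    out[[paste0("eli_", g)]] <- score_eli_component(intk[[g]], target_row(targets, g))
  }
  out$eli_total <- rowSums(out[paste0("eli_", eli_groups())])
  for (g in eldi_groups()) {
    out[[paste0("eldi_", g)]] <- score_eldi_component(intk[[g]], target_row(targets, g))
  }
  out$eldi_total <- rowSums(out[paste0("eldi_", eldi_groups())])

  w <- if ("weight" %in% names(out)) out$weight else rep(1, nrow(out))
  out_w <- dplyr::mutate(out, .w = w)
  totals <- c(wish = "wish_total", eli = "eli_total", eldi = "eldi_total")
  summarise_block <- function(d) {
    dplyr::bind_rows(lapply(names(totals), function(ix) {
      tibble::tibble(index = ix,
                     mean = weighted_mean(d[[totals[[ix]]]], d$.w),
                     sd = if (nrow(d) > 1) weighted_sd(d[[totals[[ix]]]], d$.w) else 0,
                     n = nrow(d))
    }))
  }
  component_block <- function(d) {
    comp_cols <- grep("^(wish|eli|eldi)_", names(d), value = TRUE)
    comp_cols <- setdiff(comp_cols, totals)
    dplyr::bind_rows(lapply(comp_cols, function(cc) {
      ix <- sub("_.*$", "", cc)
      tibble::tibble(index = ix, food_group = sub("^(wish|eli|eldi)_", "", cc),
                     mean = weighted_mean(d[[cc]], d$.w))
    }))
  }
  by_country <- split(out_w, out_w$country)
  index_summary <- dplyr::bind_rows(
    lapply(by_country, summarise_block), .id = "country")
  component_summary <- dplyr::bind_rows(
    lapply(by_country, component_block), .id = "country")
  if (!is.null(country_populations)) {
    pool_ix <- pooled_summary(index_summary, "mean", country_populations)
    pool_ix$country <- "Europe"
    pool_comp <- pooled_summary(component_summary, "mean", country_populations)
    pool_comp$country <- "Europe"
    index_summary <- dplyr::bind_rows(index_summary, pool_ix)
    component_summary <- dplyr::bind_rows(component_summary, pool_comp)
  }
  list(scores = out, index_summary = index_summary,
       component_summary = component_summary)
}

# internal: population-weighted pooling of a per-country summary table
pooled_summary <- function(summary_tbl, value_col, country_populations) {
  if (is.data.frame(country_populations)) {
    country_populations <- stats::setNames(
      country_populations$population_count, country_populations$country)
  }
  keys <- setdiff(names(summary_tbl), c("country", value_col, "sd", "n"))
  dplyr::summarise(
    summary_tbl,
    "{value_col}" := {
      p <- country_populations[.data$country]
      sum(p / sum(p) * .data[[value_col]])
    },
    .by = dplyr::all_of(keys)
  )
}
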