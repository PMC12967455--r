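#' Read a recipe database
#'
#' A recipe database maps composite dishes to PHD food groups through
#' standardised weight proportions, one row per (dish, group) allocation.
#' The `gated` flag marks encouraged-food allocations that are suppressed
#' because the dish is an unhealthy preparation (e.g. the whole-grain share
#' of a sugar-sweetened breakfast cereal is credited to nothing, while its
#' added sugars are still counted).
#'
#' @param path CSV with columns `dish_id`, `food_group`, `proportion`,
#'   `gated` (true/false).
#' @return A tibble with those columns, `gated` as logical.
#' @seealso [validate_recipe_db()], [disaggregate_dish()]
#' @export
read_recipe_db <- function(path) {
  db <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          dish_id = "c", food_group = "c",
                          proportion = "d", gated = "l"
                        ))
  need <- c("dish_id", "food_group", "proportion", "gated")
  miss <- setdiff(need, names(db))
  if (length(miss) > 0) {
    stop("recipe database is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  assert_food_groups(db$food_group, "recipe database")
  db
}

#' @rdname read_recipe_db
#' @param db A recipe tibble.
#' @export
write_recipe_db <- function(db, path) {
  readr::write_csv(db, path)
  invisible(path)
}

#' Diagnose structural problems in a recipe database
#'
#' Reports (without stopping) dishes whose proportions sum above 1 beyond a
#' 1e-9 tolerance, non-positive proportions, duplicate (dish, group) pairs,
#' and gated lines attached to limited food groups (gating only ever
#' withholds credit from encouraged foods).
#'
#' @param db A recipe tibble as from [read_recipe_db()].
#' @param targets Target table supplying each group's direction; defaults to
#'   [phd_targets()].
#' @return A tibble of violations with columns `dish_id`, `rule`, `detail`;
#'   zero rows when the database is well-formed.
#' @export
validate_recipe_db <- function(db, targets = phd_targets()) {
  v <- list()
  sums <- stats::aggregate(proportion ~ dish_id, data = db, FUN = sum)
  over <- sums[sums$proportion > 1 + 1e-9, , drop = FALSE]
  if (nrow(over) > 0) {
    v[[length(v) + 1L]] <- tibble::tibble(
      dish_id = over$dish_id, rule = "proportion_sum",
      detail = sprintf("sum %.6g > 1", over$proportion)
    )
  }
  bad_p <- db[db$proportion <= 0 | !is.finite(db$proportion), , drop = FALSE]
  if (nrow(bad_p) > 0) {
    v[[length(v) + 1L]] <- tibble::tibble(
      dish_id = bad_p$dish_id, rule = "nonpositive_proportion",
      detail = sprintf("%s: proportion %g", bad_p$food_group, bad_p$proportion)
    )
  }
  key <- paste(db$dish_id, db$food_group, sep = "\r")
  dup <- db[duplicated(key), , drop = FALSE]
  if (nrow(dup) > 0) {
    v[[length(v) + 1L]] <- tibble::tibble(
      dish_id = dup$dish_id, rule = "duplicate_line",
      detail = sprintf("duplicate allocation to %s", dup$food_group)
    )
  }
  dir_of <- stats::setNames(targets$direction, targets$food_group)
  gl <- db[db$gated & dir_of[db$food_group] == "limited", , drop = FALSE]
  if (nrow(gl) > 0) {
    v[[length(v) + 1L]] <- tibble::tibble(
      dish_id = gl$dish_id, rule = "gated_limited_group",
      detail = sprintf("gating applies to encouraged foods, not %s", gl$food_group)
    )
  }
  if (length(v) == 0) {
    return(tibble::tibble(dish_id = character(), rule = character(),
                          detail = character()))
  }
  dplyr::bind_rows(v)
}

#' Disaggregate one dish record into food-group grams
#'
#' Distributes the consumed weight of a composite dish over PHD food groups
#' using the dish's standardised proportions: 200 g of a ham-and-vegetable
#' sandwich specified as 20% red meat / 10% vegetables / 50% whole grains
#' yields 40 g red meat, 20 g vegetables and 100 g whole grains. Gated lines
#' contribute zero to their group. Any proportion shortfall below 1 (water,
#' broth, unclassified mass) is left unallocated.
#'
#' @param record A one-row data frame or list with `dish_id` and `grams`.
#' @param recipes Recipe tibble.
#' @param lenient If `FALSE` (default), an unknown `dish_id` is an error of
#'   class `phdiet_unknown_dish` carrying the id; if `TRUE`, the dish is
#'   skipped and all groups return 0 g.
#' @return Named numeric vector over [phd_food_groups()] (grams).
#' @export
#' @examples
#' db <- tibble::tibble(
#'   dish_id = "sandwich", food_group = c("red_meat_pork", "vegetables", "whole_grains"),
#'   proportion = c(0.2, 0.1, 0.5), gated = FALSE
#' )
#' disaggregate_dish(list(dish_id = "sandwich", grams = 200), db)
disaggregate_dish <- function(record, recipes, lenient = FALSE) {
  out <- stats::setNames(numeric(length(phd_food_groups())), phd_food_groups())
  grams <- as.numeric(record$grams)
  if (!is.finite(grams) || grams < 0) {
    stop("dish grams must be finite and non-negative", call. = FALSE)
  }
  lines <- recipes[recipes$dish_id == record$dish_id, , drop = FALSE]
  if (nrow(lines) == 0) {
    if (lenient) return(out)
    cond <- structure(
      class = c("phdiet_unknown_dish", "error", "condition"),
      list(message = paste0("unknown dish_id: ", record$dish_id),
           call = NULL, dish_id = record$dish_id)
    )
    stop(cond)
  }
  live <- lines[!lines$gated, , drop = FALSE]
  if (nrow(live) > 0) {
    alloc <- tapply(grams * live$proportion, live$food_group, sum)
    out[names(alloc)] <- as.numeric(alloc)
  }
  out
}

#' Disaggregate a dish-record table
#'
#' Vectorised table form of [disaggregate_dish()]: joins dish records to the
#' recipe database and returns per-record food-group grams in long form.
#'
#' @param dishes Tibble with `participant_id`, `day`, `dish_id`, `grams`.
#' @param recipes Recipe tibble.
#' @inheritParams disaggregate_dish
#' @return Long tibble `participant_id`, `day`, `food_group`, `grams`
#'   (non-gated allocations only).
#' @export
disaggregate_dishes <- function(dishes, recipes, lenient = FALSE) {
  stopifnot(all(c("participant_id", "day", "dish_id", "grams") %in% names(dishes)))
  if (any(!is.finite(dishes$grams) | dishes$grams < 0)) {
    stop("dish grams must be finite and non-negative", call. = FALSE)
  }
  unknown <- setdiff(unique(dishes$dish_id), unique(recipes$dish_id))
  if (length(unknown) > 0 && !lenient) {
    cond <- structure(
      class = c("phdiet_unknown_dish", "error", "condition"),
      list(message = paste0("unknown dish_id(s): ", paste(unknown, collapse = ", ")),
           call = NULL, dish_id = unknown)
    )
    stop(cond)
  }
  live <- recipes[!recipes$gated, c("dish_id", "food_group", "proportion")]
  dplyr::inner_join(dishes, live, by = "dish_id",
                    relationship = "many-to-many") |>
    dplyr::mutate(grams = .data$grams * .data$proportion) |>
    dplyr::summarise(grams = sum(.data$grams),
                     .by = c("participant_id", "day", "food_group"))
}

#' Aggregate dish and direct records to mean daily intake per participant
#'
#' Sums food-group grams within each recall day (dish-derived allocations
#' plus any direct group-level records), then averages over the participant's
#' distinct recall days, unweighted.
#'
#' @param dishes Dish-record tibble (`participant_id`, `day`, `dish_id`,
#'   `grams`); may have zero rows.
#' @param recipes Recipe tibble used to disaggregate `dishes`.
#' @param direct Optional long tibble of group-level records
#'   (`participant_id`, `day`, `food_group`, `grams`) already expressed in
#'   food-group grams.
#' @inheritParams disaggregate_dish
#' @return Wide tibble: `participant_id`, `n_days`, one column per food
#'   group (mean g/d, 0 where never consumed).
#' @export
aggregate_participant_days <- function(dishes, recipes, direct = NULL,
                                       lenient = FALSE) {
  parts <- list()
  if (nrow(dishes) > 0) {
    parts$dish <- disaggregate_dishes(dishes, recipes, lenient = lenient)
  }
  if (!is.null(direct) && nrow(direct) > 0) {
    assert_food_groups(direct$food_group, "direct records")
    parts$direct <- direct[, c("participant_id", "day", "food_group", "grams")]
  }
  if (length(parts) == 0) stop("no records to aggregate", call. = FALSE)
  long <- dplyr::bind_rows(parts)
  days <- dplyr::distinct(long, .data$participant_id, .data$day) |>
    dplyr::count(.data$participant_id, name = "n_days")
  daily <- dplyr::summarise(long, grams = sum(.data$grams),
                            .by = c("participant_id", "food_group"))
  out <- dplyr::left_join(daily, days, by = "participant_id") |>
    dplyr::mutate(grams = .data$grams / .data$n_days) |>
    tidyr::pivot_wider(id_cols = c("participant_id", "n_days"),
                       names_from = "food_group", values_from = "grams",
                       values_fill = 0)
  for (g in setdiff(phd_food_groups(), names(out))) out[[g]] <- 0
  out[, c("participant_id", "n_days", phd_food_groups())]
}
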