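#' PHD food-group taxonomy
#'
#' The closed set of food-group codes used throughout the package, following
#' the EAT-Lancet Planetary Health Diet (PHD) framework. Red meat is carried
#' as its two sub-groups (beef/lamb and pork); the total is always derived as
#' their sum via [add_red_meat_total()] and never stored independently.
#'
#' @return Character vector of the 15 stored food-group codes.
#' @export
#' @examples
#' phd_food_groups()
phd_food_groups <- function() {
  c(
    "whole_grains", "vegetables", "fruits", "tubers", "legumes", "nuts",
    "unsaturated_oils", "dairy", "red_meat_beef_lamb", "red_meat_pork",
    "poultry", "eggs", "fish", "saturated_fats", "added_sugars"
  )
}

#' Food groups scored by each PHD index
#'
#' WISH scores 13 groups (red meat as a total, tubers not scored). ELI scores
#' 14 groups (red meat split into beef/lamb and pork, tubers scored as a
#' limited food, saturated fats not scored). ELD-I scores 14 groups (red meat
#' as a total).
#'
#' @return Character vector of food-group codes in a fixed, stable order.
#' @name index_groups
NULL

#' @rdname index_groups
#' @export
wish_groups <- function() {
  c(
    "whole_grains", "vegetables", "fruits", "legumes", "nuts",
    "unsaturated_oils", "dairy", "red_meat", "poultry", "eggs", "fish",
    "saturated_fats", "added_sugars"
  )
}

#' @rdname index_groups
#' @export
eli_groups <- function() {
  c(
    "whole_grains", "vegetables", "fruits", "legumes", "nuts",
    "unsaturated_oils", "fish",
    "dairy", "red_meat_beef_lamb", "red_meat_pork", "poultry", "eggs",
    "tubers", "added_sugars"
  )
}

#' @rdname index_groups
#' @export
eldi_groups <- function() {
  c(
    "whole_grains", "vegetables", "fruits", "tubers", "legumes", "nuts",
    "unsaturated_oils", "dairy", "red_meat", "poultry", "eggs", "fish",
    "saturated_fats", "added_sugars"
  )
}

#' Derive total red meat from its sub-groups
#'
#' Adds a `red_meat` entry (or column) equal to beef/lamb plus pork. Works on
#' a named numeric vector of intakes or on a data frame with one column per
#' food group.
#'
#' @param x Named numeric vector over food-group codes, or a data frame with
#'   `red_meat_beef_lamb` and `red_meat_pork` columns.
#' @return `x` with a `red_meat` element/column appended (replaced if present).
#' @export
add_red_meat_total <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("red_meat_beef_lamb", "red_meat_pork") %in% names(x)))
    x[["red_meat"]] <- x[["red_meat_beef_lamb"]] + x[["red_meat_pork"]]
    return(x)
  }
  stopifnot(is.numeric(x), all(c("red_meat_beef_lamb", "red_meat_pork") %in% names(x)))
  x[["red_meat"]] <- x[["red_meat_beef_lamb"]] + x[["red_meat_pork"]]
  x
}

# internal: check that a code belongs to the closed taxonomy
assert_food_groups <- function(codes, where = "input") {
  bad <- setdiff(unique(codes), phd_food_groups())
  if (length(bad) > 0) {
    stop(sprintf(
      "unknown food group code(s) in %s: %s", where,
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}
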