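#' Default PHD target table
#'
#' One row per scoreable food group: the PHD reference target (g/d at a
#' 2500 kcal reference), the recommended intake range, the scoring direction
#' (`encouraged` foods should be eaten at or above target, `limited` foods at
#' or below), and the index-specific scoring parameters (WISH piecewise-linear
#' curve and ELI band cut-points).
#'
#' Targets carried by the default table are the PHD reference values: whole
#' grains 232, vegetables 300, fruits 200, tubers 50, legumes 75, nuts 50,
#' unsaturated oils 40, dairy 250, total red meat 28 (beef/lamb 14 + pork 14),
#' poultry 29, eggs 13, fish 28, saturated fats 11.8 and added sugars 31 g/d.
#' The WISH breakpoints and ELI cut-points are editable defaults derived from
#' these targets and ranges (the source indices publish their exact values in
#' supplementary material not reproduced here); they are provisional and can
#' be replaced wholesale through [read_targets()].
#'
#' `direction` drives compliance interpretation and the ELD-I sign;
#' `eli_direction` carries ELI's own emphasised/limited classification, which
#' differs from `direction` for dairy (a food to limit under ELI but whose
#' intake near target contributes positively to ELD-I).
#'
#' @return A tibble with columns `food_group`, `target`, `lower`, `upper`,
#'   `direction`, `eli_direction`, `wish_curve`, `wish_breakpoints`,
#'   `eli_bands`. Breakpoint columns are semicolon-separated numbers.
#' @export
#' @examples
#' phd_targets()
phd_targets <- function() {
  tab <- tibble::tribble(
    ~food_group,          ~target, ~lower, ~upper, ~direction,   ~eli_direction, ~wish_curve,     ~wish_breakpoints, ~eli_bands,
    "whole_grains",         232,      0,     232,  "encouraged", "emphasised",   "ramp_up",       "232",             "58;116;232",
    "vegetables",           300,    200,     600,  "encouraged", "emphasised",   "ramp_up",       "300",             "75;150;300",
    "fruits",               200,    100,     300,  "encouraged", "emphasised",   "ramp_up",       "200",             "50;100;200",
    "tubers",                50,      0,     100,  "limited",    "limited",      NA,              NA,                "50;100;200",
    "legumes",               75,      0,     150,  "encouraged", "emphasised",   "ramp_up",       "75",              "18.75;37.5;75",
    "nuts",                  50,      0,      75,  "encouraged", "emphasised",   "ramp_up",       "50",              "12.5;25;50",
    "unsaturated_oils",      40,     20,      80,  "encouraged", "emphasised",   "ramp_up",       "40",              "10;20;40",
    "dairy",                250,      0,     500,  "encouraged", "limited",      "plateau_range", "0;0;250;500",     "250;500;1000",
    "red_meat",              28,      0,      28,  "limited",    NA,             "ramp_down",     "28;112",          NA,
    "red_meat_beef_lamb",    14,      0,      14,  "limited",    "limited",      NA,              NA,                "14;28;56",
    "red_meat_pork",         14,      0,      14,  "limited",    "limited",      NA,              NA,                "14;28;56",
    "poultry",               29,      0,      58,  "limited",    "limited",      "plateau_range", "0;0;58;116",      "29;58;116",
    "eggs",                  13,      0,      25,  "limited",    "limited",      "plateau_range", "0;0;25;50",       "13;26;52",
    "fish",                  28,      0,     100,  "encouraged", "emphasised",   "ramp_up",       "28",              "7;14;28",
    "saturated_fats",      11.8,      0,    11.8,  "limited",    NA,             "ramp_down",     "11.8;47.2",       NA,
    "added_sugars",          31,      0,      31,  "limited",    "limited",      "ramp_down",     "31;124",          "31;62;124"
  )
  validate_targets(tab)
  tab
}

#' Read and write a target table
#'
#' `read_targets()` loads a targets CSV (same schema as [phd_targets()]) and
#' validates it; `write_targets()` writes one. Round-tripping a table through
#' these functions reproduces identical scoring.
#'
#' @param path Path to a targets CSV file.
#' @param targets A target table as returned by [phd_targets()].
#' @return `read_targets()`: a validated target tibble. `write_targets()`:
#'   `path`, invisibly.
#' @export
read_targets <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           food_group = "c", target = "d", lower = "d",
                           upper = "d", direction = "c", eli_direction = "c",
                           wish_curve = "c", wish_breakpoints = "c",
                           eli_bands = "c"
                         ))
  validate_targets(tab)
  tab
}

#' @rdname read_targets
#' @export
write_targets <- function(targets, path) {
  readr::write_csv(targets, path, na = "")
  invisible(path)
}

#' Validate a target table
#'
#' Checks structural invariants: known food-group codes (plus the derived
#' `red_meat` total), `lower <= target <= upper`, positive targets, valid
#' directions, well-formed WISH breakpoints per curve type, and exactly three
#' strictly increasing ELI cut-points (defining four score bands) wherever a
#' group is ELI-scored.
#'
#' @param targets A target table.
#' @return The table, invisibly; stops with a descriptive error on violation.
#' @export
validate_targets <- function(targets) {
  need <- c("food_group", "target", "lower", "upper", "direction",
            "eli_direction", "wish_curve", "wish_breakpoints", "eli_bands")
  miss <- setdiff(need, names(targets))
  if (length(miss) > 0) {
    stop("target table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  assert_food_groups(setdiff(targets$food_group, "red_meat"), "target table")
  if (anyDuplicated(targets$food_group)) {
    stop("duplicate food_group rows in target table", call. = FALSE)
  }
  if (any(targets$target <= 0)) stop("targets must be > 0", call. = FALSE)
  bad <- targets$lower > targets$target | targets$target > targets$upper
  if (any(bad)) {
    stop("lower <= target <= upper violated for: ",
         paste(targets$food_group[bad], collapse = ", "), call. = FALSE)
  }
  if (!all(targets$direction %in% c("encouraged", "limited"))) {
    stop("direction must be 'encouraged' or 'limited'", call. = FALSE)
  }
  ok_eli_dir <- is.na(targets$eli_direction) |
    targets$eli_direction %in% c("emphasised", "limited")
  if (!all(ok_eli_dir)) {
    stop("eli_direction must be 'emphasised', 'limited' or empty", call. = FALSE)
  }
  for (i in seq_len(nrow(targets))) {
    cv <- targets$wish_curve[i]
    if (!is.na(cv)) {
      bp <- parse_breakpoints(targets$wish_breakpoints[i])
      n_need <- switch(cv,
        ramp_up = 1L, ramp_down = 2L, plateau_range = 4L,
        stop("unknown wish_curve '", cv, "' for ", targets$food_group[i],
             call. = FALSE)
      )
      if (length(bp) != n_need || is.unsorted(bp)) {
        stop("malformed wish_breakpoints for ", targets$food_group[i],
             ": need ", n_need, " non-decreasing value(s)", call. = FALSE)
      }
      if (cv != "plateau_range" && any(duplicated(bp))) {
        stop("wish_breakpoints for ", targets$food_group[i],
             " must be strictly increasing", call. = FALSE)
      }
    }
    eb <- targets$eli_bands[i]
    if (!is.na(eb)) {
      cuts <- parse_breakpoints(eb)
      if (length(cuts) != 3L || any(diff(cuts) <= 0)) {
        stop("eli_bands for ", targets$food_group[i],
             " must be 3 strictly increasing cut-points", call. = FALSE)
      }
      if (is.na(targets$eli_direction[i])) {
        stop("eli_bands given without eli_direction for ",
             targets$food_group[i], call. = FALSE)
      }
    }
  }
  invisible(targets)
}

# internal: "a;b;c" -> numeric vector
parse_breakpoints <- function(x) {
  if (is.na(x) || !nzchar(x)) return(numeric(0))
  as.numeric(strsplit(x, ";", fixed = TRUE)[[1]])
}

# internal: fetch the row for one group, erroring if absent
target_row <- function(targets, group) {
  i <- match(group, targets$food_group)
  if (is.na(i)) {
    stop("food group '", group, "' missing from target table", call. = FALSE)
  }
  targets[i, ]
}
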