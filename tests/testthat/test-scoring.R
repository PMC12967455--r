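tab <- phd_targets()
row_of <- function(g) tab[tab$food_group == g, ]

test_that("compliance is the percentage of the target achieved, linear in intake", {
  expect_equal(compliance_pct(300, 300), 100)
  expect_equal(compliance_pct(0, 28), 0)
  expect_equal(compliance_pct(143.8, 28), 513.5714, tolerance = 1e-6)
  x <- seq(0, 500, by = 25)
  expect_equal(compliance_pct(3 * x, 50), 3 * compliance_pct(x, 50))
  expect_error(compliance_pct(10, 0), "target")
})

test_that("WISH components follow their piecewise-linear curves and stay in [0, 10]", {
  # ramp_up: linear interpolation to the full-compliance breakpoint
  wg <- row_of("whole_grains") # breakpoint 232
  expect_equal(score_wish_component(232, wg), 10)
  expect_equal(score_wish_component(500, wg), 10)
  expect_equal(score_wish_component(116, wg), 5)
  expect_equal(score_wish_component(0, wg), 0)
  ramp <- wg; ramp$wish_breakpoints <- "100"
  expect_equal(score_wish_component(50, ramp), 5)
  # ramp_down: 10 below the lower breakpoint, 0 at/above the upper
  rm <- row_of("red_meat") # 28;112
  expect_equal(score_wish_component(0, rm), 10)
  expect_equal(score_wish_component(28, rm), 10)
  expect_equal(score_wish_component(112, rm), 0)
  expect_equal(score_wish_component(70, rm), 10 * (112 - 70) / 84)
  # plateau_range: flat top with linear flanks
  eggs <- row_of("eggs") # 0;0;25;50
  expect_equal(score_wish_component(13, eggs), 10)
  expect_equal(score_wish_component(37.5, eggs), 5)
  expect_equal(score_wish_component(50, eggs), 0)
  # bounds over a dense grid for every WISH group
  for (g in wish_groups()) {
    s <- score_wish_component(seq(0, 1500, by = 7.5), row_of(g))
    expect_true(all(s >= 0 & s <= 10))
  }
})

test_that("WISH totals span 0 to 130 and are additive over components", {
  ex <- generate_worked_examples(tab)
  full <- score_wish(ex$compliant_diet, tab)
  expect_equal(full$total, 130)
  expect_equal(unname(full$components), rep(10, 13))
  worst <- score_wish(ex$worst_diet, tab)
  expect_equal(worst$total, 0)
  # compliant in exactly one group scores exactly that component
  one <- ex$worst_diet
  one["vegetables"] <- 300
  s1 <- score_wish(one, tab)
  expect_equal(s1$total, 10)
  expect_equal(s1$components[["vegetables"]], 10)
  expect_error(score_wish(ex$compliant_diet[-1], tab), "whole_grains")
})

test_that("ELI bands grade 0-3 with cut-point ties resolved toward higher adherence", {
  veg <- row_of("vegetables") # emphasised, 75;150;300
  expect_equal(score_eli_component(c(0, 74.9, 75, 149, 150, 299, 300, 600), veg),
               c(0, 0, 1, 1, 2, 2, 3, 3))
  pork <- row_of("red_meat_pork") # limited, 14;28;56
  expect_equal(score_eli_component(c(0, 14, 14.1, 28, 28.1, 56, 56.1), pork),
               c(3, 3, 2, 2, 1, 1, 0))
  # exhaustive sweep: every group's bands are monotone in the right direction
  for (g in eli_groups()) {
    r <- row_of(g)
    cuts <- as.numeric(strsplit(r$eli_bands, ";")[[1]])
    grid <- sort(unique(c(0, cuts, cuts + 1e-9, cuts - 1e-9, 2 * max(cuts))))
    grid <- grid[grid >= 0]
    s <- score_eli_component(grid, r)
    expect_true(all(s %in% 0:3))
    if (r$eli_direction == "emphasised") {
      expect_true(all(diff(s) >= 0))
      expect_equal(s[length(s)], 3)
      expect_equal(s[1], 0)
    } else {
      expect_true(all(diff(s) <= 0))
      expect_equal(s[1], 3)
      expect_equal(s[length(s)], 0)
    }
  }
})

test_that("ELI totals span 0 to 42 and are additive", {
  ex <- generate_worked_examples(tab)
  expect_equal(score_eli(ex$compliant_diet, tab)$total, 42)
  expect_equal(score_eli(ex$worst_diet, tab)$total, 0)
  # half the components at 3, half at 0
  half <- ex$worst_diet
  for (g in c("whole_grains", "vegetables", "fruits", "legumes", "nuts",
              "unsaturated_oils", "fish")) {
    half[g] <- row_of(g)$target
  }
  expect_equal(score_eli(half, tab)$total, 21)
})

test_that("ELD-I components are the signed relative deviation from target", {
  rm <- row_of("red_meat")
  expect_equal(round(score_eldi_component(81.4, rm), 2), -1.91)
  expect_equal(score_eldi_component(143.8, rm), -(143.8 - 28) / 28)
  expect_equal(score_eldi_component(28, rm), 0)
  # exact linearity with slope dir/target
  x <- seq(0, 300, by = 10)
  expect_equal(score_eldi_component(x, rm), -(x - 28) / 28)
  veg <- row_of("vegetables")
  expect_equal(score_eldi_component(x, veg), (x - 300) / 300)
})

test_that("ELD-I totals are additive and scale with target-relative deviations", {
  ex <- generate_worked_examples(tab)
  expect_equal(score_eldi(ex$compliant_diet, tab)$total, 0)
  low <- score_eldi(ex$red_meat_low_diet, tab)
  expect_equal(round(low$total, 2), -1.91)
  expect_equal(low$components[["red_meat"]], low$total) # all others at target
  high <- score_eldi(ex$red_meat_high_diet, tab)
  expect_equal(high$total, -(143.8 - 28) / 28)
  # doubling every target-relative deviation doubles the total
  d1 <- target_diet(tab) * 1.3
  d2 <- target_diet(tab) * 1.6
  expect_equal(score_eldi(d2, tab)$total, 2 * score_eldi(d1, tab)$total,
               tolerance = 1e-12)
})

test_that("index components are monotone in intake in the direction of each group", {
  grid <- seq(0, 1200, by = 3)
  for (g in eldi_groups()) {
    r <- row_of(g)
    s <- score_eldi_component(grid, r)
    if (r$direction == "encouraged") expect_true(all(diff(s) > 0))
    else expect_true(all(diff(s) < 0))
  }
  for (g in wish_groups()) {
    r <- row_of(g)
    s <- score_wish_component(grid, r)
    if (r$wish_curve == "ramp_up") expect_true(all(diff(s) >= 0))
    if (r$wish_curve == "ramp_down") expect_true(all(diff(s) <= 0))
  }
})

test_that("index bounds hold on 10^4 random diets", {
  set.seed(42)
  n <- 1e4
  diets <- sapply(phd_food_groups(), function(g) {
    stats::rlnorm(n, log(pmax(tab$target[tab$food_group == g], 1)), 1)
  })
  diets <- tibble::as_tibble(diets)
  diets <- add_red_meat_total(diets)
  wish_tot <- rowSums(sapply(wish_groups(), function(g)
    score_wish_component(diets[[g]], row_of(g))))
  eli_tot <- rowSums(sapply(eli_groups(), function(g)
    score_eli_component(diets[[g]], row_of(g))))
  expect_true(all(wish_tot >= 0 & wish_tot <= 130))
  expect_true(all(eli_tot >= 0 & eli_tot <= 42))
  # compliance / ELD-I consistency for encouraged groups
  for (g in c("vegetables", "whole_grains", "fish")) {
    r <- row_of(g)
    comp <- compliance_pct(diets[[g]], r$target)
    eldi <- score_eldi_component(diets[[g]], r)
    expect_equal(comp < 100, eldi < 0)
  }
})

test_that("the three indices are positively rank-correlated on a synthetic cohort", {
  sv <- generate_survey(phd_sim_config(n_per_country = 120), seed = 3)
  h <- harmonize_intake(combine_survey_intake(sv), sv$population)
  sc <- score_cohort(h$participants)
  s <- sc$scores
  expect_gt(cor(s$wish_total, s$eli_total, method = "spearman"), 0)
  expect_gt(cor(s$wish_total, s$eldi_total, method = "spearman"), 0)
  expect_gt(cor(s$eli_total, s$eldi_total, method = "spearman"), 0)
})

test_that("cohort scoring reports weighted summaries", {
  d <- toy_intake()
  h <- harmonize_intake(d, toy_population())
  sc <- score_cohort(h$participants)
  # identical diets: SD 0 and mean equal to the individual score
  one <- score_wish(stats::setNames(rep(50, 15), phd_food_groups()))
  expect_equal(
    sc$index_summary$mean[sc$index_summary$index == "wish"],
    rep(one$total, 2)
  )
  expect_equal(sc$index_summary$sd[sc$index_summary$index == "wish"], c(0, 0))
  expect_error(score_cohort(h$participants[0, ]), "empty")
  # hand-checked weighted mean: scores 10 and 20 with weights 1 and 3
  expect_equal(weighted_mean(c(10, 20), c(1, 3)), 17.5)
})
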