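test_that("country deviation measures percentage distance from the pooled mean", {
  set.seed(1)
  x <- rnorm(500, 100, 10)
  x <- (x - mean(x)) / sd(x) * 10 + 100 # exact mean 100, sd 10
  cd <- country_deviation(x, pooled_mean = 100, country = "AA")
  expect_equal(cd$deviation_pct, 0, tolerance = 1e-9)
  expect_gt(cd$p_value, 0.9)
  cd2 <- country_deviation(x * 1.2, pooled_mean = 100)
  expect_equal(cd2$deviation_pct, 20, tolerance = 1e-9)
  expect_lt(cd2$p_value, 1e-6)
  cd3 <- country_deviation(x, pooled_mean = 0)
  expect_true(is.na(cd3$deviation_pct))
  expect_true(cd3$pooled_mean_zero)
  expect_error(country_deviation(1, pooled_mean = 0), ">= 2")
})

test_that("a 0.5 SD shift at n = 50 is detected in most replicates", {
  set.seed(2024)
  hits <- vapply(1:200, function(i) {
    x <- rnorm(50, 0.5, 1)
    country_deviation(x, pooled_mean = 0)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("DerSimonian-Laird heterogeneity matches its closed form and metafor", {
  # identical estimates: no heterogeneity at all
  h0 <- random_effects_heterogeneity(rep(5, 6), rep(0.5, 6))
  expect_equal(h0$Q, 0)
  expect_equal(h0$I2, 0)
  expect_equal(h0$tau2, 0)
  # Q = df exactly clamps I2 at 0: two estimates, equal SE s, gap 2s
  s <- 0.7
  h1 <- random_effects_heterogeneity(c(0, sqrt(2) * s), c(s, s))
  expect_equal(h1$Q, 1)
  expect_equal(h1$I2, 0)
  # cross-check against metafor's DL estimator on a random fixture
  set.seed(9)
  yi <- rnorm(8, 0, 2)
  sei <- runif(8, 0.2, 1)
  h <- random_effects_heterogeneity(yi, sei)
  m <- metafor::rma(yi = yi, sei = sei, method = "DL")
  expect_equal(h$Q, unname(m$QE), tolerance = 1e-10)
  expect_equal(h$tau2, unname(m$tau2), tolerance = 1e-10)
  expect_equal(h$I2, unname(m$I2), tolerance = 1e-6)
  expect_equal(h$p_value, unname(m$QEp), tolerance = 1e-10)
  # invariance under common rescaling of estimates and SEs
  h_scaled <- random_effects_heterogeneity(3.7 * yi, 3.7 * sei)
  expect_equal(h_scaled$I2, h$I2)
  expect_equal(h_scaled$Q, h$Q)
  expect_error(random_effects_heterogeneity(1, 1), ">= 2")
})

# independent oracle: general dominance by direct lm() over all subsets
dominance_oracle <- function(y, X, w = rep(1, length(y))) {
  X <- as.data.frame(X)
  p <- ncol(X)
  r2 <- function(cols) {
    if (length(cols) == 0) return(0)
    f <- stats::as.formula(paste("y ~", paste(cols, collapse = "+")))
    summary(stats::lm(f, data = cbind(y = y, X), weights = w))$r.squared
  }
  subsets <- unlist(lapply(0:p, function(k) combn(names(X), k, simplify = FALSE)),
                    recursive = FALSE)
  vapply(names(X), function(j) {
    inc <- vapply(Filter(function(s) !(j %in% s), subsets), function(s) {
      c(r2(c(s, j)) - r2(s), length(s))
    }, numeric(2))
    mean(tapply(inc[1, ], inc[2, ], mean))
  }, numeric(1))
}

test_that("dominance weights decompose R2 (single, orthogonal and oracle cases)", {
  set.seed(5)
  n <- 80
  # single predictor: weight equals the simple-regression R2
  x1 <- rnorm(n); y <- 2 * x1 + rnorm(n)
  d1 <- general_dominance(y, cbind(a = x1))
  expect_equal(d1$weights$dominance, summary(lm(y ~ x1))$r.squared)
  expect_equal(sum(d1$weights$dominance), d1$r2_full)
  # two orthogonal predictors: weights equal the marginal R2s
  x2 <- rnorm(n); x2 <- resid(lm(x2 ~ x1)) # exactly orthogonal (centred)
  y2 <- x1 + 0.5 * x2 + rnorm(n)
  d2 <- general_dominance(y2, cbind(a = x1, b = x2))
  expect_equal(d2$weights$dominance[1], summary(lm(y2 ~ x1))$r.squared,
               tolerance = 1e-9)
  expect_equal(d2$weights$dominance[2], summary(lm(y2 ~ x2))$r.squared,
               tolerance = 1e-9)
  # y equal to one column with noise columns: that column dominates
  X3 <- cbind(sig = rnorm(n), n1 = rnorm(n), n2 = rnorm(n))
  d3 <- general_dominance(X3[, "sig"], X3)
  expect_equal(d3$weights$dominance[d3$weights$predictor == "sig"], 1,
               tolerance = 0.1)
  expect_equal(d3$weights$rank[d3$weights$predictor == "sig"], 1L)
  # full agreement with the brute-force lm oracle, weighted case included
  w <- runif(n, 0.5, 2)
  X4 <- matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c")))
  y4 <- X4 %*% c(1, -0.5, 0.2) + rnorm(n)
  d4 <- general_dominance(drop(y4), X4, weights = w)
  expect_equal(d4$weights$dominance, unname(dominance_oracle(drop(y4), X4, w)),
               tolerance = 1e-9)
})

test_that("dominance weights sum to the full-model R2 on random fixtures", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(40:120, 1)
    p <- sample(2:8, 1)
    X <- matrix(rnorm(n * p), n)
    colnames(X) <- paste0("x", 1:p)
    y <- drop(X %*% rnorm(p)) + rnorm(n, sd = 2)
    w <- runif(n, 0.2, 3)
    d <- general_dominance(y, X, weights = w)
    expect_equal(sum(d$weights$dominance), d$r2_full, tolerance = 1e-9)
  }
})

test_that("sampled dominance mode engages above the exhaustive limit and is seeded", {
  set.seed(13)
  n <- 150
  X <- matrix(rnorm(n * 5), n, dimnames = list(NULL, paste0("x", 1:5)))
  y <- drop(X %*% c(2, 1, 0.5, 0, 0)) + rnorm(n)
  dex <- general_dominance(y, X)
  dsm <- general_dominance(y, X, max_exhaustive = 3, n_samples = 400, seed = 2)
  expect_equal(dsm$method, "sampled")
  expect_true("mc_se" %in% names(dsm$weights))
  expect_equal(dsm$weights$dominance, dex$weights$dominance, tolerance = 0.05)
  dsm2 <- general_dominance(y, X, max_exhaustive = 3, n_samples = 400, seed = 2)
  expect_identical(dsm$weights, dsm2$weights)
  # exact collinearity is reported with the offending subset
  Xc <- cbind(X[, 1:2], dup = X[, 1])
  expect_error(general_dominance(y, Xc), "singular")
})

test_that("regression contrasts equal group-mean differences in the balanced case", {
  demo <- tidyr::expand_grid(age_band = c("18-44", "45-64", ">=65"),
                             sex = c("women", "men"),
                             education = c("lower", "higher"))
  demo <- demo[rep(seq_len(nrow(demo)), each = 10), ]
  eff <- c("18-44" = 0, "45-64" = 3, ">=65" = 7)
  y <- eff[demo$age_band] + 5 * (demo$sex == "men") + 2 * (demo$education == "higher")
  # noise projected orthogonal to the full design leaves coefficients exact
  set.seed(99)
  mm <- stats::model.matrix(~ age_band * sex * education, data = demo)
  y <- y + stats::resid(stats::lm(rnorm(length(y)) ~ mm))
  fit <- demographic_regression(y, demo)
  cf <- fit$coefficients
  expect_equal(cf$beta[cf$term == "age_band45-64"], 3, tolerance = 1e-9)
  expect_equal(cf$beta[cf$term == "age_band>=65"], 7, tolerance = 1e-9)
  expect_equal(cf$beta[cf$term == "sexmen"], 5, tolerance = 1e-9)
  expect_equal(cf$beta[cf$term == "educationhigher"], 2, tolerance = 1e-9)
  # standardised betas are the raw ones divided by the outcome SD
  ysd <- weighted_sd(y, rep(1, length(y)))
  slopes <- cf$term != "(Intercept)"
  expect_equal(cf$beta_std[slopes], cf$beta[slopes] / ysd, tolerance = 1e-9)
})

test_that("eta-squared uses the classical definition with the stated cut-offs", {
  set.seed(31)
  n <- 4000
  sex <- rep(c("women", "men"), n / 2)
  # a sex effect engineered to explain ~6% of outcome variance
  f2 <- 0.06 / (1 - 0.06)
  beta <- sqrt(f2 * 4) # var(dummy) = 1/4, residual var 1
  y <- beta * (sex == "men") + rnorm(n)
  demo <- tibble::tibble(age_band = sample(c("18-44", "45-64"), n, TRUE),
                         sex = sex, education = "missing")
  fit <- demographic_regression(y, demo)
  eta <- fit$eta_squared
  expect_equal(eta$eta2[eta$factor == "sex"], 0.06, tolerance = 0.2)
  expect_equal(eta$label[eta$factor == "sex"], "moderate")
  expect_true(all(eta$eta2 >= 0 & eta$eta2 <= 1))
  expect_lte(sum(eta$eta2), 1)
  # education was all-missing, so it is not in the model
  expect_false("education" %in% eta$factor)
})

test_that("null regressions show no systematic effects", {
  set.seed(55)
  cover <- replicate(200, {
    n <- 120
    demo <- tibble::tibble(
      age_band = sample(c("18-44", "45-64", ">=65"), n, TRUE),
      sex = sample(c("women", "men"), n, TRUE),
      education = sample(c("lower", "higher"), n, TRUE)
    )
    y <- rnorm(n)
    cf <- demographic_regression(y, demo)$coefficients
    main <- cf[cf$term %in% c("sexmen", "educationhigher"), ]
    all(main$conf_low <= 0 & main$conf_high >= 0)
  })
  expect_gte(mean(cover), 0.85)
})

test_that("index concordance handles identity, reversal and monotone transforms", {
  set.seed(8)
  x <- rnorm(100)
  cc <- index_concordance(tibble::tibble(a = x, b = x))
  expect_equal(cc$correlation["a", "b"], 1)
  expect_equal(cc$quintile_agreement["a", "b"], 100)
  # perfect reversal: only the middle quintile survives
  cc2 <- index_concordance(tibble::tibble(a = x, b = -x))
  expect_equal(cc2$correlation["a", "b"], -1)
  expect_equal(cc2$quintile_agreement["a", "b"], 20)
  # strictly monotone transform preserves quintiles exactly
  cc3 <- index_concordance(tibble::tibble(a = x, b = exp(x)))
  expect_equal(cc3$quintile_agreement["a", "b"], 100)
  # constant index: correlation undefined, reported as NA
  cc4 <- index_concordance(tibble::tibble(a = x, b = rep(1, 100)))
  expect_true(is.na(cc4$correlation["a", "b"]))
  expect_error(index_concordance(tibble::tibble(a = 1:4, b = 1:4)), ">= 5")
})

test_that("sample correlation concentrates near the generating correlation", {
  set.seed(123)
  n <- 5000
  rho <- 0.8
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  cc <- index_concordance(tibble::tibble(a = x, b = y))
  expect_equal(cc$correlation["a", "b"], rho, tolerance = 0.03)
})
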