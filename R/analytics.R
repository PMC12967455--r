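#' Country deviation from the pooled mean
#'
#' Weighted country mean, its standard error, the percentage deviation from
#' the pooled (population-weighted European) mean, and a weighted
#' intercept-only test of whether the country mean differs from the pooled
#' value (WLS regression of centred values on a constant).
#'
#' @param values Per-participant values for one country.
#' @param weights Survey weights (default equal).
#' @param pooled_mean Pooled mean to test against.
#' @param country Optional label carried through.
#' @return One-row tibble: `country`, `estimate`, `standard_error`,
#'   `deviation_pct` (`NA` with a flag when the pooled mean is 0), `p_value`.
#' @export
country_deviation <- function(values, weights = rep(1, length(values)),
                              pooled_mean, country = NA_character_) {
  if (length(values) < 2) stop("need >= 2 participants", call. = FALSE)
  fit <- stats::lm(I(values - pooled_mean) ~ 1, weights = weights)
  p <- summary(fit)$coefficients[1, 4]
  est <- weighted_mean(values, weights)
  tibble::tibble(
    country = country,
    estimate = est,
    standard_error = weighted_se(values, weights),
    deviation_pct = if (pooled_mean != 0) 100 * (est - pooled_mean) / pooled_mean else NA_real_,
    pooled_mean_zero = pooled_mean == 0,
    p_value = p
  )
}

#' Random-effects heterogeneity across countries
#'
#' DerSimonian-Laird random-effects summary of per-country estimates:
#' Cochran's Q on inverse-variance weights, `I2 = max(0, (Q - df) / Q) * 100`,
#' the DL moment estimate of the between-country variance `tau2`, and the
#' chi-square p-value for Q on `k - 1` degrees of freedom. I2 is invariant
#' to rescaling all estimates and standard errors by a common factor.
#'
#' @param estimates Numeric vector of per-country means (length k >= 2).
#' @param se Matching positive standard errors.
#' @return One-row tibble: `k`, `Q`, `df`, `I2` (%), `tau2`, `p_value`.
#' @export
random_effects_heterogeneity <- function(estimates, se) {
  k <- length(estimates)
  if (k < 2) stop("need >= 2 countries", call. = FALSE)
  if (length(se) != k || any(se <= 0)) {
    stop("se must be positive and match estimates", call. = FALSE)
  }
  w <- 1 / se^2
  mu <- sum(w * estimates) / sum(w)
  Q <- sum(w * (estimates - mu)^2)
  df <- k - 1
  I2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  C <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - df) / C)
  tibble::tibble(k = k, Q = Q, df = df, I2 = I2, tau2 = tau2,
                 p_value = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' General dominance analysis
#'
#' Decomposes a weighted regression's R-squared into per-predictor general
#' dominance weights: for each predictor, the average (over subset sizes) of
#' the mean incremental R-squared from adding it to every subset of the other
#' predictors — a Shapley-style decomposition over all `2^p` subset models.
#' The weights sum exactly to the full-model R-squared.
#'
#' Exhaustive enumeration is used up to `max_exhaustive` predictors; beyond
#' that, subsets are sampled with a fixed seed and a Monte-Carlo standard
#' error is reported.
#'
#' @param y Outcome vector.
#' @param X Numeric matrix or data frame of predictors (columns named).
#' @param weights Observation weights (default equal).
#' @param max_exhaustive Largest p for exhaustive mode (default 16).
#' @param n_samples Sampled permutations per predictor beyond exhaustive
#'   mode.
#' @param seed Seed for the sampled mode.
#' @return List: `weights` (tibble `predictor`, `dominance`, `rank`, and
#'   `mc_se` in sampled mode), `r2_full`, `method`.
#' @export
general_dominance <- function(y, X, weights = rep(1, length(y)),
                              max_exhaustive = 16, n_samples = 500,
                              seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  w <- weights / mean(weights)
  # weighted centring; R2 of a subset from its cross-product system
  xm <- colSums(w * X) / sum(w)
  ym <- sum(w * y) / sum(w)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  Cxx <- crossprod(Xc, w * Xc)
  Cxy <- drop(crossprod(Xc, w * yc))
  Cyy <- sum(w * yc^2)
  r2_subset <- function(idx) {
    if (length(idx) == 0) return(0)
    b <- tryCatch(solve(Cxx[idx, idx, drop = FALSE], Cxy[idx]),
                  error = function(e) {
                    stop("singular fit for subset {",
                         paste(colnames(X)[idx], collapse = ", "), "}",
                         call. = FALSE)
                  })
    sum(b * Cxy[idx]) / Cyy
  }
  if (p <= max_exhaustive) {
    n_masks <- bitwShiftL(1L, p)
    r2 <- numeric(n_masks)
    sizes <- integer(n_masks)
    idx_of <- function(mask) which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0L)
    for (m in seq_len(n_masks - 1L)) {
      idx <- idx_of(m)
      sizes[m + 1L] <- length(idx)
      r2[m + 1L] <- r2_subset(idx)
    }
    dom <- numeric(p)
    for (j in seq_len(p)) {
      bit <- bitwShiftL(1L, j - 1L)
      masks <- 0:(n_masks - 1L)
      without <- masks[bitwAnd(masks, bit) == 0L]
      inc <- r2[without + bit + 1L] - r2[without + 1L]
      by_size <- tapply(inc, sizes[without + 1L], mean)
      dom[j] <- mean(by_size)
    }
    res <- tibble::tibble(predictor = colnames(X), dominance = dom)
    method <- "exhaustive"
    mc_se <- NULL
  } else {
    # sampled Shapley: average increments over random predictor orderings
    set.seed(seed)
    inc <- matrix(0, nrow = n_samples, ncol = p)
    for (s in seq_len(n_samples)) {
      ord <- sample.int(p)
      prev <- 0
      idx <- integer(0)
      for (j in ord) {
        idx <- c(idx, j)
        cur <- r2_subset(idx)
        inc[s, j] <- cur - prev
        prev <- cur
      }
    }
    res <- tibble::tibble(predictor = colnames(X), dominance = colMeans(inc))
    mc_se <- apply(inc, 2, stats::sd) / sqrt(n_samples)
    res$mc_se <- mc_se
    method <- "sampled"
  }
  res$rank <- rank(-res$dominance, ties.method = "min")
  list(weights = res, r2_full = r2_subset(seq_len(p)), method = method)
}

#' Demographic regression of an adherence index
#'
#' Weighted least squares of a PHD index on dummy-coded age band, sex and
#' education plus their pairwise interactions, within one country. Reference
#' levels are adults aged 18-44, women, and lower education. Coefficients
#' are reported both on the raw point scale and standardised (outcome
#' z-scored by its weighted mean/SD; 0/1 dummies left unscaled), with 95%
#' confidence intervals. Per-factor eta-squared is the classical
#' `SS_effect / SS_total` from Type II sums of squares, labelled
#' small/moderate/large at 0.01/0.06/0.14. Countries lacking education data
#' (all-missing) are fitted without it.
#'
#' @param scores Per-participant index values.
#' @param demographics Tibble with `age_band` (`"18-44"`, `"45-64"`,
#'   `">=65"`), `sex` (`"women"`/`"men"`) and `education` (`"lower"`,
#'   `"higher"`, or `"missing"`).
#' @param weights Survey weights.
#' @return List: `coefficients` (term, beta raw + CI, beta standardised +
#'   CI, p), `eta_squared` (factor, eta2, label), `model` (the raw-scale
#'   `lm` fit).
#' @export
demographic_regression <- function(scores, demographics,
                                   weights = rep(1, length(scores))) {
  d <- tibble::tibble(
    y = scores,
    age_band = factor(demographics$age_band, levels = c("18-44", "45-64", ">=65")),
    sex = factor(demographics$sex, levels = c("women", "men")),
    w = weights
  )
  edu <- demographics$education
  has_edu <- !all(is.na(edu) | edu == "missing")
  if (has_edu) {
    d$education <- factor(edu, levels = c("lower", "higher"))
    d <- d[!is.na(d$education), , drop = FALSE]
  }
  for (f in c("age_band", "sex", if (has_edu) "education")) {
    lev <- levels(droplevels(d[[f]]))
    if (length(lev) < 2) {
      warning("factor '", f, "' has a single observed level; dropped",
              call. = FALSE)
      d[[f]] <- NULL
      if (f == "education") has_edu <- FALSE
    }
  }
  facs <- intersect(c("age_band", "sex", "education"), names(d))
  if (length(facs) == 0) stop("no usable demographic factors", call. = FALSE)
  rhs <- if (length(facs) > 1) {
    paste0("(", paste(facs, collapse = " + "), ")^2")
  } else {
    facs
  }
  fml <- stats::as.formula(paste("y ~", rhs))
  fit <- stats::lm(fml, data = d, weights = w)
  ym <- weighted_mean(d$y, d$w)
  ys <- weighted_sd(d$y, d$w)
  dz <- d
  dz$y <- (d$y - ym) / ys
  fit_z <- stats::lm(fml, data = dz, weights = w)
  ci <- stats::confint(fit)
  ci_z <- stats::confint(fit_z)
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(sm),
    beta = unname(sm[, 1]), conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2]),
    beta_std = unname(summary(fit_z)$coefficients[, 1]),
    conf_low_std = unname(ci_z[, 1]), conf_high_std = unname(ci_z[, 2]),
    p_value = unname(sm[, 4])
  )
  an <- car::Anova(fit, type = 2)
  ss <- an[["Sum Sq"]]
  names(ss) <- rownames(an)
  ss_total <- sum(ss)
  eff <- setdiff(rownames(an), "Residuals")
  eta <- ss[eff] / ss_total
  label <- cut(eta, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf),
               labels = c("negligible", "small", "moderate", "large"),
               right = FALSE)
  list(
    coefficients = coefs,
    eta_squared = tibble::tibble(factor = eff, eta2 = unname(eta),
                                 label = as.character(label)),
    model = fit
  )
}

#' Concordance between PHD indices
#'
#' Pairwise Pearson correlations (weighted and unweighted) between index
#' scores, and pairwise quintile agreement: participants are ranked within
#' the analysis stratum (ties broken by stable input order), cut into
#' quintiles, and agreement is the percentage falling in the same quintile
#' for both indices.
#'
#' @param scores Tibble/data frame of index columns (e.g. `wish_total`,
#'   `eli_total`, `eldi_total`), >= 5 rows for quintiles.
#' @param weights Optional survey weights for the weighted correlations.
#' @return List: `correlation` and `correlation_weighted` (matrices, `NA`
#'   where an index is constant), `quintile_agreement` (matrix, %).
#' @export
index_concordance <- function(scores, weights = NULL) {
  scores <- as.data.frame(scores)
  k <- ncol(scores)
  n <- nrow(scores)
  if (n < 5) stop("need >= 5 participants for quintiles", call. = FALSE)
  constant <- vapply(scores, function(x) stats::sd(x) == 0, logical(1))
  cor_u <- suppressWarnings(stats::cor(scores))
  cor_u[constant, ] <- NA_real_; cor_u[, constant] <- NA_real_
  diag(cor_u) <- ifelse(constant, NA_real_, 1)
  if (is.null(weights)) {
    cor_w <- cor_u
  } else {
    cw <- stats::cov.wt(as.matrix(scores), wt = weights / sum(weights),
                        cor = TRUE)
    cor_w <- cw$cor
    cor_w[constant, ] <- NA_real_; cor_w[, constant] <- NA_real_
    diag(cor_w) <- ifelse(constant, NA_real_, 1)
  }
  quint <- vapply(scores, function(x) {
    r <- rank(x, ties.method = "first")
    as.integer(ceiling(5 * r / n))
  }, integer(n))
  agree <- matrix(NA_real_, k, k, dimnames = list(names(scores), names(scores)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      agree[i, j] <- 100 * mean(quint[, i] == quint[, j])
    }
  }
  list(correlation = cor_u, correlation_weighted = cor_w,
       quintile_agreement = agree)
}
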