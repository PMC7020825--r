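test_that("eta-squared and F are the stated pure functions of SS and df", {
  expect_equal(eta_squared(50, 200), 0.25)
  expect_equal(f_statistic(50, 2, 200, 100), (50 / 2) / (200 / 100))
  # and agree with a fitted model's own anova output
  d <- toy_frame()
  fit <- fit_sequential_anova(d, "y")
  ss_res <- fit$ss[fit$term == "Residuals"]
  df_res <- fit$df[fit$term == "Residuals"]
  i <- which(fit$term == "stage")
  expect_equal(fit$eta_sq[i], eta_squared(fit$ss[i], ss_res))
  expect_equal(fit$f[i], f_statistic(fit$ss[i], fit$df[i], ss_res, df_res))
})

test_that("sequential SS equal nested-model residual-SS differences", {
  d <- toy_frame(seed = 19)
  fit <- fit_sequential_anova(d, "y")
  terms <- c("dist_nearest_point", "n_adjacent", "stage", "sex", "stage:sex")
  oracle <- oracle_sequential_ss(d, "y", terms)
  expect_equal(fit$term[1:5],
               c("dist_nearest_point", "n_adjacent", "stage", "sex", "stage:sex"))
  expect_equal(fit$ss[1:5], unname(oracle), tolerance = 1e-8)
  # SS identity: term SS + residual SS = total centred SS of complete cases
  expect_equal(sum(fit$ss), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
})

test_that("sequential SS are order-invariant for balanced orthogonal factors", {
  set.seed(3)
  d <- expand.grid(stage = c("breeder", "dominant", "helper"),
                   sex = c("F", "M"), rep = 1:8, stringsAsFactors = FALSE)
  d$dist_nearest_point <- 0 * seq_len(nrow(d))  # constant covariates excluded
  d$y <- rnorm(nrow(d)) + ifelse(d$stage == "helper", 1, 0)
  ss_ab <- anova(lm(y ~ stage + sex, d))["stage", "Sum Sq"]
  ss_ba <- anova(lm(y ~ sex + stage, d))["stage", "Sum Sq"]
  expect_equal(ss_ab, ss_ba, tolerance = 1e-10)
})

test_that("with constant covariates the stage term reduces to one-way ANOVA", {
  d <- toy_frame(seed = 23)
  d$dist_nearest_point <- 5; d$n_adjacent <- 3
  # drop aliased covariates by fitting the reduced model directly
  one_way <- anova(lm(y ~ stage + sex + stage:sex, d))
  expect_equal(one_way["stage", "Sum Sq"],
               anova(lm(y ~ stage, d))["stage", "Sum Sq"], tolerance = 1e-10)
  # the full fit errors informatively on the aliased covariate
  expect_error(fit_sequential_anova(d, "y"), "aliased|rank")
})

test_that("complete-case handling drops undefined responses and their df", {
  d <- toy_frame(seed = 29)
  d$y[c(1, 5, 9)] <- NA
  fit <- fit_sequential_anova(d, "y")
  expect_equal(attr(fit, "n_complete"), nrow(d) - 3)
  expect_equal(sum(fit$df), attr(fit, "n_complete") - 1)
})

test_that("Tukey differences and intervals match a from-scratch studentized-range computation", {
  d <- toy_frame(n_per_cell = 5, seed = 31)
  fit <- fit_sequential_anova(d, "y")
  td <- tukey_differences(fit, "stage")
  m <- attr(fit, "model")
  mf <- model.frame(m)
  mse <- sum(residuals(m)^2) / m$df.residual
  mu <- tapply(mf$y, mf$stage, mean)
  n <- tapply(mf$y, mf$stage, length)
  for (pair in list(c("breeder", "dominant"), c("dominant", "helper"),
                    c("breeder", "helper"))) {
    nm <- paste0(pair[1], "_vs_", pair[2])
    row <- td[td$comparison == nm, ]
    expect_equal(row$diff, unname(mu[pair[1]] - mu[pair[2]]), tolerance = 1e-10)
    hw <- qtukey(0.95, 3, m$df.residual) *
      sqrt(mse / 2 * (1 / n[pair[1]] + 1 / n[pair[2]]))
    expect_equal(row$ci95, unname(hw), tolerance = 1e-10)
  }
  # identical means give a zero difference
  d2 <- d; d2$y <- rep(1:10, length.out = nrow(d2)) +
    0.001 * d2$dist_nearest_point
  d2$y <- d2$y - ave(d2$y, d2$stage) # all group means 0
  fit2 <- fit_sequential_anova(d2, "y")
  expect_equal(tukey_differences(fit2, "stage")$diff, rep(0, 3),
               tolerance = 1e-10)
})

test_that("Tukey computation agrees with TukeyHSD on a one-way design", {
  set.seed(37)
  d <- data.frame(stage = rep(c("breeder", "dominant", "helper"),
                              times = c(12, 7, 9)))
  d$y <- rnorm(nrow(d), ifelse(d$stage == "helper", 2, 0))
  d$sex <- rep(c("F", "M"), length.out = nrow(d))
  d$dist_nearest_point <- rnorm(nrow(d))
  d$n_adjacent <- sample(2:5, nrow(d), TRUE)
  fit_one <- aov(y ~ stage, d)
  ref <- TukeyHSD(fit_one)$stage
  m <- lm(y ~ stage, d)
  mse <- sum(residuals(m)^2) / m$df.residual
  mu <- tapply(d$y, d$stage, mean); n <- tapply(d$y, d$stage, length)
  # same arithmetic as tukey_differences' internal row builder
  hw <- qtukey(0.95, 3, m$df.residual) *
    sqrt(mse / 2 * (1 / n["dominant"] + 1 / n["breeder"]))
  expect_equal(unname(ref["dominant-breeder", "upr"] - ref["dominant-breeder", "diff"]),
               unname(hw), tolerance = 1e-10)
})

test_that("helper sex contrast uses the stage-by-sex cell-mean family", {
  d <- toy_frame(n_per_cell = 6, seed = 41)
  fit <- fit_sequential_anova(d, "y")
  td <- tukey_differences(fit, "helper_sex")
  mf <- model.frame(attr(fit, "model"))
  muF <- mean(mf$y[mf$stage == "helper" & mf$sex == "F"])
  muM <- mean(mf$y[mf$stage == "helper" & mf$sex == "M"])
  expect_equal(td$diff, muF - muM, tolerance = 1e-10)
  m <- attr(fit, "model")
  mse <- sum(residuals(m)^2) / m$df.residual
  hw <- qtukey(0.95, 6, m$df.residual) * sqrt(mse / 2 * (1 / 6 + 1 / 6))
  expect_equal(td$ci95, hw, tolerance = 1e-10)
})

test_that("Brown-Forsythe matches the absolute-median-deviation formula", {
  # location shift only: identical deviation sets, F = 0
  bf0 <- brown_forsythe(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_equal(bf0$statistic, 0)
  # zero-spread group vs spread group: deviation means 0 vs 5, within-SS 0
  bfi <- brown_forsythe(c(0, 0, 0, 0, -5, 5, -5, 5), rep(c("a", "b"), each = 4))
  expect_true(bfi$statistic > 1e4 || is.infinite(bfi$statistic))
  # hand-computed small case
  y <- c(1, 4, 6, 2, 9, 3, 8, 8, 5)
  g <- rep(c("a", "b", "c"), each = 3)
  z <- abs(y - ave(y, g, FUN = median))
  zb <- tapply(z, g, mean); nn <- tapply(z, g, length)
  ssb <- sum(nn * (zb - mean(z))^2)
  ssw <- sum((z - ave(z, g))^2)
  f_hand <- (ssb / 2) / (ssw / 6)
  expect_equal(brown_forsythe(y, g)$statistic, f_hand, tolerance = 1e-12)
  if (requireNamespace("car", quietly = TRUE)) {
    lev <- car::leveneTest(y ~ factor(g), center = median)
    expect_equal(brown_forsythe(y, g)$statistic, lev[1, "F value"],
                 tolerance = 1e-8)
  }
  expect_error(brown_forsythe(1:4, rep("a", 4)), "two groups")
})

test_that("compare_stages detects a strong planted stage effect in the predicted direction", {
  cfg <- synthetic_config(grid_rows = 5, grid_cols = 5, weeks = 8,
                          dominant_prob = 0.2, helper_lambda = 1)
  st <- simulate_study(cfg, seed = 101)
  g <- filter_min_detections(st$gbi, 3)
  attrs <- st$attrs[st$attrs$individual_id %in% g$individuals, ]
  res <- compare_stages(g, attrs, st$covariates, n_permutations = 100,
                        swaps_per_sample = 5, seed = 11)
  cmp <- res$comparisons
  bh_deg <- cmp[cmp$metric == "degree" & cmp$comparison == "breeder_vs_helper", ]
  expect_lt(bh_deg$diff, 0)            # breeders associate with fewer birds
  expect_lt(bh_deg$p_parametric, 0.05)
  bh_up <- cmp[cmp$metric == "unique_points" & cmp$comparison == "breeder_vs_helper", ]
  expect_lt(bh_up$diff, 0)
  expect_lt(bh_up$p_parametric, 0.05)
  # unique points is invariant under the location-restricted scheme: no null
  expect_true(all(is.na(cmp$p_permutation[cmp$metric == "unique_points"])))
  expect_true(all(!is.na(cmp$p_permutation[cmp$metric != "unique_points"])))
  # the data-stream null conserves per-location detection effort, so its mean
  # tracks the observed difference (it is NOT centred at zero) and one-tailed
  # p-values are valid probabilities rather than guaranteed detections
  expect_lt(bh_deg$null_mean, 0)
  expect_lt(abs(bh_deg$null_mean - bh_deg$diff), abs(bh_deg$diff))
  expect_true(bh_deg$p_permutation > 0 && bh_deg$p_permutation <= 1)
  # homogeneity table carries permutation reference for network metrics only
  expect_true(is.na(res$homogeneity$p_permutation[res$homogeneity$metric == "unique_points"]))
  expect_true(all(res$homogeneity$f_observed >= 0))
})

test_that("permutation nulls conserve detection asymmetries (need not centre at zero)", {
  # two planted groups with unequal detection effort: the null mean of the
  # degree difference stays far from zero, unlike a naive label-shuffle null
  set.seed(53)
  n_a <- 8; n_b <- 8; n <- n_a + n_b
  rows <- list(); meta <- list(); k <- 0
  add_row <- function(members, pt) {
    k <<- k + 1
    r <- integer(n); r[members] <- 1L
    rows[[k]] <<- r
    meta[[k]] <<- data.frame(aggregation_id = paste0("g", k), point_id = pt,
                             date = NA, kind = "survey")
  }
  # group A individuals detected often (in large mixed parties), B rarely
  for (i in 1:60) add_row(unique(c(sample(1:n_a, 4), sample(1:n, 2))), "P1")
  for (i in 1:10) add_row(sample((n_a + 1):n, 2), "P2")
  inc <- do.call(rbind, rows)
  colnames(inc) <- sprintf("I%02d", 1:n)
  rownames(inc) <- paste0("g", seq_len(nrow(inc)))
  g <- gbi_matrix(inc, do.call(rbind, meta))
  stat <- function(x) {
    a <- sri_matrix(x); d <- binary_degree(a)
    mean(d[1:n_a]) - mean(d[(n_a + 1):n])
  }
  nd <- null_distribution(g, stat, n_permutations = 60, swaps_per_sample = 10,
                          seed = 3)
  label_null <- replicate(200, {
    a <- sri_matrix(g); d <- binary_degree(a)
    idx <- sample(n)
    mean(d[idx[1:n_a]]) - mean(d[idx[(n_a + 1):n]])
  })
  expect_gt(unname(nd$mean), 2)            # conserved effort asymmetry
  expect_lt(abs(mean(label_null)), 1)      # label shuffle centres near zero
})
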