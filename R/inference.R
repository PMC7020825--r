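metric_names <- c("degree", "betweenness", "clustering", "unique_points")

stage_pairs <- list(breeder_vs_dominant = c("breeder", "dominant"),
                    dominant_vs_helper = c("dominant", "helper"),
                    breeder_vs_helper = c("breeder", "helper"))

#' Predicted directions of stage differences
#'
#' One-tailed test directions for each metric and comparison, following the
#' a-priori natural-history predictions: breeders foray least and helpers
#' most, so breeders are predicted to have lower degree, lower betweenness,
#' higher clustering and fewer unique points than dominants, who in turn are
#' predicted lower/higher than helpers; female helpers (the earlier- and
#' farther-dispersing sex) are predicted to exceed male helpers in degree,
#' betweenness and unique points and to have lower clustering. Differences
#' are first-listed group minus second (breeder - dominant, etc.; female -
#' male).
#'
#' @return data frame with columns `comparison`, `metric`, `direction`.
#' @export
default_predictions <- function() {
  stage <- expand.grid(comparison = names(stage_pairs), metric = metric_names,
                       stringsAsFactors = FALSE)
  stage$direction <- ifelse(stage$metric == "clustering", "greater", "less")
  sexr <- data.frame(comparison = "female_vs_male_helpers",
                     metric = metric_names, stringsAsFactors = FALSE)
  sexr$direction <- ifelse(sexr$metric == "clustering", "less", "greater")
  rbind(stage, sexr)
}

#' Sequential (type-I) ANOVA with eta-squared
#'
#' Fits an ordinary least-squares model of a network metric on distance to
#' the nearest sampling point, number of adjacent territories, life-history
#' stage, sex and the stage-by-sex interaction, with sequential (type-I) sums
#' of squares in that fixed order. Rows with an undefined response (e.g.
#' clustering of degree-<=1 individuals) are dropped (complete-case). The
#' effect size reported per term is eta-squared defined as the term sum of
#' squares divided by the *residual* sum of squares.
#'
#' @param data model frame with columns `dist_nearest_point`, `n_adjacent`,
#'   `stage`, `sex` and the response.
#' @param response response column name (one of the four network metrics, or
#'   any numeric column).
#' @return object of class `"anova_eta"`: a data frame with columns `term`,
#'   `ss`, `df`, `f`, `eta_sq` (residual row last), with the fitted `lm` in
#'   attribute `"model"`.
#' @export
fit_sequential_anova <- function(data, response) {
  stopifnot(response %in% names(data))
  d <- data[!is.na(data[[response]]), , drop = FALSE]
  d$stage <- factor(d$stage)
  d$sex <- factor(d$sex)
  form <- stats::as.formula(paste(response,
                                  "~ dist_nearest_point + n_adjacent + stage + sex + stage:sex"))
  fit <- stats::lm(form, data = d)
  if (anyNA(stats::coef(fit))) {
    stop("rank-deficient fit; aliased coefficient(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))], collapse = ", "))
  }
  an <- stats::anova(fit)
  ss_res <- an["Residuals", "Sum Sq"]
  out <- data.frame(term = rownames(an),
                    ss = an[["Sum Sq"]],
                    df = an[["Df"]],
                    f = an[["F value"]],
                    eta_sq = an[["Sum Sq"]] / ss_res,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$eta_sq[out$term == "Residuals"] <- NA_real_
  structure(out, class = c("anova_eta", "data.frame"), model = fit,
            response = response, n_complete = nrow(d))
}

#' Eta-squared and F from printed sums of squares
#'
#' Pure-arithmetic helpers reproducing the effect-size and F conventions of
#' [fit_sequential_anova()] directly from tabulated sums of squares and
#' degrees of freedom: eta-squared is the term SS divided by the residual SS,
#' and F is the term mean square over the residual mean square.
#'
#' @param ss_term,df_term term sum of squares and degrees of freedom.
#' @param ss_resid,df_resid residual sum of squares and degrees of freedom.
#' @return `eta_squared()`: SS_term / SS_resid; `f_statistic()`:
#'   (SS_term/df_term) / (SS_resid/df_resid).
#' @export
eta_squared <- function(ss_term, ss_resid) ss_term / ss_resid

#' @rdname eta_squared
#' @export
f_statistic <- function(ss_term, df_term, ss_resid, df_resid) {
  (ss_term / df_term) / (ss_resid / df_resid)
}

# group means/sizes of a metric by stage (or helper sex) on complete cases
group_stats <- function(values, group) {
  ok <- !is.na(values)
  list(mean = tapply(values[ok], group[ok], mean),
       n = tapply(values[ok], group[ok], length))
}

#' Tukey HSD pairwise differences
#'
#' Family-wise pairwise mean differences with 95% studentized-range
#' intervals, computed on raw group means with the residual mean square and
#' residual degrees of freedom of the supplied multi-term model (the
#' behaviour of the classic HSD command applied to one term of a larger
#' fit). For `factor = "stage"` the family is the three life-history stages;
#' for `factor = "helper_sex"` the contrast is female minus male helpers
#' inside the stage-by-sex cell-mean family (k = number of non-empty cells).
#'
#' @param anova_fit an `"anova_eta"` object from [fit_sequential_anova()].
#' @param factor `"stage"` or `"helper_sex"`.
#' @return data frame `comparison`, `diff`, `ci95` (half-width),
#'   `p_parametric` (two-sided family-wise studentized-range p).
#' @export
tukey_differences <- function(anova_fit, factor = c("stage", "helper_sex")) {
  factor <- match.arg(factor)
  fit <- attr(anova_fit, "model")
  d <- stats::model.frame(fit)
  resp <- d[[1]]
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  dfres <- fit$df.residual
  if (factor == "stage") {
    gs <- group_stats(resp, d$stage)
    k <- length(gs$mean)
    rows <- lapply(names(stage_pairs), function(nm) {
      pr <- stage_pairs[[nm]]
      if (any(gs$n[pr] < 2) || anyNA(gs$n[pr])) {
        stop("level with fewer than 2 observations in pair ", nm)
      }
      tukey_row(nm, gs$mean[pr[1]] - gs$mean[pr[2]],
                gs$n[pr[1]], gs$n[pr[2]], mse, k, dfres)
    })
    do.call(rbind, rows)
  } else {
    cell <- interaction(d$stage, d$sex, drop = TRUE)
    gs <- group_stats(resp, cell)
    k <- length(gs$mean)
    f <- "helper.F"; m <- "helper.M"
    if (!all(c(f, m) %in% names(gs$mean)) || any(gs$n[c(f, m)] < 2)) {
      stop("helper cells need at least 2 observations per sex")
    }
    tukey_row("female_vs_male_helpers", gs$mean[f] - gs$mean[m],
              gs$n[f], gs$n[m], mse, k, dfres)
  }
}

tukey_row <- function(name, diff, na, nb, mse, k, dfres) {
  se2 <- (mse / 2) * (1 / na + 1 / nb)
  data.frame(comparison = name,
             diff = as.numeric(diff),
             ci95 = stats::qtukey(0.95, k, dfres) * sqrt(se2),
             p_parametric = stats::ptukey(abs(diff) / sqrt(se2), k, dfres,
                                          lower.tail = FALSE),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Brown-Forsythe test for homogeneity of variance
#'
#' One-way ANOVA F statistic on absolute deviations from the group medians,
#' `z_ij = |y_ij - median_j|`: robust to non-normality relative to Levene's
#' mean-centred version. Groups differing only by a location shift give F =
#' 0-ish; a group with zero spread is legal (its deviations are all 0).
#'
#' @param values numeric vector (NAs dropped).
#' @param group group labels, same length.
#' @return list `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
brown_forsythe <- function(values, group) {
  ok <- !is.na(values) & !is.na(group)
  y <- values[ok]; g <- factor(group[ok])
  if (nlevels(g) < 2) stop("need at least two groups")
  if (any(table(g) < 2)) stop("every group needs at least two values")
  med <- tapply(y, g, stats::median)
  z <- abs(y - med[g])
  zbar_g <- tapply(z, g, mean)
  n_g <- tapply(z, g, length)
  zbar <- mean(z)
  ssb <- sum(n_g * (zbar_g - zbar)^2)
  ssw <- sum((z - zbar_g[g])^2)
  k <- nlevels(g); n <- length(z)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(statistic = f, df1 = k - 1, df2 = n - k,
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Named vector of all permutation-referenced statistics for one GBI state:
# raw-mean Tukey differences for degree/betweenness/clustering over the three
# stage pairs and the helper sex contrast, plus Brown-Forsythe F per metric
# across stages. `frame_idx` maps analyzed individuals to columns of g.
stage_statistics <- function(g, a, frame, normalized = TRUE) {
  nm <- node_metrics(g, a, normalized = normalized)
  nm <- nm[match(frame$individual_id, nm$individual_id), , drop = FALSE]
  out <- c()
  helper <- frame$stage == "helper"
  for (met in c("degree", "betweenness", "clustering")) {
    v <- nm[[met]]
    mu <- tapply(v, frame$stage, mean, na.rm = TRUE)
    for (pn in names(stage_pairs)) {
      pr <- stage_pairs[[pn]]
      out[paste0(met, ".", pn)] <- mu[pr[1]] - mu[pr[2]]
    }
    out[paste0(met, ".female_vs_male_helpers")] <-
      mean(v[helper & frame$sex == "F"], na.rm = TRUE) -
      mean(v[helper & frame$sex == "M"], na.rm = TRUE)
    out[paste0("bf.", met)] <- brown_forsythe(v, frame$stage)$statistic
  }
  out
}

#' Stage comparisons with data-stream permutation reference
#'
#' Runs the full inferential stage of the pipeline on a filtered GBI matrix:
#' per-metric sequential ANOVA, Tukey HSD stage differences and the
#' female-vs-male helper contrast, Brown-Forsythe homogeneity statistics,
#' and — for the metrics computed from the network (degree, betweenness,
#' clustering) — a location-restricted data-stream permutation null for every
#' statistic with one-tailed p-values in the predicted directions. Unique
#' points is invariant under location-restricted swaps (each individual's
#' set of detection points is conserved by construction), so its comparisons
#' carry parametric p-values only and no null.
#'
#' @param g filtered `gbi` object (the network).
#' @param attrs individual attributes (see [read_attributes()]).
#' @param covariates territory covariates (`territory_id`,
#'   `dist_nearest_point`, `n_adjacent`).
#' @param analyzed character vector of individual ids passing the inclusion
#'   criteria; defaults to every network individual present in `attrs`.
#' @param n_permutations permutation count (0 = parametric only).
#' @param swaps_per_sample,burn_in chain controls, see [null_distribution()].
#' @param seed RNG seed for the permutation chain.
#' @param normalized betweenness normalization flag.
#' @param predictions data frame of one-tailed directions
#'   (default [default_predictions()]).
#' @return list with `anova` (per-metric `anova_eta` tables), `comparisons`
#'   (per comparison x metric: observed difference, CI half-width, parametric
#'   p, null mean, null CI, one-tailed permutation p), `homogeneity`
#'   (per-metric Brown-Forsythe with null reference), `null`
#'   (`null_distribution` or NULL), `model_frame`.
#' @export
compare_stages <- function(g, attrs, covariates, analyzed = NULL,
                           n_permutations = 1000, swaps_per_sample = 1,
                           burn_in = 0, seed = NULL, normalized = TRUE,
                           predictions = default_predictions()) {
  stopifnot(inherits(g, "gbi"))
  attrs <- validate_attributes(attrs)
  a <- sri_matrix(g)
  if (is.null(analyzed)) analyzed <- intersect(g$individuals, attrs$individual_id)
  analyzed <- intersect(analyzed, g$individuals)
  ai <- match(analyzed, attrs$individual_id)
  if (anyNA(ai)) stop("attributes missing for: ",
                      paste(analyzed[is.na(ai)], collapse = ", "))
  ti <- match(attrs$territory_id[ai], covariates$territory_id)
  if (anyNA(ti)) stop("covariates missing for territory(ies): ",
                      paste(unique(attrs$territory_id[ai][is.na(ti)]), collapse = ", "))
  nm <- node_metrics(g, a, normalized = normalized)
  frame <- data.frame(individual_id = analyzed,
                      stage = attrs$stage[ai], sex = attrs$sex[ai],
                      dist_nearest_point = covariates$dist_nearest_point[ti],
                      n_adjacent = covariates$n_adjacent[ti],
                      nm[match(analyzed, nm$individual_id),
                         c("degree", "betweenness", "clustering", "unique_points")],
                      stringsAsFactors = FALSE, row.names = NULL)

  anovas <- lapply(stats::setNames(metric_names, metric_names),
                   function(m) fit_sequential_anova(frame, m))
  comp <- do.call(rbind, lapply(metric_names, function(m) {
    td <- rbind(tukey_differences(anovas[[m]], "stage"),
                tukey_differences(anovas[[m]], "helper_sex"))
    td$metric <- m
    td
  }))
  comp <- merge(comp, predictions, by = c("comparison", "metric"),
                all.x = TRUE, sort = FALSE)
  homog <- do.call(rbind, lapply(metric_names, function(m) {
    bf <- brown_forsythe(frame[[m]], frame$stage)
    data.frame(metric = m, f_observed = bf$statistic,
               df1 = bf$df1, df2 = bf$df2, p_parametric = bf$p_value,
               stringsAsFactors = FALSE)
  }))
  comp$null_mean <- NA_real_; comp$null_ci95 <- NA_real_
  comp$p_permutation <- NA_real_
  homog$null_mean <- NA_real_; homog$null_ci95 <- NA_real_
  homog$p_permutation <- NA_real_
  nd <- NULL
  if (n_permutations > 0) {
    statfun <- function(gp) stage_statistics(gp, sri_matrix(gp), frame, normalized)
    nd <- null_distribution(g, statfun, constraint = swap_constraint(g),
                            n_permutations = n_permutations,
                            swaps_per_sample = swaps_per_sample,
                            burn_in = burn_in, seed = seed)
    for (i in seq_len(nrow(comp))) {
      key <- paste0(comp$metric[i], ".", comp$comparison[i])
      if (!key %in% colnames(nd$values)) next  # unique_points: no null
      comp$null_mean[i] <- nd$mean[key]
      comp$null_ci95[i] <- nd$ci95[key]
      comp$p_permutation[i] <- one_tailed_p(comp$diff[i], nd$values[, key],
                                            direction = comp$direction[i])
    }
    for (i in seq_len(nrow(homog))) {
      key <- paste0("bf.", homog$metric[i])
      if (!key %in% colnames(nd$values)) next
      homog$null_mean[i] <- nd$mean[key]
      homog$null_ci95[i] <- nd$ci95[key]
      homog$p_permutation[i] <- one_tailed_p(homog$f_observed[i],
                                             nd$values[, key],
                                             direction = "greater")
    }
  }
  ord <- order(match(comp$metric, metric_names),
               match(comp$comparison, c(names(stage_pairs), "female_vs_male_helpers")))
  list(anova = anovas, comparisons = comp[ord, ], homogeneity = homog,
       null = nd, model_frame = frame)
}
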