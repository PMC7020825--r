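#' Simple-ratio-index association matrix
#'
#' For every unordered dyad (A, B) the simple ratio index is
#' \deqn{SRI = x / D,} where `x` is the number of aggregations containing both
#' individuals and `D` the number containing either (the SRI denominator).
#' The SRI corrects association strength for how often each individual was
#' detected; its denominator is also the per-dyad sample size used to judge
#' network robustness.
#'
#' @param g a `gbi` object with at least two individuals.
#' @return an object of class `"association_matrix"`: `individuals`, `sri`
#'   (symmetric, zero diagonal, values in [0, 1]) and `denominator`
#'   (symmetric integer matrix of union counts).
#' @export
sri_matrix <- function(g) {
  stopifnot(inherits(g, "gbi"))
  n <- length(g$individuals)
  if (n < 2) stop("need at least two individuals to form dyads")
  x <- crossprod(g$incidence)              # joint detection counts; diag = per-individual totals
  d <- diag(x)
  denom <- outer(d, d, "+") - x            # |A union B|
  sri <- ifelse(denom > 0, x / denom, 0)
  diag(sri) <- 0
  diag(denom) <- 0L
  storage.mode(denom) <- "integer"
  dimnames(sri) <- dimnames(denom) <- list(g$individuals, g$individuals)
  structure(list(individuals = g$individuals, sri = sri, denominator = denom),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  n <- length(x$individuals)
  up <- upper.tri(x$sri)
  cat("SRI association matrix:", n, "individuals,",
      sum(x$sri[up] > 0), "of", n * (n - 1) / 2, "dyads connected\n")
  cat("  mean nonzero SRI:", signif(mean(x$sri[up][x$sri[up] > 0]), 3),
      "| mean denominator:", signif(mean(x$denominator[up]), 4), "\n")
  invisible(x)
}

#' Dyad-denominator robustness summary
#'
#' Summarises the distribution of SRI denominators over all unordered dyads:
#' the percentage of dyads whose denominator falls below a minimum-sample
#' threshold (conventionally 20), plus the mean and standard error of the
#' denominator. Optionally restricted to a subset of individuals (e.g., the
#' statistically analysed set rather than the full network).
#'
#' @param a an `association_matrix`.
#' @param threshold minimum acceptable denominator (>= 1), default 20.
#' @param individuals optional character vector restricting the dyads to
#'   pairs within this subset.
#' @return list with `percent_below` (0-100 scale), `mean_denominator`,
#'   `se_denominator`, `n_dyads` and `threshold`.
#' @export
robustness_summary <- function(a, threshold = 20, individuals = NULL) {
  stopifnot(inherits(a, "association_matrix"), threshold >= 1)
  den <- a$denominator
  if (!is.null(individuals)) {
    miss <- setdiff(individuals, a$individuals)
    if (length(miss) > 0) stop("unknown individual(s): ", paste(miss, collapse = ", "))
    den <- den[individuals, individuals, drop = FALSE]
  }
  v <- den[upper.tri(den)]
  list(percent_below = 100 * mean(v < threshold),
       mean_denominator = mean(v),
       se_denominator = stats::sd(v) / sqrt(length(v)),
       n_dyads = length(v),
       threshold = threshold)
}
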