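#' Location-restricted swap constraint
#'
#' Data-stream permutations exchange detections between aggregations, but only
#' within a restriction class so that each individual's number of detections
#' per class — here, per sampling location — is conserved. By default survey
#' aggregations are classed by their sampling point and each opportunistic
#' aggregation forms its own singleton class (it has no sampling point, so no
#' legal exchange partner); opportunistic records are therefore frozen.
#'
#' @param g a `gbi` object.
#' @param class_of optional character vector (one entry per aggregation)
#'   overriding the default classes.
#' @return object of class `"swap_constraint"` holding the class labels.
#' @export
swap_constraint <- function(g, class_of = NULL) {
  stopifnot(inherits(g, "gbi"))
  if (is.null(class_of)) {
    class_of <- ifelse(g$meta$kind == "survey",
                       paste0("pt_", g$meta$point_id),
                       paste0("opp_", g$meta$aggregation_id))
  }
  stopifnot(length(class_of) == nrow(g$incidence))
  structure(list(class_of = as.character(class_of)), class = "swap_constraint")
}

# Row-index sets (length >= 2) per restriction class; precomputed once per chain.
class_row_sets <- function(class_of) {
  sets <- split(seq_along(class_of), class_of)
  sets[lengths(sets) >= 2]
}

# One checkerboard swap on a bare incidence matrix. Proposal: pick a class
# with >= 2 aggregations (uniformly), two distinct rows in it (uniformly),
# then one column from each side of the rows' symmetric difference (where
# row1 has the 1 and row2 the 0, and vice versa) — a guaranteed checkerboard.
# The kernel is symmetric (after the flip the two column sets trade roles but
# keep their sizes), so the stationary distribution over margin-preserving
# matrices is the same uniform one as naive rejection sampling, at a far
# higher acceptance rate. Row pairs with an empty side are rejected; errors
# after max_tries rejected proposals.
swap_once <- function(inc, class_of, max_tries = 1e5,
                      row_sets = class_row_sets(class_of)) {
  if (length(row_sets) == 0) {
    stop("no restriction class contains two or more aggregations (swap stall)")
  }
  for (t in seq_len(max_tries)) {
    rows <- row_sets[[sample.int(length(row_sets), 1L)]]
    r <- rows[sample.int(length(rows), 2L)]
    v1 <- inc[r[1], ]; v2 <- inc[r[2], ]
    c1 <- which(v1 == 1L & v2 == 0L)
    c2 <- which(v1 == 0L & v2 == 1L)
    if (length(c1) == 0 || length(c2) == 0) next
    j1 <- c1[sample.int(length(c1), 1L)]
    j2 <- c2[sample.int(length(c2), 1L)]
    inc[r[1], j1] <- 0L; inc[r[1], j2] <- 1L
    inc[r[2], j1] <- 1L; inc[r[2], j2] <- 0L
    return(inc)
  }
  stop("no swappable checkerboard found after ", max_tries,
       " proposals (swap stall)")
}

#' Apply one checkerboard swap to a GBI matrix
#'
#' Selects two aggregations in the same restriction class and two individuals
#' whose 2x2 incidence submatrix is a checkerboard ([[1,0],[0,1]] or its
#' mirror) and exchanges the pattern. Row sums, column sums and per-class
#' column sums are all conserved; exactly four cells change.
#'
#' @param g a `gbi` object.
#' @param constraint a [swap_constraint()]; default built from `g`.
#' @param max_tries proposals attempted before declaring a stall.
#' @return the swapped `gbi` object.
#' @export
checkerboard_swap <- function(g, constraint = swap_constraint(g), max_tries = 1e5) {
  stopifnot(inherits(g, "gbi"), inherits(constraint, "swap_constraint"))
  g$incidence <- swap_once(g$incidence, constraint$class_of, max_tries)
  g
}

#' Null distribution of a statistic under data-stream permutation
#'
#' Runs a serial swap chain from the observed matrix: apply
#' `swaps_per_sample` accepted checkerboard swaps, record the statistic,
#' repeat `n_permutations` times. With the default single swap per sample
#' successive values are highly autocorrelated — the convention of the
#' standard data-stream implementation — so the summary interval is a 95%
#' confidence interval of the null mean, not a quantile range. `burn_in`
#' extra swaps before the first sample and larger `swaps_per_sample` improve
#' mixing at the cost of deviating from that convention.
#'
#' @param g a `gbi` object (the observed data; the chain starts here).
#' @param statistic function taking a `gbi` and returning a numeric scalar or
#'   named vector (all samples must have the same length and names).
#' @param constraint a [swap_constraint()].
#' @param n_permutations number of recorded samples (default 1000).
#' @param swaps_per_sample accepted swaps between successive samples.
#' @param burn_in accepted swaps before the first sample.
#' @param seed optional integer seed for reproducibility.
#' @param max_tries stall bound per accepted swap.
#' @return object of class `"null_distribution"`: `label`, `values` (matrix,
#'   n_permutations x n_statistics), `mean`, `ci95` (1.96 * sd / sqrt(n)),
#'   `seed`, `swaps_per_sample`, `burn_in`.
#' @export
null_distribution <- function(g, statistic, constraint = swap_constraint(g),
                              n_permutations = 1000, swaps_per_sample = 1,
                              burn_in = 0, seed = NULL, max_tries = 1e5) {
  stopifnot(inherits(g, "gbi"), is.function(statistic),
            n_permutations >= 1, swaps_per_sample >= 1)
  if (!is.null(seed)) set.seed(seed)
  s0 <- statistic(g)
  if (!all(is.finite(s0))) stop("statistic is not finite on the observed data")
  inc <- g$incidence
  cls <- constraint$class_of
  rs <- class_row_sets(cls)
  for (i in seq_len(burn_in)) inc <- swap_once(inc, cls, max_tries, rs)
  vals <- matrix(NA_real_, nrow = n_permutations, ncol = length(s0),
                 dimnames = list(NULL, names(s0)))
  gp <- g
  for (k in seq_len(n_permutations)) {
    for (i in seq_len(swaps_per_sample)) inc <- swap_once(inc, cls, max_tries, rs)
    gp$incidence <- inc
    vals[k, ] <- statistic(gp)
  }
  mu <- colMeans(vals)
  ci <- 1.96 * apply(vals, 2, stats::sd) / sqrt(n_permutations)
  structure(list(label = names(s0), values = vals, mean = mu, ci95 = ci,
                 observed = s0, seed = seed,
                 swaps_per_sample = swaps_per_sample, burn_in = burn_in),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("Data-stream permutation null:", nrow(x$values), "samples,",
      x$swaps_per_sample, "swap(s)/sample\n")
  for (j in seq_along(x$mean)) {
    cat(sprintf("  %s: null mean %.4g +/- %.2g (observed %.4g)\n",
                if (is.null(x$label[j]) || is.na(x$label[j])) paste0("stat", j) else x$label[j],
                x$mean[j], x$ci95[j], x$observed[j]))
  }
  invisible(x)
}

#' One-tailed permutation p-value
#'
#' Add-one convention: p = (1 + number of permuted values as or more extreme
#' than the observed value in the predicted direction) / (1 + number of
#' permutations). Guarantees p > 0, so an observed value beyond every
#' permuted value reports 1/(B+1) rather than 0.
#'
#' @param observed observed statistic.
#' @param null a `null_distribution` or numeric vector of permuted values.
#' @param direction `"less"` if the prediction is that the observed value is
#'   low relative to the null, `"greater"` if high.
#' @param statistic column name when `null` holds several statistics.
#' @return the one-tailed p-value.
#' @export
one_tailed_p <- function(observed, null, direction = c("less", "greater"),
                         statistic = NULL) {
  direction <- match.arg(direction)
  vals <- if (inherits(null, "null_distribution")) {
    if (!is.null(statistic)) null$values[, statistic] else null$values[, 1]
  } else as.numeric(null)
  if (length(vals) == 0) stop("empty null distribution")
  extreme <- if (direction == "less") sum(vals <= observed) else sum(vals >= observed)
  (1 + extreme) / (1 + length(vals))
}
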