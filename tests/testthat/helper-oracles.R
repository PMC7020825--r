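# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles deliberately use naive enumeration, not the package's code
# paths.

# random GBI with survey/opportunistic mix; rows guaranteed non-empty
random_gbi <- function(n_agg, n_ind, p = 0.3, n_points = 4, opp_frac = 0.2,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rbinom(n_agg * n_ind, 1, p), n_agg, n_ind)
  for (i in which(rowSums(m) == 0)) m[i, sample.int(n_ind, 1)] <- 1L
  colnames(m) <- sprintf("I%02d", seq_len(n_ind))
  rownames(m) <- sprintf("A%03d", seq_len(n_agg))
  kind <- ifelse(runif(n_agg) < opp_frac, "opportunistic", "survey")
  meta <- data.frame(aggregation_id = rownames(m),
                     point_id = ifelse(kind == "survey",
                                       sprintf("P%d", sample.int(n_points, n_agg, TRUE)),
                                       NA_character_),
                     date = "2017-03-01", kind = kind,
                     stringsAsFactors = FALSE)
  gbi_matrix(m, meta)
}

# SRI by explicit aggregation-set intersection/union per dyad
oracle_sri <- function(inc) {
  n <- ncol(inc)
  sets <- lapply(seq_len(n), function(j) which(inc[, j] == 1))
  sri <- matrix(0, n, n); den <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- length(intersect(sets[[i]], sets[[j]]))
    D <- length(union(sets[[i]], sets[[j]]))
    den[i, j] <- den[j, i] <- D
    sri[i, j] <- sri[j, i] <- if (D > 0) x / D else 0
  }
  dimnames(sri) <- dimnames(den) <- list(colnames(inc), colnames(inc))
  list(sri = sri, denominator = den)
}

# all simple paths between s and t in a weighted graph (weight = length)
all_simple_paths_rec <- function(adj, s, t, visited, path) {
  if (s == t) return(list(path))
  out <- list()
  for (v in which(adj[s, ] > 0)) {
    if (!visited[v]) {
      visited[v] <- TRUE
      out <- c(out, all_simple_paths_rec(adj, v, t, visited, c(path, v)))
      visited[v] <- FALSE
    }
  }
  out
}

# betweenness by exhaustive shortest-path enumeration with fractional credit
oracle_betweenness <- function(len, normalized = FALSE, tol = 1e-9) {
  # len: symmetric matrix of edge lengths, 0/Inf = no edge
  n <- nrow(len)
  adj <- is.finite(len) & len > 0
  bc <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    visited <- rep(FALSE, n); visited[s] <- TRUE
    paths <- all_simple_paths_rec(adj, s, t, visited, s)
    if (length(paths) == 0) next
    plen <- vapply(paths, function(p) {
      sum(len[cbind(p[-length(p)], p[-1])])
    }, numeric(1))
    best <- min(plen)
    short <- paths[plen <= best + tol]
    for (p in short) {
      interior <- setdiff(p, c(s, t))
      bc[interior] <- bc[interior] + 1 / length(short)
    }
  }
  if (normalized) bc <- bc / ((n - 1) * (n - 2) / 2)
  bc
}

# local clustering by neighbour-pair counting
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    pairs <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (adj[nb[a], nb[b]] > 0) pairs <- pairs + 1
    }
    out[i] <- pairs / choose(k, 2)
  }
  out
}

# sequential sums of squares by nested-model residual-SS differences
oracle_sequential_ss <- function(data, response, terms) {
  rhs <- c("1", Reduce(function(a, b) paste(a, b, sep = " + "), terms,
                       accumulate = TRUE))
  rss <- vapply(rhs, function(r) {
    sum(residuals(lm(as.formula(paste(response, "~", r)), data = data))^2)
  }, numeric(1))
  -diff(rss)
}

# one-round attributes/covariates for a toy analysis frame
toy_frame <- function(n_per_cell = 6, seed = 7, effect = c(breeder = 0,
                      dominant = 2, helper = 4)) {
  set.seed(seed)
  d <- expand.grid(stage = c("breeder", "dominant", "helper"),
                   sex = c("F", "M"), rep = seq_len(n_per_cell),
                   stringsAsFactors = FALSE)
  d$dist_nearest_point <- runif(nrow(d), 0, 80)
  d$n_adjacent <- sample(2:6, nrow(d), TRUE)
  d$y <- effect[d$stage] + 0.02 * d$dist_nearest_point + rnorm(nrow(d))
  d
}
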