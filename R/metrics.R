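#' Binary degree
#'
#' Number of distinct individuals with which each individual has a nonzero
#' association. Binary rather than weighted degree avoids the downward bias in
#' edge weights between group members and neighbours that arises when
#' opportunistic records are restricted to non-neighbour aggregations.
#'
#' @param a an `association_matrix`.
#' @return named integer vector of degrees.
#' @export
binary_degree <- function(a) {
  stopifnot(inherits(a, "association_matrix"))
  adj <- a$sri > 0
  diag(adj) <- FALSE
  stats::setNames(as.integer(rowSums(adj)), a$individuals)
}

assoc_graph <- function(a) {
  w <- a$sri
  diag(w) <- 0
  igraph::graph_from_adjacency_matrix(w, mode = "undirected", weighted = TRUE)
}

#' Vertex betweenness centrality under inverse-SRI edge lengths
#'
#' Betweenness counts (with fractional credit shared among tied geodesics) how
#' often a focal individual lies on shortest paths between pairs of other
#' individuals. Strong associations should make a path "shorter", so edge
#' lengths are the inverse of the SRI weights. Pairs in different components
#' contribute nothing. With `normalized = TRUE` (default) values are divided
#' by (n-1)(n-2)/2, the number of ordered-into-unordered interior pairs in an
#' undirected graph, making values comparable across years with different
#' network sizes.
#'
#' @param a an `association_matrix`.
#' @param normalized divide by (n-1)(n-2)/2?
#' @return named numeric vector of betweenness values.
#' @export
betweenness_inverse_weight <- function(a, normalized = TRUE) {
  stopifnot(inherits(a, "association_matrix"))
  n <- length(a$individuals)
  if (n < 3) return(stats::setNames(rep(0, n), a$individuals))
  gr <- assoc_graph(a)
  b <- igraph::betweenness(gr, directed = FALSE,
                           weights = 1 / igraph::E(gr)$weight)
  if (normalized) b <- b / ((n - 1) * (n - 2) / 2)
  stats::setNames(as.numeric(b), a$individuals)
}

#' Local clustering coefficient
#'
#' Proportion of a focal individual's associates that are themselves
#' associated, computed on the binary (SRI > 0) adjacency. Undefined (NA) for
#' individuals with fewer than two associates; such values propagate as
#' missing into downstream models, reducing the residual degrees of freedom.
#'
#' @param a an `association_matrix`.
#' @return named numeric vector in [0, 1], NA where degree <= 1.
#' @export
local_clustering <- function(a) {
  stopifnot(inherits(a, "association_matrix"))
  adj <- (a$sri > 0) * 1
  diag(adj) <- 0
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  cc <- igraph::transitivity(gr, type = "local", isolates = "NaN")
  cc[is.nan(cc)] <- NA_real_
  stats::setNames(as.numeric(cc), a$individuals)
}

#' Unique sampling points per individual
#'
#' Number of distinct survey points at which each individual was detected.
#' Opportunistic aggregations have no sampling point and are excluded unless
#' `include_opportunistic = TRUE`, in which case each opportunistic
#' aggregation counts as its own pseudo-point.
#'
#' @param g a `gbi` object.
#' @param include_opportunistic count opportunistic aggregations as
#'   single-use pseudo-points?
#' @return named integer vector of unique-point counts.
#' @export
unique_points <- function(g, include_opportunistic = FALSE) {
  stopifnot(inherits(g, "gbi"))
  pts <- g$meta$point_id
  use <- g$meta$kind == "survey"
  if (include_opportunistic) {
    opp <- g$meta$kind == "opportunistic"
    pts[opp] <- paste0(".opp_", g$meta$aggregation_id[opp])
    use <- use | opp
  }
  out <- vapply(seq_along(g$individuals), function(j) {
    rows <- use & g$incidence[, j] == 1L
    length(unique(pts[rows]))
  }, integer(1))
  stats::setNames(out, g$individuals)
}

#' Per-individual network position metrics
#'
#' Convenience wrapper assembling the four response variables of the stage
#' analysis into one table.
#'
#' @param g a `gbi` object (used for unique points).
#' @param a the matching `association_matrix`; computed from `g` if missing.
#' @param normalized passed to [betweenness_inverse_weight()].
#' @return data frame with columns `individual_id`, `degree`, `betweenness`,
#'   `clustering`, `unique_points`.
#' @export
node_metrics <- function(g, a = NULL, normalized = TRUE) {
  stopifnot(inherits(g, "gbi"))
  if (is.null(a)) a <- sri_matrix(g)
  stopifnot(identical(a$individuals, g$individuals))
  data.frame(individual_id = g$individuals,
             degree = as.integer(binary_degree(a)),
             betweenness = as.numeric(betweenness_inverse_weight(a, normalized)),
             clustering = as.numeric(local_clustering(a)),
             unique_points = as.integer(unique_points(g)),
             stringsAsFactors = FALSE, row.names = NULL)
}
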