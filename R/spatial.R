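#' Territory polygon
#'
#' A closed planar vertex ring in projected coordinates (metres). The ring is
#' stored without a repeated closing vertex; it must have at least three
#' vertices, positive area and no self-intersections.
#'
#' @param territory_id identifier.
#' @param x,y vertex coordinates in ring order.
#' @return object of class `"territory_polygon"`.
#' @export
territory_polygon <- function(territory_id, x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) > 1 && x[1] == x[length(x)] && y[1] == y[length(y)]) {
    x <- x[-length(x)]; y <- y[-length(y)]
  }
  if (length(x) < 3) stop("polygon ", territory_id, " has fewer than 3 vertices")
  area <- shoelace_area(x, y)
  if (abs(area) < .Machine$double.eps * 100) {
    stop("polygon ", territory_id, " has zero area (degenerate)")
  }
  if (ring_self_intersects(x, y)) {
    stop("polygon ", territory_id, " is self-intersecting")
  }
  structure(list(territory_id = territory_id, x = x, y = y,
                 area = abs(area)), class = "territory_polygon")
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

# do open segments (p1,p2) and (p3,p4) properly cross?
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

ring_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- function(i) list(c(x[i], y[i]), c(x[i %% n + 1], y[i %% n + 1]))
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the ring closure
      a <- seg(i); b <- seg(j)
      if (segments_cross(a[[1]], a[[2]], b[[1]], b[[2]])) return(TRUE)
    }
  }
  FALSE
}

# distance from point p to segment (a, b)
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  wx <- px - ax; wy <- py - ay
  L2 <- vx^2 + vy^2
  t <- ifelse(L2 > 0, pmin(1, pmax(0, (wx * vx + wy * vy) / pmax(L2, .Machine$double.xmin))), 0)
  sqrt((wx - t * vx)^2 + (wy - t * vy)^2)
}

ring_segments <- function(p) {
  n <- length(p$x)
  j <- c(2:n, 1)
  data.frame(ax = p$x, ay = p$y, bx = p$x[j], by = p$y[j])
}

#' Distance from a territory boundary to the nearest sampling point
#'
#' Minimum Euclidean distance from any boundary segment of the territory ring
#' to any sampling point. The criterion concerns proximity of sampling
#' coverage to the territory *edge*, so a point inside the territory returns
#' its distance to the nearest edge segment (0 only when it lies on the edge).
#'
#' @param t a `territory_polygon`.
#' @param points data frame with columns `x`, `y` (and optionally `point_id`).
#' @return minimum distance in metres.
#' @export
nearest_point_distance <- function(t, points) {
  stopifnot(inherits(t, "territory_polygon"), nrow(points) >= 1)
  segs <- ring_segments(t)
  mins <- vapply(seq_len(nrow(points)), function(i) {
    min(point_segment_distance(points$x[i], points$y[i],
                               segs$ax, segs$ay, segs$bx, segs$by))
  }, numeric(1))
  min(mins)
}

segment_pair_distance <- function(a, b) {
  # min distance between two segment sets (data frames of ax, ay, bx, by)
  best <- Inf
  for (i in seq_len(nrow(a))) {
    p1 <- c(a$ax[i], a$ay[i]); p2 <- c(a$bx[i], a$by[i])
    for (j in seq_len(nrow(b))) {
      p3 <- c(b$ax[j], b$ay[j]); p4 <- c(b$bx[j], b$by[j])
      if (segments_cross(p1, p2, p3, p4)) return(0)
      d <- min(point_segment_distance(p1[1], p1[2], p3[1], p3[2], p4[1], p4[2]),
               point_segment_distance(p2[1], p2[2], p3[1], p3[2], p4[1], p4[2]),
               point_segment_distance(p3[1], p3[2], p1[1], p1[2], p2[1], p2[2]),
               point_segment_distance(p4[1], p4[2], p1[1], p1[2], p2[1], p2[2]))
      if (d < best) best <- d
    }
  }
  best
}

#' Count immediately adjacent territories
#'
#' A territory is adjacent when its boundary comes within `tolerance` metres
#' of the focal boundary (shared segment or touch). Corner-only contact
#' counts as adjacent by default, matching the reporting convention of
#' polygon-neighbour tools; set `corner_counts = FALSE` to require contact
#' along more than a single point (approximated as boundary contact at two
#' ring vertices).
#'
#' @param t focal `territory_polygon`.
#' @param others list of `territory_polygon`s (the focal one is ignored if
#'   present).
#' @param tolerance contact tolerance in metres.
#' @param corner_counts count corner-only (point) contact as adjacency?
#' @return integer neighbour count.
#' @export
adjacency_count <- function(t, others, tolerance = 0.1, corner_counts = TRUE) {
  stopifnot(inherits(t, "territory_polygon"))
  segs_t <- ring_segments(t)
  n <- 0L
  for (o in others) {
    if (identical(o$territory_id, t$territory_id)) next
    # bounding-box prescreen: boundaries cannot touch if the boxes are apart
    if (min(o$x) > max(t$x) + tolerance || max(o$x) < min(t$x) - tolerance ||
        min(o$y) > max(t$y) + tolerance || max(o$y) < min(t$y) - tolerance) next
    segs_o <- ring_segments(o)
    if (corner_counts) {
      if (segment_pair_distance(segs_t, segs_o) <= tolerance) n <- n + 1L
    } else {
      # require two distinct focal vertices in contact (a shared stretch)
      vd <- vapply(seq_along(t$x), function(i) {
        min(point_segment_distance(t$x[i], t$y[i],
                                   segs_o$ax, segs_o$ay, segs_o$bx, segs_o$by))
      }, numeric(1))
      if (sum(vd <= tolerance) >= 2) n <- n + 1L
    }
  }
  n
}

#' Territory covariates from polygons and points
#'
#' Computes, for every territory, the distance from its boundary to the
#' nearest sampling point and its number of immediately adjacent territories.
#'
#' @param polygons list of `territory_polygon`s.
#' @param points data frame with `x`, `y`.
#' @param tolerance adjacency tolerance in metres.
#' @return data frame `territory_id`, `dist_nearest_point`, `n_adjacent`.
#' @export
territory_covariates <- function(polygons, points, tolerance = 0.1) {
  data.frame(
    territory_id = vapply(polygons, `[[`, character(1), "territory_id"),
    dist_nearest_point = vapply(polygons, nearest_point_distance, numeric(1),
                                points = points),
    n_adjacent = vapply(polygons, adjacency_count, integer(1),
                        others = polygons, tolerance = tolerance),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply spatial and survival inclusion criteria
#'
#' Retains individuals that survived the sampling period, whose territory has
#' a sampling point within `max_dist` metres of its boundary (boundary
#' inclusive: "within 100 m" is read as <= 100) and whose territory has at
#' least `min_adjacent` immediately adjacent neighbours ("one or fewer"
#' neighbours excluded means >= 2 retained). Exclusion reasons are tallied
#' with the declared precedence survival > distance > adjacency, so the
#' tallies partition the excluded set.
#'
#' @param attrs individual attribute data frame (must carry `territory_id`;
#'   a logical `survived` column is honoured, defaulting to TRUE).
#' @param covariates data frame `territory_id`, `dist_nearest_point`,
#'   `n_adjacent`.
#' @param max_dist maximum boundary-to-point distance in metres (default 100).
#' @param min_adjacent minimum neighbour count (default 2).
#' @return list: `retained` (character vector of individual ids),
#'   `exclusions` (data frame individual_id, reason), `tally` (named counts).
#' @export
apply_inclusion <- function(attrs, covariates, max_dist = 100, min_adjacent = 2) {
  attrs <- validate_attributes(attrs)
  idx <- match(attrs$territory_id, covariates$territory_id)
  if (anyNA(idx)) {
    stop("missing covariates for territory(ies): ",
         paste(unique(attrs$territory_id[is.na(idx)]), collapse = ", "))
  }
  dist <- covariates$dist_nearest_point[idx]
  adj <- covariates$n_adjacent[idx]
  reason <- rep(NA_character_, nrow(attrs))
  reason[!attrs$survived] <- "survival"
  reason[is.na(reason) & dist > max_dist] <- "distance"
  reason[is.na(reason) & adj < min_adjacent] <- "adjacency"
  excl <- !is.na(reason)
  list(retained = attrs$individual_id[!excl],
       exclusions = data.frame(individual_id = attrs$individual_id[excl],
                               reason = reason[excl],
                               stringsAsFactors = FALSE),
       tally = c(survival = sum(reason == "survival", na.rm = TRUE),
                 distance = sum(reason == "distance", na.rm = TRUE),
                 adjacency = sum(reason == "adjacency", na.rm = TRUE),
                 retained = sum(!excl)))
}
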