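#' Configuration for the stage-structured survey simulator
#'
#' Defaults emulate the field design the pipeline was built for: a grid of
#' ~9 ha (300 m side) territories, each held by a monogamous breeder pair or
#' occasionally by a non-breeding dominant, with 0-7 helpers residing on
#' breeder territories; playback points at territory-boundary intersections
#' at least 200 m apart, visited twice a week for 12 weeks; stage- and
#' sex-specific foray propensity (helpers foray most, female helpers more
#' than males, breeders not at all) with a short-range truncated-geometric
#' foray kernel; and occasional opportunistic aggregations recorded only when
#' they contain individuals from non-adjacent territories.
#'
#' @param grid_rows,grid_cols territory grid dimensions.
#' @param territory_side square territory side in metres (300 m = 9 ha).
#' @param dominant_prob probability a territory is held by a single
#'   non-breeding dominant instead of a breeder pair.
#' @param helper_lambda Poisson mean for helpers per breeder territory
#'   (truncated at `max_helpers`).
#' @param max_helpers hard cap on helpers per territory.
#' @param sex_ratio probability an individual of undetermined sex is female.
#' @param foray_prob named vector of per-round foray probabilities for
#'   `breeder_F`, `breeder_M`, `dominant_F`, `dominant_M`, `helper_F`,
#'   `helper_M`.
#' @param foray_geom_q success parameter of the truncated geometric
#'   distribution over foray distance in territory steps.
#' @param foray_max_steps maximum foray distance (Chebyshev territory steps).
#' @param detection_radius playback response radius in metres.
#' @param response_prob probability an in-range individual responds.
#' @param surveys_per_week,weeks sampling effort.
#' @param opportunistic_prob probability a qualifying off-territory forayer
#'   group is recorded as an opportunistic aggregation.
#' @param min_point_spacing minimum distance between sampling points (m).
#' @param point_jitter radius (m) of the uniform-disc displacement of each
#'   sampling point from its boundary intersection: points sit near, not on,
#'   the intersections. The default (50) keeps every point within 100 m of
#'   all four surrounding territory boundaries and preserves 200 m spacing
#'   on a 300 m grid, while giving the distance covariate real variation.
#' @param prob_laid_egg probability a breeder laid an egg this season.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(grid_rows = 8, grid_cols = 8, territory_side = 300,
                             dominant_prob = 0.15, helper_lambda = 0.7,
                             max_helpers = 7, sex_ratio = 0.5,
                             foray_prob = c(breeder_F = 0, breeder_M = 0,
                                            dominant_F = 0.25, dominant_M = 0.25,
                                            helper_F = 0.5, helper_M = 0.4),
                             foray_geom_q = 0.5, foray_max_steps = 3,
                             detection_radius = 200, response_prob = 1,
                             surveys_per_week = 2, weeks = 12,
                             opportunistic_prob = 0.5, min_point_spacing = 200,
                             point_jitter = 50, prob_laid_egg = 0.8) {
  stopifnot(grid_rows >= 1, grid_cols >= 1, territory_side > 0,
            dominant_prob >= 0, dominant_prob <= 1,
            helper_lambda >= 0, max_helpers >= 0, max_helpers <= 7,
            sex_ratio >= 0, sex_ratio <= 1,
            all(foray_prob >= 0), all(foray_prob <= 1),
            foray_geom_q > 0, foray_geom_q <= 1, foray_max_steps >= 1,
            detection_radius >= 0, response_prob >= 0, response_prob <= 1,
            surveys_per_week >= 1, weeks >= 1,
            opportunistic_prob >= 0, opportunistic_prob <= 1)
  req <- c("breeder_F", "breeder_M", "dominant_F", "dominant_M",
           "helper_F", "helper_M")
  stopifnot(all(req %in% names(foray_prob)))
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a stage-structured territorial population
#'
#' Lays out a rectangular grid of square territories and populates each with
#' a breeder pair (plus 0-7 helpers) or, with configured probability, a
#' single non-breeding dominant territory holder. Sexes follow the
#' configured ratio (breeder pairs are always one female + one male).
#'
#' @param cfg a [synthetic_config()].
#' @param seed RNG seed.
#' @return list of class `"synthetic_truth"`: `attrs` (individual attribute
#'   table), `polygons` (territory rings), `territory_grid` (row/col per
#'   territory), `foray_prob` per individual, `cfg`.
#' @export
generate_population <- function(cfg = synthetic_config(), seed = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (cfg$grid_rows * cfg$grid_cols < 1) stop("zero territories")
  if (!is.null(seed)) set.seed(seed)
  side <- cfg$territory_side
  grid <- expand.grid(row = seq_len(cfg$grid_rows), col = seq_len(cfg$grid_cols))
  grid$territory_id <- sprintf("T%02d_%02d", grid$row, grid$col)
  polygons <- lapply(seq_len(nrow(grid)), function(i) {
    x0 <- (grid$col[i] - 1) * side; y0 <- (grid$row[i] - 1) * side
    territory_polygon(grid$territory_id[i],
                      x = c(x0, x0 + side, x0 + side, x0),
                      y = c(y0, y0, y0 + side, y0 + side))
  })
  rows <- list(); k <- 0
  new_ind <- function(sex, stage, terr, laid) {
    k <<- k + 1
    data.frame(individual_id = sprintf("J%03d", k), sex = sex, stage = stage,
               territory_id = terr, laid_egg = laid, survived = TRUE,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(grid))) {
    terr <- grid$territory_id[i]
    if (stats::runif(1) < cfg$dominant_prob) {
      sex <- if (stats::runif(1) < cfg$sex_ratio) "F" else "M"
      rows[[length(rows) + 1]] <- new_ind(sex, "dominant", terr, NA)
    } else {
      laidF <- stats::runif(1) < cfg$prob_laid_egg
      rows[[length(rows) + 1]] <- new_ind("F", "breeder", terr, laidF)
      rows[[length(rows) + 1]] <- new_ind("M", "breeder", terr, laidF)
      nh <- min(stats::rpois(1, cfg$helper_lambda), cfg$max_helpers)
      for (h in seq_len(nh)) {
        sex <- if (stats::runif(1) < cfg$sex_ratio) "F" else "M"
        rows[[length(rows) + 1]] <- new_ind(sex, "helper", terr, NA)
      }
    }
  }
  attrs <- do.call(rbind, rows)
  fp <- cfg$foray_prob[paste0(attrs$stage, "_", attrs$sex)]
  names(fp) <- attrs$individual_id
  structure(list(attrs = attrs, polygons = polygons, territory_grid = grid,
                 foray_prob = fp, cfg = cfg),
            class = "synthetic_truth")
}

#' Place sampling points at territory-boundary intersections
#'
#' Candidate points sit near the interior corners of the territory grid
#' (where four territory boundaries meet), displaced uniformly within
#' `point_jitter` metres of the intersection, and are greedily thinned so all
#' retained points are at least `min_point_spacing` apart.
#'
#' @param truth a `synthetic_truth`.
#' @param seed optional RNG seed for the jitter.
#' @return data frame `point_id`, `x`, `y`.
#' @export
place_points <- function(truth, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$cfg; side <- cfg$territory_side
  cand <- expand.grid(cx = seq_len(max(cfg$grid_cols - 1, 1)),
                      ry = seq_len(max(cfg$grid_rows - 1, 1)))
  theta <- stats::runif(nrow(cand), 0, 2 * pi)
  r <- cfg$point_jitter * sqrt(stats::runif(nrow(cand)))
  pts <- data.frame(x = cand$cx * side + r * cos(theta),
                    y = cand$ry * side + r * sin(theta))
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    if (i < nrow(pts)) {
      later <- (i + 1):nrow(pts)
      d <- sqrt((pts$x[later] - pts$x[i])^2 + (pts$y[later] - pts$y[i])^2)
      keep[later][d < cfg$min_point_spacing] <- FALSE
    }
  }
  pts <- pts[keep, , drop = FALSE]
  data.frame(point_id = sprintf("P%02d", seq_len(nrow(pts))),
             x = pts$x, y = pts$y, stringsAsFactors = FALSE, row.names = NULL)
}

# ring of territories at Chebyshev distance d from (r, c), clipped to grid
ring_targets <- function(grid, r, c, d) {
  cheb <- pmax(abs(grid$row - r), abs(grid$col - c))
  which(cheb == d)
}

#' Simulate playback surveys and opportunistic aggregations
#'
#' Each survey round, every individual is at home or — with its stage- and
#' sex-specific foray probability — on a foray to a territory drawn by a
#' truncated-geometric kernel over territory steps; its location that round
#' is uniform within the occupied territory. Every sampling point records one
#' survey aggregation per round: all responding individuals within the
#' detection radius. Groups of two or more co-located forayers are recorded
#' as an opportunistic aggregation (no sampling point) with configured
#' probability, but only when the group contains individuals from
#' non-adjacent home territories.
#'
#' @param truth a `synthetic_truth` from [generate_population()].
#' @param points sampling points from [place_points()].
#' @param seed RNG seed.
#' @return a `gbi` object; empty point-visits are dropped.
#' @export
simulate_surveys <- function(truth, points, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- truth$cfg; side <- cfg$territory_side
  grid <- truth$territory_grid
  attrs <- truth$attrs
  n <- nrow(attrs)
  home <- match(attrs$territory_id, grid$territory_id)
  fp <- as.numeric(truth$foray_prob)
  # truncated geometric over 1..max steps
  dprob <- cfg$foray_geom_q * (1 - cfg$foray_geom_q)^(seq_len(cfg$foray_max_steps) - 1)
  dprob <- dprob / sum(dprob)
  rounds <- cfg$surveys_per_week * cfg$weeks
  start <- as.Date("2017-02-01")
  inc_rows <- list(); meta_rows <- list()
  for (rd in seq_len(rounds)) {
    date <- as.character(start + floor((rd - 1) * 7 / cfg$surveys_per_week))
    cur <- home
    foraying <- stats::runif(n) < fp
    for (i in which(foraying)) {
      d <- sample.int(cfg$foray_max_steps, 1, prob = dprob)
      tgt <- integer(0)
      while (d >= 1 && length(tgt) == 0) {   # clip to grid: fall back inward
        tgt <- ring_targets(grid, grid$row[home[i]], grid$col[home[i]], d)
        d <- d - 1
      }
      if (length(tgt) > 0) cur[i] <- tgt[sample.int(length(tgt), 1)]
    }
    locx <- (grid$col[cur] - 1) * side + stats::runif(n) * side
    locy <- (grid$row[cur] - 1) * side + stats::runif(n) * side
    for (p in seq_len(nrow(points))) {
      d2 <- (locx - points$x[p])^2 + (locy - points$y[p])^2
      hit <- d2 <= cfg$detection_radius^2
      if (cfg$response_prob < 1) hit <- hit & (stats::runif(n) < cfg$response_prob)
      if (!any(hit)) next
      row <- integer(n); row[hit] <- 1L
      inc_rows[[length(inc_rows) + 1]] <- row
      meta_rows[[length(meta_rows) + 1]] <-
        data.frame(aggregation_id = sprintf("S%03d_%s", rd, points$point_id[p]),
                   point_id = points$point_id[p], date = date, kind = "survey",
                   stringsAsFactors = FALSE)
    }
    # opportunistic aggregations of co-located forayers from non-adjacent homes
    off <- which(foraying & cur != home)
    if (length(off) >= 2) {
      for (tt in unique(cur[off])) {
        grp <- off[cur[off] == tt]
        if (length(grp) < 2) next
        hr <- grid$row[home[grp]]; hc <- grid$col[home[grp]]
        cheb <- pmax(abs(outer(hr, hr, "-")), abs(outer(hc, hc, "-")))
        if (!any(cheb[upper.tri(cheb)] >= 2)) next
        if (stats::runif(1) >= cfg$opportunistic_prob) next
        row <- integer(n); row[grp] <- 1L
        inc_rows[[length(inc_rows) + 1]] <- row
        meta_rows[[length(meta_rows) + 1]] <-
          data.frame(aggregation_id = sprintf("O%03d_%s", rd, grid$territory_id[tt]),
                     point_id = NA_character_, date = date,
                     kind = "opportunistic", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(inc_rows) == 0) {
    stop("simulation produced no detections (check detection radius/effort)")
  }
  inc <- do.call(rbind, inc_rows)
  colnames(inc) <- attrs$individual_id
  meta <- do.call(rbind, meta_rows)
  rownames(inc) <- meta$aggregation_id
  gbi_matrix(inc, meta)
}

#' Simulate a complete study
#'
#' Convenience wrapper: population, points, surveys and territory covariates
#' in one call, all driven by a single seed.
#'
#' @param cfg a [synthetic_config()].
#' @param seed RNG seed (single seed drives the whole study).
#' @return list: `truth`, `points`, `gbi`, `covariates`, `attrs`.
#' @export
simulate_study <- function(cfg = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  truth <- generate_population(cfg)
  points <- place_points(truth)
  g <- simulate_surveys(truth, points)
  cov <- territory_covariates(truth$polygons, points)
  list(truth = truth, points = points, gbi = g, covariates = cov,
       attrs = truth$attrs)
}

#' Export a synthetic study as a CSV/JSON bundle
#'
#' Writes the GBI matrix, aggregation metadata, individual attributes,
#' territory covariates, sampling points and ground truth in the same
#' dialects the readers consume, so the bundle round-trips through the
#' pipeline unchanged.
#'
#' @param study output of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gbi(study$gbi, file.path(dir, "gbi.csv"), file.path(dir, "meta.csv"))
  utils::write.csv(study$attrs, file.path(dir, "attributes.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(study$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$points, file.path(dir, "points.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    stages = stats::setNames(study$attrs$stage, study$attrs$individual_id),
    foray_prob = as.list(study$truth$foray_prob),
    config = study$truth$cfg[setdiff(names(study$truth$cfg), "")])
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
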