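#' Group-by-individual (GBI) matrix
#'
#' Container for binary aggregation-by-individual co-detection data: rows are
#' observed aggregations (one playback point-visit's responder set, or one
#' opportunistic aggregation), columns are individuals, and an entry of 1
#' records that the individual was detected in that aggregation. Each
#' aggregation carries metadata: its sampling point (for survey records), date
#' and kind.
#'
#' @param incidence binary matrix (aggregations x individuals) with individual
#'   ids as column names and aggregation ids as row names.
#' @param meta data frame with one row per aggregation and columns
#'   `aggregation_id`, `point_id` (NA for opportunistic records), `date`,
#'   `kind` (`"survey"` or `"opportunistic"`). If `NULL`, all aggregations are
#'   treated as surveys whose point id is the prefix of the aggregation id
#'   (text before the last `"_"`, or the id itself), with a warning.
#' @return an object of class `"gbi"` with elements `incidence`, `individuals`
#'   and `meta`.
#' @export
gbi_matrix <- function(incidence, meta = NULL) {
  incidence <- as.matrix(incidence)
  if (is.null(colnames(incidence))) {
    stop("incidence matrix must have individual ids as column names")
  }
  if (is.null(rownames(incidence))) {
    rownames(incidence) <- paste0("agg", seq_len(nrow(incidence)))
  }
  storage.mode(incidence) <- "integer"
  if (anyNA(incidence) || !all(incidence %in% c(0L, 1L))) {
    bad <- which(!(incidence %in% c(0L, 1L)) | is.na(incidence))[1]
    stop("incidence entries must be 0 or 1 (format error at cell ", bad, ")")
  }
  if (anyDuplicated(colnames(incidence))) {
    stop("duplicate individual id(s): ",
         paste(unique(colnames(incidence)[duplicated(colnames(incidence))]),
               collapse = ", "))
  }
  empty <- which(rowSums(incidence) == 0L)
  if (length(empty) > 0) {
    stop("aggregation(s) with no detections: ",
         paste(rownames(incidence)[empty], collapse = ", "))
  }
  if (is.null(meta)) {
    warning("no aggregation metadata supplied; assuming kind = 'survey' with ",
            "point_id taken from the aggregation-id prefix")
    ids <- rownames(incidence)
    pref <- sub("_[^_]*$", "", ids)
    meta <- data.frame(aggregation_id = ids, point_id = pref,
                       date = NA_character_, kind = "survey",
                       stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("aggregation_id", "point_id", "date", "kind")
  miss <- setdiff(req, names(meta))
  if (length(miss) > 0) stop("metadata lacks column(s): ", paste(miss, collapse = ", "))
  meta <- meta[match(rownames(incidence), meta$aggregation_id), req, drop = FALSE]
  if (anyNA(meta$aggregation_id)) {
    stop("metadata must contain one row per aggregation (keyed by aggregation_id)")
  }
  if (!all(meta$kind %in% c("survey", "opportunistic"))) {
    stop("aggregation kind must be 'survey' or 'opportunistic'")
  }
  if (any(meta$kind == "survey" & is.na(meta$point_id))) {
    stop("survey aggregations must carry a point_id")
  }
  meta$point_id[meta$kind == "opportunistic"] <- NA_character_
  rownames(meta) <- NULL
  structure(list(incidence = incidence,
                 individuals = colnames(incidence),
                 meta = meta),
            class = "gbi")
}

#' @export
print.gbi <- function(x, ...) {
  cat("Group-by-individual matrix:", nrow(x$incidence), "aggregations x",
      length(x$individuals), "individuals\n")
  cat("  surveys:", sum(x$meta$kind == "survey"),
      "| opportunistic:", sum(x$meta$kind == "opportunistic"),
      "| total detections:", sum(x$incidence), "\n")
  invisible(x)
}

#' @export
dim.gbi <- function(x) dim(x$incidence)

#' Read a group-by-individual matrix from CSV
#'
#' The matrix file has individual ids as header, aggregation ids in the first
#' column and 0/1 detection entries in the body. The optional metadata sidecar
#' is keyed by `aggregation_id` with columns `point_id`, `date` (ISO-8601) and
#' `kind`.
#'
#' @param path path to the GBI CSV.
#' @param meta_path optional path to the aggregation metadata CSV.
#' @param sep field delimiter; `","` by default, `"\t"` accepted.
#' @return a [gbi_matrix()] object.
#' @export
read_gbi <- function(path, meta_path = NULL, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric entries in GBI body (format error)")
  meta <- NULL
  if (!is.null(meta_path)) {
    if (!file.exists(meta_path)) stop("file not found: ", meta_path)
    meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE,
                              colClasses = "character")
    meta$point_id[!nzchar(meta$point_id)] <- NA_character_
  }
  gbi_matrix(m, meta)
}

#' Write a group-by-individual matrix (and metadata) to CSV
#'
#' @param g a `gbi` object.
#' @param path output path for the matrix CSV.
#' @param meta_path optional output path for the metadata CSV.
#' @return `path`, invisibly.
#' @export
write_gbi <- function(g, path, meta_path = NULL) {
  stopifnot(inherits(g, "gbi"))
  df <- data.frame(aggregation_id = rownames(g$incidence),
                   g$incidence, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    utils::write.csv(g$meta, meta_path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(path)
}

#' Restrict a GBI matrix to individuals detected at least `min_count` times
#'
#' Implements the network inclusion rule used throughout: individuals with
#' fewer than `min_count` detections (default 3) are removed, and aggregations
#' left with no detections by the removal are dropped. Dropping emptied
#' aggregations does not change any simple-ratio-index value because SRI
#' denominators only count aggregations containing at least one dyad member.
#'
#' @param g a `gbi` object.
#' @param min_count minimum number of detections (>= 1).
#' @return a filtered `gbi` object with attribute `"removed"` holding the ids
#'   of removed individuals.
#' @export
filter_min_detections <- function(g, min_count = 3) {
  stopifnot(inherits(g, "gbi"), min_count >= 1)
  keep <- colSums(g$incidence) >= min_count
  if (!any(keep)) stop("no individuals with >= ", min_count, " detections")
  inc <- g$incidence[, keep, drop = FALSE]
  rows <- rowSums(inc) > 0L
  out <- gbi_matrix(inc[rows, , drop = FALSE], g$meta[rows, , drop = FALSE])
  attr(out, "removed") <- g$individuals[!keep]
  out
}

#' Read an individual attribute table
#'
#' Columns: `individual_id`, `sex` (`F`/`M`), `stage`
#' (`breeder`/`dominant`/`helper`), `territory_id`, and optionally `laid_egg`
#' (logical, may be NA) and `survived` (logical).
#'
#' @param path attribute CSV path.
#' @return validated data frame.
#' @export
read_attributes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  at <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_attributes(at)
}

validate_attributes <- function(at) {
  req <- c("individual_id", "sex", "stage", "territory_id")
  miss <- setdiff(req, names(at))
  if (length(miss) > 0) stop("attributes lack column(s): ", paste(miss, collapse = ", "))
  if (!all(at$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (!all(at$stage %in% c("breeder", "dominant", "helper"))) {
    stop("stage must be one of breeder, dominant, helper")
  }
  if (anyDuplicated(at$individual_id)) stop("duplicate individual_id in attributes")
  if (!"laid_egg" %in% names(at)) at$laid_egg <- NA
  at$laid_egg <- as.logical(at$laid_egg)
  if (!"survived" %in% names(at)) at$survived <- TRUE
  at$survived <- as.logical(at$survived)
  at
}

#' Reassign life-history stages by a declared rule
#'
#' The built-in rule `"nonlaying_breeders_to_dominant"` reclassifies breeders
#' that did not lay an egg in the focal season as dominants, supporting the
#' sensitivity re-analysis in which pre-laying breeders are treated as
#' behaviourally dominant.
#'
#' @param attrs individual attribute data frame (see [read_attributes()]).
#' @param rule reassignment rule name.
#' @return a new attribute data frame with attribute `"n_reassigned"`.
#' @export
reassign_stages <- function(attrs, rule = "nonlaying_breeders_to_dominant") {
  rule <- match.arg(rule)
  attrs <- validate_attributes(attrs)
  breeders <- attrs$stage == "breeder"
  bad <- breeders & is.na(attrs$laid_egg)
  if (any(bad)) {
    stop("laid_egg is missing for breeder(s): ",
         paste(attrs$individual_id[bad], collapse = ", "))
  }
  out <- attrs
  hit <- breeders & !attrs$laid_egg
  out$stage[hit] <- "dominant"
  attr(out, "n_reassigned") <- sum(hit)
  out
}
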