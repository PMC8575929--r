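# Lateral-only RORA annotations: per-b-scan column intervals, their JSON
# serialization, rasterization to en-face masks, and iRORA/cRORA lesion
# classification with cross-b-scan connectivity.

# Width (micrometres) at or above which a lesion counts as complete RORA.
# The consensus definition separates complete from incomplete RORA at 250 um;
# a lesion of exactly 250 um is classified cRORA here (inclusive upper class).
CRORA_WIDTH_UM <- 250

#' Per-b-scan lateral RORA annotation
#'
#' Intervals are 0-based half-open column ranges `[start, end)` on the fast
#' axis; only the lateral extent of atrophy is recorded (the vertical span of
#' a graded bounding box carries no information for en-face evaluation).
#'
#' @param per_bscan List (one element per b-scan) of interval lists; each
#'   interval a length-2 numeric `c(start, end)`.
#' @param spacing_mm Pixel spacing `c(slow, depth, fast)` in mm/px.
#' @param grader Label of the annotation source.
#' @param width_px Optional lateral grid size used to range-check intervals.
#' @return A `rora_annotation`.
#' @export
rora_annotation <- function(per_bscan, spacing_mm, grader = "unknown",
                            width_px = NULL) {
  stopifnot(is.list(per_bscan), length(spacing_mm) == 3L, all(spacing_mm > 0))
  per_bscan <- lapply(per_bscan, function(iv) {
    lapply(iv, function(x) as.numeric(x))
  })
  ann <- structure(list(per_bscan = per_bscan,
                        spacing_mm = as.numeric(spacing_mm),
                        grader = as.character(grader),
                        width_px = if (is.null(width_px)) NULL else as.integer(width_px)),
                   class = "rora_annotation")
  validate_annotation(ann)
  ann
}

validate_annotation <- function(ann) {
  for (b in seq_along(ann$per_bscan)) {
    iv <- ann$per_bscan[[b]]
    if (length(iv) == 0L) next
    bad <- !vapply(iv, function(x) length(x) == 2L && x[1] < x[2] && x[1] >= 0,
                   logical(1))
    if (any(bad))
      stop(sprintf("b-scan %d: malformed interval (need 0 <= start < end)", b - 1L),
           call. = FALSE)
    if (!is.null(ann$width_px) &&
        any(vapply(iv, function(x) x[2] > ann$width_px, logical(1))))
      stop(sprintf("b-scan %d: interval exceeds width_px = %d", b - 1L,
                   ann$width_px), call. = FALSE)
    starts <- vapply(iv, `[`, numeric(1), 1L)
    ends <- vapply(iv, `[`, numeric(1), 2L)
    o <- order(starts)
    if (is.unsorted(starts))
      stop(sprintf("b-scan %d: intervals not sorted by start column", b - 1L),
           call. = FALSE)
    if (length(iv) > 1L && any(starts[o][-1] < ends[o][-length(iv)]))
      stop(sprintf("b-scan %d: overlapping intervals", b - 1L), call. = FALSE)
  }
  invisible(ann)
}

#' Write / read an annotation as JSON
#'
#' Schema: `{grader, spacing_mm: [slow, depth, fast], width_px,
#' bscans: [{index, intervals: [[start, end], ...]}, ...]}` with 0-based
#' b-scan indices and half-open column intervals.
#'
#' @param ann A [rora_annotation()].
#' @param path File path.
#' @return `read_annotation` returns a `rora_annotation`;
#'   `write_annotation` returns `path` invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "rora_annotation"))
  doc <- list(
    grader = ann$grader,
    spacing_mm = ann$spacing_mm,
    width_px = ann$width_px,
    bscans = lapply(seq_along(ann$per_bscan), function(b) {
      list(index = b - 1L,
           intervals = lapply(ann$per_bscan[[b]], function(x) c(x[1], x[2])))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  n <- length(doc$bscans)
  per_bscan <- vector("list", n)
  for (bs in doc$bscans) {
    i <- bs$index + 1L
    if (i < 1L || i > n) stop("b-scan index out of range in ", path, call. = FALSE)
    per_bscan[[i]] <- lapply(bs$intervals, function(x) as.numeric(unlist(x)))
  }
  rora_annotation(per_bscan,
                  spacing_mm = as.numeric(unlist(doc$spacing_mm)),
                  grader = doc$grader %||% "unknown",
                  width_px = doc$width_px)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize an annotation to a binary en-face mask
#'
#' Pixel `(b, c)` is positive iff column `c` lies inside some interval of
#' b-scan `b` (rows = b-scans, columns = a-scan positions).
#'
#' @param ann A [rora_annotation()].
#' @param n_bscans,width_px Grid dimensions.
#' @return A binary [enface_map()].
#' @export
rasterize_enface <- function(ann, n_bscans, width_px) {
  stopifnot(inherits(ann, "rora_annotation"))
  if (length(ann$per_bscan) != n_bscans)
    stop("annotation has ", length(ann$per_bscan), " b-scans, grid has ",
         n_bscans, call. = FALSE)
  grid <- matrix(0L, n_bscans, width_px)
  for (b in seq_len(n_bscans)) {
    for (iv in ann$per_bscan[[b]]) {
      if (iv[2] > width_px)
        stop(sprintf("b-scan %d: interval exceeds grid width", b - 1L),
             call. = FALSE)
      grid[b, (iv[1] + 1L):iv[2]] <- 1L
    }
  }
  enface_map(grid, spacing_mm = ann$spacing_mm[c(1, 3)], kind = "binary")
}

#' Classify annotated lesions as iRORA or cRORA
#'
#' Each interval becomes one lesion record; its width in micrometres is
#' `(end - start) * fast-axis spacing * 1000` and the grade is cRORA iff the
#' width reaches 250 um. En-face connected components are formed by linking
#' intervals on adjacent b-scans whose column ranges overlap by at least one
#' column; a component is an isolated iRORA lesion iff every member interval
#' is iRORA.
#'
#' @param ann A [rora_annotation()].
#' @return A data frame with columns `bscan_index` (0-based), `col_start`,
#'   `col_end`, `width_um`, `grade`, `component_id`, `isolated_irora`.
#' @export
classify_lesions <- function(ann) {
  stopifnot(inherits(ann, "rora_annotation"))
  fast_um <- ann$spacing_mm[3] * 1000
  recs <- do.call(rbind, lapply(seq_along(ann$per_bscan), function(b) {
    iv <- ann$per_bscan[[b]]
    if (length(iv) == 0L) return(NULL)
    data.frame(bscan_index = b - 1L,
               col_start = vapply(iv, `[`, numeric(1), 1L),
               col_end = vapply(iv, `[`, numeric(1), 2L))
  }))
  if (is.null(recs))
    return(data.frame(bscan_index = integer(), col_start = numeric(),
                      col_end = numeric(), width_um = numeric(),
                      grade = character(), component_id = integer(),
                      isolated_irora = logical()))
  recs$width_um <- (recs$col_end - recs$col_start) * fast_um
  recs$grade <- ifelse(recs$width_um >= CRORA_WIDTH_UM, "cRORA", "iRORA")

  # union-find over intervals; link laterally-overlapping intervals on
  # adjacent b-scans only
  n <- nrow(recs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (i in seq_len(n)) {
    nb <- which(recs$bscan_index == recs$bscan_index[i] + 1L)
    for (j in nb) {
      if (recs$col_start[i] < recs$col_end[j] &&
          recs$col_start[j] < recs$col_end[i]) union(i, j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  recs$component_id <- match(roots, sort(unique(roots)))
  iso <- tapply(recs$grade == "iRORA", recs$component_id, all)
  recs$isolated_irora <- as.logical(iso[as.character(recs$component_id)])
  rownames(recs) <- NULL
  recs
}

#' Discovery rate of isolated iRORA lesions
#'
#' Fraction of isolated-iRORA components whose en-face footprint overlaps at
#' least one predicted-positive pixel.
#'
#' @param pred Binary [enface_map()] (or 0/1 matrix) of predictions.
#' @param lesions Lesion table from [classify_lesions()].
#' @return Fraction in `[0, 1]`, or `NA` when no isolated iRORA lesion exists.
#' @export
discovery_rate <- function(pred, lesions) {
  grid <- if (inherits(pred, "enface_map")) pred$grid else as.matrix(pred)
  iso <- lesions[lesions$isolated_irora, , drop = FALSE]
  if (nrow(iso) == 0L) return(NA_real_)
  if (any(iso$bscan_index + 1L > nrow(grid)) || any(iso$col_end > ncol(grid)))
    stop("lesion table exceeds prediction grid dimensions", call. = FALSE)
  comps <- unique(iso$component_id)
  hit <- vapply(comps, function(cid) {
    rows <- iso[iso$component_id == cid, , drop = FALSE]
    any(vapply(seq_len(nrow(rows)), function(k) {
      any(grid[rows$bscan_index[k] + 1L,
               (rows$col_start[k] + 1L):rows$col_end[k]] > 0)
    }, logical(1)))
  }, logical(1))
  mean(hit)
}

#' @export
print.rora_annotation <- function(x, ...) {
  cat(sprintf("rora_annotation by '%s': %d b-scans, %d interval(s)\n",
              x$grader, length(x$per_bscan), sum(lengths(x$per_bscan))))
  invisible(x)
}
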