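# Synthetic OCT phantom generator: layered retina, atrophic footprints with
# RPE attenuation + choroidal hypertransmission + photoreceptor thinning,
# drusen confounders, and speckle-like noise, with paired ground truth.

LAYER_LEVELS <- c("background", "inner_retina", "photoreceptors", "RPE", "choroid")

# Baseline tissue reflectivities (arbitrary units in [0,1]) for the phantom.
LAYER_INTENSITY <- c(background = 0.05, inner_retina = 0.32,
                     photoreceptors = 0.22, RPE = 0.85, choroid = 0.28)

#' Configuration for the synthetic OCT phantom
#'
#' Defines the geometry, lesion content and noise level of a generated OCT
#' volume. Defaults are desk-scale (16 b-scans of 64 x 128 pixels) covering a
#' 6 x 6 mm macular footprint; a Spectralis-like full-scale geometry is
#' available as `synth_config(n_bscans = 49, depth_px = 496, width_px = 512)`.
#'
#' @param n_bscans Number of b-scans (slow axis).
#' @param depth_px Axial (depth) size of each b-scan in pixels.
#' @param width_px Lateral (fast axis) size of each b-scan in pixels.
#' @param spacing_mm Physical pixel spacing, `c(slow, depth, fast)` in mm/px.
#'   Default `NULL` derives it from a 6 x 6 mm en-face footprint and a 1.92 mm
#'   axial window.
#' @param n_atrophy_blobs Number of Gaussian atrophy blobs seeding the en-face
#'   footprint (0 = no atrophy).
#' @param atrophy_area_fraction Target fraction of en-face pixels inside the
#'   atrophy footprint, in `[0, 0.8]`.
#' @param n_drusen Number of drusen (RPE elevations without
#'   hypertransmission), placed outside the atrophy footprint.
#' @param rpe_attenuation Multiplicative factor in `[0, 0.3]` applied to RPE
#'   reflectivity inside atrophy.
#' @param hypertransmission_gain Factor `> 1` applied to choroid reflectivity
#'   inside atrophy (light passes the missing RPE).
#' @param speckle_sigma Relative standard deviation of the multiplicative
#'   speckle; 0 disables all noise.
#' @param healthy If `TRUE`, forces `n_atrophy_blobs = 0`.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @param patient_id Patient label attached to the volume.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_bscans = 16L, depth_px = 64L, width_px = 128L,
                         spacing_mm = NULL,
                         n_atrophy_blobs = 2L, atrophy_area_fraction = 0.15,
                         n_drusen = 2L, rpe_attenuation = 0.15,
                         hypertransmission_gain = 1.8, speckle_sigma = 0.15,
                         healthy = FALSE, seed = 1L, patient_id = "P001") {
  if (healthy) n_atrophy_blobs <- 0L
  if (is.null(spacing_mm)) {
    spacing_mm <- c(slow = 6 / n_bscans, depth = 1.92 / depth_px,
                    fast = 6 / width_px)
  }
  cfg <- list(n_bscans = as.integer(n_bscans), depth_px = as.integer(depth_px),
              width_px = as.integer(width_px), spacing_mm = spacing_mm,
              n_atrophy_blobs = as.integer(n_atrophy_blobs),
              atrophy_area_fraction = atrophy_area_fraction,
              n_drusen = as.integer(n_drusen),
              rpe_attenuation = rpe_attenuation,
              hypertransmission_gain = hypertransmission_gain,
              speckle_sigma = speckle_sigma, healthy = isTRUE(healthy),
              seed = as.integer(seed), patient_id = as.character(patient_id))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_bscans >= 1L, cfg$depth_px >= 1L, cfg$width_px >= 1L,
            cfg$n_atrophy_blobs >= 0L, cfg$n_drusen >= 0L,
            length(cfg$spacing_mm) == 3L, all(cfg$spacing_mm > 0),
            cfg$speckle_sigma >= 0)
  if (cfg$rpe_attenuation < 0 || cfg$rpe_attenuation > 0.3)
    stop("rpe_attenuation must lie in [0, 0.3]", call. = FALSE)
  if (cfg$hypertransmission_gain <= 1)
    stop("hypertransmission_gain must exceed 1", call. = FALSE)
  if (cfg$atrophy_area_fraction < 0 || cfg$atrophy_area_fraction > 0.8)
    stop("atrophy_area_fraction must lie in [0, 0.8]", call. = FALSE)
  if (cfg$healthy && cfg$n_atrophy_blobs > 0L)
    stop("healthy configuration cannot carry atrophy blobs", call. = FALSE)
  if (cfg$n_atrophy_blobs > 0L) {
    n_pos <- round(cfg$atrophy_area_fraction * cfg$n_bscans * cfg$width_px)
    if (n_pos < 1L)
      stop("requested atrophy_area_fraction does not fit in the en-face grid",
           call. = FALSE)
  }
  invisible(cfg)
}

# Run expr under a private RNG stream (global .Random.seed untouched).
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Smooth 2D random field: a few random low-frequency sinusoids, amplitude 1.
smooth_field <- function(nr, nc, n_waves = 3L) {
  f <- matrix(0, nr, nc)
  r <- seq_len(nr) / nr
  c <- seq_len(nc) / nc
  for (j in seq_len(n_waves)) {
    fr <- stats::runif(1, 0.5, 2.5)
    fc <- stats::runif(1, 0.5, 2.5)
    ph <- stats::runif(2, 0, 2 * pi)
    f <- f + outer(sin(2 * pi * fr * r + ph[1]), sin(2 * pi * fc * c + ph[2]))
  }
  f / n_waves
}

# En-face atrophy footprint: sum of anisotropic Gaussian blobs thresholded at
# the quantile giving the requested area fraction (smooth level-set borders).
atrophy_footprint <- function(cfg) {
  n <- cfg$n_bscans; w <- cfg$width_px
  if (cfg$n_atrophy_blobs == 0L || cfg$atrophy_area_fraction <= 0)
    return(matrix(FALSE, n, w))
  field <- matrix(0, n, w)
  bs <- seq_len(n); cs <- seq_len(w)
  for (j in seq_len(cfg$n_atrophy_blobs)) {
    cb <- stats::runif(1, 0.2 * n, 0.8 * n)
    cc <- stats::runif(1, 0.2 * w, 0.8 * w)
    sb <- stats::runif(1, 0.10, 0.25) * n
    sc <- stats::runif(1, 0.10, 0.25) * w
    field <- field + outer(exp(-(bs - cb)^2 / (2 * sb^2)),
                           exp(-(cs - cc)^2 / (2 * sc^2)))
  }
  n_pos <- round(cfg$atrophy_area_fraction * n * w)
  thr <- sort(field, decreasing = TRUE)[n_pos]
  field >= thr
}

# Column runs of a logical vector as 0-based half-open [start, end) intervals.
runs_to_intervals <- function(flags) {
  if (!any(flags)) return(list())
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  out <- Map(c, starts[r$values], ends[r$values])
  unname(out)
}

#' Generate one synthetic OCT volume with paired ground truth
#'
#' Builds a layered retinal phantom (inner retina / photoreceptors / RPE /
#' choroid over background), carves atrophic regions into it (attenuated RPE,
#' hypertransmissive choroid, photoreceptor band thinned by at least half),
#' adds drusen confounders (RPE elevations without hypertransmission, never
#' inside the atrophy footprint), and finally applies multiplicative speckle
#' plus additive Gaussian noise. Lateral per-b-scan annotation intervals are
#' exactly the atrophic columns.
#'
#' @param config A [synth_config()].
#' @return A `rora_bundle`: list with elements `volume` (`oct_volume`),
#'   `layers` (`layer_maps`), `annotation` (`rora_annotation`) and `enface_gt`
#'   (binary `enface_map`).
#' @export
generate_volume <- function(config) {
  validate_synth_config(config)
  with_seed(config$seed, generate_volume_impl(config))
}

generate_volume_impl <- function(cfg) {
  n <- cfg$n_bscans; d <- cfg$depth_px; w <- cfg$width_px

  footprint <- atrophy_footprint(cfg)

  # Layer geometry (rows, 1-based): smooth surfaces, anatomical order.
  ir_top0 <- 0.15 * d + 0.04 * d * smooth_field(n, w)
  th_ir <- pmax(round(0.28 * d + 0.02 * d * smooth_field(n, w)), 4)
  th_pr <- pmax(3L, round(0.13 * d))
  th_rpe <- pmax(2L, round(0.05 * d))
  th_ch <- pmax(4L, round(0.26 * d))
  ir_top <- pmax(round(ir_top0), 1)

  # Drusen: en-face domes with height map (pixels of RPE elevation), kept
  # strictly outside the atrophy footprint.
  druse_h <- matrix(0, n, w)
  max_h <- max(2, round(0.08 * d))
  placed <- 0L; tries <- 0L
  while (placed < cfg$n_drusen && tries < 50L * max(1L, cfg$n_drusen)) {
    tries <- tries + 1L
    cb <- stats::runif(1, 1, n); cc <- stats::runif(1, 0.1 * w, 0.9 * w)
    sb <- stats::runif(1, 0.04, 0.08) * n
    sc <- stats::runif(1, 0.03, 0.06) * w
    dome <- outer(exp(-(seq_len(n) - cb)^2 / (2 * sb^2)),
                  exp(-(seq_len(w) - cc)^2 / (2 * sc^2)))
    hit <- dome > 0.3
    if (any(hit & footprint)) next
    druse_h <- pmax(druse_h, max_h * dome * hit)
    placed <- placed + 1L
  }
  druse_h <- round(druse_h)
  druse_h[footprint] <- 0

  voxels <- array(0, dim = c(n, d, w))
  labels <- array(0L, dim = c(n, d, w))
  code <- stats::setNames(seq_along(LAYER_LEVELS) - 1L, LAYER_LEVELS)
  rowidx <- matrix(seq_len(d), d, w)
  byrow <- function(v) matrix(v, d, w, byrow = TRUE)

  for (b in seq_len(n)) {
    atro <- footprint[b, ]
    elev <- druse_h[b, ]

    pr_top <- ir_top[b, ] + th_ir[b, ]            # last inner-retina row
    rpe_top <- pr_top + th_pr                     # last photoreceptor row
    # Atrophy: photoreceptor band thinned by >= 50% (RPE line stays put,
    # inner retina extends down over the lost photoreceptors).
    th_pr_col <- ifelse(atro, floor(th_pr * 0.4), th_pr)
    pr_top <- rpe_top - th_pr_col
    # Drusen: the photoreceptor/RPE complex is lifted by the dome height.
    pr_top <- pr_top - elev
    rpe_top <- rpe_top - elev
    rpe_bot <- rpe_top + th_rpe
    ch_bot <- pmin(d, rpe_bot + elev + th_ch)

    lab <- matrix(code["background"], d, w)
    lab[rowidx > byrow(ir_top[b, ]) & rowidx <= byrow(pr_top)] <- code["inner_retina"]
    lab[rowidx > byrow(pr_top) & rowidx <= byrow(rpe_top)] <- code["photoreceptors"]
    lab[rowidx > byrow(rpe_top) & rowidx <= byrow(rpe_bot)] <- code["RPE"]
    lab[rowidx > byrow(rpe_bot) & rowidx <= byrow(ch_bot)] <- code["choroid"]

    rpe_val <- ifelse(atro, LAYER_INTENSITY["RPE"] * cfg$rpe_attenuation,
                      LAYER_INTENSITY["RPE"])
    ch_val <- ifelse(atro,
                     pmin(1, LAYER_INTENSITY["choroid"] * cfg$hypertransmission_gain),
                     LAYER_INTENSITY["choroid"])
    img <- matrix(LAYER_INTENSITY["background"], d, w)
    img[lab == code["inner_retina"]] <- LAYER_INTENSITY["inner_retina"]
    img[lab == code["photoreceptors"]] <- LAYER_INTENSITY["photoreceptors"]
    rpe_px <- lab == code["RPE"]
    img[rpe_px] <- byrow(rpe_val)[rpe_px]
    ch_px <- lab == code["choroid"]
    img[ch_px] <- byrow(ch_val)[ch_px]
    # druse core (between lifted RPE and original choroid top) stays at a
    # medium sub-RPE reflectivity without any transmission change
    core <- ch_px & rowidx <= byrow(rpe_bot + elev) & byrow(elev) > 0
    img[core] <- 0.45

    voxels[b, , ] <- img
    labels[b, , ] <- lab
  }

  if (cfg$speckle_sigma > 0) {
    sh <- 1 / cfg$speckle_sigma^2
    speck <- array(stats::rgamma(length(voxels), shape = sh, rate = sh),
                   dim = dim(voxels))
    voxels <- voxels * speck +
      array(stats::rnorm(length(voxels), sd = cfg$speckle_sigma / 5),
            dim = dim(voxels))
    voxels[voxels < 0] <- 0
    voxels[voxels > 1] <- 1
  }

  per_bscan <- lapply(seq_len(n), function(b) runs_to_intervals(footprint[b, ]))
  ann <- rora_annotation(per_bscan, spacing_mm = cfg$spacing_mm,
                         grader = "synthetic-gt", width_px = w)

  bundle <- list(
    volume = oct_volume(voxels, cfg$spacing_mm, cfg$patient_id),
    layers = layer_maps(labels),
    annotation = ann,
    enface_gt = enface_map((footprint) * 1L,
                           spacing_mm = cfg$spacing_mm[c(1, 3)],
                           kind = "binary"),
    config = cfg)
  class(bundle) <- "rora_bundle"
  bundle
}

#' Generate a cohort of synthetic volumes
#'
#' Each volume receives a distinct patient id and a per-volume seed derived
#' deterministically from `seed`. Across diseased volumes the number of
#' atrophy blobs varies between 1 and `base$n_atrophy_blobs + 1` (uni- to
#' multifocal presentations), the en-face lesion area fraction varies
#' uniformly between 0.5x and 2x the template value (small to confluent
#' lesions), and the drusen count varies between 0 and `base$n_drusen`.
#'
#' @param n_volumes Number of volumes (>= 1).
#' @param base A [synth_config()] serving as the template.
#' @param seed Cohort-level seed.
#' @param healthy_fraction Fraction of volumes generated without atrophy.
#' @return List of `rora_bundle` objects.
#' @export
generate_cohort <- function(n_volumes, base = synth_config(), seed = 1L,
                            healthy_fraction = 0) {
  stopifnot(n_volumes >= 1L, healthy_fraction >= 0, healthy_fraction <= 1)
  with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n_volumes)
    n_healthy <- round(healthy_fraction * n_volumes)
    healthy <- seq_len(n_volumes) <= n_healthy
    blobs <- sample(seq_len(max(1L, base$n_atrophy_blobs + 1L)), n_volumes,
                    replace = TRUE)
    areas <- pmin(0.8, pmax(0.02, stats::runif(n_volumes, 0.5, 2) *
                              base$atrophy_area_fraction))
    drusen <- sample(0:max(0L, base$n_drusen), n_volumes, replace = TRUE)
    lapply(seq_len(n_volumes), function(i) {
      cfg <- base
      cfg$seed <- seeds[i]
      cfg$patient_id <- sprintf("P%03d", i)
      cfg$healthy <- healthy[i]
      cfg$n_atrophy_blobs <- if (healthy[i]) 0L else blobs[i]
      cfg$atrophy_area_fraction <- areas[i]
      cfg$n_drusen <- drusen[i]
      class(cfg) <- "synth_config"
      generate_volume(cfg)
    })
  })
}

#' OCT volume container
#'
#' @param voxels Numeric array `[n_bscans, depth_px, width_px]` in `[0, 1]`.
#' @param spacing_mm Pixel spacing `c(slow, depth, fast)` in mm/px.
#' @param patient_id,eye Labels.
#' @return An `oct_volume`.
#' @export
oct_volume <- function(voxels, spacing_mm, patient_id = "unknown", eye = NA_character_) {
  stopifnot(length(dim(voxels)) == 3L, all(voxels >= 0), all(voxels <= 1),
            length(spacing_mm) == 3L, all(spacing_mm > 0))
  structure(list(voxels = voxels, spacing_mm = spacing_mm,
                 patient_id = patient_id, eye = eye),
            class = "oct_volume")
}

#' Retinal layer label maps
#'
#' Integer codes 0..4 for background, inner_retina, photoreceptors, RPE,
#' choroid; within each a-scan column the non-background classes appear as
#' contiguous runs in anatomical order.
#'
#' @param labels Integer array `[n_bscans, depth_px, width_px]`.
#' @return A `layer_maps`.
#' @export
layer_maps <- function(labels) {
  stopifnot(length(dim(labels)) == 3L, all(labels %in% 0:4))
  structure(list(labels = labels, levels = LAYER_LEVELS), class = "layer_maps")
}

#' En-face map
#'
#' Rows are b-scans (slow axis), columns a-scan positions (fast axis).
#'
#' @param grid Numeric matrix, probabilities in `[0,1]` or binary flags.
#' @param spacing_mm `c(slow, fast)` mm/px (optional, needed for areas).
#' @param kind `"probability"` or `"binary"`.
#' @return An `enface_map`.
#' @export
enface_map <- function(grid, spacing_mm = NULL, kind = c("probability", "binary")) {
  kind <- match.arg(kind)
  grid <- as.matrix(grid)
  if (kind == "binary") {
    stopifnot(all(grid %in% c(0, 1)))
    storage.mode(grid) <- "integer"
  } else {
    stopifnot(all(grid >= 0), all(grid <= 1))
  }
  structure(list(grid = grid, spacing_mm = spacing_mm, kind = kind),
            class = "enface_map")
}

#' @export
print.synth_config <- function(x, ...) {
  cat(sprintf("synthetic OCT config: %d b-scans of %d x %d px (%s)\n",
              x$n_bscans, x$depth_px, x$width_px,
              if (x$healthy) "healthy" else
                sprintf("%d atrophy blob(s), area fraction %.2f",
                        x$n_atrophy_blobs, x$atrophy_area_fraction)))
  invisible(x)
}

#' @export
print.rora_bundle <- function(x, ...) {
  n_int <- sum(lengths(x$annotation$per_bscan))
  cat(sprintf("rora_bundle: patient %s, %d b-scans, %d annotated interval(s), en-face positives %d\n",
              x$volume$patient_id, dim(x$volume$voxels)[1], n_int,
              sum(x$enface_gt$grid)))
  invisible(x)
}
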