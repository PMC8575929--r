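# Training-target construction: 2D layer-prior targets (lateral RORA extent
# intersected with the photoreceptor-RPE-choroid band) and 1D max-projection
# targets for the ablation mode.

PRIOR_BAND <- c("photoreceptors", "RPE", "choroid")

#' Build the 2D layer-prior training target for one b-scan
#'
#' A pixel is positive iff its column lies inside an annotated lateral RORA
#' interval AND its layer label belongs to the prior band (by default
#' photoreceptors + RPE + choroid). Pixels inside the lateral extent but
#' outside the band are negatives, not ignored: the training loss is computed
#' over the whole image against this masked target, steering the network's
#' attention to the layers that define RORA.
#'
#' @param intervals List of 0-based half-open `c(start, end)` column intervals.
#' @param layer_mask Integer matrix `[depth_px x width_px]` with codes 0..4
#'   (background, inner_retina, photoreceptors, RPE, choroid).
#' @param band Character vector of layer names forming the vertical prior.
#' @return Binary matrix `[depth_px x width_px]`.
#' @export
build_prior_target <- function(intervals, layer_mask, band = PRIOR_BAND) {
  stopifnot(is.matrix(layer_mask), all(band %in% LAYER_LEVELS))
  codes <- match(band, LAYER_LEVELS) - 1L
  in_band <- matrix(layer_mask %in% codes, nrow(layer_mask), ncol(layer_mask))
  cols <- build_projection_target(intervals, ncol(layer_mask))
  tgt <- in_band & matrix(as.logical(cols), nrow(layer_mask), ncol(layer_mask),
                          byrow = TRUE)
  mode(tgt) <- "integer"
  tgt
}

#' Build the 1D projection training target for one b-scan
#'
#' Entry `c` is positive iff column `c` lies inside some annotated interval.
#' This is the target for the ablation mode, where the vertical span of the
#' ground truth is undefined and the loss compares maximum-probability
#' projections.
#'
#' @param intervals List of 0-based half-open `c(start, end)` intervals.
#' @param width_px Lateral size of the b-scan.
#' @return Integer 0/1 vector of length `width_px`.
#' @export
build_projection_target <- function(intervals, width_px) {
  v <- integer(width_px)
  for (iv in intervals) {
    stopifnot(length(iv) == 2L, iv[1] < iv[2], iv[1] >= 0, iv[2] <= width_px)
    v[(iv[1] + 1L):iv[2]] <- 1L
  }
  v
}

#' Assemble per-b-scan training samples from ground-truth bundles
#'
#' One sample per b-scan; the sample order is shuffled deterministically
#' under `seed`. Layer maps are consumed only in `"prior"` mode — they are a
#' training-time device and are never required at inference.
#'
#' @param bundles List of `rora_bundle` objects (see [generate_volume()]), or
#'   lists with elements `volume`, `annotation` and (for prior mode) `layers`.
#' @param mode `"prior"` (2D masked target) or `"projection"` (1D target).
#' @param seed Shuffle seed.
#' @param band Layer band passed to [build_prior_target()].
#' @return List of `training_sample` objects: `image`, `target2d` or
#'   `target1d`, `mode`, `source = c(volume_id, bscan_index)`.
#' @export
make_dataset <- function(bundles, mode = c("prior", "projection"), seed = 0L,
                         band = PRIOR_BAND) {
  mode <- match.arg(mode)
  samples <- list()
  for (bd in bundles) {
    if (mode == "prior" && is.null(bd$layers))
      stop("prior mode requires layer maps in every bundle", call. = FALSE)
    vox <- bd$volume$voxels
    n <- dim(vox)[1]
    for (b in seq_len(n)) {
      iv <- bd$annotation$per_bscan[[b]]
      img <- vox[b, , ]
      s <- list(image = img, mode = mode,
                source = c(volume_id = bd$volume$patient_id, bscan = b))
      if (mode == "prior") {
        s$target2d <- build_prior_target(iv, bd$layers$labels[b, , ], band)
      } else {
        s$target1d <- build_projection_target(iv, ncol(img))
      }
      class(s) <- "training_sample"
      samples[[length(samples) + 1L]] <- s
    }
  }
  with_seed(seed, samples[sample.int(length(samples))])
}
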