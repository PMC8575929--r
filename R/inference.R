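# Volume-level inference: per-b-scan prediction, en-face maximum-probability
# projection, and binarization at 0.5. No layer information is consumed here.

#' Predict the per-pixel atrophy probability of one b-scan
#'
#' The image is min-max normalised and passed through the network; the
#' output has the same spatial shape with values in (0, 1).
#'
#' @param model A `rora_model`.
#' @param image Numeric matrix `[depth_px x width_px]` (height and width
#'   multiples of 4).
#' @return Probability matrix of the same shape.
#' @export
predict_bscan <- function(model, image) {
  stopifnot(inherits(model, "rora_model"), is.matrix(image))
  H <- nrow(image); W <- ncol(image)
  if (H %% 4L != 0L || W %% 4L != 0L)
    stop("b-scan dimensions must be multiples of 4", call. = FALSE)
  img <- normalize_bscan(image)
  x <- matrix(as.numeric(img), H * W, 1L)
  matrix(unet_fwd(model$params, x, H, W)$prob, H, W)
}

#' Max-project per-b-scan probability maps to an en-face map
#'
#' Entry `(b, c)` of the result is the maximum probability along depth of
#' column `c` in b-scan `b`.
#'
#' @param prob_maps List of probability matrices (one per b-scan, equal
#'   shapes) or a 3D array `[n_bscans, depth, width]`.
#' @param spacing_mm Optional `c(slow, fast)` mm/px attached to the result.
#' @return A probability [enface_map()].
#' @export
project_enface <- function(prob_maps, spacing_mm = NULL) {
  if (is.array(prob_maps) && length(dim(prob_maps)) == 3L) {
    prob_maps <- lapply(seq_len(dim(prob_maps)[1]),
                        function(b) prob_maps[b, , ])
  }
  if (length(prob_maps) == 0L) stop("empty probability stack", call. = FALSE)
  dims <- vapply(prob_maps, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all probability maps must share one shape", call. = FALSE)
  grid <- do.call(rbind, lapply(prob_maps, function(m) apply(m, 2L, max)))
  enface_map(grid, spacing_mm = spacing_mm, kind = "probability")
}

#' Threshold a probability en-face map
#'
#' A pixel is positive iff its probability is `>= threshold` (inclusive).
#'
#' @param enface A probability [enface_map()].
#' @param threshold Decision threshold, default 0.5.
#' @return A binary [enface_map()].
#' @export
binarize_enface <- function(enface, threshold = 0.5) {
  stopifnot(inherits(enface, "enface_map"))
  if (enface$kind != "probability")
    stop("binarize_enface expects a probability map", call. = FALSE)
  enface_map((enface$grid >= threshold) * 1L, spacing_mm = enface$spacing_mm,
             kind = "binary")
}

#' Predict the en-face atrophy map of a whole OCT volume
#'
#' Each b-scan is fed to the network, the per-pixel probabilities are
#' max-projected along depth, and the projection is thresholded. Layer masks
#' are never used at inference time.
#'
#' @param model A trained `rora_model`.
#' @param volume An [oct_volume()].
#' @param threshold Binarization threshold, default 0.5.
#' @return List with `prob` (probability [enface_map()]) and `binary`
#'   (binary [enface_map()]).
#' @export
predict_volume <- function(model, volume, threshold = 0.5) {
  stopifnot(inherits(model, "rora_model"), inherits(volume, "oct_volume"))
  if (!model$trained)
    warning("predicting with an untrained model", call. = FALSE)
  maps <- lapply(seq_len(dim(volume$voxels)[1]),
                 function(b) predict_bscan(model, volume$voxels[b, , ]))
  prob <- project_enface(maps, spacing_mm = volume$spacing_mm[c(1, 3)])
  list(prob = prob, binary = binarize_enface(prob, threshold))
}

#' @describeIn predict_volume S3 predict method; `newdata` is an
#'   [oct_volume()].
#' @param object A trained `rora_model`.
#' @param newdata An [oct_volume()].
#' @param ... Ignored.
#' @export
predict.rora_model <- function(object, newdata, threshold = 0.5, ...) {
  predict_volume(object, newdata, threshold = threshold)
}
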