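# On-disk bundle format: multi-page TIFF for volumes and layer masks, JSON
# for annotations and metadata, PNG for binary en-face masks.

#' Write a ground-truth bundle to a directory
#'
#' Layout: `volume.tiff` (one 32-bit float page per b-scan), `layers.tiff`
#' (8-bit label codes), `annotation.json`, `enface_gt.png`, `meta.json`.
#'
#' @param bundle A `rora_bundle` from [generate_volume()].
#' @param dir Target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- bundle$volume$voxels
  pages <- lapply(seq_len(dim(vox)[1]), function(b) vox[b, , ])
  tiff::writeTIFF(pages, file.path(dir, "volume.tiff"),
                  bits.per.sample = 32L)
  lab <- bundle$layers$labels
  lab_pages <- lapply(seq_len(dim(lab)[1]), function(b) lab[b, , ] / 255)
  tiff::writeTIFF(lab_pages, file.path(dir, "layers.tiff"),
                  bits.per.sample = 8L)
  write_annotation(bundle$annotation, file.path(dir, "annotation.json"))
  png::writePNG(bundle$enface_gt$grid + 0, file.path(dir, "enface_gt.png"))
  meta <- list(patient_id = bundle$volume$patient_id,
               eye = bundle$volume$eye,
               spacing_mm = bundle$volume$spacing_mm,
               dim = dim(vox))
  if (!is.null(bundle$config)) meta$config <- unclass(bundle$config)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read a ground-truth bundle from a directory
#'
#' @param dir Directory written by [write_bundle()].
#' @return A `rora_bundle`.
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  pages <- tiff::readTIFF(file.path(dir, "volume.tiff"), all = TRUE)
  vox <- array(0, dim = meta$dim)
  for (b in seq_along(pages)) vox[b, , ] <- pages[[b]]
  lab_pages <- tiff::readTIFF(file.path(dir, "layers.tiff"), all = TRUE)
  lab <- array(0L, dim = meta$dim)
  for (b in seq_along(lab_pages)) lab[b, , ] <- as.integer(round(lab_pages[[b]] * 255))
  ann <- read_annotation(file.path(dir, "annotation.json"))
  gt <- png::readPNG(file.path(dir, "enface_gt.png"))
  if (length(dim(gt)) == 3L) gt <- gt[, , 1]
  eye <- meta$eye
  if (is.null(eye)) eye <- NA_character_
  bundle <- list(
    volume = oct_volume(vox, meta$spacing_mm, meta$patient_id, eye),
    layers = layer_maps(lab),
    annotation = ann,
    enface_gt = enface_map(round(gt), spacing_mm = meta$spacing_mm[c(1, 3)],
                           kind = "binary"),
    config = meta$config)
  class(bundle) <- "rora_bundle"
  bundle
}

#' Write an en-face prediction with its JSON sidecar
#'
#' @param pred List with `prob` and `binary` [enface_map()]s, as returned by
#'   [predict_volume()].
#' @param dir Target directory.
#' @param threshold Threshold recorded in the sidecar.
#' @return `dir`, invisibly.
#' @export
write_prediction <- function(pred, dir, threshold = 0.5) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pred$prob$grid, file.path(dir, "enface_prob.tiff"),
                  bits.per.sample = 32L)
  png::writePNG(pred$binary$grid + 0, file.path(dir, "enface_binary.png"))
  jsonlite::write_json(list(spacing_mm = pred$prob$spacing_mm,
                            threshold = threshold,
                            positive_pixels = sum(pred$binary$grid)),
                       file.path(dir, "prediction.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
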