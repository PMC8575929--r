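# Per-volume en-face agreement metrics, cohort aggregation, Bland-Altman
# area agreement, and patient-grouped cross-validation splitting.

as_binary_grid <- function(x, what = "mask") {
  if (inherits(x, "enface_map")) {
    if (x$kind != "binary")
      stop(what, " must be a binary en-face map", call. = FALSE)
    return(x$grid)
  }
  m <- as.matrix(x)
  stopifnot(all(m %in% c(0, 1)))
  m
}

#' Confusion counts between two binary en-face masks
#'
#' @param pred,ref Binary [enface_map()] objects or 0/1 matrices of equal
#'   dimensions.
#' @return Named integer vector `c(TP, FP, FN, TN)`.
#' @export
confusion_counts <- function(pred, ref) {
  p <- as_binary_grid(pred, "pred")
  r <- as_binary_grid(ref, "ref")
  if (!all(dim(p) == dim(r)))
    stop("prediction and reference dimensions differ", call. = FALSE)
  tp <- sum(p == 1 & r == 1)
  fp <- sum(p == 1 & r == 0)
  fn <- sum(p == 0 & r == 1)
  tn <- sum(p == 0 & r == 0)
  c(TP = tp, FP = fp, FN = fn, TN = tn)
}

metrics_from_counts <- function(cc) {
  tp <- cc["TP"]; fp <- cc["FP"]; fn <- cc["FN"]; tn <- cc["TN"]
  n <- sum(cc)
  if (tp + fp + fn == 0) {            # both masks empty: perfect agreement
    return(c(dice = 1, precision = 1, recall = 1, kappa = 1))
  }
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (abs(1 - pe) < 1e-15) {
    if (po == 1) 1 else 0             # both masks constant
  } else (po - pe) / (1 - pe)
  c(dice = unname(dice), precision = unname(precision),
    recall = unname(recall), kappa = unname(kappa))
}

#' Per-volume en-face agreement metrics
#'
#' Dice, precision, recall (sensitivity) and Cohen's kappa computed on
#' en-face pixels, plus segmented areas in mm^2. Degenerate conventions:
#' both masks empty gives all metrics 1; an empty prediction against a
#' nonempty reference gives dice = precision = recall = 0; kappa when both
#' masks are constant is 1 if they agree and 0 otherwise.
#'
#' @param pred,ref Binary [enface_map()] objects or 0/1 matrices.
#' @param spacing_mm `c(slow, fast)` mm/px; taken from `pred`/`ref` when
#'   they carry spacing.
#' @param volume_id,reference Labels stored in the result.
#' @return A one-row data frame (`volume_metrics`).
#' @export
volume_metrics <- function(pred, ref, spacing_mm = NULL,
                           volume_id = "volume", reference = "reference") {
  if (is.null(spacing_mm)) {
    for (x in list(pred, ref))
      if (inherits(x, "enface_map") && !is.null(x$spacing_mm))
        spacing_mm <- x$spacing_mm
  }
  cc <- confusion_counts(pred, ref)
  m <- metrics_from_counts(cc)
  px_mm2 <- if (is.null(spacing_mm)) NA_real_ else prod(spacing_mm[1:2])
  data.frame(volume_id = volume_id, reference = reference,
             dice = m["dice"], precision = m["precision"],
             recall = m["recall"], kappa = m["kappa"],
             area_pred_mm2 = sum(as_binary_grid(pred)) * px_mm2,
             area_ref_mm2 = sum(as_binary_grid(ref)) * px_mm2,
             row.names = NULL)
}

#' Aggregate per-volume metrics into a cohort report
#'
#' Unweighted mean and sample (n-1) standard deviation per metric across
#' volumes (never pixel-pooled); a single volume reports sd 0.
#'
#' @param metrics Data frame of rows from [volume_metrics()], or a list of
#'   such rows.
#' @return A `cohort_report`: list with `per_volume` and `summary`.
#' @export
aggregate_metrics <- function(metrics) {
  if (is.list(metrics) && !is.data.frame(metrics))
    metrics <- do.call(rbind, metrics)
  if (is.null(metrics) || nrow(metrics) == 0L)
    stop("no volume metrics to aggregate", call. = FALSE)
  cols <- c("dice", "precision", "recall", "kappa")
  summ <- data.frame(
    metric = cols,
    mean = vapply(cols, function(cl) mean(metrics[[cl]]), numeric(1)),
    sd = vapply(cols, function(cl)
      if (nrow(metrics) < 2L) 0 else stats::sd(metrics[[cl]]), numeric(1)),
    row.names = NULL)
  structure(list(per_volume = metrics, summary = summ),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("cohort report: %d volume(s)\n", nrow(x$per_volume)))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-9s %.3f ± %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  invisible(x)
}

#' Bland-Altman agreement for paired area measurements
#'
#' Differences `d_i = a_i - b_i`; reports their mean, sample standard
#' deviation and the limits of agreement `mean +/- 1.96 sd`.
#'
#' @param a,b Numeric vectors of paired measurements (e.g. RORA areas in
#'   mm^2), or `a` a two-column matrix/data frame.
#' @return A `bland_altman` list: `pairs`, `mean_difference`, `sd_difference`,
#'   `loa_low`, `loa_high`.
#' @export
bland_altman <- function(a, b = NULL) {
  if (is.null(b)) {
    m <- as.matrix(a)
    stopifnot(ncol(m) == 2L)
    a <- m[, 1]; b <- m[, 2]
  }
  stopifnot(length(a) == length(b))
  if (length(a) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- a - b
  md <- mean(d)
  sdd <- stats::sd(d)
  structure(list(pairs = cbind(a = a, b = b), mean_difference = md,
                 sd_difference = sdd,
                 loa_low = md - 1.96 * sdd, loa_high = md + 1.96 * sdd),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (%d pairs): mean difference %.4f, LoA [%.4f, %.4f]\n",
              nrow(x$pairs), x$mean_difference, x$loa_low, x$loa_high))
  invisible(x)
}

#' Plot a Bland-Altman agreement analysis
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  means <- rowMeans(x$pairs)
  diffs <- x$pairs[, 1] - x$pairs[, 2]
  graphics::plot(means, diffs, xlab = "mean of pair", ylab = "difference",
                 ...)
  graphics::abline(h = c(x$loa_low, x$mean_difference, x$loa_high),
                   lty = c(2, 1, 2))
  invisible(x)
}

#' Patient-grouped k-fold split
#'
#' Folds partition patients: all volumes (e.g. both eyes) of one patient end
#' up in the same test fold, avoiding intra-patient correlation between
#' training and testing. Deterministic per seed.
#'
#' @param volume_ids Character vector of volume labels.
#' @param patient_ids Character vector of the owning patient per volume.
#' @param k Number of folds.
#' @param seed Shuffle seed.
#' @return List of `k` lists with elements `train` and `test` (volume ids).
#' @export
cv_split <- function(volume_ids, patient_ids, k = 5L, seed = 1L) {
  stopifnot(length(volume_ids) == length(patient_ids), k >= 2L)
  patients <- unique(patient_ids)
  if (k > length(patients))
    stop("k exceeds the number of patients", call. = FALSE)
  shuffled <- with_seed(seed, sample(patients))
  fold_of_patient <- rep_len(seq_len(k), length(shuffled))
  names(fold_of_patient) <- shuffled
  lapply(seq_len(k), function(f) {
    test_pat <- shuffled[fold_of_patient == f]
    list(train = volume_ids[!(patient_ids %in% test_pat)],
         test = volume_ids[patient_ids %in% test_pat])
  })
}
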