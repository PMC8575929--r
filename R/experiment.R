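# Experiment drivers: held-out test evaluation, patient-grouped
# cross-validation, and the layer-prior vs projection-loss ablation,
# all on synthetic cohorts.

#' Desk-scale experiment profile
#'
#' The default experiment conditions: 30 synthetic volumes of 16 b-scans at
#' 64 x 128 px (6 x 6 mm footprint), default atrophy and noise, a tiny
#' randomly initialised encoder trained for 15 epochs. The clinical-scale default
#' learning rate (2.5e-5) suits a large ImageNet-pretrained encoder;
#' a compact network trained from scratch needs a correspondingly larger
#' step size, so this profile uses Adam at 1e-3 with batches of 8 b-scans.
#'
#' @param seed Base seed for data generation, splitting and training.
#' @param mode Training mode, `"prior"` by default.
#' @return List with `synth`, `train`, `n_volumes`, `n_test`, `threshold`,
#'   `k_folds`, `seed`.
#' @export
desk_profile <- function(seed = 1L, mode = "prior") {
  list(synth = synth_config(),
       train = train_config(mode = mode, encoder = "tiny",
                            learning_rate = 1e-3, batch_size = 8L,
                            epochs = 15L, seed = seed),
       n_volumes = 30L, n_test = 6L, threshold = 0.5, k_folds = 5L,
       seed = as.integer(seed))
}

evaluate_volumes <- function(model, bundles, threshold = 0.5,
                             reference = "synthetic-gt") {
  rows <- lapply(bundles, function(bd) {
    pred <- predict_volume(model, bd$volume, threshold)
    volume_metrics(pred$binary, bd$enface_gt,
                   spacing_mm = bd$volume$spacing_mm[c(1, 3)],
                   volume_id = bd$volume$patient_id, reference = reference)
  })
  do.call(rbind, rows)
}

#' Held-out test experiment on a synthetic cohort
#'
#' Generates `n_volumes` phantoms (one per patient), holds out `n_test`
#' patients, trains a model on the remaining volumes' b-scans and evaluates
#' per-volume en-face metrics on the held-out set.
#'
#' @param profile Experiment profile, see [desk_profile()].
#' @param verbose Print training progress.
#' @return List with `model`, `report` (a `cohort_report`), `bundles`,
#'   `test_idx`, `areas` (per-test-volume predicted vs reference areas).
#' @export
run_holdout <- function(profile = desk_profile(), verbose = FALSE) {
  bundles <- generate_cohort(profile$n_volumes, base = profile$synth,
                             seed = profile$seed)
  test_idx <- with_seed(profile$seed + 17L,
                        sort(sample.int(profile$n_volumes, profile$n_test)))
  train_bundles <- bundles[-test_idx]
  samples <- make_dataset(train_bundles, mode = profile$train$mode,
                          seed = profile$seed)
  model <- fit_rora(samples, config = profile$train, verbose = verbose)
  metrics <- evaluate_volumes(model, bundles[test_idx], profile$threshold)
  report <- aggregate_metrics(metrics)
  list(model = model, report = report, bundles = bundles,
       test_idx = test_idx,
       areas = metrics[, c("volume_id", "area_pred_mm2", "area_ref_mm2")])
}

#' Patient-grouped k-fold cross-validation
#'
#' Trains one model per fold (folds partition patients) and evaluates each
#' test fold, mirroring a fivefold cross-validation design.
#'
#' @param bundles List of `rora_bundle` objects.
#' @param profile Experiment profile (its `train`, `threshold`, `k_folds`
#'   and `seed` are used).
#' @param verbose Print training progress.
#' @return List of per-fold `cohort_report`s plus a `folds_table` data frame
#'   with one row per fold (mean Dice/precision/recall/kappa).
#' @export
run_crossval <- function(bundles, profile = desk_profile(), verbose = FALSE) {
  vols <- vapply(bundles, function(b) b$volume$patient_id, character(1))
  pats <- vols  # synthetic cohorts carry one volume per patient
  folds <- cv_split(vols, pats, k = profile$k_folds, seed = profile$seed)
  reports <- vector("list", length(folds))
  rows <- NULL
  for (f in seq_along(folds)) {
    tr <- bundles[vols %in% folds[[f]]$train]
    te <- bundles[vols %in% folds[[f]]$test]
    cfg <- profile$train
    cfg$seed <- profile$train$seed + f
    samples <- make_dataset(tr, mode = cfg$mode, seed = cfg$seed)
    model <- fit_rora(samples, config = cfg, verbose = verbose)
    rep <- aggregate_metrics(evaluate_volumes(model, te, profile$threshold))
    reports[[f]] <- rep
    s <- rep$summary
    rows <- rbind(rows, data.frame(fold = f,
                                   dice = s$mean[s$metric == "dice"],
                                   precision = s$mean[s$metric == "precision"],
                                   recall = s$mean[s$metric == "recall"],
                                   kappa = s$mean[s$metric == "kappa"]))
  }
  list(reports = reports, folds_table = rows, folds = folds)
}

#' Layer-prior ablation
#'
#' Trains the 2D layer-prior model and the 1D projection-loss model on the
#' identical train/test split and seed, and reports both side by side.
#'
#' @param profile Experiment profile, see [desk_profile()].
#' @param verbose Print training progress.
#' @return List with `prior` and `projection` `run_holdout()` results and a
#'   `comparison` data frame.
#' @export
run_ablation <- function(profile = desk_profile(), verbose = FALSE) {
  prof_prior <- profile
  prof_prior$train$mode <- "prior"
  prof_proj <- profile
  prof_proj$train$mode <- "projection"
  res_prior <- run_holdout(prof_prior, verbose = verbose)
  res_proj <- run_holdout(prof_proj, verbose = verbose)
  mk <- function(res, label) {
    s <- res$report$summary
    data.frame(model = label,
               dice = s$mean[s$metric == "dice"],
               precision = s$mean[s$metric == "precision"],
               recall = s$mean[s$metric == "recall"],
               kappa = s$mean[s$metric == "kappa"])
  }
  list(prior = res_prior, projection = res_proj,
       comparison = rbind(mk(res_proj, "without layer prior"),
                          mk(res_prior, "with layer prior")))
}

#' Write a synthetic cohort to disk
#'
#' One directory per volume plus a `manifest.json`; idempotent for a fixed
#' seed (regenerating writes byte-identical annotations and manifest).
#'
#' @param n_volumes Number of volumes.
#' @param dir Output directory.
#' @param base Template [synth_config()].
#' @param seed Cohort seed.
#' @param healthy_fraction Fraction of healthy volumes.
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(n_volumes, dir, base = synth_config(), seed = 1L,
                         healthy_fraction = 0) {
  stopifnot(n_volumes >= 1L)
  bundles <- generate_cohort(n_volumes, base = base, seed = seed,
                             healthy_fraction = healthy_fraction)
  entries <- lapply(seq_along(bundles), function(i) {
    sub <- sprintf("vol_%03d", i)
    write_bundle(bundles[[i]], file.path(dir, sub))
    list(path = sub,
         patient_id = bundles[[i]]$volume$patient_id,
         healthy = bundles[[i]]$config$healthy,
         seed = bundles[[i]]$config$seed,
         n_intervals = sum(lengths(bundles[[i]]$annotation$per_bscan)))
  })
  manifest <- list(n_volumes = n_volumes, seed = seed,
                   healthy_fraction = healthy_fraction, volumes = entries)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
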