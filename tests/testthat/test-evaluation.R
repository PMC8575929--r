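# Brute-force metric oracle: recompute everything from the pixel-level
# contingency table with plain arithmetic.
oracle_metrics <- function(p, r) {
  tp <- sum(p == 1 & r == 1); fp <- sum(p == 1 & r == 0)
  fn <- sum(p == 0 & r == 1); tn <- sum(p == 0 & r == 0)
  n <- tp + fp + fn + tn
  if (tp + fp + fn == 0) return(c(dice = 1, precision = 1, recall = 1, kappa = 1))
  dice <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 0
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  po <- (tp + tn) / n
  pe <- ((tp + fp) / n) * ((tp + fn) / n) + ((fp + tn) / n) * ((fn + tn) / n)
  kap <- if (abs(1 - pe) < 1e-15) { if (po == 1) 1 else 0 } else (po - pe) / (1 - pe)
  c(dice = dice, precision = prec, recall = rec, kappa = kap)
}

test_that("confusion counts enumerate the four outcomes", {
  a <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(confusion_counts(a, a), c(TP = 2L, FP = 0L, FN = 0L, TN = 2L))
  expect_equal(confusion_counts(a, 1 - a)[c("TP", "TN")], c(TP = 0L, TN = 0L))
  # worked 2x2 example: pred = {(1,1),(1,2)}, ref = {(1,2),(2,2)}
  pred <- matrix(0, 2, 2); pred[1, 1] <- 1; pred[1, 2] <- 1
  ref <- matrix(0, 2, 2); ref[1, 2] <- 1; ref[2, 2] <- 1
  expect_equal(confusion_counts(pred, ref),
               c(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 2)), "dimensions")
})

test_that("the 2x2 worked example yields dice 0.5 and kappa 0", {
  pred <- matrix(0, 2, 2); pred[1, 1] <- 1; pred[1, 2] <- 1
  ref <- matrix(0, 2, 2); ref[1, 2] <- 1; ref[2, 2] <- 1
  vm <- volume_metrics(pred, ref)
  expect_equal(vm$dice, 0.5)
  expect_equal(vm$precision, 0.5)
  expect_equal(vm$recall, 0.5)
  expect_equal(vm$kappa, 0)
})

test_that("metric edge cases follow the documented conventions", {
  full <- matrix(1, 3, 4); empty <- matrix(0, 3, 4)
  half <- matrix(rep(c(1, 0), each = 6), 3, 4)
  # identical non-trivial masks
  vm <- volume_metrics(half, half)
  expect_equal(unlist(vm[c("dice", "precision", "recall", "kappa")]),
               c(dice = 1, precision = 1, recall = 1, kappa = 1))
  # all-positive prediction against half-positive reference
  vm2 <- volume_metrics(full, half)
  expect_equal(vm2$recall, 1)
  expect_equal(vm2$precision, 0.5)
  expect_equal(vm2$kappa, 0)
  # both masks empty -> perfect agreement by convention
  vm3 <- volume_metrics(empty, empty)
  expect_equal(unlist(vm3[c("dice", "precision", "recall", "kappa")]),
               c(dice = 1, precision = 1, recall = 1, kappa = 1))
  # empty prediction against nonempty reference
  vm4 <- volume_metrics(empty, half)
  expect_equal(unlist(vm4[c("dice", "precision", "recall")]),
               c(dice = 0, precision = 0, recall = 0))
  # constant disagreeing masks: p_e = 1, masks differ -> kappa 0
  expect_equal(volume_metrics(full, empty)$kappa, 0)
  expect_equal(volume_metrics(full, full)$kappa, 1)
})

test_that("metrics match the brute-force oracle on 200 random mask pairs", {
  set.seed(2024)
  for (rep in 1:200) {
    nr <- sample(1:6, 1); nc <- sample(1:8, 1)
    # include degenerate all-0 / all-1 masks with non-trivial probability
    p_dens <- sample(c(0, 1, runif(1)), 1)
    r_dens <- sample(c(0, 1, runif(1)), 1)
    p <- matrix(rbinom(nr * nc, 1, p_dens), nr, nc)
    r <- matrix(rbinom(nr * nc, 1, r_dens), nr, nc)
    vm <- volume_metrics(p, r)
    om <- oracle_metrics(p, r)
    expect_equal(unlist(vm[c("dice", "precision", "recall", "kappa")]),
                 om, tolerance = 1e-14, ignore_attr = TRUE)
    # harmonic-mean identity when TP > 0
    if (sum(p == 1 & r == 1) > 0) {
      expect_equal(vm$dice,
                   2 * vm$precision * vm$recall / (vm$precision + vm$recall),
                   tolerance = 1e-12)
    }
    # swapping pred/ref swaps precision and recall, keeps dice and kappa
    sw <- volume_metrics(r, p)
    expect_equal(sw$precision, vm$recall, tolerance = 1e-12)
    expect_equal(sw$recall, vm$precision, tolerance = 1e-12)
    expect_equal(sw$dice, vm$dice, tolerance = 1e-12)
    expect_equal(sw$kappa, vm$kappa, tolerance = 1e-12)
  }
})

test_that("areas scale with pixel spacing", {
  p <- matrix(1, 2, 3)
  vm <- volume_metrics(p, p, spacing_mm = c(0.25, 0.05))
  expect_equal(vm$area_pred_mm2, 6 * 0.25 * 0.05)
  expect_equal(vm$area_ref_mm2, vm$area_pred_mm2)
})

test_that("cohort aggregation averages per-volume metrics", {
  m1 <- volume_metrics(matrix(1, 2, 2), matrix(1, 2, 2), volume_id = "a")
  m2 <- volume_metrics(matrix(c(1, 1, 0, 0), 2), matrix(c(1, 0, 1, 0), 2),
                       volume_id = "b")
  rep1 <- aggregate_metrics(m1)
  expect_equal(rep1$summary$mean[rep1$summary$metric == "dice"], 1)
  expect_true(all(rep1$summary$sd == 0))
  rep2 <- aggregate_metrics(rbind(m1, m2))
  expect_equal(rep2$summary$mean[rep2$summary$metric == "dice"],
               mean(c(m1$dice, m2$dice)))
  expect_equal(rep2$summary$sd[rep2$summary$metric == "dice"],
               sd(c(m1$dice, m2$dice)))
  # permutation invariance of the summary
  rep3 <- aggregate_metrics(rbind(m2, m1))
  expect_equal(rep3$summary, rep2$summary)
  expect_error(aggregate_metrics(list()), "no volume metrics")
})

test_that("Bland-Altman limits follow mean +/- 1.96 sd of differences", {
  ba0 <- bland_altman(c(2, 3, 4), c(2, 3, 4))
  expect_equal(ba0$mean_difference, 0)
  expect_equal(c(ba0$loa_low, ba0$loa_high), c(0, 0))
  # differences {1, -1}: mean 0, sample sd sqrt(2)
  ba <- bland_altman(c(2, 1), c(1, 2))
  expect_equal(ba$mean_difference, 0)
  expect_equal(ba$sd_difference, sqrt(2))
  expect_equal(ba$loa_high, 1.96 * sqrt(2))
  expect_equal(ba$loa_low, -1.96 * sqrt(2))
  # swapping the pair order negates the mean difference
  x <- c(5, 7, 9); y <- c(4, 8, 7)
  expect_equal(bland_altman(x, y)$mean_difference,
               -bland_altman(y, x)$mean_difference)
  expect_error(bland_altman(1, 2), "at least 2")
  expect_true(ba$loa_low <= ba$mean_difference &&
                ba$mean_difference <= ba$loa_high)
})

test_that("cross-validation folds partition volumes by patient", {
  vols <- sprintf("V%02d", 1:14)
  pats <- c(rep(sprintf("p%d", 1:4), each = 2), sprintf("p%d", 5:10))
  folds <- cv_split(vols, pats, k = 5, seed = 3)
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tests, vols)
  expect_equal(anyDuplicated(tests), 0)
  for (f in folds) {
    expect_setequal(union(f$train, f$test), vols)
    # no patient spans the train/test boundary
    test_pats <- pats[match(f$test, vols)]
    train_pats <- pats[match(f$train, vols)]
    expect_length(intersect(test_pats, train_pats), 0)
    # both volumes of a two-volume patient sit in the same fold
    for (tp in unique(test_pats))
      expect_true(all(vols[pats == tp] %in% f$test))
  }
  # determinism and patient-count balance
  expect_identical(cv_split(vols, pats, k = 5, seed = 3), folds)
  ten <- cv_split(sprintf("v%d", 1:10), sprintf("q%d", 1:10), k = 5, seed = 1)
  expect_true(all(vapply(ten, function(f) length(f$test), integer(1)) == 2L))
  expect_error(cv_split(vols, pats, k = 11, seed = 1), "exceeds")
})
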