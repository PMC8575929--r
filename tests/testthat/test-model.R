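# Independent scalar evaluation of the focal loss used as an oracle below.
focal_scalar <- function(p, y, gamma) {
  pt <- if (y == 1) p else 1 - p
  -(1 - pt)^gamma * log(pt)
}

test_that("focal loss matches its closed forms", {
  # confident correct prediction costs ~0
  expect_lt(focal_bce(0.999999, 1, 2), 1e-10)
  # p = 0.5, y = 1, gamma = 2: (0.5)^2 * ln 2
  expect_equal(focal_bce(0.5, 1, 2), 0.25 * log(2), tolerance = 1e-12)
  # gamma = 0 reduces to plain binary cross-entropy
  set.seed(9)
  for (i in 1:100) {
    p <- runif(1, 0.01, 0.99); y <- rbinom(1, 1, 0.5)
    expect_equal(focal_bce(p, y, 0),
                 -(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
  }
})

test_that("focal loss agrees with an independent scalar oracle", {
  set.seed(10)
  for (i in 1:100) {
    p <- runif(1, 0.01, 0.99); y <- rbinom(1, 1, 0.5)
    gamma <- runif(1, 0, 4)
    expect_equal(focal_bce(p, y, gamma), focal_scalar(p, y, gamma),
                 tolerance = 1e-10)
  }
  # batched input averages elementwise losses
  p <- runif(12, 0.05, 0.95); y <- rbinom(12, 1, 0.5)
  expect_equal(focal_bce(p, y, 2),
               mean(mapply(focal_scalar, p, y, 2)), tolerance = 1e-12)
  # decreasing in p_t
  ps <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(ps, focal_bce, numeric(1), y = 1, gamma = 2)) < 0))
})

test_that("analytic gradients match finite differences in both modes", {
  cfg <- train_config(seed = 2)
  m <- build_network(cfg)
  set.seed(31)
  H <- 8L; W <- 12L
  x <- matrix(runif(H * W), H, W)
  s2 <- list(image = x, target2d = matrix(rbinom(H * W, 1, 0.3), H, W),
             mode = "prior")
  s1 <- list(image = x, target1d = as.integer(rbinom(W, 1, 0.4)),
             mode = "projection")
  fd <- function(params, nm, i, j, s, mode) {
    eps <- 1e-6
    up <- params; up[[nm]]$W[i, j] <- up[[nm]]$W[i, j] + eps
    dn <- params; dn[[nm]]$W[i, j] <- dn[[nm]]$W[i, j] - eps
    (roraseg:::sample_pass(up, s, 2, mode, backward = FALSE)$loss -
       roraseg:::sample_pass(dn, s, 2, mode, backward = FALSE)$loss) / (2 * eps)
  }
  for (s in list(s2, s1)) {
    mode <- s$mode
    g <- roraseg:::sample_pass(m$params, s, 2, mode)$grads
    for (nm in c("e1a", "e2b", "bb", "d2", "d1", "out")) {
      i <- nrow(m$params[[nm]]$W); j <- ncol(m$params[[nm]]$W)
      expect_equal(g[[nm]]$dW[i, j], fd(m$params, nm, i, j, s, mode),
                   tolerance = 1e-5, label = paste(mode, nm))
      expect_equal(g[[nm]]$dW[1, 1], fd(m$params, nm, 1, 1, s, mode),
                   tolerance = 1e-5, label = paste(mode, nm, "first"))
    }
  }
})

test_that("projection loss depends only on column maxima", {
  cfg <- train_config(seed = 4)
  m <- build_network(cfg)
  set.seed(77)
  H <- 8L; W <- 12L
  p <- matrix(runif(H * W, 0.05, 0.95), H, W)
  y <- as.integer(rbinom(W, 1, 0.5))
  loss_of <- function(pm) focal_bce(apply(pm, 2, max), y, 2)
  base <- loss_of(p)
  for (rep in 1:10) {
    perm <- p[sample(H), ]   # permute rows within the grid
    expect_equal(loss_of(perm), base, tolerance = 1e-12)
  }
})

test_that("augmentation transforms image and target consistently", {
  set.seed(5)
  img <- matrix(runif(16 * 24), 16, 24)
  t2 <- matrix(0L, 16, 24); t2[6:9, 10:18] <- 1L
  s <- list(image = img, target2d = t2, mode = "prior")
  flip <- function(x) x[, rev(seq_len(ncol(x))), drop = FALSE]
  # flip-only augmentation is an involution
  aug <- list(hflip = TRUE, scale_range = c(1, 1), blur = FALSE, noise = FALSE)
  flipped <- FALSE
  for (i in 1:20) {
    a <- augment_sample(s, aug)
    if (!isTRUE(all.equal(a$image, img))) {
      flipped <- TRUE
      expect_equal(flip(a$image), img)
      expect_equal(flip(a$target2d), t2)
    } else {
      expect_equal(a$target2d, t2)
    }
  }
  expect_true(flipped)
  # 1D target flips to the reversed vector
  s1 <- list(image = img, target1d = c(rep(0L, 20), rep(1L, 4)),
             mode = "projection")
  seen <- replicate(20, augment_sample(s1, aug)$target1d, simplify = FALSE)
  expect_true(any(vapply(seen, function(v) identical(v, rev(s1$target1d)),
                         logical(1))))
  # degenerate settings are the identity
  ident <- augment_sample(s, list(hflip = FALSE, scale_range = c(1, 1),
                                  blur = FALSE, noise = FALSE))
  expect_identical(ident$image, img)
  expect_identical(ident$target2d, t2)
  # scaling restores the original dimensions
  sc <- augment_sample(s, list(hflip = FALSE, scale_range = c(0.8, 1.2),
                               blur = FALSE, noise = FALSE))
  expect_equal(dim(sc$image), dim(img))
  expect_equal(dim(sc$target2d), dim(t2))
  expect_true(all(sc$target2d %in% c(0L, 1L)))
})

test_that("build_network meets its output contract", {
  cfg <- train_config(seed = 6)
  m1 <- build_network(cfg)
  m2 <- build_network(cfg)
  expect_identical(m1$params, m2$params)
  expect_error(train_config(encoder = "resnet"), "arg")
  img <- matrix(runif(16 * 24), 16, 24)
  p <- predict_bscan(m1, img)
  expect_equal(dim(p), c(16L, 24L))
  expect_true(all(p > 0 & p < 1))
  expect_gt(roraseg:::n_params(m1$params), 0)
})

test_that("training reduces the loss and is reproducible", {
  co <- fixture_clean_cohort(2)
  ds <- make_dataset(co, mode = "prior", seed = 2)[1:12]
  cfg <- train_config(mode = "prior", learning_rate = 1e-3, batch_size = 4L,
                      epochs = 3L, seed = 11)
  m1 <- fit_rora(ds, config = cfg)
  expect_lt(m1$history$train_loss[3], m1$history$train_loss[1])
  m2 <- fit_rora(ds, config = cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
  # mode mismatch and empty input are rejected
  expect_error(fit_rora(ds, config = train_config(mode = "projection")),
               "mode")
  expect_error(fit_rora(list(), config = cfg), "no training samples")
})

test_that("a tiny prior-mode model learns a clean cohort (Dice > 0.95)", {
  co <- fixture_clean_cohort(6)
  ds <- make_dataset(co, mode = "prior", seed = 3)
  cfg <- train_config(mode = "prior", learning_rate = 1e-3, batch_size = 8L,
                      epochs = 15L, seed = 21)
  m <- fit_rora(ds, config = cfg)
  # training Dice, pixel-pooled over all training b-scans
  tp <- 0; fp <- 0; fn <- 0
  for (s in ds) {
    pred <- predict_bscan(m, s$image) >= 0.5
    tp <- tp + sum(pred & s$target2d == 1)
    fp <- fp + sum(pred & s$target2d == 0)
    fn <- fn + sum(!pred & s$target2d == 1)
  }
  dice <- 2 * tp / (2 * tp + fp + fn)
  expect_gt(dice, 0.95)
})

test_that("model checkpoints round-trip through JSON", {
  m <- build_network(train_config(seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  back <- load_model(path)
  img <- matrix(runif(16 * 16), 16, 16)
  expect_equal(predict_bscan(back, img), predict_bscan(m, img),
               tolerance = 1e-12)
  expect_equal(back$config$mode, m$config$mode)
})
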