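# The trainable encoder-decoder: focal binary cross-entropy in 2D (prior)
# and 1D (projection) modes, data augmentation, and the Adam training loop.

#' Training configuration
#'
#' Defaults are the clinical-scale training recipe (Adam, learning rate
#' 2.5e-5, batches of 32 b-scans, focal gamma 2, 50 epochs, horizontal flip /
#' 0.8-1.2 scaling / Gaussian blur / additive noise augmentation). Those
#' values suit a large pretrained encoder; for the compact randomly
#' initialised encoders shipped here, [desk_profile()] provides a matching
#' desk-scale recipe.
#'
#' @param mode `"prior"` (2D layer-masked loss) or `"projection"` (1D loss on
#'   column-wise maximum probabilities).
#' @param encoder `"tiny"` (three levels, ~15k parameters) or `"small"`.
#' @param pretrained Must be `FALSE`; no pretrained weights ship with the
#'   package.
#' @param learning_rate Adam learning rate.
#' @param batch_size B-scans per optimisation step.
#' @param epochs Training epochs (no early stopping).
#' @param focal_gamma Focusing exponent of the focal loss (0 = plain BCE).
#' @param augment List of flags: `hflip`, `scale_range` (`c(lo, hi)` with
#'   `lo <= 1 <= hi`), `blur`, `noise`.
#' @param seed Seed controlling initialisation, shuffling and augmentation.
#' @return A `train_config`.
#' @export
train_config <- function(mode = c("prior", "projection"),
                         encoder = c("tiny", "small"),
                         pretrained = FALSE,
                         learning_rate = 2.5e-5, batch_size = 32L,
                         epochs = 50L, focal_gamma = 2,
                         augment = list(hflip = TRUE, scale_range = c(0.8, 1.2),
                                        blur = TRUE, noise = TRUE),
                         seed = 1L) {
  mode <- match.arg(mode)
  encoder <- match.arg(encoder)
  if (isTRUE(pretrained))
    stop("no pretrained encoder weights are available", call. = FALSE)
  stopifnot(learning_rate > 0, batch_size >= 1L, epochs >= 1L,
            focal_gamma >= 0)
  sr <- augment$scale_range %||% c(1, 1)
  if (!(sr[1] <= 1 && sr[2] >= 1))
    stop("scale_range must bracket 1", call. = FALSE)
  structure(list(mode = mode, encoder = encoder, pretrained = FALSE,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), focal_gamma = focal_gamma,
                 augment = augment, seed = as.integer(seed)),
            class = "train_config")
}

#' Focal binary cross-entropy
#'
#' `FL(p_t) = -(1 - p_t)^gamma * log(p_t)` with `p_t = p` where `y = 1` and
#' `1 - p` where `y = 0`, averaged over elements. `gamma = 0` reduces to
#' plain binary cross-entropy. Probabilities are clamped away from 0 and 1.
#'
#' @param p Predicted probabilities (any shape).
#' @param y Binary targets, same shape.
#' @param gamma Nonnegative focusing exponent.
#' @return Mean focal loss (nonnegative scalar).
#' @export
focal_bce <- function(p, y, gamma = 2) {
  stopifnot(length(p) == length(y), gamma >= 0)
  eps <- 1e-12
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  mean(-(1 - pt)^gamma * log(pt))
}

# Elementwise gradient of the focal loss w.r.t. the pre-sigmoid logit z
# (p = sigmoid(z)), without the 1/N mean factor.
focal_bce_grad_z <- function(p, y, gamma) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  pt <- ifelse(y == 1, p, 1 - p)
  # dL/dpt = gamma*(1-pt)^(gamma-1)*log(pt) - (1-pt)^gamma/pt
  dpt <- if (gamma == 0) -1 / pt else
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  # dpt/dz = pt*(1-pt) * sign, with sign +1 for y=1 and -1 for y=0; the
  # pt(1-pt) factor is symmetric in pt -> 1-pt
  dz <- dpt * pt * (1 - pt)
  ifelse(y == 1, dz, -dz)
}

# --- augmentation helpers ---------------------------------------------------

gauss_kernel1d <- function(sigma) {
  r <- max(1L, ceiling(2 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with replicated edges.
gauss_blur <- function(m, sigma) {
  k <- gauss_kernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  pad_idx <- function(n) pmin(pmax(seq(1 - r, n + r), 1L), n)
  mp <- m[pad_idx(nrow(m)), , drop = FALSE]
  m1 <- apply(mp, 2L, function(col) stats::filter(col, k)[(r + 1):(r + nrow(m))])
  mp2 <- m1[, pad_idx(ncol(m)), drop = FALSE]
  t(apply(mp2, 1L, function(row) stats::filter(row, k)[(r + 1):(r + ncol(m))]))
}

# Bilinear resize of a matrix to (nh, nw).
resize_bilinear <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  ry <- (seq_len(nh) - 0.5) * h / nh + 0.5
  rx <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmin(pmax(floor(ry), 1L), h); y1 <- pmin(y0 + 1L, h)
  x0 <- pmin(pmax(floor(rx), 1L), w); x1 <- pmin(x0 + 1L, w)
  fy <- pmin(pmax(ry - y0, 0), 1); fx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0, x0, drop = FALSE] * outer(1 - fy, 1 - fx) +
    m[y1, x0, drop = FALSE] * outer(fy, 1 - fx) +
    m[y0, x1, drop = FALSE] * outer(1 - fy, fx) +
    m[y1, x1, drop = FALSE] * outer(fy, fx)
  a
}

resize_nearest <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  yi <- pmin(pmax(ceiling((seq_len(nh) - 0.5) * h / nh), 1L), h)
  xi <- pmin(pmax(ceiling((seq_len(nw) - 0.5) * w / nw), 1L), w)
  m[yi, xi, drop = FALSE]
}

# Scale by factor s about the image centre, then crop/pad back to (h, w).
scale_and_restore <- function(m, s, nearest = FALSE) {
  h <- nrow(m); w <- ncol(m)
  nh <- max(1L, round(h * s)); nw <- max(1L, round(w * s))
  z <- if (nearest) resize_nearest(m, nh, nw) else resize_bilinear(m, nh, nw)
  out <- matrix(0, h, w)
  sy <- max(0L, (nh - h) %/% 2L); sx <- max(0L, (nw - w) %/% 2L)
  oy <- max(0L, (h - nh) %/% 2L); ox <- max(0L, (w - nw) %/% 2L)
  cy <- min(h, nh); cx <- min(w, nw)
  out[oy + seq_len(cy), ox + seq_len(cx)] <-
    z[sy + seq_len(cy), sx + seq_len(cx)]
  out
}

#' Randomly augment a training sample
#'
#' Horizontal flip and isotropic scaling (restored to the original size by
#' centre crop / zero pad) are applied consistently to image and target;
#' Gaussian blur and additive noise touch the image only. Randomness comes
#' from the current RNG stream.
#'
#' @param sample A `training_sample` from [make_dataset()].
#' @param augment Augmentation flag list, see [train_config()].
#' @return The transformed sample.
#' @export
augment_sample <- function(sample, augment = list(hflip = TRUE,
                                                  scale_range = c(0.8, 1.2),
                                                  blur = TRUE, noise = TRUE)) {
  img <- sample$image
  t2 <- sample$target2d
  t1 <- sample$target1d
  if (isTRUE(augment$hflip) && stats::runif(1) < 0.5) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    if (!is.null(t2)) t2 <- t2[, rev(seq_len(ncol(t2))), drop = FALSE]
    if (!is.null(t1)) t1 <- rev(t1)
  }
  sr <- augment$scale_range
  if (!is.null(sr) && (sr[1] < 1 || sr[2] > 1)) {
    s <- stats::runif(1, sr[1], sr[2])
    if (abs(s - 1) > 1e-8) {
      img <- scale_and_restore(img, s)
      if (!is.null(t2)) t2 <- scale_and_restore(t2, s, nearest = TRUE)
      if (!is.null(t1)) {
        t1 <- as.numeric(scale_and_restore(matrix(t1, 1L), s, nearest = TRUE))
      }
    }
  }
  if (isTRUE(augment$blur) && stats::runif(1) < 0.3)
    img <- gauss_blur(img, stats::runif(1, 0.4, 1.0))
  if (isTRUE(augment$noise) && stats::runif(1) < 0.5)
    img <- img + matrix(stats::rnorm(length(img), sd = 0.02),
                        nrow(img), ncol(img))
  img[img < 0] <- 0; img[img > 1] <- 1
  sample$image <- img
  if (!is.null(t2)) { mode(t2) <- "integer"; sample$target2d <- t2 }
  if (!is.null(t1)) sample$target1d <- as.integer(t1 > 0.5)
  sample
}

# Per-b-scan min-max normalisation to [0, 1].
normalize_bscan <- function(img) {
  rng <- range(img)
  if (rng[2] - rng[1] < 1e-12) return(img * 0)
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Build an untrained segmentation network
#'
#' A fully convolutional U-Net-style encoder-decoder: three resolution
#' levels, 3x3 convolutions + ReLU, 2x2 max pooling, nearest-neighbour
#' upsampling with skip concatenation, and a sigmoid-bounded 1x1 output head.
#' It maps any single-channel b-scan whose height and width are multiples of
#' 4 to a per-pixel atrophy probability grid of the same shape.
#'
#' @param config A [train_config()].
#' @return An untrained `rora_model`.
#' @export
build_network <- function(config = train_config()) {
  stopifnot(inherits(config, "train_config"))
  params <- with_seed(config$seed, unet_init(config$encoder))
  structure(list(params = params, config = config, history = NULL,
                 trained = FALSE),
            class = "rora_model")
}

# Forward + loss + logit gradient for one (already normalised) sample.
sample_pass <- function(params, s, gamma, mode, backward = TRUE) {
  H <- nrow(s$image); W <- ncol(s$image)
  x <- matrix(as.numeric(s$image), H * W, 1L)
  fw <- unet_fwd(params, x, H, W, keep_cache = backward)
  p <- matrix(fw$prob, H, W)
  if (mode == "prior") {
    y <- s$target2d
    loss <- focal_bce(p, y, gamma)
    if (!backward) return(list(loss = loss))
    dz <- matrix(focal_bce_grad_z(p, y, gamma) / (H * W), H * W, 1L)
  } else {
    ridx <- max.col(t(p), ties.method = "first")
    q <- p[cbind(ridx, seq_len(W))]
    y <- s$target1d
    loss <- focal_bce(q, y, gamma)
    if (!backward) return(list(loss = loss))
    dq <- focal_bce_grad_z(q, y, gamma) / W
    dzm <- matrix(0, H, W)
    dzm[cbind(ridx, seq_len(W))] <- dq
    dz <- matrix(dzm, H * W, 1L)
  }
  list(loss = loss, grads = unet_bwd(params, fw$cache, dz))
}

#' Fit the RORA segmentation model
#'
#' Trains the encoder-decoder with Adam on focal binary cross-entropy. In
#' `"prior"` mode the loss is computed per pixel against the 2D layer-masked
#' target; in `"projection"` mode against the 1D target using the
#' column-wise maximum of the predicted probability grid (gradients flow
#' through the maximal element of each column). Images are min-max
#' normalised per b-scan. Fully deterministic for a fixed seed.
#'
#' @param samples Training samples from [make_dataset()]; all must share
#'   `config$mode`.
#' @param val Optional validation samples (loss logged per epoch, never
#'   augmented).
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return A trained `rora_model` with a `history` data frame
#'   (`epoch`, `train_loss`, `val_loss`).
#' @export
fit_rora <- function(samples, val = NULL, config = train_config(),
                     verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(samples) == 0L) stop("no training samples", call. = FALSE)
  modes <- vapply(samples, `[[`, character(1), "mode")
  if (any(modes != config$mode))
    stop("sample mode does not match config mode '", config$mode, "'",
         call. = FALSE)
  model <- build_network(config)
  params <- model$params
  opt <- adam_init(params)
  gamma <- config$focal_gamma
  n <- length(samples)
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())

  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        acc <- NULL
        for (i in idx) {
          s <- samples[[i]]
          s <- augment_sample(s, config$augment)
          s$image <- normalize_bscan(s$image)
          res <- sample_pass(params, s, gamma, config$mode)
          ep_loss <- ep_loss + res$loss
          acc <- add_grads(acc, res$grads)
        }
        acc <- scale_grads(acc, 1 / length(idx))
        st <- adam_step(params, acc, opt, config$learning_rate)
        params <- st$params
        opt <- st$state
      }
      vl <- if (is.null(val)) NA_real_ else
        mean(vapply(val, function(s) {
          s$image <- normalize_bscan(s$image)
          sample_pass(params, s, gamma, config$mode, backward = FALSE)$loss
        }, numeric(1)))
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss / n,
                                     val_loss = vl))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %s", ep, ep_loss / n,
                        ifelse(is.na(vl), "-", sprintf("%.5f", vl))))
    }
  })
  model$params <- params
  model$history <- hist
  model$trained <- TRUE
  model
}

#' @export
print.rora_model <- function(x, ...) {
  cat(sprintf("RORA segmentation model (%s encoder, %s mode): %d parameters, %s\n",
              x$config$encoder, x$config$mode, n_params(x$params),
              if (x$trained) sprintf("trained %d epochs", nrow(x$history))
              else "untrained"))
  invisible(x)
}

#' @export
summary.rora_model <- function(object, ...) {
  print(object)
  if (object$trained) {
    h <- object$history
    cat(sprintf("  final train loss %.5f", h$train_loss[nrow(h)]))
    if (!all(is.na(h$val_loss)))
      cat(sprintf(", final val loss %.5f", h$val_loss[nrow(h)]))
    cat("\n")
    cat(sprintf("  lr %g, batch %d, focal gamma %g, seed %d\n",
                object$config$learning_rate, object$config$batch_size,
                object$config$focal_gamma, object$config$seed))
  }
  invisible(object)
}

#' Plot training history
#'
#' @param x A trained `rora_model`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rora_model <- function(x, ...) {
  if (!x$trained) stop("model is untrained", call. = FALSE)
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "focal BCE loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' Save / load a model checkpoint as JSON
#'
#' Parameters, configuration snapshot and training history are stored as a
#' plain JSON document (text format, no binary serialisation).
#'
#' @param model A `rora_model`.
#' @param path File path.
#' @return `load_model` returns the restored `rora_model`.
#' @export
save_model <- function(model, path) {
  doc <- list(config = unclass(model$config),
              trained = model$trained,
              history = model$history,
              params = lapply(model$params, function(p)
                list(W = list(dim = dim(p$W), data = as.numeric(p$W)),
                     b = as.numeric(p$b))))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- doc$config
  config <- train_config(mode = cfg$mode, encoder = cfg$encoder,
                         learning_rate = cfg$learning_rate,
                         batch_size = cfg$batch_size, epochs = cfg$epochs,
                         focal_gamma = cfg$focal_gamma,
                         augment = as.list(cfg$augment), seed = cfg$seed)
  params <- lapply(doc$params, function(p) {
    W <- matrix(p$W$data, p$W$dim[1], p$W$dim[2])
    list(W = W, b = as.numeric(p$b))
  })
  structure(list(params = params, config = config,
                 history = as.data.frame(doc$history),
                 trained = isTRUE(doc$trained)),
            class = "rora_model")
}
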