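# Compact convolutional encoder-decoder (U-Net style) with hand-written
# backpropagation. Feature maps are (H*W) x C matrices (depth row fastest);
# 3x3 convolutions run as im2col (compiled) + BLAS matrix products.

#' @useDynLib roraseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

relu <- function(x) {
  x[x < 0] <- 0
  x
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# He-normal initialisation for a 3x3 conv: weight matrix (9*cin) x cout.
init_conv <- function(cin, cout, k = 3L) {
  fan_in <- k * k * cin
  list(W = matrix(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
                  k * k * cin, cout),
       b = numeric(cout))
}

conv3_fwd <- function(x, par, H, W) {
  patch <- im2col3(x, H, W)
  out <- patch %*% par$W
  out <- sweep(out, 2L, par$b, "+")
  list(out = out, patch = patch)
}

conv3_bwd <- function(dout, patch, par, H, W, cin) {
  list(dW = crossprod(patch, dout),
       db = colSums(dout),
       dx = col2im3(dout %*% t(par$W), H, W, cin))
}

#' @noRd
unet_channels <- function(encoder) {
  switch(encoder,
         tiny  = c(6L, 12L, 24L),
         small = c(12L, 24L, 48L),
         stop("unknown encoder: ", encoder, call. = FALSE))
}

# Parameter container: named list of conv params (W, b each).
unet_init <- function(encoder = "tiny", in_channels = 1L) {
  ch <- unet_channels(encoder)
  list(
    e1a = init_conv(in_channels, ch[1]),
    e1b = init_conv(ch[1], ch[1]),
    e2a = init_conv(ch[1], ch[2]),
    e2b = init_conv(ch[2], ch[2]),
    ba  = init_conv(ch[2], ch[3]),
    bb  = init_conv(ch[3], ch[3]),
    d2  = init_conv(ch[3] + ch[2], ch[2]),
    d1  = init_conv(ch[2] + ch[1], ch[1]),
    out = list(W = matrix(stats::rnorm(ch[1], sd = sqrt(2 / ch[1])), ch[1], 1L),
               b = 0)
  )
}

n_params <- function(params) {
  sum(vapply(params, function(p) length(p$W) + length(p$b), numeric(1)))
}

# Forward pass. x: (H*W) x 1 matrix in [0,1]. Returns per-pixel probability
# matrix (H*W) x 1 plus, optionally, the cache needed for backprop.
unet_fwd <- function(params, x, H, W, keep_cache = FALSE) {
  stopifnot(H %% 4L == 0L, W %% 4L == 0L)
  H2 <- H %/% 2L; W2 <- W %/% 2L; H4 <- H %/% 4L; W4 <- W %/% 4L

  c1 <- conv3_fwd(x, params$e1a, H, W);  a1 <- relu(c1$out)
  c2 <- conv3_fwd(a1, params$e1b, H, W); e1 <- relu(c2$out)
  p1 <- maxpool2(e1, H, W)
  c3 <- conv3_fwd(p1$out, params$e2a, H2, W2); a3 <- relu(c3$out)
  c4 <- conv3_fwd(a3, params$e2b, H2, W2);     e2 <- relu(c4$out)
  p2 <- maxpool2(e2, H2, W2)
  c5 <- conv3_fwd(p2$out, params$ba, H4, W4); a5 <- relu(c5$out)
  c6 <- conv3_fwd(a5, params$bb, H4, W4);     bt <- relu(c6$out)
  u2 <- upsample2(bt, H4, W4)
  cat2 <- cbind(u2, e2)
  c7 <- conv3_fwd(cat2, params$d2, H2, W2); d2 <- relu(c7$out)
  u1 <- upsample2(d2, H2, W2)
  cat1 <- cbind(u1, e1)
  c8 <- conv3_fwd(cat1, params$d1, H, W); d1 <- relu(c8$out)
  z <- d1 %*% params$out$W + params$out$b
  p <- sigmoid(z)

  if (!keep_cache) return(list(prob = p))
  list(prob = p, cache = list(
    x = x, a1 = a1, e1 = e1, p1 = p1, a3 = a3, e2 = e2, p2 = p2,
    a5 = a5, bt = bt, d2 = d2, d1 = d1,
    patches = list(c1$patch, c2$patch, c3$patch, c4$patch, c5$patch,
                   c6$patch, c7$patch, c8$patch),
    H = H, W = W))
}

# Backward pass from dz (gradient of the loss w.r.t. pre-sigmoid logits,
# (H*W) x 1). Returns gradients in the same structure as the parameters.
unet_bwd <- function(params, cache, dz) {
  H <- cache$H; W <- cache$W
  H2 <- H %/% 2L; W2 <- W %/% 2L; H4 <- H %/% 4L; W4 <- W %/% 4L
  ch <- vapply(params[c("e1a", "e2a", "ba")], function(p) ncol(p$W), integer(1))
  pc <- cache$patches
  g <- list()

  g$out <- list(dW = crossprod(cache$d1, dz), db = sum(dz))
  dd1 <- (dz %*% t(params$out$W)) * (cache$d1 > 0)
  b8 <- conv3_bwd(dd1, pc[[8]], params$d1, H, W, ncol(params$e2a$W) + ncol(params$e1a$W))
  g$d1 <- b8[c("dW", "db")]
  du1 <- b8$dx[, seq_len(ch[2]), drop = FALSE]
  de1 <- b8$dx[, ch[2] + seq_len(ch[1]), drop = FALSE]

  dd2 <- upsample2_bwd(du1, H2, W2) * (cache$d2 > 0)
  b7 <- conv3_bwd(dd2, pc[[7]], params$d2, H2, W2, ncol(params$ba$W) + ncol(params$e2a$W))
  g$d2 <- b7[c("dW", "db")]
  du2 <- b7$dx[, seq_len(ch[3]), drop = FALSE]
  de2 <- b7$dx[, ch[3] + seq_len(ch[2]), drop = FALSE]

  dbt <- upsample2_bwd(du2, H4, W4) * (cache$bt > 0)
  b6 <- conv3_bwd(dbt, pc[[6]], params$bb, H4, W4, ch[3])
  g$bb <- b6[c("dW", "db")]
  da5 <- b6$dx * (cache$a5 > 0)
  b5 <- conv3_bwd(da5, pc[[5]], params$ba, H4, W4, ch[2])
  g$ba <- b5[c("dW", "db")]

  de2 <- de2 + maxpool2_bwd(b5$dx, cache$p2$argmax, H2, W2)
  de2 <- de2 * (cache$e2 > 0)
  b4 <- conv3_bwd(de2, pc[[4]], params$e2b, H2, W2, ch[2])
  g$e2b <- b4[c("dW", "db")]
  da3 <- b4$dx * (cache$a3 > 0)
  b3 <- conv3_bwd(da3, pc[[3]], params$e2a, H2, W2, ch[1])
  g$e2a <- b3[c("dW", "db")]

  de1 <- de1 + maxpool2_bwd(b3$dx, cache$p1$argmax, H, W)
  de1 <- de1 * (cache$e1 > 0)
  b2 <- conv3_bwd(de1, pc[[2]], params$e1b, H, W, ch[1])
  g$e1b <- b2[c("dW", "db")]
  da1 <- b2$dx * (cache$a1 > 0)
  b1 <- conv3_bwd(da1, pc[[1]], params$e1a, H, W, ncol(cache$x))
  g$e1a <- b1[c("dW", "db")]

  g[names(params)]
}

adam_init <- function(params) {
  zero <- function(p) list(dW = p$W * 0, db = p$b * 0)
  list(m = lapply(params, zero), v = lapply(params, zero), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    for (fld in c("dW", "db")) {
      tgt <- if (fld == "dW") "W" else "b"
      gmat <- grads[[nm]][[fld]]
      state$m[[nm]][[fld]] <- beta1 * state$m[[nm]][[fld]] + (1 - beta1) * gmat
      state$v[[nm]][[fld]] <- beta2 * state$v[[nm]][[fld]] + (1 - beta2) * gmat^2
      mhat <- state$m[[nm]][[fld]] / bc1
      vhat <- state$v[[nm]][[fld]] / bc2
      params[[nm]][[tgt]] <- params[[nm]][[tgt]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (nm in names(g)) {
    acc[[nm]]$dW <- acc[[nm]]$dW + g[[nm]]$dW
    acc[[nm]]$db <- acc[[nm]]$db + g[[nm]]$db
  }
  acc
}

scale_grads <- function(g, s) {
  for (nm in names(g)) {
    g[[nm]]$dW <- g[[nm]]$dW * s
    g[[nm]]$db <- g[[nm]]$db * s
  }
  g
}
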