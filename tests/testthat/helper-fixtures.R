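# Shared fixtures. The desk-scale ablation experiment (two model trainings)
# is expensive, so it is computed once per test session and reused by the
# tests that need a converged model.

.fixtures <- new.env(parent = emptyenv())

fixture_ablation <- function() {
  if (is.null(.fixtures$ablation))
    .fixtures$ablation <- run_ablation(desk_profile(1))
  .fixtures$ablation
}

fixture_prior_model <- function() fixture_ablation()$prior$model

# A tiny clean (noise-free) cohort for fast learnability checks.
fixture_clean_cohort <- function(n = 6L) {
  generate_cohort(n, base = synth_config(speckle_sigma = 0, n_drusen = 1L),
                  seed = 303L)
}

# Random small annotation on an n x w grid, valid by construction.
random_annotation <- function(n_bscans, width_px, spacing_mm = c(0.25, 0.03, 0.04),
                              p_interval = 0.6) {
  per <- lapply(seq_len(n_bscans), function(b) {
    if (stats::runif(1) > p_interval) return(list())
    k <- sample(1:2, 1)
    cuts <- sort(sample(0:width_px, 2 * k))
    iv <- split(cuts, rep(seq_len(k), each = 2))
    Filter(function(x) x[2] > x[1], unname(lapply(iv, unname)))
  })
  rora_annotation(per, spacing_mm = spacing_mm, width_px = width_px)
}

# Brute-force 4-connected component labelling of a binary matrix (BFS);
# independent oracle for the interval-linkage rule: lateral runs on one
# b-scan plus >=1-column overlap on adjacent b-scans is exactly
# 4-connectivity on the rasterized map.
brute_components <- function(grid) {
  lab <- matrix(0L, nrow(grid), ncol(grid))
  cur <- 0L
  for (i in seq_len(nrow(grid))) for (j in seq_len(ncol(grid))) {
    if (grid[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] < 1 || q[1] > nrow(grid) || q[2] < 1 || q[2] > ncol(grid)) next
        if (grid[q[1], q[2]] == 1 && lab[q[1], q[2]] == 0L) {
          lab[q[1], q[2]] <- cur
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  lab
}
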