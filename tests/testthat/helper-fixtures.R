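# Shared fixtures, memoized per session where expensive.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# local geometry/seed helpers (independent of package internals)
fix_disk <- function(nr, nc, cy, cx, r) {
  outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+") <= r * r
}
fix_seeded <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

# ideal bright disk on dark background (no noise)
ideal_disk_image <- function(size = 256L, r = 80, lo = 40, hi = 200) {
  img <- matrix(lo, size, size)
  c0 <- (size + 1) / 2
  img[fix_disk(size, size, c0, c0, r)] <- hi
  img
}

# 2-level checkerboard
checkerboard_image <- function(size = 32L, lo = 0, hi = 255) {
  (outer(seq_len(size), seq_len(size), "+") %% 2L) * (hi - lo) + lo
}

# two dark blobs on a bright field; mask covers only the blobs
two_blob_fixture <- function(size = 96L) {
  img <- matrix(200, size, size)
  m1 <- fix_disk(size, size, 30, 30, 12)
  m2 <- fix_disk(size, size, 66, 66, 12)
  img[m1 | m2] <- 60
  list(image = img, mask = m1 | m2)
}

# vertical step edge at a known column
step_edge_fixture <- function(size = 64L, at = 32L) {
  img <- matrix(50, size, size)
  img[, (at + 1L):size] <- 200
  list(image = img, edge_col = at + 0.5)
}

# linearly separable 3-class tabular data (ANN sanity oracle)
separable_blobs <- function(n_per_class = 100L, p = 24L, sep = 6, seed = 99L) {
  fix_seeded(seed, {
    centers <- matrix(0, 3, p)
    centers[1, 1] <- -sep; centers[2, 2] <- sep; centers[3, 1] <- sep
    X <- do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(rnorm(n_per_class * p), n_per_class, p), 2, centers[k, ], "+")))
    list(X = X, y = rep(1:3, each = n_per_class))
  })
}

# mildly overlapping 3-class tabular data (GA fitness landscape)
noisy_blobs <- function(n_per_class = 60L, p = 8L, sep = 1.6, seed = 7L) {
  fix_seeded(seed, {
    centers <- matrix(rnorm(3 * p), 3, p) * sep
    X <- do.call(rbind, lapply(1:3, function(k)
      sweep(matrix(rnorm(n_per_class * p), n_per_class, p), 2, centers[k, ], "+")))
    list(X = X, y = rep(1:3, each = n_per_class))
  })
}

# a hand-specified linear softmax "model" usable with predict_grade /
# evaluate_blind: class scores are x %*% W
linear_stub_model <- function(W, b = rep(0, 3)) {
  structure(list(
    genome = default_genome(),
    scaler = list(mean = rep(0, nrow(W)), sd = rep(1, nrow(W))),
    weights = list(W),
    biases = list(b),
    activation = "logistic",
    train_loss_curve = numeric(0),
    input_dim = nrow(W),
    output_dim = 3L
  ), class = "trained_ann")
}

# reference synthetic dataset at experiment scale, built once per session
ref_dataset <- function() memo("ref_dataset",
  generate_dataset(synth_config(), 126L, seed = derive_seed(42L, 1L)))

# full reference pipeline run (seed 42), built once per session
ref_run <- function() memo("ref_run", run_pipeline(pipeline_config()))
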