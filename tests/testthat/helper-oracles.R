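# Independent oracles and small fixtures used across the suite.

# Naive double-loop moving average with truncated renormalised windows.
naive_ma <- function(x, N) {
  n <- length(x)
  vapply(seq_len(n), function(t) {
    w <- max(1, t - N):min(n, t + N)
    mean(x[w])
  }, numeric(1))
}

# Naive modified difference built on the naive moving average.
naive_md <- function(x, N0, N1) {
  s <- naive_ma(x, N1)
  n <- length(x)
  vapply(seq_len(n), function(t)
    s[min(n, t + N0 + N1)] - s[max(1, t - N0 - N1)], numeric(1))
}

# Exhaustive-enumeration Viterbi oracle: argmax over all 2^T paths.
brute_viterbi <- function(symbols, model) {
  T <- length(symbols)
  paths <- as.matrix(expand.grid(rep(list(1:2), T)))
  lp <- apply(paths, 1, function(p) {
    v <- log(model$pi[p[1]]) + log(model$B[p[1], symbols[1]])
    if (T > 1) for (t in 2:T)
      v <- v + log(model$A[p[t - 1], p[t]]) + log(model$B[p[t], symbols[t]])
    v
  })
  c("S1", "S2")[paths[which.max(lp), ]]
}

# Random strictly-positive 2-state/8-symbol model (no ties in practice).
rand_model <- function() {
  A <- matrix(stats::runif(4, 0.05, 1), 2)
  A <- A / rowSums(A)
  B <- matrix(stats::runif(16, 0.05, 1), 2)
  B <- B / rowSums(B)
  pi <- stats::runif(2, 0.05, 1)
  list(A = A, B = B, pi = pi / sum(pi))
}

# Filled-rectangle mask; bounds are 0-based inclusive pixel coordinates.
rect_mask <- function(nr, nc, r0, r1, c0, c1) {
  m <- matrix(0L, nr, nc)
  m[(r0:r1) + 1L, (c0:c1) + 1L] <- 1L
  m
}

# Filled-ellipse mask centred at (row = cy, col = cx), 0-based.
ellipse_mask <- function(nr, nc, cy, cx, ry, rx) {
  X <- matrix(rep(0:(nc - 1), each = nr), nr, nc)
  Y <- matrix(rep(0:(nr - 1), nc), nr, nc)
  matrix(as.integer(((X - cx) / rx)^2 + ((Y - cy) / ry)^2 <= 1), nr, nc)
}

iou <- function(a, b) {
  u <- sum(a != 0 | b != 0)
  if (u == 0) return(1)
  sum(a != 0 & b != 0) / u
}

# Paper-printed worked matrices (the "Mr. ONE" video).
PRINTED_M <- matrix(c(900, 11550, 11550, 148225), 2, byrow = TRUE)
PRINTED_A <- matrix(c(0.07229, 0.92771, 0.07229, 0.92771), 2, byrow = TRUE)
printed_B <- function() {
  B <- matrix(c(0.75, 0, 0.25, 0, 0, 0, 0, 0,
                0.020672, 0.062016, 0.015504, 0, 0,
                0.069767, 0.054264, 0.777778), 2, byrow = TRUE)
  B / rowSums(B)     # renormalise away the 1e-6 printing residue
}

# Compact scene configuration used by scene-based tests.
small_cfg <- function(seed, ...) {
  scene_config(width = 120, height = 90, person_height = 36, seed = seed,
               ...)
}
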