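# Two-state discrete-emission HMM machinery: symbol encoding, supervised
# counting estimators, Viterbi decoding and frame-level evaluation.

STATES <- c("S1", "S2")          # S1 abnormal (falling), S2 normal
SYMBOLS <- paste0("o", 1:8)
ENCODING_VERSION <- "dar-tree-v1"

#' Encode per-frame observation symbols from detected intervals
#'
#' Each feature `F` in `d`, `a`, `r` contributes a binary flag per frame:
#' 1 when the frame lies inside that feature's detected half-width
#' interval `[floor(f1), ceiling(f2)]` *and* the interval's half-width
#' reaches the period-detection threshold `PD(F)`.  The three flags index
#' the leaves of a binary tree, giving eight observable symbols:
#' `o = 1 + 4 (1 - flag_d) + 2 (1 - flag_a) + (1 - flag_r)`, so a frame
#' inside all three fall intervals is `o1` and a frame inside none is
#' `o8`.
#'
#' @param intervals A `fall_analysis` object, or a data frame with
#'   columns `feature` (`"d"`, `"a"`, `"r"`), `f1`, `f2`, `v_hw`.
#' @param thresholds A `period_thresholds` object.
#' @param n_frames Number of frames to encode.
#' @return Integer vector of symbol indices (1..8) with the per-feature
#'   flag matrix attached as attribute `"flags"`.
#' @export
symbolize <- function(intervals, thresholds, n_frames) {
  if (n_frames <= 0) stop("n_frames must be positive")
  stopifnot(inherits(thresholds, "period_thresholds"))
  if (inherits(intervals, "fall_analysis")) {
    rows <- lapply(c("d", "a", "r"), function(f) {
      ev <- intervals$features[[f]]$event
      if (is.null(ev)) return(NULL)
      data.frame(feature = f, f1 = ev$f1, f2 = ev$f2, v_hw = ev$v_hw)
    })
    intervals <- do.call(rbind, rows)
  }
  flags <- matrix(0L, n_frames, 3, dimnames = list(NULL, c("d", "a", "r")))
  if (!is.null(intervals) && nrow(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      f <- intervals$feature[i]
      if (intervals$v_hw[i] < thresholds$pd[[f]]) next
      lo <- max(0L, floor(intervals$f1[i]))
      hi <- min(n_frames - 1L, ceiling(intervals$f2[i]))
      if (hi >= lo) flags[(lo:hi) + 1L, f] <- 1L
    }
  }
  sym <- 1L + 4L * (1L - flags[, "d"]) + 2L * (1L - flags[, "a"]) +
    (1L - flags[, "r"])
  attr(sym, "flags") <- flags
  sym
}

#' Co-occurrence matrix of consecutive state pairs
#'
#' Counts the ordered pairs `(state_t, state_{t+1})` over all consecutive
#' frames: `C11` pairs (S1,S1), `C12` pairs (S1,S2), and so on.
#'
#' @param states Character/factor vector of `"S1"`/`"S2"` labels, length
#'   at least 2.
#' @return A 2x2 integer matrix with dimnames `S1`, `S2`.
#' @export
count_cooccurrences <- function(states) {
  states <- as.character(states)
  n <- length(states)
  if (n < 2) stop("need at least 2 frames to count state pairs")
  if (!all(states %in% STATES)) stop("states must be 'S1' or 'S2'")
  from <- factor(states[-n], levels = STATES)
  to <- factor(states[-1], levels = STATES)
  M <- table(from, to)
  matrix(as.integer(M), 2, 2, dimnames = list(STATES, STATES))
}

#' Transition matrix from co-occurrence counts
#'
#' `a_ij = C_ij / C_i` with `C_i` the row sum.  A state that never occurs
#' (zero row) gets a uniform row with a warning.
#'
#' @param M 2x2 nonnegative count matrix.
#' @return A 2x2 row-stochastic matrix.
#' @export
transition_matrix <- function(M) {
  stopifnot(is.matrix(M), all(dim(M) == 2), all(M >= 0))
  rs <- rowSums(M)
  A <- matrix(0.5, 2, 2, dimnames = list(STATES, STATES))
  for (i in 1:2) {
    if (rs[i] > 0) A[i, ] <- M[i, ] / rs[i]
    else warning("state ", STATES[i],
                 " never observed; using a uniform transition row")
  }
  A
}

#' Emission matrix from aligned state and symbol sequences
#'
#' `b_j(k)` is the fraction of state-`Sj` frames that emitted symbol
#' `o_k`, with optional additive smoothing:
#' `b_j(k) = (n_jk + pseudocount) / (n_j + 8 pseudocount)`.  The default
#' `pseudocount = 0` keeps exact empirical zeros.  A state with no frames
#' (and no smoothing) gets a uniform row with a warning.
#'
#' @param states Character vector of `"S1"`/`"S2"` labels.
#' @param symbols Integer vector of symbol indices (1..8), same length.
#' @param pseudocount Nonnegative smoothing constant.
#' @return A 2x8 row-stochastic matrix.
#' @export
emission_matrix <- function(states, symbols, pseudocount = 0) {
  states <- as.character(states)
  if (length(states) != length(symbols))
    stop("states and symbols must have equal length")
  stopifnot(pseudocount >= 0, all(symbols %in% 1:8),
            all(states %in% STATES))
  B <- matrix(0, 2, 8, dimnames = list(STATES, SYMBOLS))
  for (j in 1:2) {
    nj <- sum(states == STATES[j])
    cnt <- tabulate(symbols[states == STATES[j]], nbins = 8)
    denom <- nj + 8 * pseudocount
    if (denom == 0) {
      warning("state ", STATES[j],
              " never observed; using a uniform emission row")
      B[j, ] <- 1 / 8
    } else {
      B[j, ] <- (cnt + pseudocount) / denom
    }
  }
  B
}

#' Viterbi decoding of a symbol sequence
#'
#' Computes the maximum-probability hidden state path under the model
#' `lambda = (A, B, pi)`, in log space; zero probabilities become `-Inf`
#' and are never smoothed silently.  Ties are broken toward the lower
#' state index (S1).
#'
#' @param symbols Integer vector of symbol indices (1..8).
#' @param model A `fall_hmm` object (or any list with `A`, `B`, `pi`).
#' @return Character vector of `"S1"`/`"S2"` labels.
#' @export
viterbi <- function(symbols, model) {
  A <- model$A; B <- model$B; pi <- model$pi
  n <- length(symbols)
  if (!n) stop("empty symbol sequence")
  stopifnot(all(symbols %in% 1:8))
  dead <- which(B[1, symbols] == 0 & B[2, symbols] == 0)
  if (length(dead))
    stop("symbol o", symbols[dead[1]], " at frame ", dead[1] - 1L,
         " has zero emission probability in both states")
  lA <- log(A); lB <- log(B); lpi <- log(pi)
  delta <- matrix(-Inf, n, 2)
  back <- matrix(1L, n, 2)
  delta[1, ] <- lpi + lB[, symbols[1]]
  for (t in 2:max(2, n)) {
    if (t > n) break
    for (j in 1:2) {
      cand <- delta[t - 1, ] + lA[, j]
      back[t, j] <- which.max(cand)       # first max -> prefers S1 on ties
      delta[t, j] <- cand[back[t, j]] + lB[j, symbols[t]]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) for (t in seq(n - 1, 1)) path[t] <- back[t + 1, path[t + 1]]
  STATES[path]
}

#' Frame-level evaluation of decoded states
#'
#' Counts the four outcomes — detected abnormal (`As1`), undetected
#' abnormal (`As2`), correct normal (`Ns1`), mis-detected normal (`Ns2`)
#' — and reports precision, recall, accuracy, specificity and negative
#' predictive value as percentages.  A zero denominator yields `NaN` with
#' a warning.
#'
#' With `guard > 0`, normal-truth frames within `guard` frames of a true
#' abnormal interval are excluded from the counts when mis-detected
#' ("undecided" frames: borderline false alarms adjacent to a real fall
#' are not penalised).  Off by default.
#'
#' @param predicted,truth Character vectors of `"S1"`/`"S2"` labels,
#'   equal length.
#' @param guard Nonnegative integer guard window (frames).
#' @return An object of class `fall_eval`: the counts and the metrics.
#' @export
evaluate_states <- function(predicted, truth, guard = 0) {
  predicted <- as.character(predicted); truth <- as.character(truth)
  if (!length(truth)) stop("empty input")
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  keep <- rep(TRUE, length(truth))
  if (guard > 0) {
    near <- which(truth == "S1")
    if (length(near)) {
      guard_zone <- unique(unlist(lapply(near, function(i)
        seq(max(1, i - guard), min(length(truth), i + guard)))))
      drop <- intersect(guard_zone,
                        which(truth == "S2" & predicted == "S1"))
      keep[drop] <- FALSE
    }
  }
  p <- predicted[keep]; tr <- truth[keep]
  As1 <- sum(p == "S1" & tr == "S1")
  As2 <- sum(p == "S2" & tr == "S1")
  Ns1 <- sum(p == "S2" & tr == "S2")
  Ns2 <- sum(p == "S1" & tr == "S2")
  pct <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NaN)
    }
    num / den * 100
  }
  structure(list(
    counts = c(As1 = As1, As2 = As2, Ns1 = Ns1, Ns2 = Ns2),
    precision = pct(As1, As1 + Ns2, "precision"),
    recall = pct(As1, As1 + As2, "recall"),
    accuracy = pct(As1 + Ns1, As1 + As2 + Ns1 + Ns2, "accuracy"),
    specificity = pct(Ns1, Ns1 + Ns2, "specificity"),
    npv = pct(Ns1, Ns1 + As2, "NPV"),
    guard = guard
  ), class = "fall_eval")
}

#' @export
print.fall_eval <- function(x, ...) {
  cat("Frame-level evaluation\n")
  cat(sprintf("  As1=%d  As2=%d  Ns1=%d  Ns2=%d%s\n",
              x$counts["As1"], x$counts["As2"], x$counts["Ns1"],
              x$counts["Ns2"],
              if (x$guard > 0) sprintf("  (guard = %d)", x$guard) else ""))
  cat(sprintf(
    "  precision %.2f%%  recall %.2f%%  accuracy %.2f%%  specificity %.2f%%  NPV %.2f%%\n",
    x$precision, x$recall, x$accuracy, x$specificity, x$npv))
  invisible(x)
}
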