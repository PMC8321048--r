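#' Fit the two-state fall-detection hidden Markov model
#'
#' Supervised fit of `lambda = (A, B, pi)` from aligned per-frame state
#' labels and observation symbols: the transition matrix is estimated by
#' counting consecutive state pairs ([count_cooccurrences()] followed by
#' [transition_matrix()]) and the emission matrix by counting symbols
#' within each state ([emission_matrix()]).  No EM is involved; the
#' training labels come from manual (or synthetic ground-truth)
#' annotation.
#'
#' @param states Character vector of `"S1"`/`"S2"` labels, or a list of
#'   such vectors (one per video; transitions are counted within videos
#'   only, emissions pooled).
#' @param symbols Integer vector(s) of symbol indices (1..8) aligned with
#'   `states`.
#' @param pi Initial state probabilities; the method's operating
#'   assumption is `(0.8, 0.2)`.
#' @param pseudocount Additive smoothing for the emission counts; 0 keeps
#'   exact empirical zeros.
#' @return An object of class `fall_hmm` with components `A`, `B`, `pi`,
#'   the co-occurrence matrix `M`, the number of training frames `n`, and
#'   the symbol-encoding version tag.
#' @seealso [predict.fall_hmm()] for Viterbi decoding,
#'   [simulate.fall_hmm()] for sampling, [write_model()] for JSON
#'   serialization.
#' @examples
#' states <- rep(c("S2", "S1", "S2"), c(40, 10, 50))
#' symbols <- ifelse(states == "S1", 1L, 8L)
#' fit <- fall_hmm(states, symbols)
#' coef(fit)$A
#' predict(fit, symbols)[1:5]
#' @export
fall_hmm <- function(states, symbols, pi = c(0.8, 0.2), pseudocount = 0) {
  if (!is.list(states)) states <- list(states)
  if (!is.list(symbols)) symbols <- list(symbols)
  stopifnot(length(states) == length(symbols))
  if (!is.numeric(pi) || length(pi) != 2 || any(pi < 0) ||
      abs(sum(pi) - 1) > 1e-8)
    stop("pi must be two nonnegative numbers summing to 1")
  M <- Reduce(`+`, lapply(states, count_cooccurrences))
  A <- transition_matrix(M)
  B <- emission_matrix(unlist(lapply(states, as.character)),
                       unlist(symbols), pseudocount)
  obj <- new_fall_hmm(A, B, pi)
  obj$M <- M
  obj$n <- sum(lengths(states))
  obj$pseudocount <- pseudocount
  obj$call <- match.call()
  obj
}

new_fall_hmm <- function(A, B, pi, encoding = ENCODING_VERSION) {
  stopifnot(all(dim(A) == c(2, 2)), all(dim(B) == c(2, 8)),
            length(pi) == 2)
  if (any(abs(rowSums(A) - 1) > 1e-9)) stop("A rows must sum to 1")
  if (any(abs(rowSums(B) - 1) > 1e-6)) stop("B rows must sum to 1")
  dimnames(A) <- list(STATES, STATES)
  dimnames(B) <- list(STATES, SYMBOLS)
  structure(list(A = A, B = B, pi = as.numeric(pi), encoding = encoding),
            class = "fall_hmm")
}

#' @export
print.fall_hmm <- function(x, digits = 5, ...) {
  cat("Two-state fall-detection HMM (S1 abnormal, S2 normal)\n")
  if (!is.null(x$n)) cat(sprintf("  fitted on %d frames\n", x$n))
  cat("Transition matrix A:\n")
  print(round(x$A, digits))
  cat("Initial probabilities pi:", format(x$pi), "\n")
  invisible(x)
}

#' @export
summary.fall_hmm <- function(object, ...) {
  structure(list(model = object), class = "summary.fall_hmm")
}

#' @export
print.summary.fall_hmm <- function(x, digits = 5, ...) {
  print(x$model, digits = digits)
  cat("Emission matrix B:\n")
  print(round(x$model$B, digits))
  if (!is.null(x$model$M)) {
    cat("Co-occurrence counts M:\n")
    print(x$model$M)
  }
  cat("Symbol encoding:", x$model$encoding, "\n")
  invisible(x)
}

#' @export
coef.fall_hmm <- function(object, ...) {
  list(A = object$A, B = object$B, pi = object$pi)
}

#' Decode a symbol sequence with a fitted model
#'
#' Runs [viterbi()] on new observations and returns the most probable
#' per-frame state path.
#'
#' @param object A `fall_hmm` object.
#' @param newdata Integer vector of symbol indices (1..8).
#' @param ... Unused.
#' @return Character vector of `"S1"`/`"S2"` labels.
#' @export
predict.fall_hmm <- function(object, newdata, ...) {
  viterbi(newdata, object)
}

#' Simulate state and symbol sequences from a fitted model
#'
#' Samples the initial state from `pi`, transitions from `A` and symbols
#' from `B`.  Follows the [stats::simulate()] seed contract: with `seed`
#' set the result is reproducible and the caller's RNG state is restored.
#'
#' @param object A `fall_hmm` object.
#' @param nsim Number of sequences.
#' @param seed Optional integer seed.
#' @param n Length of each sequence (frames).
#' @param ... Unused.
#' @return A list of `nsim` elements, each a list with character `states`
#'   and integer `symbols`.
#' @export
simulate.fall_hmm <- function(object, nsim = 1, seed = NULL, n = 100, ...) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  replicate(nsim, sample_hmm(object, n), simplify = FALSE)
}
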