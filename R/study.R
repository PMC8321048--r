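#' Jaccard overlap of two frame-index sets
#'
#' @param a,b Integer vectors of frame indices.
#' @return `|a intersect b| / |a union b|`; 1 when both are empty.
#' @export
jaccard_frames <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)
  length(intersect(a, b)) / u
}

#' Run the full synthetic fall-detection study
#'
#' Generates `n_fall` fall scenes and `n_normal` normal scenes with the
#' synthetic generator, runs the complete pipeline on each (silhouette
#' features, moving-average/modified-difference analysis, half-width
#' extraction), learns the period-detection thresholds on half of the
#' scenes, fits the two-state HMM on the same training half (ground-truth
#' states, derived symbols), and evaluates on the held-out half:
#' video-level fall/normal classification, frame-level Viterbi decoding
#' accuracy and the overlap between decoded abnormal frames and the true
#' fall frames.
#'
#' Emissions are smoothed with `pseudocount = 1` so that held-out scenes
#' whose boundary frames produce symbols unseen in training remain
#' decodable; the transition estimates stay raw counts.
#'
#' @param seed Master seed; scene seeds are derived from it.
#' @param n_fall,n_normal Scenes per class (split evenly into
#'   train/test).
#' @param total Scene duration in seconds.
#' @param config A [fall_config()].
#' @return A list with the learned `thresholds`, the fitted `model`, the
#'   per-scene table `scenes`, and the held-out metrics
#'   (`video_accuracy`, `frame_accuracy`, `evaluation`, `mean_jaccard`).
#' @export
synthetic_study <- function(seed = 1, n_fall = 10, n_normal = 10,
                            total = 50, config = fall_config()) {
  n <- n_fall + n_normal
  kind <- rep(c("fall", "normal"), c(n_fall, n_normal))
  widths <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("d", "a", "r")))
  analyses <- vector("list", n)
  truths <- vector("list", n)
  n_frames <- integer(n)
  for (i in seq_len(n)) {
    sseed <- seed * 1000L + i
    sc <- generate_scene(scene_script(kind[i], seed = sseed, total = total),
                         scene_config(seed = sseed))
    feats <- extract_feature_series(sc$masks, config)
    analyses[[i]] <- analyze_video(feats, config)
    widths[i, ] <- video_widths(analyses[[i]])
    truths[[i]] <- sc$states
    n_frames[i] <- sc$n_frames
    rm(sc, feats); gc(FALSE)
  }

  train <- c(seq_len(n_fall %/% 2), n_fall + seq_len(n_normal %/% 2))
  test <- setdiff(seq_len(n), train)

  thr <- learn_period_thresholds(
    data.frame(class = kind[train],
               d = widths[train, "d"], a = widths[train, "a"],
               r = widths[train, "r"]))

  symbols <- lapply(seq_len(n), function(i)
    symbolize(analyses[[i]], thr, n_frames[i]))

  model <- fall_hmm(truths[train], symbols[train],
                    pi = config$initial_probs, pseudocount = 1)

  pred_class <- vapply(test, function(i)
    predict(thr, widths[i, ])$video_class, character(1))
  true_class <- ifelse(kind[test] == "fall", "l1", "l2")
  video_accuracy <- mean(pred_class == true_class)

  decoded <- lapply(test, function(i) predict(model, symbols[[i]]))
  ev <- evaluate_states(unlist(decoded), unlist(truths[test]))
  frame_accuracy <- ev$accuracy / 100

  jac <- vapply(seq_along(test), function(k) {
    i <- test[k]
    if (kind[i] != "fall") return(NA_real_)
    jaccard_frames(which(decoded[[k]] == "S1") - 1L,
                   which(truths[[i]] == "S1") - 1L)
  }, numeric(1))

  list(thresholds = thr, model = model,
       scenes = data.frame(scene = seq_len(n), kind = kind,
                           split = ifelse(seq_len(n) %in% train,
                                          "train", "test"),
                           d = widths[, "d"], a = widths[, "a"],
                           r = widths[, "r"]),
       video_accuracy = video_accuracy,
       frame_accuracy = frame_accuracy,
       evaluation = ev,
       jaccard = jac[!is.na(jac)],
       mean_jaccard = mean(jac, na.rm = TRUE))
}
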