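# Temporal analysis of feature series: centered moving average, modified
# difference, extremum localisation, full width at half maximum, and the
# half-width threshold classifier separating fall from normal videos.

#' Centered moving average
#'
#' `MA(t) = mean(x[t - N .. t + N])`; windows at the series boundary are
#' truncated to the available frames and renormalised by the actual
#' count, so the output has the same length as the input and `N = 0`
#' returns the input unchanged.
#'
#' @param x Numeric series.
#' @param N Half-window (integer, `>= 0`); full window spans `2N + 1`.
#' @return Numeric vector, same length as `x`.
#' @export
moving_average <- function(x, N) {
  n <- length(x)
  if (n == 0) stop("empty series")
  stopifnot(N >= 0, N == round(N))
  if (N == 0) return(as.numeric(x))
  cs <- cumsum(as.numeric(x))
  t <- seq_len(n)
  hi <- pmin(n, t + N)
  lo <- pmax(1, t - N)
  (cs[hi] - c(0, cs)[lo]) / (hi - lo + 1)
}

#' Modified difference
#'
#' A smoothed symmetric derivative: the series is smoothed with a
#' centered moving average of half-window `N1`, and
#' `MD(t) = MA(t + N0 + N1) - MA(t - N0 - N1)` with indices clamped to
#' the series ends.  On a constant series MD is identically zero; abrupt
#' feature changes (falls) produce a dominant extremum whose sign depends
#' on the feature and fall direction.
#'
#' @param x Numeric series of length at least `2 (N0 + N1) + 1`.
#' @param N0,N1 Nonnegative integer offsets; `N1 >= 1` is the smoothing
#'   half-window.
#' @return Numeric vector, same length as `x`.
#' @export
modified_difference <- function(x, N0, N1) {
  stopifnot(N0 >= 0, N1 >= 1, N0 == round(N0), N1 == round(N1))
  n <- length(x)
  if (n < 2 * (N0 + N1) + 1)
    stop("series of length ", n, " too short for N0=", N0, ", N1=", N1,
         " (need at least ", 2 * (N0 + N1) + 1, ")")
  s <- moving_average(x, N1)
  t <- seq_len(n)
  s[pmin(n, t + N0 + N1)] - s[pmax(1, t - N0 - N1)]
}

#' Locate the dominant extremum of a modified-difference series
#'
#' Returns the global maximum (`polarity = "max"`) or global minimum
#' (`polarity = "min"`) of the series.  An identically zero series has no
#' event and returns `NULL`.  Ties are broken toward the earliest frame.
#'
#' @param md Numeric modified-difference series.
#' @param polarity `"max"` or `"min"`.
#' @return A list of class `md_event` with `polarity`, `t_star` (0-based
#'   frame), and `value`, or `NULL`.
#' @export
find_extremum <- function(md, polarity = c("max", "min")) {
  polarity <- match.arg(polarity)
  if (!length(md) || all(md == 0)) return(NULL)
  i <- if (polarity == "max") which.max(md) else which.min(md)
  structure(list(polarity = polarity, t_star = i - 1L, value = md[i]),
            class = "md_event")
}

#' Full width at half maximum of an extremum
#'
#' Walks outward from the extremum to the nearest crossing of half the
#' extremum value on each side, interpolating linearly between frames;
#' `f1` and `f2` are the (real-valued, 0-based) crossing frames and
#' `v_hw = |f1 - f2|` estimates the event duration.  A side with no
#' crossing (series monotone to the boundary) is clamped to the series
#' end with a warning.
#'
#' @param md Numeric modified-difference series.
#' @param event An `md_event` from [find_extremum()].
#' @return The event with `f1`, `f2` and `v_hw` added.
#' @export
half_width <- function(md, event) {
  stopifnot(inherits(event, "md_event"))
  n <- length(md)
  i <- event$t_star + 1L
  h <- event$value / 2
  s0 <- sign(event$value)
  cross <- function(j, k) {
    # crossing of level h between frames j and k (1-based), 0-based result
    if (md[k] == md[j]) return(j - 1)
    (j - 1) + (h - md[j]) / (md[k] - md[j]) * (k - j)
  }
  f1 <- NA_real_
  if (i > 1) {
    for (j in seq(i - 1, 1)) {
      if (sign(md[j] - h) != s0 || md[j] == h) { f1 <- cross(j, j + 1); break }
    }
  }
  if (is.na(f1)) {
    warning("no half-level crossing left of the extremum; clamping to 0")
    f1 <- 0
  }
  f2 <- NA_real_
  if (i < n) {
    for (j in seq(i + 1, n)) {
      if (sign(md[j] - h) != s0 || md[j] == h) { f2 <- cross(j - 1, j); break }
    }
  }
  if (is.na(f2)) {
    warning("no half-level crossing right of the extremum; clamping to ",
            n - 1)
    f2 <- n - 1
  }
  event$f1 <- f1
  event$f2 <- f2
  event$v_hw <- abs(f2 - f1)
  event
}

#' @export
print.md_event <- function(x, ...) {
  cat(sprintf("MD %s at frame %g (value %.4g)", x$polarity, x$t_star,
              x$value))
  if (!is.null(x$v_hw))
    cat(sprintf("; f1 = %.2f, f2 = %.2f, v_hw = %.2f", x$f1, x$f2, x$v_hw))
  cat("\n")
  invisible(x)
}

#' Learn period-detection thresholds from labelled videos
#'
#' For each feature `F` in `d`, `a`, `r`: `alpha1(F)` is the smallest
#' half-width among fall videos, `alpha2(F)` the largest among normal
#' videos, and the decision threshold is the midpoint
#' `PD(F) = (alpha1 + alpha2) / 2`.  A video is classed `l1` (contains a
#' fall) when its half-width is at least `PD`.
#'
#' @param widths Data frame with one row per training video: a `class`
#'   column (`"fall"` or `"normal"`) and numeric half-width columns `d`,
#'   `a`, `r`.
#' @return An object of class `period_thresholds` with named vectors
#'   `alpha1`, `alpha2`, `pd`.
#' @export
learn_period_thresholds <- function(widths) {
  stopifnot(is.data.frame(widths),
            all(c("class", "d", "a", "r") %in% names(widths)))
  if (!any(widths$class == "fall") || !any(widths$class == "normal"))
    stop("need at least one fall-labelled and one normal-labelled video")
  feats <- c("d", "a", "r")
  alpha1 <- vapply(feats, function(f)
    min(widths[[f]][widths$class == "fall"]), numeric(1))
  alpha2 <- vapply(feats, function(f)
    max(widths[[f]][widths$class == "normal"]), numeric(1))
  structure(list(alpha1 = alpha1, alpha2 = alpha2,
                 pd = (alpha1 + alpha2) / 2),
            class = "period_thresholds")
}

#' @export
print.period_thresholds <- function(x, ...) {
  cat("Period-detection thresholds (frames)\n")
  tab <- rbind(alpha1 = x$alpha1, alpha2 = x$alpha2, PD = x$pd)
  print(round(tab, 2))
  invisible(x)
}

#' Classify video half-widths against learned thresholds
#'
#' @param object A `period_thresholds` object.
#' @param widths Named numeric vector (or one-row data frame) of
#'   half-widths for features `d`, `a`, `r`, or a `fall_analysis` object.
#' @param ... Unused.
#' @return A list with `feature_labels` (`"l1"`/`"l2"` per feature) and
#'   `video_class` (majority vote over the three features; `"l1"` means
#'   the video contains a fall).
#' @export
predict.period_thresholds <- function(object, widths, ...) {
  if (inherits(widths, "fall_analysis")) widths <- video_widths(widths)
  if (is.data.frame(widths)) widths <- unlist(widths[1, c("d", "a", "r")])
  feats <- c("d", "a", "r")
  lab <- ifelse(widths[feats] >= object$pd[feats], "l1", "l2")
  names(lab) <- feats
  list(feature_labels = lab,
       video_class = if (sum(lab == "l1") >= 2) "l1" else "l2")
}

#' Analyze a video's feature series for a fall event
#'
#' Runs the moving-average / modified-difference analysis on each of the
#' three features with the feature-specific polarity rules: the point
#' distance `d` drops at a fall (global minimum), the aspect ratio `r`
#' rises (global maximum), and the area `a` may do either depending on
#' fall direction, so both polarities are evaluated and the larger
#' absolute extremum kept.  Each extremum gets its half-width interval
#' `[f1, f2]`.
#'
#' @param features A `fall_features` data frame from
#'   [extract_feature_series()].
#' @param config A [fall_config()]; supplies `N0` and `N1`.
#' @return An object of class `fall_analysis`: per-feature events, the MD
#'   series, and the frame count.
#' @export
analyze_video <- function(features, config = fall_config()) {
  stopifnot(is.data.frame(features))
  ok <- features$valid == 1L
  if (!any(ok)) stop("no valid frames to analyze")
  frames <- features$frame[ok]
  N0 <- config$md_offset0; N1 <- config$md_offset1
  res <- list()
  for (f in c("d", "a", "r")) {
    x <- features[[f]][ok]
    md <- modified_difference(x, N0, N1)
    ev <- if (f == "d") {
      find_extremum(md, "min")
    } else if (f == "r") {
      find_extremum(md, "max")
    } else {
      e1 <- find_extremum(md, "max")
      e2 <- find_extremum(md, "min")
      if (is.null(e1)) e2
      else if (is.null(e2)) e1
      else if (abs(e1$value) >= abs(e2$value)) e1 else e2
    }
    if (!is.null(ev)) {
      ev <- half_width(md, ev)
      # map positions in the valid-frame series back to original frames
      remap <- function(p) stats::approx(seq_along(frames) - 1, frames,
                                         xout = p, rule = 2)$y
      ev$t_star <- remap(ev$t_star)
      ev$f1 <- remap(ev$f1)
      ev$f2 <- remap(ev$f2)
      ev$v_hw <- abs(ev$f2 - ev$f1)
    }
    res[[f]] <- list(event = ev, md = md, frames = frames)
  }
  structure(list(features = res, n_frames = nrow(features),
                 config = config),
            class = "fall_analysis")
}

#' Half-widths of an analyzed video
#'
#' @param analysis A `fall_analysis` object.
#' @return Named numeric vector `c(d=, a=, r=)` of half-widths; features
#'   with no detected extremum get 0.
#' @export
video_widths <- function(analysis) {
  stopifnot(inherits(analysis, "fall_analysis"))
  vapply(c(d = "d", a = "a", r = "r"), function(f) {
    ev <- analysis$features[[f]]$event
    if (is.null(ev)) 0 else ev$v_hw
  }, numeric(1))
}

#' @export
print.fall_analysis <- function(x, ...) {
  cat(sprintf("Fall analysis over %d frames\n", x$n_frames))
  for (f in c("d", "a", "r")) {
    ev <- x$features[[f]]$event
    cat(sprintf("  %s: ", f))
    if (is.null(ev)) cat("no extremum (constant MD)\n") else print(ev)
  }
  invisible(x)
}

#' Plot the modified-difference curves of an analyzed video
#'
#' One panel per feature showing the MD series with the extremum and its
#' half-width interval marked.
#'
#' @param x A `fall_analysis` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fall_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (f in c("d", "a", "r")) {
    el <- x$features[[f]]
    graphics::plot(el$frames, el$md, type = "l", xlab = "frame",
                   ylab = paste0("MD(", f, ")"), ...)
    ev <- el$event
    if (!is.null(ev)) {
      graphics::abline(v = c(ev$f1, ev$f2), lty = 2, col = "grey40")
      graphics::points(ev$t_star, ev$value, pch = 19, col = "red")
      graphics::mtext(sprintf("v_hw = %.1f", ev$v_hw), side = 3,
                      line = 0.2, cex = 0.8)
    }
  }
  invisible(x)
}
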