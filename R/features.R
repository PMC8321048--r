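# Posture/position features of a silhouette mask.  Image coordinates are
# raster: x = column, y = row, y increases downward.  Coordinates are
# 0-based to match frame indexing in all on-disk artifacts.

#' Centroid of a silhouette
#'
#' Mean of the foreground pixel coordinates: `x_c` is the mean column and
#' `y_c` the mean row (0-based raster coordinates, sub-pixel reals).
#'
#' @param mask A 0/1 matrix.
#' @return Named numeric vector `c(x_c, y_c)`, or `NULL` for an empty mask
#'   (invalid-frame signal).
#' @export
centroid <- function(mask) {
  a <- sum(mask != 0)
  if (a == 0) return(NULL)
  rs <- rowSums(mask != 0)
  cs <- colSums(mask != 0)
  c(x_c = sum((seq_len(ncol(mask)) - 1) * cs) / a,
    y_c = sum((seq_len(nrow(mask)) - 1) * rs) / a)
}

#' Virtual grounding point of a silhouette
#'
#' The point where the vertical line through the centroid meets the
#' ground side of the object: `x_vgp = x_c` and `y_vgp` is the bottom-most
#' foreground row of the mask's bounding box.  Its vertical distance from
#' the centroid (the point distance `d`) is large for an upright posture
#' and small for a lying one.
#'
#' @param mask A 0/1 matrix.
#' @return Named numeric vector `c(x_vgp, y_vgp)`, or `NULL` for an empty
#'   mask.
#' @export
virtual_grounding_point <- function(mask) {
  ctr <- centroid(mask)
  if (is.null(ctr)) return(NULL)
  rows <- which(rowSums(mask != 0) > 0)
  c(x_vgp = unname(ctr["x_c"]), y_vgp = max(rows) - 1)
}

#' Per-frame silhouette features
#'
#' Computes the point distance `d = |y_vgp - y_c|`, the area `a` (count of
#' foreground pixels), the tight bounding-box width `w` and height `h`,
#' and the aspect ratio `r = w / h`.  Standing gives `r < 1` and large
#' `d`; lying gives `r > 1` and small `d`.
#'
#' @param mask A 0/1 matrix.
#' @return A one-row data frame with columns `x_c`, `y_c`, `x_vgp`,
#'   `y_vgp`, `d`, `a`, `r`, `w`, `h`, `valid`; for an empty mask all
#'   features are `NA` and `valid = 0`.
#' @export
frame_features <- function(mask) {
  ctr <- centroid(mask)
  if (is.null(ctr)) {
    return(data.frame(x_c = NA_real_, y_c = NA_real_, x_vgp = NA_real_,
                      y_vgp = NA_real_, d = NA_real_, a = NA_real_,
                      r = NA_real_, w = NA_real_, h = NA_real_,
                      valid = 0L))
  }
  rows <- which(rowSums(mask != 0) > 0)
  cols <- which(colSums(mask != 0) > 0)
  w <- max(cols) - min(cols) + 1
  h <- max(rows) - min(rows) + 1
  y_vgp <- max(rows) - 1
  data.frame(x_c = ctr[["x_c"]], y_c = ctr[["y_c"]],
             x_vgp = ctr[["x_c"]], y_vgp = y_vgp,
             d = abs(y_vgp - ctr[["y_c"]]),
             a = sum(mask != 0), r = w / h, w = w, h = h, valid = 1L)
}

#' Extract the feature series of a mask sequence
#'
#' Applies [frame_features()] to every mask (after reducing each to its
#' largest connected component) and bridges short runs of invalid frames
#' (empty masks) by linear interpolation when the gap is at most
#' `interpolation_max_gap`; leading/trailing invalid runs within the gap
#' limit are filled from the nearest valid frame.  Longer gaps stay
#' invalid and are excluded downstream.
#'
#' @param masks List of 0/1 matrices.
#' @param config A [fall_config()].
#' @param clean If `TRUE` (default), keep only each mask's largest
#'   component before measuring.
#' @return A data frame of class `fall_features`, one row per frame, with
#'   a 0-based `frame` column.
#' @export
extract_feature_series <- function(masks, config = fall_config(),
                                   clean = TRUE) {
  if (!length(masks)) stop("empty mask sequence")
  rows <- lapply(masks, function(m) {
    if (clean && sum(m != 0) > 0) m <- largest_component(m)
    frame_features(m)
  })
  feats <- do.call(rbind, rows)
  feats <- cbind(frame = seq_len(nrow(feats)) - 1L, feats)
  if (all(feats$valid == 0L)) stop("all frames invalid (empty masks)")

  num_cols <- c("x_c", "y_c", "x_vgp", "y_vgp", "d", "a", "r", "w", "h")
  valid <- feats$valid == 1L
  gaps <- rle(!valid)
  pos <- cumsum(c(1L, gaps$lengths))
  for (g in which(gaps$values)) {
    len <- gaps$lengths[g]
    if (len > config$interpolation_max_gap) next
    i0 <- pos[g]; i1 <- pos[g] + len - 1L
    left <- i0 - 1L; right <- i1 + 1L
    for (col in num_cols) {
      if (left >= 1L && right <= nrow(feats)) {
        feats[[col]][i0:i1] <- feats[[col]][left] +
          (seq_len(len) / (len + 1L)) *
          (feats[[col]][right] - feats[[col]][left])
      } else if (left >= 1L) {
        feats[[col]][i0:i1] <- feats[[col]][left]
      } else {
        feats[[col]][i0:i1] <- feats[[col]][right]
      }
    }
    feats$valid[i0:i1] <- 1L
  }
  class(feats) <- c("fall_features", "data.frame")
  feats
}
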