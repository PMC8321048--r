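#' Read an ordered sequence of binary silhouette masks
#'
#' Masks are PNG images in one directory with zero-padded numeric
#' filenames; they are read in filename order.  Any nonzero pixel becomes
#' foreground (1).  All frames must share one resolution.
#'
#' @param path Directory containing `.png` mask files.
#' @return A list of 0/1 integer matrices (rows x cols).
#' @export
read_mask_sequence <- function(path) {
  if (!dir.exists(path)) stop("mask directory not found: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG masks found in ", path)
  masks <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    m <- matrix(0L, nrow(img), ncol(img))
    m[img != 0] <- 1L
    m
  })
  dims <- vapply(masks, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("masks have mixed resolutions in ", path)
  masks
}

#' Write a sequence of binary masks as PNG files
#'
#' @param masks List of 0/1 matrices.
#' @param path Output directory (created if missing).
#' @param prefix Filename prefix.
#' @return The directory path, invisibly.
#' @export
write_mask_sequence <- function(masks, path, prefix = "mask") {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  width <- max(6L, nchar(length(masks)))
  for (i in seq_along(masks)) {
    f <- file.path(path, sprintf("%s_%0*d.png", prefix, width, i - 1L))
    png::writePNG(matrix(as.numeric(masks[[i]] != 0),
                         nrow(masks[[i]]), ncol(masks[[i]])), f)
  }
  invisible(path)
}

#' Read a sequence of grayscale frames
#'
#' Frames are PNG images read in filename order and converted to grayscale
#' matrices with intensities in `[0, 1]` (colour images are averaged over
#' channels).
#'
#' @param path Directory containing `.png` frames.
#' @return A list of numeric matrices in `[0, 1]`.
#' @export
read_frame_sequence <- function(path) {
  if (!dir.exists(path)) stop("frame directory not found: ", path)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop("no PNG frames found in ", path)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3L) {
      nc <- min(3L, dim(img)[3])
      img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
    }
    img
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames have mixed resolutions in ", path)
  frames
}

#' Write grayscale frames as PNG files
#'
#' @param frames List of numeric matrices in `[0, 1]`.
#' @inheritParams write_mask_sequence
#' @return The directory path, invisibly.
#' @export
write_frame_sequence <- function(frames, path, prefix = "frame") {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  width <- max(6L, nchar(length(frames)))
  for (i in seq_along(frames)) {
    f <- file.path(path, sprintf("%s_%0*d.png", prefix, width, i - 1L))
    png::writePNG(matrix(pmin(1, pmax(0, frames[[i]])),
                         nrow(frames[[i]]), ncol(frames[[i]])), f)
  }
  invisible(path)
}

#' Write and read the per-frame feature table
#'
#' One CSV row per frame with columns `frame` (0-based), `x_c`, `y_c`,
#' `x_vgp`, `y_vgp`, `d`, `a`, `r` and `valid`.  Invalid frames keep empty
#' feature cells and `valid = 0`.
#'
#' @param features A `fall_features` data frame from
#'   [extract_feature_series()].
#' @param path CSV file path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a `fall_features` data frame.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("frame", "x_c", "y_c", "x_vgp", "y_vgp", "d", "a", "r", "valid")
  if (!all(cols %in% names(features)))
    stop("feature table must have columns: ", paste(cols, collapse = ", "))
  n <- unique(vapply(features[cols], length, integer(1)))
  if (length(n) != 1L) stop("feature series have mismatched lengths")
  out <- features[cols]
  bad <- out$valid == 0
  for (col in setdiff(cols, c("frame", "valid"))) out[[col]][bad] <- NA_real_
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  x <- utils::read.csv(path)
  x$valid <- as.integer(x$valid)
  class(x) <- c("fall_features", "data.frame")
  x
}

#' Write and read per-frame state labels
#'
#' Two-column CSV `frame,state` with 0-based contiguous frame indices and
#' states in `{S1, S2}` (S1 = abnormal/falling, S2 = normal).
#'
#' @param states Character or factor vector of `"S1"`/`"S2"` labels.
#' @param path CSV file path.
#' @return `write_labels` returns `path` invisibly; `read_labels` returns
#'   a character vector of labels (one per frame, frame 0 first).
#' @export
write_labels <- function(states, path) {
  states <- as.character(states)
  if (!all(states %in% c("S1", "S2")))
    stop("states must be 'S1' or 'S2'")
  utils::write.csv(
    data.frame(frame = seq_along(states) - 1L, state = states),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path)
  x <- utils::read.csv(path, colClasses = c("integer", "character"))
  if (!identical(names(x), c("frame", "state")))
    stop("label file must have columns frame,state")
  if (!all(x$state %in% c("S1", "S2")))
    stop("states must be 'S1' or 'S2'")
  if (!identical(x$frame, seq_len(nrow(x)) - 1L))
    stop("frame indices must be contiguous from 0")
  x$state
}

#' Serialize a fitted hidden Markov model to JSON
#'
#' Stores the transition matrix `A`, emission matrix `B`, initial vector
#' `pi`, the state and symbol name lists, and the symbol-encoding version
#' tag.
#'
#' @param model A `fall_hmm` object.
#' @param path JSON file path.
#' @return `write_model` returns `path` invisibly; `read_model` returns a
#'   `fall_hmm` object.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "fall_hmm"))
  obj <- list(
    states = rownames(model$A),
    symbols = colnames(model$B),
    encoding = model$encoding,
    A = unname(apply(model$A, 1, as.numeric, simplify = FALSE)),
    B = unname(apply(model$B, 1, as.numeric, simplify = FALSE)),
    pi = as.numeric(model$pi)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_rows <- function(x, ncol) {
    if (is.matrix(x)) x else matrix(unlist(x), nrow = 2, byrow = TRUE)
  }
  A <- as_rows(obj$A, 2)
  B <- as_rows(obj$B, 8)
  dimnames(A) <- list(obj$states, obj$states)
  dimnames(B) <- list(obj$states, obj$symbols)
  new_fall_hmm(A = A, B = B, pi = as.numeric(obj$pi),
               encoding = obj$encoding)
}

#' Serialize period-detection thresholds to JSON
#'
#' @param thresholds A `period_thresholds` object.
#' @param path JSON file path.
#' @return `write_thresholds` returns `path` invisibly;
#'   `read_thresholds` returns a `period_thresholds` object.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "period_thresholds"))
  obj <- lapply(unclass(thresholds), as.list)   # keep the feature names
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("thresholds file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- c("d", "a", "r")
  structure(list(alpha1 = unlist(obj$alpha1)[feats],
                 alpha2 = unlist(obj$alpha2)[feats],
                 pd = unlist(obj$pd)[feats]),
            class = "period_thresholds")
}
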