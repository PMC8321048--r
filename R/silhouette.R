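#' Per-pixel mixture-of-Gaussians background model
#'
#' Creates an empty online background model with `K` Gaussian components
#' per pixel.  The model is fed frames one at a time with
#' [update_background()]; pixels whose intensity is not explained by the
#' background components are flagged foreground.  Intensities are on the
#' `[0, 1]` scale used by [read_frame_sequence()].
#'
#' @param nrow,ncol Frame dimensions.
#' @param config A [fall_config()]; supplies `mog_components`,
#'   `mog_learning_rate`, `mog_match_sd` and `mog_background_fraction`.
#' @return An object of class `mog_model`.
#' @export
background_model <- function(nrow, ncol, config = fall_config()) {
  K <- as.integer(config$mog_components)
  npix <- nrow * ncol
  model <- list(
    nrow = nrow, ncol = ncol, K = K,
    alpha = config$mog_learning_rate,
    match_sd = config$mog_match_sd,
    bg_fraction = config$mog_background_fraction,
    init_var = 0.0225,                       # sd 0.15 on [0,1] intensities
    weight = matrix(0, npix, K),
    mean = matrix(0, npix, K),
    var = matrix(0.0225, npix, K),
    initialized = FALSE
  )
  class(model) <- "mog_model"
  model
}

#' Online background update and raw foreground mask
#'
#' One step of the frame-by-frame mixture update: each pixel's intensity
#' is matched against its components (within `mog_match_sd` standard
#' deviations); a matched component adapts its weight, mean and variance,
#' an unmatched pixel replaces its weakest component.  Components are
#' ranked by weight/sd and the top-ranked set holding at least
#' `mog_background_fraction` of the weight is the background; a pixel
#' matching no background component is raw foreground.
#'
#' The very first frame initialises the model and returns an all-background
#' mask (cold-start contract: no history, nothing can be foreground).
#'
#' @param model A `mog_model`.
#' @param frame Numeric matrix in `[0, 1]`, same shape as the model.
#' @return A list with elements `model` (updated) and `mask` (0/1 raw
#'   foreground matrix).
#' @export
update_background <- function(model, frame) {
  stopifnot(inherits(model, "mog_model"))
  if (nrow(frame) != model$nrow || ncol(frame) != model$ncol)
    stop("frame shape does not match background model")
  npix <- model$nrow * model$ncol
  K <- model$K
  I <- as.numeric(frame)

  if (!model$initialized) {
    model$weight[] <- 0
    model$weight[, 1] <- 1
    model$mean[, 1] <- I
    model$var[] <- model$init_var
    model$initialized <- TRUE
    return(list(model = model,
                mask = matrix(0L, model$nrow, model$ncol)))
  }

  sdv <- sqrt(model$var)
  dist <- abs(model$mean - I) / sdv              # npix x K
  matched <- dist < model$match_sd & model$weight > 0
  dist[!matched] <- Inf
  best <- max.col(-dist, ties.method = "first")  # per-pixel closest match
  has_match <- is.finite(dist[cbind(seq_len(npix), best)])

  a <- model$alpha
  model$weight <- (1 - a) * model$weight
  hit <- cbind(which(has_match), best[has_match])
  model$weight[hit] <- model$weight[hit] + a
  delta <- I[hit[, 1]] - model$mean[hit]
  model$mean[hit] <- model$mean[hit] + a * delta
  model$var[hit] <- pmax(1e-6,
    (1 - a) * model$var[hit] + a * (I[hit[, 1]] - model$mean[hit])^2)

  # unmatched pixels: replace the weakest component
  if (any(!has_match)) {
    miss <- which(!has_match)
    weakest <- max.col(-model$weight[miss, , drop = FALSE],
                       ties.method = "first")
    rep_idx <- cbind(miss, weakest)
    model$weight[rep_idx] <- a
    model$mean[rep_idx] <- I[miss]
    model$var[rep_idx] <- model$init_var
  }
  model$weight <- model$weight / rowSums(model$weight)

  # background set: top-ranked (by weight/sd) components covering
  # bg_fraction of the weight
  ratio <- model$weight / sqrt(model$var)
  cumw_before <- matrix(0, npix, K)
  for (k in seq_len(K)) {
    for (j in seq_len(K)) {
      if (j == k) next
      beats <- ratio[, j] > ratio[, k] | (ratio[, j] == ratio[, k] & j < k)
      cumw_before[, k] <- cumw_before[, k] + model$weight[, j] * beats
    }
  }
  is_bg <- cumw_before <= model$bg_fraction     # prefix not yet saturated

  fg <- !has_match
  mb <- cbind(seq_len(npix), best)
  fg[has_match] <- !is_bg[mb][has_match]
  list(model = model,
       mask = matrix(as.integer(fg), model$nrow, model$ncol))
}

#' Segment a frame sequence into silhouette masks
#'
#' Full object-detection chain: online mixture-of-Gaussians background
#' subtraction, graph-cut refinement seeded from the stored raw mask
#' (seeds refreshed every `reseed_interval` frames), morphological
#' opening/closing, and largest-component selection.
#'
#' @param frames List of grayscale matrices in `[0, 1]`.
#' @param config A [fall_config()].
#' @return A list of 0/1 silhouette masks, one per frame.
#' @export
segment_sequence <- function(frames, config = fall_config()) {
  if (!length(frames)) stop("empty frame sequence")
  model <- background_model(nrow(frames[[1]]), ncol(frames[[1]]), config)
  seeds <- NULL
  app <- NULL
  out <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    st <- update_background(model, frames[[i]])
    model <- st$model
    raw <- st$mask
    fresh <- FALSE
    if ((is.null(seeds) || (i - 1L) %% config$reseed_interval == 0L) &&
        sum(raw) > 0) {
      seeds <- raw
      app <- fit_appearance(frames[[i]], raw)
      fresh <- TRUE
    }
    m <- if (is.null(seeds) || sum(seeds) == 0) raw
         else refine_mask(frames[[i]], raw, config, seeds = seeds,
                          appearance = app, use_cores = fresh)
    if (config$morph_radius > 0) {
      m <- close_mask(open_mask(m, config$morph_radius), config$morph_radius)
    }
    out[[i]] <- largest_component(m)
  }
  out
}
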