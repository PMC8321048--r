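#' Pipeline run configuration
#'
#' Collects every tunable constant of the pipeline in one object.  The
#' defaults are the operating point of the method: a 25 fps camera, a
#' centered moving-average half-window of 51 frames (about two seconds of
#' video on either side), modified-difference offsets `N0 = 0`, `N1 = 51`,
#' graph-cut seeds refreshed from the background model every 100th frame,
#' and initial state probabilities (0.8, 0.2) for the abnormal/normal
#' hidden states.
#'
#' @param fps Frames per second of the input video. Must be positive.
#' @param ma_window_half Half-window `N` of the centered moving average;
#'   the full window spans `2N + 1` frames.
#' @param md_offset0,md_offset1 Offsets `N0` and `N1` of the modified
#'   difference: `MD(t) = MA(t + N0 + N1) - MA(t - N0 - N1)` where `MA`
#'   uses half-window `N1`.
#' @param reseed_interval Frames between refreshes of the graph-cut seed
#'   mask from the raw background-subtraction mask.
#' @param initial_probs Length-2 nonnegative vector summing to 1: initial
#'   probabilities of states S1 (abnormal) and S2 (normal).
#' @param interpolation_max_gap Longest run of invalid (empty-mask) frames
#'   that feature extraction will bridge by linear interpolation.
#' @param pseudocount Additive smoothing applied to emission counts when
#'   fitting the hidden Markov model; 0 keeps exact empirical zeros.
#' @param mog_components Number of Gaussian components per pixel in the
#'   background model.
#' @param mog_learning_rate Online update rate of the background model.
#' @param mog_match_sd Match threshold in standard deviations.
#' @param mog_background_fraction Minimum cumulative weight of the
#'   components regarded as background.
#' @param gc_lambda Contrast-term weight of the graph-cut energy.
#' @param gc_seed_erosion Radius (in 3x3 erosion passes) used to obtain
#'   hard foreground/background seed cores.
#' @param morph_radius Passes of 3x3 morphological opening/closing applied
#'   to the refined mask before largest-component selection; 0 disables.
#'
#' @return An object of class `fall_config`, a validated named list.
#' @examples
#' cfg <- fall_config()
#' cfg$ma_window_half
#' @export
fall_config <- function(fps = 25,
                        ma_window_half = 51,
                        md_offset0 = 0,
                        md_offset1 = 51,
                        reseed_interval = 100,
                        initial_probs = c(0.8, 0.2),
                        interpolation_max_gap = 12,
                        pseudocount = 0,
                        mog_components = 3,
                        mog_learning_rate = 0.02,
                        mog_match_sd = 2.5,
                        mog_background_fraction = 0.7,
                        gc_lambda = 10,
                        gc_seed_erosion = 1,
                        morph_radius = 1) {
  cfg <- list(
    fps = fps,
    ma_window_half = ma_window_half,
    md_offset0 = md_offset0,
    md_offset1 = md_offset1,
    reseed_interval = reseed_interval,
    initial_probs = initial_probs,
    interpolation_max_gap = interpolation_max_gap,
    pseudocount = pseudocount,
    mog_components = mog_components,
    mog_learning_rate = mog_learning_rate,
    mog_match_sd = mog_match_sd,
    mog_background_fraction = mog_background_fraction,
    gc_lambda = gc_lambda,
    gc_seed_erosion = gc_seed_erosion,
    morph_radius = morph_radius
  )
  class(cfg) <- "fall_config"
  validate_config(cfg)
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$fps) || cfg$fps <= 0) stop("fps must be a positive number")
  if (!num1(cfg$ma_window_half) || cfg$ma_window_half < 1 ||
      cfg$ma_window_half != round(cfg$ma_window_half))
    stop("ma_window_half must be an integer >= 1")
  if (!num1(cfg$md_offset0) || cfg$md_offset0 < 0 ||
      cfg$md_offset0 != round(cfg$md_offset0))
    stop("md_offset0 (N0) must be an integer >= 0")
  if (!num1(cfg$md_offset1) || cfg$md_offset1 < 1 ||
      cfg$md_offset1 != round(cfg$md_offset1))
    stop("md_offset1 (N1) must be an integer >= 1")
  if (!num1(cfg$reseed_interval) || cfg$reseed_interval < 1)
    stop("reseed_interval must be >= 1")
  p <- cfg$initial_probs
  if (!is.numeric(p) || length(p) != 2L || any(p < 0) ||
      abs(sum(p) - 1) > 1e-8)
    stop("initial_probs must be two nonnegative numbers summing to 1")
  if (!num1(cfg$interpolation_max_gap) || cfg$interpolation_max_gap < 0)
    stop("interpolation_max_gap must be >= 0")
  if (!num1(cfg$pseudocount) || cfg$pseudocount < 0)
    stop("pseudocount must be nonnegative")
  if (!num1(cfg$mog_components) || cfg$mog_components < 1)
    stop("mog_components must be >= 1")
  if (!num1(cfg$mog_learning_rate) || cfg$mog_learning_rate <= 0 ||
      cfg$mog_learning_rate > 1)
    stop("mog_learning_rate must be in (0, 1]")
  cfg
}

#' Read or write a run configuration
#'
#' Configurations are stored as a single JSON or YAML document; the file
#' extension (`.json`, `.yaml`, `.yml`) selects the format.  Fields absent
#' from the file keep their [fall_config()] defaults; unknown fields are an
#' error.
#'
#' @param path File to read from or write to.
#' @param cfg A `fall_config` object.
#' @return `read_config` returns a validated `fall_config`;
#'   `write_config` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml  = yaml::read_yaml(path),
    stop("unsupported config format: .", ext)
  )
  known <- names(formals(fall_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(fall_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(cfg)
  switch(ext,
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA),
    yaml = ,
    yml  = yaml::write_yaml(x, path),
    stop("unsupported config format: .", ext)
  )
  invisible(path)
}

#' @export
print.fall_config <- function(x, ...) {
  cat("Fall-detection run configuration\n")
  cat(sprintf("  fps: %g   MA half-window: %d   MD offsets: N0=%d N1=%d\n",
              x$fps, x$ma_window_half, x$md_offset0, x$md_offset1))
  cat(sprintf("  reseed interval: %g frames   initial probs: (%.2f, %.2f)\n",
              x$reseed_interval, x$initial_probs[1], x$initial_probs[2]))
  cat(sprintf("  interpolation max gap: %g   emission pseudocount: %g\n",
              x$interpolation_max_gap, x$pseudocount))
  invisible(x)
}
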