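# Synthetic labelled scenes: a single actor rendered as a filled ellipse
# whose bounding box morphs between posture keyframes, emulating scripted
# walk/sit/lie/fall sequences captured at 25 fps, 320 x 240 — the study
# conditions of simulated fall-detection corpora.  Ground-truth states
# (S1 during fall actions, S2 otherwise) come with every scene.

ACTIONS <- c("walk", "stand", "sit", "lie", "sit_to_lie", "lie_to_sit",
             "sit_to_stand", "walk_to_sit", "fall_sideways",
             "fall_forward", "fall_backward")

#' Build an action script
#'
#' An ordered list of (action, duration) pairs drawn from the observable
#' action vocabulary: falling, lying, lying to sitting, sitting to
#' standing, walking, walking to sitting, sitting, sitting to lying,
#' plus standing.  Fall actions must last at most 1.5 s (a fall is, by
#' definition, abrupt).
#'
#' @param actions Character vector of action names.
#' @param durations Positive durations in seconds, same length.
#' @return A data frame of class `action_script`.
#' @export
action_script <- function(actions, durations) {
  stopifnot(length(actions) == length(durations), length(actions) > 0)
  bad <- setdiff(actions, ACTIONS)
  if (length(bad)) stop("unknown actions: ", paste(bad, collapse = ", "))
  if (any(durations <= 0)) stop("durations must be positive")
  falls <- startsWith(actions, "fall")
  if (any(durations[falls] > 1.5))
    stop("fall actions must last at most 1.5 s")
  structure(data.frame(action = actions, duration = durations),
            class = c("action_script", "data.frame"))
}

#' Scene configuration for the synthetic generator
#'
#' Defaults emulate the target corpus: 320 x 240 frames at 25 fps with a
#' single actor about 90 px tall.  One seed fixes every source of
#' randomness in the scene (start position, walking speed, gait phase,
#' pixel noise).
#'
#' @param width,height Frame size in pixels.
#' @param fps Frames per second.
#' @param person_height Standing height of the actor in pixels.
#' @param person_width Standing width; defaults to a third of the height.
#' @param floor Row (0-based) of the ground line the actor stands on.
#' @param noise_sigma Gaussian pixel noise of the grayscale rendering, in
#'   8-bit gray levels.
#' @param walk_speed Nominal walking speed in px/s (jittered per seed).
#' @param bob_amplitude Relative gait oscillation of the body height.
#' @param bob_freq Gait frequency in Hz.
#' @param seed Integer seed.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 320, height = 240, fps = 25,
                         person_height = 90, person_width = NULL,
                         floor = NULL, noise_sigma = 5,
                         walk_speed = 40, bob_amplitude = 0.02,
                         bob_freq = 2, seed = 1) {
  if (is.null(person_width)) person_width <- person_height / 3
  if (is.null(floor)) floor <- height - 11
  cfg <- list(width = width, height = height, fps = fps,
              person_height = person_height, person_width = person_width,
              floor = floor, noise_sigma = noise_sigma,
              walk_speed = walk_speed, bob_amplitude = bob_amplitude,
              bob_freq = bob_freq, seed = as.integer(seed))
  if (person_height >= height || person_width >= width)
    stop("person does not fit in the frame")
  class(cfg) <- "scene_config"
  cfg
}

# posture keyframes as ellipse half-axes (rx, ry) and an area scale
posture_params <- function(cfg) {
  W <- cfg$person_width; H <- cfg$person_height
  list(stand = c(rx = W / 2, ry = H / 2),
       sit = c(rx = 0.7 * W, ry = 0.275 * H),
       lie = c(rx = H / 2, ry = W / 2))
}

#' Generate a synthetic labelled scene
#'
#' Renders the scripted actor as per-frame binary silhouette masks
#' (optionally also noisy grayscale frames), with per-frame ground-truth
#' states and the true fall intervals.  Transitions (`sit_to_lie`,
#' `fall_*`, ...) interpolate the ellipse parameters linearly over the
#' action's duration; fall directions differ in their area profile
#' (a forward fall spreads the silhouette, area up; sideways and
#' backward falls foreshorten it, area down), so the area feature
#' exercises both extremum polarities.  Walking adds a small gait
#' oscillation and reverses at the frame margins; the actor never leaves
#' the frame (a configuration that would force it to is an error).
#'
#' @param script An [action_script()].
#' @param config A [scene_config()].
#' @param render `"mask"` (default) or `"gray"` to also produce noisy
#'   grayscale frames.
#' @return A list with `masks` (list of 0/1 matrices), `frames` (list of
#'   grayscale matrices or `NULL`), `states` (character vector,
#'   `"S1"`/`"S2"`), `fall_intervals` (data frame `start`, `end`,
#'   0-based inclusive) and `n_frames`.
#' @export
generate_scene <- function(script, config = scene_config(),
                           render = c("mask", "gray")) {
  render <- match.arg(render)
  stopifnot(inherits(script, "action_script"))
  cfg <- config
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(cfg$seed)

  pp <- posture_params(cfg)
  nf_action <- pmax(1L, as.integer(round(script$duration * cfg$fps)))
  n <- sum(nf_action)

  speed <- cfg$walk_speed * stats::runif(1, 0.75, 1.25) / cfg$fps
  dir <- sample(c(-1, 1), 1)
  phase <- stats::runif(1, 0, 2 * pi)
  margin <- max(pp$stand["rx"], pp$lie["rx"]) + 2
  if (2 * margin >= cfg$width - 1)
    stop("person leaves the frame; shrink the person or widen the frame")
  cx <- stats::runif(1, margin, cfg$width - 1 - margin)

  rx <- numeric(n); ry <- numeric(n); xs <- numeric(n)
  state <- rep("S2", n)
  cur <- pp$stand
  scale <- 1                       # carried area scale (sprawl after fall)
  t0 <- 0L
  for (k in seq_len(nrow(script))) {
    act <- script$action[k]
    nf <- nf_action[k]
    idx <- t0 + seq_len(nf)
    target <- switch(act,
      walk = , stand = pp$stand,
      sit = , walk_to_sit = pp$sit,
      lie = , sit_to_lie = pp$lie * sqrt(scale),
      lie_to_sit = pp$sit,
      sit_to_stand = pp$stand,
      fall_sideways = pp$lie * sqrt(0.8),
      fall_forward = pp$lie * sqrt(1.25),
      fall_backward = pp$lie * sqrt(0.85))
    transition <- act %in% c("sit_to_lie", "lie_to_sit", "sit_to_stand",
                             "walk_to_sit", "fall_sideways",
                             "fall_forward", "fall_backward")
    if (transition) {
      u <- seq_len(nf) / nf
      rx[idx] <- cur["rx"] + u * (target["rx"] - cur["rx"])
      ry[idx] <- cur["ry"] + u * (target["ry"] - cur["ry"])
    } else {
      rx[idx] <- target["rx"]
      ry[idx] <- target["ry"]
    }
    if (startsWith(act, "fall")) {
      state[idx] <- "S1"
      scale <- switch(act, fall_sideways = 0.8, fall_forward = 1.25,
                      fall_backward = 0.85)
    }
    if (act == "walk") {
      tt <- (idx - 1) / cfg$fps
      bob <- 1 + cfg$bob_amplitude * sin(2 * pi * cfg$bob_freq * tt + phase)
      ry[idx] <- ry[idx] * bob
      for (i in idx) {
        nxt <- cx + dir * speed
        if (nxt < margin || nxt > cfg$width - 1 - margin) dir <- -dir
        cx <- cx + dir * speed
        xs[i] <- cx
      }
    } else {
      xs[idx] <- cx
    }
    cur <- c(rx = rx[t0 + nf], ry = ry[t0 + nf])
    t0 <- t0 + nf
  }
  cy <- cfg$floor - ry
  if (any(xs - rx < 0) || any(xs + rx > cfg$width - 1) ||
      any(cy - ry < 0) || any(cy + ry > cfg$height - 1))
    stop("person leaves the frame; shrink the person or the walk range")

  X <- matrix(rep(0:(cfg$width - 1), each = cfg$height),
              cfg$height, cfg$width)
  Y <- matrix(rep(0:(cfg$height - 1), cfg$width), cfg$height, cfg$width)
  bgtex <- 0.55 + 0.08 * sin(2 * pi * X / 64) + 0.05 * sin(2 * pi * Y / 48)

  masks <- vector("list", n)
  frames <- if (render == "gray") vector("list", n) else NULL
  for (i in seq_len(n)) {
    m <- ((X - xs[i]) / rx[i])^2 + ((Y - cy[i]) / ry[i])^2 <= 1
    masks[[i]] <- matrix(as.integer(m), cfg$height, cfg$width)
    if (render == "gray") {
      f <- bgtex
      f[m] <- 0.15
      if (cfg$noise_sigma > 0)
        f <- f + matrix(stats::rnorm(length(f), 0, cfg$noise_sigma / 255),
                        cfg$height, cfg$width)
      frames[[i]] <- matrix(pmin(1, pmax(0, f)), cfg$height, cfg$width)
    }
  }

  runs <- rle(state == "S1")
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  fi <- data.frame(start = starts[runs$values] - 1L,
                   end = ends[runs$values] - 1L)
  list(masks = masks, frames = frames, states = state,
       fall_intervals = fi, n_frames = n)
}

#' Randomized study scripts
#'
#' Draws a scene script of the kind used throughout the synthetic study:
#' fall scenes walk about, then fall (random direction) and lie still;
#' normal scenes only walk and stand.  Durations are jittered per seed;
#' every scene lasts 50 s, long enough for the two-second smoothing
#' windows of the temporal analysis.
#'
#' @param kind `"fall"` or `"normal"`.
#' @param seed Integer seed.
#' @param total Total scene duration in seconds.
#' @return An [action_script()].
#' @export
scene_script <- function(kind = c("fall", "normal"), seed = 1, total = 50) {
  kind <- match.arg(kind)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed + 1000L)
  if (kind == "fall") {
    w1 <- stats::runif(1, 8, 14)
    s1 <- stats::runif(1, 2, 4)
    w2 <- stats::runif(1, 6, 10)
    fd <- stats::runif(1, 0.7, 1.2)
    fall <- sample(c("fall_sideways", "fall_forward", "fall_backward"), 1)
    lie <- max(1, total - w1 - s1 - w2 - fd)
    action_script(c("walk", "stand", "walk", fall, "lie"),
                  c(w1, s1, w2, fd, lie))
  } else {
    w1 <- stats::runif(1, 10, 18)
    s1 <- stats::runif(1, 3, 6)
    w2 <- stats::runif(1, 8, 14)
    s2 <- stats::runif(1, 2, 5)
    w3 <- max(1, total - w1 - s1 - w2 - s2)
    action_script(c("walk", "stand", "walk", "stand", "walk"),
                  c(w1, s1, w2, s2, w3))
  }
}

#' Sample a state/symbol sequence from an HMM
#'
#' Draws the initial state from `pi`, transitions from `A` and symbols
#' from `B`.  Used as the recovery oracle for the supervised counting
#' estimators.
#'
#' @param model A `fall_hmm` (or any list with valid `A`, `B`, `pi`).
#' @param n Sequence length (frames), at least 1.
#' @param seed Optional integer seed.
#' @return A list with character `states` and integer `symbols`.
#' @export
sample_hmm <- function(model, n, seed = NULL) {
  A <- model$A; B <- model$B; pi <- model$pi
  stopifnot(n >= 1)
  if (any(A < 0) || any(abs(rowSums(A) - 1) > 1e-9))
    stop("invalid transition matrix")
  if (any(B < 0) || any(abs(rowSums(B) - 1) > 1e-6))
    stop("invalid emission matrix")
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    }
    set.seed(seed)
  }
  states <- integer(n)
  states[1] <- sample(1:2, 1, prob = pi)
  for (t in seq_len(n - 1))
    states[t + 1] <- sample(1:2, 1, prob = A[states[t], ])
  symbols <- vapply(states, function(s)
    sample(1:8, 1, prob = B[s, ]), integer(1))
  list(states = STATES[states], symbols = symbols)
}
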