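# Graph-cut mask refinement: binary labeling over the 4-connected pixel
# grid minimising unary (appearance/seed) + pairwise (contrast) energy
# via max-flow/min-cut.

# Foreground/background intensity models (Gaussians) fitted to a frame
# under a seed mask.  In the segmentation pipeline these are fitted when
# the seeds are refreshed and reused until the next refresh, so the
# appearance follows the person even as the stored seed mask goes stale
# spatially.
fit_appearance <- function(frame, seeds) {
  I <- as.numeric(frame)
  eps_sd <- 1e-3
  fg <- I[seeds != 0]; bg <- I[seeds == 0]
  list(mu_fg = mean(fg), sd_fg = max(stats::sd(fg), eps_sd, na.rm = TRUE),
       mu_bg = mean(bg), sd_bg = max(stats::sd(bg), eps_sd, na.rm = TRUE))
}

# Energy terms: unary costs are negative Gaussian log-likelihoods of the
# pixel intensity under the appearance models, with optional hard
# constraints at the eroded seed cores (only meaningful when the seeds
# were taken from this very frame).  Pairwise weights on 4-connected
# edges are lambda * exp(-dI^2 / (2 beta)), beta = mean squared
# neighbour difference.
build_energy <- function(frame, seeds, config, appearance = NULL,
                         use_cores = TRUE) {
  nr <- nrow(frame); nc <- ncol(frame)
  npix <- nr * nc
  big <- 1e6
  if (is.null(appearance)) appearance <- fit_appearance(frame, seeds)

  I <- as.numeric(frame)
  d_fg <- pmin(big, -stats::dnorm(I, appearance$mu_fg, appearance$sd_fg,
                                  log = TRUE))
  d_bg <- pmin(big, -stats::dnorm(I, appearance$mu_bg, appearance$sd_bg,
                                  log = TRUE))
  if (use_cores) {
    fg_core <- erode_mask(seeds, config$gc_seed_erosion)
    if (sum(fg_core) == 0) fg_core <- seeds
    bg_core <- 1L - dilate_mask(seeds, config$gc_seed_erosion)
    d_fg[fg_core != 0] <- 0;  d_bg[fg_core != 0] <- big
    if (sum(bg_core) > 0) {
      d_bg[bg_core != 0] <- 0;  d_fg[bg_core != 0] <- big
    }
  }

  # 4-connected neighbour pairs (down, right)
  idx <- matrix(seq_len(npix), nr, nc)
  p_down <- cbind(as.vector(idx[-nr, ]), as.vector(idx[-1, ]))
  p_right <- cbind(as.vector(idx[, -nc]), as.vector(idx[, -1]))
  pairs <- rbind(p_down, p_right)
  dI2 <- (I[pairs[, 1]] - I[pairs[, 2]])^2
  beta <- max(mean(dI2), 1e-8)
  w <- config$gc_lambda * exp(-dI2 / (2 * beta))

  list(nrow = nr, ncol = nc, d_fg = d_fg, d_bg = d_bg,
       pairs = pairs, w = w, beta = beta, big = big)
}

energy_of <- function(energy, labels) {
  lab <- as.integer(labels != 0)
  un <- sum(ifelse(lab == 1L, energy$d_fg, energy$d_bg))
  pw <- sum(energy$w[lab[energy$pairs[, 1]] != lab[energy$pairs[, 2]]])
  un + pw
}

#' Evaluate the graph-cut energy of a labeling
#'
#' Rebuilds the energy used by [refine_mask()] for the given frame and
#' seeds and returns the total (unary + pairwise) energy of `labels`.
#' Useful for checking that refinement never increases the energy of the
#' seed labeling.
#'
#' @param frame Grayscale matrix in `[0, 1]`.
#' @param labels Candidate 0/1 labeling.
#' @param seeds Seed mask that defines the unary terms (defaults to
#'   `labels`).
#' @param config A [fall_config()].
#' @param appearance,use_cores See [refine_mask()].
#' @return The scalar energy.
#' @export
graphcut_energy <- function(frame, labels, seeds = labels,
                            config = fall_config(), appearance = NULL,
                            use_cores = TRUE) {
  energy_of(build_energy(frame, seeds, config, appearance, use_cores),
            labels)
}

#' Refine a raw foreground mask by min-cut segmentation
#'
#' Builds a graph over the pixels (4-connected lattice plus source/sink
#' terminals), with unary capacities from the foreground/background
#' appearance models and pairwise contrast capacities, and returns the
#' minimum-cut binary labeling computed by max-flow.
#'
#' Standalone use refines `raw_mask` against itself: the appearance
#' models are fitted to this frame under the raw mask, and eroded seed
#' cores are pinned hard.  In [segment_sequence()] the seeds and
#' appearance are refreshed from the raw background-subtraction mask
#' every `reseed_interval` frames and reused in between (`use_cores =
#' FALSE` then, since the stored seed positions go stale as the person
#' moves).
#'
#' An empty raw mask cannot seed the models and is passed through
#' unchanged.  Degenerate seeds (entirely one label) are returned
#' unchanged with a warning.
#'
#' @param frame Grayscale matrix in `[0, 1]`.
#' @param raw_mask Raw 0/1 foreground mask from [update_background()].
#' @param config A [fall_config()]; `gc_lambda = 0` reduces the cut to
#'   the per-pixel unary-optimal decision.
#' @param seeds Optional stored seed mask (defaults to `raw_mask`).
#' @param appearance Optional stored appearance models from an earlier
#'   seed frame; fitted from `frame` and `seeds` when `NULL`.
#' @param use_cores Pin eroded seed cores as hard constraints; disable
#'   when the seeds come from an earlier frame.
#' @return A 0/1 matrix, the minimum-energy labeling.
#' @export
refine_mask <- function(frame, raw_mask, config = fall_config(),
                        seeds = NULL, appearance = NULL,
                        use_cores = TRUE) {
  if (is.null(seeds)) seeds <- raw_mask
  if (sum(seeds) == 0) seeds <- raw_mask
  ns <- sum(seeds)
  if (ns == 0) return(raw_mask + 0L)
  if (ns == length(seeds)) {
    warning("degenerate graph-cut seeds (single label); returning seeds")
    return(seeds + 0L)
  }
  en <- build_energy(frame, seeds, config, appearance, use_cores)
  npix <- en$nrow * en$ncol
  s <- npix + 1L; t <- npix + 2L

  tl_s <- cbind(s, seq_len(npix))            # cut when pixel -> background
  tl_t <- cbind(seq_len(npix), t)            # cut when pixel -> foreground
  caps <- c(en$d_bg, en$d_fg, en$w)
  edges <- rbind(tl_s, tl_t, en$pairs)
  keep <- caps > 1e-12
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                   directed = FALSE)
  if (igraph::vcount(g) < t) g <- igraph::add_vertices(g, t - igraph::vcount(g))
  flow <- igraph::max_flow(g, source = s, target = t,
                           capacity = caps[keep])
  fg_side <- as.integer(flow$partition1)
  lab <- matrix(0L, en$nrow, en$ncol)
  lab[fg_side[fg_side <= npix]] <- 1L
  lab
}
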