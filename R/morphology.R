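# Binary 3x3 morphology via shift-and-combine; masks are 0/1 matrices.

shift_mask <- function(m, dr, dc, pad = 0L) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(pad, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

neigh8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

#' Binary morphological operators (3x3 structuring element)
#'
#' Plain-matrix erosion, dilation, opening and closing with the full 3x3
#' neighbourhood, applied `passes` times.  The image border is treated as
#' background.
#'
#' @param mask A 0/1 matrix.
#' @param passes Number of passes; 0 returns the mask unchanged.
#' @return A 0/1 integer matrix of the same shape.
#' @export
erode_mask <- function(mask, passes = 1) {
  m <- mask != 0
  for (p in seq_len(passes)) {
    acc <- m
    for (k in seq_len(nrow(neigh8)))
      acc <- acc & shift_mask(m, neigh8[k, 1], neigh8[k, 2], pad = FALSE)
    m <- acc
  }
  mode(m) <- "integer"
  m
}

#' @rdname erode_mask
#' @export
dilate_mask <- function(mask, passes = 1) {
  m <- mask != 0
  for (p in seq_len(passes)) {
    acc <- m
    for (k in seq_len(nrow(neigh8)))
      acc <- acc | shift_mask(m, neigh8[k, 1], neigh8[k, 2], pad = FALSE)
    m <- acc
  }
  mode(m) <- "integer"
  m
}

#' @rdname erode_mask
#' @export
open_mask <- function(mask, passes = 1) {
  if (passes < 1) return(mask + 0L)
  dilate_mask(erode_mask(mask, passes), passes)
}

#' @rdname erode_mask
#' @export
close_mask <- function(mask, passes = 1) {
  if (passes < 1) return(mask + 0L)
  erode_mask(dilate_mask(mask, passes), passes)
}

#' Keep only the largest 8-connected foreground component
#'
#' Components are 8-connected.  An empty mask is returned unchanged.  When
#' two components tie in size, the one containing the first foreground
#' pixel in raster order (row by row, left to right) is kept; the method
#' assumes a single monitored person, so ties are rare and the rule only
#' fixes determinism.
#'
#' @param mask A 0/1 matrix.
#' @return A 0/1 integer matrix containing one component (or empty).
#' @export
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  fg <- which(mask != 0)
  out <- matrix(0L, nr, nc)
  if (!length(fg)) return(out)
  rank <- integer(nr * nc)        # foreground vertex id by linear index
  rank[fg] <- seq_along(fg)
  edges <- NULL
  for (sh in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
    r <- ((fg - 1L) %% nr) + 1L
    c <- ((fg - 1L) %/% nr) + 1L
    r2 <- r + sh[1]; c2 <- c + sh[2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    idx2 <- (c2[ok] - 1L) * nr + r2[ok]
    both <- mask[idx2] != 0
    if (any(both))
      edges <- rbind(edges, cbind(rank[fg[ok][both]], rank[idx2[both]]))
  }
  if (is.null(edges)) {
    comp <- seq_along(fg)          # all isolated pixels
    sizes <- rep(1L, length(fg))
  } else {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
    cc <- igraph::components(g)
    comp <- cc$membership[seq_along(fg)]
    sizes <- as.integer(cc$csize)
  }
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    # raster-order rank of each candidate component's first pixel
    r <- ((fg - 1L) %% nr) + 1L
    c <- ((fg - 1L) %/% nr) + 1L
    raster <- (r - 1L) * nc + c
    first <- vapply(best, function(b) min(raster[comp == b]), numeric(1))
    best <- best[which.min(first)]
  }
  out[fg[comp == best]] <- 1L
  out
}
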