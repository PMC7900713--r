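#' Render traces into a two-channel image stack with label masks
#'
#' Draws each cell as a disk at its per-frame centroid. The donor channel
#' carries a constant per-cell expression level; the acceptor (sensitized
#' emission) channel is donor times the cell's true FRET ratio at that frame,
#' so measuring mean acceptor / mean donor over the mask recovers the ratio
#' exactly in the noise-free case. Optional Poisson photon noise is applied
#' per pixel. Where disks overlap, the higher cell id wins (deterministic).
#'
#' @param traces long data.frame with `cell_id`, `frame`, `ratio`, `x`, `y`
#'   (pixel coordinates; x = column, y = row).
#' @param image_shape c(height, width) in pixels.
#' @param cell_radius disk radius in pixels (>= 2).
#' @param donor_levels named (by cell id) or single donor intensity; default
#'   1000 photons for every cell.
#' @param poisson_noise apply per-pixel Poisson noise to both channels.
#' @param seed RNG seed for the noise.
#' @return list of `donor`, `acceptor` (lists of h x w matrices) and `masks`
#'   (list of integer label matrices; background 0).
#' @export
render_movie <- function(traces, image_shape = c(256, 256), cell_radius = 8,
                         donor_levels = 1000, poisson_noise = FALSE,
                         seed = 1L) {
  stopifnot(cell_radius >= 2)
  set.seed(seed)
  h <- image_shape[1]; w <- image_shape[2]
  frames <- if (nrow(traces) > 0) sort(unique(traces$frame)) else integer(0)
  ids <- if (nrow(traces) > 0) sort(unique(traces$cell_id)) else integer(0)
  if (length(donor_levels) == 1 && is.null(names(donor_levels)))
    donor_levels <- stats::setNames(rep(donor_levels, length(ids)), ids)
  off <- disk_offsets(cell_radius)
  empty <- function() matrix(0, h, w)
  donor <- list(); acceptor <- list(); masks <- list()
  if (length(frames) == 0)
    return(list(donor = list(empty()), acceptor = list(empty()),
                masks = list(matrix(0L, h, w))))
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    sub <- traces[traces$frame == fr, , drop = FALSE]
    sub <- sub[order(sub$cell_id), , drop = FALSE]
    d <- empty(); a <- empty(); m <- matrix(0L, h, w)
    for (k in seq_len(nrow(sub))) {
      cx <- round(sub$x[k]); cy <- round(sub$y[k])
      rows <- cy + off$dy; cols <- cx + off$dx
      ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
      idx <- cbind(rows[ok], cols[ok])
      lvl <- donor_levels[[as.character(sub$cell_id[k])]]
      d[idx] <- lvl
      a[idx] <- lvl * sub$ratio[k]
      m[idx] <- as.integer(sub$cell_id[k])
    }
    if (poisson_noise) {
      d[] <- stats::rpois(length(d), d)
      a[] <- stats::rpois(length(a), a)
    }
    donor[[fi]] <- d; acceptor[[fi]] <- a; masks[[fi]] <- m
  }
  list(donor = donor, acceptor = acceptor, masks = masks, frames = frames)
}

disk_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= r^2, ]
  list(dy = g$dy, dx = g$dx)
}
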