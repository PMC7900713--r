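#' Segment cells in a single-channel frame
#'
#' Otsu threshold on the intensity histogram, connected-component labeling,
#' and an area filter. Components are relabeled 1..K in raster order (by their
#' first pixel, column-major) so labeling is deterministic.
#'
#' @param image non-negative intensity matrix.
#' @param min_area minimum component area in pixels.
#' @return integer label matrix (0 = background).
#' @export
segment_cells <- function(image, min_area = 20) {
  stopifnot(all(image >= 0))
  if (max(image) == 0) return(matrix(0L, nrow(image), ncol(image)))
  norm <- image / max(image)
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  lab <- EBImage::bwlabel(norm > thr)
  lab <- EBImage::imageData(lab)
  if (max(lab) == 0) return(matrix(0L, nrow(image), ncol(image)))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  out <- matrix(0L, nrow(image), ncol(image))
  if (length(keep) == 0) return(out)
  first_px <- vapply(keep, function(k) which(lab == k)[1], numeric(1))
  keep <- keep[order(first_px)]
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Per-cell FRET measurement from a two-channel frame
#'
#' For every label, the background-subtracted mean pixel intensity of the
#' donor and sensitized-emission (acceptor) channels, and their ratio
#' acceptor/donor (ratio of means, not mean of ratios). Cells whose donor
#' mean is non-positive after background subtraction get `NA` ratio and a
#' `flagged` mark rather than being dropped.
#'
#' @param donor,acceptor intensity matrices of equal shape.
#' @param mask integer label matrix (0 = background).
#' @param background "mode" (default; modal intensity of non-mask pixels per
#'   channel), "none", or a numeric length-2 vector c(donor_bg, acceptor_bg).
#' @return data.frame: label, n_px, donor_mean, acceptor_mean, ratio, flagged.
#' @export
measure_cell_fret <- function(donor, acceptor, mask, background = "mode") {
  stopifnot(identical(dim(donor), dim(acceptor)),
            identical(dim(donor), dim(mask)))
  if (is.character(background) && background == "mode") {
    bg <- c(pixel_mode(donor[mask == 0]), pixel_mode(acceptor[mask == 0]))
  } else if (is.character(background) && background == "none") {
    bg <- c(0, 0)
  } else {
    bg <- as.numeric(background)
    stopifnot(length(bg) == 2)
  }
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0)
    return(data.frame(label = integer(0), n_px = integer(0),
                      donor_mean = numeric(0), acceptor_mean = numeric(0),
                      ratio = numeric(0), flagged = logical(0)))
  dm <- tapply(donor[mask > 0], mask[mask > 0], mean) - bg[1]
  am <- tapply(acceptor[mask > 0], mask[mask > 0], mean) - bg[2]
  np <- tapply(rep(1, sum(mask > 0)), mask[mask > 0], sum)
  flagged <- dm <= 0
  ratio <- ifelse(flagged, NA_real_, am / dm)
  data.frame(label = as.integer(names(dm)), n_px = as.integer(np),
             donor_mean = as.numeric(dm), acceptor_mean = as.numeric(am),
             ratio = as.numeric(ratio), flagged = as.logical(flagged),
             row.names = NULL)
}

# modal value of a pixel population; exact mode for integer-valued data,
# histogram mode (256 bins) otherwise
pixel_mode <- function(v) {
  if (length(v) == 0) return(0)
  if (all(v == round(v))) {
    tb <- table(v)
    as.numeric(names(tb)[which.max(tb)])
  } else {
    h <- graphics::hist(v, breaks = 256, plot = FALSE)
    h$mids[which.max(h$counts)]
  }
}

#' Link per-frame label masks into cell tracks with division detection
#'
#' Nearest-centroid linking: every detection in frame t+1 claims the nearest
#' active track centroid within `max_dist`. A track claimed by one detection
#' continues; a track claimed by two or more detections ends in a division and
#' the two nearest claimants start as daughter tracks (`parent_id` set; any
#' further claimants start as new parentless tracks). Unclaimed tracks
#' terminate; unclaimed detections start new tracks.
#'
#' @param masks list of integer label matrices, one per frame.
#' @param max_dist maximum link distance in pixels.
#' @return data.frame: cell_id, parent_id, frame, x, y, label (the mask label
#'   in that frame).
#' @export
track_cells <- function(masks, max_dist = 15) {
  cents <- lapply(masks, mask_centroids)
  rows <- list(); nxt <- 0L
  active <- data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0))
  add_row <- function(id, parent, frame, det) {
    rows[[length(rows) + 1]] <<- data.frame(
      cell_id = id, parent_id = parent, frame = frame,
      x = det$x, y = det$y, label = det$label)
  }
  parent_of <- integer(0)
  for (f in seq_along(cents)) {
    det <- cents[[f]]
    if (f == 1 || nrow(active) == 0) {
      claims <- rep(NA_integer_, nrow(det))
    } else {
      claims <- vapply(seq_len(nrow(det)), function(i) {
        dd <- sqrt((active$x - det$x[i])^2 + (active$y - det$y[i])^2)
        j <- which.min(dd)
        if (length(j) && dd[j] <= max_dist) active$cell_id[j] else NA_integer_
      }, integer(1))
    }
    new_active <- list()
    for (tid in unique(claims[!is.na(claims)])) {
      di <- which(claims == tid)
      if (length(di) == 1) {
        add_row(tid, parent_of[[as.character(tid)]], f, det[di, ])
        new_active[[length(new_active) + 1]] <-
          data.frame(cell_id = tid, x = det$x[di], y = det$y[di])
      } else {
        # division: parent track ends, two nearest claimants become daughters
        px <- active$x[active$cell_id == tid]
        py <- active$y[active$cell_id == tid]
        dd <- sqrt((det$x[di] - px)^2 + (det$y[di] - py)^2)
        di <- di[order(dd)]
        for (k in seq_along(di)) {
          nxt <- nxt + 1L
          par <- if (k <= 2) tid else NA_integer_
          parent_of[[as.character(nxt)]] <- par
          add_row(nxt, par, f, det[di[k], ])
          new_active[[length(new_active) + 1]] <-
            data.frame(cell_id = nxt, x = det$x[di[k]], y = det$y[di[k]])
        }
      }
    }
    for (di in which(is.na(claims))) {
      nxt <- nxt + 1L
      parent_of[[as.character(nxt)]] <- NA_integer_
      add_row(nxt, NA_integer_, f, det[di, ])
      new_active[[length(new_active) + 1]] <-
        data.frame(cell_id = nxt, x = det$x[di], y = det$y[di])
    }
    active <- if (length(new_active)) do.call(rbind, new_active) else
      data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0))
  }
  if (length(rows) == 0)
    return(data.frame(cell_id = integer(0), parent_id = integer(0),
                      frame = integer(0), x = numeric(0), y = numeric(0),
                      label = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

mask_centroids <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (length(labs) == 0)
    return(data.frame(label = integer(0), x = numeric(0), y = numeric(0)))
  idx <- which(mask > 0, arr.ind = TRUE)
  l <- mask[mask > 0]
  data.frame(label = labs,
             x = as.numeric(tapply(idx[, 2], l, mean)),
             y = as.numeric(tapply(idx[, 1], l, mean)))
}

#' Classify cells into quartile metabolic states
#'
#' Rank-based quartile binning of a population snapshot of FRET ratios:
#' top-quartile cells are called "high" (high intracellular glucose), bottom
#' quartile "low", the rest "mid". Ties are broken by cell id order so calls
#' are deterministic and bin counts are exact quartile counts (+/- 1).
#'
#' @param ratios numeric vector of per-cell ratios (>= 8 cells).
#' @param cell_ids optional ids (default seq_along).
#' @return data.frame: cell_id, ratio, quartile (1-4), label.
#' @export
classify_state <- function(ratios, cell_ids = seq_along(ratios)) {
  n <- length(ratios)
  if (n < 8) stop("need at least 8 cells for quartile state calls")
  if (length(unique(ratios)) == 1) {
    warning("all ratios identical; no high/low calls made")
    return(data.frame(cell_id = cell_ids, ratio = ratios,
                      quartile = NA_integer_, label = "mid"))
  }
  ord <- order(ratios, cell_ids)
  q <- integer(n)
  q[ord] <- ceiling(4 * seq_len(n) / n)
  label <- c("low", "mid", "mid", "high")[q]
  data.frame(cell_id = cell_ids, ratio = ratios, quartile = q, label = label)
}

#' Two-sample Kolmogorov-Smirnov comparison of FRET distributions
#'
#' Thin wrapper over the two-sample KS test (exact p-value where the
#' underlying implementation supports it for the sample sizes, asymptotic
#' otherwise), returning the ECDF sup-distance D and p-value.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `D`, `p_value`, `n_a`, `n_b`.
#' @export
compare_distributions <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  kt <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(kt$statistic), p_value = kt$p.value,
       n_a = length(a), n_b = length(b))
}
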