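#' Write an image stack as a multi-page TIFF
#'
#' Intensity stacks are written as 32-bit float pages; integer label masks as
#' 16-bit (labels must be < 65536).
#'
#' @param stack list of matrices (or a single matrix).
#' @param path output file.
#' @param type "float" (intensities) or "label" (integer masks).
#' @export
write_stack_tiff <- function(stack, path, type = c("float", "label")) {
  type <- match.arg(type)
  if (is.matrix(stack)) stack <- list(stack)
  if (type == "label") {
    mx <- max(vapply(stack, max, numeric(1)))
    if (mx > 65535) stop("label ids must fit 16 bits")
    pages <- lapply(stack, function(m) m / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  } else {
    # 32-bit float pages; the writer expects [0, 1], so intensities are
    # stored scaled by 2^-16 (values must be < 65536)
    if (max(vapply(stack, max, numeric(1))) >= 65536)
      stop("float intensities must be < 65536")
    if (min(vapply(stack, min, numeric(1))) < 0)
      stop("float intensities must be >= 0")
    pages <- lapply(stack, function(m) m / 65536)
    tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  }
  invisible(path)
}

#' Read an image stack from a multi-page TIFF
#'
#' @param path TIFF written by [write_stack_tiff()].
#' @param type "float" returns matrices as stored; "label" rescales 16-bit
#'   pages back to integer labels.
#' @return list of matrices.
#' @export
read_stack_tiff <- function(path, type = c("float", "label")) {
  type <- match.arg(type)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (type == "label")
    lapply(pages, function(m) {
      m <- round(m * 65535)
      storage.mode(m) <- "integer"
      m
    })
  else lapply(pages, function(m) m * 65536)
}

#' Write / read long-format trace tables
#'
#' Plain CSV with one row per (cell, frame); the common exchange format
#' between the quantification, kinetics, lineage and dose stages.
#'
#' @param traces data.frame.
#' @param path CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  utils::read.csv(path)
}
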