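## File I/O: raster images (PNG/JPEG via EBImage), per-region numeric maps,
## gaze logs and bias tables as CSV.

#' Read / write raster images
#'
#' Images on disk are PNG or JPEG; in memory they are numeric arrays of dim
#' c(height, width, 3) with intensities in [0, 1]. Grayscale files are
#' replicated across the three channels; an alpha channel is dropped.
#'
#' @param path file path.
#' @return `readRasterImage`: the image array.
#' @export
readRasterImage <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3L] > 3L) a <- a[, , 1:3, drop = FALSE]
  clamp(aperm(a, c(2L, 1L, 3L)), 0, 1)
}

#' @rdname readRasterImage
#' @param image numeric array c(h, w, 3) in [0, 1], or a h x w matrix
#'   (written as grayscale).
#' @export
writeRasterImage <- function(image, path) {
  a <- if (length(dim(image)) == 3L) aperm(image, c(2L, 1L, 3L))
       else t(image)
  EBImage::writeImage(EBImage::Image(clamp(a, 0, 1),
                                     colormode = if (length(dim(image)) == 3L)
                                       "Color" else "Grayscale"), path)
  invisible(path)
}

#' Read / write a per-region numeric map as CSV
#'
#' Layout: one line per region with columns `row`, `col`, `value`
#' (row-major order).
#'
#' @param values numeric vector, length `nRegions(grid)`.
#' @param grid the \linkS4class{GridSpec}.
#' @param path file path.
#' @export
writeRegionMap <- function(values, grid, path) {
  rc <- regionRowCol(grid, seq_len(nRegions(grid)))
  utils::write.csv(data.frame(row = rc[, "row"], col = rc[, "col"],
                              value = values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRegionMap
#' @return `readRegionMap`: the numeric vector in row-major order.
#' @export
readRegionMap <- function(path, grid) {
  d <- utils::read.csv(path)
  out <- numeric(nRegions(grid))
  out[regionIndex(grid, d$row, d$col)] <- d$value
  out
}

#' Read / write gaze logs as CSV
#'
#' Documented columns: subject_id, trial_id, image_id, event_type
#' ("fixation" or "saccade"), x_px, y_px, duration_ms, amplitude_deg,
#' peak_speed_deg_s, outcome, change_x_px, change_y_px, change_r_px.
#' Fixation rows carry coordinates and durations; saccade rows carry
#' amplitude, duration and peak speed.
#'
#' @param logs a gaze-log data.frame (see [makeGazeLogs()]).
#' @param path file path.
#' @export
writeGazeLogs <- function(logs, path) {
  utils::write.csv(logs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGazeLogs
#' @export
readGazeLogs <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read / write a saccade bias distribution as CSV
#'
#' Layout: amplitude_lo, amplitude_hi, angle_lo, angle_hi, density (one line
#' per polar-grid cell; densities are probability masses summing to 1).
#'
#' @param bias a \linkS4class{BiasDistribution}.
#' @param path file path.
#' @export
writeBiasDistribution <- function(bias, path) {
  na <- nrow(bias@density); nn <- ncol(bias@density)
  d <- data.frame(
    amplitude_lo = rep(bias@amp_breaks[-(na + 1L)], nn),
    amplitude_hi = rep(bias@amp_breaks[-1L], nn),
    angle_lo = rep(bias@angle_breaks[-(nn + 1L)], each = na),
    angle_hi = rep(bias@angle_breaks[-1L], each = na),
    density = as.vector(bias@density))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeBiasDistribution
#' @export
readBiasDistribution <- function(path) {
  d <- utils::read.csv(path)
  amp_breaks <- sort(unique(c(d$amplitude_lo, d$amplitude_hi)))
  angle_breaks <- sort(unique(c(d$angle_lo, d$angle_hi)))
  na <- length(amp_breaks) - 1L; nn <- length(angle_breaks) - 1L
  den <- matrix(0, na, nn)
  ai <- findInterval(d$amplitude_lo, amp_breaks)
  ni <- findInterval(d$angle_lo, angle_breaks)
  den[cbind(ai, ni)] <- d$density
  new("BiasDistribution", density = den / sum(den),
      amp_breaks = amp_breaks, angle_breaks = angle_breaks)
}

#' Export per-bin evidence traces from a trial
#'
#' Writes the traces recorded by [runTrial()] with `trace_regions` set, as
#' CSV with columns trial_id, bin, region, E.
#'
#' @param result a \linkS4class{TrialResult} run with traces enabled.
#' @param path file path.
#' @param trial_id identifier written into the first column.
#' @export
writeEvidenceTraces <- function(result, path, trial_id = 1L) {
  if (!length(result@trace)) stop("trial was run without trace_regions")
  d <- do.call(rbind, lapply(names(result@trace), function(r) {
    e <- result@trace[[r]]
    data.frame(trial_id = trial_id, bin = seq_along(e),
               region = as.integer(r), E = e)
  }))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
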