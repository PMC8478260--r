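## Image pipeline: grid partition, Cartesian variable resolution (CVR)
## foveation, frequency-tuned saliency, and the saliency -> firing-rate map.

#' Partition an image into a grid of non-overlapping square regions
#'
#' The reference 864 x 648 px frame with 12 px patches yields the 72 x 54
#' grid (N = 3888). Portrait images get the x/y resolutions swapped
#' automatically because rows and columns are derived independently.
#'
#' @param width_px,height_px image size in pixels.
#' @param patch_px side of each square region (default 12).
#' @return a \linkS4class{GridSpec}.
#' @examples
#' partitionGrid(864, 648, 12)  # 72 x 54 = 3888 regions
#' @export
partitionGrid <- function(width_px, height_px, patch_px = 12L) {
  stopifnot_scalar(width_px); stopifnot_scalar(height_px)
  stopifnot_scalar(patch_px)
  if (patch_px < 1L) stop("patch_px must be >= 1")
  if (patch_px > width_px || patch_px > height_px)
    stop("patch is larger than the image")
  new("GridSpec", patch_px = as.integer(patch_px),
      n_cols = as.integer(width_px %/% patch_px),
      n_rows = as.integer(height_px %/% patch_px))
}

# forward CVR offset map: signed offset d (px) -> transformed offset (px)
cvr_offset <- function(d, beta, s_f) sign(d) * log(beta * abs(d) + 1) * s_f
# inverse: transformed offset -> source offset
cvr_offset_inv <- function(dv, beta, s_f) {
  sign(dv) * (exp(abs(dv) / s_f) - 1) / beta
}

#' Foveally magnify an image with the CVR transform
#'
#' Each pixel at signed offset (dx, dy) from the fixation centre maps to
#' sign(dx) * ln(beta |dx| + 1) * S_fx (analogously in y). The output is
#' resampled onto the original pixel lattice by inverse mapping with bilinear
#' interpolation; source coordinates falling outside the image are clipped to
#' its bounds (edge replication). The transform is applied to |d| with the
#' sign restored, is odd about the centre and strictly increasing in |d|;
#' local magnification at the centre is beta * S_f.
#'
#' @param image numeric array c(h, w, 3) in [0, 1] (a plain h x w matrix is
#'   also accepted).
#' @param params a \linkS4class{CVRParams}; its centre must lie inside the
#'   image.
#' @return the foveated image, same dimensions as the input.
#' @export
cvrForward <- function(image, params) {
  validObject(params)
  d <- dim(image)
  h <- d[1L]; w <- d[2L]
  x0 <- params@center[1L]; y0 <- params@center[2L]
  if (x0 < 1 || x0 > w || y0 < 1 || y0 > h)
    stop("CVR centre lies outside the image")
  # inverse map: output lattice offset -> source coordinate
  sx <- clamp(x0 + cvr_offset_inv(seq_len(w) - x0, params@beta, params@s_fx),
              1, w)
  sy <- clamp(y0 + cvr_offset_inv(seq_len(h) - y0, params@beta, params@s_fy),
              1, h)
  bilinear_sample(image, sx, sy)
}

# separable bilinear resampling of a h x w (x channel) array at source
# columns sx (length w') and rows sy (length h')
bilinear_sample <- function(image, sx, sy) {
  d <- dim(image)
  if (length(d) == 3L) {
    out <- array(0, c(length(sy), length(sx), d[3L]))
    for (ch in seq_len(d[3L]))
      out[, , ch] <- bilinear_cpp(image[, , ch], sx, sy)
    out
  } else {
    bilinear_cpp(image, sx, sy)
  }
}

#' Project a per-region map from CVR space back to original image space
#'
#' Each original-space region receives the value of the CVR-space region its
#' centre maps into under the forward transform (coordinates clipped to the
#' image bounds). The fixated region is a fixed point, and a constant map is
#' projected to the same constant.
#'
#' @param values_cvr numeric vector of per-region values in CVR space
#'   (row-major, length `nRegions(grid)`).
#' @param params the \linkS4class{CVRParams} used for the forward transform.
#' @param grid the \linkS4class{GridSpec} shared by both spaces.
#' @return numeric vector of per-region values in original image space.
#' @export
cvrInverseProject <- function(values_cvr, params, grid) {
  if (length(values_cvr) != nRegions(grid))
    stop("values_cvr length must be nRegions(grid)")
  values_cvr[cvr_projection_index(params, grid)]
}

# original-space region i reads CVR-space region cvr_projection_index()[i]
cvr_projection_index <- function(params, grid) {
  n <- nRegions(grid)
  ctr <- regionCenter(grid, seq_len(n))
  w <- grid@n_cols * grid@patch_px
  h <- grid@n_rows * grid@patch_px
  vx <- clamp(params@center[1L] +
                cvr_offset(ctr[, "x"] - params@center[1L], params@beta,
                           params@s_fx), 1, w)
  vy <- clamp(params@center[2L] +
                cvr_offset(ctr[, "y"] - params@center[2L], params@beta,
                           params@s_fy), 1, h)
  col <- clamp(ceiling(vx / grid@patch_px), 1, grid@n_cols)
  row <- clamp(ceiling(vy / grid@patch_px), 1, grid@n_rows)
  regionIndex(grid, row, col)
}

# RGB [0,1] array -> n x 3 Lab matrix (pixels in column-major order)
rgb_to_lab <- function(image) {
  d <- dim(image)
  m <- matrix(image, d[1L] * d[2L], 3L) * 255
  farver::convert_colour(m, from = "rgb", to = "lab")
}

# separable Gaussian blur of a matrix (edge replication)
gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  conv_sep_cpp(m, k / sum(k))
}

#' Frequency-tuned saliency map
#'
#' Per-pixel saliency is the Euclidean distance, in CIELab space, between the
#' image's global mean Lab vector and the Gaussian-blurred Lab image, min-max
#' normalised to [0, 1]. A constant image (blurred image equal to the mean
#' everywhere) returns an all-zero map.
#'
#' @param image numeric array c(h, w, 3) in [0, 1].
#' @param blur_sigma Gaussian blur standard deviation in px (default 1.6).
#' @return h x w saliency matrix in [0, 1].
#' @export
computeSaliency <- function(image, blur_sigma = 1.6) {
  d <- dim(image)
  if (length(d) != 3L || d[3L] != 3L) stop("image must be h x w x 3")
  saliency_from_lab(array(rgb_to_lab(image), d), blur_sigma)
}

# mean of a h x w matrix over each grid region -> vector length nRegions
# (row-major); pixels beyond the tiled area are ignored
region_means <- function(values, grid) {
  region_mean_cpp(values, grid@patch_px, grid@n_rows, grid@n_cols)
}

# saliency from an already-converted h x w x 3 Lab array
saliency_from_lab <- function(lab, blur_sigma) {
  d <- dim(lab)
  s <- matrix(0, d[1L], d[2L])
  for (ch in 1:3) {
    m <- lab[, , ch]
    b <- if (min(d[1:2]) > 4) gaussian_blur(m, blur_sigma) else m
    s <- s + (b - mean(m))^2
  }
  s <- sqrt(s)
  rng <- range(s)
  if (rng[2L] - rng[1L] < 1e-12) return(matrix(0, d[1L], d[2L]))
  (s - rng[1L]) / (rng[2L] - rng[1L])
}

#' Map region-averaged saliency to Poisson firing rates
#'
#' lambda_i = lambda_min + (lambda_max - lambda_min) * mean saliency of the
#' pixels in region i; a linear, monotone map with rates bounded in
#' [lambda_min, lambda_max] spikes/bin.
#'
#' @param sal h x w saliency matrix, normalised to [0, 1].
#' @param grid the \linkS4class{GridSpec}.
#' @param lambda_min,lambda_max firing-rate bounds (spikes/bin).
#' @return numeric vector of per-region rates (row-major).
#' @export
saliencyToRates <- function(sal, grid, lambda_min = 5, lambda_max = 120) {
  if (lambda_min >= lambda_max) stop("lambda_min must be < lambda_max")
  lambda_min + (lambda_max - lambda_min) * region_means(sal, grid)
}

#' Per-region firing-rate maps for a fixation
#'
#' Applies the model's encoding pipeline for one fixation: CVR-foveate each
#' image of the pair at the given region's centre, compute the
#' frequency-tuned saliency of the foveated image, and average it per region
#' into bounded Poisson rates. Maps are memoised per fixation centre in
#' `cache` (an environment), the model's precomputation short-cut; catch
#' pairs (identical images) are computed once.
#'
#' @param pair an \linkS4class{ImagePair}.
#' @param region fixated region index.
#' @param grid the \linkS4class{GridSpec}.
#' @param params a \linkS4class{ModelParams}.
#' @param cache optional environment used as a memo table.
#' @return list with per-region rate vectors `lam_a` and `lam_ap`.
#' @export
fixationRateMaps <- function(pair, region, grid, params,
                             cache = new.env(parent = emptyenv())) {
  key <- sprintf("r%d_f%g", region, params@fmf)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  d <- dim(pair@a)
  ## the Lab representation of each image is fixation-independent: convert
  ## once and foveate the Lab planes at each fixation centre
  if (is.null(cache$.lab_a)) {
    cache$.lab_a <- array(rgb_to_lab(pair@a), d)
    cache$.lab_ap <- if (identical(pair@a, pair@a_prime)) cache$.lab_a
                     else array(rgb_to_lab(pair@a_prime), d)
  }
  ctr <- regionCenter(grid, region)
  cvr <- cvrParamsFor(c(ctr[1L, "x"], ctr[1L, "y"]), d[2L], d[1L],
                      beta = params@fmf)
  one <- function(lab) {
    fov <- cvrForward(lab, cvr)
    sal <- saliency_from_lab(fov, params@blur_sigma)
    saliencyToRates(sal, grid, params@lambda_min, params@lambda_max)
  }
  lam_a <- one(cache$.lab_a)
  lam_ap <- if (identical(pair@a, pair@a_prime)) lam_a
            else one(cache$.lab_ap)
  out <- list(lam_a = lam_a, lam_ap = lam_ap,
              proj = cvr_projection_index(cvr, grid))
  cache[[key]] <- out
  out
}
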