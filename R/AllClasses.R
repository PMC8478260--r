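## Central S4 containers.
##
## Conventions used throughout the package (stated here once):
##  * raster images are numeric arrays of dim c(height, width, 3) with
##    intensities in [0, 1]; pixel coordinates are 1-based with the origin at
##    the top-left, x indexing columns and y indexing rows;
##  * grid regions are indexed 1..N in row-major order; region i sits at
##    row = (i - 1) %/% n_cols + 1, col = (i - 1) %% n_cols + 1.

#' Grid partition of an image into non-overlapping square regions
#'
#' @slot patch_px side length of each square region, in pixels.
#' @slot n_cols,n_rows number of grid columns / rows.
#' @export
setClass("GridSpec",
  representation(patch_px = "integer", n_cols = "integer", n_rows = "integer"),
  validity = function(object) {
    if (object@patch_px < 1L) return("patch_px must be >= 1")
    if (object@n_cols < 1L || object@n_rows < 1L)
      return("grid must have at least one row and one column")
    TRUE
  })

#' Parameters of the Cartesian variable resolution (foveation) transform
#'
#' The transform maps a signed pixel offset d from the fixation centre to
#' sign(d) * ln(beta * |d| + 1) * S_f, magnifying the fovea (local
#' magnification beta * S_f at the centre) and compressing the far periphery.
#'
#' @slot beta foveal magnification constant (the FMF; unitless, > 0).
#' @slot s_fx,s_fy scale factors along x and y (unitless, > 0).
#' @slot center fixation centre c(x, y) in pixel coordinates.
#' @export
setClass("CVRParams",
  representation(beta = "numeric", s_fx = "numeric", s_fy = "numeric",
                 center = "numeric"),
  validity = function(object) {
    if (object@beta <= 0) return("beta must be > 0")
    if (object@s_fx <= 0 || object@s_fy <= 0) return("scale factors must be > 0")
    if (length(object@center) != 2L) return("center must be c(x, y)")
    TRUE
  })

#' A flicker stimulus: original image, altered image, ground-truth change mask
#'
#' @slot a,a_prime numeric arrays dim c(h, w, 3), intensities in [0, 1].
#' @slot mask logical matrix dim c(h, w); TRUE where the two images differ.
#' @export
setClass("ImagePair",
  representation(a = "array", a_prime = "array", mask = "matrix"),
  validity = function(object) {
    da <- dim(object@a); db <- dim(object@a_prime)
    if (length(da) != 3L || da[3L] != 3L) return("a must be h x w x 3")
    if (!identical(da, db)) return("a and a_prime must have identical dims")
    if (!identical(dim(object@mask), da[1:2]))
      return("mask must match the image height x width")
    rng <- range(object@a, object@a_prime)
    if (rng[1L] < 0 || rng[2L] > 1) return("intensities must lie in [0, 1]")
    TRUE
  })

#' Full parameter set of the SPRT change-detection model
#'
#' Defaults reproduce the model's reference configuration: 25 ms time bins,
#' 250 ms image and blank epochs, 60 s trials, softmax temperature 0.01,
#' evidence decay peak 0.004 with spatial scale 4 grid units, accumulation
#' noise U(-5, 5), prior odds 0.1, decision bounds +100 / -20, no-change
#' bound decay 0, foveal magnification factor 0.05, firing rates in
#' [5, 120] spikes/bin and a firing-rate-difference prior of 3 spikes/bin.
#'
#' @slot dt_ms time bin duration (ms).
#' @slot tau_img,tau_blank image / blank epoch durations (bins).
#' @slot trial_bins total trial duration (bins).
#' @slot temperature softmax temperature T.
#' @slot gamma peak evidence decay factor in [0, 1] (larger = leakier).
#' @slot beta_decay spatial scale of the decay field (grid units).
#' @slot noise_half_width evidence noise half-width w; W ~ U(-w, w).
#' @slot prior_odds prior odds of change to no change, P.
#' @slot f_c,f_n change ( > 0 ) and no-change ( < 0 ) evidence bounds.
#' @slot zeta decay rate of the no-change bound (per bin within a fixation).
#' @slot fmf foveal magnification factor (beta of the CVR transform).
#' @slot lambda_min,lambda_max firing-rate bounds (spikes/bin).
#' @slot mu_f prior on the firing-rate difference at the change (spikes/bin).
#' @slot prior_scope "fixated" (default) applies log P at the fixated region
#'   only; "all" applies it at every region (the literal accumulation rule).
#' @slot reset_on_fixation reset the fixated region's evidence to 0 at
#'   fixation onset (a fresh sequential test at the new location).
#' @slot check_all_regions check the change bound at every region rather than
#'   only the fixated one.
#' @slot blur_sigma Gaussian blur (px) of the frequency-tuned saliency step.
#' @export
setClass("ModelParams",
  representation(
    dt_ms = "numeric", tau_img = "integer", tau_blank = "integer",
    trial_bins = "integer", temperature = "numeric", gamma = "numeric",
    beta_decay = "numeric", noise_half_width = "numeric",
    prior_odds = "numeric", f_c = "numeric", f_n = "numeric",
    zeta = "numeric", fmf = "numeric", lambda_min = "numeric",
    lambda_max = "numeric", mu_f = "numeric", prior_scope = "character",
    reset_on_fixation = "logical", check_all_regions = "logical",
    blur_sigma = "numeric"),
  validity = function(object) {
    if (object@f_c <= 0 || object@f_n >= 0) return("need f_n < 0 < f_c")
    if (object@gamma < 0 || object@gamma > 1) return("gamma must be in [0, 1]")
    if (object@prior_odds <= 0) return("prior_odds must be > 0")
    if (object@zeta < 0) return("zeta must be >= 0")
    if (object@lambda_min >= object@lambda_max)
      return("lambda_min must be < lambda_max")
    if (object@temperature <= 0) return("temperature must be > 0")
    if (!object@prior_scope %in% c("fixated", "all"))
      return("prior_scope must be 'fixated' or 'all'")
    if (object@tau_img < 0L || object@tau_blank < 0L)
      return("epoch durations must be >= 0")
    TRUE
  })

#' Joint saccade amplitude / turn-angle bias distribution
#'
#' Tabulated probability masses on a polar grid; masses sum to 1. Amplitudes
#' are in grid units; turn angles in degrees in (-180, 180] relative to the
#' previous saccade direction.
#'
#' @slot density amplitude-bin x angle-bin matrix of probability masses.
#' @slot amp_breaks,angle_breaks bin boundaries (lengths nrow+1 / ncol+1).
#' @export
setClass("BiasDistribution",
  representation(density = "matrix", amp_breaks = "numeric",
                 angle_breaks = "numeric"),
  validity = function(object) {
    if (any(object@density < 0)) return("density must be non-negative")
    if (abs(sum(object@density) - 1) > 1e-8) return("density must sum to 1")
    if (length(object@amp_breaks) != nrow(object@density) + 1L)
      return("amp_breaks length must be nrow(density) + 1")
    if (length(object@angle_breaks) != ncol(object@density) + 1L)
      return("angle_breaks length must be ncol(density) + 1")
    TRUE
  })

#' Outcome of one simulated flicker trial
#'
#' @slot outcome "hit", "miss" or "false_alarm".
#' @slot detection_bin bin of the change signal (NA for a miss).
#' @slot scanpath data.frame: region, row, col, onset_bin, duration_bins.
#' @slot seed the RNG seed the trial was run with.
#' @slot trace optional list of per-bin evidence traces.
#' @export
setClass("TrialResult",
  representation(outcome = "character", detection_bin = "numeric",
                 scanpath = "data.frame", seed = "numeric", trace = "list"),
  validity = function(object) {
    if (!object@outcome %in% c("hit", "miss", "false_alarm"))
      return("outcome must be hit, miss or false_alarm")
    TRUE
  })

#' Fixation cluster model with BIC profile
#'
#' @slot centers k x 2 matrix of cluster centres (x, y in px).
#' @slot cluster integer assignment per input point; 0 denotes the
#'   low-density ("sparse") singleton cluster.
#' @slot bic data.frame of the BIC profile over candidate k.
#' @slot k the selected number of k-means clusters.
#' @export
setClass("ClusterModel",
  representation(centers = "matrix", cluster = "integer",
                 bic = "data.frame", k = "integer"),
  validity = function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (nrow(object@centers) != object@k) return("centers must have k rows")
    TRUE
  })

#' Scanpath encoded as a string of cluster labels
#'
#' @slot labels integer cluster label per retained fixation (0 = sparse).
#' @slot string single-character encoding ("." for the sparse cluster).
#' @export
setClass("ScanString",
  representation(labels = "integer", string = "character"),
  validity = function(object) {
    if (nchar(object@string) != length(object@labels))
      return("string length must equal the number of labels")
    TRUE
  })

#' @export
#' @noRd
setMethod("show", "GridSpec", function(object) {
  cat(sprintf("GridSpec: %d x %d regions (%d total), %d px patches\n",
              object@n_cols, object@n_rows, nRegions(object),
              object@patch_px))
})

#' @export
#' @noRd
setMethod("show", "ModelParams", function(object) {
  cat("ModelParams (SPRT change-detection model)\n")
  cat(sprintf("  dt = %g ms | image/blank = %d/%d bins | trial = %d bins\n",
              object@dt_ms, object@tau_img, object@tau_blank,
              object@trial_bins))
  cat(sprintf("  T = %g | gamma = %g | beta_decay = %g | W = U(-%g, %g)\n",
              object@temperature, object@gamma, object@beta_decay,
              object@noise_half_width, object@noise_half_width))
  cat(sprintf("  P = %g | F_c = %g | F_n = %g | zeta = %g\n",
              object@prior_odds, object@f_c, object@f_n, object@zeta))
  cat(sprintf("  FMF = %g | lambda in [%g, %g] spikes/bin | mu_f = %g\n",
              object@fmf, object@lambda_min, object@lambda_max, object@mu_f))
})

#' @export
#' @noRd
setMethod("show", "ImagePair", function(object) {
  d <- dim(object@a)
  cat(sprintf("ImagePair: %d x %d px, %s (%d changed px)\n", d[2L], d[1L],
              if (any(object@mask)) "change pair" else "catch pair",
              sum(object@mask)))
})

#' @export
#' @noRd
setMethod("show", "TrialResult", function(object) {
  cat(sprintf("TrialResult: %s%s, %d fixations (seed %s)\n", object@outcome,
              if (is.na(object@detection_bin)) ""
              else sprintf(" at bin %d", as.integer(object@detection_bin)),
              nrow(object@scanpath), format(object@seed)))
})

#' @export
#' @noRd
setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: k = %d clusters, %d points (%d in the sparse cluster)\n",
              object@k, length(object@cluster), sum(object@cluster == 0L)))
})

#' @export
#' @noRd
setMethod("show", "BiasDistribution", function(object) {
  cat(sprintf("BiasDistribution: %d amplitude x %d angle bins\n",
              nrow(object@density), ncol(object@density)))
})

## ---- accessors ----

#' Number of grid regions
#' @param grid a \linkS4class{GridSpec}.
#' @return integer, n_cols * n_rows.
#' @export
nRegions <- function(grid) grid@n_cols * grid@n_rows

#' Region index to (row, col) and back
#'
#' Regions are numbered 1..N row-major.
#' @param grid a \linkS4class{GridSpec}.
#' @param region integer region index (vectorised).
#' @return `regionRowCol`: a 2-column matrix (row, col); `regionIndex`: the
#'   integer index.
#' @export
regionRowCol <- function(grid, region) {
  cbind(row = (region - 1L) %/% grid@n_cols + 1L,
        col = (region - 1L) %% grid@n_cols + 1L)
}

#' @rdname regionRowCol
#' @param row,col grid row/column (vectorised).
#' @export
regionIndex <- function(grid, row, col) {
  as.integer((row - 1L) * grid@n_cols + col)
}

#' Region centre in pixel coordinates
#' @inheritParams regionRowCol
#' @return 2-column matrix (x, y) of region centres, px.
#' @export
regionCenter <- function(grid, region) {
  rc <- regionRowCol(grid, region)
  cbind(x = (rc[, "col"] - 0.5) * grid@patch_px,
        y = (rc[, "row"] - 0.5) * grid@patch_px)
}

#' Accessors for \linkS4class{ImagePair}
#' @param pair an \linkS4class{ImagePair}.
#' @return the original image array, altered image array, or logical mask.
#' @export
originalImage <- function(pair) pair@a

#' @rdname originalImage
#' @export
alteredImage <- function(pair) pair@a_prime

#' @rdname originalImage
#' @export
changeMask <- function(pair) pair@mask

#' Accessors for \linkS4class{TrialResult}
#' @param result a \linkS4class{TrialResult}.
#' @return outcome string / scanpath data.frame / detection time in seconds.
#' @export
trialOutcome <- function(result) result@outcome

#' @rdname trialOutcome
#' @export
scanPath <- function(result) result@scanpath

#' @rdname trialOutcome
#' @param params the \linkS4class{ModelParams} the trial was run with.
#' @export
detectionTime <- function(result, params) {
  result@detection_bin * params@dt_ms / 1000
}
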