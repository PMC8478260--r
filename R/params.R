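#' Construct the SPRT model parameter set
#'
#' All arguments default to the model's reference values (see
#' \linkS4class{ModelParams}). `tau_img` and `tau_blank` are separate so the
#' image/blank split can be varied while holding their sum fixed.
#'
#' @param dt_ms time bin (ms).
#' @param tau_img,tau_blank image / blank epoch durations (bins).
#' @param trial_bins total trial bins (2400 bins = 60 s at 25 ms bins).
#' @param temperature softmax temperature T (> 0).
#' @param gamma peak decay factor, in [0, 1].
#' @param beta_decay spatial decay scale (grid units).
#' @param noise_half_width half-width w of the accumulation noise U(-w, w).
#' @param prior_odds prior odds of change to no change.
#' @param f_c,f_n change / no-change evidence bounds.
#' @param zeta decay rate of the no-change bound.
#' @param fmf foveal magnification factor (CVR beta).
#' @param lambda_min,lambda_max firing-rate bounds (spikes/bin).
#' @param mu_f prior firing-rate difference (spikes/bin).
#' @param prior_scope,reset_on_fixation,check_all_regions evidence-rule
#'   switches; see \linkS4class{ModelParams}.
#' @param blur_sigma saliency blur (px).
#' @return a validated \linkS4class{ModelParams} object.
#' @examples
#' p <- modelParams()
#' p
#' @export
modelParams <- function(dt_ms = 25, tau_img = 10L, tau_blank = 10L,
                        trial_bins = 2400L, temperature = 0.01,
                        gamma = 0.004, beta_decay = 4.0,
                        noise_half_width = 5, prior_odds = 0.1,
                        f_c = 100, f_n = -20, zeta = 0, fmf = 0.05,
                        lambda_min = 5, lambda_max = 120, mu_f = 3,
                        prior_scope = "fixated", reset_on_fixation = TRUE,
                        check_all_regions = FALSE, blur_sigma = 1.6) {
  new("ModelParams", dt_ms = dt_ms, tau_img = as.integer(tau_img),
      tau_blank = as.integer(tau_blank), trial_bins = as.integer(trial_bins),
      temperature = temperature, gamma = gamma, beta_decay = beta_decay,
      noise_half_width = noise_half_width, prior_odds = prior_odds,
      f_c = f_c, f_n = f_n, zeta = zeta, fmf = fmf,
      lambda_min = lambda_min, lambda_max = lambda_max, mu_f = mu_f,
      prior_scope = prior_scope, reset_on_fixation = reset_on_fixation,
      check_all_regions = check_all_regions, blur_sigma = blur_sigma)
}

#' Construct CVR transform parameters
#'
#' The scale factors default to 200, the value tied to the reference
#' 864 x 648 px frame. [cvrParamsFor()] scales them to other image sizes so
#' the visible-field geometry (the fraction of the image reachable before the
#' transform maps beyond the frame) is preserved.
#'
#' @param center fixation centre c(x, y), px.
#' @param beta foveal magnification constant (> 0).
#' @param s_fx,s_fy scale factors (> 0).
#' @return a validated \linkS4class{CVRParams} object.
#' @export
cvrParams <- function(center, beta = 0.05, s_fx = 200, s_fy = 200) {
  new("CVRParams", beta = beta, s_fx = s_fx, s_fy = s_fy,
      center = as.numeric(center))
}

#' @rdname cvrParams
#' @param width_px,height_px size of the image the transform will act on.
#' @export
cvrParamsFor <- function(center, width_px, height_px, beta = 0.05) {
  cvrParams(center, beta = beta,
            s_fx = 200 * width_px / 864,
            s_fy = 200 * height_px / 648)
}
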