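#' Acquisition configuration for synthetic TIRF movies
#'
#' Bundles the camera/optics parameters used both to simulate trajectories
#' (frame interval, number of frames) and to render them as diffraction-limited
#' emitters. Defaults follow a typical quantum-dot TIRF acquisition of
#' spreading platelets: 12.8 Hz (78 ms/frame) with a 75-frame analysis window
#' spanning 5.8 s.
#'
#' @param frame_interval_s Seconds per frame. Default 0.078 (12.8 Hz).
#' @param n_frames Number of frames in the analysis window. Default 75.
#' @param pixel_size_um Pixel size in the sample plane, micrometres. Default 0.1.
#' @param field_size_px Integer vector `c(width, height)` in pixels.
#' @param psf_sigma_um Gaussian PSF standard deviation, micrometres. Default 0.13.
#' @param photon_rate Expected photons per emitter per on-frame. Default 300.
#' @param background_rate Expected background photons per pixel per frame. Default 20.
#' @param read_noise_sd Camera read noise standard deviation, detector units. Default 2.
#'
#' @return An object of class `acq_config` (a named list).
#' @examples
#' acq <- acq_config()
#' acq$n_frames * acq$frame_interval_s  # ~5.8 s window
#' @export
acq_config <- function(frame_interval_s = 0.078,
                       n_frames = 75,
                       pixel_size_um = 0.1,
                       field_size_px = c(128L, 128L),
                       psf_sigma_um = 0.13,
                       photon_rate = 300,
                       background_rate = 20,
                       read_noise_sd = 2) {
  stopifnot(
    "frame_interval_s must be a positive finite number" =
      is.numeric(frame_interval_s) && length(frame_interval_s) == 1L &&
      is.finite(frame_interval_s) && frame_interval_s > 0,
    "n_frames must be >= 2" = is.numeric(n_frames) && n_frames >= 2,
    "pixel_size_um must be > 0" = is.numeric(pixel_size_um) && pixel_size_um > 0,
    "psf_sigma_um must be > 0" = is.numeric(psf_sigma_um) && psf_sigma_um > 0,
    "field_size_px must be two positive integers" =
      length(field_size_px) == 2L && all(field_size_px >= 1),
    "photon_rate must be >= 0" = photon_rate >= 0,
    "background_rate must be >= 0" = background_rate >= 0,
    "read_noise_sd must be >= 0" = read_noise_sd >= 0
  )
  structure(list(
    frame_interval_s = frame_interval_s,
    n_frames = as.integer(n_frames),
    pixel_size_um = pixel_size_um,
    field_size_px = as.integer(field_size_px),
    psf_sigma_um = psf_sigma_um,
    photon_rate = photon_rate,
    background_rate = background_rate,
    read_noise_sd = read_noise_sd
  ), class = "acq_config")
}

#' Ground-truth mobility preset
#'
#' A motion preset holds the ground-truth parameters of one mobility regime:
#' the generalized diffusion coefficient `D_alpha` (um^2/s^alpha), the
#' anomalous exponent `alpha` (subdiffusive below 1, Brownian at 1), an
#' optional drift speed `v` along `axis_deg`, an optional reflecting circular
#' corral of radius `confinement_radius_um`, quantum-dot blinking kinetics and
#' localization noise.
#'
#' @param name Preset label.
#' @param D_alpha Generalized diffusion coefficient, um^2/s^alpha; >= 0.
#' @param alpha Anomalous exponent in (0, 2].
#' @param v Drift speed, um/s; >= 0.
#' @param axis_deg Drift direction, degrees (0 = +x).
#' @param confinement_radius_um Reflecting corral radius in um, `Inf` for none.
#' @param blink_off_prob Per-frame on-to-off transition probability.
#' @param blink_on_prob Per-frame off-to-on transition probability.
#' @param loc_noise_sd_um Localization noise standard deviation, um.
#'
#' @return An object of class `motion_preset`.
#' @seealso [motion_presets()] for the shipped platelet-region presets.
#' @export
motion_preset <- function(name,
                          D_alpha,
                          alpha = 1,
                          v = 0,
                          axis_deg = 0,
                          confinement_radius_um = Inf,
                          blink_off_prob = 0.1,
                          blink_on_prob = 0.3,
                          loc_noise_sd_um = 0.02) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  stopifnot(
    "D_alpha must be a finite number >= 0" = num1(D_alpha) && is.finite(D_alpha) && D_alpha >= 0,
    "alpha must be in (0, 2]" = num1(alpha) && is.finite(alpha) && alpha > 0 && alpha <= 2,
    "v must be a finite number >= 0" = num1(v) && is.finite(v) && v >= 0,
    "axis_deg must be finite" = num1(axis_deg) && is.finite(axis_deg),
    "confinement_radius_um must be > 0 (Inf for unconfined)" =
      num1(confinement_radius_um) && confinement_radius_um > 0,
    "blink probabilities must be in [0, 1]" =
      num1(blink_off_prob) && blink_off_prob >= 0 && blink_off_prob <= 1 &&
      num1(blink_on_prob) && blink_on_prob >= 0 && blink_on_prob <= 1,
    "loc_noise_sd_um must be finite and >= 0" =
      num1(loc_noise_sd_um) && is.finite(loc_noise_sd_um) && loc_noise_sd_um >= 0
  )
  structure(list(
    name = as.character(name),
    D_alpha = D_alpha, alpha = alpha, v = v, axis_deg = axis_deg,
    confinement_radius_um = confinement_radius_um,
    blink_off_prob = blink_off_prob, blink_on_prob = blink_on_prob,
    loc_noise_sd_um = loc_noise_sd_um
  ), class = "motion_preset")
}

#' Shipped platelet-region mobility presets
#'
#' Ground-truth presets for the three platelet regions and their
#' cytoskeleton-inhibition variants. Diffusion coefficients are the measured
#' region-level values for FcgammaRIIA on spreading platelets: control
#' filopodia 0.035, lamellipodia 0.034, body 0.013 um^2/s; cytochalasin-D
#' treated 0.016 / 0.014 / 0.010; blebbistatin treated 0.014 / 0.012 / 0.011.
#' Directed transport on filopodia and lamellipodia is modelled as drift at
#' 0.32 and 0.30 um/s (the scale of motor-driven / actin-treadmilling-coupled
#' transport, ~1.9 um of directional displacement over the 5.8 s window),
#' which makes the directed MSD signature identifiable on single 75-frame
#' tracks while short lags still pin the diffusion coefficient; confined
#' motion on the body is modelled as subdiffusion (alpha = 0.6) inside a
#' reflecting 0.5 um corral.
#'
#' @return Named list of [motion_preset()] objects:
#'   `filopodium`, `lamellipodium`, `body`, and `_cytoD` / `_blebb` variants.
#' @examples
#' motion_presets()$body$alpha
#' @export
motion_presets <- function() {
  fil <- function(name, D) motion_preset(name, D_alpha = D, alpha = 1, v = 0.32, axis_deg = 0)
  lam <- function(name, D) motion_preset(name, D_alpha = D, alpha = 1, v = 0.30, axis_deg = 90)
  bod <- function(name, D) motion_preset(name, D_alpha = D, alpha = 0.6, v = 0,
                                         confinement_radius_um = 0.5)
  list(
    filopodium          = fil("filopodium", 0.035),
    lamellipodium       = lam("lamellipodium", 0.034),
    body                = bod("body", 0.013),
    filopodium_cytoD    = fil("filopodium_cytoD", 0.016),
    filopodium_blebb    = fil("filopodium_blebb", 0.014),
    lamellipodium_cytoD = lam("lamellipodium_cytoD", 0.014),
    lamellipodium_blebb = lam("lamellipodium_blebb", 0.012),
    body_cytoD          = bod("body_cytoD", 0.010),
    body_blebb          = bod("body_blebb", 0.011)
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf("<acq_config> %d frames @ %.0f ms, %dx%d px (%.2f um/px), PSF sigma %.2f um\n",
              x$n_frames, 1000 * x$frame_interval_s,
              x$field_size_px[1], x$field_size_px[2],
              x$pixel_size_um, x$psf_sigma_um))
  invisible(x)
}

#' @export
print.motion_preset <- function(x, ...) {
  cat(sprintf("<motion_preset> %s: D_alpha=%.4g um^2/s^a, alpha=%.2f, v=%.3g um/s%s\n",
              x$name, x$D_alpha, x$alpha, x$v,
              if (is.finite(x$confinement_radius_um))
                sprintf(", corral %.2g um", x$confinement_radius_um) else ""))
  invisible(x)
}

# region label codes used in mask images and track tables
REGION_CODES <- c(body = 1L, lamellipodium = 2L, filopodium = 3L)
REGION_NAMES <- c("body", "lamellipodium", "filopodium")
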