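# Trajectory simulation: anomalous + directed 2D motion with optional
# reflecting corral, quantum-dot blinking, and rendering into noisy movies.

# cache of Cholesky factors of the unit-variance fGn correlation matrix,
# keyed by (alpha, n); avoids refactorizing for every trajectory
.fgn_cache <- new.env(parent = emptyenv())

# Cholesky factor (upper triangular) of the correlation matrix of n steps of
# fractional Gaussian noise with Hurst exponent H = alpha/2 and unit variance.
.fgn_chol <- function(alpha, n) {
  key <- sprintf("%.10g_%d", alpha, n)
  hit <- .fgn_cache[[key]]
  if (!is.null(hit)) return(hit)
  H2 <- alpha # 2H
  k <- 0:n
  # autocovariance of unit fGn: rho(k) = ((k+1)^2H - 2 k^2H + (k-1)^2H) / 2
  rho <- (abs(k + 1)^H2 - 2 * abs(k)^H2 + abs(k - 1)^H2) / 2
  C <- toeplitz(rho[seq_len(n)])
  R <- chol(C)
  .fgn_cache[[key]] <- R
  R
}

# n correlated fGn increments per axis, scaled so the ensemble per-axis MSD of
# the cumulative sum is 2 * D * (m*dt)^alpha (4 D t^alpha in 2D)
.fgn_increments <- function(n, D, alpha, dt) {
  if (D == 0 || n == 0) return(numeric(n))
  sd_step <- sqrt(2 * D * dt^alpha)
  if (alpha == 1) return(stats::rnorm(n, sd = sd_step))
  R <- .fgn_chol(alpha, n)
  as.vector(crossprod(R, stats::rnorm(n))) * sd_step
}

# reflect a point into a circular corral of radius R about `center`
.reflect_into_corral <- function(p, center, R) {
  for (i in 1:16) {
    d <- p - center
    r <- sqrt(sum(d^2))
    if (r <= R) return(p)
    p <- center + d * ((2 * R - r) / r)
    if (2 * R - r < 0) { # pathological overshoot: clamp to the boundary
      d <- p - center
      r <- sqrt(sum(d^2))
      if (r > R) return(center + d * (R / r))
    }
  }
  p
}

#' Simulate one ground-truth receptor trajectory
#'
#' Samples a 2D trajectory under the combined anomalous + directed diffusion
#' model: per-axis fractional Gaussian increments with Hurst exponent
#' `alpha/2`, scaled so the ensemble MSD obeys `4 * D_alpha * t^alpha`, plus a
#' deterministic drift `v * dt` along `axis_deg`. When
#' `confinement_radius_um` is finite the position is reflected back into a
#' circular corral centred on the start position after every step. Emitter
#' blinking is simulated as a two-state Markov chain starting in the on state.
#'
#' @param preset A [motion_preset()].
#' @param acq An [acq_config()]; supplies `frame_interval_s` and `n_frames`.
#' @param start_xy Numeric length-2 start position, um.
#' @param seed Optional integer seed; identical arguments and seed reproduce
#'   the trajectory exactly.
#' @param region_label Optional region tag carried through to downstream
#'   tables.
#'
#' @return A `gt_trajectory`: list with `positions` (data.frame `frame`,
#'   `x_um`, `y_um`), `on_states` (logical per frame), `region_label`,
#'   `preset_name`.
#' @examples
#' tr <- simulate_trajectory(motion_presets()$body, acq_config(), seed = 1)
#' head(tr$positions)
#' @export
simulate_trajectory <- function(preset, acq, start_xy = c(0, 0), seed = NULL,
                                region_label = NA_character_) {
  stopifnot(inherits(preset, "motion_preset"), inherits(acq, "acq_config"),
            "start_xy must be two finite numbers" =
              length(start_xy) == 2L && all(is.finite(start_xy)))
  if (!is.null(seed)) set.seed(seed)
  n_frames <- acq$n_frames
  n <- n_frames - 1L
  dt <- acq$frame_interval_s

  dx <- .fgn_increments(n, preset$D_alpha, preset$alpha, dt)
  dy <- .fgn_increments(n, preset$D_alpha, preset$alpha, dt)
  theta <- preset$axis_deg * pi / 180
  dx <- dx + preset$v * dt * cos(theta)
  dy <- dy + preset$v * dt * sin(theta)

  if (is.finite(preset$confinement_radius_um)) {
    pos <- matrix(0, n_frames, 2)
    pos[1, ] <- start_xy
    for (i in seq_len(n)) {
      p <- pos[i, ] + c(dx[i], dy[i])
      pos[i + 1L, ] <- .reflect_into_corral(p, start_xy, preset$confinement_radius_um)
    }
    x <- pos[, 1]; y <- pos[, 2]
  } else {
    x <- start_xy[1] + cumsum(c(0, dx))
    y <- start_xy[2] + cumsum(c(0, dy))
  }

  on <- logical(n_frames)
  on[1] <- TRUE
  if (n_frames > 1L) {
    u <- stats::runif(n_frames - 1L)
    for (i in 2:n_frames) {
      on[i] <- if (on[i - 1L]) u[i - 1L] >= preset$blink_off_prob
               else u[i - 1L] < preset$blink_on_prob
    }
  }

  structure(list(
    positions = data.frame(frame = 0:(n_frames - 1L), x_um = x, y_um = y),
    on_states = on,
    region_label = region_label,
    preset_name = preset$name
  ), class = "gt_trajectory")
}

#' Simulate a table of observed tracks from one preset
#'
#' Convenience wrapper over [simulate_trajectory()] that produces a tidy
#' track table in the same dialect the tracking module emits: one row per
#' localized spot with columns `track_id`, `frame`, `x_um`, `y_um`,
#' `region_label`. Localization noise (Gaussian, `loc_noise_sd_um`) is added
#' to the true positions to mimic detection; with `blinking = TRUE` off-frames
#' are dropped, leaving gaps.
#'
#' @param preset A [motion_preset()].
#' @param n_tracks Number of trajectories.
#' @param acq An [acq_config()].
#' @param seed Optional integer seed.
#' @param start_xy Start position shared by all tracks (positions are relative;
#'   mobility statistics are translation invariant).
#' @param localization_noise Add Gaussian localization noise? Default TRUE.
#' @param blinking Drop blink-off frames (leaving gaps)? Default FALSE.
#' @param region_label Region tag for all tracks; defaults to the preset name.
#'
#' @return A data.frame of localized spots, plus attribute `"truth"` holding
#'   the noiseless ground-truth table.
#' @export
simulate_tracks <- function(preset, n_tracks, acq, seed = NULL,
                            start_xy = c(0, 0), localization_noise = TRUE,
                            blinking = FALSE,
                            region_label = preset$name) {
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", n_tracks)
  truth <- vector("list", n_tracks)
  for (i in seq_len(n_tracks)) {
    tr <- simulate_trajectory(preset, acq, start_xy = start_xy,
                              region_label = region_label)
    df <- tr$positions
    df$on_state <- tr$on_states
    df$track_id <- i
    df$region_label <- region_label
    truth[[i]] <- df
    obs <- df
    if (blinking) obs <- obs[obs$on_state, , drop = FALSE]
    if (localization_noise && preset$loc_noise_sd_um > 0) {
      obs$x_um <- obs$x_um + stats::rnorm(nrow(obs), sd = preset$loc_noise_sd_um)
      obs$y_um <- obs$y_um + stats::rnorm(nrow(obs), sd = preset$loc_noise_sd_um)
    }
    out[[i]] <- obs[, c("track_id", "frame", "x_um", "y_um", "region_label")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "truth") <- do.call(rbind, truth)
  res
}

#' Generate a platelet-like region label mask
#'
#' Builds a labeled image partitioning the field into a circular platelet
#' body, a surrounding lamellipodial rim (annulus) and radial filopodium rods
#' emanating from the rim, emulating the region assignment of a spread
#' platelet in a TIRF image. Label codes: 0 background, 1 body,
#' 2 lamellipodium, 3 filopodium.
#'
#' @param geometry Named list of geometry parameters (um):
#'   `body_radius_um` (default 2), `rim_outer_um` (3.5), `n_filopodia` (6),
#'   `filopodium_length_um` (4), `filopodium_width_um` (0.4), and optionally
#'   `center_um` (defaults to the field centre).
#' @param acq An [acq_config()] supplying field size and pixel size.
#' @param seed Optional seed for the random angular offset of the filopodia
#'   (rods are evenly spaced with a seeded rotation).
#'
#' @return A `region_mask`: list with `label_image` (integer matrix, rows =
#'   y), `geometry`, `pixel_size_um` and `region_codes`.
#' @export
make_region_mask <- function(geometry = list(), acq = acq_config(), seed = NULL) {
  g <- utils::modifyList(list(
    body_radius_um = 2, rim_outer_um = 3.5, n_filopodia = 6L,
    filopodium_length_um = 4, filopodium_width_um = 0.4, center_um = NULL
  ), geometry)
  ps <- acq$pixel_size_um
  w <- acq$field_size_px[1]; h <- acq$field_size_px[2]
  ext_x <- (w - 1) * ps; ext_y <- (h - 1) * ps
  if (is.null(g$center_um)) g$center_um <- c(ext_x, ext_y) / 2
  if (!(g$body_radius_um < g$rim_outer_um))
    stop("geometry error: body_radius_um must be < rim_outer_um")
  reach <- g$rim_outer_um + if (g$n_filopodia > 0) g$filopodium_length_um else 0
  max_reach <- min(g$center_um[1], ext_x - g$center_um[1],
                   g$center_um[2], ext_y - g$center_um[2])
  if (reach > max_reach)
    stop("geometry error: body + rim + filopodia exceed the field extent")

  if (!is.null(seed)) set.seed(seed)
  xs <- (0:(w - 1)) * ps - g$center_um[1]
  ys <- (0:(h - 1)) * ps - g$center_um[2]
  X <- matrix(xs, h, w, byrow = TRUE)
  Y <- matrix(ys, h, w)
  d <- sqrt(X^2 + Y^2)
  lab <- matrix(0L, h, w)
  lab[d <= g$rim_outer_um] <- REGION_CODES[["lamellipodium"]]
  lab[d <= g$body_radius_um] <- REGION_CODES[["body"]]

  if (g$n_filopodia > 0) {
    offset <- stats::runif(1, 0, 2 * pi)
    ang <- offset + 2 * pi * (seq_len(g$n_filopodia) - 1) / g$n_filopodia
    hw <- g$filopodium_width_um / 2
    r0 <- g$rim_outer_um - ps # rod base just inside the rim so it touches it
    r1 <- g$rim_outer_um + g$filopodium_length_um
    for (a in ang) {
      u <- c(cos(a), sin(a))
      # signed distance along / across the rod axis
      s <- X * u[1] + Y * u[2]
      q <- abs(-X * u[2] + Y * u[1])
      hit <- s >= r0 & s <= r1 & q <= hw & lab == 0L
      lab[hit] <- REGION_CODES[["filopodium"]]
    }
  }
  structure(list(label_image = lab, geometry = g, pixel_size_um = ps,
                 region_codes = REGION_CODES), class = "region_mask")
}

# pixel-integrated Gaussian PSF: photon fractions over pixel columns/rows
.psf_profile <- function(idx, center_um, ps, sigma) {
  stats::pnorm((idx + 0.5) * ps, mean = center_um, sd = sigma) -
    stats::pnorm((idx - 0.5) * ps, mean = center_um, sd = sigma)
}

#' Render trajectories into a noisy blinking-emitter movie
#'
#' Each on-state emitter is rendered as a pixel-integrated 2D Gaussian of
#' standard deviation `psf_sigma_um` carrying `photon_rate` expected photons;
#' per-pixel photon shot noise is Poisson on signal plus background, with
#' additive Gaussian read noise. Off-frames contribute background only.
#'
#' @param trajectories List of `gt_trajectory` objects (from
#'   [simulate_trajectory()]).
#' @param acq An [acq_config()].
#' @param seed Optional integer seed for the noise.
#' @param poisson_noise Apply Poisson shot noise? Disable for noiseless
#'   reference renders. Default TRUE.
#'
#' @return An `spt_movie`: list with `stack` (numeric array height x width x
#'   frames, photon counts) and `truth` (data.frame `trajectory_id`, `frame`,
#'   `x_um`, `y_um`, `on_state`, `region_label`).
#' @export
render_movie <- function(trajectories, acq, seed = NULL, poisson_noise = TRUE) {
  stopifnot(inherits(acq, "acq_config"))
  if (!is.null(seed)) set.seed(seed)
  ps <- acq$pixel_size_um
  w <- acq$field_size_px[1]; h <- acq$field_size_px[2]
  nf <- acq$n_frames
  sigma <- acq$psf_sigma_um
  win <- ceiling(4 * sigma / ps)

  for (tr in trajectories) {
    p <- tr$positions
    if (any(p$x_um < -ps / 2 | p$x_um > (w - 0.5) * ps |
            p$y_um < -ps / 2 | p$y_um > (h - 0.5) * ps))
      stop("trajectory leaves the imaging field; enlarge field_size_px or move start_xy")
  }

  stack <- array(0, dim = c(h, w, nf))
  truth <- vector("list", length(trajectories))
  for (k in seq_along(trajectories)) {
    tr <- trajectories[[k]]
    p <- tr$positions
    for (i in seq_len(nrow(p))) {
      f <- p$frame[i] + 1L
      if (f > nf || !tr$on_states[i]) next
      cx <- p$x_um[i] / ps; cy <- p$y_um[i] / ps
      c0 <- round(cx); r0 <- round(cy)
      cols <- max(0, c0 - win):min(w - 1, c0 + win)
      rows <- max(0, r0 - win):min(h - 1, r0 + win)
      fx <- .psf_profile(cols, p$x_um[i], ps, sigma)
      fy <- .psf_profile(rows, p$y_um[i], ps, sigma)
      stack[rows + 1L, cols + 1L, f] <-
        stack[rows + 1L, cols + 1L, f] + acq$photon_rate * outer(fy, fx)
    }
    truth[[k]] <- data.frame(trajectory_id = k, frame = p$frame,
                             x_um = p$x_um, y_um = p$y_um,
                             on_state = tr$on_states,
                             region_label = tr$region_label)
  }

  expected <- stack + acq$background_rate
  if (poisson_noise) {
    stack <- array(stats::rpois(length(expected), expected), dim = dim(expected))
  } else {
    stack <- expected
  }
  if (acq$read_noise_sd > 0) {
    stack <- stack + array(stats::rnorm(length(stack), sd = acq$read_noise_sd),
                           dim = dim(stack))
    stack[stack < 0] <- 0
  }
  structure(list(stack = stack,
                 truth = if (length(truth)) do.call(rbind, truth) else
                   data.frame(trajectory_id = integer(), frame = integer(),
                              x_um = numeric(), y_um = numeric(),
                              on_state = logical(), region_label = character())),
            class = "spt_movie")
}
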