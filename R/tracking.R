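# Track recovery from movies: Laplacian-of-Gaussian spot detection with
# subpixel refinement, phase-correlation drift estimation, and greedy
# gap-closing nearest-neighbour linking.

.log_kernel <- function(sigma_px) {
  w <- ceiling(4 * sigma_px)
  idx <- -w:w
  X <- matrix(idx, length(idx), length(idx), byrow = TRUE)
  Y <- t(X)
  r2 <- X^2 + Y^2
  k <- (r2 - 2 * sigma_px^2) / sigma_px^4 * exp(-r2 / (2 * sigma_px^2))
  k - mean(k) # zero-sum: flat background gives zero response
}

# value of the strict 8-neighbourhood maximum at every pixel
.neighbour_max <- function(m) {
  h <- nrow(m); w <- ncol(m)
  pad <- matrix(-Inf, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shifts <- list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0),
                 c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  out <- matrix(-Inf, h, w)
  for (s in shifts)
    out <- pmax(out, pad[2:(h + 1) + s[1], 2:(w + 1) + s[2]])
  out
}

#' Detect emitter spots in one frame
#'
#' Laplacian-of-Gaussian blob detection matched to the PSF width: local maxima
#' of the (sign-flipped, scale-normalized) LoG response above
#' `quality_threshold` are refined to subpixel position by a Gaussian-weighted
#' intensity centroid in a `2*ceil(2*sigma)+1` pixel window. No two reported
#' spots lie closer than `2*sigma` (the brighter response wins). Spot
#' intensity is the background-annulus-subtracted sum inside a `3*sigma`
#' radius.
#'
#' @param image Numeric matrix (rows = y), e.g. one plane of a movie stack.
#' @param psf_sigma_um PSF standard deviation, um.
#' @param pixel_size_um Pixel size, um.
#' @param quality_threshold Minimum LoG response; `NULL` (default) estimates a
#'   robust noise floor as `median + 5 * MAD` of the response image.
#'
#' @return Data.frame of spots: `x_um`, `y_um`, `intensity`, `quality`.
#'   Empty (zero rows) when nothing exceeds the threshold.
#' @export
detect_spots <- function(image, psf_sigma_um, pixel_size_um,
                         quality_threshold = NULL) {
  stopifnot(is.matrix(image), psf_sigma_um > 0, pixel_size_um > 0)
  s_px <- psf_sigma_um / pixel_size_um
  kern <- .log_kernel(s_px)
  resp <- -s_px^2 * EBImage::filter2(image, kern, boundary = "replicate")
  resp <- as.matrix(resp)
  if (is.null(quality_threshold))
    quality_threshold <- stats::median(resp) + 5 * stats::mad(resp)

  is_max <- resp > .neighbour_max(resp) & resp >= quality_threshold
  # exclude a border margin where the centroid window would fall off the image
  w_sub <- ceiling(2 * s_px)
  margin <- w_sub + 1L
  h <- nrow(image); wd <- ncol(image)
  if (h <= 2 * margin || wd <= 2 * margin) return(.empty_spots())
  keep <- matrix(FALSE, h, wd)
  keep[(margin + 1):(h - margin), (margin + 1):(wd - margin)] <- TRUE
  is_max <- is_max & keep
  if (!any(is_max)) return(.empty_spots())

  idx <- which(is_max, arr.ind = TRUE)
  q <- resp[is_max]
  ord <- order(q, decreasing = TRUE)
  idx <- idx[ord, , drop = FALSE]; q <- q[ord]
  # non-maximum suppression: drop candidates within 2*sigma of a kept spot
  min_sep2 <- (2 * s_px)^2
  kept <- logical(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    ok <- TRUE
    if (any(kept)) {
      j <- which(kept)
      d2 <- (idx[j, 1] - idx[i, 1])^2 + (idx[j, 2] - idx[i, 2])^2
      ok <- all(d2 >= min_sep2)
    }
    kept[i] <- ok
  }
  idx <- idx[kept, , drop = FALSE]; q <- q[kept]

  gw <- exp(-((-w_sub:w_sub)^2) / (2 * s_px^2))
  G <- outer(gw, gw)
  r_int <- ceiling(3 * s_px)
  res <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    r0 <- idx[i, 1]; c0 <- idx[i, 2]
    rows <- (r0 - w_sub):(r0 + w_sub)
    cols <- (c0 - w_sub):(c0 + w_sub)
    patch <- image[rows, cols]
    wts <- pmax(patch - min(patch), 0) * G
    sw <- sum(wts)
    cy <- if (sw > 0) sum(wts * (rows - 1)) / sw else r0 - 1
    cx <- if (sw > 0) sum(wts * t(matrix(cols - 1, length(cols), length(rows)))) / sw else c0 - 1
    # integrated intensity minus local background from the surrounding annulus
    rr <- max(1, r0 - 2 * r_int):min(h, r0 + 2 * r_int)
    cc <- max(1, c0 - 2 * r_int):min(wd, c0 + 2 * r_int)
    d2 <- outer((rr - r0)^2, (cc - c0)^2, "+")
    disc <- d2 <= r_int^2
    annulus <- d2 > r_int^2 & d2 <= (2 * r_int)^2
    bg <- if (any(annulus)) stats::median(image[rr, cc][annulus]) else 0
    res[[i]] <- c(cx * pixel_size_um, cy * pixel_size_um,
                  sum(image[rr, cc][disc]) - bg * sum(disc), q[i])
  }
  m <- do.call(rbind, res)
  data.frame(x_um = m[, 1], y_um = m[, 2], intensity = m[, 3], quality = m[, 4])
}

.empty_spots <- function() {
  data.frame(x_um = numeric(), y_um = numeric(),
             intensity = numeric(), quality = numeric())
}

#' Detect spots in every frame of a movie stack
#'
#' @param stack Numeric array height x width x frames, or an `spt_movie`.
#' @param acq An [acq_config()] supplying PSF width and pixel size.
#' @param quality_threshold Passed to [detect_spots()].
#' @return Data.frame of spots with a 0-based `frame` column.
#' @export
detect_spots_stack <- function(stack, acq, quality_threshold = NULL) {
  if (inherits(stack, "spt_movie")) stack <- stack$stack
  out <- lapply(seq_len(dim(stack)[3]), function(f) {
    sp <- detect_spots(stack[, , f], acq$psf_sigma_um, acq$pixel_size_um,
                       quality_threshold)
    if (nrow(sp)) sp$frame <- f - 1L else sp$frame <- integer()
    sp
  })
  res <- do.call(rbind, out)
  res[, c("frame", "x_um", "y_um", "intensity", "quality")]
}

# Fourier cross-correlation between two equal-size real images; returns the
# (dy, dx) shift of `b` relative to `a` in pixels, subpixel by 3-point
# parabolic fit (exact for the smooth Gaussian-splat maps used here, where a
# whitened phase-correlation peak would be too sharp to interpolate)
.phase_corr_shift <- function(a, b) {
  Fa <- stats::fft(a); Fb <- stats::fft(b)
  R <- Fa * Conj(Fb)
  r <- Re(stats::fft(R, inverse = TRUE)) / length(a)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  n <- dim(r)
  wrap <- function(i, m) ifelse(i - 1 > m / 2, i - 1 - m, i - 1)
  para <- function(rm, rz, rp) { # vertex offset in [-0.5, 0.5]
    # log-parabola is exact for a Gaussian correlation peak; fall back to a
    # plain parabola when a neighbour is non-positive
    if (rm > 0 && rz > 0 && rp > 0) { rm <- log(rm); rz <- log(rz); rp <- log(rp) }
    den <- rm - 2 * rz + rp
    if (abs(den) < 1e-12) 0 else max(-0.5, min(0.5, 0.5 * (rm - rp) / den))
  }
  ii <- pk[1]; jj <- pk[2]
  im <- if (ii == 1) n[1] else ii - 1; ip <- if (ii == n[1]) 1 else ii + 1
  jm <- if (jj == 1) n[2] else jj - 1; jp <- if (jj == n[2]) 1 else jj + 1
  dy <- wrap(ii, n[1]) + para(r[im, jj], r[ii, jj], r[ip, jj])
  dx <- wrap(jj, n[2]) + para(r[ii, jm], r[ii, jj], r[ii, jp])
  # peak at +s means b is a copy of a shifted by -s; flip to "b relative to a"
  c(dy = -dy, dx = -dx)
}

.rasterize_spots <- function(sp, acq, splat_sigma_px = 1) {
  h <- acq$field_size_px[2]; w <- acq$field_size_px[1]
  m <- matrix(0, h, w)
  ps <- acq$pixel_size_um
  for (i in seq_len(nrow(sp))) {
    cx <- sp$x_um[i] / ps; cy <- sp$y_um[i] / ps
    lc <- max(0, round(cx) - 4); hc <- min(w - 1, round(cx) + 4)
    lr <- max(0, round(cy) - 4); hr <- min(h - 1, round(cy) + 4)
    if (lc > hc || lr > hr) next # spot outside the rasterized field
    cols <- lc:hc
    rows <- lr:hr
    m[rows + 1L, cols + 1L] <- m[rows + 1L, cols + 1L] +
      outer(exp(-(rows - cy)^2 / (2 * splat_sigma_px^2)),
            exp(-(cols - cx)^2 / (2 * splat_sigma_px^2)))
  }
  m
}

#' Estimate per-frame lateral stage drift from detected spots
#'
#' Rasterizes each frame's spots as Gaussian splats and cross-correlates
#' consecutive maps in the Fourier domain (with parabolic subpixel peak
#' interpolation); per-frame displacements are median-smoothed and
#' accumulated into a cumulative drift curve. Frames without spots get
#' linearly interpolated drift.
#'
#' @param spots Data.frame with `frame`, `x_um`, `y_um` (0-based frames).
#' @param acq An [acq_config()] (field size, pixel size).
#' @param smooth_k Odd window for the running-median smoother; default 5.
#' @return Data.frame `frame`, `dx_um`, `dy_um`: cumulative drift of each
#'   frame relative to the first.
#' @export
estimate_drift <- function(spots, acq, smooth_k = 5) {
  frames <- seq(min(spots$frame), max(spots$frame))
  with_spots <- frames[frames %in% unique(spots$frame)]
  if (length(with_spots) < 2L)
    stop("insufficient frames: drift estimation needs >= 2 frames with spots")
  maps <- lapply(frames, function(f)
    .rasterize_spots(spots[spots$frame == f, , drop = FALSE], acq))
  nonempty <- vapply(maps, function(m) any(m > 0), logical(1))
  nF <- length(frames)
  dxy <- matrix(NA_real_, nF, 2)
  dxy[1, ] <- 0
  for (i in 2:nF) {
    if (nonempty[i - 1] && nonempty[i])
      dxy[i, ] <- rev(.phase_corr_shift(maps[[i - 1]], maps[[i]])) # (dx, dy)
  }
  fill <- function(v) { # linear interpolation across empty frames
    if (anyNA(v))
      v <- stats::approx(which(!is.na(v)), v[!is.na(v)], xout = seq_along(v),
                         rule = 2)$y
    v
  }
  dx <- fill(dxy[, 1]); dy <- fill(dxy[, 2])
  if (nF > smooth_k) {
    dx[-1] <- stats::runmed(dx[-1], smooth_k)
    dy[-1] <- stats::runmed(dy[-1], smooth_k)
  }
  ps <- acq$pixel_size_um
  data.frame(frame = frames, dx_um = cumsum(dx) * ps, dy_um = cumsum(dy) * ps)
}

#' Subtract estimated drift from spot positions
#' @param spots Data.frame with `frame`, `x_um`, `y_um`.
#' @param drift Output of [estimate_drift()].
#' @return `spots` with corrected positions.
#' @export
apply_drift <- function(spots, drift) {
  i <- match(spots$frame, drift$frame)
  spots$x_um <- spots$x_um - drift$dx_um[i]
  spots$y_um <- spots$y_um - drift$dy_um[i]
  spots
}

#' Link spots into tracks with gap closing
#'
#' Greedy nearest-neighbour linking: candidate (track end, spot) pairs within
#' the distance budget are assigned in order of ascending distance (ties
#' broken by lower spot index), each spot used at most once. A track end
#' missing from up to `max_gap_frames` consecutive frames stays eligible, with
#' the distance budget scaled to `max_link_dist_um * (gap + 1)` — this closes
#' the gaps quantum-dot blinking leaves. Tracks with fewer than
#' `min_spots` localized spots are discarded.
#'
#' @param spots Data.frame with `frame`, `x_um`, `y_um` (drift-corrected).
#' @param max_link_dist_um Maximum consecutive-frame link distance, um.
#'   Default 0.38 = 3 * sqrt(4 * D_max * dt) at D_max 0.05 um^2/s, dt 0.078 s.
#' @param max_gap_frames Maximum number of skipped frames to bridge. Default 2.
#' @param min_spots Minimum spots per reported track. Default 5 (at least 4
#'   MSD lags).
#' @return Data.frame of the input spots with a `track_id` column, ordered by
#'   track then frame; spots in discarded short tracks are dropped.
#' @export
link_tracks <- function(spots, max_link_dist_um = 0.38, max_gap_frames = 2L,
                        min_spots = 5L) {
  if (!nrow(spots)) {
    spots$track_id <- integer()
    return(spots)
  }
  spots <- spots[order(spots$frame), , drop = FALSE]
  n <- nrow(spots)
  track_of <- integer(n)
  # active ends: row index of the last spot of each open track
  end_rows <- integer(0)
  next_track <- 1L
  for (f in seq(min(spots$frame), max(spots$frame))) {
    rows_f <- which(spots$frame == f)
    if (length(end_rows)) {
      gap <- f - spots$frame[end_rows] - 1L
      end_rows <- end_rows[gap <= max_gap_frames]
    }
    if (length(rows_f) && length(end_rows)) {
      gap <- f - spots$frame[end_rows] - 1L
      budget <- max_link_dist_um * (gap + 1)
      dx <- outer(spots$x_um[end_rows], spots$x_um[rows_f], "-")
      dy <- outer(spots$y_um[end_rows], spots$y_um[rows_f], "-")
      dmat <- sqrt(dx^2 + dy^2)
      ok <- which(dmat <= budget, arr.ind = TRUE)
      if (nrow(ok)) {
        ord <- order(dmat[ok], rows_f[ok[, 2]])
        ok <- ok[ord, , drop = FALSE]
        used_end <- logical(length(end_rows))
        used_spot <- logical(length(rows_f))
        for (p in seq_len(nrow(ok))) {
          ei <- ok[p, 1]; si <- ok[p, 2]
          if (used_end[ei] || used_spot[si]) next
          used_end[ei] <- TRUE; used_spot[si] <- TRUE
          r <- rows_f[si]
          track_of[r] <- track_of[end_rows[ei]]
          end_rows[ei] <- r # the linked spot becomes the track's new end
        }
        for (si in which(!used_spot)) {
          r <- rows_f[si]
          track_of[r] <- next_track
          next_track <- next_track + 1L
          end_rows <- c(end_rows, r)
        }
      } else {
        for (r in rows_f) {
          track_of[r] <- next_track
          next_track <- next_track + 1L
          end_rows <- c(end_rows, r)
        }
      }
    } else if (length(rows_f)) {
      for (r in rows_f) {
        track_of[r] <- next_track
        next_track <- next_track + 1L
        end_rows <- c(end_rows, r)
      }
    }
  }
  spots$track_id <- track_of
  counts <- table(track_of)
  keep <- spots$track_id %in% as.integer(names(counts)[counts >= min_spots])
  spots <- spots[keep, , drop = FALSE]
  spots$track_id <- as.integer(factor(spots$track_id))
  spots <- spots[order(spots$track_id, spots$frame), , drop = FALSE]
  rownames(spots) <- NULL
  spots
}
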