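# Per-track mobility quantification: time-averaged MSD, the combined
# anomalous + directed diffusion model MSD(t) = 4 D t^alpha + v^2 t^2,
# track length, motion classification and region assignment.

#' Time-averaged mean squared displacement of one track
#'
#' Overlapping-pair estimator: for each lag of n frames, the mean squared
#' Euclidean displacement over all spot pairs separated by exactly n frames.
#' Gaps (missing frames from blinking) simply contribute no pairs at the
#' affected lags; lags with zero pairs are omitted. Lags are limited to
#' `ceil(max_lag_fraction * span)` frames (at least `min_lags`), restricting
#' the fit to the well-supported short-lag regime.
#'
#' @param track Data.frame of one track with columns `frame`, `x_um`, `y_um`.
#' @param frame_interval_s Seconds per frame.
#' @param max_lag_fraction Fraction of the track's frame span to keep.
#'   Default 0.25.
#' @param min_lags Minimum number of lags retained. Default 4.
#'
#' @return An `msd_curve`: data.frame `lag_s`, `msd_um2`, `n_pairs`.
#' @examples
#' tr <- data.frame(frame = 0:9, x_um = 0.1 * (0:9), y_um = 0)
#' compute_msd(tr, frame_interval_s = 1)
#' @export
compute_msd <- function(track, frame_interval_s, max_lag_fraction = 0.25,
                        min_lags = 4L) {
  stopifnot(all(c("frame", "x_um", "y_um") %in% names(track)),
            frame_interval_s > 0)
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 5L)
    stop("insufficient data: MSD needs a track with >= 5 localized spots")
  if (anyDuplicated(track$frame))
    stop("track has duplicated frames")
  span <- max(track$frame) - min(track$frame)
  max_lag <- max(as.integer(min_lags), ceiling(max_lag_fraction * span))
  max_lag <- min(max_lag, span)
  f <- track$frame
  lag_s <- msd <- np <- numeric(0)
  for (n in seq_len(max_lag)) {
    j <- match(f + n, f)
    ok <- !is.na(j)
    if (!any(ok)) next
    d2 <- (track$x_um[j[ok]] - track$x_um[ok])^2 +
          (track$y_um[j[ok]] - track$y_um[ok])^2
    lag_s <- c(lag_s, n * frame_interval_s)
    msd <- c(msd, mean(d2))
    np <- c(np, sum(ok))
  }
  structure(data.frame(lag_s = lag_s, msd_um2 = msd, n_pairs = np),
            class = c("msd_curve", "data.frame"))
}

#' Ensemble mean squared displacement of many tracks
#'
#' Displacement from each track's first localized position, averaged across
#' tracks at each lag; a diagnostic complement to the per-track time-averaged
#' estimator.
#'
#' @param tracks Data.frame with `track_id`, `frame`, `x_um`, `y_um`.
#' @param frame_interval_s Seconds per frame.
#' @return Data.frame `lag_s`, `msd_um2`, `n_tracks`.
#' @export
ensemble_msd <- function(tracks, frame_interval_s) {
  sp <- split(tracks, tracks$track_id)
  per <- lapply(sp, function(tr) {
    tr <- tr[order(tr$frame), , drop = FALSE]
    data.frame(lag = tr$frame - tr$frame[1],
               d2 = (tr$x_um - tr$x_um[1])^2 + (tr$y_um - tr$y_um[1])^2)
  })
  all <- do.call(rbind, per)
  all <- all[all$lag > 0, , drop = FALSE]
  agg <- stats::aggregate(d2 ~ lag, data = all, FUN = mean)
  cnt <- stats::aggregate(d2 ~ lag, data = all, FUN = length)
  data.frame(lag_s = agg$lag * frame_interval_s, msd_um2 = agg$d2,
             n_tracks = cnt$d2)
}

#' Fit the combined anomalous + directed diffusion model to an MSD curve
#'
#' Weighted nonlinear least squares of `MSD(t) = 4 * D * t^alpha + v^2 * t^2`
#' with weights equal to the displacement-pair counts, bounds `D >= 0`,
#' `alpha` in (0.1, 2], `v >= 0`, and a deterministic multi-start over
#' `alpha0` in {0.5, 1, 1.5} crossed with `v0` in {0, v_init}; the start with
#' the lowest weighted residual sum of squares wins. An exactly zero curve
#' (stationary track) short-circuits to `D = 0, v = 0`.
#'
#' @param curve An `msd_curve` from [compute_msd()] (or any data.frame with
#'   `lag_s`, `msd_um2`, `n_pairs`).
#' @param drop_first_lag Drop the first lag before fitting (mitigates
#'   localization-noise inflation of short lags)? Default FALSE: the model
#'   carries no constant offset term, matching the MSD equation as used.
#'
#' @return A `mobility_fit`: list with `D` (um^2/s^alpha, reported in
#'   summaries as um^2/s), `alpha`, `v` (um/s), `rss` (weighted), `n_lags_fit`,
#'   `converged`, and `motion_class` ([classify_motion()] applied to the
#'   fitted curve; [analyze_tracks()] reclassifies on the full-lag curve).
#' @examples
#' t <- (1:10) * 0.078
#' fit_msd_model(data.frame(lag_s = t, msd_um2 = 4 * 0.03 * t,
#'                          n_pairs = rep(50, 10)))
#' @export
fit_msd_model <- function(curve, drop_first_lag = FALSE) {
  stopifnot(all(c("lag_s", "msd_um2", "n_pairs") %in% names(curve)))
  if (drop_first_lag && nrow(curve) > 4L) curve <- curve[-1L, , drop = FALSE]
  if (nrow(curve) < 4L)
    stop("insufficient data: model fit needs >= 4 MSD lags")
  t <- curve$lag_s; y <- curve$msd_um2; w <- curve$n_pairs

  finish <- function(D, alpha, v, rss, converged) {
    fit <- structure(list(D = D, alpha = alpha, v = v, rss = rss,
                          n_lags_fit = length(t), converged = converged,
                          motion_class = NA_character_),
                     class = "mobility_fit")
    fit$motion_class <- classify_motion(fit, curve)
    fit
  }

  if (all(abs(y) < 1e-14)) return(finish(0, 1, 0, 0, TRUE))

  v_init <- sqrt(max(y)) / max(t)
  D1 <- max(y[1] / (4 * t[1]), 1e-8)
  best <- NULL
  for (a0 in c(0.5, 1, 1.5)) for (v0 in c(0, v_init)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ 4 * D * t^alpha + v^2 * t^2,
        start = list(D = D1, alpha = a0, v = v0),
        lower = c(D = 0, alpha = 0.1, v = 0),
        upper = c(D = Inf, alpha = 2, v = Inf),
        weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL)
    if (is.null(fit)) next
    dev <- stats::deviance(fit)
    if (is.null(best) || dev < best$dev)
      best <- list(par = stats::coef(fit), dev = dev)
  }
  if (is.null(best)) return(finish(NA_real_, NA_real_, NA_real_, NA_real_, FALSE))
  p <- best$par
  finish(unname(p["D"]), unname(p["alpha"]), unname(p["v"]), best$dev, TRUE)
}

#' @export
print.mobility_fit <- function(x, ...) {
  cat(sprintf("<mobility_fit> D=%.4g um^2/s, alpha=%.3f, v=%.3g um/s, class=%s (rss %.3g, %d lags)\n",
              x$D, x$alpha, x$v, x$motion_class, x$rss, x$n_lags_fit))
  invisible(x)
}

#' Track length: total summed displacement
#'
#' `L = sum over consecutive localized spots of sqrt(dx^2 + dy^2)`; a gap from
#' blinking is bridged as a single displacement. Distinct from the net
#' (start-to-end) displacement, which it always bounds from above.
#'
#' @param track Data.frame of one track with `frame`, `x_um`, `y_um`.
#' @return Track length in um.
#' @examples
#' track_length(data.frame(frame = 0:1, x_um = c(0, 3), y_um = c(0, 4))) # 5
#' @export
track_length <- function(track) {
  track <- track[order(track$frame), , drop = FALSE]
  if (nrow(track) < 2L)
    stop("insufficient data: track length needs >= 2 spots")
  sum(sqrt(diff(track$x_um)^2 + diff(track$y_um)^2))
}

#' Classify the motion mode of a track from its MSD curve
#'
#' Formalizes the qualitative read of an MSD curve's shape: the curve's tail
#' (mean MSD over the last 20% of lags) is compared with the linear (free
#' Brownian) extrapolation `4 * D1 * t` of its first lags, where `D1` is the
#' apparent short-lag diffusion coefficient (mean of `msd / (4 t)` over the
#' first `n_ref_lags` lags). A supra-linear tail
#' (`ratio >= ratio_directed`, default 1.5) is directed transport; a
#' sub-linear, plateauing tail (`ratio <= ratio_confined`, default 0.5) is
#' confined motion; curves tracking the linear extrapolation are Brownian.
#' Non-converged fits return `"unclassified"`; an immobile track (MSD
#' identically 0) is reported as confined.
#'
#' For reliable discrimination pass the full-lag curve
#' (`compute_msd(..., max_lag_fraction = 1)`), where directed and confined
#' signatures are strongest; [analyze_tracks()] does this.
#'
#' @param fit A `mobility_fit` (used for the convergence gate).
#' @param curve The `msd_curve` to classify.
#' @param ratio_directed Tail-to-linear ratio at or above which motion is
#'   directed. Default 1.5.
#' @param ratio_confined Tail-to-linear ratio at or below which motion is
#'   confined. Default 0.5.
#' @param n_ref_lags Number of leading lags defining the short-lag reference
#'   slope. Default 4.
#' @return One of `"directed"`, `"confined"`, `"brownian"`, `"unclassified"`.
#' @export
classify_motion <- function(fit, curve, ratio_directed = 1.5,
                            ratio_confined = 0.5, n_ref_lags = 4L) {
  if (!isTRUE(fit$converged) || is.na(fit$D)) return("unclassified")
  n <- nrow(curve)
  k <- min(as.integer(n_ref_lags), n)
  D1 <- mean(curve$msd_um2[1:k] / (4 * curve$lag_s[1:k]))
  if (D1 <= 0) return("confined") # immobile
  m <- max(1L, ceiling(0.2 * n))
  idx <- (n - m + 1L):n
  ratio <- mean(curve$msd_um2[idx]) / (4 * D1 * mean(curve$lag_s[idx]))
  if (ratio >= ratio_directed) return("directed")
  if (ratio <= ratio_confined) return("confined")
  "brownian"
}

#' Assign a track to a platelet region
#'
#' Majority vote of the region labels under the track's spot positions; ties
#' broken by precedence filopodium > lamellipodium > body. Tracks whose
#' majority position lies on background are labeled `"off-cell"`.
#'
#' @param track Data.frame of one track with `x_um`, `y_um`.
#' @param mask A `region_mask` from [make_region_mask()].
#' @return Region label string.
#' @export
assign_region <- function(track, mask) {
  stopifnot(inherits(mask, "region_mask"))
  lab <- mask$label_image
  ps <- mask$pixel_size_um
  col <- pmin(pmax(round(track$x_um / ps), 0), ncol(lab) - 1L) + 1L
  row <- pmin(pmax(round(track$y_um / ps), 0), nrow(lab) - 1L) + 1L
  codes <- lab[cbind(row, col)]
  tab <- tabulate(codes + 1L, nbins = 4L) # counts for codes 0..3
  best <- max(tab)
  if (tab[1] == best && all(tab[2:4] < best)) return("off-cell")
  # precedence on ties: filopodium (3) > lamellipodium (2) > body (1)
  for (code in c(3L, 2L, 1L)) if (tab[code + 1L] == max(tab[2:4])) {
    if (tab[code + 1L] >= tab[1]) return(REGION_NAMES[code])
  }
  "off-cell"
}

#' Per-track mobility metrics for a table of tracks
#'
#' Runs [compute_msd()], [fit_msd_model()], [track_length()] and (optionally)
#' [assign_region()] on every track of a track table, collecting one row per
#' track. Tracks too short to analyse, or with non-converged fits, are
#' dropped with a count reported in the `"n_excluded"` attribute.
#'
#' @param tracks Data.frame with `track_id`, `frame`, `x_um`, `y_um`, and
#'   optionally `region_label` (used when no mask is given).
#' @param frame_interval_s Seconds per frame.
#' @param mask Optional `region_mask` for region assignment; off-cell tracks
#'   are excluded.
#' @param max_lag_fraction,drop_first_lag Passed to [compute_msd()] /
#'   [fit_msd_model()].
#' @return Data.frame: `track_id`, `region`, `n_spots`, `duration_s`, `L_um`,
#'   `net_disp_um`, `D`, `alpha`, `v`, `rss`, `motion_class`.
#' @export
analyze_tracks <- function(tracks, frame_interval_s, mask = NULL,
                           max_lag_fraction = 0.25, drop_first_lag = FALSE) {
  sp <- split(tracks, tracks$track_id)
  rows <- vector("list", length(sp))
  excluded <- 0L
  for (i in seq_along(sp)) {
    tr <- sp[[i]][order(sp[[i]]$frame), , drop = FALSE]
    region <- if (!is.null(mask)) assign_region(tr, mask)
              else if ("region_label" %in% names(tr)) tr$region_label[1]
              else NA_character_
    if (identical(region, "off-cell")) { excluded <- excluded + 1L; next }
    res <- tryCatch({
      curve <- compute_msd(tr, frame_interval_s,
                           max_lag_fraction = max_lag_fraction)
      fit <- fit_msd_model(curve, drop_first_lag = drop_first_lag)
      if (!fit$converged) stop("fit did not converge")
      # classify on the full-lag curve, where the directed / confined
      # signatures are strongest; parameters stay from the short-lag fit
      full_curve <- compute_msd(tr, frame_interval_s, max_lag_fraction = 1)
      cls <- classify_motion(fit, full_curve)
      data.frame(
        track_id = tr$track_id[1], region = region, n_spots = nrow(tr),
        duration_s = (max(tr$frame) - min(tr$frame)) * frame_interval_s,
        L_um = track_length(tr),
        net_disp_um = sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                           (tr$y_um[nrow(tr)] - tr$y_um[1])^2),
        D = fit$D, alpha = fit$alpha, v = fit$v, rss = fit$rss,
        motion_class = cls,
        stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(res)) excluded <- excluded + 1L else rows[[i]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}
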