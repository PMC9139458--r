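# spot detection, drift estimation, gap-closing linking

test_that("background-only frames yield no spots", {
  acq <- acq_config(field_size_px = c(48, 48), background_rate = 20)
  mv <- render_movie(list(), acq, seed = 21)
  sp <- detect_spots(mv$stack[, , 1], acq$psf_sigma_um, acq$pixel_size_um)
  expect_identical(nrow(sp), 0L)
})

test_that("a rendered emitter is localized within half a pixel", {
  acq <- acq_config(n_frames = 2, field_size_px = c(48, 48),
                    background_rate = 0, read_noise_sd = 0)
  tr <- simulate_trajectory(clean_preset(D = 0, v = 0), acq,
                            start_xy = c(1.23, 0.77), seed = 22)
  mv <- render_movie(list(tr), acq, poisson_noise = FALSE)
  sp <- detect_spots(mv$stack[, , 1], acq$psf_sigma_um, acq$pixel_size_um,
                     quality_threshold = 1)
  expect_identical(nrow(sp), 1L)
  expect_lt(abs(sp$x_um - 1.23), 0.5 * acq$pixel_size_um)
  expect_lt(abs(sp$y_um - 0.77), 0.5 * acq$pixel_size_um)
  expect_gt(sp$intensity, 0.5 * acq$photon_rate)
})

test_that("two well-separated emitters give exactly two spots", {
  acq <- acq_config(n_frames = 2, field_size_px = c(64, 64),
                    background_rate = 0, read_noise_sd = 0)
  trs <- list(
    simulate_trajectory(clean_preset(D = 0, v = 0), acq, start_xy = c(1.5, 1.5)),
    simulate_trajectory(clean_preset(D = 0, v = 0), acq, start_xy = c(4.0, 4.0))
  )
  mv <- render_movie(trs, acq, poisson_noise = FALSE)
  sp <- detect_spots(mv$stack[, , 1], acq$psf_sigma_um, acq$pixel_size_um,
                     quality_threshold = 1)
  expect_identical(nrow(sp), 2L)
})

test_that("detection achieves >= 0.9 recall and precision at default noise", {
  acq <- acq_config(field_size_px = c(96, 96))
  pr <- motion_presets()$body
  set.seed(23)
  starts <- cbind(runif(6, 1.5, 8), runif(6, 1.5, 8))
  trs <- lapply(1:6, function(i)
    simulate_trajectory(pr, acq, start_xy = starts[i, ]))
  mv <- render_movie(trs, acq, seed = 24)
  spots <- detect_spots_stack(mv, acq)
  tp <- 0; fp <- 0; fn <- 0
  tol <- 2 * acq$pixel_size_um
  for (f in 0:(acq$n_frames - 1)) {
    truth <- mv$truth[mv$truth$frame == f & mv$truth$on_state, ]
    det <- spots[spots$frame == f, ]
    used <- logical(nrow(det))
    for (i in seq_len(nrow(truth))) {
      d <- sqrt((det$x_um - truth$x_um[i])^2 + (det$y_um - truth$y_um[i])^2)
      j <- which(!used & d < tol)
      if (length(j)) { used[j[which.min(d[j])]] <- TRUE; tp <- tp + 1 }
      else fn <- fn + 1
    }
    fp <- fp + sum(!used)
  }
  expect_gte(tp / (tp + fn), 0.9)
  expect_gte(tp / (tp + fp), 0.9)
})

test_that("drift estimation recovers injected drift and is null without", {
  acq <- acq_config(n_frames = 30, field_size_px = c(64, 64))
  set.seed(25)
  base <- data.frame(x = runif(8, 1, 5.2), y = runif(8, 1, 5.2))
  mk_spots <- function(drift_per_frame) {
    do.call(rbind, lapply(0:29, function(f)
      data.frame(frame = f, x_um = base$x + f * drift_per_frame,
                 y_um = base$y)))
  }
  still <- estimate_drift(mk_spots(0), acq)
  expect_lt(max(abs(c(still$dx_um, still$dy_um))), 0.1 * acq$pixel_size_um)

  drifted <- estimate_drift(mk_spots(0.02), acq)
  total <- drifted$dx_um[nrow(drifted)]
  expect_lt(abs(total - 0.02 * 29) / (0.02 * 29), 0.1)

  expect_error(estimate_drift(data.frame(frame = 0, x_um = 1, y_um = 1), acq),
               "insufficient")
})

test_that("drift correction does not masquerade as directed motion", {
  acq <- small_acq(n_frames = 40)
  pr <- clean_preset(D = 0.02)
  set.seed(26)
  tt <- simulate_tracks(pr, 12, acq, seed = 26)
  tt$x_um <- tt$x_um + 3 + tt$track_id %% 5 # spread emitters over the field
  tt$y_um <- tt$y_um + 3 + (tt$track_id * 7) %% 5
  drift <- estimate_drift(tt, acq)
  corr <- apply_drift(tt, drift)
  mets <- analyze_tracks(corr, acq$frame_interval_s)
  # no injected drift: corrected tracks still fit to about the true D
  expect_lt(abs(mean(mets$D) / 0.02 - 1), 0.35)
})

test_that("single persistent spot sequence links into one full-length track", {
  sp <- data.frame(frame = 0:74, x_um = 2 + 0.01 * (0:74), y_um = 3)
  tr <- link_tracks(sp)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 75L)
})

test_that("two distant stationary emitters never swap identities", {
  sp <- rbind(data.frame(frame = rep(0:74, each = 1), x_um = 1, y_um = 1),
              data.frame(frame = 0:74, x_um = 21, y_um = 1))
  sp <- sp[order(sp$frame), ]
  tr <- link_tracks(sp)
  expect_identical(length(unique(tr$track_id)), 2L)
  for (id in unique(tr$track_id))
    expect_identical(length(unique(tr$x_um[tr$track_id == id])), 1L)
})

test_that("gap closing bridges blink-offs and short tracks are discarded", {
  sp <- data.frame(frame = c(0, 1, 2, 5, 6, 7, 8), x_um = 1, y_um = 1)
  tr <- link_tracks(sp, max_gap_frames = 2)
  expect_identical(length(unique(tr$track_id)), 1L)
  expect_identical(nrow(tr), 7L)
  # a 3-frame gap exceeds the budget: fragments, each below min length, dropped
  sp2 <- data.frame(frame = c(0, 1, 2, 6, 7, 8), x_um = 1, y_um = 1)
  expect_identical(nrow(link_tracks(sp2, max_gap_frames = 2)), 0L)
  # link displacement never exceeds the per-gap budget
  set.seed(27)
  tt <- simulate_tracks(motion_presets()$body, 5, small_acq(), seed = 27,
                        blinking = TRUE)
  lt <- link_tracks(tt[, c("frame", "x_um", "y_um")])
  for (id in unique(lt$track_id)) {
    d <- lt[lt$track_id == id, ]
    gap <- diff(d$frame)
    step <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2)
    expect_true(all(step <= 0.38 * gap + 1e-9))
  }
})

test_that("end-to-end recovery on a sparse blinking field is nearly lossless", {
  # <= 0.05 emitters/um^2, blinking on, full render-detect-link loop
  acq <- acq_config(field_size_px = c(96, 96))
  pr <- motion_presets()$lamellipodium
  set.seed(28)
  starts <- expand.grid(x = c(2, 4.75, 7.5), y = c(2, 4.75, 7.5))[1:4, ]
  trs <- lapply(1:4, function(i)
    simulate_trajectory(pr, acq, start_xy = as.numeric(starts[i, ]),
                        region_label = "lam"))
  mv <- render_movie(trs, acq, seed = 29)
  spots <- detect_spots_stack(mv, acq)
  tracks <- link_tracks(spots)
  # ground-truth links: consecutive on-frames of each emitter within gap <= 2
  truth <- mv$truth[mv$truth$on_state, ]
  n_links <- 0; n_found <- 0
  tol <- 2 * acq$pixel_size_um
  match_spot <- function(f, x, y) {
    cand <- tracks[tracks$frame == f, ]
    if (!nrow(cand)) return(NA_integer_)
    d <- sqrt((cand$x_um - x)^2 + (cand$y_um - y)^2)
    if (min(d) > tol) return(NA_integer_)
    cand$track_id[which.min(d)]
  }
  for (k in unique(truth$trajectory_id)) {
    g <- truth[truth$trajectory_id == k, ]
    for (i in seq_len(nrow(g) - 1)) {
      if (g$frame[i + 1] - g$frame[i] > 3) next
      n_links <- n_links + 1
      a <- match_spot(g$frame[i], g$x_um[i], g$y_um[i])
      b <- match_spot(g$frame[i + 1], g$x_um[i + 1], g$y_um[i + 1])
      if (!is.na(a) && !is.na(b) && a == b) n_found <- n_found + 1
    }
  }
  expect_gte(n_found / n_links, 0.95)
})
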