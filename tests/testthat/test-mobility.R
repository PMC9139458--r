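# MSD estimation, model fitting, track length, classification, regions

test_that("MSD of deterministic tracks is exact", {
  # stationary: identically zero at all lags
  st <- data.frame(frame = 0:9, x_um = 1, y_um = 2)
  cv <- compute_msd(st, frame_interval_s = 1, max_lag_fraction = 1)
  expect_equal(cv$msd_um2, rep(0, nrow(cv)))

  # constant velocity 0.1 um/frame at dt = 1 s: MSD(n) = (0.1 n)^2 exactly
  lin <- data.frame(frame = 0:9, x_um = 0.1 * (0:9), y_um = 0)
  cv <- compute_msd(lin, frame_interval_s = 1, max_lag_fraction = 1)
  expect_equal(cv$msd_um2, (0.1 * cv$lag_s)^2, tolerance = 1e-12)
  expect_equal(cv$n_pairs, 9:1)
})

test_that("MSD handles gaps by pair counting and omits unsupported lags", {
  tr <- data.frame(frame = c(0, 1, 2, 4, 5, 6), x_um = c(0, 1, 2, 4, 5, 6),
                   y_um = 0)
  cv <- compute_msd(tr, frame_interval_s = 1, max_lag_fraction = 1)
  # lag 1: pairs (0,1),(1,2),(4,5),(5,6); lag 2: (0,2),(2,4),(4,6)
  expect_equal(cv$n_pairs[cv$lag_s == 1], 4)
  expect_equal(cv$n_pairs[cv$lag_s == 2], 3)
  expect_equal(cv$msd_um2[cv$lag_s == 2], 4)
  expect_error(compute_msd(tr[1:4, ], 1), "insufficient")
})

test_that("ensemble MSD of Brownian tracks matches 4Dt within 3%", {
  acq <- small_acq()
  tt <- simulate_tracks(clean_preset(D = 0.02), 1000, acq, seed = 11,
                        localization_noise = FALSE)
  em <- ensemble_msd(tt, acq$frame_interval_s)
  sel <- em$lag_s <= 20 * acq$frame_interval_s
  expect_equal(em$msd_um2[sel], 4 * 0.02 * em$lag_s[sel], tolerance = 0.03)
})

test_that("model fit recovers exact anomalous and drift curves", {
  t <- (1:12) * 0.078
  pure_d <- data.frame(lag_s = t, msd_um2 = 4 * 0.03 * t, n_pairs = 74 - (1:12))
  f <- fit_msd_model(pure_d)
  expect_equal(f$D, 0.03, tolerance = 1e-4)
  expect_equal(f$alpha, 1, tolerance = 1e-3)
  expect_equal(f$v, 0, tolerance = 1e-3)
  expect_lt(f$rss, 1e-10)

  drift <- data.frame(lag_s = t, msd_um2 = (0.1 * t)^2, n_pairs = 74 - (1:12))
  f2 <- fit_msd_model(drift)
  expect_equal(f2$v, 0.1, tolerance = 1e-3)
  expect_lt(4 * f2$D * max(t)^f2$alpha, 0.01 * (0.1 * max(t))^2)

  anom <- data.frame(lag_s = t, msd_um2 = 4 * 0.013 * t^0.6, n_pairs = 74 - (1:12))
  f3 <- fit_msd_model(anom)
  expect_equal(f3$D, 0.013, tolerance = 1e-3)
  expect_equal(f3$alpha, 0.6, tolerance = 1e-2)

  expect_error(fit_msd_model(pure_d[1:3, ]), "insufficient")
})

test_that("a stationary track yields the zero fit", {
  st <- data.frame(frame = 0:9, x_um = 1, y_um = 2)
  f <- fit_msd_model(compute_msd(st, 0.078))
  expect_equal(f$D, 0)
  expect_equal(f$v, 0)
  expect_equal(f$rss, 0)
})

test_that("track length sums step lengths and bounds the net displacement", {
  expect_equal(track_length(data.frame(frame = 0:1, x_um = c(0, 3),
                                       y_um = c(0, 4))), 5)
  sq <- data.frame(frame = 0:4, x_um = c(0, 1, 1, 0, 0), y_um = c(0, 0, 1, 1, 0))
  expect_equal(track_length(sq), 4)
  expect_error(track_length(sq[1, ]), "insufficient")

  # additivity under concatenation; triangle inequality on simulated tracks
  set.seed(12)
  tt <- simulate_tracks(clean_preset(D = 0.02), 20, small_acq(), seed = 12)
  for (tr in split(tt, tt$track_id)) {
    L <- track_length(tr)
    net <- sqrt(diff(range(0, tr$x_um[c(1, nrow(tr))]))^2) # placeholder
    net <- sqrt((tr$x_um[nrow(tr)] - tr$x_um[1])^2 +
                (tr$y_um[nrow(tr)] - tr$y_um[1])^2)
    expect_gte(L, net)
    k <- nrow(tr) %/% 2
    expect_equal(track_length(tr[1:k, ]) + track_length(tr[k:nrow(tr), ]), L,
                 tolerance = 1e-12)
  }
})

test_that("MSD, fit and L are invariant under rigid rotation and translation", {
  set.seed(13)
  tt <- simulate_tracks(motion_presets()$filopodium, 1, small_acq(), seed = 13)
  th <- 0.7
  rot <- data.frame(frame = tt$frame,
                    x_um = cos(th) * tt$x_um - sin(th) * tt$y_um + 5,
                    y_um = sin(th) * tt$x_um + cos(th) * tt$y_um - 2)
  cv1 <- compute_msd(tt, 0.078); cv2 <- compute_msd(rot, 0.078)
  expect_equal(cv1$msd_um2, cv2$msd_um2, tolerance = 1e-10)
  f1 <- fit_msd_model(cv1); f2 <- fit_msd_model(cv2)
  expect_equal(f1$D, f2$D, tolerance = 1e-6)
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-6)
  expect_equal(track_length(tt), track_length(rot), tolerance = 1e-10)
})

test_that("motion classification matches the canonical MSD shapes", {
  t <- (1:74) * 0.078
  np <- 74:1
  fit_ok <- structure(list(D = 0, alpha = 1, v = 0.1, rss = 0, n_lags_fit = 74,
                           converged = TRUE), class = "mobility_fit")
  drift <- data.frame(lag_s = t, msd_um2 = (0.1 * t)^2, n_pairs = np)
  expect_identical(classify_motion(fit_ok, drift), "directed")

  sub <- data.frame(lag_s = t, msd_um2 = 4 * 0.02 * t^0.5, n_pairs = np)
  expect_identical(classify_motion(fit_ok, sub), "confined")

  brown <- data.frame(lag_s = t, msd_um2 = 4 * 0.02 * t, n_pairs = np)
  expect_identical(classify_motion(fit_ok, brown), "brownian")

  bad <- structure(list(D = NA_real_, converged = FALSE), class = "mobility_fit")
  expect_identical(classify_motion(bad, brown), "unclassified")
})

test_that("preset ensembles classify as the motion modes they emulate", {
  acq <- small_acq()
  pres <- motion_presets()
  tt_f <- simulate_tracks(pres$filopodium, 100, acq, seed = 14)
  m_f <- analyze_tracks(tt_f, acq$frame_interval_s)
  expect_gte(mean(m_f$motion_class == "directed"), 0.8)

  tt_b <- simulate_tracks(pres$body, 100, acq, seed = 15)
  m_b <- analyze_tracks(tt_b, acq$frame_interval_s)
  expect_gte(mean(m_b$motion_class == "confined"), 0.8)
  # the corral flattens the apparent exponent well below the Brownian value
  expect_lt(mean(m_b$alpha), 0.8)
  # unconfined directed presets keep their exponent near Brownian
  expect_lt(abs(mean(m_f$alpha) - 1), 0.15)
})

test_that("tracks are assigned to the region their spots occupy", {
  acq <- acq_config(field_size_px = c(160, 160))
  mask <- make_region_mask(list(n_filopodia = 4), acq, seed = 16)
  ctr <- mask$geometry$center_um

  body_tr <- data.frame(frame = 0:9, x_um = ctr[1] + seq(0, 0.5, length.out = 10),
                        y_um = ctr[2])
  expect_identical(assign_region(body_tr, mask), "body")

  off_tr <- data.frame(frame = 0:9, x_um = rep(0.3, 10), y_um = rep(0.3, 10))
  expect_identical(assign_region(off_tr, mask), "off-cell")

  # seeded tracks inside each region are recovered >= 95% of the time;
  # the walker is confined tightly enough to respect the 0.2 um rod half-width
  set.seed(17)
  seeder <- clean_preset(D = 0.013, alpha = 0.6, confinement_radius_um = 0.15)
  pres <- list(body = seeder)
  fil_ang <- which(mask$label_image == 3L, arr.ind = TRUE)
  n_ok <- 0; n_all <- 0
  for (i in 1:30) {
    # body track: confined walk at the centre
    tr <- simulate_trajectory(pres$body, acq, start_xy = ctr)
    n_all <- n_all + 1
    n_ok <- n_ok + (assign_region(tr$positions, mask) == "body")
    # lamellipodium track at mid-annulus
    r0 <- (mask$geometry$body_radius_um + mask$geometry$rim_outer_um) / 2
    a <- runif(1, 0, 2 * pi)
    tr2 <- simulate_trajectory(pres$body, acq,
                               start_xy = ctr + r0 * c(cos(a), sin(a)))
    n_all <- n_all + 1
    n_ok <- n_ok + (assign_region(tr2$positions, mask) == "lamellipodium")
    # filopodium track: pick a random rod pixel as start
    px <- fil_ang[sample(nrow(fil_ang), 1), ]
    tr3 <- simulate_trajectory(pres$body, acq,
                               start_xy = c((px[2] - 1), (px[1] - 1)) * acq$pixel_size_um)
    n_all <- n_all + 1
    n_ok <- n_ok + (assign_region(tr3$positions, mask) == "filopodium")
  }
  expect_gte(n_ok / n_all, 0.95)
})

test_that("parameter recovery degrades gracefully when localization noise triples", {
  acq <- small_acq()
  base <- motion_presets()$lamellipodium
  noisy <- motion_preset("noisy3x", D_alpha = base$D_alpha, alpha = base$alpha,
                         v = base$v, axis_deg = base$axis_deg,
                         loc_noise_sd_um = 3 * base$loc_noise_sd_um)
  tt1 <- simulate_tracks(base, 80, acq, seed = 18)
  tt3 <- simulate_tracks(noisy, 80, acq, seed = 18)
  d1 <- mean(analyze_tracks(tt1, acq$frame_interval_s)$D)
  d3 <- mean(analyze_tracks(tt3, acq$frame_interval_s)$D)
  # tripled noise shifts the estimate only modestly: still the right decade,
  # and close to the clean-noise estimate
  expect_lt(abs(d3 / base$D_alpha - 1), 0.5)
  expect_lt(abs(d3 - d1) / d1, 0.3)
})
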