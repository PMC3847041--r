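# The synthetic generators: determinism, parameter validation, and the
# closed-form/closed-loop guarantees their ground truth makes.

test_that("generators are bit-identical under a fixed seed", {
  p <- scene_params(0.2, noise_sd = 0.02, seed = 11)
  expect_identical(generate_fret_scene(p)$pre$data,
                   generate_fret_scene(p)$pre$data)
  s1 <- generate_ratiometric_series(p, 0.1, 5, 12, dt = 1)
  s2 <- generate_ratiometric_series(p, 0.1, 5, 12, dt = 1)
  expect_identical(s1$stacks[[8]]$data, s2$stacks[[8]]$data)
  ap <- assembly_params(seed = 3, image_shape = c(64, 64), n_cells = 9,
                        rate_true = 0.05)
  expect_identical(generate_assembly_movie(ap)$movie$data,
                   generate_assembly_movie(ap)$movie$data)
  dp <- disassembly_params(seed = 4, noise_sd = 0.02)
  expect_identical(generate_disassembly_movie(dp)$movie$data,
                   generate_disassembly_movie(dp)$movie$data)
  sp <- spheroid_params(seed = 5, duration = 2, frame_interval = 30)
  expect_identical(generate_spheroid_movie(sp)$movie$data,
                   generate_spheroid_movie(sp)$movie$data)
  expect_identical(generate_section_image(seed = 6, noise_sd = 0.05)$image$data,
                   generate_section_image(seed = 6, noise_sd = 0.05)$image$data)
})

test_that("generator parameter validation rejects invalid physics", {
  expect_error(scene_params(fret_ratio_true = 1), "range")
  expect_error(scene_params(0.1, band_centers = c(473, 481)), "3 spectral")
  expect_error(scene_params(0.1, noise_sd = -1), "range")
  expect_error(disassembly_params(tau_true = 0), "range")
  expect_error(disassembly_params(2, lag_true = -1), "range")
  expect_error(assembly_params(rate_true = -0.1), "range")
  expect_error(assembly_params(0.2, duration = 20, baseline_min = 30),
               "duration")
  expect_error(spheroid_params(tau_fast = 5, tau_slow = 2), "tau_fast")
  expect_error(spheroid_params(roundness_start = 0), "range")
  expect_error(generate_ratiometric_series(scene_params(0.1), 0.1, 50, 35),
               "event_time")
})

test_that("no-FRET scenes leave the junction donor unchanged pre/post", {
  p <- scene_params(fret_ratio_true = 0, noise_sd = 0, read_noise = 0)
  sc <- generate_fret_scene(p)
  jm <- sc$truth$junction_mask
  for (b in seq_along(p$band_centers)) {
    pre_d <- sc$pre$data[, , b][jm]
    post_d <- sc$post$data[, , b][jm]
    # post differs only by the bleached acceptor contribution
    expect_true(all(post_d <= pre_d + 1e-12))
  }
})

test_that("ratiometric truth covers the flat, fixture and full-drop limits", {
  p <- scene_params(0.1, noise_sd = 0, read_noise = 0, seed = 2)
  flat <- generate_ratiometric_series(p, 0, 5, 12, dt = 1)
  expect_equal(flat$truth$fret_after, 100)
  jm <- flat$truth$junction_mask
  b6 <- vapply(flat$stacks, function(s) mean(s$data[, , 6][jm]), numeric(1))
  expect_equal(max(b6) - min(b6), 0, tolerance = 1e-12)

  wt <- generate_ratiometric_series(p, 0.104, 5, 12, dt = 1)
  expect_equal(wt$truth$fret_after, 89.6)

  full <- generate_ratiometric_series(p, 1, 4, 40, dt = 1, relax_time = 1)
  # acceptor contribution at the junction vanishes at late times
  acc_band <- which.max(spectrum_gaussian(p$band_centers, p$acceptor_peak))
  late <- full$stacks[[41]]$data[, , acc_band][jm]
  don_only <- spectrum_gaussian(p$band_centers, p$donor_peak)[acc_band] * 1.0
  expect_lt(max(abs(late - p$background - don_only)), 1e-6)
})

test_that("disassembly traces follow the closed form and the lag rule", {
  dp <- disassembly_params(tau_true = 2.63, lag_true = 0, noise_sd = 0)
  tr <- generate_disassembly_trace(dp)
  gen <- generate_disassembly_movie(dp)
  expect_equal(tr$values, gen$truth$intensity(tr$times), tolerance = 1e-9)

  lag <- disassembly_params(tau_true = 7.28, lag_true = 10, noise_sd = 0)
  trl <- generate_disassembly_trace(lag)
  # constant up to event + lag
  expect_equal(trl$values[trl$times <= 25],
               rep(trl$values[1], sum(trl$times <= 25)), tolerance = 1e-12)
  expect_lt(trl$values[trl$times == 30], trl$values[1])

  flatp <- disassembly_params(tau_true = 5, plateau_fraction = 1,
                              noise_sd = 0)
  trf <- generate_disassembly_trace(flatp)
  expect_equal(max(trf$values) - min(trf$values), 0, tolerance = 1e-12)
})

test_that("assembly truth: zero rate, full presence, and birth-rate law", {
  z <- generate_assembly_movie(assembly_params(rate_true = 0, seed = 1,
                                               image_shape = c(64, 64),
                                               n_cells = 9))
  expect_equal(nrow(z$truth$junctions), 0)

  fp <- generate_assembly_movie(assembly_params(rate_true = 0.1,
                                                presence_fraction = 1,
                                                seed = 2))
  pres <- fp$truth$presence
  for (k in seq_len(nrow(pres))) {
    f0 <- fp$truth$junctions$birth_frame[k]
    expect_true(all(pres[k, f0:ncol(pres)]))
  }

  # law of large numbers: mean observed count grows at rate_true
  counts <- matrix(0, 100, 61)
  for (s in 1:100) {
    g <- generate_assembly_movie(assembly_params(
      rate_true = 0.203, presence_fraction = 1, n_cells = 25,
      image_shape = c(96, 96), n_z = 1, seed = 1000 + s))
    counts[s, ] <- colSums(g$truth$presence)
  }
  times <- seq(0, 120, 2)
  post <- times > 40
  slope <- coef(lm(colMeans(counts)[post] ~ times[post]))[2]
  expect_equal(unname(slope), 0.203, tolerance = 0.05)
})

test_that("spheroid truth trajectory is rendered faithfully", {
  flat <- spheroid_params(roundness_start = 0.6, roundness_plateau = 0.6,
                          tau_fast = 1, tau_slow = 8,
                          duration = 3, frame_interval = 60, noise_sd = 0)
  expect_equal(diff(range(spheroid_trajectory(flat, 0:3))), 0)

  expect_lt(ca_roundness_map(0), ca_roundness_map(2.1))

  sp <- spheroid_params(roundness_start = 0.15, roundness_plateau = 0.68,
                        duration = 48, frame_interval = 120, seed = 3)
  gen <- generate_spheroid_movie(sp)
  tr <- roundness_timeseries(gen$movie)
  expect_lt(max(abs(tr$values - gen$truth$roundness)), 0.02)
  # monotone non-decreasing after baseline (within measurement jitter)
  post <- tr$times >= sp$baseline_h
  expect_true(all(diff(tr$values[post]) > -0.015))
})

test_that("section images encode the hollow core and laminin ring", {
  filled <- generate_section_image(hollow = FALSE, laminin_level = 0.8)
  hollow <- generate_section_image(hollow = TRUE, laminin_level = 0.8)
  jf <- filled$image$data[1, 1, 1, , ]
  jh <- hollow$image$data[1, 1, 1, , ]
  ctr <- filled$truth$center
  r_core <- 0.5 * filled$truth$inner_frac * filled$truth$radius
  g <- adherens:::pixel_grid(dim(jf))
  core <- (g$y - ctr[1])^2 + (g$x - ctr[2])^2 <= r_core^2
  expect_gt(mean(jf[core]), 0.1)     # lattice fills the core when not hollow
  expect_lt(mean(jh[core]), 0.03)    # empty core when hollow
  lam0 <- generate_section_image(laminin_level = 0)$image$data[1, 1, 2, , ]
  expect_equal(max(lam0), 0)
})

test_that("estimator dispersion grows with generator noise", {
  est <- function(noise, seeds) {
    vapply(seeds, function(s) {
      sc <- generate_fret_scene(scene_params(0.199, noise_sd = noise,
                                             seed = s))
      sdp <- build_reference_spectrum(sc$pre, sc$truth$donor_roi, "donor")
      sap <- build_reference_spectrum(sc$pre, sc$truth$acceptor_roi,
                                      "acceptor")
      acceptor_bleach_fret(unmix(sc$pre, list(sdp, sap)),
                           unmix(sc$post, list(sdp, sap)),
                           sc$truth$junction_mask,
                           sc$truth$bleach_roi)$fret_ratio
    }, numeric(1))
  }
  s_lo <- sd(est(0.01, 1:12))
  s_hi <- sd(est(0.08, 1:12))
  expect_lt(s_lo, s_hi)
})
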