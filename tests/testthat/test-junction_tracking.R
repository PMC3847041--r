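# Junction detection/tracking: projections, masks, cell identity, pair
# maps, track extraction and the derived statistics.

blob_volume <- function(centers_by_frame, shape, r = 5) {
  nt <- length(centers_by_frame)
  vol <- array(0, c(shape, nt))
  g <- adherens:::pixel_grid(shape)
  for (f in seq_len(nt)) {
    img <- matrix(0, shape[1], shape[2])
    for (cc in centers_by_frame[[f]])
      img <- img + exp(-((g$y - cc[1])^2 + (g$x - cc[2])^2) / (2 * r^2))
    vol[, , f] <- img
  }
  vol
}

test_that("central projection picks the two central planes", {
  set.seed(1)
  d <- array(runif(2 * 6 * 1 * 5 * 5), c(2, 6, 1, 5, 5))
  fs <- frame_stack(d)
  proj <- central_projection(fs)
  expect_equal(proj[, , 1], pmax(d[1, 3, 1, , ], d[1, 4, 1, , ]))
  expect_equal(proj[, , 2], pmax(d[2, 3, 1, , ], d[2, 4, 1, , ]))

  d2 <- array(runif(1 * 2 * 1 * 4 * 4), c(1, 2, 1, 4, 4))
  expect_equal(central_projection(frame_stack(d2))[, , 1],
               pmax(d2[1, 1, 1, , ], d2[1, 2, 1, , ]))

  same <- array(rep(d2[1, 1, 1, , ], 2), c(4, 4, 2))
  d3 <- array(aperm(same, c(3, 1, 2)), c(1, 2, 1, 4, 4))
  expect_equal(central_projection(frame_stack(d3))[, , 1], d3[1, 1, 1, , ])

  expect_warning(central_projection(frame_stack(array(1, c(1, 1, 1, 3, 3)))),
                 "single z")
})

test_that("threshold mask isolates bright structure and matches brute-force Otsu", {
  img <- matrix(0.05, 40, 40)
  img[10:20, 10:20] <- 1
  m <- threshold_mask(img)
  expect_equal(which(m), which(img == 1))

  # overlapping modes so the between-class-variance maximum is unique
  set.seed(3)
  bimodal <- matrix(c(rnorm(600, 90, 25), rnorm(400, 170, 25)), 25, 40)
  th_pkg <- {
    rng <- range(bimodal)
    rng[1] + EBImage::otsu(EBImage::Image((bimodal - rng[1]) / diff(rng)),
                           range = c(0, 1)) * diff(rng)
  }
  th_brute <- brute_otsu(bimodal)
  expect_lt(abs(th_pkg - th_brute), 2 * diff(range(bimodal)) / 256)

  expect_error(threshold_mask(matrix(1, 5, 5)), "no contrast")
})

test_that("stationary cells keep constant identities across frames", {
  vol <- blob_volume(rep(list(list(c(15, 15), c(40, 42))), 5), c(56, 56))
  cen <- segment_cells_xyt(vol)
  expect_equal(length(unique(cen$cell_id)), 2)
  for (id in unique(cen$cell_id)) {
    sub <- cen[cen$cell_id == id, ]
    expect_equal(nrow(sub), 5)
    expect_lt(max(abs(sub$y - sub$y[1])), 0.5)
  }
  expect_error(segment_cells_xyt(array(0, c(10, 10, 2))), "no cells")
})

test_that("a drifting cell keeps one id, agreeing with an overlap oracle", {
  frames <- lapply(0:7, function(f) list(c(12 + 2 * f, 10 + 1.5 * f)))
  vol <- blob_volume(frames, c(48, 48))
  cen <- segment_cells_xyt(vol)
  expect_equal(length(unique(cen$cell_id)), 1)
  oracle <- oracle_track_blobs(vol, threshold = 0.3)
  expect_true(all(vapply(oracle, function(d) d$id[1], numeric(1)) == 1))
  # centroid agreement between the two independent routes
  expect_lt(max(abs(cen$y - vapply(oracle, function(d) d$y[1], numeric(1)))),
            1.5)
})

test_that("merging cells end one identity and exclude affected junctions", {
  frames <- lapply(0:5, function(f)
    list(c(24, 14 + 2.6 * f), c(24, 40 - 2.6 * f), c(42, 48)))
  vol <- blob_volume(frames, c(48, 56), r = 4)
  cen <- segment_cells_xyt(vol)
  per_frame <- table(cen$frame)
  expect_gt(per_frame[[1]], per_frame[[length(per_frame)]])  # ids collapse
  # a junction between the merging pair gets flagged
  nt <- length(frames)
  jm <- matrix(FALSE, 48, 56); jm[20:28, 26:28] <- TRUE
  masks <- rep(list(jm), nt)
  pmaps <- two_closest_neighbor_map(cen, c(48, 56))
  dmasks <- rep(list(matrix(TRUE, 48, 56)), nt)
  tracks <- extract_junctions(masks, pmaps, dmasks, centers = cen,
                              exclude_border = FALSE)
  expect_true(any(vapply(tracks, `[[`, logical(1), "excluded")))
})

test_that("two-closest-neighbor map matches brute force and its tie rule", {
  cen2 <- data.frame(frame = 1, cell_id = c(1, 2),
                     y = c(10, 30), x = c(12, 28))
  pm <- two_closest_neighbor_map(cen2, c(40, 40))[[1]]
  expect_equal(unique(as.numeric(pm)), pair_key(1, 2))

  # three collinear cells at x = 1, 11, 21: a pixel at x = 5 pairs the
  # first two
  cen3 <- data.frame(frame = 1, cell_id = 1:3, y = c(5, 5, 5),
                     x = c(1, 11, 21))
  pm3 <- two_closest_neighbor_map(cen3, c(9, 24))[[1]]
  expect_equal(pm3[5, 5], pair_key(1, 2))
  expect_equal(pm3[5, 17], pair_key(2, 3))
  # equidistant to all three: lowest two ids win
  expect_equal(pm3[1, 11], pair_key(1, 2))

  set.seed(9)
  cen5 <- data.frame(frame = 1, cell_id = c(2, 5, 7, 8, 11),
                     y = runif(5, 5, 59), x = runif(5, 5, 59))
  pm5 <- two_closest_neighbor_map(cen5, c(64, 64))[[1]]
  expect_identical(pm5, brute_two_closest(cen5$y, cen5$x, cen5$cell_id,
                                          c(64, 64)))
  expect_error(two_closest_neighbor_map(cen2[1, ], c(10, 10)),
               "insufficient cells")
})

test_that("distance masks agree with direct distance computation", {
  cen <- data.frame(frame = 1, cell_id = 1, y = 20, x = 20)
  dm <- distance_mask(cen, c(40, 40), max_dist = 8)[[1]]
  g <- adherens:::pixel_grid(c(40, 40))
  expect_equal(dm, sqrt((g$y - 20)^2 + (g$x - 20)^2) <= 8)
  expect_true(all(distance_mask(cen, c(40, 40), max_dist = 1e9)[[1]]))

  set.seed(5)
  cen64 <- data.frame(frame = 1, cell_id = 1:6,
                      y = runif(6, 1, 64), x = runif(6, 1, 64))
  dm64 <- distance_mask(cen64, c(64, 64), max_dist = 12)[[1]]
  g64 <- adherens:::pixel_grid(c(64, 64))
  dist_all <- sapply(1:6, function(i)
    sqrt((c(g64$y) - cen64$y[i])^2 + (c(g64$x) - cen64$x[i])^2))
  expect_equal(dm64, matrix(apply(dist_all, 1, min) <= 12, 64, 64))
  # micrometer conversion
  dm_um <- distance_mask(cen, c(40, 40), max_dist = 4, pixel_size = 0.5)[[1]]
  expect_equal(dm_um, sqrt((g$y - 20)^2 + (g$x - 20)^2) <= 8)
})

test_that("junction tracks preserve identity through gaps", {
  nt <- 6
  jm <- matrix(FALSE, 32, 32); jm[14:18, 15:17] <- TRUE
  masks <- lapply(seq_len(nt), function(f) if (f == 3)
    matrix(FALSE, 32, 32) else jm)            # sub-threshold at frame 3
  cen <- do.call(rbind, lapply(seq_len(nt), function(f)
    data.frame(frame = f, cell_id = c(1, 2), y = c(16, 16), x = c(8, 24))))
  pmaps <- two_closest_neighbor_map(cen, c(32, 32))
  dmasks <- rep(list(matrix(TRUE, 32, 32)), nt)
  tracks <- extract_junctions(masks, pmaps, dmasks, exclude_border = FALSE)
  expect_length(tracks, 1)
  expect_equal(tracks[[1]]$junction_id, pair_key(1, 2))
  expect_equal(tracks[[1]]$presence, c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(tracks[[1]]$birth_frame, 1)

  none <- extract_junctions(rep(list(matrix(FALSE, 32, 32)), nt), pmaps,
                            dmasks)
  expect_length(none, 0)
})

test_that("the tracker recovers synthetic junctions, counts and births", {
  gen <- generate_assembly_movie(assembly_params(rate_true = 0.203,
                                                 presence_fraction = 0.82,
                                                 seed = 5))
  res <- track_junctions(gen$movie)
  keep <- Filter(function(t) !t$excluded, res$tracks)
  expect_equal(length(keep), nrow(gen$truth$junctions))
  curve <- assembly_curve(res$tracks, res$times)
  truth_curve <- colSums(gen$truth$presence)
  expect_true(all(abs(curve$values - truth_curve) <= 1))
  births <- sort(vapply(keep, `[[`, numeric(1), "birth_frame"))
  expect_true(mean(abs(births - sort(gen$truth$junctions$birth_frame)) <= 1)
              >= 0.9)
  # pair-key identity bound
  expect_lte(length(res$tracks), choose(25, 2))
})

test_that("junction lifetime is the windowed presence percentage", {
  npx <- c(rep(10, 20), rep(0, 10))
  tr <- adherens:::new_junction_track(pair_key(1, 2), c(1, 2), npx,
                                      lapply(npx, seq_len), min_area = 5)
  times <- seq(0, 58, by = 2)
  expect_equal(junction_lifetime(tr, times, 0, 38), 100)
  expect_equal(junction_lifetime(tr, times, 40, 58), 0)
  # 41 of 50 frames present: the published WT mean as arithmetic
  npx2 <- integer(50); npx2[1:41] <- 9
  tr2 <- adherens:::new_junction_track(pair_key(1, 3), c(1, 3), npx2,
                                       lapply(npx2, seq_len), min_area = 5)
  t2 <- seq_len(50)
  expect_equal(junction_lifetime(tr2, t2, 1, 50), 82)
  expect_error(junction_lifetime(tr, times, 100, 120), "empty")
})

test_that("lifetime statistic is unbiased on synthetic presence tracks", {
  tracks <- generate_junction_tracks(
    assembly_params(rate_true = 0.203, presence_fraction = 0.82, seed = 2),
    n_junctions = 60)
  times <- attr(tracks, "times")
  lt <- vapply(tracks, junction_lifetime, numeric(1), times = times,
               window_start = 60, window_end = 120)
  expect_equal(mean(lt), 82, tolerance = 0.02)
})

test_that("intensity traces honor the holdover rule", {
  imgs <- array(2, c(16, 16, 4))
  imgs[, , 3] <- 7
  npx <- c(6, 6, 0, 6)
  px <- list(1:6, 7:12, integer(0), 13:18)
  tr <- adherens:::new_junction_track(pair_key(1, 2), c(1, 2), npx, px,
                                      min_area = 5)
  trace <- junction_intensity_trace(tr, imgs, times = c(0, 5, 10, 15))
  expect_equal(trace$values, c(2, 2, 7, 2))   # frame 3 uses frame-2 pixels

  const <- junction_intensity_trace(matrix(TRUE, 16, 16),
                                    array(3, c(16, 16, 3)), times = 0:2)
  expect_equal(const$values, rep(3, 3))

  empty <- adherens:::new_junction_track(pair_key(1, 2), c(1, 2),
                                         integer(4), rep(list(integer(0)), 4),
                                         min_area = 5)
  expect_error(junction_intensity_trace(empty, imgs, 0:3), "no pixels")
})
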