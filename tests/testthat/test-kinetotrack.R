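make_det <- function(truth) {
  data.frame(frame = truth$frame, label = truth$spot_id,
             y_px = truth$y_px, x_px = truth$x_px)
}

test_that("static and vanishing particles link as expected", {
  pts <- expand.grid(frame = 1:10, label = 1:5)
  pts$y_px <- pts$label * 10; pts$x_px <- pts$label * 7
  tr <- link_particles(pts, max_disp_px = 5)
  expect_equal(length(unique(tr$track_id)), 5L)
  expect_true(all(table(tr$track_id) == 10))
  # identity mapping: positions constant within a track
  expect_true(all(tapply(tr$y_px, tr$track_id,
                         function(v) length(unique(v)) == 1)))

  # a particle vanishing at frame k ends its track at k-1
  pts2 <- pts[!(pts$label == 3 & pts$frame >= 6), ]
  tr2 <- link_particles(pts2, max_disp_px = 5)
  lens <- table(tr2$track_id)
  expect_equal(sort(as.integer(lens)), c(5L, rep(10L, 4)))
})

test_that("linking recovers generator identities under drift", {
  for (s in 1:5) {
    cfg <- image_sim_config(n_pairs = 25, n_frames = 30, img_size = 360,
                            cell_radius_px = 160, drift_px_per_frame = 0.5,
                            seed = s)
    sim <- sim_image_stack(cfg, render = FALSE)
    truth <- sim$truth$spots
    tr <- link_particles(make_det(truth), max_disp_px = 5)
    expect_equal(length(unique(tr$track_id)), 50L)
    m <- merge(tr, truth[, c("frame", "spot_id", "y_px", "x_px")],
               by = c("frame", "y_px", "x_px"))
    expect_true(all(tapply(m$spot_id, m$track_id,
                           function(v) length(unique(v)) == 1)))
  }

  # displacements beyond the hard limit break the track
  jump <- data.frame(frame = c(1, 2), label = 1,
                     y_px = c(0, 10), x_px = 0)
  expect_equal(length(unique(link_particles(jump, 5)$track_id)), 2L)
})

test_that("sister pairing is a mutual-proximity matching inside the window", {
  two <- data.frame(label = 1:2, y_px = c(0, 10), x_px = 0)  # 1.0 um at 0.1
  p <- pair_sisters(two, 0.1)
  expect_equal(nrow(p$pairs), 1L)
  expect_equal(p$pairs$separation_um, 1.0)

  # three collinear points at 0, 1.0, 3.0 um: one pair, one unpaired
  three <- data.frame(label = 1:3, y_px = c(0, 10, 30), x_px = 0)
  p3 <- pair_sisters(three, 0.1)
  expect_equal(nrow(p3$pairs), 1L)
  expect_setequal(c(p3$pairs$a, p3$pairs$b), c(1L, 2L))
  expect_equal(p3$unpaired, 3L)

  # separation outside the window: no pair
  far <- data.frame(label = 1:2, y_px = c(0, 30), x_px = 0)
  expect_equal(nrow(pair_sisters(far, 0.1)$pairs), 0L)

  # matching: no particle in two pairs; invariant under relabeling
  sim <- sim_image_stack(image_sim_config(n_pairs = 12, seed = 3),
                         render = FALSE)
  f1 <- make_det(sim$truth$spots[sim$truth$spots$frame == 1, ])
  pr <- pair_sisters(f1, 0.1)
  expect_equal(anyDuplicated(c(pr$pairs$a, pr$pairs$b)), 0L)
  perm <- f1[sample(nrow(f1)), ]
  pr2 <- pair_sisters(perm, 0.1)
  key <- function(p) sort(paste(pmin(p$pairs$a, p$pairs$b),
                                pmax(p$pairs$a, p$pairs$b)))
  expect_equal(key(pr2), key(pr))
  # and every recovered pair is a true sister pair
  tp <- sim$truth$spots[sim$truth$spots$frame == 1, ]
  expect_true(all(tp$pair_id[match(pr$pairs$a, tp$spot_id)] ==
                  tp$pair_id[match(pr$pairs$b, tp$spot_id)]))
})

test_that("inter-centromere series scale, subset and normalize correctly", {
  a <- data.frame(frame = 1:3, y_px = 0, x_px = 0)
  b <- data.frame(frame = 1:3, y_px = 0, x_px = 10)
  s <- intercentromere_series(a, b, 0.1)
  expect_equal(s$d_um, rep(1.0, 3))

  # ragged overlap restricted to common frames
  a2 <- data.frame(frame = 1:7, y_px = 0, x_px = 0)
  b2 <- data.frame(frame = 3:9, y_px = 0, x_px = 12)
  s2 <- intercentromere_series(a2, b2, 0.1)
  expect_equal(s2$frames, 3:7)

  expect_error(intercentromere_series(a, data.frame(frame = 9, y_px = 0,
                                                    x_px = 0), 0.1),
               "fewer than 2")

  # T0 normalization: argmin mode and exact unity at T0
  s3 <- structure(list(pair_id = 1, frames = 1:3,
                       d_um = c(1.2, 1.0, 1.5)), class = "stretch_series")
  n3 <- normalize_t0(s3)
  expect_equal(n3$t0_index, 2L)
  expect_equal(n3$n, c(1.2, 1.0, 1.5))
  expect_identical(n3$n[n3$t0_index], 1)
  nf <- normalize_t0(s3, mode = "first")
  expect_equal(nf$t0_index, 1L)
  expect_equal(nf$n[1], 1)

  cst <- structure(list(pair_id = 1, frames = 1:4, d_um = rep(2, 4)),
                   class = "stretch_series")
  expect_true(all(normalize_t0(cst)$n == 1))
  expect_true(all(normalize_t0(cst, "first")$n == 1))

  zero <- structure(list(pair_id = 1, frames = 1:2, d_um = c(0, 1)),
                    class = "stretch_series")
  expect_error(normalize_t0(zero), "zero distance")
})

test_that("series are invariant under rotation and translation", {
  set.seed(8)
  a <- data.frame(frame = 1:5, y_px = cumsum(rnorm(5)),
                  x_px = cumsum(rnorm(5)))
  b <- data.frame(frame = 1:5, y_px = a$y_px + 8 + rnorm(5, 0, 0.3),
                  x_px = a$x_px + 6 + rnorm(5, 0, 0.3))
  d0 <- intercentromere_series(a, b, 0.1)$d_um
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- function(df) {
    m <- as.matrix(df[, c("y_px", "x_px")]) %*% R
    data.frame(frame = df$frame, y_px = m[, 1] + 40, x_px = m[, 2] - 13)
  }
  d1 <- intercentromere_series(rot(a), rot(b), 0.1)$d_um
  expect_equal(d1, d0, tolerance = 1e-12)
})

test_that("noise-free sinusoidal stretch is recovered to machine precision", {
  cfg <- image_sim_config(n_frames = 20, seed = 6)
  sim <- sim_image_stack(cfg, render = FALSE)
  truth <- sim$truth$spots
  tr <- link_particles(make_det(truth), max_disp_px = 5)
  f1 <- tr[tr$frame == 1, ]
  pr <- pair_sisters(f1, 0.1)
  s <- normalize_t0(intercentromere_series(
    tr[tr$track_id == pr$pairs$a[1], ],
    tr[tr$track_id == pr$pairs$b[1], ], 0.1, pair_id = 1))
  tp1 <- truth[truth$frame == 1, ]
  pid <- tp1$pair_id[match(pr$pairs$a[1], tp1$spot_id)]
  d_true <- sim$truth$pairs$d_um[sim$truth$pairs$pair_id == pid]
  expect_equal(s$d_um, d_true, tolerance = 1e-9)

  summ <- stretch_summary(list(s), frame_interval_min = 6)
  expect_equal(summ$d_max_um, max(d_true), tolerance = 1e-9)
  expect_equal(summ$duration_min, 19 * 6)
  # amplitude recovery: d_max - d_min spans up to twice the amplitude
  expect_lte(max(d_true) - min(d_true), 2 * 0.3 + 1e-9)

  # constant pair: n_max exactly 1
  cst <- structure(list(pair_id = 9, frames = 1:4, d_um = rep(1.4, 4)),
                   class = "stretch_series")
  expect_equal(stretch_summary(list(cst))$n_max, 1)
  expect_equal(nrow(stretch_summary(list())), 0L)
})

test_that("dynamic ratio decay along trajectories is recovered within 10%", {
  ratios <- seq(2.0, 1.5, length.out = 6)
  sim <- sim_image_stack(image_sim_config(n_frames = 6, true_ratio = ratios,
                                          seed = 11))
  m <- quantify_stack(sim$stack)
  tr <- link_particles(m, max_disp_px = 5)
  mm <- merge(tr, m, by = c("frame", "label", "y_px", "x_px"))
  full <- names(which(table(tr$track_id) == 6))
  slopes <- vapply(full, function(id) {
    ratio_trend(mm[mm$track_id == as.integer(id), ],
                frame_interval_min = 6)$slope_per_min
  }, numeric(1))
  true_slope <- (1.5 - 2.0) / (5 * 6)
  expect_lt(abs(mean(slopes) - true_slope) / abs(true_slope), 0.10)
})
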