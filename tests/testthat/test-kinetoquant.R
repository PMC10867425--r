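test_that("Z projection reduces stacks as expected", {
  a <- array(0, dim = c(1, 1, 1, 4, 5)); a[1, 1, 1, , ] <- matrix(1:20, 4, 5)
  s1 <- image_stack(a, "ch")
  expect_equal(project_stack(s1)[1, 1, , ], matrix(1:20, 4, 5))

  b <- array(0, dim = c(1, 3, 1, 4, 4))
  b[1, 2, 1, , ] <- 7           # one bright plane
  s2 <- image_stack(b, "ch")
  expect_equal(project_stack(s2, "max")[1, 1, , ], matrix(7, 4, 4))
  expect_equal(project_stack(s2, "mean")[1, 1, , ], matrix(7 / 3, 4, 4))

  cst <- array(3, dim = c(2, 3, 1, 4, 4))
  expect_true(all(project_stack(image_stack(cst, "ch"), "mean") == 3))
})

test_that("particle detection recovers noise-free spot positions", {
  set.seed(1)
  n <- 10
  img <- matrix(0, 100, 100)
  cy <- seq(15, 85, length.out = 5)[rep(1:5, 2)]
  cx <- rep(c(30, 70), each = 5)
  for (i in 1:n)
    img <- img + 500 * exp(-((row(img) - cy[i])^2 + (col(img) - cx[i])^2) / (2 * 1.5^2))
  det <- detect_particles(img)
  expect_equal(nrow(det$table), n)
  d <- sqrt(outer(cy - 1, det$table$y_px, "-")^2 +
            outer(cx - 1, det$table$x_px, "-")^2)
  expect_true(all(apply(d, 1, min) <= 1))

  # uniform image -> no labels, no error
  expect_equal(nrow(detect_particles(matrix(5, 50, 50))$table), 0L)

  # single-pixel impulse removed by the size filter
  imp <- matrix(0, 50, 50); imp[25, 25] <- 100
  expect_equal(nrow(detect_particles(imp, min_size_px = 4,
                                     close_radius = 1)$table), 0L)
})

test_that("mean-in-mask measurement is exact and conserves the label set", {
  lab <- matrix(0L, 6, 6)
  lab[2:3, 2:3] <- 1L
  lab[5, 1:4] <- 2L
  mask <- structure(list(labels = lab, table = NULL), class = "label_mask")
  counter <- matrix(seq_len(36), 6, 6)
  out <- measure_in_mask(mask, counter)
  expect_equal(out$label, c(1L, 2L))
  expect_equal(out$mean[1], mean(counter[2:3, 2:3]))
  expect_equal(out$mean[2], mean(counter[5, 1:4]))

  expect_equal(mean(counter[2:3, 2:3]), mean(c(8, 9, 14, 15)))  # by hand

  # constant image: every mean equals the constant
  out2 <- measure_in_mask(mask, matrix(42, 6, 6))
  expect_true(all(out2$mean == 42))

  expect_equal(nrow(measure_in_mask(matrix(0L, 6, 6), counter)), 0L)
  expect_error(measure_in_mask(mask, matrix(0, 5, 5)), "shapes differ")

  # one output row per input label on real detections
  sim <- sim_image_stack(image_sim_config(seed = 4))
  ref <- project_stack(sim$stack, "mean")[1, 1, , ]
  det <- detect_particles(ref)
  expect_equal(sort(measure_in_mask(det, ref)$label), sort(det$table$label))
})

test_that("cell and ring masks obey their geometry", {
  img <- matrix(0, 140, 140)
  disk <- (row(img) - 70)^2 + (col(img) - 70)^2 <= 50^2
  img[disk] <- 200
  img <- img + 10   # offset background
  cr <- cell_and_ring(img, smooth_sigma = 2,
                      erode_outer_px = 5, erode_inner_px = 15)
  expect_true(all(cr$ring | !cr$ring))          # logical masks
  expect_true(all(cr$cell[cr$ring]))            # ring inside cell
  # ring area equals the difference of the two erosions
  er <- function(r) EBImage::erode(cr$cell, EBImage::makeBrush(2 * r + 1, "disc"))
  expect_equal(sum(cr$ring), sum(er(5)) - sum(er(15)))

  # particles are excluded from the ring
  pm <- matrix(0L, 140, 140); pm[70, 28:32] <- 1L
  det <- structure(list(labels = pm, table = NULL), class = "label_mask")
  cr2 <- cell_and_ring(img, particle_mask = det)
  expect_equal(sum(cr2$ring & (pm > 0)), 0L)

  expect_error(cell_and_ring(matrix(0, 50, 50)), "no cell")
})

test_that("ratio arithmetic and crescent scoring behave", {
  expect_equal(kc_cyto_ratio(300, 200, 100), 2)
  expect_equal(kc_cyto_ratio(200, 200, 0), 1)
  expect_error(kc_cyto_ratio(300, 90, 100), "indistinguishable")

  cls <- crescent_class(c(0.5, 1.0, 1.2, 2.0),
                        thresholds = c(0.9, 1.1, 1.3))
  expect_equal(as.character(cls), c("none", "low", "medium", "high"))
  expect_error(crescent_class(1, thresholds = c(1.3, 1.1, 0.9)),
               "increasing")
  # monotone: larger ratio never maps to a lower class
  r <- sort(runif(50, 0, 3))
  k <- crescent_class(r, thresholds = c(0.9, 1.1, 1.3))
  expect_true(all(diff(as.integer(k)) >= 0))
  # control quartiles as defaults: quartiles of ctrl are (0.95, 1.1, 1.25)
  ctrl <- c(0.8, 1.0, 1.2, 1.4)
  expect_equal(as.character(crescent_class(1.2, control = ctrl)), "medium")
  expect_equal(as.character(crescent_class(0.9, control = ctrl)), "none")
})

test_that("the pipeline recovers the true kinetochore/cytoplasm ratio", {
  # noise-free single-plane: exact recovery through the truth aperture
  cfg0 <- image_sim_config(poisson = FALSE, gaussian_sigma = 0, n_z = 1,
                           seed = 2)
  sim0 <- sim_image_stack(cfg0)
  img <- project_stack(sim0$stack, "mean")
  meas <- img[1, 2, , ]
  truth <- sim0$truth$spots
  sel1 <- (row(meas) - (round(truth$y_px[1]) + 1))^2 +
    (col(meas) - (round(truth$x_px[1]) + 1))^2 <= 3^2
  ratio_exact <- (mean(meas[sel1]) - 100) / 200
  expect_equal(ratio_exact, 2, tolerance = 1e-12)

  # noise-free pixel at a spot centre in the reference channel:
  # offset + cytoplasm + amplitude (up to subpixel placement)
  ref <- project_stack(sim0$stack, "max")[1, 1, , ]
  peak <- ref[round(truth$y_px[1]) + 1, round(truth$x_px[1]) + 1]
  expect_equal(peak, 100 + 30 + 400, tolerance = 0.05 * 400)

  # SNR 10 with shot noise: mean ratio within 5%
  errs <- vapply(1:5, function(s) {
    sim <- sim_image_stack(image_sim_config(seed = s))
    m <- quantify_stack(sim$stack)
    abs(mean(m$ratio) - 2) / 2
  }, numeric(1))
  expect_lt(mean(errs), 0.05)

  # SNR 3: mean ratio within 15%
  errs3 <- vapply(1:5, function(s) {
    sim <- sim_image_stack(image_sim_config(gaussian_sigma = 400 / 3, seed = s))
    m <- quantify_stack(sim$stack)
    abs(mean(m$ratio) - 2) / 2
  }, numeric(1))
  expect_lt(mean(errs3), 0.15)
})

test_that("detection meets precision/recall targets and masks stay disjoint", {
  for (s in 1:5) {
    sim <- sim_image_stack(image_sim_config(seed = s))
    proj <- project_stack(sim$stack, "mean")
    det <- detect_particles(proj[1, 1, , ])
    pr <- match_detections(sim$truth$spots, det$table)
    expect_gte(pr["recall"], 0.95)
    expect_gte(pr["precision"], 0.95)
    cr <- cell_and_ring(proj[1, 2, , ], particle_mask = det)
    expect_equal(sum(cr$ring & (det$labels > 0)), 0L)
    expect_true(all(cr$cell[cr$ring]))
  }
})

test_that("ratios are invariant under affine rescaling of the measurement channel", {
  sim <- sim_image_stack(image_sim_config(seed = 9))
  proj <- project_stack(sim$stack, "mean")
  ref <- proj[1, 1, , ]; meas <- proj[1, 2, , ]
  m1 <- quantify_frame(ref, meas)
  g <- 1.7; o <- 250
  m2 <- quantify_frame(ref, g * meas + o)
  expect_equal(m2$ratio, m1$ratio, tolerance = 0.02)
})
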