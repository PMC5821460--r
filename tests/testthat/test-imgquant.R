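test_that("isodata threshold agrees with the brute-force intermeans iteration", {
  # two-delta histogram converges to the midpoint
  x <- rep(c(10, 50), times = c(70, 30))
  expect_equal(isodata_threshold(x), 30)
  expect_equal(isodata_threshold(x), brute_isodata(x))
  withr::with_seed(15, {
    for (i in 1:5) {
      y <- c(rnorm(500, 20, 5), rnorm(200, 90, 10))
      expect_equal(isodata_threshold(y), brute_isodata(y), tolerance = 1e-6)
    }
  })
  # constant image: no foreground at the returned threshold
  expect_equal(sum(matrix(5, 10, 10) > isodata_threshold(matrix(5, 10, 10))), 0)
})

test_that("nucleus segmentation finds exactly the disks that are there", {
  expect_equal(max(segment_nuclei(matrix(7, 40, 40))), 0)
  f <- gen_cell_field(10, frac_nuclear = 0, width = 300, height = 300, seed = 16)
  img <- gen_image(f, intensity = image_intensity_params(noise_sd = 0), seed = 16)
  lab <- segment_nuclei(img$nuclear_channel)
  expect_equal(max(lab), 10)
  # specks below the area floor are discarded
  sp <- matrix(0, 60, 60); sp[30, 30] <- 1000; sp[10:20, 10:20] <- 1000
  expect_equal(max(segment_nuclei(sp, background_radius = 25)), 1)
})

test_that("compartment geometry: erosion, disjointness and the ring partition", {
  # disk of radius 10 eroded by 4 leaves the concentric disk of radius ~6
  m <- matrix(0L, 50, 50)
  ctr <- expand.grid(r = 1:50, c = 1:50)
  m[as.matrix(ctr[ (ctr$r - 25)^2 + (ctr$c - 25)^2 <= 100, ])] <- 1L
  comp <- build_compartments(m, compartment_geometry(inner_offset = 4))
  a <- sum(comp$circle == 1)
  expect_gt(a, pi * 5.5^2); expect_lt(a, pi * 6.5^2)
  expect_true(all(m[comp$circle == 1] == 1))          # circle inside nucleus
  expect_equal(sum(comp$circle > 0 & comp$ring > 0), 0)
  expect_equal(sum(comp$ring > 0 & m > 0), 0)          # ring outside nucleus
  # nucleus smaller than the erosion is flagged with an empty circle
  tiny <- matrix(0L, 20, 20); tiny[9:11, 9:11] <- 1L
  ct <- build_compartments(tiny, compartment_geometry(inner_offset = 4))
  expect_equal(ct$empty_circle, 1L)
  expect_equal(sum(ct$circle > 0), 0)
})

test_that("contested ring pixels go to the nearest nucleus (brute-force oracle)", {
  lab <- matrix(0L, 60, 60)
  grid <- as.matrix(expand.grid(r = 1:60, c = 1:60))
  d1 <- (grid[, 1] - 30)^2 + (grid[, 2] - 20)^2 <= 49
  d2 <- (grid[, 1] - 30)^2 + (grid[, 2] - 38)^2 <= 49
  lab[grid[d1, ]] <- 1L
  lab[grid[d2 & !d1, ]] <- 2L
  comp <- build_compartments(lab, compartment_geometry())
  # brute-force per-pixel scan: distance to the nearest pixel of each nucleus
  nuc1 <- grid[lab[grid] == 1L, , drop = FALSE]
  nuc2 <- grid[lab[grid] == 2L, , drop = FALSE]
  ring_px <- grid[comp$ring[grid] > 0, , drop = FALSE]
  for (j in seq_len(nrow(ring_px))) {
    p <- ring_px[j, ]
    dd1 <- min(sqrt((nuc1[, 1] - p[1])^2 + (nuc1[, 2] - p[2])^2))
    dd2 <- min(sqrt((nuc2[, 1] - p[1])^2 + (nuc2[, 2] - p[2])^2))
    want <- if (dd1 <= dd2) 1L else 2L   # ties to the lower label id
    expect_equal(comp$ring[p[1], p[2]], want)
  }
})

test_that("limits come from the negative-control maximum and re-score clean", {
  neg <- data.frame(circle_mean = c(10, 40, 25), ring_mean = c(5, 8, 30))
  lim <- calibrate_limits(neg)
  expect_equal(lim$circle_limit, 40)
  expect_equal(lim$ring_limit, 30)
  expect_error(calibrate_limits(neg[0, ]), "at least one")
  # definitional: no negative cell is positive at its own limits
  expect_equal(sum(neg$circle_mean > lim$circle_limit), 0)
  expect_equal(sum(neg$ring_mean > lim$ring_limit), 0)
})

test_that("quantification applies the percent-nuclear formula and recovers truth", {
  f <- gen_cell_field(50, frac_nuclear = 0.3, width = 400, height = 400,
                      seed = 17)
  img <- gen_image(f, seed = 17)
  lim <- make_negative_limits(seed = 9100)
  q <- quantify_localization(img, lim)
  s <- q$summary
  expect_equal(s$percent_nuclear,
               100 * s$nuclear_positive / s$cytoplasmic_positive)
  expect_lte(s$nuclear_positive, s$total_cells)
  expect_lte(s$cytoplasmic_positive, s$total_cells)
  expect_lt(abs(s$percent_nuclear - 100 * mean(f$cells$nuclear_positive)),
            2)  # ground-truth recovery, +-2 percentage points
  # nothing above an unreachable limit: counts zero, percent missing
  inf_lim <- structure(list(circle_limit = Inf, ring_limit = Inf,
                            statistic = "mean"), class = "limits")
  expect_warning(q0 <- quantify_localization(img, inf_lim), "undefined")
  expect_equal(q0$summary$nuclear_positive, 0)
  expect_true(is.na(q0$summary$percent_nuclear))
})

test_that("quantification is covariant under a constant intensity shift", {
  f <- gen_cell_field(30, frac_nuclear = 0.4, width = 300, height = 300,
                      seed = 18)
  img <- gen_image(f, seed = 18)
  lim <- make_negative_limits(n_fields = 1, width = 300, height = 300,
                              seed = 9200)
  q1 <- quantify_localization(img, lim)
  shift <- 250
  img2 <- img
  img2$marker_channel <- img$marker_channel + shift
  lim2 <- lim
  lim2$circle_limit <- lim$circle_limit + shift
  lim2$ring_limit <- lim$ring_limit + shift
  q2 <- quantify_localization(img2, lim2)
  expect_identical(q1$cells$nuclear_positive, q2$cells$nuclear_positive)
  expect_identical(q1$cells$cytoplasmic_positive, q2$cells$cytoplasmic_positive)
})
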