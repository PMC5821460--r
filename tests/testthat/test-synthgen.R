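test_that("cell-field generator honours counts, labels and pairing", {
  expect_equal(nrow(gen_cell_field(0, seed = 1)$cells), 0)
  f0 <- gen_cell_field(300, frac_nuclear = 0, seed = 2)
  expect_false(any(f0$cells$nuclear_positive))
  expect_error(gen_cell_field(-5), "n_cells")
  expect_error(gen_cell_field(10, frac_nuclear = 2), "fraction")
  f <- gen_cell_field(500, frac_nuclear = 0.3, frac_paired = 0.5, seed = 3)
  cc <- f$cells
  expect_true(all(cc$x >= 0 & cc$x <= f$width & cc$y >= 0 & cc$y <= f$height))
  expect_false(anyDuplicated(cc$id) > 0)
  # pair ids group exactly two cells, all nuclear-positive
  pid <- cc$pair_id[!is.na(cc$pair_id)]
  expect_true(all(table(pid) == 2))
  expect_true(all(cc$nuclear_positive[!is.na(cc$pair_id)]))
  # determinism
  expect_identical(f$cells, gen_cell_field(500, frac_nuclear = 0.3,
                                           frac_paired = 0.5, seed = 3)$cells)
})

test_that("within-pair separation matches the requested law", {
  f <- gen_cell_field(10000, frac_nuclear = 1, frac_paired = 1,
                      pair_sep_mean = 10, pair_sep_sd = 1,
                      width = 2000, height = 2000, seed = 4)
  cc <- f$cells[!is.na(f$cells$pair_id), ]
  cc <- cc[order(cc$pair_id), ]
  sep <- sqrt(diff(cc$x)[c(TRUE, FALSE)]^2 + diff(cc$y)[c(TRUE, FALSE)]^2)
  expect_equal(length(sep), 5000)
  expect_equal(mean(sep), 10, tolerance = 0.1 / 10)  # sample-mean oracle
})

test_that("image generator produces exact noiseless intensities and truth", {
  empty <- gen_cell_field(0, width = 60, height = 60)
  img0 <- gen_image(empty, intensity = image_intensity_params(noise_sd = 0))
  expect_true(all(img0$nuclear_channel == 100))  # pure background
  expect_true(all(img0$marker_channel == 100))
  # one nuclear-positive cell, no noise: marker over the nucleus disk is
  # exactly nuclear_marker_mean + background
  f1 <- gen_cell_field(1, frac_nuclear = 1, width = 80, height = 80, seed = 5)
  img1 <- gen_image(f1, intensity = image_intensity_params(noise_sd = 0))
  tr <- img1$truth
  disk <- expand.grid(dx = -6:6, dy = -6:6)
  disk <- disk[disk$dx^2 + disk$dy^2 <= 36, ]
  vals <- img1$marker_channel[cbind(tr$cy + disk$dy, tr$cx + disk$dx)]
  expect_true(all(vals == 800 + 100))
  expect_true(tr$nuclear_positive)
  expect_error(gen_image(f1, nucleus_radius = 1), "nucleus_radius")
  # overcrowded field cannot be placed
  dense <- gen_cell_field(300, width = 40, height = 40, seed = 6)
  expect_error(gen_image(dense, max_iter = 5), "too dense")
})

test_that("snapshot generator reproduces planted phase mixtures and DNA model", {
  m <- hela_cycle_model()
  g1 <- gen_facs_snapshot(m, n = 200, event_rule = "fixed_phase_mixture",
                          mixture = phase_fractions(1, 0, 0), dna_cv = 0,
                          seed = 7)
  expect_true(all(g1$events$dna == 100))  # every G1 event exactly at 2N
  expect_error(gen_facs_snapshot(m, n = 10, event_rule = "fixed_phase_mixture",
                                 mixture = c(0.5, 0.3, 0.3)), "sum to 1")
  expect_error(gen_facs_snapshot(m, n = 10, event_rule = "uniform_in_S",
                                 mixture = phase_fractions(1, 0, 0)), "mixture")
  mix <- phase_fractions(0.5, 0.3, 0.2)
  n <- 100000
  fx <- gen_facs_snapshot(m, n = n, event_rule = "fixed_phase_mixture",
                          mixture = mix, seed = 8)
  emp <- table(fx$events$true_phase) / n
  se <- sqrt(unclass(mix) * (1 - unclass(mix)) / n)  # multinomial oracle
  expect_true(all(abs(emp - unclass(mix)) < 3 * se))
  expect_true(all(fx$events$blue >= 0 & fx$events$red >= 0 & fx$events$dna >= 0))
  # S-restricted events enrich S among blue+ red-low cells
  fk <- gen_facs_snapshot(m, n = 30000, event_rule = "uniform_in_S", seed = 9)
  g <- gate_ft(fk)
  low_phases <- fk$events$true_phase[g$labels == "blue_pos_red_low"]
  expect_gt(mean(low_phases == "S"), 0.5)
  expect_false(any(fk$events$true_phase[g$labels != "blue_neg"] == "G1"))
})

test_that("time-course generator: events, delays and the asynchronous control", {
  m <- hela_cycle_model()
  tc0 <- gen_timecourse(m, seq(0, 24, 3), 2000, event_prob = 0, seed = 10)
  expect_true(all(tc0$gfp_percent == 0))
  expect_error(gen_timecourse(m, c(3), 100), "two timepoints")
  expect_error(gen_timecourse(m, c(0, 3, 3), 100), "increasing")
  # synchronized, zero delay: events live strictly in the S window, and the
  # steepest rise sits inside S (truth event-time histogram oracle)
  tc <- gen_timecourse(m, seq(0, 24, 3), 50000, event_prob = 0.05, seed = 11)
  ev <- tc$truth$event_time
  expect_true(all(is.na(ev) | (ev >= m$d_G1 & ev <= m$d_G1 + m$d_S)))
  hist_peak <- which.max(diff(tc$gfp_percent))
  windows <- phase_windows_from_model(m)
  mid <- (tc$timepoints[hist_peak] + tc$timepoints[hist_peak + 1]) / 2
  expect_true(mid > windows$start[2] && mid < windows$end[2])
  # asynchronous control rises near-linearly: no significant slope peak
  tca <- gen_timecourse(m, seq(0, 24, 3), 50000, event_prob = 0.05,
                        synchronized = FALSE, seed = 12)
  ssa <- slope_analysis(tca$timepoints, tca$gfp_percent)
  expect_true(ssa$no_peak)
})

test_that("peptide-table generator plants classes that classify back exactly", {
  empty <- gen_peptide_table(c(red = 0, orange = 0, yellow = 0, gray = 0))
  expect_equal(nrow(empty), 0)
  tab <- gen_peptide_table(c(red = 5, orange = 5, yellow = 5, gray = 5),
                           seed = 13)
  rep <- classify_confidence(tab)
  expect_equal(as.character(rep$proteins$class), tab$planted_class)
  # gray-only table leaves no interactors after filtering
  gray <- gen_peptide_table(c(red = 0, orange = 0, yellow = 0, gray = 8),
                            seed = 14)
  flt <- filter_min_unique(gray)
  expect_true(all(exclusive_interactors(flt, 1) %in% character(0)) ||
                nrow(flt) == 0 || all(flt$IgG_1 > 0))
  repg <- classify_confidence(gray)
  expect_true(all(repg$proteins$class == "gray"))
})
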