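test_that("DNA-content deconvolution handles degenerate and planted inputs", {
  expect_equal(unname(unclass(deconvolve_dna(rep(100, 2000))$fractions)),
               c(1, 0, 0))
  m <- hela_cycle_model()
  # planted mixtures recovered within 2 percentage points (10 seeds)
  mix <- phase_fractions(0.5, 0.3, 0.2)
  for (s in 1:10) {
    f <- gen_facs_snapshot(m, n = 100000, event_rule = "fixed_phase_mixture",
                           mixture = mix, seed = 500 + s)
    fit <- deconvolve_dna(f$events$dna)
    expect_true(all(abs(unclass(fit$fractions) - unclass(mix)) < 0.02))
  }
  expect_warning(deconvolve_dna(rnorm(500, 100, 5)), "fewer than 1000")
})

test_that("slope analysis: hand finite differences, peak and no-peak calls", {
  ss <- slope_analysis(c(0, 3, 6, 9, 12), c(0, 0, 2, 8, 9))
  expect_equal(ss$intervals$slope, c(0, 2 / 3, 2, 1 / 3))
  expect_equal(ss$peak_interval, c(6, 9))
  expect_false(ss$no_peak)
  # perfectly linear rise raises the no-peak flag
  lin <- slope_analysis(seq(0, 24, 3), seq(0, 8, 1))
  expect_true(lin$no_peak)
  expect_error(slope_analysis(c(0, 3), c(1, 2)), "3 timepoints")
  expect_error(slope_analysis(c(0, 3, 2), c(1, 2, 3)), "increasing")
  # interval annotation by majority overlap with the phase windows
  w <- phase_windows_from_model(hela_cycle_model())
  ss2 <- slope_analysis(c(0, 3, 6, 9, 12, 15, 18, 21, 24),
                        c(0, 0, 0, 0, 1, 3, 4, 4.5, 4.6), w)
  expect_equal(ss2$peak_phase, "S")
})

test_that("timer traces follow first-order closed forms", {
  kin <- ft_kinetics()
  tr <- ft_trace(kin, seq(0, 15, 0.1))
  expect_equal(tr$red[1], 0)
  expect_equal(tr$red, 1 - exp(-kin$k_mat * tr$times), tolerance = 1e-9)
  expect_equal(tr$conversion_time, log(2) / kin$k_mat)
  # ongoing transcription keeps a standing blue pool while red accumulates
  tro <- ft_trace(kin, seq(0, 30, 0.5), "ongoing_transcription", rate = 2)
  expect_lt(diff(utils::tail(tro$blue, 2)), 1e-3)   # blue at steady state
  expect_gt(diff(utils::tail(tro$red, 2)), 0.9)     # red still rising ~rate
  expect_error(ft_kinetics(k_mat = -1), "positive")
})

test_that("conversion-time estimator: exactness, spread and bias across rates", {
  tr0 <- gen_ft_traces(10, conv_sd = 1e-12, noise_sd = 0, seed = 27)
  est0 <- estimate_conversion_time(tr0)
  expect_equal(est0$mean, 2.35, tolerance = 0.01 / 2.35)
  expect_equal(est0$sd, 0, tolerance = 1e-6)
  one <- estimate_conversion_time(tr0[1])
  expect_equal(one$sd, 0)
  # bias below 5% over a grid of maturation rates, noise sd 5% of plateau
  for (k in c(0.1, 0.3, 0.6, 1.0)) {
    kin <- ft_kinetics(k_mat = k)
    horizon <- ceiling(6 * log(2) / k)
    tr <- gen_ft_traces(100, kin, times = seq(0, horizon, 0.25),
                        conv_sd = 1e-12, noise_sd = 0.05, seed = 28)
    est <- estimate_conversion_time(tr)
    expect_lt(abs(est$mean - log(2) / k) / (log(2) / k), 0.05)
  }
  # traces cut before the plateau are excluded, not mis-scored
  kin <- ft_kinetics(k_mat = 0.05)
  short <- gen_ft_traces(5, kin, times = seq(0, 4, 0.25), conv_sd = 1e-12,
                         noise_sd = 0, seed = 29)
  expect_error(estimate_conversion_time(short), "plateau")
})

test_that("onset quantiles: step curve, closed-form lognormal and warnings", {
  oc <- onset_curve(rep(3, 1000))
  q <- onset_quantiles(oc)
  expect_equal(unname(q), c(3, 3), tolerance = 0.01)
  # analytic lognormal delay matches the inverse CDF
  kin <- ft_kinetics()
  tt <- seq(0, 30, 0.001)
  q2 <- onset_quantiles(tt, stats::plnorm(tt, kin$onset_meanlog, kin$onset_sdlog))
  expect_equal(unname(q2["t50"]), 2.71, tolerance = 1e-3)
  expect_equal(unname(q2["t90"]), 8.01, tolerance = 1e-3)
  expect_warning(q3 <- onset_quantiles(c(0, 1, 2), c(0, 0.3, 0.6)),
                 "never reaches")
  expect_true(is.na(q3["t90"]))
  expect_error(onset_quantiles(c(0, 1), c(0.5, 0.2)), "nondecreasing")
})

test_that("timer gating is order-based and respects the negative rule", {
  ev <- data.frame(blue = c(1, 2, 3), red = c(5, 1, 2),
                   true_event_time = c(NA, NA, NA))
  g <- expect_warning(gate_ft(ev, blue_threshold = 10), "no blue-positive")
  expect_true(all(g$labels == "blue_neg"))
  m <- hela_cycle_model()
  f <- gen_facs_snapshot(m, n = 5000, event_rule = "uniform_in_S", seed = 30)
  g1 <- gate_ft(f)
  # auto threshold is the negative-control maximum
  expect_equal(g1$blue_threshold,
               max(f$events$blue[is.na(f$events$true_event_time)]))
  # invariance under monotone rescaling with matching thresholds
  ev2 <- f$events
  ev2$blue <- ev2$blue * 3; ev2$red <- ev2$red * 5
  g2 <- gate_ft(ev2, blue_threshold = g1$blue_threshold * 3,
                red_split = g1$red_threshold * 5)
  expect_identical(g1$labels, g2$labels)
})

test_that("FUCCI contingency counts and the binomial control", {
  fc0 <- fucci_contingency(logical(0), character(0))
  expect_equal(fc0$total, 0)
  expect_true(all(fc0$table == 0))
  expect_error(fucci_contingency(TRUE, "blue"), "unknown")
  # random colours at G1 fraction q: red & nuclear ~ Binomial(n_nuclear, q)
  withr::with_seed(31, {
    q <- 0.495
    nuc <- rep(c(TRUE, FALSE), c(400, 600))
    col <- sample(c("red", "green"), 1000, replace = TRUE, prob = c(q, 1 - q))
    fc <- fucci_contingency(nuc, col)
    expect_lt(abs(fc$table["TRUE", "red"] - q * 400),
              3 * sqrt(400 * q * (1 - q)))
    expect_equal(fc$total, 1000)
  })
})

test_that("western normalization is the H3 ratio anchored at time zero", {
  r <- normalize_westerns(c(0, 3), c(100, 300), c(100, 150))
  expect_equal(r$relative_units, c(1, 2))
  same <- normalize_westerns(c(0, 2, 4), c(5, 7, 9), c(5, 7, 9))
  expect_equal(same$relative_units, c(1, 1, 1))
  expect_error(normalize_westerns(c(0, 1), c(1, 2), c(0, 1)), "positive")
  expect_equal(normalize_westerns(0, 42, 7)$relative_units, 1)
})
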