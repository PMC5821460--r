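test_that("nearest-neighbour distances match hand values and the O(n^2) oracle", {
  expect_equal(nn_distances(rbind(c(0, 0), c(3, 4))), c(5, 5))
  expect_error(nn_distances(rbind(c(1, 1))), "at least 2")
  withr::with_seed(19, {
    for (n in c(10, 50, 200)) {
      xy <- cbind(runif(n, 0, 100), runif(n, 0, 100))
      expect_equal(nn_distances(xy), brute_nn(xy))
    }
  })
})

test_that("resampled null matches exhaustive enumeration and density scaling", {
  # degenerate: population of exactly k cells gives identical rows
  f2 <- gen_cell_field(2, frac_nuclear = 0, seed = 20)
  nl <- resample_null(f2, k = 2, n_perm = 50, seed = 1)
  expect_equal(nrow(unique(nl)), 1)
  expect_error(resample_null(f2, k = 3, n_perm = 10), "smaller than")
  # 5 cells, k = 2: the 10 possible subsets each surface with frequency
  # ~1/10 (exhaustive oracle, Monte-Carlo tolerance)
  f5 <- gen_cell_field(5, frac_nuclear = 0, seed = 21)
  xy <- cbind(f5$cells$x, f5$cells$y)
  pairs <- utils::combn(5, 2)
  exhaustive <- sort(apply(pairs, 2, function(ij)
    sqrt(sum((xy[ij[1], ] - xy[ij[2], ])^2))))
  nl5 <- resample_null(f5, k = 2, n_perm = 1000, source = "all", seed = 2)
  expect_true(all(nl5[, 1] == nl5[, 2]))           # both members share the NN
  expect_setequal(round(unique(nl5[, 1]), 9), round(exhaustive, 9))
  freq <- table(factor(round(nl5[, 1], 9), levels = round(exhaustive, 9))) / 1000
  expect_true(all(abs(freq - 0.1) < 0.05))
  # null mean NN distance falls as field density rises
  lo <- gen_cell_field(100, frac_nuclear = 0, seed = 22)
  hi <- gen_cell_field(400, frac_nuclear = 0, seed = 23)
  expect_gt(mean(resample_null(lo, 10, 200, seed = 3)),
            mean(resample_null(hi, 10, 200, seed = 3)))
})

test_that("per-cell permutation p-values use add-one pooling and BH", {
  null <- matrix(2:101, nrow = 100)  # pooled null 2..101
  sig <- per_cell_significance(c(1, 200), null)
  expect_equal(sig$p[1], 1 / 101)            # smaller than all null values
  expect_equal(sig$p[2], 1)
  med <- per_cell_significance(stats::median(2:101), null)$p
  expect_equal(med, 0.5, tolerance = 0.02)
  expect_error(per_cell_significance(1, matrix(numeric(0), 0, 0)), "empty")
  # hand-computed Benjamini-Hochberg
  p <- c(0.01, 0.02, 0.04, 0.5)
  q_hand <- c(0.04, 0.04, 0.04 * 4 / 3, 0.5)
  expect_equal(stats::p.adjust(p, "BH"), q_hand)
  fake <- per_cell_significance(c(3, 4, 6, 80), matrix(2:101, 100))
  expect_true(all(fake$q >= fake$p))
})

test_that("proximity test end-to-end: errors, determinism, planted signal", {
  all_nuc <- gen_cell_field(20, frac_nuclear = 1, seed = 24)
  expect_error(proximity_test(all_nuc), "non-nuclear")
  f <- gen_cell_field(150, frac_nuclear = 0.15, seed = 25)
  r1 <- proximity_test(f, seed = 5)
  r2 <- proximity_test(f, seed = 5)
  expect_identical(r1, r2)  # bit-for-bit reproducible
  expect_equal(length(r1$observed_nn), r1$k)
  expect_true(all(r1$per_cell$p > 0 & r1$per_cell$p <= 1))
  # planted daughter pairs: strong signal on every output
  fp <- gen_cell_field(200, frac_nuclear = 0.15, frac_paired = 0.8,
                       pair_sep_mean = 10, pair_sep_sd = 1, seed = 26)
  rp <- proximity_test(fp, seed = 6)
  expect_lt(rp$ranksum_p, 1e-3)
  expect_lt(rp$ranksum_p_all, 1e-3)
  expect_equal(rp$ranksum_p_calibrated, 1 / 1001)  # permutation floor
  expect_gt(length(rp$selected), 0)
})

test_that("per-cell permutation p-values are valid under random labelling", {
  # P(p <= alpha) <= alpha + Monte-Carlo tolerance, pooling cells over fields
  hits <- 0; tot <- 0
  for (s in 1:30) {
    f <- gen_cell_field(100, frac_nuclear = 0.12, seed = 400 + s)
    nuc <- f$cells[f$cells$nuclear_positive, ]
    if (nrow(nuc) < 2) next
    obs <- nn_distances(cbind(nuc$x, nuc$y))
    nl <- resample_null(f, nrow(nuc), n_perm = 200, seed = s)
    p <- per_cell_significance(obs, nl)$p
    hits <- hits + sum(p <= 0.1); tot <- tot + length(p)
  }
  expect_lt(hits / tot, 0.1 + 3 * sqrt(0.1 * 0.9 / tot))
})
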