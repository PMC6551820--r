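# Normalization, relative fluorescence, fold change, BH adjustment,
# classification.

make_table <- function(pairs, values, batch = 1L) {
  # pairs: list of c(n, c); values: list of numeric replicate vectors
  rows <- mapply(function(p, v) {
    data.frame(construct_n = p[1], construct_c = p[2],
               replicate = seq_along(v), batch = batch,
               raw_fluorescence = v, normalizer = 1,
               stringsAsFactors = FALSE)
  }, pairs, values, SIMPLIFY = FALSE)
  do.call(rbind, rows)
}

test_that("normalization is the record-wise ratio and scale invariant", {
  tab <- make_table(list(c("A", "A")), list(c(1000, 800)))
  tab$normalizer <- c(0.5, 0.4)
  expect_equal(normalize_assay(tab)$normalized, c(2000, 2000))
  tab3 <- tab
  tab3$raw_fluorescence <- tab3$raw_fluorescence * 3
  tab3$normalizer <- tab3$normalizer * 3
  expect_equal(normalize_assay(tab3)$normalized,
               normalize_assay(tab)$normalized)
  bad <- tab; bad$normalizer[2] <- 0
  expect_error(normalize_assay(bad), "record 2")
  bad2 <- tab; bad2$raw_fluorescence[1] <- 0
  expect_error(normalize_assay(bad2), "positive")
  dup <- rbind(tab, tab[1, ])
  expect_error(normalize_assay(dup), "duplicate")
})

test_that("relative fluorescence pins the positive control at 1", {
  tab <- make_table(list(c("GpA", "GpA"), c("X", "X")),
                    list(c(2.0, 2.4, 1.6), c(0.9, 1.1)))
  rel <- relative_to_control(normalize_assay(tab), c("GpA", "GpA"))
  expect_equal(mean(rel$relative[rel$construct_n == "GpA"]), 1)
  expect_equal(mean(rel$relative[rel$construct_n == "X"]), 0.5)
  expect_error(relative_to_control(normalize_assay(tab), c("Zz", "Zz")),
               "absent")
  # batch-wise control matching
  t1 <- make_table(list(c("GpA", "GpA"), c("X", "X")),
                   list(c(2, 2), c(1, 1)), batch = 1L)
  t2 <- make_table(list(c("GpA", "GpA"), c("X", "X")),
                   list(c(4, 4), c(2, 2)), batch = 2L)
  both <- relative_to_control(normalize_assay(rbind(t1, t2)),
                              c("GpA", "GpA"), batchwise = TRUE)
  expect_equal(both$relative[both$construct_n == "X"], rep(0.5, 4))
  missing_ctrl <- rbind(t1, make_table(list(c("X", "X")), list(c(2, 2)),
                                       batch = 3L))
  expect_error(relative_to_control(normalize_assay(missing_ctrl),
                                   c("GpA", "GpA"), batchwise = TRUE),
               "batch")
})

test_that("hetero fold change uses the merged homo reference", {
  # X/X mean 1.0, Y/Y mean 0.6, hetero mean 0.4 -> fold change 0.4/0.8 = 0.5
  tab <- make_table(list(c("X", "X"), c("Y", "Y"), c("X", "Y")),
                    list(c(0.9, 1.1, 1.0, 1.0), c(0.5, 0.7, 0.6, 0.6),
                         c(0.35, 0.45, 0.4, 0.4)))
  tab <- normalize_assay(tab); tab$relative <- tab$normalized
  fc <- hetero_fold_change(tab, c("X", "Y"))
  expect_equal(fc$fold_change, 0.5)
  expect_equal(fc$n_reference, 8L)
  # identical samples: fold change 1, p = 1
  same <- make_table(list(c("X", "X"), c("Y", "Y"), c("X", "Y")),
                     list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3, 1, 2, 3)))
  same <- normalize_assay(same); same$relative <- same$normalized
  fc2 <- hetero_fold_change(same, c("X", "Y"))
  expect_equal(fc2$fold_change, 1)
  expect_equal(fc2$p_value, 1, tolerance = 1e-12)
  # far-separated samples: p below 1e-4, agreeing with a direct t CDF
  shifted <- make_table(list(c("X", "X"), c("Y", "Y"), c("X", "Y")),
                        list(c(10, 10.1, 9.9, 10, 10.05, 9.95),
                             c(10.1, 9.9, 10, 10.02, 9.98, 10),
                             c(1, 1.1, 0.9, 1, 1.05, 0.95)))
  shifted <- normalize_assay(shifted); shifted$relative <- shifted$normalized
  fc3 <- hetero_fold_change(shifted, c("X", "Y"))
  expect_lt(fc3$p_value, 1e-4)
  x <- shifted$relative[shifted$construct_n == "X" &
                          shifted$construct_c == "Y"]
  y <- shifted$relative[shifted$construct_n == shifted$construct_c]
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  tstat <- (mean(x) - mean(y)) / (sp * sqrt(1 / length(x) + 1 / length(y)))
  expect_equal(fc3$p_value,
               2 * pt(-abs(tstat), df = length(x) + length(y) - 2),
               tolerance = 1e-12)
  expect_error(hetero_fold_change(tab, c("X", "Z")), "homo")
})

test_that("BH adjustment matches brute-force enumeration", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(19)
  for (i in 1:25) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_lt(max(abs(q - brute_force_bh(p))), 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("classification implements the three-way decision rule", {
  res <- data.frame(q_vs_negative = c(0.001, 0.001, 0.50),
                    q_vs_homo     = c(0.80,  0.01,  0.01))
  expect_equal(classify_pairs(res), c("dimer", "reduced", "background"))
  expect_error(classify_pairs(data.frame(q_vs_negative = 0.1)), "q_vs")
})

test_that("the end-to-end analysis flags the configured background pair", {
  design <- data.frame(
    construct_n = c("GpA", "H2", "17L", "29L", "17L", "17L"),
    construct_c = c("GpA", "H2", "17L", "29L", "29L", "H2"),
    effect      = c(1.0,   0.05, 0.8,   0.7,   0.75,  0.05))
  tab <- generate_assay_table(design, n_replicates = 6, cv = 0.1, seed = 21)
  res <- analyze_assay(tab, c("GpA", "GpA"), c("H2", "H2"))
  key <- paste(res$construct_x, res$construct_y, sep = "/")
  expect_equal(res$call[key == "17L/H2"], "background")
  expect_equal(res$call[key == "17L/29L"], "dimer")
  expect_true(all(res$q_vs_homo >= res$p_vs_homo - 1e-15))
})

test_that("fold change is invariant under global rescaling", {
  design <- data.frame(construct_n = c("X", "Y", "X"),
                       construct_c = c("X", "Y", "Y"),
                       effect = c(1.0, 0.6, 0.4))
  tab <- generate_assay_table(design, n_replicates = 8, cv = 0.1, seed = 22)
  tab <- normalize_assay(tab); tab$relative <- tab$normalized
  fc1 <- hetero_fold_change(tab, c("X", "Y"))
  tab2 <- tab; tab2$relative <- tab2$relative * 37
  fc2 <- hetero_fold_change(tab2, c("X", "Y"))
  expect_equal(fc1$fold_change, fc2$fold_change, tolerance = 1e-12)
  expect_equal(fc1$p_value, fc2$p_value, tolerance = 1e-12)
})

test_that("false-negative rate falls as the effect gap grows", {
  fnr <- vapply(c(0.9, 0.7, 0.5), function(eff) {
    misses <- 0L
    for (s in 1:150) {
      design <- data.frame(construct_n = c("GpA", "H2", "X", "Y", "X"),
                           construct_c = c("GpA", "H2", "X", "Y", "Y"),
                           effect = c(1.0, 0.05, 1.0, 1.0, eff))
      tab <- generate_assay_table(design, n_replicates = 6, cv = 0.1,
                                  seed = 1000 + s)
      res <- analyze_assay(tab, c("GpA", "GpA"), c("H2", "H2"))
      row <- res[res$construct_x == "X" & res$construct_y == "Y", ]
      if (row$call != "reduced") misses <- misses + 1L
    }
    misses / 150
  }, numeric(1))
  # power rises with the gap; the strong effects may saturate at FNR = 0
  expect_true(all(diff(fnr) <= 0))
  expect_gt(fnr[1], fnr[3])
  expect_lt(fnr[3], 0.1)  # a halved effect is essentially always caught
})
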