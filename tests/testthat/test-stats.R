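test_that("log2 pseudo-count transform is exact and invertible", {
  m <- toy_matrix(matrix(c(0, 7, 3, 1e8), 2, 2))
  lg <- log2p1(m, 1)
  expect_identical(unclass(lg)[1, 1], 0)
  expect_identical(unclass(lg)[2, 1], 3)
  expect_true(attr(lg, "log_scale"))
  back <- 2^unclass(lg) - 1
  expect_equal(back, unclass(m), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(log2p1(m, -1), "pseudo_count")
  expect_error(log2p1(lg), "already")
})

test_that("half-minimum imputation replaces zeros per metabolite", {
  m <- toy_matrix(rbind(c(0, 4, 8, 0),
                        c(0, 0, 0, 0),
                        c(1, 2, 3, 4)))
  imp <- half_min_impute(m)
  expect_identical(unname(unclass(imp)[1, ]), c(2, 4, 8, 2))
  expect_identical(unname(unclass(imp)[2, ]), rep(0, 4))
  expect_identical(attr(imp, "undetected"), "m2")
  expect_identical(unclass(imp)[3, ], unclass(m)[3, ])
  # minimum is taken across all samples, not per group
  expect_identical(unclass(imp)[1, 4], 2)
})

test_that("RLE size factors equal the hand-computed median of ratios", {
  a <- c(10, 100)
  m <- toy_matrix(cbind(a, 2 * a), smp = c("A", "B"))
  f <- rle_size_factors(m)
  expect_equal(unname(f), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

  # identical samples: unit factors
  same <- toy_matrix(cbind(a, a))
  expect_equal(unname(rle_size_factors(same)), c(1, 1), tolerance = 1e-12)

  # permuting samples permutes factors
  m3 <- toy_matrix(cbind(a, 2 * a, 5 * a), smp = c("A", "B", "C"))
  f3 <- rle_size_factors(m3)
  perm <- toy_matrix(cbind(5 * a, a, 2 * a), smp = c("C", "A", "B"))
  expect_equal(rle_size_factors(perm)[names(f3)], f3, tolerance = 1e-12)

  # scale equivariance before the geometric-mean-1 constraint
  m4 <- toy_matrix(cbind(a, 3 * a), smp = c("A", "B"))
  f4 <- rle_size_factors(m4)
  expect_equal(unname(f4[2] / f4[1]), 3, tolerance = 1e-12)

  expect_error(rle_size_factors(toy_matrix(rbind(c(0, 1), c(2, 0)))),
               "half_min_impute")
})

test_that("RLE normalization equalizes scaled samples and is idempotent", {
  a <- c(10, 100, 55)
  m <- toy_matrix(cbind(a, 2 * a), smp = c("A", "B"))
  norm <- rle_normalize(m)
  expect_equal(unclass(norm)[, 1], unclass(norm)[, 2], tolerance = 1e-12)
  expect_true(attr(norm, "normalized"))
  refac <- rle_size_factors(im_raw <- toy_matrix(unclass(norm),
                                                 smp = c("A", "B")))
  expect_equal(unname(refac), c(1, 1), tolerance = 1e-9)
  single <- toy_matrix(matrix(a, ncol = 1))
  expect_equal(unclass(rle_normalize(single)), unclass(single),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("mean equalization makes per-sample means equal over the id set", {
  a <- c(10, 100, 50)
  m <- toy_matrix(cbind(a, 3 * a, 1.7 * a), smp = c("A", "B", "C"))
  eq <- mean_equalize(m, c("m1", "m2", "m3"))
  means <- colMeans(unclass(eq))
  expect_equal(max(means) / min(means), 1, tolerance = 1e-9)
  # the x3 sample is scaled down by 3 relative to the x1 sample
  expect_equal(unclass(eq)[, "B"] / unclass(eq)[, "A"], rep(1, 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  already <- mean_equalize(eq, c("m1", "m2", "m3"))
  expect_equal(unclass(already), unclass(eq), tolerance = 1e-12)
  expect_error(mean_equalize(m, character(0)), "no metabolites")
})

test_that("Gaussian GLM group test matches classical t-tests to 1e-10", {
  set.seed(11)
  for (rep in 1:5) {
    y <- rnorm(12, mean = rep(c(10, 11), each = 6), sd = 0.8)
    g <- rep(c("ref", "tst"), each = 6)
    fit <- fit_group_test(y, g)
    tt <- stats::t.test(y[g == "tst"], y[g == "ref"], var.equal = TRUE)
    expect_equal(fit$p_value, tt$p.value, tolerance = 1e-10)
    expect_equal(fit$coefficient,
                 mean(y[g == "tst"]) - mean(y[g == "ref"]),
                 tolerance = 1e-10)

    pair <- rep(sprintf("p%d", 1:6), 2)
    pfit <- fit_group_test(y, g, pair = pair)
    ptt <- stats::t.test(y[g == "tst"], y[g == "ref"], paired = TRUE)
    expect_equal(pfit$p_value, ptt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate and rank-deficient designs are handled by convention", {
  y <- rep(5, 8)
  g <- rep(c("a", "b"), each = 4)
  fit <- fit_group_test(y, g)
  expect_equal(fit$coefficient, 0, tolerance = 1e-12)
  expect_identical(fit$p_value, 1)
  expect_true(fit$degenerate)

  # exact shift with zero residual variance: p -> 0, flagged
  y2 <- rep(c(5, 7), each = 4)
  fit2 <- fit_group_test(y2, g)
  expect_equal(fit2$coefficient, 2, tolerance = 1e-12)
  expect_identical(fit2$p_value, 0)
  expect_true(fit2$degenerate)

  # batch perfectly confounded with group
  expect_error(fit_group_test(rnorm(8), g, batch = g), "collinear")
  expect_error(fit_group_test(rnorm(8), rep("a", 8)), "two levels")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(benjamini_hochberg(c(0.01, 0.04)), c(0.02, 0.04))
  expect_identical(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 7)), rep(0.2, 7))
  set.seed(3)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))^sample(1:3, 1)
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("above-background calls clear cells against sheath-fluid blanks", {
  # one real metabolite plus one null so BH has >1 test
  m <- toy_matrix(rbind(c(0, 0, 0, 100, 110, 90),
                        c(50, 55, 45, 52, 50, 49)),
                  smp = c("bl1", "bl2", "bl3", "c1", "c2", "c3"))
  meta <- toy_meta(colnames(m), rep(c("blank", "cell"), each = 3),
                   rep(c("blank", "X"), each = 3))
  calls <- above_background(m, meta)
  expect_true(calls$above_background[1])
  expect_false(calls$above_background[2])
  # hand oracle for the fold over blank: ratio of geometric means of x+1
  lg <- log2(unclass(m) + 1)
  expect_equal(calls$log2_fc[1], mean(lg[1, 4:6]) - mean(lg[1, 1:3]),
               tolerance = 1e-10)

  expect_error(above_background(m, toy_meta(colnames(m), rep("cell", 6),
                                            rep("X", 6))), "blank")
  expect_error(above_background(log2p1(m), meta), "raw")
})

test_that("differential abundance recovers a planted effect and respects symmetry", {
  set.seed(21)
  n <- 40L
  base <- 2^rnorm(n, 17, 0.3)
  a <- sapply(1:4, function(i) base * 2^rnorm(n, 0, 0.25))
  b <- sapply(1:4, function(i) base * 2^rnorm(n, 0, 0.25))
  b[1, ] <- b[1, ] * 8 # planted 8-fold increase in the test group
  m <- toy_matrix(cbind(a, b), smp = sprintf("s%d", 1:8))
  meta <- toy_meta(colnames(m), rep("cell", 8), rep(c("A", "B"), each = 4))
  res <- differential_abundance(m, meta, "A", "B")
  expect_true(res$significant[res$metabolite_id == "m1"])
  expect_identical(res$direction[res$metabolite_id == "m1"], "up")
  expect_equal(res$log2_fc[1], 3, tolerance = 0.6)

  # swapping groups negates log2 fold changes and preserves p values
  swap <- differential_abundance(m, meta, "B", "A")
  expect_equal(swap$log2_fc, -res$log2_fc, tolerance = 1e-10)
  expect_equal(swap$p_value, res$p_value, tolerance = 1e-10)

  # invariance to a global intensity rescaling
  scaled <- differential_abundance(toy_matrix(unclass(m) * 37,
                                              smp = colnames(m)),
                                   meta, "A", "B")
  expect_equal(scaled$log2_fc, res$log2_fc, tolerance = 1e-9)
  expect_equal(scaled$p_value, res$p_value, tolerance = 1e-9)

  expect_error(differential_abundance(m, meta, "A", "B",
                                      universe = character(0)), "universe")
  expect_error(differential_abundance(m, meta, "A", "C"), "no samples")
  expect_error(differential_abundance(m, meta, "A", "B",
                                      covariates = "pair"), "pair")
})

test_that("secondary-threshold counting is monotone and matches enumeration", {
  res <- data.frame(
    metabolite_id = sprintf("m%d", 1:6),
    fold_change = c(3, 2.6, 2.0, 0.3, 1.2, 10),
    fdr = c(0.01, 0.2, 0.01, 0.04, 0.001, 0.049)
  )
  # manual: fdr<0.05 & fc beyond cutoff -> m1, m4, m6 at 2; m1, m4, m6 at 2.5
  expect_identical(count_significant(res, 2), 3L)
  expect_identical(count_significant(res, 2.5), 3L)
  expect_identical(count_significant(res, 9), 1L)
  expect_true(count_significant(res, 2.5) <= count_significant(res, 2))
  expect_identical(count_significant(res[0, ]), 0L)
  # fold change exactly at the cutoff does not count (strict inequality)
  expect_identical(count_significant(data.frame(metabolite_id = "x",
                                                fold_change = 2,
                                                fdr = 0.001), 2), 0L)
})
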