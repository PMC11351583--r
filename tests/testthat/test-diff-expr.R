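test_that("median-of-ratios size factors match hand values and symmetries", {
  set.seed(7)
  # identical samples -> all factors 1
  m <- count_matrix(matrix(c(5, 9, 5, 9), 2, 2), c("a", "b"), c("s1", "s2"))
  expect_equal(unname(size_factors(m)), c(1, 1))

  # hand-computed median-of-ratios
  m2 <- count_matrix(matrix(c(10, 20, 30, 60), 2, 2, byrow = TRUE),
                     c("a", "b"), c("s1", "s2"))
  expect_equal(unname(round(size_factors(m2), 4)), c(0.7071, 1.4142))

  # scale equivariance of the factor ratios: multiplying one column by c
  # multiplies that sample's factor by c relative to every other sample
  # (factors are only identified up to a common constant)
  m3 <- count_matrix(matrix(rpois(40, 50) + 1, 10, 4),
                     paste0("f", 1:10), paste0("s", 1:4))
  s3 <- size_factors(m3)
  m4 <- unclass(m3)
  m4[, 2] <- m4[, 2] * 3
  s4 <- size_factors(count_matrix(m4))
  expect_equal(s4[2] / s4[1], 3 * s3[2] / s3[1], tolerance = 1e-12)
  expect_equal(s4[3] / s4[4], s3[3] / s3[4], tolerance = 1e-12)

  # permutation invariance over features
  s5 <- size_factors(count_matrix(unclass(m3)[sample(10), ]))
  expect_equal(s5, s3)

  # all-zero-containing features only -> informative error
  m6 <- count_matrix(matrix(c(0, 3, 4, 0), 2, 2), c("a", "b"), c("s1", "s2"))
  expect_error(size_factors(m6), "pseudocount")
})

test_that("size factors agree with the DESeq2 median-of-ratios implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(1)
  # odd feature count: the arithmetic and geometric median tie conventions
  # coincide on an odd number of ratios
  m <- matrix(rnbinom(606, mu = 80, size = 10) + 1, 101, 6,
              dimnames = list(paste0("f", 1:101), paste0("s", 1:6)))
  ours <- size_factors(count_matrix(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("normalization divides by the sample factor and feeds base_mean", {
  m <- toy_counts()
  expect_equal(normalize_counts(m, setNames(rep(1, 4), sample_ids(m))),
               unclass(m) + 0.0)
  expect_equal(normalize_counts(m, setNames(c(2, 1, 1, 1), sample_ids(m)))[1, 1],
               5)
  # base_mean reported by the Wald test equals row means of normalized counts
  set.seed(2)
  cm <- count_matrix(matrix(rnbinom(300, mu = 100, size = 10), 50, 6),
                     paste0("f", 1:50), paste0("s", 1:6))
  st <- sample_table(paste0("s", 1:6), rep(c("case", "control"), each = 3))
  de <- nb_wald_test(cm, st)
  norm <- normalize_counts(cm)
  expect_equal(de$base_mean, unname(rowMeans(norm[de$feature_id, ])),
               tolerance = 1e-12)
})

test_that("moments dispersion estimator recovers the generating regimes", {
  st <- sample_table(paste0("s", 1:200), rep(c("case", "control"), each = 100))
  # Poisson counts: estimate at or near the floor for most features
  set.seed(3)
  pois <- matrix(rpois(500 * 200, 100), 500, 200,
                 dimnames = list(paste0("f", 1:500), paste0("s", 1:200)))
  a_pois <- estimate_dispersion(pois + 0.0, st)
  expect_gte(mean(a_pois < 0.01), 0.9)

  # constant feature -> floor exactly
  const <- matrix(7, 2, 200, dimnames = list(c("c1", "c2"), paste0("s", 1:200)))
  expect_equal(unname(estimate_dispersion(const + 0.0, st)), rep(1e-8, 2))

  # NB alpha = 0.2: median estimate within [0.1, 0.3]
  set.seed(4)
  nb <- matrix(rnbinom(500 * 200, mu = 100, size = 5), 500, 200,
               dimnames = list(paste0("f", 1:500), paste0("s", 1:200)))
  a_nb <- estimate_dispersion(nb + 0.0, st)
  expect_gt(median(a_nb), 0.1)
  expect_lt(median(a_nb), 0.3)
})

test_that("BH adjustment matches the step-up definition and oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.123), 0.123)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(5)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }

  # permutation invariance and the minimum-p lower bound
  p <- runif(30)
  perm <- sample(30)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_gte(min(bh_adjust(p)), min(p))
})

test_that("the NB Wald test behaves on degenerate and signed inputs", {
  # identical counts everywhere with equal size factors: no signal
  cm <- count_matrix(matrix(50, 4, 6), paste0("f", 1:4), paste0("s", 1:6))
  st <- sample_table(paste0("s", 1:6), rep(c("case", "control"), each = 3))
  de <- nb_wald_test(cm, st)
  expect_equal(de$log2fc, rep(0, 4), tolerance = 1e-10)
  expect_true(all(de$p >= 0.99))

  # sign convention: positive log2fc when cases are higher
  m <- matrix(c(200, 210, 190, 100, 95, 105), 1, 6)
  m <- rbind(m, 100)  # second feature flat, keeps size factors sane
  cm2 <- count_matrix(m, c("up", "flat"), paste0("s", 1:6))
  de2 <- nb_wald_test(cm2, st, de_config(min_total_count = 0))
  expect_gt(de2$log2fc[de2$feature_id == "up"], 0)

  # one group all zero: pseudocount fallback, finite and flagged
  m3 <- rbind(c(0, 0, 0, 40, 50, 60), c(100, 90, 110, 100, 95, 105))
  cm3 <- count_matrix(m3, c("z", "flat"), paste0("s", 1:6))
  de3 <- nb_wald_test(cm3, st, de_config(min_total_count = 0))
  expect_true(de3$zero_group[de3$feature_id == "z"])
  expect_true(all(is.finite(de3$log2fc)))
  expect_lt(de3$log2fc[de3$feature_id == "z"], 0)
})

test_that("swapping group labels negates fold changes and preserves p-values", {
  set.seed(6)
  cfg <- simulation_config(n_genes = 200, n_mirnas = 20, n_de_genes = 20,
                           n_de_mirnas = 4, n_true_pairs = 8, seed = 13)
  sim <- simulate_paired_experiment(cfg)
  de1 <- nb_wald_test(sim$mrna, sim$samples)
  flipped <- sample_table(sim$samples$sample_id,
                          ifelse(sim$samples$condition == "case",
                                 "control", "case"))
  de2 <- nb_wald_test(sim$mrna, flipped)
  expect_equal(de1$log2fc, -de2$log2fc, tolerance = 1e-10)
  expect_equal(de1$p, de2$p, tolerance = 1e-10)
})

test_that("detection requires a positive count in every sample", {
  tab2 <- load_fixture("table2_counts")
  expect_identical(length(detected_features(tab2)), 59L)
  m <- count_matrix(matrix(c(1, 0, 2, 3), 2, 2), c("a", "b"), c("s1", "s2"))
  expect_identical(detected_features(m), "a")  # b has a zero in s1
  empty <- count_matrix(matrix(integer(), 0, 2), character(), c("s1", "s2"))
  expect_identical(detected_features(empty), character(0))
})

test_that("CPM fold changes reproduce hand values and the printed directions", {
  st <- sample_table(paste0("s", 1:4), c("case", "case", "control", "control"))
  # identical groups -> 0
  cm <- count_matrix(matrix(c(10, 10, 10, 10, 90, 90, 90, 90), 2, 4,
                            byrow = TRUE), c("a", "b"), paste0("s", 1:4))
  expect_equal(cpm_group_log2fc(cm, st, "a"), 0)
  # case mean CPM exactly twice the control mean -> 1
  cm2 <- count_matrix(matrix(c(200, 200, 100, 100,
                               800, 800, 900, 900), 2, 4, byrow = TRUE),
                      c("a", "b"), paste0("s", 1:4))
  expect_equal(cpm_group_log2fc(cm2, st, "a"), 1)
  expect_error(cpm_group_log2fc(cm2, st, "zzz"), "not found")

  # frozen values from the printed count fixture (CPM over column sums)
  tab2 <- load_fixture("table2_counts")
  t2s <- table2_samples()
  expect_equal(cpm_group_log2fc(tab2, t2s, "hsa-miR-145-5p"), 1.815594,
               tolerance = 1e-6)
  expect_equal(cpm_group_log2fc(tab2, t2s, "hsa-miR-140-3p"), 1.537038,
               tolerance = 1e-6)
  expect_equal(cpm_group_log2fc(tab2, t2s, "hsa-let-7e-5p"), -1.257560,
               tolerance = 1e-6)
  expect_equal(cpm_group_log2fc(tab2, t2s, "hsa-miR-125a-5p"), -0.917941,
               tolerance = 1e-6)
})
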