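test_that("gaussian kernel matches its closed form", {
  # unit diagonal for identical rows
  x <- matrix(rnorm(10), 5, 2)
  k <- gaussian_kernel(x, x, kernel_spec(bandwidths = 1.3))
  expect_equal(diag(k), rep(1, 5))
  expect_true(all(k > 0 & k <= 1))

  # ||x - y||^2 = 4, sigma = sqrt(2) -> exp(-1)
  k <- gaussian_kernel(matrix(c(0, 0), 1), matrix(c(2, 0), 1),
                       kernel_spec(bandwidths = sqrt(2)))
  expect_equal(k[1, 1], exp(-1))

  # multi-bandwidth kernel is the mean of the single-bandwidth kernels
  x <- matrix(rnorm(6), 3, 2); y <- matrix(rnorm(4), 2, 2)
  k12 <- gaussian_kernel(x, y, kernel_spec(bandwidths = c(1, 2)))
  k1 <- gaussian_kernel(x, y, kernel_spec(bandwidths = 1))
  k2 <- gaussian_kernel(x, y, kernel_spec(bandwidths = 2))
  expect_equal(k12, (k1 + k2) / 2)

  expect_error(kernel_spec(bandwidths = 0), "> 0")
})

test_that("mmd reproduces the 1-D two-point closed form", {
  v <- mmd(matrix(0), matrix(1), kernel_spec(bandwidths = 1))
  expect_equal(v, 2 - 2 * exp(-0.5))
})

test_that("mmd is zero on identical batches, symmetric and nonnegative", {
  set.seed(21)
  for (rep in 1:10) {
    a <- random_features(sample(3:15, 1), 4)
    b <- random_features(sample(3:15, 1), 4)
    expect_equal(mmd(a, a), 0, tolerance = 1e-12)
    expect_equal(mmd(a, b), mmd(b, a), tolerance = 1e-12)
    expect_gte(mmd(a, b), -1e-9)
  }
  expect_error(mmd(matrix(numeric(0), 0, 2), matrix(0, 1, 2)),
               "sample|nonempty")
})

test_that("mmd equals the explicit double-loop oracle", {
  set.seed(31)
  sig <- c(0.8, 1.6)
  fs <- matrix(rnorm(17 * 5), 17, 5)
  ft <- matrix(rnorm(23 * 5), 23, 5)
  expect_equal(mmd(fs, ft, kernel_spec(bandwidths = sig)),
               oracle_mmd(fs, ft, sig), tolerance = 1e-10)
})

test_that("the as-printed cross-term normalization is available but distinct", {
  fs <- matrix(rnorm(8), 4, 2); ft <- matrix(rnorm(6), 3, 2)
  std <- mmd(fs, ft, kernel_spec(bandwidths = 1))
  printed <- mmd(fs, ft, kernel_spec(bandwidths = 1), cross_term = "ns2nt2")
  # the printed form divides the cross term by the extra 1/(ns * nt)
  k <- gaussian_kernel(fs, ft, kernel_spec(bandwidths = 1))
  expect_equal(printed - std, 2 * sum(k) / (4 * 3) - 2 * sum(k) / (16 * 9))
})

test_that("class-aware discrepancy matches its literal-summation oracle", {
  set.seed(41)
  sig <- c(1, 2)
  for (rep in 1:5) {
    ls <- sample(0:2, 12, replace = TRUE)
    lt <- sample(0:2, 14, replace = TRUE)
    fs <- matrix(rnorm(12 * 3), 12, 3)
    ft <- matrix(rnorm(14 * 3), 14, 3)
    for (pair in list(c(0, 0), c(0, 1), c(2, 1))) {
      if (!(pair[1] %in% ls) || !(pair[2] %in% lt)) next
      got <- class_aware_discrepancy(feature_batch(fs, ls), feature_batch(ft, lt),
                                     pair[1], pair[2],
                                     kernel_spec(bandwidths = sig))$value
      expect_equal(got, oracle_cad(fs, ls, ft, lt, pair[1], pair[2], sig),
                   tolerance = 1e-10)
    }
  }
})

test_that("class-aware discrepancy handles identical and separated clusters", {
  feats <- matrix(rnorm(10 * 2), 10, 2)
  labs <- rep(c(0L, 1L), 5)
  a <- feature_batch(feats, labs)
  expect_equal(class_aware_discrepancy(a, a, 0, 0, kernel_spec(bandwidths = 1))$value,
               0, tolerance = 1e-12)

  # clusters ~100 bandwidths apart: every cross kernel ~ 0, so D ~ e1 + e2
  spec <- kernel_spec(bandwidths = 1)
  fs <- matrix(rnorm(8 * 2), 8, 2)
  ft <- matrix(rnorm(8 * 2) + 100, 8, 2)
  out <- class_aware_discrepancy(feature_batch(fs, rep(0L, 8)),
                                 feature_batch(ft, rep(1L, 8)), 0, 1, spec)
  expect_equal(out$value, out$report$e1 + out$report$e2, tolerance = 1e-10)
  expect_gt(out$value, 0)

  # empty class mask -> explicit undefined-term error
  expect_error(
    class_aware_discrepancy(feature_batch(fs, rep(0L, 8)),
                            feature_batch(ft, rep(1L, 8)), 1, 1, spec),
    "undefined class term")
})

test_that("cdd equals its oracle and decomposes over class pairs", {
  set.seed(51)
  sig <- c(0.9, 1.8)
  spec <- kernel_spec(bandwidths = sig)
  for (rep in 1:5) {
    ls <- sample(0:2, 15, replace = TRUE)
    lt <- sample(0:2, 18, replace = TRUE)
    if (length(unique(ls)) < 2 || length(unique(lt)) < 2) next
    fs <- matrix(rnorm(15 * 4), 15, 4)
    ft <- matrix(rnorm(18 * 4), 18, 4)
    got <- cdd(feature_batch(fs, ls), feature_batch(ft, lt), class_set = 0:2,
               spec = spec)
    expect_equal(got$value, oracle_cdd(fs, ls, ft, lt, 0:2, sig),
                 tolerance = 1e-10)
    # definitional decomposition via class_aware_discrepancy
    terms <- got$report
    expect_equal(got$value,
                 mean(terms$value[terms$kind == "intra"]) -
                   mean(terms$value[terms$kind == "inter"]),
                 tolerance = 1e-12)
  }
})

test_that("cdd is negative for per-class-identical, well-separated domains", {
  # same class clusters in both domains, classes far apart: intra terms are 0,
  # inter terms positive, so cdd = -(mean inter) < 0
  spec <- kernel_spec(bandwidths = 1)
  base <- rbind(matrix(rnorm(10, sd = 0.1), 5, 2),
                matrix(rnorm(10, sd = 0.1) + 50, 5, 2))
  labs <- rep(0:1, each = 5)
  out <- cdd(feature_batch(base, labs), feature_batch(base, labs),
             class_set = 0:1, spec = spec)
  expect_lt(out$value, 0)
  inter <- out$report$value[out$report$kind == "inter"]
  expect_equal(out$value, 0 - mean(inter), tolerance = 1e-10)
})

test_that("cdd is invariant to within-domain sample permutation", {
  set.seed(61)
  ls <- sample(0:1, 12, replace = TRUE)
  fs <- matrix(rnorm(24), 12, 2)
  lt <- sample(0:1, 10, replace = TRUE)
  ft <- matrix(rnorm(20), 10, 2)
  spec <- kernel_spec(bandwidths = c(1, 2))
  a <- cdd(feature_batch(fs, ls), feature_batch(ft, lt), 0:1, spec)$value
  p <- sample(12); q <- sample(10)
  b <- cdd(feature_batch(fs[p, ], ls[p]), feature_batch(ft[q, ], lt[q]),
           0:1, spec)$value
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("cdd requires at least two classes", {
  fs <- matrix(rnorm(10), 5, 2)
  expect_error(cdd(feature_batch(fs, rep(0L, 5)), feature_batch(fs, rep(0L, 5)),
                   class_set = 0L), "two classes")
})

test_that("block-wise discrepancy is the class-restricted mmd", {
  set.seed(71)
  spec <- kernel_spec(bandwidths = c(1, 2))
  fa <- matrix(rnorm(20 * 3), 20, 3); la <- sample(0:1, 20, replace = TRUE)
  fb <- matrix(rnorm(16 * 3), 16, 3); lb <- sample(0:1, 16, replace = TRUE)
  a <- feature_batch(fa, la, subject_id = "S01", session_idx = 0L, block_idx = 0L)
  b <- feature_batch(fb, lb, subject_id = "S01", session_idx = 0L, block_idx = 1L)
  got <- bwise_discrepancy(a, b, 1L, spec)
  expect_equal(got, mmd(fa[la == 1L, ], fb[lb == 1L, ], spec), tolerance = 1e-12)

  # identical class-c features across blocks -> 0
  b2 <- feature_batch(fa, la, subject_id = "S01", session_idx = 0L, block_idx = 2L)
  expect_equal(bwise_discrepancy(a, b2, 0L, spec), 0, tolerance = 1e-12)

  # missing class -> NA skip signal, not an error
  b3 <- feature_batch(fb[lb == 0L, , drop = FALSE], lb[lb == 0L],
                      subject_id = "S01", session_idx = 0L, block_idx = 1L)
  expect_true(is.na(bwise_discrepancy(a, b3, 1L, spec)))

  # key violations are domain-mismatch errors
  other <- feature_batch(fb, lb, subject_id = "S02", session_idx = 0L,
                         block_idx = 1L)
  expect_error(bwise_discrepancy(a, other, 1L, spec), "same subject")
  same_block <- feature_batch(fb, lb, subject_id = "S01", session_idx = 0L,
                              block_idx = 0L)
  expect_error(bwise_discrepancy(a, same_block, 1L, spec), "different blocks")
})

test_that("block-wise discrepancy grows with the mean shift", {
  set.seed(81)
  spec <- kernel_spec(bandwidths = 1)
  fa <- matrix(rnorm(30 * 2), 30, 2); la <- rep(0L, 30)
  a <- feature_batch(fa, la, "S01", 0L, 0L)
  vals <- vapply(c(0.5, 1, 2), function(delta) {
    b <- feature_batch(fa + delta, la, "S01", 0L, 1L)
    bwise_discrepancy(a, b, 0L, spec)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("the total objective combines its terms as specified", {
  logits <- matrix(c(5, -5, -5, 5), 2, 2, byrow = TRUE)
  labels <- c(1L, 2L)
  # alpha = 0 -> pure cross-entropy
  out <- total_objective(logits, labels, d_cdd = 0.7, d_bwise = 0.3,
                         objective_config(alpha = 0))
  expect_equal(out$total, out$cross_entropy)

  # published discrepancy weighting (alpha = 1.1): with ce = 0.5,
  # d_cdd = 0.2, d_bwise = 0.1 the objective is 0.5 + 1.1 * 0.3 = 0.83
  z <- -log(exp(0.5) - 1) # binary logit margin whose cross-entropy is 0.5
  margin_logits <- matrix(c(z, 0, 0, z), 2, 2, byrow = TRUE)
  out <- total_objective(margin_logits, labels, d_cdd = 0.2, d_bwise = 0.1,
                         objective_config(alpha = 1.1, da_mode = "block"))
  expect_equal(out$cross_entropy, 0.5, tolerance = 1e-12)
  expect_equal(out$total, 0.83, tolerance = 1e-12)

  # subject mode zeroes the block-wise term
  out <- total_objective(logits, labels, d_cdd = 0.2, d_bwise = 0.1,
                         objective_config(alpha = 1, da_mode = "subject"))
  expect_equal(out$d_bwise, 0)
  expect_equal(out$total, out$cross_entropy + 0.2)

  # uniform logits -> ln M
  m <- 5L
  uniform <- matrix(0, 3, m)
  out <- total_objective(uniform, c(1L, 3L, 5L), 0, 0, objective_config(alpha = 0))
  expect_equal(out$cross_entropy, log(m))
})
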