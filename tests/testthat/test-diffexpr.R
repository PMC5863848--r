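test_that("size factors match hand computations and symmetry", {
  m <- matrix(c(10, 20, 30, 60), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1 / sqrt(2), sqrt(2)))

  same <- matrix(rep(c(5, 9, 13), 3), ncol = 3,
                 dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(unname(estimate_size_factors(same)), rep(1, 3))
})

test_that("size factors equal the brute-force median-of-ratios oracle", {
  set.seed(11)
  m <- matrix(rpois(30, 40) + 1L, nrow = 10, ncol = 3,
              dimnames = list(sprintf("g%02d", 1:10), NULL))
  expect_equal(unname(estimate_size_factors(m)), sf_brute(m))

  # doubling one column doubles its factor relative to every other column
  m2 <- m
  m2[, 2] <- m[, 2] * 2L
  f0 <- estimate_size_factors(m)
  f2 <- estimate_size_factors(m2)
  expect_equal(unname(f2[2] / f2[1]), unname(2 * f0[2] / f0[1]), tolerance = 1e-12)
  expect_equal(unname(f2[2] / f2[3]), unname(2 * f0[2] / f0[3]), tolerance = 1e-12)
  expect_equal(sf_brute(m2), unname(f2))
})

test_that("size factors agree with the Bioconductor reference implementation", {
  set.seed(21)
  m <- matrix(rnbinom(60, mu = 80, size = 5), nrow = 20, ncol = 3,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  m[20, 1] <- 0L   # odd number of all-positive genes: the two median
                   # interpolation conventions coincide exactly
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(estimate_size_factors(m)), unname(ref), tolerance = 1e-10)
})

test_that("matrices without an all-positive gene need the pseudo-reference fallback", {
  m <- matrix(c(0, 5, 7, 0), nrow = 2, dimnames = list(c("a", "b"), NULL))
  expect_error(estimate_size_factors(m), "pseudo_reference")
  sf <- estimate_size_factors(m, pseudo_reference = TRUE)
  expect_true(all(is.finite(sf) & sf > 0))
})

test_that("identical groups give zero fold change and non-significant p", {
  m <- matrix(rep(c(40L, 100L, 7L, 250L), 6), nrow = 4,
              dimnames = list(paste0("g", 1:4), NULL))
  x <- trio_counts(m, roles = rep(c("parent_female", "parent_male", "f1"), each = 2))
  t <- nb_test(x, c("parent_female", "f1"))
  expect_equal(t$log2fc, rep(0, 4))
  expect_true(all(t$p_raw >= 0.99))
})

test_that("the Poisson special case agrees with the exact conditional binomial test", {
  pairs <- rbind(c(100, 130), c(20, 35), c(200, 260), c(300, 360), c(40, 40))
  for (i in seq_len(nrow(pairs))) {
    k <- pairs[i, ]
    m <- matrix(c(k[1], 50L, k[2]), nrow = 1,
                dimnames = list("g1", NULL))
    x <- trio_counts(m, roles = c("parent_female", "parent_male", "f1"))
    t <- nb_test(x, c("parent_female", "f1"), dispersion_mode = 0,
                 size_factors = rep(1, 3))
    exact <- stats::binom.test(k[1], sum(k), 0.5)$p.value
    expect_lt(abs(t$p_raw - min(exact, 1)), 0.02)
  }
})

test_that("swapping the contrast negates log2fc and preserves p", {
  sim <- simulate_trio_counts(sim_config(n_genes = 150, n_replicates = 3, seed = 2))
  a <- nb_test(sim$counts, c("parent_female", "f1"))
  b <- nb_test(sim$counts, c("f1", "parent_female"))
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$p_raw, b$p_raw)
})

test_that("type-I error under the null is close to nominal", {
  cfg <- sim_config(n_genes = 2000, class_proportions = c(null = 1),
                    n_replicates = 3, dispersion = 0.1, seed = 17)
  sim <- simulate_trio_counts(cfg)
  t <- nb_test(sim$counts, c("parent_female", "f1"))
  frac <- mean(t$p_raw < 0.05)
  expect_gte(frac, 0.025)
  expect_lte(frac, 0.10)
})

test_that("dispersion-mode preconditions are enforced", {
  m <- matrix(c(10L, 20L, 30L, 15L, 25L, 35L), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  x <- trio_counts(m, roles = c("parent_female", "parent_male", "f1"))
  expect_error(nb_test(x, c("parent_female", "f1"), dispersion_mode = "per_group"),
               "per_group")
  expect_error(nb_test(x, c("parent_female", "f1"), dispersion_mode = -0.5),
               ">= 0")
  expect_error(nb_test(x, c("parent_female", "parent_female")), "distinct")
})

test_that("BH adjustment equals the brute-force step-up on exhaustive small grids", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))

  grid <- c(0.01, 0.2, 0.5, 0.8, 0.99)
  for (len in 1:3) {
    combos <- as.matrix(expand.grid(rep(list(grid), len)))
    for (r in seq_len(nrow(combos))) {
      p <- unname(combos[r, ])
      expect_equal(bh_adjust(p), bh_brute(p))
    }
  }
  set.seed(31)
  for (len in 4:6) {
    for (rep in 1:60) {
      p <- sample(seq(0.01, 0.99, by = 0.01), len, replace = TRUE)
      expect_equal(bh_adjust(p), bh_brute(p))
    }
  }
})

test_that("BH output is monotone in sorted p and validates its input", {
  set.seed(41)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(!is.unsorted(q[order(p)]))
  expect_error(bh_adjust(c(0.1, NaN, 0.2)), "2")
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("DEG calls apply the joint significance and fold criterion", {
  tab <- data.frame(gene_id = paste0("g", 1:4),
                    log2fc = c(1.5, 0.5, 5, -1.7),
                    p_raw = c(0.04, 0.04, 0.5, 0.01),
                    q_bh = c(0.04, 0.04, 0.5, 0.01))
  out <- call_deg(tab, alpha = 0.05, min_fold = 2)
  expect_equal(as.character(out$call), c("up", "ns", "ns", "down"))
  # raw-p mode and fold gate of 1
  out2 <- call_deg(transform(tab, q_bh = 1), alpha = 0.05, min_fold = 1,
                   use_adjusted = FALSE)
  expect_equal(as.character(out2$call), c("up", "up", "ns", "down"))
  expect_error(call_deg(tab, alpha = 0), "alpha")
  expect_error(call_deg(tab, min_fold = 0.5), "min_fold")
})
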