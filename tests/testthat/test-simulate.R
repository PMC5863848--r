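test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 200, seed = 42)
  a <- simulate_trio_counts(cfg)
  b <- simulate_trio_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$lengths, b$lengths)
})

test_that("class proportions shape the truth table by construction", {
  sim <- simulate_trio_counts(sim_config(n_genes = 1000,
                                         class_proportions = c(null = 1)))
  expect_equal(nrow(sim$truth), 1000)
  expect_true(all(sim$truth$true_pattern == "null"))

  mix <- simulate_trio_counts(sim_config(
    n_genes = 300,
    class_proportions = c(uod_3sub = 0.5, dod_3sub = 0.5)))
  expect_equal(sum(mix$truth$true_pattern %in% c("P7", "P8", "P9")), 150)
  expect_equal(sum(mix$truth$true_pattern %in% c("P10", "P11", "P12")), 150)
})

test_that("sample means converge to configured genotype means at high replication", {
  # law-of-large-numbers check: near-Poisson noise, 50 replicates
  cfg <- sim_config(n_genes = 60, class_proportions = c(hpd_m = 1),
                    n_replicates = 50, dispersion = 0,
                    effect_size_log2 = 1,
                    baseline_mean_log = c(log(200), 0.5), seed = 3)
  sim <- simulate_trio_counts(cfg)
  for (role in c("parent_female", "parent_male", "f1")) {
    obs <- rowMeans(sim$counts$counts[, role_columns(sim$counts, role)])
    cfgd <- sim$truth[[paste0("mean_", sub("parent_", "", role))]]
    expect_lt(max(abs(obs / cfgd - 1)), 0.05)
  }
  # hpd_m plants male parent and F1 at double the female baseline
  expect_true(all(sim$truth$true_pattern == "P3"))
  expect_equal(sim$truth$mean_male, 2 * sim$truth$mean_female)
  expect_equal(sim$truth$mean_f1, sim$truth$mean_male)
})

test_that("counts are non-negative integers and column sums track library size factors", {
  # all-null so per-role expected totals coincide and only the library
  # factors separate the columns
  cfg <- sim_config(n_genes = 1500, class_proportions = c(null = 1),
                    library_size_factors = c(1, 2, 4), seed = 5)
  sim <- simulate_trio_counts(cfg)
  cts <- sim$counts$counts
  expect_true(is.integer(cts))
  expect_true(all(cts >= 0))
  ratios <- colSums(cts) / colSums(cts)[1]
  expect_equal(ratios, c(1, 2, 4), tolerance = 0.05, ignore_attr = TRUE)
})

test_that("invalid simulation configurations are rejected with the field named", {
  expect_error(sim_config(class_proportions = c(null = 0.5)), "class_proportions")
  expect_error(sim_config(class_proportions = c(bogus = 1)), "class_proportions")
  expect_error(sim_config(dispersion = -1), "dispersion")
  expect_error(sim_config(library_size_factors = c(1, 2)), "library_size_factors")
  expect_error(sim_config(n_replicates = 0), "n_replicates")
  expect_error(simulate_trio_counts(sim_config(baseline_mean_log = c(1e300, 500))))
})

test_that("phenotype simulation reproduces configured means at zero noise", {
  means <- data.frame(genotype = c("parent_female", "parent_male", "f1"),
                      stage = "AT", mean = c(2.5, 1.8, 3.1))
  tab <- simulate_phenotype(means, noise_sd = 0, n_replicates = 3)
  expect_equal(nrow(tab), 9)
  expect_equal(c(tapply(tab$value, tab$genotype, mean))[c("parent_female", "parent_male", "f1")],
               c(parent_female = 2.5, parent_male = 1.8, f1 = 3.1))
  expect_identical(simulate_phenotype(means, 0.2, 3, seed = 9),
                   simulate_phenotype(means, 0.2, 3, seed = 9))
  expect_error(simulate_phenotype(means, noise_sd = -1), "noise_sd")
  expect_error(simulate_phenotype(transform(means, mean = -mean)), "> 0")
})

test_that("planted mid-parent heterosis is recovered from simulated phenotypes", {
  # F1 planted at 1.3456 x mid-parent: MPH must come back as 34.56
  mp <- (2.4 + 1.6) / 2
  means <- data.frame(genotype = c("parent_female", "parent_male", "f1"),
                      stage = "AT", mean = c(2.4, 1.6, 1.3456 * mp))
  tab <- simulate_phenotype(means, noise_sd = 0.02, n_replicates = 30, seed = 4)
  h <- phenotype_heterosis(tab)
  expect_equal(h$mph_pct, 34.56, tolerance = 0.02)
})

test_that("study-condition phenotype means reproduce the published index table", {
  means <- nicotine_study_means()
  tab <- simulate_phenotype(means, noise_sd = 0, n_replicates = 3)
  h <- phenotype_heterosis(tab)
  ref <- read.delim(system.file("extdata", "nicotine_heterosis.tsv",
                                package = "triohet"))
  m <- merge(h, ref, by = c("year", "stage"))
  expect_equal(m$oph_pct, m$oph, tolerance = 1e-8)
  expect_equal(m$bph_pct, m$bph, tolerance = 1e-8)
  # MPH follows from the other two up to the table's printed rounding
  expect_lt(max(abs(m$mph_pct - m$mph)), 0.01)
})

test_that("simulated Ct tables invert the ddCt transform", {
  ct <- simulate_ct(c(gA = 4), noise_sd = 0)
  fold <- ddct_relative_expression(ct, target = "gA")
  expect_equal(fold$fold[fold$genotype == "f1"], 4)
  expect_equal(fold$fold[fold$genotype == "parent_female"], 1)

  ct1 <- simulate_ct(c(gB = 1), noise_sd = 0)
  f1 <- ddct_relative_expression(ct1, target = "gB")
  expect_equal(f1$ddct, c(0, 0))

  expect_error(simulate_ct(c(g = -2)), "positive")
  expect_identical(simulate_ct(c(g = 2), noise_sd = 0.3, seed = 8),
                   simulate_ct(c(g = 2), noise_sd = 0.3, seed = 8))
})
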