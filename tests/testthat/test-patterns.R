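# Enumerated oracle: the full 27-cell decision table, written out literally.
pattern_oracle <- function(pp, ff, fm) {
  if (pp == "f_higher" && ff == "down" && fm == "up") return("P1")
  if (pp == "m_higher" && ff == "up" && fm == "down") return("P2")
  if (pp == "m_higher" && ff == "up" && fm == "ns") return("P3")
  if (pp == "f_higher" && ff == "ns" && fm == "up") return("P4")
  if (pp == "f_higher" && ff == "down" && fm == "ns") return("P5")
  if (pp == "m_higher" && ff == "ns" && fm == "down") return("P6")
  if (ff == "up" && fm == "up")
    return(switch(pp, f_higher = "P7", m_higher = "P8", ns = "P9"))
  if (ff == "down" && fm == "down")
    return(switch(pp, f_higher = "P10", m_higher = "P11", ns = "P12"))
  "NC"
}

test_that("the classifier is total on the 27-cell space and matches the oracle", {
  cells <- expand.grid(call_pp = c("f_higher", "m_higher", "ns"),
                       call_f1f = c("up", "down", "ns"),
                       call_f1m = c("up", "down", "ns"),
                       stringsAsFactors = FALSE)
  got <- classify_pattern(cells)
  want <- mapply(pattern_oracle, cells$call_pp, cells$call_f1f, cells$call_f1m)
  expect_equal(got$pattern, unname(want))
  expect_true(all(got$pattern %in% c(paste0("P", 1:12), "NC")))
  # each of the 12 patterns is hit by exactly one cell
  expect_equal(as.integer(table(got$pattern)[paste0("P", 1:12)]), rep(1L, 12))
  expect_equal(sum(got$pattern == "NC"), 15)
  # rollup scheme: 2 additive, 4 dominant, 6 overdominant patterns
  expect_equal(sum(got$rollup == "additive"), 2)
  expect_equal(sum(got$rollup %in% c("HPD", "LPD")), 4)
  expect_equal(sum(got$rollup %in% c("UOD", "DOD")), 6)
  expect_equal(got$rollup, unname(rollup_of[got$pattern]))
})

test_that("canonical single-gene calls land in the documented patterns", {
  one <- function(pp, ff, fm)
    classify_pattern(data.frame(call_pp = pp, call_f1f = ff, call_f1m = fm))
  # paternal higher-parent dominance
  expect_equal(one("m_higher", "up", "ns")$pattern, "P3")
  expect_equal(one("m_higher", "up", "ns")$rollup, "HPD")
  # up-overdominance with indistinguishable parents
  expect_equal(one("ns", "up", "up")$pattern, "P9")
  expect_equal(one("ns", "up", "up")$rollup, "UOD")
  # no signal anywhere
  expect_equal(one("ns", "ns", "ns")$pattern, "NC")
  expect_equal(one("ns", "ns", "ns")$rollup, "none")
  # conflicting evidence is never forced into a pattern
  expect_equal(one("ns", "up", "down")$pattern, "NC")
  expect_error(one("higher", "up", "ns"), "unknown call token")
})

test_that("rollup sets partition the non-additive assignments", {
  asg <- classify_pattern(data.frame(
    gene_id = paste0("g", 1:4),
    call_pp = c("f_higher", "f_higher", "ns", "ns"),
    call_f1f = c("ns", "down", "ns", "up"),
    call_f1m = c("up", "down", "ns", "down")))
  sets <- build_rollup_sets(asg)
  expect_equal(sets$HPDG, "g1")   # P4
  expect_equal(sets$DODG, "g2")   # P10
  expect_equal(sets$LPDG, character(0))
  expect_equal(sets$UODG, character(0))
  all_ids <- unlist(sets)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_true(all(all_ids %in% asg$gene_id))

  none <- classify_pattern(data.frame(gene_id = "x", call_pp = "ns",
                                      call_f1f = "ns", call_f1m = "ns"))
  expect_true(all(lengths(build_rollup_sets(none)) == 0))
})

test_that("pattern summaries count every gene once and ignore gene order", {
  empty <- classify_pattern(data.frame(call_pp = character(0),
                                       call_f1f = character(0),
                                       call_f1m = character(0)))
  expect_true(all(pattern_summary(empty) == 0))

  set.seed(13)
  cells <- data.frame(
    call_pp = sample(c("f_higher", "m_higher", "ns"), 60, TRUE),
    call_f1f = sample(c("up", "down", "ns"), 60, TRUE),
    call_f1m = sample(c("up", "down", "ns"), 60, TRUE))
  a <- pattern_summary(classify_pattern(cells))
  b <- pattern_summary(classify_pattern(cells[sample(60), ]))
  expect_equal(sum(a), 60)
  expect_identical(a, b)
})

test_that("strongly planted patterns dominate their recovered counts", {
  cfg <- sim_config(n_genes = 600, n_replicates = 5, dispersion = 0.05,
                    effect_size_log2 = 2, seed = 19)
  sim <- simulate_trio_counts(cfg)
  fit <- fit_trio(sim$counts, sim$lengths)
  m <- merge(sim$truth, fit$assignments, by = "gene_id")
  for (p in paste0("P", 1:12)) {
    sub <- m[m$true_pattern == p, ]
    recovered <- names(which.max(table(sub$pattern)))
    expect_equal(recovered, p)
  }
})
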