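# RNG discipline: every simulator seeds a private substream (global seed +
# fixed per-operation offset) and restores the caller's RNG state on exit.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.seed_offsets <- c(counts = 0L, phenotype = 1013L, ct = 2027L)

#' Simulation configuration for a trio RNA-seq experiment
#'
#' Defines the generative model for [simulate_trio_counts()]: negative-binomial
#' counts (variance = mu + alpha * mu^2; alpha = 0 degenerates to Poisson) with
#' per-gene genotype means set by a planted inheritance class.
#'
#' Class vocabulary (`class_proportions` names): `additive_f` / `additive_m`
#' (F1 at mid-parent, female resp. male parent higher), `hpd_f` / `hpd_m`
#' (higher-parent dominance, F1 tracking the named higher parent), `lpd_f` /
#' `lpd_m` (lower-parent dominance, F1 tracking the named lower parent),
#' `uod_3sub` / `dod_3sub` (up-/down-regulated overdominance, spread evenly
#' over the three parental sub-patterns), and `null` (no effect). The default
#' mixture keeps most genes null and emulates a single library per genotype,
#' the design of the motivating field study.
#'
#' @param n_genes number of genes.
#' @param class_proportions named fractions over the class vocabulary,
#'   summing to 1.
#' @param n_replicates per-genotype replicate count (1 emulates the
#'   one-library-per-genotype design).
#' @param baseline_mean_log length-2 numeric `(meanlog, sdlog)` of the
#'   log-normal distribution of baseline expression means.
#' @param dispersion NB dispersion alpha (scalar >= 0) or a function of the
#'   mean returning per-gene alpha.
#' @param effect_size_log2 magnitude (log2) of planted parental and hybrid
#'   shifts; 2 means 4-fold.
#' @param library_size_factors per-sample multipliers (scalar or length
#'   `3 * n_replicates`).
#' @param gene_length_range bp interval for simulated gene lengths.
#' @param seed integer global seed.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       class_proportions = c(additive_f = 0.025, additive_m = 0.025,
                                             hpd_f = 0.05, hpd_m = 0.05,
                                             lpd_f = 0.05, lpd_m = 0.05,
                                             uod_3sub = 0.025, dod_3sub = 0.025,
                                             null = 0.7),
                       n_replicates = 1,
                       baseline_mean_log = c(meanlog = log(100), sdlog = 1.2),
                       dispersion = 0.1,
                       effect_size_log2 = 2,
                       library_size_factors = 1,
                       gene_length_range = c(200, 5000),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              class_proportions = class_proportions,
              n_replicates = as.integer(n_replicates),
              baseline_mean_log = unname(baseline_mean_log),
              dispersion = dispersion,
              effect_size_log2 = effect_size_log2,
              library_size_factors = library_size_factors,
              gene_length_range = gene_length_range,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.class_vocab <- c("additive_f", "additive_m", "hpd_f", "hpd_m",
                  "lpd_f", "lpd_m", "uod_3sub", "dod_3sub", "null")

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("n_genes must be a positive integer")
  pr <- cfg$class_proportions
  unknown <- setdiff(names(pr), .class_vocab)
  if (length(unknown))
    stop("class_proportions: unknown class name(s): ", paste(unknown, collapse = ", "))
  if (any(pr < 0)) stop("class_proportions must be non-negative")
  if (abs(sum(pr) - 1) > 1e-9)
    stop(sprintf("class_proportions must sum to 1 (got %.12f)", sum(pr)))
  if (cfg$n_replicates < 1L) stop("n_replicates must be >= 1")
  if (length(cfg$baseline_mean_log) != 2L || !all(is.finite(cfg$baseline_mean_log)))
    stop("baseline_mean_log must be finite (meanlog, sdlog)")
  if (is.numeric(cfg$dispersion) && any(cfg$dispersion < 0))
    stop("dispersion must be >= 0")
  if (!is.numeric(cfg$dispersion) && !is.function(cfg$dispersion))
    stop("dispersion must be a scalar or a function of the mean")
  if (any(cfg$library_size_factors <= 0) || any(!is.finite(cfg$library_size_factors)))
    stop("library_size_factors must be positive and finite")
  n_samples <- 3L * cfg$n_replicates
  if (!length(cfg$library_size_factors) %in% c(1L, n_samples))
    stop(sprintf("library_size_factors must have length 1 or %d", n_samples))
  if (length(cfg$gene_length_range) != 2L || cfg$gene_length_range[1] < 1 ||
      diff(cfg$gene_length_range) < 0)
    stop("gene_length_range must be an increasing bp interval with min >= 1")
  invisible(cfg)
}

# Largest-remainder apportionment of n_genes over class proportions.
.apportion <- function(n, pr) {
  raw <- n * pr
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    order_rem <- order(raw - base, decreasing = TRUE)
    base[order_rem[seq_len(left)]] <- base[order_rem[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Genotype mean multipliers for a planted sub-pattern. e = 2^effect_size_log2.
# Returns c(female, male, f1) multipliers of the baseline mean.
.pattern_multipliers <- function(pattern, e) {
  switch(pattern,
    null = c(1, 1, 1),
    P1  = c(e, 1, (e + 1) / 2),   # additive, female higher
    P2  = c(1, e, (e + 1) / 2),   # additive, male higher
    P3  = c(1, e, e),             # HPD: F1 ~ male, male higher
    P4  = c(e, 1, e),             # HPD: F1 ~ female, female higher
    P5  = c(e, 1, 1),             # LPD: F1 ~ male, male lower
    P6  = c(1, e, 1),             # LPD: F1 ~ female, female lower
    P7  = c(e, 1, e * e),         # up-OD, female > male
    P8  = c(1, e, e * e),         # up-OD, male > female
    P9  = c(1, 1, e),             # up-OD, parents equal
    P10 = c(e, 1, 1 / e),         # down-OD, female > male
    P11 = c(1, e, 1 / e),         # down-OD, male > female
    P12 = c(1, 1, 1 / e),         # down-OD, parents equal
    stop("unknown pattern: ", pattern))
}

.class_to_patterns <- list(
  additive_f = "P1", additive_m = "P2",
  hpd_f = "P4", hpd_m = "P3",
  lpd_f = "P6", lpd_m = "P5",
  uod_3sub = c("P7", "P8", "P9"),
  dod_3sub = c("P10", "P11", "P12"),
  null = "null")

#' Simulate a trio count matrix with planted inheritance modes
#'
#' Draws per-gene baseline means from a log-normal distribution, sets
#' genotype means according to each gene's planted class (additive genes sit
#' at the arithmetic mid-parent; dominant genes track one parent;
#' overdominant genes exceed or undercut both parents by the configured
#' effect), then samples negative-binomial counts with the configured
#' dispersion and per-sample library size factors.
#'
#' @param config a [sim_config()] object.
#' @return A list of class `trio_sim`: `counts` ([trio_counts()]),
#'   `truth` (data.frame: `gene_id`, `class`, `true_pattern`, the three
#'   genotype means, and true log2 fold changes `log2fc_pp` (female over
#'   male), `log2fc_f1f`, `log2fc_f1m`), and `lengths` (named bp vector).
#' @export
simulate_trio_counts <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  n <- config$n_genes
  e <- 2^config$effect_size_log2

  .with_seed(config$seed + .seed_offsets[["counts"]], {
    gene_ids <- sprintf("gene%05d", seq_len(n))
    lambda <- stats::rlnorm(n, config$baseline_mean_log[1], config$baseline_mean_log[2])
    if (any(!is.finite(lambda)) || any(lambda <= 0))
      stop("baseline_mean_log produced non-finite or non-positive means")

    pr <- config$class_proportions
    n_per_class <- .apportion(n, pr)
    classes <- rep(names(pr), times = n_per_class)
    # spread uod/dod genes round-robin over their three sub-patterns
    patterns <- character(n)
    for (cl in unique(classes)) {
      idx <- which(classes == cl)
      subs <- .class_to_patterns[[cl]]
      patterns[idx] <- rep_len(subs, length(idx))
    }

    mult <- t(vapply(patterns, .pattern_multipliers, numeric(3), e = e))
    mu <- lambda * mult                     # genes x (female, male, f1)
    colnames(mu) <- c("parent_female", "parent_male", "f1")

    n_rep <- config$n_replicates
    roles <- rep(.roles, each = n_rep)
    sf <- rep_len(config$library_size_factors, length(roles))
    alpha <- if (is.function(config$dispersion)) NULL else config$dispersion

    counts <- matrix(0L, n, length(roles))
    for (s in seq_along(roles)) {
      m_s <- mu[, roles[s]] * sf[s]
      a_s <- if (is.null(alpha)) config$dispersion(m_s) else rep_len(alpha, n)
      pois <- a_s <= 0
      draw <- integer(n)
      if (any(pois)) draw[pois] <- stats::rpois(sum(pois), m_s[pois])
      if (any(!pois))
        draw[!pois] <- stats::rnbinom(sum(!pois), mu = m_s[!pois], size = 1 / a_s[!pois])
      counts[, s] <- draw
    }
    rownames(counts) <- gene_ids

    lengths <- stats::setNames(
      round(stats::runif(n, config$gene_length_range[1], config$gene_length_range[2])),
      gene_ids)

    truth <- data.frame(
      gene_id = gene_ids,
      class = classes,
      true_pattern = patterns,
      mean_female = mu[, "parent_female"],
      mean_male = mu[, "parent_male"],
      mean_f1 = mu[, "f1"],
      log2fc_pp = log2(mu[, "parent_female"] / mu[, "parent_male"]),
      log2fc_f1f = log2(mu[, "f1"] / mu[, "parent_female"]),
      log2fc_f1m = log2(mu[, "f1"] / mu[, "parent_male"]),
      stringsAsFactors = FALSE, row.names = NULL)

    structure(list(counts = trio_counts(counts, roles = roles,
                                        replicates = rep(seq_len(n_rep), times = 3)),
                   truth = truth,
                   lengths = lengths),
              class = "trio_sim")
  })
}

#' @export
print.trio_sim <- function(x, ...) {
  cat(sprintf("Simulated trio dataset: %d genes, %d samples\n",
              nrow(x$counts$counts), ncol(x$counts$counts)))
  print(table(planted = x$truth$true_pattern))
  invisible(x)
}

#' Simulate a phenotype trait table
#'
#' Gaussian replicate noise around configured genotype-by-stage trait means,
#' emulating a multi-year field trial of a trait such as leaf nicotine
#' content measured before (BT) and after (AT) topping.
#'
#' @param genotype_means data.frame with columns `genotype` (role token),
#'   `stage`, `mean`, and optionally `year`.
#' @param noise_sd Gaussian replicate standard deviation (trait units).
#' @param n_replicates replicates per cell (field default: 3).
#' @param seed integer seed.
#' @return long data.frame: `genotype`, `year`, `stage`, `replicate`, `value`.
#' @export
simulate_phenotype <- function(genotype_means, noise_sd = 0, n_replicates = 3,
                               seed = 1L) {
  req <- c("genotype", "stage", "mean")
  if (!all(req %in% colnames(genotype_means)))
    stop("genotype_means needs columns: ", paste(req, collapse = ", "))
  if (any(genotype_means$mean <= 0)) stop("trait means must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (!"year" %in% colnames(genotype_means)) genotype_means$year <- "Y1"

  .with_seed(seed + .seed_offsets[["phenotype"]], {
    idx <- rep(seq_len(nrow(genotype_means)), each = n_replicates)
    out <- data.frame(
      genotype = genotype_means$genotype[idx],
      year = genotype_means$year[idx],
      stage = genotype_means$stage[idx],
      replicate = rep(seq_len(n_replicates), times = nrow(genotype_means)),
      value = genotype_means$mean[idx] +
        stats::rnorm(length(idx), 0, noise_sd),
      stringsAsFactors = FALSE)
    out
  })
}

#' Trait means of the motivating nicotine field study
#'
#' Reconstructs genotype mean nicotine contents (% dry weight) per year and
#' stage from the study's published heterosis indices: the low parent is set
#' to a stage-typical base value, the high parent follows from the ratio of
#' the low- and high-parent indices, and the F1 from the low-parent index.
#' The maternal flue-cured parent is taken as the high-nicotine parent.
#'
#' @param lp_base named base values (% dry weight) for the low parent per
#'   stage; defaults are typical upper-leaf contents before/after topping.
#' @return data.frame usable as `genotype_means` in [simulate_phenotype()].
#' @export
nicotine_study_means <- function(lp_base = c(BT = 1.6, AT = 2.6)) {
  tab <- utils::read.delim(system.file("extdata", "nicotine_heterosis.tsv",
                                       package = "triohet"),
                           stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    lp <- lp_base[[r$stage]]
    hp <- lp * (1 + r$bph / 100) / (1 + r$oph / 100)
    f1 <- lp * (1 + r$bph / 100)
    data.frame(genotype = c("parent_female", "parent_male", "f1"),
               year = r$year, stage = r$stage,
               mean = c(hp, lp, f1), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a qPCR Ct table consistent with known fold changes
#'
#' Inverse of the 2^-ddCt calculation: reference-gene Ct values are constant
#' across genotypes, and each target gene's Ct in the test genotype is shifted
#' by -log2(fold) cycles relative to the calibrator, so that
#' [ddct_relative_expression()] recovers the configured fold changes exactly
#' at zero noise (amplification efficiency fixed at 2).
#'
#' @param fold_changes named positive vector: per-gene fold change of the
#'   test genotype relative to the calibrator.
#' @param reference_ct Ct of the reference gene (cycles), all samples.
#' @param noise_sd Gaussian technical noise per well (cycles).
#' @param n_tech technical replicates per (sample, gene).
#' @param calibrator,test genotype role tokens.
#' @param reference_gene id given to the reference gene rows.
#' @param base_ct_range calibrator Ct range the targets are drawn from.
#' @param seed integer seed.
#' @return data.frame of class `ct_table`: `sample`, `genotype`, `gene_id`,
#'   `tech_rep`, `ct`, with the reference gene id stored in
#'   `attr(, "reference_gene")`.
#' @export
simulate_ct <- function(fold_changes, reference_ct = 15, noise_sd = 0,
                        n_tech = 3, calibrator = "parent_female", test = "f1",
                        reference_gene = "Actin2",
                        base_ct_range = c(22, 30), seed = 1L) {
  if (is.null(names(fold_changes)))
    names(fold_changes) <- sprintf("target%02d", seq_along(fold_changes))
  if (any(!is.finite(fold_changes)) || any(fold_changes <= 0))
    stop("fold changes must be positive and finite")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  .with_seed(seed + .seed_offsets[["ct"]], {
    genes <- names(fold_changes)
    base_ct <- stats::setNames(
      stats::runif(length(genes), base_ct_range[1], base_ct_range[2]), genes)
    genos <- c(calibrator, test)
    grid <- expand.grid(gene_id = c(genes, reference_gene), genotype = genos,
                        tech_rep = seq_len(n_tech),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    ct0 <- ifelse(grid$gene_id == reference_gene, reference_ct,
                  base_ct[grid$gene_id] -
                    ifelse(grid$genotype == test,
                           log2(fold_changes[grid$gene_id]), 0))
    out <- data.frame(sample = paste0(grid$genotype, "_1"),
                      genotype = grid$genotype,
                      gene_id = grid$gene_id,
                      tech_rep = grid$tech_rep,
                      ct = ct0 + stats::rnorm(nrow(grid), 0, noise_sd),
                      stringsAsFactors = FALSE)
    attr(out, "reference_gene") <- reference_gene
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
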