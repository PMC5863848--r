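#' Median-of-ratios size factors
#'
#' DESeq-style normalization: each sample's factor is the median, over genes
#' observed in every sample, of the ratio of its count to the per-gene
#' geometric mean across samples.
#'
#' @param counts a [trio_counts()] object or count matrix.
#' @param pseudo_reference if `TRUE`, compute per-gene geometric means over
#'   positive entries only, so matrices without any all-positive gene can
#'   still be normalized.
#' @param normalize if `TRUE`, rescale the factors to geometric mean 1.
#' @return named positive numeric vector, one factor per sample.
#' @export
estimate_size_factors <- function(counts, pseudo_reference = FALSE,
                                  normalize = FALSE) {
  mat <- if (inherits(counts, "trio_counts")) counts$counts else as.matrix(counts)
  logm <- log(mat)
  if (pseudo_reference) {
    loggeo <- apply(logm, 1, function(r) mean(r[is.finite(r)]))
  } else {
    loggeo <- rowMeans(logm)
  }
  usable <- is.finite(loggeo)
  if (!any(usable))
    stop("no gene has nonzero counts in every sample; re-run with ",
         "pseudo_reference = TRUE to normalize against positive entries only")
  # median taken on the ratio scale (an even number of usable genes then
  # interpolates arithmetically, as the definition states)
  sf <- apply(mat, 2, function(cnt) {
    r <- cnt / exp(loggeo)
    stats::median(r[usable & cnt > 0])
  })
  if (any(!is.finite(sf) | sf <= 0))
    stop("degenerate size factor for sample(s): ",
         paste(colnames(mat)[!is.finite(sf) | sf <= 0], collapse = ", "))
  if (normalize) sf <- sf / exp(mean(log(sf)))
  sf
}

.row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

# Method-of-moments NB dispersion from normalized counts q over columns `idx`.
# E[s^2] = mu * mean(1/sf) + alpha * mu^2, so alpha = (s^2 - xi*mu)/mu^2.
.mom_dispersion <- function(q, sf, idx) {
  sub <- q[, idx, drop = FALSE]
  mu <- rowMeans(sub)
  s2 <- .row_vars(sub)
  xi <- mean(1 / sf[idx])
  a <- (s2 - xi * mu) / mu^2
  a[!is.finite(a)] <- NA_real_
  list(mu = mu, alpha = a)
}

# Fit a global mean-dispersion trend alpha(mu) = a0 + a1/mu on the raw
# method-of-moments estimates (trimmed least squares), then shrink each gene's
# estimate toward it: alpha_hat = (1-w) * max(alpha_raw, 0) + w * trend.
.shrink_dispersion <- function(alpha_raw, mu, weight) {
  ok <- is.finite(alpha_raw) & is.finite(mu) & mu > 0
  trend <- function(m) rep(0, length(m))
  if (sum(ok) >= 10) {
    a <- alpha_raw[ok]
    lo <- stats::quantile(a, 0.01)
    hi <- stats::quantile(a, 0.99)
    keep <- a >= lo & a <= hi
    fit <- stats::lm.fit(cbind(1, 1 / mu[ok][keep]), a[keep])
    a0 <- max(fit$coefficients[1], 0)
    a1 <- max(fit$coefficients[2], 0)
    trend <- function(m) a0 + a1 / pmax(m, 1e-8)
  } else if (any(ok)) {
    med <- max(stats::median(alpha_raw[ok]), 0)
    trend <- function(m) rep(med, length(m))
  }
  raw <- pmax(ifelse(is.finite(alpha_raw), alpha_raw, 0), 0)
  tr <- trend(mu)
  pmax((1 - weight) * raw + weight * tr, 0)
}

#' Negative-binomial Wald test for one trio contrast
#'
#' Tests, per gene, whether the normalized mean expression differs between
#' two genotype roles. Counts are normalized by median-of-ratios size
#' factors; the NB dispersion (variance = mu + alpha * mu^2) is estimated by
#' method of moments and shrunk toward a global mean-dispersion trend; the
#' test statistic is a Wald z on the difference of log means. With a single
#' library per genotype, dispersion must be pooled blindly across all samples
#' (conservative for truly differential genes) or fixed.
#'
#' @param counts a [trio_counts()] object.
#' @param contrast character pair of genotype roles `(reference, test)`;
#'   reported `log2fc` is test over reference.
#' @param dispersion_mode `"per_group"` (within-group moments, needs >= 2
#'   replicates per group), `"blind_pooled"` (moments across all samples of
#'   the matrix), or a single non-negative number (fixed alpha; 0 = Poisson).
#'   Default: `"per_group"` when both groups have replicates, else
#'   `"blind_pooled"`.
#' @param size_factors optional precomputed size factors for all samples.
#' @param shrink_weight weight in \[0, 1\] of the fitted global trend in the
#'   per-gene dispersion (ignored for fixed dispersion). Default 0.5,
#'   rising to 1 (trend only) at 10 or fewer residual degrees of freedom.
#' @param pseudo pseudo-count added to normalized group means for the
#'   fold-change and variance denominators, keeping log2fc finite for
#'   zero-count genes.
#' @return data.frame: `gene_id`, `base_mean`, `log2fc`, `dispersion`,
#'   `p_raw`, `q_bh`, with the contrast stored in `attr(, "contrast")`.
#' @export
nb_test <- function(counts, contrast, dispersion_mode = NULL,
                    size_factors = NULL, shrink_weight = NULL, pseudo = 0.5) {
  stopifnot(inherits(counts, "trio_counts"))
  contrast <- match.arg(contrast, .roles, several.ok = TRUE)
  if (length(contrast) != 2L || contrast[1] == contrast[2])
    stop("contrast must be two distinct genotype roles")
  idx1 <- role_columns(counts, contrast[1])
  idx2 <- role_columns(counts, contrast[2])
  if (!length(idx1) || !length(idx2))
    stop("contrast role absent from the matrix: ",
         contrast[c(!length(idx1), !length(idx2))][1])

  fixed_alpha <- NULL
  if (is.numeric(dispersion_mode)) {
    if (dispersion_mode < 0) stop("fixed dispersion must be >= 0")
    fixed_alpha <- dispersion_mode
    dispersion_mode <- "fixed"
  } else if (is.null(dispersion_mode)) {
    dispersion_mode <- if (min(length(idx1), length(idx2)) >= 2L)
      "per_group" else "blind_pooled"
  } else {
    dispersion_mode <- match.arg(dispersion_mode, c("per_group", "blind_pooled"))
  }
  if (dispersion_mode == "per_group" && min(length(idx1), length(idx2)) < 2L)
    stop("per_group dispersion needs >= 2 replicates in both groups; ",
         "use blind_pooled or a fixed value")

  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- size_factors
  q <- sweep(counts$counts, 2, sf, "/")
  mu1 <- rowMeans(q[, idx1, drop = FALSE])
  mu2 <- rowMeans(q[, idx2, drop = FALSE])

  if (dispersion_mode == "fixed") {
    alpha <- rep(fixed_alpha, nrow(q))
  } else {
    if (dispersion_mode == "blind_pooled") {
      mom <- .mom_dispersion(q, sf, seq_len(ncol(q)))
      df_resid <- ncol(q) - 1L
      alpha_raw <- mom$alpha
      mu_all <- mom$mu
    } else {
      mom1 <- .mom_dispersion(q, sf, idx1)
      mom2 <- .mom_dispersion(q, sf, idx2)
      w1 <- length(idx1) - 1L
      w2 <- length(idx2) - 1L
      alpha_raw <- (w1 * mom1$alpha + w2 * mom2$alpha) / (w1 + w2)
      df_resid <- w1 + w2
      mu_all <- (length(idx1) * mu1 + length(idx2) * mu2) /
        (length(idx1) + length(idx2))
    }
    # with few residual df a per-gene moment estimate of alpha carries ~50%
    # relative error, so the fitted trend takes over entirely
    if (is.null(shrink_weight)) shrink_weight <- if (df_resid <= 10L) 1 else 0.5
    alpha <- .shrink_dispersion(alpha_raw, mu_all, shrink_weight)
  }

  m1 <- mu1 + pseudo
  m2 <- mu2 + pseudo
  delta <- log(m2) - log(m1)
  xi1 <- mean(1 / sf[idx1])
  xi2 <- mean(1 / sf[idx2])
  se2 <- (xi1 / m1 + alpha) / length(idx1) + (xi2 / m2 + alpha) / length(idx2)
  z <- delta / sqrt(pmax(se2, 1e-12))
  p <- 2 * stats::pnorm(-abs(z))
  p[delta == 0] <- 1

  out <- data.frame(gene_id = rownames(counts$counts),
                    base_mean = (mu1 + mu2) / 2,
                    log2fc = delta / log(2),
                    dispersion = alpha,
                    p_raw = p,
                    q_bh = bh_adjust(p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrast") <- contrast
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity; output order matches
#' input order. Thin validating wrapper around [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of BH-adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  bad <- which(is.na(p) | is.nan(p))
  if (length(bad))
    stop("NaN/NA p-values at index(es): ",
         paste(utils::head(bad, 10), collapse = ", "))
  if (any(p < 0 | p > 1))
    stop("p-values outside [0, 1] at index(es): ",
         paste(utils::head(which(p < 0 | p > 1), 10), collapse = ", "))
  stats::p.adjust(p, method = "BH")
}

#' Three-level differential-expression calls
#'
#' Applies the joint significance and fold-change criterion: a gene is
#' `up` when significant with `log2fc >= log2(min_fold)`, `down` when
#' significant with `log2fc <= -log2(min_fold)`, else `ns`.
#'
#' @param table output of [nb_test()].
#' @param alpha significance level on the chosen p-value column.
#' @param min_fold minimum fold change (>= 1); 2 reproduces the classic
#'   "q <= 0.05 and FC >= 2" DEG definition, 1 disables the fold gate.
#' @param use_adjusted use BH-adjusted q (`TRUE`, default) or raw p.
#' @return the input table with a `call` factor column (`up`/`down`/`ns`).
#' @export
call_deg <- function(table, alpha = 0.05, min_fold = 2.0, use_adjusted = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (min_fold < 1) stop("min_fold must be >= 1")
  sig <- if (use_adjusted) table$q_bh else table$p_raw
  lfc <- log2(min_fold)
  # min_fold = 1 edge: a significant gene with log2fc exactly 0 stays ns
  call <- rep("ns", nrow(table))
  call[sig <= alpha & table$log2fc >= lfc & table$log2fc > 0] <- "up"
  call[sig <= alpha & table$log2fc <= -lfc & table$log2fc < 0] <- "down"
  table$call <- factor(call, levels = c("up", "down", "ns"))
  table
}

#' Differential-expression calls for all three trio contrasts
#'
#' Runs [nb_test()] for parent-vs-parent, F1-vs-female and F1-vs-male and
#' translates them into the closed call vocabulary used by the pattern
#' classifier. Shared size factors are estimated once on the full matrix.
#'
#' @inheritParams nb_test
#' @param alpha,min_fold,use_adjusted passed to [call_deg()]. The default
#'   `min_fold = 1` classifies on significance alone, which is required for
#'   additive patterns to be observable (an F1 at the exact mid-parent is
#'   always < 2-fold from the high parent).
#' @return list with `calls` (data.frame: `gene_id`, `call_pp` in
#'   \{`f_higher`, `m_higher`, `ns`\}, `call_f1f`, `call_f1m` in
#'   \{`up`, `down`, `ns`\}) and `tables` (the three annotated nb_test
#'   tables `pp`, `f1f`, `f1m`).
#' @export
trio_calls <- function(counts, alpha = 0.05, min_fold = 1.0,
                       use_adjusted = TRUE, dispersion_mode = NULL,
                       size_factors = NULL, shrink_weight = NULL) {
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  run <- function(ref, test) {
    call_deg(nb_test(counts, c(ref, test), dispersion_mode = dispersion_mode,
                     size_factors = size_factors, shrink_weight = shrink_weight),
             alpha = alpha, min_fold = min_fold, use_adjusted = use_adjusted)
  }
  pp <- run("parent_male", "parent_female")   # log2fc = female over male
  f1f <- run("parent_female", "f1")
  f1m <- run("parent_male", "f1")
  calls <- data.frame(
    gene_id = pp$gene_id,
    call_pp = c(up = "f_higher", down = "m_higher", ns = "ns")[as.character(pp$call)],
    call_f1f = as.character(f1f$call),
    call_f1m = as.character(f1m$call),
    stringsAsFactors = FALSE, row.names = NULL)
  list(calls = calls, tables = list(pp = pp, f1f = f1f, f1m = f1m))
}

#' @rdname nb_test
#' @param x an nb_test table.
#' @param path file path.
#' @export
write_de_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
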