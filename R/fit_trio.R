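# Subset a trio_counts object to a gene-id vector, preserving order.
.subset_genes <- function(x, ids) {
  structure(list(counts = x$counts[ids, , drop = FALSE], meta = x$meta),
            class = "trio_counts")
}

#' Fit the trio inheritance-pattern model
#'
#' The package's central estimator. From a trio count matrix and gene
#' lengths it (1) computes FPKM and restricts the analysis universe to
#' genes with FPKM > `fpkm_min` in at least one sample, (2) estimates
#' median-of-ratios size factors, (3) runs the negative-binomial Wald test
#' for the three contrasts (parent vs parent, F1 vs each parent),
#' (4) derives DEG calls at the reporting thresholds (default q <= 0.05 and
#' fold >= 2) and pattern calls at the classification thresholds (default
#' significance only), and (5) assigns every gene to one of the 12
#' additive / dominant / overdominant inheritance patterns with the four
#' non-additive rollup gene sets.
#'
#' @inheritParams nb_test
#' @param lengths named gene-length vector (bp).
#' @param fpkm_min expression filter threshold (strict, any sample).
#' @param alpha significance level for calls.
#' @param min_fold fold-change gate for the reported DEG tables.
#' @param pattern_min_fold fold-change gate for the calls fed to the
#'   pattern classifier; 1 (default) classifies on significance alone so
#'   that mid-parent (additive) expression remains observable.
#' @param pattern_call significance rule for the classifier's calls:
#'   `"fwer"` (default) tests each of the three contrasts at `alpha / 3`
#'   on raw p, controlling the probability of any false contrast call per
#'   gene at `alpha` — the relevant error unit when a gene's label rests on
#'   all three calls simultaneously; `"bh"` uses the per-contrast
#'   BH-adjusted q at `alpha`; `"raw"` uses raw p at `alpha`.
#' @param use_adjusted use BH-adjusted q-values (default) or raw p for the
#'   reported DEG tables.
#' @param totals optional per-sample totals for the FPKM denominator.
#' @return object of class `trio_fit`; see [summary.trio_fit()].
#' @export
fit_trio <- function(counts, lengths, fpkm_min = 1.0, alpha = 0.05,
                     min_fold = 2.0, pattern_min_fold = 1.0,
                     pattern_call = c("fwer", "bh", "raw"),
                     use_adjusted = TRUE, dispersion_mode = NULL,
                     shrink_weight = NULL, totals = NULL) {
  pattern_call <- match.arg(pattern_call)
  stopifnot(inherits(counts, "trio_counts"))
  fpkm_all <- compute_fpkm(counts, lengths, totals = totals)
  expressed <- filter_expressed(fpkm_all, threshold = fpkm_min)
  if (!length(expressed)) stop("no genes pass the expression filter")
  cexp <- .subset_genes(counts, expressed)
  sf <- estimate_size_factors(cexp)

  tests <- list(
    pp = nb_test(cexp, c("parent_male", "parent_female"),
                 dispersion_mode = dispersion_mode, size_factors = sf,
                 shrink_weight = shrink_weight),
    f1f = nb_test(cexp, c("parent_female", "f1"),
                  dispersion_mode = dispersion_mode, size_factors = sf,
                  shrink_weight = shrink_weight),
    f1m = nb_test(cexp, c("parent_male", "f1"),
                  dispersion_mode = dispersion_mode, size_factors = sf,
                  shrink_weight = shrink_weight))

  deg <- lapply(tests, call_deg, alpha = alpha, min_fold = min_fold,
                use_adjusted = use_adjusted)
  pat <- switch(pattern_call,
    fwer = lapply(tests, call_deg, alpha = alpha / 3,
                  min_fold = pattern_min_fold, use_adjusted = FALSE),
    bh = lapply(tests, call_deg, alpha = alpha,
                min_fold = pattern_min_fold, use_adjusted = TRUE),
    raw = lapply(tests, call_deg, alpha = alpha,
                 min_fold = pattern_min_fold, use_adjusted = FALSE))

  calls <- data.frame(
    gene_id = pat$pp$gene_id,
    call_pp = c(up = "f_higher", down = "m_higher",
                ns = "ns")[as.character(pat$pp$call)],
    call_f1f = as.character(pat$f1f$call),
    call_f1m = as.character(pat$f1m$call),
    stringsAsFactors = FALSE, row.names = NULL)
  assignments <- classify_pattern(calls)

  structure(list(
    counts = counts,
    lengths = lengths,
    fpkm = fpkm_all[expressed, , drop = FALSE],
    expressed = expressed,
    size_factors = sf,
    tests = deg,
    calls = calls,
    assignments = assignments,
    rollup_sets = build_rollup_sets(assignments),
    pattern_counts = pattern_summary(assignments),
    params = list(fpkm_min = fpkm_min, alpha = alpha, min_fold = min_fold,
                  pattern_min_fold = pattern_min_fold,
                  pattern_call = pattern_call,
                  use_adjusted = use_adjusted,
                  dispersion_mode = dispersion_mode)),
    class = "trio_fit")
}

#' @export
print.trio_fit <- function(x, ...) {
  cat(sprintf("Trio inheritance-pattern fit: %d/%d genes pass FPKM > %g\n",
              length(x$expressed), nrow(x$counts$counts), x$params$fpkm_min))
  n_deg <- vapply(x$tests, function(t) sum(t$call != "ns"), 0L)
  cat(sprintf("  DEGs (q<=%g, fold>=%g): parent-parent %d, F1-female %d, F1-male %d\n",
              x$params$alpha, x$params$min_fold,
              n_deg[["pp"]], n_deg[["f1f"]], n_deg[["f1m"]]))
  nonadd <- sum(x$pattern_counts[paste0("P", 3:12)])
  cat(sprintf("  patterns: %d additive, %d non-additive, %d NC\n",
              sum(x$pattern_counts[c("P1", "P2")]), nonadd,
              x$pattern_counts[["NC"]]))
  invisible(x)
}

#' Summarize a trio fit
#'
#' @param object a [fit_trio()] result.
#' @param ... unused.
#' @return list with per-contrast up/down DEG counts, the per-pattern gene
#'   counts, and the rollup set sizes.
#' @export
summary.trio_fit <- function(object, ...) {
  deg <- t(vapply(object$tests, function(t)
    c(up = sum(t$call == "up"), down = sum(t$call == "down")), c(up = 0, down = 0)))
  out <- list(deg_counts = deg,
              pattern_counts = object$pattern_counts,
              rollup_sizes = vapply(object$rollup_sets, length, 0L),
              n_expressed = length(object$expressed))
  class(out) <- "summary.trio_fit"
  out
}

#' @export
print.summary.trio_fit <- function(x, ...) {
  cat(sprintf("Expressed genes: %d\n", x$n_expressed))
  cat("DEG counts per contrast:\n")
  print(x$deg_counts)
  cat("Pattern counts:\n")
  print(x$pattern_counts)
  cat("Rollup gene-set sizes:\n")
  print(x$rollup_sizes)
  invisible(x)
}

#' @export
coef.trio_fit <- function(object, ...) {
  cbind(log2fc_pp = object$tests$pp$log2fc,
        log2fc_f1f = object$tests$f1f$log2fc,
        log2fc_f1m = object$tests$f1m$log2fc) |>
    `rownames<-`(object$tests$pp$gene_id)
}

#' Barplot of the 12-pattern gene counts
#'
#' @param x a [fit_trio()] result.
#' @param include_nc include the NC (not classifiable) bar.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.trio_fit <- function(x, include_nc = FALSE, ...) {
  counts <- x$pattern_counts
  if (!include_nc) counts <- counts[names(counts) != "NC"]
  cols <- c(rep("grey60", 2), rep("steelblue", 4), rep("firebrick", 6),
            if (include_nc) "white")
  graphics::barplot(counts, col = cols[seq_along(counts)], las = 2,
                    ylab = "genes", main = "Inheritance patterns", ...)
  invisible(x)
}
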