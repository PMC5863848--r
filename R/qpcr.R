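#' Relative expression by the 2^-ddCt method
#'
#' Livak relative quantification with amplification efficiency fixed at 2.
#' Technical replicates are averaged on the Ct (cycle) scale; per genotype,
#' dCt = mean Ct(target) - mean Ct(reference); ddCt subtracts the
#' calibrator genotype's dCt, and fold = 2^-ddCt, so the calibrator's fold
#' is 1 by construction. Folds are invariant to global Ct shifts.
#'
#' @param ct a Ct table ([simulate_ct()] output or any data.frame with
#'   columns `genotype`, `gene_id`, `ct`).
#' @param target target gene id(s); defaults to every non-reference gene
#'   in the table.
#' @param reference reference (housekeeping) gene id; defaults to the
#'   table's `reference_gene` attribute.
#' @param calibrator genotype role used as the fold = 1 baseline.
#' @return data.frame: `gene_id`, `genotype`, `dct`, `ddct`, `fold`.
#' @export
ddct_relative_expression <- function(ct, target = NULL, reference = NULL,
                                     calibrator = "parent_female") {
  req <- c("genotype", "gene_id", "ct")
  if (!all(req %in% colnames(ct)))
    stop("ct table needs columns: ", paste(req, collapse = ", "))
  if (is.null(reference)) reference <- attr(ct, "reference_gene")
  if (is.null(reference)) stop("no reference gene given or recorded in the table")
  if (is.null(target)) target <- setdiff(unique(ct$gene_id), reference)
  if (reference %in% target) stop("target and reference genes must differ")
  if (!calibrator %in% ct$genotype) stop("calibrator genotype absent: ", calibrator)

  mean_ct <- function(gene, geno) {
    v <- ct$ct[ct$gene_id == gene & ct$genotype == geno]
    if (!length(v)) NA_real_ else mean(v)
  }
  genos <- unique(ct$genotype)
  ref_ct <- vapply(genos, function(g) mean_ct(reference, g), numeric(1))
  if (any(is.na(ref_ct)))
    stop("missing reference-gene measurements for genotype(s): ",
         paste(genos[is.na(ref_ct)], collapse = ", "))
  rows <- lapply(target, function(gene) {
    tgt <- vapply(genos, function(g) mean_ct(gene, g), numeric(1))
    dct <- tgt - ref_ct
    ddct <- dct - dct[[calibrator]]
    data.frame(gene_id = gene, genotype = genos,
               dct = unname(dct), ddct = unname(ddct),
               fold = unname(2^-ddct),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' RNA-seq / qPCR fold-change concordance
#'
#' Ordinary least-squares regression of qPCR log2 fold changes on RNA-seq
#' log2 fold changes over the shared genes, with the squared Pearson
#' correlation as the concordance measure.
#'
#' @param rnaseq_log2fc,qpcr_log2fc named numeric vectors of per-gene log2
#'   fold changes; matched by name when both are named, by position
#'   otherwise. At least 3 shared finite pairs required.
#' @return list of class `concordance`: `slope`, `intercept`, `r_squared`,
#'   `n`.
#' @export
concordance <- function(rnaseq_log2fc, qpcr_log2fc) {
  if (!is.null(names(rnaseq_log2fc)) && !is.null(names(qpcr_log2fc))) {
    shared <- intersect(names(rnaseq_log2fc), names(qpcr_log2fc))
    x <- rnaseq_log2fc[shared]
    y <- qpcr_log2fc[shared]
  } else {
    if (length(rnaseq_log2fc) != length(qpcr_log2fc))
      stop("unnamed fold-change vectors must have equal length")
    x <- rnaseq_log2fc
    y <- qpcr_log2fc
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need >= 3 shared genes with finite fold changes")
  if (stats::sd(x) == 0) stop("zero variance in the RNA-seq fold changes")
  fit <- stats::lm(y ~ x)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = stats::cor(x, y)^2,
                 n = length(x)),
            class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("qPCR/RNA-seq concordance on %d genes: r^2 = %.3f (slope %.3f, intercept %.3f)\n",
              x$n, x$r_squared, x$slope, x$intercept))
  invisible(x)
}

#' Read / write a long Ct table (TSV)
#' @param path file path.
#' @param reference_gene reference gene id to record on the table.
#' @return data.frame of class `ct_table`.
#' @export
read_ct_tsv <- function(path, reference_gene = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample", "genotype", "gene_id", "tech_rep", "ct")
  if (!all(req %in% colnames(df)))
    stop("ct table needs columns: ", paste(req, collapse = ", "))
  if (!is.null(reference_gene)) attr(df, "reference_gene") <- reference_gene
  class(df) <- c("ct_table", "data.frame")
  df
}

#' @rdname read_ct_tsv
#' @param x ct table.
#' @export
write_ct_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
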