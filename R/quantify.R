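#' FPKM from a count matrix and gene lengths
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' \deqn{FPKM_{gs} = count_{gs} \times 10^9 / (length_g \times total_s)}
#' where `total_s` is by default the column sum of the supplied matrix.
#'
#' @param counts a [trio_counts()] object or a plain count matrix with gene
#'   rownames.
#' @param lengths named numeric vector of gene lengths in bp (>= 1).
#' @param totals optional per-sample totals to use as the per-million
#'   denominator (e.g. uniquely-mapped read counts); defaults to column sums.
#' @return numeric matrix of FPKM values, genes x samples.
#' @export
compute_fpkm <- function(counts, lengths, totals = NULL) {
  mat <- if (inherits(counts, "trio_counts")) counts$counts else as.matrix(counts)
  missing_len <- setdiff(rownames(mat), names(lengths))
  if (length(missing_len))
    stop("missing gene length for: ",
         paste(utils::head(missing_len, 5), collapse = ", "),
         if (length(missing_len) > 5) sprintf(" (and %d more)", length(missing_len) - 5))
  len <- lengths[rownames(mat)]
  if (any(len < 1)) stop("gene lengths must be >= 1 bp; offending gene: ",
                         rownames(mat)[which(len < 1)[1]])
  if (is.null(totals)) totals <- colSums(mat)
  if (any(totals <= 0)) {
    bad <- colnames(mat)[which(totals <= 0)[1]]
    stop("sample with non-positive total count: ", bad)
  }
  fpkm <- sweep(mat / len, 2, totals, "/") * 1e9
  dimnames(fpkm) <- dimnames(mat)
  fpkm
}

#' Expression filter on an FPKM matrix
#'
#' Keeps genes whose FPKM exceeds `threshold` (strictly) in at least one
#' sample — the standard "FPKM > 1 in at least 1 sample" analysis universe.
#'
#' @param fpkm numeric FPKM matrix with gene rownames.
#' @param threshold non-negative FPKM cut-off.
#' @return character vector of retained gene ids, input order preserved.
#' @export
filter_expressed <- function(fpkm, threshold = 1.0) {
  if (threshold < 0) stop("threshold must be >= 0")
  keep <- apply(fpkm > threshold, 1, any)
  rownames(fpkm)[keep]
}

#' @rdname compute_fpkm
#' @param x FPKM matrix.
#' @param path file path.
#' @export
write_fpkm_tsv <- function(x, path) {
  utils::write.table(data.frame(gene_id = rownames(x), x, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
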