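#' @keywords internal
.roles <- c("parent_female", "parent_male", "f1")

#' Trio count matrix
#'
#' Container for gene-level RNA-seq counts from a two-parent / F1-hybrid trio.
#' Columns are samples; each sample carries a genotype role (maternal parent,
#' paternal parent or hybrid) and a replicate index.
#'
#' @param counts integer matrix, genes x samples, with rownames as gene ids.
#' @param roles character vector, one of `"parent_female"`, `"parent_male"`,
#'   `"f1"` per sample (column).
#' @param replicates integer replicate index per sample; defaults to 1..n
#'   within each role.
#' @param sample_ids sample names; default `<role>_<replicate>` with the
#'   shorthand female/male/hybrid.
#'
#' @return An object of class `trio_counts`: a list with elements `counts`
#'   (integer matrix) and `meta` (data.frame with columns `sample`, `role`,
#'   `replicate`).
#' @export
trio_counts <- function(counts, roles, replicates = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("no genes: count matrix has zero rows")
  if (is.null(rownames(counts))) stop("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  storage <- counts
  if (any(!is.finite(storage)) || any(storage < 0) ||
      any(abs(storage - round(storage)) > 1e-8)) {
    bad <- which(!is.finite(storage) | storage < 0 |
                   abs(storage - round(storage)) > 1e-8, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf("counts must be non-negative integers; offending cell gene '%s', sample column %d",
                 rownames(storage)[bad[1]], bad[2]))
  }
  mode(counts) <- "integer"
  roles <- as.character(roles)
  if (length(roles) != ncol(counts))
    stop("roles must have one entry per sample column")
  unknown <- setdiff(unique(roles), .roles)
  if (length(unknown))
    stop("unknown genotype token(s): ", paste(unknown, collapse = ", "),
         "; expected ", paste(.roles, collapse = ", "))
  missing_roles <- setdiff(.roles, roles)
  if (length(missing_roles))
    stop("every genotype role must be present; missing: ",
         paste(missing_roles, collapse = ", "))
  if (is.null(replicates)) {
    replicates <- stats::ave(seq_along(roles), roles, FUN = seq_along)
  }
  replicates <- as.integer(replicates)
  if (is.null(sample_ids)) {
    short <- c(parent_female = "female", parent_male = "male", f1 = "hybrid")
    sample_ids <- paste0(short[roles], "_", replicates)
  }
  colnames(counts) <- sample_ids
  meta <- data.frame(sample = sample_ids, role = roles,
                     replicate = replicates, stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta), class = "trio_counts")
}

#' @export
print.trio_counts <- function(x, ...) {
  tab <- table(x$meta$role)
  cat(sprintf("Trio count matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  parent_female: %d, parent_male: %d, f1: %d sample(s)\n",
              tab[["parent_female"]], tab[["parent_male"]], tab[["f1"]]))
  invisible(x)
}

#' @export
dim.trio_counts <- function(x) dim(x$counts)

#' Columns of a trio matrix belonging to one genotype role
#' @param x a `trio_counts` object.
#' @param role genotype role token.
#' @return integer column indices.
#' @export
role_columns <- function(x, role) {
  role <- match.arg(role, .roles)
  which(x$meta$role == role)
}

#' Read / write a trio count matrix as TSV
#'
#' The header encodes sample metadata as `sample:genotype:replicate`
#' (for example `hybrid_1:f1:1`); the first column is `gene_id`.
#'
#' @param path file path.
#' @return `read_counts_tsv` returns a [trio_counts()] object.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("counts file needs gene_id plus at least one sample column")
  gene_ids <- as.character(raw[[1]])
  mat <- raw[, -1, drop = FALSE]
  headers <- colnames(mat)
  parts <- strsplit(headers, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed sample header (expected sample:genotype:replicate): ",
         headers[bad[1]])
  for (j in seq_along(mat)) {
    v <- suppressWarnings(as.numeric(mat[[j]]))
    if (any(is.na(v) & !is.na(mat[[j]])) || any(!is.na(v) & v != round(v)))
      stop(sprintf("non-integer count in column '%s', row %d (gene '%s')",
                   headers[j],
                   which(is.na(v) | v != round(v))[1],
                   gene_ids[which(is.na(v) | v != round(v))[1]]))
    mat[[j]] <- as.integer(v)
  }
  m <- as.matrix(mat)
  rownames(m) <- gene_ids
  trio_counts(m,
              roles = vapply(parts, `[`, "", 2L),
              replicates = as.integer(vapply(parts, `[`, "", 3L)),
              sample_ids = vapply(parts, `[`, "", 1L))
}

#' @rdname read_counts_tsv
#' @param x a `trio_counts` object.
#' @export
write_counts_tsv <- function(x, path) {
  stopifnot(inherits(x, "trio_counts"))
  hdr <- paste(x$meta$sample, x$meta$role, x$meta$replicate, sep = ":")
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("gene_id", hdr)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column gene-length table (gene_id, length_bp)
#' @param path file path.
#' @return named numeric vector of lengths in bp.
#' @export
read_lengths_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "length_bp") %in% colnames(df)))
    stop("gene-length table must have columns gene_id and length_bp")
  stats::setNames(as.numeric(df$length_bp), df$gene_id)
}

#' @rdname read_lengths_tsv
#' @param lengths named numeric vector (names = gene ids, values = bp).
#' @export
write_lengths_tsv <- function(lengths, path) {
  utils::write.table(
    data.frame(gene_id = names(lengths), length_bp = as.numeric(lengths)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
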