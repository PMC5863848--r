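#' Read a GMT gene-set file
#'
#' Standard tab-delimited gene-set format: one term per line as
#' `term_id <TAB> description <TAB> member1 <TAB> member2 ...`. Duplicate
#' members within a term are deduplicated; duplicate term ids are an error.
#'
#' @param path file path.
#' @return object of class `term_map`: a named list of unique member-gene
#'   character vectors, with term descriptions in `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  sets <- list()
  desc <- character(0)
  for (i in which(keep)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: expected term, description and >= 1 member", i))
    id <- f[1]
    if (id %in% names(sets)) stop("duplicate term id: ", id)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    sets[[id]] <- members
    desc[id] <- f[2]
  }
  structure(sets, description = desc, class = "term_map")
}

#' @export
print.term_map <- function(x, ...) {
  cat(sprintf("Term map: %d term(s), %d distinct gene(s)\n",
              length(x), length(unique(unlist(x)))))
  invisible(x)
}

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, tests whether the study set over-represents the term's
#' members relative to the population, with an upper-tail hypergeometric
#' p-value \eqn{P(X \ge count)} where N = |population|, K = term size after
#' restriction to the population, n = |study|. P-values are BH-adjusted
#' across the tested terms.
#'
#' @param study character vector of study gene ids (must be, or be
#'   restricted to, a subset of `population`).
#' @param population character vector: the gene universe (typically all
#'   genes passing the expression filter, guarding against detection bias).
#' @param terms a [read_gmt()] `term_map` or named list of member vectors.
#' @param min_term_size terms with fewer in-population members are not
#'   tested (singletons only inflate the BH denominator).
#' @param auto_restrict if `TRUE`, silently drop study genes missing from
#'   the population instead of erroring.
#' @return data.frame (class `enrichment`): `term_id`, `count`, `size`,
#'   `term`, `p_raw`, `p_adjust`, sorted by `p_adjust` then `term_id`.
#' @export
hypergeom_enrich <- function(study, population, terms, min_term_size = 2,
                             auto_restrict = FALSE) {
  if (!length(population)) stop("population must be non-empty")
  population <- unique(population)
  study <- unique(study)
  stray <- setdiff(study, population)
  if (length(stray)) {
    if (!auto_restrict)
      stop("study gene(s) absent from population: ",
           paste(utils::head(stray, 10), collapse = ", "),
           if (length(stray) > 10) sprintf(" (and %d more)", length(stray) - 10),
           "; set auto_restrict = TRUE to drop them")
    study <- intersect(study, population)
  }
  desc <- attr(terms, "description")
  N <- length(population)
  n <- length(study)
  rows <- lapply(names(terms), function(id) {
    members <- intersect(unique(terms[[id]]), population)
    K <- length(members)
    if (K < min_term_size) return(NULL)
    cnt <- length(intersect(members, study))
    p <- stats::phyper(cnt - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, count = cnt, size = K,
               term = if (!is.null(desc) && id %in% names(desc)) desc[[id]] else "",
               p_raw = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(term_id = character(0), count = integer(0),
                      size = integer(0), term = character(0),
                      p_raw = numeric(0), p_adjust = numeric(0))
  } else {
    out <- do.call(rbind, rows)
    out$p_adjust <- bh_adjust(out$p_raw)
    out <- out[order(out$p_adjust, out$term_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("enrichment", "data.frame")
  out
}

#' @rdname hypergeom_enrich
#' @param x enrichment table.
#' @param path file path.
#' @export
write_enrichment_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
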