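#' Heterosis indices of an F1 hybrid
#'
#' For a trait value of the hybrid (F1) and its two parents, computes the
#' three classical indices, as percent:
#' \deqn{OPH = (F1 - HP)/HP \times 100}
#' \deqn{MPH = (F1 - MP)/MP \times 100}
#' \deqn{BPH = (F1 - LP)/LP \times 100}
#' where HP and LP are the high- and low-value parent for that measurement
#' and MP = (parent1 + parent2) / 2. HP/LP rank is assigned per call, so a
#' parent may switch rank between environments. All three arguments are
#' vectorized.
#'
#' @param f1 hybrid trait value(s).
#' @param parent1,parent2 parental trait values (> 0).
#' @return data.frame of class `heterosis`: `f1`, `hp`, `lp`, `mp`,
#'   `oph_pct`, `mph_pct`, `bph_pct`.
#' @export
heterosis_indices <- function(f1, parent1, parent2) {
  if (any(parent1 <= 0) || any(parent2 <= 0))
    stop("parent trait values must be > 0 for percent heterosis")
  hp <- pmax(parent1, parent2)
  lp <- pmin(parent1, parent2)
  mp <- (parent1 + parent2) / 2
  out <- data.frame(f1 = f1, hp = hp, lp = lp, mp = mp,
                    oph_pct = (f1 - hp) / hp * 100,
                    mph_pct = (f1 - mp) / mp * 100,
                    bph_pct = (f1 - lp) / lp * 100)
  class(out) <- c("heterosis", "data.frame")
  out
}

#' @export
print.heterosis <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mid-parent heterosis implied by the parent-relative indices
#'
#' Eliminating F1, HP and LP from the three index definitions leaves MPH as
#' a harmonic-mean combination of OPH and BPH:
#' \deqn{MPH = \left(\frac{2}{\frac{1}{1+OPH/100} + \frac{1}{1+BPH/100}} - 1\right) \times 100}
#' This is an exact algebraic identity, so a published (MPH, OPH, BPH)
#' triple can be checked for internal consistency without the underlying
#' trait means.
#'
#' @param oph_pct,bph_pct high- and low-parent indices in percent
#'   (each > -100).
#' @return mid-parent heterosis in percent.
#' @export
mph_from_oph_bph <- function(oph_pct, bph_pct) {
  if (any(oph_pct <= -100) || any(bph_pct <= -100))
    stop("indices must be > -100 percent")
  rh <- 1 / (1 + oph_pct / 100)
  rl <- 1 / (1 + bph_pct / 100)
  (2 / (rh + rl) - 1) * 100
}

#' Heterosis per year and developmental stage from a phenotype table
#'
#' Averages replicate trait values per genotype within each (year, stage)
#' cell, then applies [heterosis_indices()].
#'
#' @param table long data.frame with columns `genotype` (`parent_female`,
#'   `parent_male`, `f1`), `year`, `stage`, `replicate`, `value`.
#' @return data.frame: `year`, `stage`, genotype means and the three
#'   indices (class `heterosis`).
#' @export
phenotype_heterosis <- function(table) {
  req <- c("genotype", "year", "stage", "replicate", "value")
  if (!all(req %in% colnames(table)))
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  cells <- unique(table[, c("year", "stage")])
  cells <- cells[order(cells$year, cells$stage), , drop = FALSE]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    yr <- cells$year[i]; st <- cells$stage[i]
    sub <- table[table$year == yr & table$stage == st, ]
    miss <- setdiff(.roles, unique(sub$genotype))
    if (length(miss))
      stop(sprintf("missing genotype %s in cell (year=%s, stage=%s)",
                   paste(miss, collapse = ","), yr, st))
    m <- tapply(sub$value, sub$genotype, mean)
    h <- heterosis_indices(m[["f1"]], m[["parent_female"]], m[["parent_male"]])
    cbind(data.frame(year = yr, stage = st), as.data.frame(h))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("heterosis", "data.frame")
  out
}

#' Per-gene expression heterosis
#'
#' Applies the heterosis formulas to genotype-mean FPKM per gene. Genes for
#' which either parental mean is zero are flagged and their indices set to
#' NA rather than dropped.
#'
#' @param fpkm FPKM matrix, genes x samples.
#' @param meta sample metadata data.frame with columns `sample` and `role`
#'   (as in `trio_counts$meta`).
#' @return data.frame: `gene_id`, genotype mean FPKM, the three indices,
#'   and `flagged` (TRUE when a parental mean is zero).
#' @export
gene_expression_heterosis <- function(fpkm, meta) {
  mean_role <- function(role)
    rowMeans(fpkm[, meta$sample[meta$role == role], drop = FALSE])
  mf <- mean_role("parent_female")
  mm <- mean_role("parent_male")
  mh <- mean_role("f1")
  ok <- mf > 0 & mm > 0
  out <- data.frame(gene_id = rownames(fpkm),
                    mean_female = mf, mean_male = mm, mean_f1 = mh,
                    oph_pct = NA_real_, mph_pct = NA_real_, bph_pct = NA_real_,
                    flagged = !ok, stringsAsFactors = FALSE, row.names = NULL)
  if (any(ok)) {
    h <- heterosis_indices(mh[ok], mf[ok], mm[ok])
    out$oph_pct[ok] <- h$oph_pct
    out$mph_pct[ok] <- h$mph_pct
    out$bph_pct[ok] <- h$bph_pct
  }
  out
}

#' Read / write a long phenotype trait table (TSV)
#' @param path file path.
#' @return data.frame with columns genotype, year, stage, replicate, value.
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("genotype", "year", "stage", "replicate", "value")
  if (!all(req %in% colnames(df)))
    stop("phenotype table needs columns: ", paste(req, collapse = ", "))
  df
}

#' @rdname read_phenotype_tsv
#' @param x phenotype data.frame.
#' @export
write_phenotype_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
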