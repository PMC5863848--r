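# The 12 inheritance patterns of an F1 trio, as a total decision table over
# the 3 x 3 x 3 call space (parent-vs-parent, F1-vs-female, F1-vs-male).
# P1/P2 additive; P3/P4 higher-parent dominant; P5/P6 lower-parent dominant;
# P7-P9 up-regulated overdominant; P10-P12 down-regulated overdominant.
# Any call combination carrying conflicting or incomplete evidence is NC.
.pattern_rules <- data.frame(
  pattern = c("P1", "P2", "P3", "P4", "P5", "P6",
              "P7", "P8", "P9", "P10", "P11", "P12"),
  call_pp = c("f_higher", "m_higher",   # additive: F1 between sig-different parents
              "m_higher", "f_higher",   # HPD: F1 tracks the higher parent
              "f_higher", "m_higher",   # LPD: F1 tracks the lower parent
              "f_higher", "m_higher", "ns",   # up-OD by parental relation
              "f_higher", "m_higher", "ns"),  # down-OD by parental relation
  call_f1f = c("down", "up",
               "up", "ns",
               "down", "ns",
               "up", "up", "up",
               "down", "down", "down"),
  call_f1m = c("up", "down",
               "ns", "up",
               "ns", "down",
               "up", "up", "up",
               "down", "down", "down"),
  stringsAsFactors = FALSE)

.rollup_of_pattern <- c(P1 = "additive", P2 = "additive",
                        P3 = "HPD", P4 = "HPD", P5 = "LPD", P6 = "LPD",
                        P7 = "UOD", P8 = "UOD", P9 = "UOD",
                        P10 = "DOD", P11 = "DOD", P12 = "DOD",
                        NC = "none")

#' Classify trio call combinations into the 12 inheritance patterns
#'
#' Maps each gene's three differential-expression calls to one of the
#' patterns P1-P12 or NC (not classifiable). Additive genes (P1, P2) have an
#' F1 strictly between significantly different parents; dominant genes
#' (P3-P6) match one parent and differ from the other while the parents
#' differ; overdominant genes (P7-P12) are significantly above or below both
#' parents, sub-indexed by the parental relation. All remaining call
#' combinations (15 of the 27 cells) are NC.
#'
#' @param calls data.frame with columns `call_pp` (`f_higher` / `m_higher` /
#'   `ns`), `call_f1f` and `call_f1m` (`up` / `down` / `ns`), plus optionally
#'   `gene_id` — e.g. `trio_calls()$calls`.
#' @return data.frame with `gene_id` (if supplied), `pattern` in
#'   \{P1..P12, NC\} and `rollup` in \{additive, HPD, LPD, UOD, DOD, none\}.
#' @export
classify_pattern <- function(calls) {
  need <- c("call_pp", "call_f1f", "call_f1m")
  if (!all(need %in% colnames(calls)))
    stop("calls needs columns: ", paste(need, collapse = ", "))
  chk <- function(x, vocab, nm) {
    bad <- setdiff(unique(as.character(x)), vocab)
    if (length(bad)) stop("unknown call token in ", nm, ": ",
                          paste(bad, collapse = ", "))
  }
  chk(calls$call_pp, c("f_higher", "m_higher", "ns"), "call_pp")
  chk(calls$call_f1f, c("up", "down", "ns"), "call_f1f")
  chk(calls$call_f1m, c("up", "down", "ns"), "call_f1m")

  key <- paste(calls$call_pp, calls$call_f1f, calls$call_f1m, sep = "|")
  rule_key <- paste(.pattern_rules$call_pp, .pattern_rules$call_f1f,
                    .pattern_rules$call_f1m, sep = "|")
  pattern <- .pattern_rules$pattern[match(key, rule_key)]
  pattern[is.na(pattern)] <- "NC"
  out <- data.frame(pattern = pattern,
                    rollup = unname(.rollup_of_pattern[pattern]),
                    stringsAsFactors = FALSE, row.names = NULL)
  if ("gene_id" %in% colnames(calls))
    out <- cbind(data.frame(gene_id = calls$gene_id,
                            stringsAsFactors = FALSE), out)
  out
}

#' The four non-additive rollup gene sets
#'
#' Splits pattern assignments into the higher-parent dominant (HPDG),
#' lower-parent dominant (LPDG), up-regulated overdominant (UODG) and
#' down-regulated overdominant (DODG) gene sets. Additive and NC genes
#' belong to none of them; the four sets are pairwise disjoint.
#'
#' @param assignments output of [classify_pattern()] (needs `gene_id`).
#' @return named list of character vectors `HPDG`, `LPDG`, `UODG`, `DODG`.
#' @export
build_rollup_sets <- function(assignments) {
  if (!"gene_id" %in% colnames(assignments))
    stop("assignments must carry gene_id")
  list(HPDG = assignments$gene_id[assignments$rollup == "HPD"],
       LPDG = assignments$gene_id[assignments$rollup == "LPD"],
       UODG = assignments$gene_id[assignments$rollup == "UOD"],
       DODG = assignments$gene_id[assignments$rollup == "DOD"])
}

#' Per-pattern gene counts
#'
#' @param assignments output of [classify_pattern()].
#' @return named integer vector over P1..P12 and NC, summing to the number
#'   of classified genes.
#' @export
pattern_summary <- function(assignments) {
  lv <- c(.pattern_rules$pattern, "NC")
  tab <- table(factor(assignments$pattern, levels = lv))
  stats::setNames(as.integer(tab), lv)
}

#' @rdname classify_pattern
#' @param path file path.
#' @param x an assignment data.frame.
#' @export
write_patterns_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
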