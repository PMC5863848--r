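#' Pipeline configuration
#'
#' Bundles input paths and analysis thresholds for [run_pipeline()].
#'
#' @param counts,lengths paths to the counts TSV and gene-length TSV
#'   (required).
#' @param gmt,phenotype,ct optional paths to a GMT term file, a long
#'   phenotype TSV and a long Ct TSV; the matching pipeline stages are
#'   skipped when absent.
#' @param outdir output directory (created if needed).
#' @param fpkm_min,alpha,min_fold,pattern_min_fold,use_adjusted,dispersion_mode
#'   analysis thresholds, as in [fit_trio()].
#' @param qpcr_reference reference gene id in the Ct table.
#' @param qpcr_calibrator calibrator genotype role.
#' @param seed integer seed recorded in the manifest (the analysis itself
#'   is deterministic).
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(counts, lengths, gmt = NULL, phenotype = NULL,
                            ct = NULL, outdir = tempfile("triohet_run_"),
                            fpkm_min = 1.0, alpha = 0.05, min_fold = 2.0,
                            pattern_min_fold = 1.0, use_adjusted = TRUE,
                            dispersion_mode = NULL,
                            qpcr_reference = "Actin2",
                            qpcr_calibrator = "parent_female", seed = 1L) {
  cfg <- list(paths = list(counts = counts, lengths = lengths, gmt = gmt,
                           phenotype = phenotype, ct = ct),
              outdir = outdir,
              fpkm_min = fpkm_min, alpha = alpha, min_fold = min_fold,
              pattern_min_fold = pattern_min_fold,
              use_adjusted = use_adjusted, dispersion_mode = dispersion_mode,
              qpcr_reference = qpcr_reference,
              qpcr_calibrator = qpcr_calibrator, seed = as.integer(seed))
  if (cfg$fpkm_min < 0) stop("fpkm_min must be >= 0")
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("alpha must be in (0, 1)")
  if (cfg$min_fold < 1 || cfg$pattern_min_fold < 1)
    stop("fold thresholds must be >= 1")
  for (nm in c("counts", "lengths")) {
    if (is.null(cfg$paths[[nm]])) stop("config requires a ", nm, " path")
    if (!file.exists(cfg$paths[[nm]]))
      stop(nm, " file does not exist: ", cfg$paths[[nm]])
  }
  for (nm in c("gmt", "phenotype", "ct")) {
    p <- cfg$paths[[nm]]
    if (!is.null(p) && !file.exists(p)) stop(nm, " file does not exist: ", p)
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path path to a YAML file whose keys mirror the
#'   `pipeline_config()` arguments (paths under a `paths:` block or at the
#'   top level).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$paths)) {
    y <- c(y$paths, y[setdiff(names(y), "paths")])
  }
  known <- names(formals(pipeline_config))
  do.call(pipeline_config, y[intersect(names(y), known)])
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full trio heterosis pipeline
#'
#' Reads the configured inputs, fits the trio inheritance-pattern model
#' ([fit_trio()]), then runs the optional downstream stages: term
#' over-representation of the four rollup gene sets against the expressed
#' universe, phenotype heterosis per (year, stage), and qPCR fold changes
#' with RNA-seq concordance. Every result table is written as TSV (JSON for
#' concordance) under `config$outdir` together with `manifest.json`
#' recording input/output md5 hashes, parameters and the package version,
#' so a re-run on identical inputs is byte-reproducible.
#'
#' @param config a [pipeline_config()] object (or path to one in YAML).
#' @return list of class `trio_pipeline`: `fit` (the `trio_fit`),
#'   `enrichment` (per rollup set), `phenotype` (heterosis table), `qpcr`
#'   (fold table + `concordance`), `manifest`, `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(writer, obj, file) {
    path <- file.path(config$outdir, file)
    writer(obj, path)
    written <<- c(written, path)
    path
  }

  counts <- .stage("read_counts", read_counts_tsv(config$paths$counts))
  lengths <- .stage("read_lengths", read_lengths_tsv(config$paths$lengths))

  fit <- .stage("fit_trio", fit_trio(
    counts, lengths, fpkm_min = config$fpkm_min, alpha = config$alpha,
    min_fold = config$min_fold, pattern_min_fold = config$pattern_min_fold,
    use_adjusted = config$use_adjusted,
    dispersion_mode = config$dispersion_mode))

  emit(write_fpkm_tsv, fit$fpkm, "fpkm.tsv")
  for (nm in names(fit$tests))
    emit(write_de_tsv, fit$tests[[nm]], paste0("de_", nm, ".tsv"))
  emit(write_patterns_tsv, fit$assignments, "patterns.tsv")
  emit(write_patterns_tsv,
       data.frame(pattern = names(fit$pattern_counts),
                  n_genes = unname(fit$pattern_counts)),
       "pattern_summary.tsv")

  enr <- NULL
  if (!is.null(config$paths$gmt)) {
    terms <- .stage("read_gmt", read_gmt(config$paths$gmt))
    enr <- .stage("enrichment", lapply(fit$rollup_sets, function(set) {
      hypergeom_enrich(set, population = fit$expressed, terms = terms,
                       auto_restrict = TRUE)
    }))
    for (nm in names(enr))
      emit(write_enrichment_tsv, enr[[nm]], paste0("enrichment_", nm, ".tsv"))
  }

  pheno <- NULL
  if (!is.null(config$paths$phenotype)) {
    tab <- .stage("read_phenotype", read_phenotype_tsv(config$paths$phenotype))
    pheno <- .stage("phenotype_heterosis", phenotype_heterosis(tab))
    emit(write_phenotype_tsv, as.data.frame(pheno), "heterosis.tsv")
  }

  qp <- NULL
  if (!is.null(config$paths$ct)) {
    ct <- .stage("read_ct", read_ct_tsv(config$paths$ct,
                                        reference_gene = config$qpcr_reference))
    folds <- .stage("ddct", ddct_relative_expression(
      ct, reference = config$qpcr_reference,
      calibrator = config$qpcr_calibrator))
    emit(write_ct_tsv, folds, "qpcr_folds.tsv")
    # concordance with the RNA-seq contrast matching calibrator -> F1
    contrast_tab <- if (config$qpcr_calibrator == "parent_male")
      fit$tests$f1m else fit$tests$f1f
    rna <- stats::setNames(contrast_tab$log2fc, contrast_tab$gene_id)
    f1 <- folds[folds$genotype == "f1", ]
    qfc <- stats::setNames(log2(f1$fold), f1$gene_id)
    shared <- intersect(names(rna), names(qfc))
    conc <- if (length(shared) >= 3)
      .stage("concordance", concordance(rna[shared], qfc[shared])) else NULL
    if (!is.null(conc)) {
      path <- file.path(config$outdir, "concordance.json")
      jsonlite::write_json(unclass(conc), path, auto_unbox = TRUE, digits = NA)
      written <- c(written, path)
    }
    qp <- list(folds = folds, concordance = conc)
  }

  inputs <- Filter(Negate(is.null), config$paths)
  manifest <- list(
    package = "triohet",
    version = as.character(utils::packageVersion("triohet")),
    parameters = config[setdiff(names(config), c("paths", "outdir"))],
    inputs = as.list(tools::md5sum(unlist(inputs))),
    outputs = as.list(tools::md5sum(written)))
  manifest_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  structure(list(fit = fit, enrichment = enr, phenotype = pheno, qpcr = qp,
                 manifest = manifest, outdir = config$outdir),
            class = "trio_pipeline")
}

#' @export
print.trio_pipeline <- function(x, ...) {
  cat("Trio heterosis pipeline run ->", x$outdir, "\n")
  print(x$fit)
  if (!is.null(x$phenotype)) {
    cat("Phenotype heterosis:\n")
    print(x$phenotype)
  }
  if (!is.null(x$qpcr) && !is.null(x$qpcr$concordance)) print(x$qpcr$concordance)
  invisible(x)
}
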