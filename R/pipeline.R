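#' Pipeline configuration
#'
#' Bundles input paths and stage configurations for an end-to-end run.
#' Defaults follow the field-study conventions the package emulates: kNN
#' imputation with k = 5, 50 ensemble network runs, 5 SGCCA components, and
#' FDR 0.05 for both enrichment steps.
#'
#' @param chem_path Path to the chemical table (ignored in synthetic mode).
#' @param counts_path Path to the gene count matrix (ignored in synthetic
#'   mode).
#' @param gmt_path Path to a GMT pathway annotation, or `NULL` to skip
#'   pathway overrepresentation.
#' @param output_dir Output directory for persisted stage artifacts.
#' @param synth Optional [synth_config()]; if supplied, inputs are generated
#'   rather than read.
#' @param max_missing_frac Chemical detection-filter threshold.
#' @param knn_k Neighbours for imputation.
#' @param normalization Expression normalization method.
#' @param ensemble An [ensemble_config()].
#' @param sgcca An [sgcca_config()].
#' @param min_module_size Minimum module size.
#' @param alpha FDR level for enrichment and overrepresentation.
#' @param sw_cutoff Squared-weight cutoff for chemical contributors.
#' @param seed Global seed; per-stage seeds derive as
#'   `(seed + 1000 * stage_index) %% 2^31` in stage order (simulate,
#'   network, sgcca), so stage-level reruns reproduce pipeline results.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(chem_path = NULL, counts_path = NULL,
                            gmt_path = NULL, output_dir = tempfile("chemolink_run_"),
                            synth = NULL, max_missing_frac = 0.5, knn_k = 5,
                            normalization = "log_cpm_quantile",
                            ensemble = NULL, sgcca = NULL,
                            min_module_size = 10, alpha = 0.05,
                            sw_cutoff = 0.01, seed = 1) {
  if (is.null(synth)) {
    for (p in c(chem_path, counts_path)) {
      if (is.null(p) || !file.exists(p)) {
        stop("non-synthetic mode requires existing `chem_path` and `counts_path`")
      }
    }
  }
  if (!is.null(gmt_path) && !file.exists(gmt_path)) {
    stop(sprintf("GMT file not found: %s", gmt_path))
  }
  stage_seed <- function(i) (seed + 1000L * i) %% .Machine$integer.max
  structure(list(chem_path = chem_path, counts_path = counts_path,
                 gmt_path = gmt_path, output_dir = output_dir, synth = synth,
                 max_missing_frac = max_missing_frac, knn_k = knn_k,
                 normalization = normalization,
                 ensemble = if (is.null(ensemble)) ensemble_config(seed = stage_seed(2)) else ensemble,
                 sgcca = if (is.null(sgcca)) sgcca_config(seed = stage_seed(3)) else sgcca,
                 min_module_size = min_module_size, alpha = alpha,
                 sw_cutoff = sw_cutoff, seed = seed,
                 stage_seed = stage_seed),
            class = "pipeline_config")
}

#' Validate pipeline input files
#'
#' Checks table parseability, id uniqueness, sample concordance between the
#' chemical and expression blocks (order-insensitive; reordering is noted,
#' not an error), and GMT well-formedness. Never throws for data defects:
#' every defect is listed in the returned report.
#'
#' @param chem_path Chemical table path.
#' @param counts_path Count matrix path.
#' @param gmt_path Optional GMT path.
#' @return List with `ok` (logical), `defects` (character vector) and
#'   `notes` (character vector).
#' @export
validate_inputs <- function(chem_path, counts_path, gmt_path = NULL) {
  defects <- character(0); notes <- character(0)
  chem <- tryCatch(read_chem_table(chem_path), error = function(e) {
    defects <<- c(defects, sprintf("chemical table unreadable: %s", conditionMessage(e)))
    NULL
  })
  expr <- tryCatch({
    df <- utils::read.table(counts_path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    ids <- df[[1]]
    if (anyDuplicated(ids)) {
      defects <- c(defects, sprintf("duplicate gene id: %s",
                                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
      NULL
    } else {
      m <- as.matrix(df[, -1, drop = FALSE]); rownames(m) <- ids
      expr_matrix(m)
    }
  }, error = function(e) {
    defects <<- c(defects, sprintf("count matrix unreadable: %s", conditionMessage(e)))
    NULL
  })
  if (!is.null(chem) && !is.null(expr)) {
    cs <- sample_ids(chem); es <- colnames(expr)
    only_chem <- setdiff(cs, es); only_expr <- setdiff(es, cs)
    for (s in only_chem) defects <- c(defects, sprintf("unmatched sample '%s' (chemical table only)", s))
    for (s in only_expr) defects <- c(defects, sprintf("unmatched sample '%s' (count matrix only)", s))
    shared <- intersect(cs, es)
    if (length(shared) && !identical(cs[cs %in% shared], es[es %in% shared])) {
      notes <- c(notes, "sample order differs between blocks; reordering applied downstream")
    }
  }
  if (!is.null(gmt_path)) {
    tryCatch(read_gmt(gmt_path), error = function(e) {
      defects <<- c(defects, sprintf("GMT malformed: %s", conditionMessage(e)))
    })
  }
  list(ok = length(defects) == 0, defects = defects, notes = notes)
}

#' Run the full linking pipeline
#'
#' Executes, in order: chemical preprocessing (filter, kNN imputation,
#' standardization), expression preprocessing (count filter, normalization),
#' consensus coexpression network and module detection, SGCCA, module
#' enrichment, pathway overrepresentation (if a GMT is supplied), and the
#' per-component link report. Every stage's artifacts are persisted under
#' `config$output_dir`; a manifest records dimensions, warnings and file
#' checksums, so an identical configuration yields identical checksums.
#'
#' @param config A [pipeline_config()].
#' @return A `run_manifest`: list with `config`, `stages` (per-stage
#'   dimensions), `checksums` (md5 per artifact), `warnings`, plus the
#'   in-memory `results` (network, partition, fit, enrichment, pathways,
#'   report).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list(); warns <- character(0)
  log_stage <- function(name, ...) {
    message(sprintf("[chemolink] %s: %s", name, sprintf(...)))
  }
  with_stage <- function(name, expr) {
    tryCatch(withCallingHandlers(expr, warning = function(w) {
      warns <<- c(warns, sprintf("%s: %s", name, conditionMessage(w)))
      invokeRestart("muffleWarning")
    }), error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # inputs
  if (!is.null(config$synth)) {
    ds <- with_stage("simulate", generate_dataset(config$synth))
    chem <- ds$chem; expr <- ds$expr
    with_stage("simulate", write_fixture(ds, file.path(config$output_dir, "synthetic")))
  } else {
    chem <- with_stage("read", read_chem_table(config$chem_path))
    expr <- with_stage("read", read_expr_matrix(config$counts_path))
  }
  annotation <- if (!is.null(config$gmt_path)) {
    with_stage("read", read_gmt(config$gmt_path))
  } else NULL

  # harmonize samples across blocks (drop unshared with a warning)
  shared <- intersect(sample_ids(chem), colnames(expr))
  if (length(shared) < max(nrow(chem), ncol(expr))) {
    warns <- c(warns, sprintf("dropped %d sample(s) present in only one block",
                              max(nrow(chem), ncol(expr)) - length(shared)))
  }
  if (length(shared) < 4) stop("pipeline failed at stage 'harmonize': fewer than 4 shared samples")
  chem <- as_chem_table(unclass_matrix(chem)[shared, , drop = FALSE], chem)
  keep_expr <- unclass_matrix(expr)[, shared, drop = FALSE]
  expr <- expr_matrix(keep_expr, gene_covariate = unname(attr(expr, "gene_covariate")),
                      normalized = is_normalized(expr))

  # chemical block
  filt <- with_stage("chem_preprocess", filter_chemicals(chem, config$max_missing_frac))
  log_stage("chem_preprocess", "%d/%d chemicals retained",
            filt$report$n_retained, filt$report$n_input)
  chem_imp <- with_stage("chem_preprocess", knn_impute(filt$table, k = config$knn_k))
  chem_std <- with_stage("chem_preprocess", standardize_chemicals(chem_imp))
  write_chem_table(chem_std, file.path(config$output_dir, "chemicals_processed.tsv"))

  # gene block
  gf <- with_stage("expr_preprocess", filter_genes(expr))
  log_stage("expr_preprocess", "%d/%d genes retained",
            gf$report$n_retained, gf$report$n_input)
  norm <- with_stage("expr_preprocess",
                     normalize_expression(gf$expr, method = config$normalization))
  write_expr_matrix(norm, file.path(config$output_dir, "expression_normalized.tsv"))

  # network + modules
  network <- with_stage("coexpression", build_consensus_network(norm, config$ensemble))
  partition <- with_stage("coexpression",
                          detect_modules(network, min_module_size = config$min_module_size,
                                         seed = config$stage_seed(2)))
  log_stage("coexpression", "%d consensus edges, %d modules",
            sum(network$edges$in_consensus), length(partition$sizes))
  write_network(network, partition, config$output_dir)

  # multiblock correlation
  blocks <- list(chemicals = unclass_matrix(chem_std),
                 genes = t(unclass_matrix(norm)))
  fit <- with_stage("sgcca", fit_sgcca(blocks, config$sgcca))
  log_stage("sgcca", "%d component(s), correlations %s", fit$n_components,
            paste(sprintf("%.2f", fit$component_correlation), collapse = ", "))
  write_sgcca_fit(fit, file.path(config$output_dir, "sgcca"))

  # enrichment
  enr <- with_stage("enrichment",
                    module_enrichment(fit$squared_weights$genes, partition,
                                      alpha = config$alpha))
  write_tsv(enr, file.path(config$output_dir, "module_enrichment.tsv"))

  pw_tab <- NULL
  if (!is.null(annotation)) {
    universe <- rownames(norm)
    sig <- unique(enr[enr$significant, c("module", "component")])
    pw_rows <- list()
    for (i in seq_len(nrow(sig))) {
      m <- sig$module[i]; comp <- sig$component[i]
      genes_m <- names(partition$assignment)[!is.na(partition$assignment) &
                                               partition$assignment == m]
      pt <- with_stage("enrichment",
                       pathway_overrepresentation(genes_m, universe, annotation,
                                                  alpha = config$alpha))
      if (nrow(pt)) {
        pt$module <- m; pt$component <- comp
        pw_rows[[length(pw_rows) + 1]] <- pt
      }
    }
    pw_tab <- if (length(pw_rows)) do.call(rbind, pw_rows) else NULL
    if (!is.null(pw_tab)) {
      class(pw_tab) <- c("pathway_table", "data.frame")
      write_tsv(pw_tab, file.path(config$output_dir, "pathway_overrepresentation.tsv"))
    }
  }

  report <- with_stage("report",
                       link_report(fit, enr, pathways = pw_tab,
                                   sw_cutoff = config$sw_cutoff))
  write_link_report(report, config$output_dir)

  stages$chem_preprocess <- c(n_input = filt$report$n_input,
                              n_retained = filt$report$n_retained)
  stages$expr_preprocess <- c(n_input = gf$report$n_input,
                              n_retained = gf$report$n_retained)
  stages$coexpression <- c(n_consensus_edges = sum(network$edges$in_consensus),
                           n_modules = length(partition$sizes))
  stages$sgcca <- c(n_components = fit$n_components)

  files <- list.files(config$output_dir, recursive = TRUE, full.names = TRUE)
  checksums <- tools::md5sum(files)
  names(checksums) <- substring(files, nchar(config$output_dir) + 2)

  structure(list(config = config,
                 version = as.character(utils::packageVersion("chemolink")),
                 stages = stages, checksums = checksums, warnings = warns,
                 results = list(network = network, partition = partition,
                                fit = fit, enrichment = enr,
                                pathways = pw_tab, report = report)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("chemolink run manifest\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %s: %s\n", s,
                paste(sprintf("%s=%s", names(x$stages[[s]]), x$stages[[s]]),
                      collapse = ", ")))
  }
  if (length(x$warnings)) cat(sprintf("  warnings: %d\n", length(x$warnings)))
  invisible(x)
}
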