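#' @title Pipeline orchestration
#' @description A seeded, configured end-to-end run: simulate (or load)
#'   transcript counts, summarise to genes, normalise and filter,
#'   estimate surrogates, fit the factorial NB model, shrink LFCs, call
#'   and tabulate interactions, compute exclusive DE-set intersections,
#'   cluster interaction-gene profiles, and (when annotations are given)
#'   run elim enrichment.  Every intermediate artifact is written as TSV
#'   and a manifest records the configuration actually applied.
#' @name pipeline
NULL

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a transcript count table written by the pipeline
#'
#' @param path TSV with columns transcript_id, gene_id, effective_length,
#'   then one numeric column per sample.
#' @return data.frame in the [simulate_counts()] layout.
#' @export
read_transcript_counts <- function(path) {
  tx <- read_tsv(path)
  need <- c("transcript_id", "gene_id", "effective_length")
  if (!all(need %in% names(tx)))
    stop("malformed transcript table: ", path)
  class(tx) <- c("facstress_tx", "data.frame")
  tx
}

#' Read a sample design table
#'
#' @param path TSV with sample_id, one column per factor, and optionally
#'   replicate and batch columns.
#' @param factors Factor column names.
#' @param levels Two level names, reference first.
#' @return Design data.frame as from [make_design()].
#' @export
read_design <- function(path, factors = c("Salinity", "Sediment", "Flow"),
                        levels = c("ambient", "treated")) {
  d <- read_tsv(path)
  if (!all(c("sample_id", factors) %in% names(d)))
    stop("malformed design table: ", path)
  for (f in factors) d[[f]] <- factor(d[[f]], levels = levels)
  d
}

#' Pipeline run configuration
#'
#' Collects thresholds and simulation parameters with validation.  The
#' defaults match the analysis conventions: FDR 0.1, independent filter
#' of 10 normalised counts in 8 samples, minimum profile-cluster size 10.
#'
#' @param n_genes Genes to simulate (ignored when \code{counts_path} set).
#' @param counts_path,design_path Optional paths to existing TSV inputs
#'   instead of simulation.
#' @param annotation_path,edges_path Optional gene-term annotation and
#'   child-parent term edge TSVs enabling the enrichment stage.
#' @param fdr,min_count,min_samples,min_cluster,alpha_elim Thresholds.
#' @param sv_alpha,sv_nperm Surrogate permutation-test parameters.
#' @param effects [effect_config()] list for the simulator.
#' @param stages Character vector of stages to run, in pipeline order.
#' @return Validated list of class \code{facstress_config}.
#' @export
run_config <- function(n_genes = 2000L,
                       counts_path = NULL, design_path = NULL,
                       annotation_path = NULL, edges_path = NULL,
                       fdr = 0.1, min_count = 10, min_samples = 8L,
                       min_cluster = 10L, alpha_elim = 0.01,
                       sv_alpha = 0.05, sv_nperm = 100L,
                       effects = effect_config(),
                       stages = c("simulate", "preprocess", "covariates",
                                  "fit", "interactions", "profiles",
                                  "enrichment")) {
  cfg <- list(n_genes = as.integer(n_genes), counts_path = counts_path,
              design_path = design_path, annotation_path = annotation_path,
              edges_path = edges_path, fdr = fdr, min_count = min_count,
              min_samples = as.integer(min_samples),
              min_cluster = as.integer(min_cluster),
              alpha_elim = alpha_elim, sv_alpha = sv_alpha,
              sv_nperm = as.integer(sv_nperm), effects = effects,
              stages = stages)
  if (cfg$fdr <= 0 || cfg$fdr >= 1) stop("'fdr' must lie in (0, 1)")
  if (cfg$min_count < 0) stop("'min_count' must be non-negative")
  if (cfg$min_samples < 1) stop("'min_samples' must be positive")
  if (cfg$min_cluster < 2) stop("'min_cluster' must be at least 2")
  if (cfg$alpha_elim < 0 || cfg$alpha_elim > 1)
    stop("'alpha_elim' must lie in [0, 1]")
  structure(cfg, class = "facstress_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are [run_config()] arguments
#' (thresholds, paths, simulation sizes; an \code{effects} sub-mapping is
#' passed to [effect_config()]) and validates it.
#'
#' @param path Path to a YAML file.
#' @return Validated \code{facstress_config} list.
#' @export
load_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read configuration files")
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effects))
    raw$effects <- do.call(effect_config, raw$effects)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Executes the configured stages in order.  With an output directory,
#' every intermediate table is written as TSV together with a
#' \code{manifest.json} capturing the configuration, seed and per-stage
#' row counts; a failed stage leaves partial outputs plus a
#' \code{FAILED} marker naming the stage.
#'
#' @param config From [run_config()].
#' @param out_dir Output directory (created), or NULL for in-memory only.
#' @param seed Integer seed covering all stochastic stages.
#' @return List with the stage results: \code{design}, \code{truth},
#'   \code{tx}, \code{genes} (filtered), \code{sf}, \code{sv},
#'   \code{fit}, \code{shrunken}, \code{calls}, \code{interaction_table},
#'   \code{intersections}, \code{clusters}, \code{enrichment},
#'   \code{manifest}.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, seed) {
  if (missing(seed)) stop("'seed' is required")
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  res <- list()
  counts <- stats::setNames(vector("list", 0L), character(0))
  stage <- "validate"
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_tsv(df, file.path(out_dir, name))
  }
  tryCatch({
    stage <- "simulate"
    if (!is.null(config$counts_path)) {
      res$tx <- read_transcript_counts(config$counts_path)
      res$design <- read_design(config$design_path)
      res$truth <- NULL
    } else if ("simulate" %in% config$stages) {
      res$design <- make_design()
      res$truth <- sample_truth(config$n_genes, config$effects, seed = seed)
      res$tx <- simulate_counts(res$truth, res$design, seed = seed + 1L)
      emit(res$truth, "truth.tsv")
      emit(res$tx, "transcript_counts.tsv")
      emit(res$design, "design.tsv")
    }
    if (config$min_samples > nrow(res$design))
      stop("'min_samples' exceeds the number of samples")
    counts$n_transcripts <- nrow(res$tx)

    stage <- "preprocess"
    gc_all <- summarise_to_gene(res$tx)
    res$sf <- size_factors(gc_all)
    res$genes <- filter_genes(gc_all, res$sf,
                              min_count = config$min_count,
                              min_samples = config$min_samples)
    counts$n_genes_total <- nrow(gc_all$counts)
    counts$n_genes_tested <- nrow(res$genes$counts)
    emit(data.frame(gene_id = res$genes$gene_id), "genes_tested.tsv")
    emit(data.frame(sample_id = names(res$sf), size_factor = res$sf),
         "size_factors.tsv")

    stage <- "covariates"
    v <- vst(res$genes, res$sf)
    if ("covariates" %in% config$stages) {
      res$sv <- estimate_surrogates(v, res$design, n_perm = config$sv_nperm,
                                    alpha = config$sv_alpha, seed = seed + 2L)
    } else {
      res$sv <- NULL
    }
    counts$n_surrogates <- if (is.null(res$sv)) 0L else res$sv$k
    if (!is.null(res$sv) && res$sv$k > 0L)
      emit(data.frame(sample_id = res$design$sample_id, res$sv$sv),
           "surrogates.tsv")

    stage <- "fit"
    if ("fit" %in% config$stages) {
      mm <- build_model_matrix(res$design, res$sv)
      res$fit <- fit_factorial_nb(res$genes, mm, res$sf)
      res$shrunken <- shrink_fit(res$fit)
      counts$n_converged <- sum(res$fit$converged)
      emit(fit_table(res$fit, res$shrunken), "fit_results.tsv")
    }

    stage <- "interactions"
    if (!is.null(res$fit) && "interactions" %in% config$stages) {
      res$calls <- call_interactions(res$fit, fdr = config$fdr,
                                     lfc = res$shrunken)
      res$interaction_table <- tabulate_interactions(res$calls)
      de_sets <- de_gene_sets(res$fit, fdr = config$fdr)
      res$intersections <- exclusive_intersections(de_sets)
      counts$n_interaction_calls <- nrow(res$calls)
      emit(res$calls, "interaction_calls.tsv")
      emit(as.data.frame(res$interaction_table), "interaction_table.tsv")
      emit(res$intersections[, c("signature", "count")], "intersections.tsv")
    }

    stage <- "profiles"
    int_genes <- unique(res$calls$gene_id)
    if (length(int_genes) >= 2L && "profiles" %in% config$stages) {
      corrected <- freeze_correct(v, res$design, res$sv)
      z <- zscore_profiles(corrected, int_genes)
      res$clusters <- cluster_profiles(z, res$design,
                                       min_size = config$min_cluster,
                                       seed = seed + 3L)
      counts$n_clusters <- res$clusters$k
      emit(data.frame(gene_id = names(res$clusters$membership),
                      cluster = res$clusters$membership), "clusters.tsv")
    }

    stage <- "enrichment"
    if (!is.null(config$annotation_path) && !is.null(res$fit) &&
        "enrichment" %in% config$stages) {
      dag <- ontology_dag(read_tsv(config$edges_path),
                          read_tsv(config$annotation_path))
      dag <- propagate_annotations(dag)
      universe <- res$genes$gene_id
      de_sets <- de_gene_sets(res$fit, fdr = config$fdr)
      res$enrichment <- lapply(de_sets, function(s)
        elim_enrichment(dag, intersect(s, universe), universe,
                        alpha_elim = config$alpha_elim))
      if (!is.null(out_dir))
        for (nm in names(res$enrichment))
          emit(res$enrichment[[nm]], paste0("enrichment_", gsub("[^A-Za-z0-9_]",
               "_", nm), ".tsv"))
    }

    stage <- "manifest"
    res$manifest <- list(
      package_version = as.character(utils::packageVersion("facstress")),
      seed = seed,
      thresholds = config[c("fdr", "min_count", "min_samples",
                            "min_cluster", "alpha_elim", "sv_alpha",
                            "sv_nperm")],
      stages = config$stages,
      counts = counts)
    if (!is.null(out_dir))
      jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res
  }, error = function(e) {
    if (!is.null(out_dir))
      writeLines(c(stage, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# Up/down DE gene sets per non-surrogate, non-intercept term.
de_gene_sets <- function(fit, fdr = 0.1) {
  terms <- setdiff(colnames(fit$padj),
                   grep("^SV[0-9]+$", colnames(fit$padj), value = TRUE))
  sets <- list()
  for (tm in terms) {
    sig <- !is.na(fit$padj[, tm]) & fit$padj[, tm] < fdr
    sets[[paste0(tm, "_up")]] <- rownames(fit$beta)[sig & fit$beta[, tm] > 0]
    sets[[paste0(tm, "_down")]] <- rownames(fit$beta)[sig & fit$beta[, tm] < 0]
  }
  sets
}

# Long-format per-gene, per-term results table.
fit_table <- function(fit, shrunken = NULL) {
  terms <- setdiff(colnames(fit$beta), "Intercept")
  rows <- lapply(terms, function(tm) {
    data.frame(gene_id = rownames(fit$beta), term = tm,
               beta = fit$beta[, tm], se = fit$se[, tm],
               z = fit$z[, tm], p = fit$p[, tm],
               padj = if (tm %in% colnames(fit$padj)) fit$padj[, tm] else NA,
               shrunken_lfc = if (!is.null(shrunken) &&
                                  tm %in% colnames(shrunken))
                 shrunken[, tm] else NA,
               converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a pipeline run
#'
#' Produces the condensed report: per-treatment up/down differential
#' expression counts, the interaction class table, the exclusive
#' intersection partition, the cluster summary, and top enriched terms.
#'
#' @param bundle Result list from [run_pipeline()].
#' @param top_n Number of top enrichment terms per study set (default 5).
#' @return List (valid for [jsonlite::toJSON]) with components
#'   \code{de_counts}, \code{interaction_table}, \code{intersections},
#'   \code{clusters}, \code{enrichment_top}.
#' @export
summarise_run <- function(bundle, top_n = 5L) {
  rep_ <- list()
  if (!is.null(bundle$fit)) {
    sets <- de_gene_sets(bundle$fit)
    rep_$de_counts <- lapply(sets, length)
  } else rep_$de_counts <- "stage skipped"
  rep_$interaction_table <- if (!is.null(bundle$interaction_table))
    as.data.frame(bundle$interaction_table) else "stage skipped"
  rep_$intersections <- if (!is.null(bundle$intersections))
    bundle$intersections[, c("signature", "count")] else "stage skipped"
  rep_$clusters <- if (!is.null(bundle$clusters))
    list(k = bundle$clusters$k,
         sizes = lengths(bundle$clusters$clusters),
         unassigned = length(bundle$clusters$unassigned))
  else "stage skipped"
  rep_$enrichment_top <- if (!is.null(bundle$enrichment))
    lapply(bundle$enrichment, function(e)
      utils::head(e[, c("term", "k", "K", "p_fisher", "p_elim")], top_n))
  else "stage skipped"
  rep_
}
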