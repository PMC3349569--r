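#' Run the full core-module discovery workflow
#'
#' End-to-end orchestration: per-gene statistics, pathway filtering to
#' the shared gene universe, activity inference, pairwise
#' inference/validation marker selection over every ordered cohort pair,
#' core-module assembly, optional reference-list enrichment of the core
#' genes, and optional network exploration (induced subnetwork, hubs,
#' drivers). When `out_dir` is given, every intermediate table is
#' written as TSV together with a machine-readable JSON run manifest.
#'
#' @param cohorts Named list of [expression_dataset()]s (at least two).
#' @param pc A [pathway_collection()] (filtered internally).
#' @param method Activity-inference method id (default "CMI").
#' @param alpha DEG significance level.
#' @param max_k Member cap for selective inference.
#' @param filter_min,filter_max Pathway-size bounds after intersection
#'   with the shared gene universe.
#' @param top_n Activities carried into each pairwise validation.
#' @param classifier "LDA" or "SVM".
#' @param n_repeats,n_splits,n_folds Consensus-elimination ensemble
#'   sizes.
#' @param enrichment_refs Optional named list of reference gene vectors
#'   (or file paths) for core-gene enrichment.
#' @param network Optional [interaction_network()] for hub/driver
#'   analysis.
#' @param n_hubs Hub count for driver extraction.
#' @param out_dir Optional output directory.
#' @param seed Master seed; every stochastic stage derives its seed from
#'   it, so reruns are bit-identical.
#' @return List: `core` (the `CoreModule`), `pair_results`,
#'   `filter_report`, `enrichment` (or NULL), `network_report` (or
#'   NULL), `manifest`.
#' @export
run_study <- function(cohorts, pc, method = "CMI", alpha = 0.05,
                      max_k = 20, filter_min = 5, filter_max = 200,
                      top_n = 100, classifier = c("LDA", "SVM"),
                      n_repeats = 100, n_splits = 100, n_folds = 5,
                      enrichment_refs = NULL, network = NULL,
                      n_hubs = 20, out_dir = NULL, seed = 1) {
  classifier <- match.arg(classifier)
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  cohorts <- lapply(cohorts, function(d)
    if (is_normalized(d)) d else zscore_normalize(d))
  shared <- Reduce(intersect, lapply(cohorts, `[[`, "gene_ids"))
  pc_f <- filter_pathways(pc, shared, min_size = filter_min,
                          max_size = filter_max)
  pair_results <- run_all_pairs(
    cohorts, pc_f, method = method, top_n = top_n,
    classifier = classifier, alpha = alpha, max_k = max_k,
    n_repeats = n_repeats, n_splits = n_splits, n_folds = n_folds,
    seed = seed)
  core <- assemble_core_module(pair_results, cohorts, alpha = alpha)

  enrich <- NULL
  if (!is.null(enrichment_refs) && nrow(core$core_genes) > 0) {
    universe <- intersect(shared, pc_f$universe)
    enrich <- enrichment_table(core$core_genes$gene, enrichment_refs,
                               universe)
  }
  net_report <- NULL
  if (!is.null(network) && nrow(core$core_genes) > 0) {
    sub <- induced_subnetwork(network, core$core_genes$gene)
    if (igraph::vcount(sub$graph) > 0) {
      hubs <- hub_genes(sub, n_hubs = n_hubs)
      drivers <- driver_genes(hubs, core$core_genes$gene)
      reg <- stats::setNames(core$core_genes$regulation,
                             core$core_genes$gene)
      hubs$regulation <- reg[hubs$gene]
      hubs$is_driver <- hubs$gene %in% drivers
      net_report <- list(subnetwork = sub, hubs = hubs,
                         drivers = drivers)
    }
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("coremod")),
    cohorts = lapply(cohorts, function(d)
      list(genes = length(d$gene_ids), samples = length(d$sample_ids),
           cases = sum(d$labels == 1))),
    parameters = list(method = method, alpha = alpha, max_k = max_k,
                      filter_min = filter_min, filter_max = filter_max,
                      top_n = top_n, classifier = classifier,
                      n_repeats = n_repeats, n_splits = n_splits,
                      n_folds = n_folds, n_hubs = n_hubs, seed = seed),
    n_pathways_after_filter = length(pc_f$pathways),
    n_core_markers = nrow(core$marker_pathways),
    n_core_genes = nrow(core$core_genes))
  out <- list(core = core, pair_results = pair_results,
              filter_report = attr(pc_f, "filter_report"),
              enrichment = enrich, network_report = net_report,
              manifest = manifest)
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(run$filter_report, "pathway_filter_report.tsv")
  sel <- do.call(rbind, lapply(names(run$pair_results), function(k) {
    r <- run$pair_results[[k]]
    data.frame(inference = r$inference, validation = r$validation,
               max_mean_auc = r$max_mean_auc,
               selected = paste(r$selected, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  wt(sel, "pairwise_selection.tsv")
  wt(run$core$marker_pathways, "core_markers.tsv")
  wt(run$core$core_genes, "core_genes.tsv")
  if (!is.null(run$enrichment)) wt(run$enrichment, "enrichment.tsv")
  if (!is.null(run$network_report))
    wt(run$network_report$hubs, "hub_genes.tsv")
  jsonlite::write_json(run$manifest,
                       file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
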