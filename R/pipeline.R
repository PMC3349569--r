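#' Pairwise inference/validation marker selection
#'
#' The unit step of the multi-level validation framework: infer activity
#' models for every pathway on the inference cohort, keep the `top_n`
#' best-ranked models, project their activities onto the validation
#' cohort, and run repeated consensus feature elimination against the
#' validation labels. The pathways surviving that selection are the
#' markers this (inference, validation) pair supports.
#'
#' @param inference,validation [expression_dataset()]s sharing the
#'   filtered gene universe (normalized internally if needed).
#' @param pc Filtered [pathway_collection()].
#' @param method Activity-inference method id.
#' @param top_n Activities retained by descending inference t-score
#'   (default 100; fewer are used, with a warning, when fewer models are
#'   inferable).
#' @param classifier "LDA" (default) or "SVM".
#' @param alpha DEG significance level.
#' @param max_k Member-count cap for selective methods.
#' @param n_repeats,n_splits,n_folds Consensus-elimination ensemble sizes
#'   (see [select_final_markers()]).
#' @param seed Integer seed.
#' @return List: `selected` (pathway ids), `max_mean_auc`, `models`
#'   (the top-ranked models), `selection` (full
#'   [select_final_markers()] output).
#' @export
run_pairwise_validation <- function(inference, validation, pc,
                                    method = "CMI", top_n = 100,
                                    classifier = c("LDA", "SVM"),
                                    alpha = 0.05, max_k = 20,
                                    n_repeats = 100, n_splits = 100,
                                    n_folds = 5, seed = 1) {
  classifier <- match.arg(classifier)
  if (!is_normalized(inference)) inference <- zscore_normalize(inference)
  if (!is_normalized(validation)) validation <- zscore_normalize(validation)
  st <- gene_stats(inference, alpha = alpha)
  models <- rank_models(infer_models(inference, st, pc,
                                     method = method, max_k = max_k))
  if (!length(models)) stop("no inferable activity model")
  if (length(models) < top_n) {
    warning("only ", length(models), " inferable models; top_n reduced")
    top_n <- length(models)
  }
  models <- models[seq_len(top_n)]
  am <- activity_matrix(models, validation)
  sel <- select_final_markers(am, classifier = classifier,
                              n_repeats = n_repeats, n_splits = n_splits,
                              n_folds = n_folds, seed = seed)
  list(selected = sel$selected_features,
       max_mean_auc = sel$max_mean_auc,
       models = models, selection = sel)
}

#' Run every ordered inference/validation cohort pair
#'
#' @param cohorts Named list of at least two [expression_dataset()]s.
#' @param pc Filtered [pathway_collection()].
#' @param ... Passed to [run_pairwise_validation()].
#' @param seed Master seed; each ordered pair gets a derived seed.
#' @return Named list (keys "inf->val") of pairwise results.
#' @export
run_all_pairs <- function(cohorts, pc, ..., seed = 1) {
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  pairs <- expand.grid(inference = names(cohorts),
                       validation = names(cohorts),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$inference != pairs$validation, ]
  pairs <- pairs[order(pairs$inference, pairs$validation), ]
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nrow(pairs))
  out <- vector("list", nrow(pairs))
  names(out) <- paste0(pairs$inference, "->", pairs$validation)
  for (i in seq_len(nrow(pairs))) {
    out[[i]] <- run_pairwise_validation(
      cohorts[[pairs$inference[i]]], cohorts[[pairs$validation[i]]],
      pc, ..., seed = seeds[i])
    out[[i]]$inference <- pairs$inference[i]
    out[[i]]$validation <- pairs$validation[i]
  }
  out
}

#' Assemble the core module from pairwise validation results
#'
#' A pathway inferred from cohort D becomes a core marker only when it is
#' selected in the pairwise validation against *every* other cohort —
#' the strictest reading of "consistently reproducible". Core markers
#' are pooled over all inference cohorts; the core genes are the union
#' of member genes of core-marker models, annotated with the sign of
#' each gene's t-score in every cohort.
#'
#' @param pair_results Output of [run_all_pairs()].
#' @param cohorts The named cohort list the pairs were run on.
#' @param alpha DEG significance level used for the per-cohort gene sign
#'   annotation.
#' @return An object of class `CoreModule`: `marker_pathways`
#'   (data.frame pathway_id x inference cohort, with validation cohorts
#'   and max mean AUC), `models` (the selected models, keyed
#'   "pathway@cohort"), `core_genes` (data.frame gene, regulation,
#'   per-cohort t-score sign), `provenance`.
#' @export
assemble_core_module <- function(pair_results, cohorts, alpha = 0.05) {
  infs <- unique(vapply(pair_results, `[[`, character(1), "inference"))
  markers <- list(); models <- list(); prov <- list()
  for (D in sort(infs)) {
    res_D <- pair_results[vapply(pair_results, function(r)
      r$inference == D, logical(1))]
    sel_sets <- lapply(res_D, `[[`, "selected")
    core_D <- Reduce(intersect, sel_sets)
    for (p in sort(core_D)) {
      mod <- res_D[[1]]$models[[which(vapply(res_D[[1]]$models, `[[`,
        character(1), "pathway_id") == p)]]
      key <- paste0(p, "@", D)
      models[[key]] <- mod
      markers[[key]] <- data.frame(
        pathway_id = p, inference_cohort = D,
        validation_cohorts = paste(sort(vapply(res_D, `[[`, character(1),
                                               "validation")),
                                   collapse = ","),
        max_mean_auc = mean(vapply(res_D, `[[`, numeric(1),
                                   "max_mean_auc")),
        stringsAsFactors = FALSE)
      prov[[key]] <- vapply(res_D, `[[`, character(1), "validation")
    }
  }
  marker_df <- if (length(markers)) do.call(rbind, c(markers,
                 list(make.row.names = FALSE)))
               else data.frame(pathway_id = character(),
                               inference_cohort = character(),
                               validation_cohorts = character(),
                               max_mean_auc = numeric())
  genes <- sort(unique(unlist(lapply(models, `[[`, "member_genes"))))
  if (!length(marker_df$pathway_id))
    warning("empty core module")
  normd <- lapply(cohorts, function(d)
    if (is_normalized(d)) d else zscore_normalize(d))
  stats_by <- lapply(normd, gene_stats, alpha = alpha)
  gene_df <- NULL
  if (length(genes)) {
    signs <- sapply(stats_by, function(st)
      ifelse(genes %in% rownames(st),
             sign(st[genes, "tscore"]), NA_real_))  # genes x cohorts
    if (is.null(dim(signs))) signs <- matrix(signs, nrow = length(genes))
    reg <- apply(signs, 1, function(s) {
      if (anyNA(s)) NA_character_
      else if (all(s > 0)) "up"
      else if (all(s < 0)) "down"
      else "contradictory"
    })
    gene_df <- data.frame(gene = genes, regulation = reg,
                          stringsAsFactors = FALSE)
    for (j in seq_along(cohorts))
      gene_df[[paste0("sign_", names(cohorts)[j])]] <- signs[, j]
    pw_of <- vapply(genes, function(g) paste(sort(unique(vapply(
      models[vapply(models, function(m) g %in% m$member_genes,
                    logical(1))], `[[`, character(1), "pathway_id"))),
      collapse = ","), character(1))
    gene_df$pathways <- pw_of
  } else {
    gene_df <- data.frame(gene = character(), regulation = character(),
                          pathways = character())
  }
  structure(list(marker_pathways = marker_df, models = models,
                 core_genes = gene_df, provenance = prov),
            class = "CoreModule")
}

#' @export
print.CoreModule <- function(x, ...) {
  cat(sprintf("CoreModule: %d marker pathway/cohort entries, %d core genes\n",
              nrow(x$marker_pathways), nrow(x$core_genes)))
  invisible(x)
}

#' Genes shared by two core modules
#'
#' Intersection of the core gene sets of two modules built on the same
#' gene universe (for example, modules derived with two different
#' activity-inference methods).
#'
#' @param core_a,core_b `CoreModule` objects.
#' @return Character vector of common marker genes.
#' @export
common_markers <- function(core_a, core_b) {
  stopifnot(inherits(core_a, "CoreModule"), inherits(core_b, "CoreModule"))
  sort(intersect(core_a$core_genes$gene, core_b$core_genes$gene))
}
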