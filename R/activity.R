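#' @name activity-models
#' @title Pathway activity models
#' @description
#' A pathway activity (PA) is a per-sample scalar summarizing the
#' expression of selected genes of one pathway, used downstream as a
#' classification feature. A `PathwayActivityModel` freezes everything
#' needed to evaluate that activity on any cohort: the ordered member
#' genes, their signs, the inference method, method-specific parameters,
#' and the discriminative t-score the activity achieved on the inference
#' cohort.
NULL

new_activity_model <- function(pathway_id, method, member_genes, signs,
                               inference_tscore, divisor = "j",
                               pca_loadings = NULL, llr_params = NULL) {
  structure(
    list(pathway_id = pathway_id, method = method,
         member_genes = unname(member_genes), signs = unname(signs),
         K = length(member_genes), divisor = divisor,
         pca_loadings = pca_loadings, llr_params = llr_params,
         inference_tscore = unname(inference_tscore)),
    class = "PathwayActivityModel")
}

#' @export
print.PathwayActivityModel <- function(x, ...) {
  cat(sprintf("PathwayActivityModel %s [%s]: K=%d, inference t=%.3f\n",
              x$pathway_id, x$method, x$K, x$inference_tscore))
  invisible(x)
}

# genes of `pathway` present in ds, with their stats rows
match_pathway <- function(ds, stats, pathway_genes) {
  g <- intersect(pathway_genes, ds$gene_ids)
  stats[intersect(g, stats$gene_id), , drop = FALSE]
}

#' Core-module inference of a pathway activity
#'
#' Ranks the pathway's differentially expressed genes (DEGs) by descending
#' absolute t-score and searches all prefixes of that ranking: the prefix
#' activity for size j is the mean over the top-j DEGs of each gene's
#' z-score multiplied by the sign of its t-score, so up- and
#' down-regulated genes reinforce rather than cancel. The returned model
#' keeps the prefix size K whose activity vector has the largest
#' discriminative t-score on the inference cohort (ties resolved toward
#' the smallest K). Member count is capped at `max_k` DEGs (default 20).
#' A pathway with no DEG has activity identically zero and yields `NULL`.
#'
#' @param ds A z-normalized [expression_dataset()] (the inference cohort).
#' @param stats [gene_stats()] computed on `ds`.
#' @param pathway Character vector of the pathway's gene symbols.
#' @param max_k Largest admissible member count (default 20).
#' @param pathway_id Identifier stored in the model.
#' @param divisor Prefix normalizer: `"j"` (default, average) or
#'   `"sqrt_j"` (sum over the square root of the prefix size).
#' @return A `PathwayActivityModel`, or `NULL` when the pathway has no
#'   DEG in the dataset.
#' @export
infer_cmi <- function(ds, stats, pathway, max_k = 20,
                      pathway_id = "pathway", divisor = c("j", "sqrt_j")) {
  divisor <- match.arg(divisor)
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is_normalized(ds)) stop("dataset must be z-normalized")
  m <- match_pathway(ds, stats, pathway)
  if (nrow(m) == 0) {
    warning("no pathway gene present in dataset: ", pathway_id)
    return(NULL)
  }
  degs <- m[m$is_deg, , drop = FALSE]
  if (nrow(degs) == 0) return(NULL)
  degs <- degs[order(-abs(degs$tscore), degs$gene_id), , drop = FALSE]
  jmax <- min(nrow(degs), max_k)
  degs <- degs[seq_len(jmax), , drop = FALSE]
  signs <- sign(degs$tscore)
  signs[signs == 0] <- 1
  z <- ds$values[degs$gene_id, , drop = FALSE] * signs
  cum <- apply(z, 2, cumsum)
  if (jmax == 1) cum <- matrix(cum, nrow = 1)
  den <- if (divisor == "j") seq_len(jmax) else sqrt(seq_len(jmax))
  pa <- cum / den
  tj <- row_tstats(pa, ds$labels)$t
  K <- if (max(tj) > 0) which.max(tj) else which.max(abs(tj))
  new_activity_model(pathway_id, "CMI",
                     degs$gene_id[seq_len(K)], signs[seq_len(K)],
                     tj[K], divisor = divisor)
}

#' Condition-responsive-gene (CORG) activity inference
#'
#' The comparator scheme that grows the member set within the up-regulated
#' (t > 0) or down-regulated (t < 0) subset only. Within each subset,
#' genes are ranked by descending absolute t-score and added greedily
#' while the activity's t-score keeps improving (activity = sum of member
#' z-scores over sqrt(member count); the down subset is negated). The
#' subset whose best activity has the larger absolute t wins. Unlike
#' core-module inference it cannot mix up- and down-regulated genes and
#' uses all pathway genes, not only DEGs.
#'
#' @inheritParams infer_cmi
#' @return A `PathwayActivityModel` or `NULL` when no pathway gene with a
#'   nonzero t-score is present.
#' @export
infer_corg <- function(ds, stats, pathway, max_k = 20,
                       pathway_id = "pathway") {
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is_normalized(ds)) stop("dataset must be z-normalized")
  m <- match_pathway(ds, stats, pathway)
  if (nrow(m) == 0) return(NULL)

  grow <- function(sub, dir) {
    # dir +1: up subset; -1: down subset (activity negated)
    if (nrow(sub) == 0) return(NULL)
    sub <- sub[order(-abs(sub$tscore), sub$gene_id), , drop = FALSE]
    jmax <- min(nrow(sub), max_k)
    best_t <- -Inf; best_j <- 0
    z <- ds$values[sub$gene_id[seq_len(jmax)], , drop = FALSE]
    cum <- apply(z, 2, cumsum)
    if (jmax == 1) cum <- matrix(cum, nrow = 1)
    for (j in seq_len(jmax)) {
      tj <- two_sample_t(dir * cum[j, ] / sqrt(j), ds$labels)
      if (tj > best_t) { best_t <- tj; best_j <- j } else break
    }
    list(genes = sub$gene_id[seq_len(best_j)], t = best_t, dir = dir)
  }
  up <- grow(m[m$tscore > 0, , drop = FALSE], +1)
  down <- grow(m[m$tscore < 0, , drop = FALSE], -1)
  cand <- Filter(Negate(is.null), list(up, down))
  if (!length(cand)) return(NULL)
  win <- cand[[which.max(vapply(cand, function(s) abs(s$t), numeric(1)))]]
  new_activity_model(pathway_id, "CORG", win$genes,
                     rep(win$dir, length(win$genes)), win$t,
                     divisor = "sqrt_j")
}

#' Simple pathway-activity comparators
#'
#' Non-selective activity summaries over all pathway genes present in the
#' cohort: per-sample MEAN or MEDIAN of member z-scores; PCA, the first
#' principal-component score of the pathway's z-matrix (orientation fixed
#' so the inference t-score is non-negative, loadings stored for
#' projection); LLR, the summed per-gene Gaussian log-likelihood ratio of
#' case versus control class-conditional densities fitted on the
#' inference cohort (class variances floored at 1e-6); GENE, one model
#' per member gene whose activity is simply that gene's z-score row.
#'
#' @inheritParams infer_cmi
#' @param method One of "MEAN", "MEDIAN", "PCA", "LLR", "GENE".
#' @return A `PathwayActivityModel` (a list of them for "GENE"), or
#'   `NULL` when no pathway gene is present.
#' @export
infer_simple <- function(ds, stats, pathway,
                         method = c("MEAN", "MEDIAN", "PCA", "LLR", "GENE"),
                         pathway_id = "pathway") {
  method <- match.arg(method)
  stopifnot(inherits(ds, "ExpressionDataset"))
  if (!is_normalized(ds)) stop("dataset must be z-normalized")
  genes <- intersect(pathway, ds$gene_ids)
  if (!length(genes)) return(NULL)
  z <- ds$values[genes, , drop = FALSE]

  if (method == "GENE") {
    return(lapply(genes, function(g) {
      new_activity_model(g, "GENE", g, 1, two_sample_t(ds$values[g, ], ds$labels))
    }))
  }
  if (method %in% c("MEAN", "MEDIAN")) {
    act <- if (method == "MEAN") colMeans(z)
           else apply(z, 2, stats::median)
    return(new_activity_model(pathway_id, method, genes,
                              rep(1, length(genes)),
                              two_sample_t(act, ds$labels)))
  }
  if (method == "PCA") {
    if (length(genes) == 1) {
      load <- stats::setNames(1, genes)
    } else {
      # rows already centered by z-normalization; principal axis of the
      # gene covariance across samples
      sv <- svd(z, nu = length(genes), nv = 0)
      load <- stats::setNames(sv$u[, 1], genes)
    }
    act <- drop(crossprod(z, load))
    t1 <- two_sample_t(act, ds$labels)
    if (t1 < 0) { load <- -load; t1 <- -t1 }
    return(new_activity_model(pathway_id, "PCA", genes,
                              rep(1, length(genes)), t1,
                              pca_loadings = load))
  }
  # LLR
  case <- ds$labels == 1
  fit_class <- function(idx) {
    mu <- rowMeans(z[, idx, drop = FALSE])
    va <- apply(z[, idx, drop = FALSE], 1, stats::var)
    low <- va < 1e-6
    if (any(low)) {
      warning("LLR class variance floored for ", sum(low), " gene(s)")
      va[low] <- 1e-6
    }
    list(mu = mu, va = va)
  }
  pos <- fit_class(case); neg <- fit_class(!case)
  params <- list(mu_pos = pos$mu, var_pos = pos$va,
                 mu_neg = neg$mu, var_neg = neg$va)
  act <- llr_activity(z, params)
  new_activity_model(pathway_id, "LLR", genes, rep(1, length(genes)),
                     two_sample_t(act, ds$labels), llr_params = params)
}

llr_activity <- function(z, params) {
  g <- rownames(z)
  lp <- stats::dnorm(z, params$mu_pos[g], sqrt(params$var_pos[g]), log = TRUE)
  ln <- stats::dnorm(z, params$mu_neg[g], sqrt(params$var_neg[g]), log = TRUE)
  colSums(lp - ln)
}

#' Project a pathway-activity model onto a cohort
#'
#' Evaluates a frozen model on any z-normalized cohort using the model's
#' stored member genes, signs, normalizer and method parameters. Member
#' genes absent from the target are dropped with a warning and the
#' normalizer adjusted to the surviving member count.
#'
#' @param model A `PathwayActivityModel`.
#' @param ds_target A z-normalized [expression_dataset()].
#' @return Named numeric activity vector, one value per target sample.
#' @export
project_activity <- function(model, ds_target) {
  stopifnot(inherits(model, "PathwayActivityModel"),
            inherits(ds_target, "ExpressionDataset"))
  if (!is_normalized(ds_target)) stop("target dataset must be z-normalized")
  present <- model$member_genes %in% ds_target$gene_ids
  if (!any(present))
    stop("no member gene of model '", model$pathway_id,
         "' present in target cohort")
  if (!all(present))
    warning(sum(!present), " member gene(s) of '", model$pathway_id,
            "' missing from target; divisor adjusted")
  genes <- model$member_genes[present]
  signs <- model$signs[present]
  z <- ds_target$values[genes, , drop = FALSE]
  k <- length(genes)
  switch(model$method,
    CMI = {
      den <- if (model$divisor == "j") k else sqrt(k)
      drop(colSums(z * signs)) / den
    },
    CORG = drop(colSums(z * signs)) / sqrt(k),
    MEAN = colMeans(z),
    MEDIAN = apply(z, 2, stats::median),
    PCA = drop(crossprod(z, model$pca_loadings[genes])),
    LLR = llr_activity(z, model$llr_params),
    GENE = drop(z[1, ]) * signs[1],
    stop("unknown method: ", model$method))
}

#' Infer activity models for every pathway of a collection
#'
#' Applies one inference method to each pathway of `pc` on the inference
#' cohort and drops pathways that yield no model (for core-module
#' inference, pathways without any DEG). For the "GENE" method the
#' features are individual genes of the collection's universe and
#' pathways play no role.
#'
#' @inheritParams infer_cmi
#' @param pc A [pathway_collection()].
#' @param method Inference method id.
#' @return Named list of `PathwayActivityModel`s.
#' @export
infer_models <- function(ds, stats, pc,
                         method = c("CMI", "CORG", "MEAN", "MEDIAN",
                                    "PCA", "LLR", "GENE"),
                         max_k = 20) {
  method <- match.arg(method)
  stopifnot(inherits(pc, "PathwayCollection"))
  if (method == "GENE") {
    genes <- intersect(pc$universe, ds$gene_ids)
    models <- infer_simple(ds, stats, genes, method = "GENE")
    names(models) <- vapply(models, `[[`, character(1), "pathway_id")
    return(models)
  }
  models <- lapply(names(pc$pathways), function(id) {
    p <- pc$pathways[[id]]
    switch(method,
      CMI = infer_cmi(ds, stats, p, max_k = max_k, pathway_id = id),
      CORG = infer_corg(ds, stats, p, max_k = max_k, pathway_id = id),
      infer_simple(ds, stats, p, method = method, pathway_id = id))
  })
  names(models) <- names(pc$pathways)
  Filter(Negate(is.null), models)
}

#' Rank activity models by discriminative t-score
#'
#' Sign-aligned constructions (CMI, CORG) are ranked by descending signed
#' inference t-score; methods whose activities can legitimately point
#' either way (MEAN, MEDIAN, PCA, LLR, GENE) are ranked by descending
#' absolute t-score, the sign being carried by the t-scores themselves in
#' any downstream product.
#'
#' @param models List of `PathwayActivityModel`s of one method.
#' @return The list, ranked.
#' @export
rank_models <- function(models) {
  if (!length(models)) return(models)
  t <- vapply(models, `[[`, numeric(1), "inference_tscore")
  method <- models[[1]]$method
  key <- if (method %in% c("CMI", "CORG")) -t else -abs(t)
  models[order(key, vapply(models, `[[`, character(1), "pathway_id"))]
}

#' Build an activity matrix by projecting models onto a cohort
#'
#' @param models List of `PathwayActivityModel`s.
#' @param ds A z-normalized [expression_dataset()].
#' @return Features-by-samples numeric matrix of class `ActivityMatrix`
#'   with the cohort labels in attribute `"labels"` and the models in
#'   attribute `"models"`. Unprojectable models are dropped with a
#'   warning.
#' @export
activity_matrix <- function(models, ds) {
  rows <- lapply(models, function(m) {
    tryCatch(project_activity(m, ds), error = function(e) NULL)
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!all(keep))
    warning(sum(!keep), " model(s) unprojectable onto target cohort; dropped")
  rows <- rows[keep]
  models <- models[keep]
  if (!length(rows)) stop("no projectable models")
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(models, `[[`, character(1), "pathway_id")
  colnames(mat) <- ds$sample_ids
  structure(mat, labels = ds$labels, models = models,
            class = c("ActivityMatrix", "matrix", "array"))
}
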