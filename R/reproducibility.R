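#' Cross-cohort reproducibility score of ranked pathway activities
#'
#' For the top-n ranked activity models of an inference cohort, the
#' reproducibility score is the mean over the top n of the product of the
#' model's discriminative t-score on the inference cohort and the t-score
#' of the same frozen activity projected onto the validation cohort.
#' Activities that discriminate in the same direction in both cohorts
#' contribute positively; direction reversals are penalized.
#'
#' @param inference_models List of `PathwayActivityModel`s already ranked
#'   (see [rank_models()]).
#' @param validation_ds A z-normalized [expression_dataset()] (the
#'   validation cohort).
#' @param n Number of top-ranked models to average over.
#' @return The score (a single number). Unprojectable models are excluded
#'   with a warning and `n` is reduced accordingly.
#' @export
cscore <- function(inference_models, validation_ds, n) {
  if (n < 1) stop("n must be >= 1")
  if (n > length(inference_models))
    stop("n (", n, ") exceeds the number of models (",
         length(inference_models), ")")
  top <- inference_models[seq_len(n)]
  t_i <- vapply(top, `[[`, numeric(1), "inference_tscore")
  t_v <- vapply(top, function(m) {
    tryCatch(two_sample_t(project_activity(m, validation_ds),
                          validation_ds$labels),
             error = function(e) NA_real_)
  }, numeric(1))
  if (anyNA(t_v)) {
    warning(sum(is.na(t_v)),
            " model(s) unprojectable onto validation cohort; n reduced")
    keep <- !is.na(t_v)
    t_i <- t_i[keep]; t_v <- t_v[keep]
    if (!length(t_i)) stop("no projectable models among the top ", n)
  }
  mean(t_i * t_v)
}

#' Overall reproducibility over all ordered cohort pairs
#'
#' Infers activity models on every cohort, then for every ordered
#' (inference, validation) pair of distinct cohorts and every top-N in
#' `n_grid` computes the reproducibility score; the overall value per N
#' is the arithmetic mean over all ordered pairs (six pairs for three
#' cohorts).
#'
#' @param cohorts Named list of [expression_dataset()]s (z-normalized or
#'   not; normalization is applied per cohort if needed).
#' @param pc A [pathway_collection()] already filtered to the shared gene
#'   universe.
#' @param method Activity-inference method id (see [infer_models()]).
#' @param n_grid Integer vector of top-N values.
#' @param alpha DEG significance level.
#' @param max_k Member-count cap for selective methods.
#' @return List with `pairs` (data.frame: method, inference, validation,
#'   n, cscore) and `overall` (data.frame: method, n, cscore).
#' @export
overall_reproducibility <- function(cohorts, pc, method = "CMI",
                                    n_grid = c(5, 10, 20),
                                    alpha = 0.05, max_k = 20) {
  if (length(cohorts) < 2) stop("need at least 2 cohorts")
  if (is.null(names(cohorts)))
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  cohorts <- lapply(cohorts, function(d)
    if (is_normalized(d)) d else zscore_normalize(d))
  ranked <- lapply(cohorts, function(d) {
    st <- gene_stats(d, alpha = alpha)
    rank_models(infer_models(d, st, pc, method = method, max_k = max_k))
  })
  rows <- list()
  for (inf in names(cohorts)) for (val in names(cohorts)) {
    if (inf == val) next
    for (n in n_grid) {
      n_use <- min(n, length(ranked[[inf]]))
      if (n_use < n)
        warning("pair ", inf, "->", val, ": only ", n_use,
                " models available for N=", n)
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, inference = inf, validation = val, n = n,
        cscore = cscore(ranked[[inf]], cohorts[[val]], n_use),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  overall <- stats::aggregate(cscore ~ method + n, data = pairs, FUN = mean)
  overall <- overall[order(overall$n), c("method", "n", "cscore")]
  rownames(overall) <- NULL
  list(pairs = pairs, overall = overall)
}
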