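#' @name cfe
#' @title Consensus feature elimination with linear classifiers
#' @description
#' Biomarker selection needs features that are accurate *and* stable
#' across resampling. Classical recursive feature elimination ranks
#' features by the weights of a single classifier and is notoriously
#' unstable. Consensus feature elimination instead builds, at every
#' elimination step, an ensemble of linear classifiers over many
#' stratified cross-validation splits, ranks each feature by its mean
#' squared weight across the ensemble, and removes the lowest-ranked
#' feature; the retained set is the one whose ensemble mean held-out AUC
#' is maximal. The whole procedure is repeated with fresh splits and the
#' most frequently selected set is kept as the final marker set.
NULL

# Ledoit-Wolf shrinkage of a covariance estimated from centered rows X
# (n x p), toward the scaled identity. Returns the shrunk covariance.
lw_shrink <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  m <- mean(diag(S))
  d2 <- sum((S - diag(m, p))^2) / p
  if (d2 <= .Machine$double.eps) return(diag(max(m, 1e-8), p))
  sq <- rowSums(Xc^2)
  b2bar <- (sum(sq^2) / n^2 - sum(S^2) / n) / p
  b2 <- min(max(b2bar, 0), d2)
  # numerical floor keeps the shrunk covariance invertible even when a
  # feature is exactly constant within both classes
  lambda <- min(1, max(b2 / d2, 1e-6))
  (1 - lambda) * S + diag(lambda * m, p)
}

#' Train a (shrinkage-regularized) linear discriminant classifier
#'
#' Fisher's linear discriminant with a Ledoit-Wolf shrinkage estimate of
#' the pooled within-class covariance, so collinear or high-dimensional
#' feature sets stay well-posed. The weight vector is
#' w = S^-1 (mu+ - mu-) and the bias places the decision boundary midway
#' between the projected class means; decision value D(x) = w.x + b with
#' D > 0 calling class +1.
#'
#' @param X Samples-by-features numeric matrix.
#' @param y Labels in -1/+1.
#' @return A `LinearClassifier` list: `weights`, `bias`, `kind`.
#' @export
train_lda <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes required")
  pos <- y == 1
  mu1 <- colMeans(X[pos, , drop = FALSE])
  mu0 <- colMeans(X[!pos, , drop = FALSE])
  Xc <- rbind(sweep(X[pos, , drop = FALSE], 2, mu1),
              sweep(X[!pos, , drop = FALSE], 2, mu0))
  S <- lw_shrink(Xc)
  w <- drop(solve(S, mu1 - mu0))
  b <- -sum(w * (mu1 + mu0)) / 2
  structure(list(weights = stats::setNames(w, colnames(X)),
                 bias = b, kind = "LDA"),
            class = "LinearClassifier")
}

#' Train a soft-margin linear support vector machine
#'
#' Thin wrapper over [e1071::svm()] (linear kernel) that extracts the
#' primal weight vector and bias, oriented so that D(x) = w.x + b is
#' positive for class +1.
#'
#' @inheritParams train_lda
#' @param cost Soft-margin regularization constant (default 1).
#' @return A `LinearClassifier` list: `weights`, `bias`, `kind`.
#' @export
train_linear_svm <- function(X, y, cost = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes required")
  fit <- e1071::svm(x = X, y = factor(y, levels = c(-1, 1)),
                    kernel = "linear", cost = cost, scale = FALSE)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  d <- drop(X %*% w) + b
  if (mean(d[y == 1]) < mean(d[y == -1])) { w <- -w; b <- -b }
  structure(list(weights = stats::setNames(w, colnames(X)),
                 bias = b, kind = "SVM"),
            class = "LinearClassifier")
}

#' Decision values of a linear classifier
#' @param clf A `LinearClassifier`.
#' @param X Samples-by-features matrix (columns matching the weights).
#' @return Numeric vector of decision values w.x + b.
#' @export
decision_values <- function(clf, X) {
  drop(as.matrix(X) %*% clf$weights) + clf$bias
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a random case scores above a random control; ties
#' contribute one half (midrank convention).
#'
#' @param scores Numeric score per sample.
#' @param y Labels in -1/+1 (or 0/1); both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, y) {
  y <- as.numeric(y)
  pos <- y == 1 | y == max(y)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: within each class, shuffled round-robin.
stratified_folds <- function(y, n_folds) {
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    f[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(n_folds), length(idx))
  }
  f
}

fit_classifier <- function(kind, X, y, cost = 1) {
  if (kind == "LDA") train_lda(X, y) else train_linear_svm(X, y, cost)
}

#' Consensus feature elimination
#'
#' At every step, `n_splits` stratified `n_folds`-fold splits of the
#' samples yield `n_splits * n_folds` classifier fits (500 with the
#' defaults); each fit records its held-out-fold AUC and weight vector.
#' Features are ranked by mean squared weight over all fits and the
#' lowest-ranked feature is removed; the loop runs down to a single
#' feature. The selected set is the feature set at the step with maximal
#' mean AUC (ties resolved toward fewer features).
#'
#' @param X Features-by-samples [activity_matrix()], or a plain
#'   samples-by-features matrix given together with `y`.
#' @param y Labels in -1/+1 (taken from `X` when it is an
#'   `ActivityMatrix`).
#' @param classifier "LDA" (default) or "SVM".
#' @param n_splits Number of cross-validation splits per step
#'   (default 100).
#' @param n_folds Folds per split (default 5).
#' @param seed Integer seed making the run reproducible.
#' @param cost SVM regularization constant.
#' @return A `CFEResult` list: `trajectory` (data.frame with step,
#'   n_features, mean_auc, sd_auc, removed_feature), `selected_features`,
#'   `weight_ranks` (mean squared weight per feature per step, long
#'   form), `max_mean_auc`, `seed`.
#' @export
consensus_feature_elimination <- function(X, y = NULL,
                                          classifier = c("LDA", "SVM"),
                                          n_splits = 100, n_folds = 5,
                                          seed = 1, cost = 1) {
  classifier <- match.arg(classifier)
  if (inherits(X, "ActivityMatrix")) {
    y <- attr(X, "labels")
    X <- t(unclass(X))
  } else {
    X <- as.matrix(X)
    if (is.null(y)) stop("`y` required for a plain matrix")
  }
  y <- as.numeric(y)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  n1 <- sum(y == 1); n0 <- sum(y == -1)
  if (min(n1, n0) < n_folds)
    stop("need at least n_folds (", n_folds, ") samples per class")
  set.seed(seed)

  features <- colnames(X)
  n_steps <- length(features)
  traj <- vector("list", n_steps)
  wlog <- vector("list", n_steps)
  feat_sets <- vector("list", n_steps)
  for (step in seq_len(n_steps)) {
    cur <- features
    feat_sets[[step]] <- cur
    aucs <- numeric(n_splits * n_folds)
    wsq <- numeric(length(cur))
    k <- 0L
    for (s in seq_len(n_splits)) {
      fold <- stratified_folds(y, n_folds)
      for (fo in seq_len(n_folds)) {
        tr <- fold != fo
        clf <- fit_classifier(classifier, X[tr, cur, drop = FALSE],
                              y[tr], cost)
        if (any(!is.finite(clf$weights)))
          stop("non-finite classifier weights at elimination step ", step)
        k <- k + 1L
        aucs[k] <- auc(decision_values(clf, X[!tr, cur, drop = FALSE]),
                       y[!tr])
        wsq <- wsq + clf$weights^2
      }
    }
    wbar <- wsq / (n_splits * n_folds)
    traj[[step]] <- data.frame(
      step = step, n_features = length(cur),
      mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
      removed_feature = if (length(cur) > 1) cur[which.min(wbar)]
                        else NA_character_,
      stringsAsFactors = FALSE)
    wlog[[step]] <- data.frame(step = step, feature = cur,
                               mean_sq_weight = wbar,
                               stringsAsFactors = FALSE)
    if (length(cur) > 1)
      features <- setdiff(cur, cur[which.min(wbar)])
  }
  trajectory <- do.call(rbind, traj)
  best <- max(trajectory$mean_auc)
  cand <- which(trajectory$mean_auc == best)
  pick <- cand[which.min(trajectory$n_features[cand])]
  structure(
    list(trajectory = trajectory,
         selected_features = sort(feat_sets[[pick]]),
         weight_ranks = do.call(rbind, wlog),
         max_mean_auc = best, seed = seed),
    class = "CFEResult")
}

#' @export
print.CFEResult <- function(x, ...) {
  cat(sprintf("CFEResult: %d elimination steps, max mean AUC %.3f, %d feature(s) selected\n",
              nrow(x$trajectory), x$max_mean_auc,
              length(x$selected_features)))
  invisible(x)
}

#' Final marker selection by repeated consensus feature elimination
#'
#' Runs [consensus_feature_elimination()] `n_repeats` times with
#' deterministically derived seeds and returns the most frequently
#' selected exact feature set (ties resolved toward the smaller set, then
#' lexicographically). Per-feature selection frequencies are reported as
#' a stability diagnostic.
#'
#' @inheritParams consensus_feature_elimination
#' @param n_repeats Number of independent elimination runs (default 100).
#' @return List: `selected_features`, `set_frequencies` (data.frame of
#'   distinct sets with counts), `feature_frequencies` (named vector of
#'   per-feature selection proportions), `max_mean_auc` (mean over the
#'   repeats that produced the winning set), `seed`.
#' @export
select_final_markers <- function(X, y = NULL,
                                 classifier = c("LDA", "SVM"),
                                 n_repeats = 100, n_splits = 100,
                                 n_folds = 5, seed = 1, cost = 1) {
  classifier <- match.arg(classifier)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_repeats)
  runs <- lapply(seeds, function(s)
    consensus_feature_elimination(X, y, classifier = classifier,
                                  n_splits = n_splits, n_folds = n_folds,
                                  seed = s, cost = cost))
  sets <- lapply(runs, `[[`, "selected_features")
  keys <- vapply(sets, paste, character(1), collapse = "|")
  tab <- table(keys)
  top <- names(tab)[tab == max(tab)]
  # tie-break: smaller set, then lexicographic key
  sizes <- vapply(strsplit(top, "|", fixed = TRUE), length, integer(1))
  top <- sort(top[sizes == min(sizes)])[1]
  winner <- strsplit(top, "|", fixed = TRUE)[[1]]
  all_feats <- sort(unique(unlist(sets)))
  freq <- vapply(all_feats, function(f)
    mean(vapply(sets, function(s) f %in% s, logical(1))), numeric(1))
  list(selected_features = winner,
       set_frequencies = data.frame(
         set = names(tab), count = as.integer(tab),
         row.names = NULL, stringsAsFactors = FALSE),
       feature_frequencies = freq,
       max_mean_auc = mean(vapply(runs[keys == top], `[[`,
                                  numeric(1), "max_mean_auc")),
       seed = seed)
}
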