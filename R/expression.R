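#' Construct an expression dataset for one cohort
#'
#' Bundles a genes-by-samples expression matrix with a binary phenotype
#' label per sample. Labels are coded internally as -1/+1, where +1 is the
#' case (poor outcome) class; 0/1 input codings are mapped to -1/+1.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample identifiers).
#' @param labels Numeric or integer vector of per-sample phenotype labels,
#'   one per column of `values`, coded -1/+1 or 0/1.
#' @return An object of class `ExpressionDataset`: a list with elements
#'   `values` (the matrix), `labels` (named -1/+1 vector), `gene_ids`,
#'   `sample_ids` and the logical attribute `normalized`.
#' @examples
#' m <- matrix(rnorm(20), nrow = 5,
#'             dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
#' ds <- expression_dataset(m, c(1, 1, 0, 0))
#' ds$labels
#' @export
expression_dataset <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  dup <- unique(rownames(values)[duplicated(rownames(values))])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample IDs")
  if (length(labels) != ncol(values))
    stop("length(labels) must equal ncol(values)")
  labels <- as.numeric(labels)
  if (all(labels %in% c(0, 1))) labels <- ifelse(labels == 1, 1, -1)
  if (!all(labels %in% c(-1, 1)))
    stop("labels must be coded -1/+1 or 0/1")
  if (sum(labels == 1) < 2 || sum(labels == -1) < 2)
    stop("each class needs at least 2 samples")
  names(labels) <- colnames(values)
  structure(
    list(values = values, labels = labels,
         gene_ids = rownames(values), sample_ids = colnames(values)),
    class = "ExpressionDataset", normalized = FALSE)
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d genes x %d samples (%d cases, %d controls)%s\n",
              nrow(x$values), ncol(x$values),
              sum(x$labels == 1), sum(x$labels == -1),
              if (isTRUE(attr(x, "normalized"))) ", z-normalized" else ""))
  invisible(x)
}

#' Read a cohort expression matrix from a TSV file
#'
#' Expects a tab-separated file whose first column holds gene symbols and
#' whose header row holds sample identifiers. Phenotype labels come either
#' from a row whose gene column equals `label_row` (conventionally the
#' second row, named "CLASS"), or from a two-column side file
#' (sample_id, label) given as `labels_file`.
#'
#' @param path Path to the TSV expression matrix.
#' @param label_row Name of the in-file label row (default "CLASS");
#'   ignored when `labels_file` is given.
#' @param labels_file Optional path to a two-column TSV of sample labels.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(path, label_row = "CLASS", labels_file = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0) stop("no data rows in ", path)
  ids <- raw[[1]]
  labels <- NULL
  if (!is.null(labels_file)) {
    lab <- utils::read.delim(labels_file, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE)
    if (ncol(lab) < 2) stop("labels file needs two columns (sample, label)")
    labels <- stats::setNames(as.numeric(lab[[2]]), as.character(lab[[1]]))
  } else {
    hit <- which(ids == label_row)
    if (length(hit) != 1)
      stop("expected exactly one '", label_row, "' row in ", path)
    labels <- suppressWarnings(as.numeric(raw[hit, -1]))
    if (anyNA(labels)) stop("non-numeric label in row '", label_row, "'")
    names(labels) <- colnames(raw)[-1]
    raw <- raw[-hit, , drop = FALSE]
    ids <- raw[[1]]
  }
  if (nrow(raw) == 0) stop("no data rows in ", path)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene IDs: ", paste(dup, collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric value at gene '%s', sample '%s'",
                 ids[bad[1]], colnames(vals)[bad[2]]))
  }
  dimnames(num) <- list(ids, colnames(vals))
  if (!is.null(labels_file)) {
    missing <- setdiff(colnames(num), names(labels))
    if (length(missing))
      stop("samples without labels: ", paste(missing, collapse = ", "))
    labels <- labels[colnames(num)]
  }
  expression_dataset(num, labels)
}

#' Z-score normalize each gene across all samples of a cohort
#'
#' Centers and scales every gene row to mean 0 and (sample) standard
#' deviation 1 over all samples, cases and controls together. Rows with
#' zero variance are set to all zeros with a warning, and retained so that
#' the gene universe stays aligned across cohorts.
#'
#' @param ds An [expression_dataset()].
#' @return The dataset with normalized values and attribute
#'   `normalized = TRUE`. The operation is idempotent.
#' @export
zscore_normalize <- function(ds) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  v <- ds$values
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  flat <- sdv == 0 | !is.finite(sdv)
  if (any(flat)) {
    warning(sum(flat), " zero-variance gene(s) set to all-zero z-scores")
    sdv[flat] <- 1
  }
  z <- (v - mu) / sdv
  z[flat, ] <- 0
  ds$values <- z
  attr(ds, "normalized") <- TRUE
  ds
}

#' Is a dataset z-normalized?
#' @param ds An [expression_dataset()].
#' @return Logical.
#' @export
is_normalized <- function(ds) isTRUE(attr(ds, "normalized"))

# Vectorized two-sample t statistics for every row of `mat`.
# Positive t means higher mean in class +1. Returns list(t, p, df).
row_tstats <- function(mat, labels, var_equal = TRUE) {
  case <- labels == 1
  n1 <- sum(case); n0 <- sum(!case)
  if (n1 < 2 || n0 < 2) stop("each class needs at least 2 samples")
  m1 <- rowMeans(mat[, case, drop = FALSE])
  m0 <- rowMeans(mat[, !case, drop = FALSE])
  v1 <- rowSums((mat[, case, drop = FALSE] - m1)^2) / (n1 - 1)
  v0 <- rowSums((mat[, !case, drop = FALSE] - m0)^2) / (n0 - 1)
  diff <- m1 - m0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(diff))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t <- diff / se
  # zero pooled variance: equal means -> t = 0; unequal -> +/- Inf stands
  t[se == 0 & diff == 0] <- 0
  df[!is.finite(df)] <- n1 + n0 - 2
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t)] <- 0
  list(t = t, p = p, df = df)
}

# Two-sample t of a single numeric vector against -1/+1 labels.
two_sample_t <- function(x, labels, var_equal = TRUE) {
  row_tstats(matrix(x, nrow = 1), labels, var_equal)$t[1]
}

#' Per-gene differential expression statistics
#'
#' Two-tailed two-sample t-test of cases (+1) against controls (-1) for
#' every gene; genes with p-value at or below `alpha` are flagged as
#' differentially expressed (DEGs). The pooled-variance test is the
#' default; set `var_equal = FALSE` for Welch.
#'
#' @param ds An [expression_dataset()].
#' @param alpha DEG significance level (default 0.05).
#' @param var_equal Pooled-variance t (TRUE, default) or Welch (FALSE).
#' @return A data.frame of class `gene_stats` with columns `gene_id`,
#'   `tscore` (positive = higher in cases), `pvalue`, `is_deg`; `alpha`
#'   and `var_equal` stored as attributes.
#' @export
gene_stats <- function(ds, alpha = 0.05, var_equal = TRUE) {
  stopifnot(inherits(ds, "ExpressionDataset"))
  st <- row_tstats(ds$values, ds$labels, var_equal)
  out <- data.frame(gene_id = ds$gene_ids, tscore = st$t, pvalue = st$p,
                    is_deg = st$p <= alpha, stringsAsFactors = FALSE)
  rownames(out) <- out$gene_id
  attr(out, "alpha") <- alpha
  attr(out, "var_equal") <- var_equal
  class(out) <- c("gene_stats", "data.frame")
  out
}
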