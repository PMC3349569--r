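#' Hypergeometric enrichment p-value
#'
#' Probability of drawing strictly more than `n_overlap` reference genes
#' when `n_signature` genes are sampled without replacement from a
#' universe of `n_universe` genes containing `n_reference` reference
#' genes, i.e. the upper hypergeometric tail P(X > K). The conventional
#' inclusive tail P(X >= K) is available with `strict = FALSE`.
#'
#' @param n_universe Total genes N in the universe.
#' @param n_reference Reference (e.g. known cancer) genes M in the
#'   universe.
#' @param n_signature Signature size J.
#' @param n_overlap Observed overlap K.
#' @param strict Use the strict tail P(X > K) (default TRUE).
#' @return The p-value.
#' @export
hypergeom_pvalue <- function(n_universe, n_reference, n_signature,
                             n_overlap, strict = TRUE) {
  N <- n_universe; M <- n_reference; J <- n_signature; K <- n_overlap
  if (any(c(N, M, J, K) < 0) || M > N || J > N || K > min(J, M))
    stop("invalid enrichment counts: need 0 <= K <= min(J, M), M <= N, J <= N")
  k <- if (strict) K else K - 1
  stats::phyper(k, M, N - M, J, lower.tail = FALSE)
}

#' Enrichment rate of a signature in a reference gene list
#'
#' Fraction of the signature's in-universe genes that are reference
#' genes, plus the counts needed for the hypergeometric p-value.
#' Signature genes outside the universe are dropped with a warning.
#'
#' @param signature Character vector of signature gene symbols.
#' @param reference Character vector of reference gene symbols.
#' @param universe Character vector: the gene universe (typically the
#'   genes shared by all cohorts and present in the filtered pathway
#'   collection).
#' @param strict Passed to [hypergeom_pvalue()].
#' @return List: `rate`, `pvalue`, and the counts `n_universe`,
#'   `n_reference`, `n_signature`, `n_overlap`.
#' @export
enrichment_rate <- function(signature, reference, universe, strict = TRUE) {
  universe <- unique(as.character(universe))
  signature <- unique(as.character(signature))
  reference <- unique(as.character(reference))
  outside <- setdiff(signature, universe)
  if (length(outside))
    warning(length(outside), " signature gene(s) outside the universe dropped")
  sig <- intersect(signature, universe)
  if (!length(sig)) stop("no signature gene in the universe")
  ref <- intersect(reference, universe)
  ov <- intersect(sig, ref)
  list(rate = length(ov) / length(sig),
       pvalue = hypergeom_pvalue(length(universe), length(ref),
                                 length(sig), length(ov), strict = strict),
       n_universe = length(universe), n_reference = length(ref),
       n_signature = length(sig), n_overlap = length(ov))
}

#' Enrichment of a signature against several reference lists
#'
#' @param signature Character vector of signature genes.
#' @param references Named list of reference gene vectors (or paths to
#'   one-symbol-per-line text files).
#' @param universe Gene universe.
#' @param bonferroni Also report Bonferroni-adjusted p-values across the
#'   reference lists (default FALSE; raw p-values are always reported).
#' @inheritParams enrichment_rate
#' @return data.frame: reference, rate, n_overlap, n_signature,
#'   n_reference, n_universe, pvalue (and p_adjusted if requested).
#' @export
enrichment_table <- function(signature, references, universe,
                             strict = TRUE, bonferroni = FALSE) {
  refs <- lapply(references, function(r)
    if (is.character(r) && length(r) == 1 && file.exists(r))
      readLines(r, warn = FALSE) else as.character(r))
  rows <- lapply(names(refs), function(nm) {
    e <- enrichment_rate(signature, refs[[nm]], universe, strict = strict)
    data.frame(reference = nm, rate = e$rate, n_overlap = e$n_overlap,
               n_signature = e$n_signature, n_reference = e$n_reference,
               n_universe = e$n_universe, pvalue = e$pvalue,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (bonferroni)
    out$p_adjusted <- pmin(1, out$pvalue * nrow(out))
  out
}
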