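# Shared fixtures and independent oracles for the suite.

# Small labelled dataset with iid N(0,1) values; optionally shift `shift`
# on `shift_genes` in cases.
make_dataset <- function(n_genes = 30, n = 40, seed = 1,
                         shift_genes = character(), shift = 0) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  labels <- rep(c(1, -1), each = n / 2)
  v <- matrix(rnorm(n_genes * n), nrow = n_genes,
              dimnames = list(genes, sprintf("s%03d", seq_len(n))))
  if (length(shift_genes))
    v[shift_genes, labels == 1] <- v[shift_genes, labels == 1] + shift
  expression_dataset(v, labels)
}

# Dataset with prescribed value rows, flagged as normalized (for exact
# hand-evaluated projection/score checks).
make_z_dataset <- function(rows, labels) {
  ds <- expression_dataset(rows, labels)
  attr(ds, "normalized") <- TRUE
  ds
}

# Exhaustive prefix oracle for core-module inference: evaluates every
# prefix of the |t|-ranked DEG list directly and returns the best.
cmi_oracle <- function(ds, stats, pathway, max_k = 20) {
  m <- stats[intersect(intersect(pathway, ds$gene_ids), stats$gene_id), ,
             drop = FALSE]
  degs <- m[m$is_deg, , drop = FALSE]
  if (nrow(degs) == 0) return(NULL)
  degs <- degs[order(-abs(degs$tscore), degs$gene_id), , drop = FALSE]
  jmax <- min(nrow(degs), max_k)
  tj <- vapply(seq_len(jmax), function(j) {
    g <- degs$gene_id[seq_len(j)]
    s <- sign(degs$tscore[seq_len(j)]); s[s == 0] <- 1
    act <- colSums(ds$values[g, , drop = FALSE] * s) / j
    unname(stats::t.test(act[ds$labels == 1], act[ds$labels == -1],
                         var.equal = TRUE)$statistic)
  }, numeric(1))
  K <- if (max(tj) > 0) which.max(tj) else which.max(abs(tj))
  g <- degs$gene_id[seq_len(K)]
  s <- sign(degs$tscore[seq_len(K)]); s[s == 0] <- 1
  list(K = K, genes = g,
       activity = colSums(ds$values[g, , drop = FALSE] * s) / K,
       tscore = tj[K])
}

# O(n^2) pair-counting AUC oracle (ties count one half).
auc_oracle <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y != 1]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Enumeration oracle for the strict hypergeometric upper tail:
# P(overlap > K) over all C(N, J) equally likely signature draws.
hyper_oracle <- function(N, M, J, K) {
  if (J == 0) return(as.numeric(0 > K))
  draws <- utils::combn(N, J)
  overlaps <- colSums(draws <= M)  # reference genes are 1..M
  mean(overlaps > K)
}
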