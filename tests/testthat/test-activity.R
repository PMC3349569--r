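norm_stats <- function(ds) {
  z <- zscore_normalize(ds)
  list(z = z, st = gene_stats(z))
}

test_that("core-module inference matches the exhaustive prefix oracle", {
  ds <- make_dataset(n_genes = 60, n = 50, seed = 21,
                     shift_genes = sprintf("g%03d", 1:12), shift = 0.9)
  ns <- norm_stats(ds)
  set.seed(99)
  for (rep in 1:25) {
    pathway <- sample(ds$gene_ids, sample(3:15, 1))
    model <- infer_cmi(ns$z, ns$st, pathway, pathway_id = "p")
    oracle <- cmi_oracle(ns$z, ns$st, pathway)
    if (is.null(oracle)) {
      expect_null(model)
    } else {
      expect_equal(model$K, oracle$K)
      expect_equal(model$member_genes, oracle$genes)
      expect_equal(project_activity(model, ns$z), oracle$activity,
                   tolerance = 1e-10)
      expect_equal(model$inference_tscore, oracle$tscore,
                   tolerance = 1e-8)
    }
  }
})

test_that("pathways without DEGs yield NULL and single-DEG pathways give K = 1", {
  ds <- make_dataset(n_genes = 30, n = 40, seed = 22,
                     shift_genes = "g001", shift = 2.5)
  ns <- norm_stats(ds)
  null_genes <- ns$st$gene_id[!ns$st$is_deg]
  expect_null(infer_cmi(ns$z, ns$st, null_genes[1:5]))
  m <- infer_cmi(ns$z, ns$st, c("g001", null_genes[1:4]))
  expect_equal(m$K, 1)
  expect_equal(m$member_genes, "g001")
  expect_equal(project_activity(m, ns$z),
               ns$z$values["g001", ] * sign(ns$st["g001", "tscore"]),
               tolerance = 1e-12)
})

test_that("member count never exceeds the cap", {
  ds <- make_dataset(n_genes = 80, n = 60, seed = 23,
                     shift_genes = sprintf("g%03d", 1:40), shift = 1.2)
  ns <- norm_stats(ds)
  m <- infer_cmi(ns$z, ns$st, ds$gene_ids)
  expect_lte(m$K, 20)
  m5 <- infer_cmi(ns$z, ns$st, ds$gene_ids, max_k = 5)
  expect_lte(m5$K, 5)
})

test_that("CORG picks single-signed members and matches an exhaustive search on a mixed toy", {
  # strong up pair, strong down gene, near-null gene
  ds <- make_dataset(n_genes = 6, n = 60, seed = 24)
  ds$values["g001", ds$labels == 1] <- ds$values["g001", ds$labels == 1] + 1.5
  ds$values["g002", ds$labels == 1] <- ds$values["g002", ds$labels == 1] + 1.2
  ds$values["g003", ds$labels == 1] <- ds$values["g003", ds$labels == 1] - 1.4
  ns <- norm_stats(ds)
  pathway <- c("g001", "g002", "g003", "g004")
  m <- infer_corg(ns$z, ns$st, pathway, pathway_id = "toy")
  expect_true(all(m$signs == m$signs[1]))

  # exhaustive oracle over both subsets' prefixes (sum / sqrt(j) scoring)
  stats <- ns$st[pathway, ]
  best <- list(t = 0, genes = NULL)
  for (dir in c(1, -1)) {
    sub <- stats[sign(stats$tscore) == dir, , drop = FALSE]
    sub <- sub[order(-abs(sub$tscore)), , drop = FALSE]
    for (j in seq_len(nrow(sub))) {
      act <- dir * colSums(ns$z$values[sub$gene_id[seq_len(j)], ,
                                       drop = FALSE]) / sqrt(j)
      tj <- unname(t.test(act[ds$labels == 1], act[ds$labels == -1],
                          var.equal = TRUE)$statistic)
      if (abs(tj) > abs(best$t))
        best <- list(t = tj, genes = sub$gene_id[seq_len(j)], dir = dir)
    }
  }
  expect_equal(m$member_genes, best$genes)
  expect_equal(m$inference_tscore, best$t, tolerance = 1e-8)

  # all-upregulated pathway: same ranked list as the mixed-sign search
  m_up <- infer_corg(ns$z, ns$st, c("g001", "g002"))
  expect_true(all(ns$st[m_up$member_genes, "tscore"] > 0))
})

test_that("simple comparators behave as their definitions require", {
  ds <- make_dataset(n_genes = 12, n = 40, seed = 25,
                     shift_genes = c("g001", "g002"), shift = 1.3)
  ns <- norm_stats(ds)

  # MEAN of one gene is that gene's z-row
  m1 <- infer_simple(ns$z, ns$st, "g003", method = "MEAN")
  expect_equal(project_activity(m1, ns$z), ns$z$values["g003", ],
               tolerance = 1e-12)

  # MEDIAN recomputes the per-sample median
  mm <- infer_simple(ns$z, ns$st, c("g001", "g002", "g003"),
                     method = "MEDIAN")
  expect_equal(project_activity(mm, ns$z),
               apply(ns$z$values[c("g001", "g002", "g003"), ], 2, median),
               tolerance = 1e-12)

  # PCA scores align (up to sign) with the eigen-decomposition oracle
  genes <- sprintf("g%03d", 1:6)
  mp <- infer_simple(ns$z, ns$st, genes, method = "PCA")
  act <- project_activity(mp, ns$z)
  z <- ns$z$values[genes, ]
  ev <- eigen(tcrossprod(z) / (ncol(z) - 1))$vectors[, 1]
  oracle <- drop(crossprod(z, ev))
  expect_equal(abs(cor(act, oracle)), 1, tolerance = 1e-8)
  expect_gte(mp$inference_tscore, 0)

  # GENE activities equal z-rows exactly
  mg <- infer_simple(ns$z, ns$st, c("g005", "g006"), method = "GENE")
  expect_equal(length(mg), 2)
  expect_equal(project_activity(mg[[1]], ns$z), ns$z$values["g005", ],
               tolerance = 1e-12)

  # LLR with identical class distributions is identically zero
  v <- matrix(c(1, -1, -1, 1,
                -1, 1, 1, -1), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  dsym <- make_z_dataset(v, c(1, 1, -1, -1))
  ssym <- gene_stats(dsym)
  ml <- infer_simple(dsym, ssym, c("a", "b"), method = "LLR")
  expect_equal(unname(project_activity(ml, dsym)), rep(0, 4),
               tolerance = 1e-10)
})

test_that("projection honours frozen members, signs and the drop rule", {
  # hand-evaluated two-member projection
  target <- make_z_dataset(
    matrix(c(1, -1, 1, -1,
             -1, 1, -1, 1), nrow = 2, byrow = TRUE,
           dimnames = list(c("g1", "g2"), paste0("s", 1:4))),
    c(1, 1, -1, -1))
  model <- coremod:::new_activity_model("p", "CMI", c("g1", "g2"),
                                        c(1, -1), 2.0)
  expect_equal(unname(project_activity(model, target)),
               c(1, -1, 1, -1))

  # one member missing: divisor adjusts to the survivor
  t2 <- make_z_dataset(
    matrix(c(1, -1, 1, -1), nrow = 1,
           dimnames = list("g1", paste0("s", 1:4))),
    c(1, 1, -1, -1))
  expect_warning(act <- project_activity(model, t2), "missing")
  expect_equal(unname(act), c(1, -1, 1, -1))

  # all members missing is an error naming the model
  t3 <- make_z_dataset(
    matrix(rnorm(8), nrow = 2,
           dimnames = list(c("h1", "h2"), paste0("s", 1:4))),
    c(1, 1, -1, -1))
  expect_error(project_activity(model, t3), "p")
})

test_that("permuting sample order permutes activities identically", {
  ds <- make_dataset(n_genes = 20, n = 30, seed = 26,
                     shift_genes = c("g001", "g002", "g003"), shift = 1)
  ns <- norm_stats(ds)
  set.seed(77)
  perm <- sample(seq_len(30))
  ds_p <- ds
  ds_p$values <- ds$values[, perm]
  ds_p$labels <- ds$labels[perm]
  ds_p$sample_ids <- ds$sample_ids[perm]
  z_p <- zscore_normalize(ds_p)
  for (method in c("CMI", "CORG", "MEAN", "PCA", "LLR")) {
    m <- switch(method,
                CMI = infer_cmi(ns$z, ns$st, ds$gene_ids[1:8]),
                CORG = infer_corg(ns$z, ns$st, ds$gene_ids[1:8]),
                infer_simple(ns$z, ns$st, ds$gene_ids[1:8], method = method))
    expect_equal(project_activity(m, z_p),
                 project_activity(m, ns$z)[perm],
                 tolerance = 1e-10, info = method)
  }
})

test_that("model ranking is signed for sign-aligned methods, absolute otherwise", {
  mk <- function(id, method, t) coremod:::new_activity_model(
    id, method, "g", 1, t)
  cmi <- list(mk("a", "CMI", 2), mk("b", "CMI", 5), mk("c", "CMI", 3))
  expect_equal(vapply(rank_models(cmi), `[[`, character(1), "pathway_id"),
               c("b", "c", "a"))
  gene <- list(mk("a", "GENE", 2), mk("b", "GENE", -5), mk("c", "GENE", 3))
  expect_equal(vapply(rank_models(gene), `[[`, character(1), "pathway_id"),
               c("b", "c", "a"))
})
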