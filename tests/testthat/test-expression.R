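test_that("TSV parsing honours label conventions and rejects bad input", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cohort.tsv")
  writeLines(c("GENE\ts1\ts2\ts3\ts4",
               "CLASS\t1\t1\t0\t0",
               "TP53\t1.5\t2.0\t0.5\t0.1",
               "BRCA1\t0.2\t0.4\t1.2\t1.9",
               "MYC\t3.0\t2.5\t2.8\t2.2"), path)
  ds <- read_expression(path)
  expect_equal(unname(ds$labels), c(1, 1, -1, -1))
  expect_equal(ds$gene_ids, c("TP53", "BRCA1", "MYC"))
  expect_equal(ds$values["TP53", "s2"], 2.0)

  # side-file labels override the in-file convention
  lab <- file.path(dir, "labels.tsv")
  writeLines(c("s1\t1", "s2\t0", "s3\t0", "s4\t1"), lab)
  body <- c("GENE\ts1\ts2\ts3\ts4",
            "TP53\t1.5\t2.0\t0.5\t0.1",
            "BRCA1\t0.2\t0.4\t1.2\t1.9")
  p2 <- file.path(dir, "cohort2.tsv")
  writeLines(body, p2)
  ds2 <- read_expression(p2, labels_file = lab)
  expect_equal(unname(ds2$labels), c(1, -1, -1, 1))

  # duplicate gene row named in the error
  p3 <- file.path(dir, "dup.tsv")
  writeLines(c("GENE\ts1\ts2\ts3\ts4", "CLASS\t1\t1\t0\t0",
               "TP53\t1\t2\t3\t4", "TP53\t4\t3\t2\t1",
               "MYC\t1\t1\t1\t2"), p3)
  expect_error(read_expression(p3), "TP53")

  # non-numeric cell located; empty file refused
  p4 <- file.path(dir, "bad.tsv")
  writeLines(c("GENE\ts1\ts2\ts3\ts4", "CLASS\t1\t1\t0\t0",
               "TP53\t1\tNA?\t3\t4"), p4)
  expect_error(read_expression(p4), "TP53.*s2")
  p5 <- file.path(dir, "empty.tsv")
  writeLines("GENE\ts1\ts2", p5)
  expect_error(read_expression(p5), "no data rows")

  # single-class labels refused
  p6 <- file.path(dir, "oneclass.tsv")
  writeLines(c("GENE\ts1\ts2\ts3\ts4", "CLASS\t1\t1\t1\t1",
               "TP53\t1\t2\t3\t4"), p6)
  expect_error(read_expression(p6), "class")
})

test_that("z-score normalization gives mean 0 / sd 1 per gene and is idempotent", {
  ds <- make_dataset(n_genes = 25, n = 30, seed = 11)
  ds$values[3, ] <- ds$values[3, ] * 50 + 7   # wild scale
  z <- zscore_normalize(ds)
  expect_true(is_normalized(z))
  expect_lt(max(abs(rowMeans(z$values))), 1e-10)
  expect_lt(max(abs(apply(z$values, 1, sd) - 1)), 1e-10)
  z2 <- zscore_normalize(z)
  expect_lt(max(abs(z2$values - z$values)), 1e-10)
})

test_that("constant gene rows are zeroed with a warning and retained", {
  ds <- make_dataset(n_genes = 5, n = 20, seed = 2)
  ds$values["g002", ] <- 5
  expect_warning(z <- zscore_normalize(ds), "zero-variance")
  expect_equal(unname(z$values["g002", ]), rep(0, 20))
  expect_equal(nrow(z$values), 5)
})

test_that("gene t statistics match t.test and the DEG rule", {
  ds <- make_dataset(n_genes = 40, n = 36, seed = 3,
                     shift_genes = sprintf("g%03d", 1:5), shift = 1.5)
  st <- gene_stats(ds, alpha = 0.05)
  for (g in c("g001", "g004", "g020", "g039")) {
    o <- t.test(ds$values[g, ds$labels == 1],
                ds$values[g, ds$labels == -1], var.equal = TRUE)
    expect_equal(st[g, "tscore"], unname(o$statistic), tolerance = 1e-8)
    expect_equal(st[g, "pvalue"], o$p.value, tolerance = 1e-8)
  }
  expect_true(all(st$is_deg == (st$pvalue <= 0.05)))
  expect_true(all(st[sprintf("g%03d", 1:5), "tscore"] > 0))
  expect_true(all(st[sprintf("g%03d", 1:5), "is_deg"]))
  # alpha = 1 marks everything
  expect_true(all(gene_stats(ds, alpha = 1)$is_deg))
  # Welch variant agrees with t.test default
  stw <- gene_stats(ds, var_equal = FALSE)
  o <- t.test(ds$values["g001", ds$labels == 1],
              ds$values["g001", ds$labels == -1])
  expect_equal(stw["g001", "tscore"], unname(o$statistic), tolerance = 1e-8)
  expect_equal(stw["g001", "pvalue"], o$p.value, tolerance = 1e-8)
})

test_that("flipping labels negates t-scores and preserves p-values", {
  ds <- make_dataset(n_genes = 20, n = 24, seed = 4,
                     shift_genes = "g001", shift = 2)
  st <- gene_stats(ds)
  flipped <- ds
  flipped$labels <- -ds$labels
  st2 <- gene_stats(flipped)
  expect_equal(st2$tscore, -st$tscore, tolerance = 1e-12)
  expect_equal(st2$pvalue, st$pvalue, tolerance = 1e-12)
})

test_that("identical class means give t = 0 and classes need 2 samples", {
  v <- matrix(c(1, 2, 1, 2,
                5, 5, 5, 5), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  ds <- expression_dataset(v, c(1, 1, -1, -1))
  st <- gene_stats(ds)
  expect_equal(st["a", "tscore"], 0)
  expect_false(st["a", "is_deg"])
  expect_error(expression_dataset(v, c(1, -1, -1, -1)), "2 samples")
})
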