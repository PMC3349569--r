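#' Simulation configuration for a multi-cohort study
#'
#' Defines the planted-signal structure the biomarker framework assumes:
#' a small set of driver pathways whose member genes are differentially
#' expressed with the *same* direction in every cohort, cohort-private
#' passenger genes differentially expressed in one cohort only, and
#' Gaussian baseline noise.
#'
#' @param n_cohorts Number of cohorts (default 3).
#' @param n_genes Genes per cohort (default 600; all cohorts share the
#'   gene universe).
#' @param samples_per_cohort Samples per cohort (default 100).
#' @param case_fraction Fraction of case (+1) samples (default 0.5).
#' @param n_pathways Number of pathways (default 50).
#' @param pathway_size_range Min/max pathway size (default c(8, 15)).
#' @param n_driver_pathways Pathways carrying the shared disease signal
#'   (default 5).
#' @param driver_effect Case-minus-control mean shift of driver member
#'   genes, in units of `noise_sd` (default 0.8).
#' @param driver_member_count Shifted member genes per driver pathway
#'   (default 5).
#' @param n_passenger_degs_per_cohort Cohort-private differentially
#'   expressed genes (default 25), drawn outside driver pathways and
#'   disjoint across cohorts.
#' @param passenger_effect Mean shift of passenger genes in their own
#'   cohort, in `noise_sd` units (default 0.8).
#' @param noise_sd Baseline expression standard deviation (default 1).
#' @param noise One of "gaussian" (default) or "t" (heavier-tailed,
#'   Student t with `t_df` degrees of freedom scaled to `noise_sd`).
#' @param t_df Degrees of freedom for t noise (default 5).
#' @param background_degree Expected background degree of the
#'   interaction network (default 4).
#' @param driver_extra_degree Extra random edges attached to each driver
#'   gene, planting them as hubs (default 30).
#' @param seed RNG seed (default 1).
#' @return A `SimulationConfig` list.
#' @export
simulation_config <- function(n_cohorts = 3, n_genes = 600,
                              samples_per_cohort = 100,
                              case_fraction = 0.5, n_pathways = 50,
                              pathway_size_range = c(8, 15),
                              n_driver_pathways = 5, driver_effect = 0.8,
                              driver_member_count = 5,
                              n_passenger_degs_per_cohort = 25,
                              passenger_effect = 0.8, noise_sd = 1,
                              noise = c("gaussian", "t"), t_df = 5,
                              background_degree = 4,
                              driver_extra_degree = 30, seed = 1) {
  noise <- match.arg(noise)
  cfg <- list(n_cohorts = n_cohorts, n_genes = n_genes,
              samples_per_cohort = samples_per_cohort,
              case_fraction = case_fraction, n_pathways = n_pathways,
              pathway_size_range = pathway_size_range,
              n_driver_pathways = n_driver_pathways,
              driver_effect = driver_effect,
              driver_member_count = driver_member_count,
              n_passenger_degs_per_cohort = n_passenger_degs_per_cohort,
              passenger_effect = passenger_effect, noise_sd = noise_sd,
              noise = noise, t_df = t_df,
              background_degree = background_degree,
              driver_extra_degree = driver_extra_degree, seed = seed)
  counts <- c("n_cohorts", "n_genes", "samples_per_cohort", "n_pathways",
              "n_driver_pathways", "driver_member_count", "noise_sd")
  if (any(unlist(cfg[counts]) <= 0)) stop("all counts must be positive")
  if (case_fraction <= 0 || case_fraction >= 1)
    stop("case_fraction must be in (0,1)")
  if (n_driver_pathways > n_pathways)
    stop("more driver pathways than pathways")
  if (driver_member_count > pathway_size_range[1])
    stop("driver_member_count exceeds the minimum pathway size")
  if (n_pathways * pathway_size_range[2] > 50 * n_genes)
    stop("infeasible pathway configuration")
  structure(cfg, class = "SimulationConfig")
}

#' Simulate a multi-cohort expression study with planted structure
#'
#' Generates `n_cohorts` case/control expression matrices sharing a gene
#' universe, a pathway collection, a gene interaction network, and a
#' ground-truth manifest. The same driver pathways receive a consistent
#' case-vs-control mean shift (one sign per gene, drawn once, shared by
#' all cohorts) on `driver_member_count` member genes; every cohort
#' additionally gets its own private passenger genes, shifted in that
#' cohort only and disjoint across cohorts. Non-driver pathways draw
#' their genes from the non-driver gene pool, so passenger genes sit
#' inside ordinary pathways, as they would downstream of a real disease
#' process. Driver genes are planted as network hubs by attaching extra
#' random edges.
#'
#' @param cfg A [simulation_config()].
#' @return A `SimulatedStudy` list: `cohorts` (named list of
#'   [expression_dataset()]s), `pathways` ([pathway_collection()]),
#'   `network` ([interaction_network()]), `truth` (driver pathway ids,
#'   driver genes with signs, per-cohort passenger genes, per-cohort
#'   passenger-containing pathway ids), `config`.
#' @export
simulate_study <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))

  # pathway memberships: driver pathways take disjoint leading blocks
  sizes <- sample(seq(cfg$pathway_size_range[1], cfg$pathway_size_range[2]),
                  cfg$n_pathways, replace = TRUE)
  pw_ids <- sprintf("PW%03d", seq_len(cfg$n_pathways))
  driver_ids <- pw_ids[seq_len(cfg$n_driver_pathways)]
  need <- sum(sizes[seq_len(cfg$n_driver_pathways)])
  if (need > cfg$n_genes) stop("not enough genes for driver pathways")
  pw <- vector("list", cfg$n_pathways)
  names(pw) <- pw_ids
  offset <- 0
  for (i in seq_len(cfg$n_driver_pathways)) {
    pw[[i]] <- genes[offset + seq_len(sizes[i])]
    offset <- offset + sizes[i]
  }
  pool <- genes[(offset + 1):cfg$n_genes]
  for (i in seq(cfg$n_driver_pathways + 1, cfg$n_pathways))
    pw[[i]] <- sample(pool, sizes[i])
  pathways <- pathway_collection(pw)

  # planted signal: first driver_member_count genes of each driver block
  driver_genes <- unlist(lapply(pw[driver_ids], function(g)
    g[seq_len(cfg$driver_member_count)]), use.names = FALSE)
  driver_signs <- stats::setNames(
    sample(c(-1, 1), length(driver_genes), replace = TRUE), driver_genes)

  # cohort-private passengers, disjoint across cohorts, outside drivers
  pas_pool <- sample(pool)
  n_pas <- cfg$n_passenger_degs_per_cohort
  if (n_pas * cfg$n_cohorts > length(pas_pool))
    stop("not enough non-driver genes for passengers")
  passengers <- lapply(seq_len(cfg$n_cohorts), function(i)
    pas_pool[(i - 1) * n_pas + seq_len(n_pas)])

  rnoise <- function(n) {
    if (cfg$noise == "gaussian") stats::rnorm(n, 0, cfg$noise_sd)
    else stats::rt(n, cfg$t_df) * cfg$noise_sd /
      sqrt(cfg$t_df / (cfg$t_df - 2))
  }

  cohort_names <- paste0("cohort", seq_len(cfg$n_cohorts))
  cohorts <- vector("list", cfg$n_cohorts)
  names(cohorts) <- cohort_names
  for (i in seq_len(cfg$n_cohorts)) {
    n <- cfg$samples_per_cohort
    n_case <- round(cfg$case_fraction * n)
    labels <- sample(c(rep(1, n_case), rep(-1, n - n_case)))
    v <- matrix(rnoise(cfg$n_genes * n), nrow = cfg$n_genes,
                dimnames = list(genes,
                                sprintf("%s_S%03d", cohort_names[i],
                                        seq_len(n))))
    case <- labels == 1
    v[driver_genes, case] <- v[driver_genes, case] +
      driver_signs * cfg$driver_effect * cfg$noise_sd
    pas_signs <- sample(c(-1, 1), n_pas, replace = TRUE)
    v[passengers[[i]], case] <- v[passengers[[i]], case] +
      pas_signs * cfg$passenger_effect * cfg$noise_sd
    cohorts[[i]] <- expression_dataset(v, labels)
  }

  # interaction network: sparse background + planted driver hubs
  p_bg <- min(1, cfg$background_degree / (cfg$n_genes - 1))
  bg <- igraph::sample_gnp(cfg$n_genes, p_bg)
  igraph::V(bg)$name <- genes
  bg_edges <- igraph::as_data_frame(bg, what = "edges")
  hub_edges <- do.call(rbind, lapply(driver_genes, function(g) {
    partners <- sample(setdiff(genes, g), cfg$driver_extra_degree)
    data.frame(from = g, to = partners, stringsAsFactors = FALSE)
  }))
  edges <- rbind(bg_edges, hub_edges)
  edges$score <- stats::runif(nrow(edges), 0.5, 1)
  names(edges) <- c("gene_a", "gene_b", "score")
  network <- suppressWarnings(interaction_network(edges))

  passenger_pathways <- lapply(passengers, function(pg)
    names(pw)[vapply(pw, function(g)
      length(intersect(g, pg)) > 0, logical(1))])
  names(passengers) <- cohort_names
  names(passenger_pathways) <- cohort_names

  structure(
    list(cohorts = cohorts, pathways = pathways, network = network,
         truth = list(driver_pathways = driver_ids,
                      driver_genes = driver_genes,
                      driver_signs = driver_signs,
                      passenger_genes = passengers,
                      passenger_pathways = passenger_pathways),
         config = cfg),
    class = "SimulatedStudy")
}

#' Write a simulated study to disk in the pipeline's input formats
#'
#' Emits one expression TSV per cohort (CLASS label row convention), the
#' pathway collection as GMT, the interaction network as an edge-list
#' TSV, and a ground-truth manifest TSV.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "SimulatedStudy"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in names(study$cohorts)) {
    ds <- study$cohorts[[nm]]
    p <- file.path(dir, paste0(nm, ".tsv"))
    header <- c("GENE", ds$sample_ids)
    class_row <- c("CLASS", ds$labels)
    body <- cbind(ds$gene_ids,
                  format(ds$values, trim = TRUE, digits = 8))
    con <- file(p, "w")
    writeLines(paste(header, collapse = "\t"), con)
    writeLines(paste(class_row, collapse = "\t"), con)
    writeLines(apply(body, 1, paste, collapse = "\t"), con)
    close(con)
    paths[nm] <- p
  }
  gmt <- file.path(dir, "pathways.gmt")
  writeLines(vapply(names(study$pathways$pathways), function(id)
    paste(c(id, "simulated", study$pathways$pathways[[id]]),
          collapse = "\t"), character(1)), gmt)
  paths["gmt"] <- gmt
  net <- file.path(dir, "network.tsv")
  ed <- igraph::as_data_frame(study$network$graph, what = "edges")
  utils::write.table(
    data.frame(gene_a = ed$from, gene_b = ed$to,
               score = round(ed$score, 4)),
    net, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["network"] <- net
  truth <- file.path(dir, "truth.tsv")
  tr <- rbind(
    data.frame(kind = "driver_pathway",
               id = study$truth$driver_pathways, cohort = "all",
               sign = NA, stringsAsFactors = FALSE),
    data.frame(kind = "driver_gene", id = study$truth$driver_genes,
               cohort = "all",
               sign = study$truth$driver_signs[study$truth$driver_genes],
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(names(study$truth$passenger_genes), function(nm)
      data.frame(kind = "passenger_gene",
                 id = study$truth$passenger_genes[[nm]], cohort = nm,
                 sign = NA, stringsAsFactors = FALSE))))
  utils::write.table(tr, truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- truth
  invisible(paths)
}
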