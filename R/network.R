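#' Construct a gene interaction network
#'
#' Undirected gene graph with optional per-edge confidence scores in
#' \[0, 1\]. Self-loops are dropped with a warning and duplicate edges
#' (in either orientation) collapsed, keeping the maximum score.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b` and
#'   optionally `score`.
#' @return Object of class `InteractionNetwork` wrapping an
#'   [igraph::graph] (element `graph`).
#' @export
interaction_network <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  names(edges)[1:2] <- c("gene_a", "gene_b")
  loops <- edges$gene_a == edges$gene_b
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if ("score" %in% names(edges)) {
    g <- igraph::simplify(g, edge.attr.comb = list(score = "max"))
  } else {
    g <- igraph::simplify(g)
  }
  structure(list(graph = g), class = "InteractionNetwork")
}

#' @export
print.InteractionNetwork <- function(x, ...) {
  cat(sprintf("InteractionNetwork: %d nodes, %d edges%s\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              if ("score" %in% igraph::edge_attr_names(x$graph))
                " (scored)" else ""))
  invisible(x)
}

#' Read a gene-gene interaction edge list
#'
#' Tab-separated file with columns gene_a, gene_b and optionally a
#' confidence score in \[0, 1\] (the common export format of interaction
#' databases). Edges below `min_confidence` are dropped; the graph is
#' undirected and deduplicated.
#'
#' @param path Path to the edge-list TSV (no header row required; a
#'   header line starting with "gene" is skipped).
#' @param min_confidence Minimum edge score kept (default 0).
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path, min_confidence = 0) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && grepl("^gene", lines[1], ignore.case = TRUE))
    lines <- lines[-1]
  if (!length(lines)) stop("no edges in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) stop("malformed edge at line ", bad[1])
  has_score <- lengths(parts) >= 3
  score <- rep(NA_real_, length(parts))
  score[has_score] <- suppressWarnings(
    as.numeric(vapply(parts[has_score], `[[`, character(1), 3)))
  if (any(has_score & is.na(score)))
    stop("malformed edge score at line ", which(has_score & is.na(score))[1])
  edges <- data.frame(
    gene_a = vapply(parts, `[[`, character(1), 1),
    gene_b = vapply(parts, `[[`, character(1), 2),
    stringsAsFactors = FALSE)
  if (any(has_score)) {
    score[!has_score] <- 1
    edges$score <- score
    edges <- edges[edges$score >= min_confidence, , drop = FALSE]
  }
  if (!nrow(edges)) stop("no edges left after confidence filtering")
  interaction_network(edges)
}

#' Induced subnetwork on a gene set
#'
#' @param net An [interaction_network()].
#' @param genes Character vector; the subnetwork keeps these nodes (those
#'   present in the network) and the edges with both endpoints among
#'   them.
#' @return An `InteractionNetwork`.
#' @export
induced_subnetwork <- function(net, genes) {
  stopifnot(inherits(net, "InteractionNetwork"))
  keep <- intersect(as.character(genes),
                    igraph::V(net$graph)$name)
  g <- igraph::induced_subgraph(net$graph, keep)
  structure(list(graph = g), class = "InteractionNetwork")
}

#' Hub genes of an interaction network
#'
#' Nodes ranked by degree — confidence-weighted degree (strength) when
#' edge scores are present — with ties broken by weighted degree and
#' then gene symbol.
#'
#' @param net An [interaction_network()].
#' @param n_hubs Number of top-connected genes returned (default 20).
#' @return data.frame: gene, degree, weighted_degree, ranked.
#' @export
hub_genes <- function(net, n_hubs = 20) {
  stopifnot(inherits(net, "InteractionNetwork"))
  g <- net$graph
  if (igraph::vcount(g) == 0) stop("empty network")
  deg <- igraph::degree(g)
  wdeg <- if ("score" %in% igraph::edge_attr_names(g))
    igraph::strength(g, weights = igraph::E(g)$score) else deg
  ord <- order(-wdeg, -deg, names(deg))
  top <- head(ord, n_hubs)
  data.frame(gene = names(deg)[top], degree = as.integer(deg[top]),
             weighted_degree = as.numeric(wdeg[top]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Driver genes: hubs that are also common markers
#'
#' The highly connected genes of the core-module subnetwork that also
#' belong to the common marker set are called driver genes.
#'
#' @param hubs Character vector of hub genes (or the data.frame from
#'   [hub_genes()]).
#' @param common Character vector of common marker genes.
#' @return Sorted character vector of driver genes.
#' @export
driver_genes <- function(hubs, common) {
  if (is.data.frame(hubs)) hubs <- hubs$gene
  sort(intersect(as.character(hubs), as.character(common)))
}

#' Per-gene regulation direction across cohorts
#'
#' "up" when the gene's t-score is positive in every cohort, "down" when
#' negative in every cohort, "contradictory" otherwise (a zero t-score in
#' any cohort counts as contradictory — no direction).
#'
#' @param genes Character vector of genes to annotate.
#' @param per_cohort_stats Named list of [gene_stats()] data.frames, one
#'   per cohort.
#' @return Named character vector over `genes` with values in
#'   up/down/contradictory (NA for genes absent from some cohort).
#' @export
annotate_regulation <- function(genes, per_cohort_stats) {
  vapply(as.character(genes), function(g) {
    t <- vapply(per_cohort_stats, function(st)
      if (g %in% rownames(st)) st[g, "tscore"] else NA_real_, numeric(1))
    if (anyNA(t)) return(NA_character_)
    if (all(t > 0)) "up" else if (all(t < 0)) "down" else "contradictory"
  }, character(1))
}
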