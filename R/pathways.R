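#' Construct a pathway collection
#'
#' @param pathways Named list; each element a character vector of gene
#'   symbols belonging to one pathway (names are pathway ids).
#' @param descriptions Optional named character vector of descriptions.
#' @return Object of class `PathwayCollection` with elements `pathways`,
#'   `descriptions` and `universe` (union of all member genes).
#' @export
pathway_collection <- function(pathways, descriptions = NULL) {
  if (is.null(names(pathways)) || any(names(pathways) == ""))
    stop("every pathway needs an id")
  if (anyDuplicated(names(pathways)))
    stop("duplicate pathway ids: ",
         paste(unique(names(pathways)[duplicated(names(pathways))]),
               collapse = ", "))
  pathways <- lapply(pathways, function(g) unique(as.character(g)))
  if (any(lengths(pathways) == 0)) stop("empty pathway gene set")
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(pathways)), names(pathways))
  structure(
    list(pathways = pathways, descriptions = descriptions,
         universe = unique(unlist(pathways, use.names = FALSE))),
    class = "PathwayCollection")
}

#' @export
print.PathwayCollection <- function(x, ...) {
  cat(sprintf("PathwayCollection: %d pathways, %d genes in universe\n",
              length(x$pathways), length(x$universe)))
  invisible(x)
}

#' Parse a GMT gene-set file
#'
#' One gene set per line: id, description, then one or more gene symbols,
#' tab-separated (the MSigDB convention). Duplicate genes within a line
#' are deduplicated.
#'
#' @param path Path to the GMT file.
#' @param case_fold Fold gene symbols to upper case before matching
#'   (default FALSE; matching is exact and case-sensitive).
#' @return A [pathway_collection()].
#' @export
read_gmt <- function(path, case_fold = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("no gene sets in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short))
    stop("malformed GMT record (fewer than 3 fields) at line ", short[1])
  ids <- vapply(fields, `[[`, character(1), 1)
  desc <- vapply(fields, `[[`, character(1), 2)
  genes <- lapply(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (case_fold) g <- toupper(g)
    unique(g)
  })
  names(genes) <- ids
  pathway_collection(genes, stats::setNames(desc, ids))
}

#' Filter a pathway collection against a shared gene universe
#'
#' Intersects every pathway with the genes shared by all cohorts under
#' study and drops pathways whose surviving membership falls outside
#' `[min_size, max_size]`. This removes "bulky" catch-all pathways (for
#' example multi-hundred-gene disease super-pathways) that blur
#' submodule-level signal, and pathways too small to aggregate.
#'
#' @param pc A [pathway_collection()].
#' @param shared_genes Character vector: intersection of the gene
#'   universes of all cohorts.
#' @param min_size,max_size Bounds on post-intersection pathway size
#'   (defaults 5 and 200).
#' @return The filtered [pathway_collection()]; a per-pathway report
#'   data.frame (pathway_id, original_size, filtered_size, kept) is
#'   attached as attribute `"filter_report"`.
#' @export
filter_pathways <- function(pc, shared_genes, min_size = 5, max_size = 200) {
  stopifnot(inherits(pc, "PathwayCollection"))
  shared_genes <- unique(as.character(shared_genes))
  if (!length(shared_genes)) stop("empty shared gene set")
  trimmed <- lapply(pc$pathways, function(g) intersect(g, shared_genes))
  sizes <- lengths(trimmed)
  keep <- sizes >= min_size & sizes <= max_size
  report <- data.frame(
    pathway_id = names(pc$pathways),
    original_size = lengths(pc$pathways),
    filtered_size = sizes,
    kept = keep,
    row.names = NULL, stringsAsFactors = FALSE)
  if (!any(keep))
    warning("no pathways survive filtering")
  out <- pathway_collection(trimmed[keep], pc$descriptions[keep])
  attr(out, "filter_report") <- report
  out
}
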