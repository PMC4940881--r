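# Typed genetic-interaction networks: construction, BFS distance shells
# around a focal gene, shortest-path enumeration, and shell-conditioned
# annotation enrichment. Graph machinery is backed by igraph; edges are
# undirected and unweighted (interaction-type labels never weight edges).

#' Build a simple undirected interaction network from an edge list
#'
#' Self-loops are dropped; parallel edges (in either orientation) are
#' merged into one edge carrying the union of their interaction-type
#' labels (semicolon-joined, sorted).
#'
#' @param edges an `InteractionEdgeList` data.frame (`gene_a`, `gene_b`,
#'   optional `interaction_type`).
#' @return igraph object of class `InteractionNetwork` with edge
#'   attribute `types`.
#' @export
build_network <- function(edges) {
  stopifnot(is.data.frame(edges))
  a <- toupper(as.character(edges$gene_a))
  b <- toupper(as.character(edges$gene_b))
  types <- if ("interaction_type" %in% names(edges)) {
    as.character(edges$interaction_type)
  } else rep("other", length(a))
  nodes <- sort(unique(c(a, b)))
  loop <- a == b
  a2 <- a[!loop]; b2 <- b[!loop]; t2 <- types[!loop]
  lo <- pmin(a2, b2); hi <- pmax(a2, b2)
  key <- paste(lo, hi, sep = "\r")
  merged <- if (length(key)) {
    tapply(t2, key, function(x) paste(sort(unique(x)), collapse = ";"))
  } else {
    setNames(character(0), character(0))
  }
  pairs <- strsplit(names(merged), "\r", fixed = TRUE)
  el <- cbind(vapply(pairs, `[`, "", 1L), vapply(pairs, `[`, "", 2L))
  g <- igraph::graph_from_data_frame(
    data.frame(from = el[, 1], to = el[, 2],
               types = as.character(merged), stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  class(g) <- unique(c("InteractionNetwork", class(g)))
  g
}

as_network <- function(g) {
  stopifnot(inherits(g, "igraph"))
  g
}

#' Subnetwork induced by a gene set
#'
#' @param network an `InteractionNetwork`.
#' @param gene_set character vector of genes to retain.
#' @return induced subgraph (nodes = network intersect gene_set, edges
#'   with both endpoints retained).
#' @export
induce_subnetwork <- function(network, gene_set) {
  g <- as_network(network)
  keep <- intersect(igraph::V(g)$name, toupper(gene_set))
  sub <- igraph::induced_subgraph(g, keep)
  class(sub) <- unique(c("InteractionNetwork", class(sub)))
  sub
}

#' Connected component containing a focal gene
#'
#' @param network an `InteractionNetwork`.
#' @param focal focal gene id (must be a node).
#' @return the maximal connected subgraph containing `focal`.
#' @export
connected_component <- function(network, focal) {
  g <- as_network(network)
  focal <- toupper(focal)
  if (!focal %in% igraph::V(g)$name) {
    abort_cf("focal gene %s absent from network", focal)
  }
  comp <- igraph::components(g)
  keep <- igraph::V(g)$name[comp$membership ==
                              comp$membership[[focal]]]
  induce_subnetwork(g, keep)
}

#' Breadth-first distance shells around a focal gene
#'
#' @param network an `InteractionNetwork`.
#' @param focal focal gene id.
#' @return list of class `ShellDecomposition`: `focal`, `shells` (named
#'   list, distance as character -> sorted node set), `eccentricity`
#'   (max populated distance), `unreachable` (nodes in other components).
#' @export
bfs_shells <- function(network, focal) {
  g <- as_network(network)
  focal <- toupper(focal)
  if (!focal %in% igraph::V(g)$name) {
    abort_cf("focal gene %s absent from network", focal)
  }
  d <- igraph::distances(g, v = focal)[1, ]
  finite <- d[is.finite(d) & d > 0]
  shells <- lapply(split(names(finite), finite), sort)
  structure(list(
    focal = focal,
    shells = shells,
    eccentricity = if (length(finite)) as.integer(max(finite)) else 0L,
    unreachable = sort(names(d)[!is.finite(d)])
  ), class = "ShellDecomposition")
}

#' All shortest paths between two genes
#'
#' Enumerates every distinct shortest path, returned in lexicographic
#' order of the node sequences, truncated (with a flag) at `max_paths`.
#'
#' @param network an `InteractionNetwork`.
#' @param source,target gene ids in the same component.
#' @param max_paths truncation bound (default 10000).
#' @return list of class `PathSet`: `source`, `target`, `length` (graph
#'   distance), `paths` (list of node-id vectors), `truncated` flag.
#' @export
all_shortest_paths_between <- function(network, source, target,
                                       max_paths = 10000L) {
  g <- as_network(network)
  source <- toupper(source); target <- toupper(target)
  for (v in c(source, target)) {
    if (!v %in% igraph::V(g)$name) {
      abort_cf("gene %s absent from network", v)
    }
  }
  d <- igraph::distances(g, v = source, to = target)[1, 1]
  if (!is.finite(d)) {
    abort_cf("gene %s present but disconnected from %s", target, source)
  }
  sp <- igraph::all_shortest_paths(g, from = source, to = target)$vpaths
  paths <- lapply(sp, function(p) igraph::V(g)$name[as.integer(p)])
  keys <- vapply(paths, paste, "", collapse = "\r")
  paths <- paths[order(keys)]
  truncated <- length(paths) > max_paths
  if (truncated) paths <- paths[seq_len(max_paths)]
  structure(list(source = source, target = target,
                 length = as.integer(d), paths = paths,
                 truncated = truncated),
            class = "PathSet")
}

#' Shell-conditioned annotation enrichment
#'
#' Tests over-representation of a term among the genes of one distance
#' shell against an explicit background population (which need not
#' contain the shell: the classic recipe tests a subnetwork shell against
#' a complete-network shell population). Delegates to
#' [hypergeom_upper_tail()].
#'
#' @param shell_genes genes of the tested shell (sample, n).
#' @param background_genes background population (N).
#' @param annotation named list gene -> terms.
#' @param term annotation term to test.
#' @param include_observed tail convention, see [hypergeom_upper_tail()].
#' @return one-row `EnrichmentResult` data.frame.
#' @export
shell_enrichment <- function(shell_genes, background_genes, annotation,
                             term, include_observed = TRUE) {
  if (!length(background_genes)) abort_cf("empty background population")
  shell_genes <- unique(toupper(shell_genes))
  background_genes <- unique(toupper(background_genes))
  has_term <- function(genes) {
    sum(vapply(genes, function(gn) {
      term %in% (annotation[[gn]] %||% character(0))
    }, logical(1)))
  }
  N <- length(background_genes)
  K <- has_term(background_genes)
  n <- length(shell_genes)
  k <- has_term(shell_genes)
  # population and sample may be disjoint sets; clamp k into test bounds
  k_eff <- min(k, K, n)
  p <- hypergeom_upper_tail(k_eff, n, K, N,
                            include_observed = include_observed)
  new_enrichment_result(term, k, n, K, N, p, 1L, "none", 0.05)
}

#' Export a network as SIF plus an edge-attribute TSV
#'
#' @param network an `InteractionNetwork`.
#' @param sif_path output SIF path (node, relation, node; the relation is
#'   the semicolon-joined type set).
#' @param attr_path optional TSV of edge attributes.
#' @export
write_sif <- function(network, sif_path, attr_path = NULL) {
  g <- as_network(network)
  el <- igraph::as_edgelist(g)
  types <- igraph::E(g)$types %||% rep("other", nrow(el))
  types <- gsub(" ", "_", types)
  lines <- if (nrow(el)) {
    paste(el[, 1], types, el[, 2], sep = "\t")
  } else character(0)
  iso <- setdiff(igraph::V(g)$name, as.vector(el))
  writeLines(c(lines, iso), sif_path)
  if (!is.null(attr_path)) {
    df <- data.frame(gene_a = el[, 1], gene_b = el[, 2], types = types,
                     stringsAsFactors = FALSE)
    write.table(df, attr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(sif_path)
}
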