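# Seeded generators for every input the pipeline consumes, each with
# planted ground truth, so all stages are testable without any download.

#' Specification for a synthetic 2x2 factorial expression experiment
#'
#' Per-gene model on the log2 scale:
#' `log2 x = baseline + a*I[DEL] + b*I[HIGH] + c*I[DEL]*I[HIGH] + eps`,
#' `eps ~ N(0, noise_sd_log2)`; emitted values are linear scale `2^log2x`.
#' Planted classes fix the signs of (a, b, c):
#' * `G1` deletion-only: `a = +/-e`, b = c = 0
#' * `G2` copper-only: `b = +/-e`
#' * `G3.1`-`G3.4` additive, sign pattern (deletion, copper) =
#'   (down,up), (down,down), (up,up), (up,down), `c = 0`
#' * `G4` interaction: a pure crossover — copper response `+e` in one
#'   strain and `-e` in the other (`b = +/-e`, `c = -2b`), the canonical
#'   strain-dependent copper response
#' * `NULL` genes have a = b = c = 0.
#'
#' Default class proportions follow the relative sizes observed in a
#' genome-scale deletion-by-copper study (210 : 733 : 57 : 17 : 22 : 10 :
#' 305 responsive genes out of 5667).
#'
#' @param n_genes number of genes.
#' @param class_proportions named fractions over
#'   `NULL, G1, G2, G3.1, G3.2, G3.3, G3.4, G4`; must sum to 1.
#' @param effect_size_log2 planted effect magnitude `e` (log2 units).
#' @param noise_sd_log2 replicate noise sd (log2 units); >= 0, where 0 is
#'   the exact closed-form limit.
#' @param baseline_log2 baseline log2 expression.
#' @param replicates_per_cell replicates per design cell.
#' @param seed integer seed.
#' @return list of class `FactorialSimSpec`.
#' @export
factorial_sim_spec <- function(n_genes = 5667,
                               class_proportions = NULL,
                               effect_size_log2 = 1.0,
                               noise_sd_log2 = 0.25,
                               baseline_log2 = 10.0,
                               replicates_per_cell = 2L,
                               seed = 1L) {
  classes <- c("NULL", "G1", "G2", "G3.1", "G3.2", "G3.3", "G3.4", "G4")
  if (is.null(class_proportions)) {
    counts <- c(G1 = 210, G2 = 733, G3.1 = 57, G3.2 = 17, G3.3 = 22,
                G3.4 = 10, G4 = 305)
    p <- counts / 5667
    class_proportions <- c("NULL" = 1 - sum(p), p)
  }
  if (is.null(names(class_proportions)) ||
      !setequal(names(class_proportions), classes)) {
    abort_cf("class_proportions must be named over %s",
             paste(classes, collapse = ", "))
  }
  class_proportions <- class_proportions[classes]
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    abort_cf("class proportions must be non-negative and sum to 1")
  }
  if (!is_count(n_genes)) abort_cf("n_genes must be a positive count")
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 < 0) {
    abort_cf("noise_sd_log2 must be >= 0")
  }
  if (!is.numeric(effect_size_log2) || effect_size_log2 <= 0) {
    abort_cf("effect_size_log2 must be > 0")
  }
  if (!is_count(replicates_per_cell) || replicates_per_cell < 2) {
    abort_cf("replicates_per_cell must be >= 2")
  }
  structure(list(
    n_genes = as.integer(n_genes),
    class_proportions = class_proportions,
    effect_size_log2 = effect_size_log2,
    noise_sd_log2 = noise_sd_log2,
    baseline_log2 = baseline_log2,
    replicates_per_cell = as.integer(replicates_per_cell),
    seed = as.integer(seed)
  ), class = "FactorialSimSpec")
}

planted_effects <- function(class, e, sign) {
  # sign = +/-1 randomizes the orientation of classes without a fixed one
  switch(class,
    "NULL" = c(a = 0, b = 0, c = 0),
    "G1"   = c(a = sign * e, b = 0, c = 0),
    "G2"   = c(a = 0, b = sign * e, c = 0),
    "G3.1" = c(a = -e, b =  e, c = 0),
    "G3.2" = c(a = -e, b = -e, c = 0),
    "G3.3" = c(a =  e, b =  e, c = 0),
    "G3.4" = c(a =  e, b = -e, c = 0),
    "G4"   = c(a = 0, b = sign * e, c = -2 * sign * e)
  )
}

#' Simulate a 2x2 factorial expression experiment with planted truth
#'
#' @param spec a [factorial_sim_spec()].
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame gene, planted_class, a, b, c in log2 units).
#' @export
simulate_factorial_expression <- function(spec) {
  stopifnot(inherits(spec, "FactorialSimSpec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_genes
    r <- spec$replicates_per_cell
    classes <- names(spec$class_proportions)
    planted <- sample(classes, n, replace = TRUE,
                      prob = spec$class_proportions)
    signs <- sample(c(-1, 1), n, replace = TRUE)
    eff <- t(mapply(planted_effects, planted,
                    MoreArgs = list(e = spec$effect_size_log2),
                    sign = signs))
    genes <- sprintf("GENE%05d", seq_len(n))
    cells <- design_cells()
    meta <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
      data.frame(sample_id = paste(cells$strain[i], cells$copper[i],
                                   seq_len(r), sep = "_"),
                 strain = cells$strain[i], copper = cells$copper[i],
                 replicate = seq_len(r), stringsAsFactors = FALSE)
    }))
    idel <- as.numeric(meta$strain == "DEL")
    ihigh <- as.numeric(meta$copper == "HIGH")
    mu <- spec$baseline_log2 +
      outer(eff[, "a"], idel) + outer(eff[, "b"], ihigh) +
      outer(eff[, "c"], idel * ihigh)
    eps <- matrix(rnorm(n * nrow(meta), sd = spec$noise_sd_log2),
                  nrow = n)
    vals <- 2^(mu + eps)
    dimnames(vals) <- list(genes, meta$sample_id)
    truth <- data.frame(gene = genes, planted_class = planted,
                        a = eff[, "a"], b = eff[, "b"], c = eff[, "c"],
                        stringsAsFactors = FALSE, row.names = NULL)
    list(matrix = expression_matrix(vals, meta), truth = truth)
  })
}

#' Specification for a synthetic genetic-interaction network
#'
#' An Erdos-Renyi graph repaired to connectivity by the smallest number of
#' bridging edges, with a focal node and a binary annotation planted at an
#' elevated rate inside one breadth-first shell of the focal node and at a
#' background rate elsewhere.
#'
#' @param n_nodes node count.
#' @param edge_density ER edge probability.
#' @param focal_gene focal node identifier (defaults to the first node).
#' @param enriched_shell BFS distance (>= 1) whose members receive the
#'   elevated annotation rate.
#' @param annotation_rate_in_shell,annotation_rate_background Bernoulli
#'   rates inside/outside the enriched shell.
#' @param seed integer seed.
#' @return list of class `NetworkSimSpec`.
#' @export
network_sim_spec <- function(n_nodes = 500, edge_density = 0.008,
                             focal_gene = NULL, enriched_shell = 3,
                             annotation_rate_in_shell = 0.8,
                             annotation_rate_background = 0.1,
                             seed = 1L) {
  if (!is_count(n_nodes)) abort_cf("n_nodes must be a positive count")
  if (!is_prob(annotation_rate_in_shell) ||
      !is_prob(annotation_rate_background)) {
    abort_cf("annotation rates must be probabilities in [0, 1]")
  }
  if (!is_count(enriched_shell)) abort_cf("enriched_shell must be >= 1")
  if (n_nodes < enriched_shell + 1) {
    abort_cf("n_nodes must exceed enriched_shell (%d)", enriched_shell)
  }
  structure(list(
    n_nodes = as.integer(n_nodes), edge_density = edge_density,
    focal_gene = focal_gene, enriched_shell = as.integer(enriched_shell),
    annotation_rate_in_shell = annotation_rate_in_shell,
    annotation_rate_background = annotation_rate_background,
    seed = as.integer(seed)
  ), class = "NetworkSimSpec")
}

#' Simulate a connected interaction network with a planted enriched shell
#'
#' @param spec a [network_sim_spec()].
#' @param edges optional explicit edge data.frame (`gene_a`, `gene_b`)
#'   overriding random topology (annotation planting still applies).
#' @param node_names optional character vector of length `n_nodes` to use
#'   as node identifiers instead of the default `NODE####` labels.
#' @return list with `edges` (an `InteractionEdgeList`), `annotation`
#'   (an `AnnotationMap` for term `"planted"`), and `shell_truth` (the
#'   [bfs_shells()] decomposition used when planting).
#' @export
simulate_interaction_network <- function(spec, edges = NULL,
                                         node_names = NULL) {
  stopifnot(inherits(spec, "NetworkSimSpec"))
  if (!is.null(node_names) && length(node_names) != spec$n_nodes) {
    abort_cf("node_names must have length n_nodes (%d)", spec$n_nodes)
  }
  withr::with_seed(spec$seed, {
    nodes <- if (is.null(node_names)) {
      sprintf("NODE%04d", seq_len(spec$n_nodes))
    } else toupper(node_names)
    if (is.null(edges)) {
      g <- igraph::sample_gnp(spec$n_nodes, spec$edge_density,
                              directed = FALSE)
      igraph::V(g)$name <- nodes
      # connectivity repair: bridge successive components with single edges
      comp <- igraph::components(g)
      while (comp$no > 1L) {
        reps <- vapply(seq_len(comp$no),
                       function(i) which(comp$membership == i)[1], 1L)
        g <- igraph::add_edges(g, as.vector(rbind(reps[-length(reps)],
                                                  reps[-1])))
        comp <- igraph::components(g)
      }
      el <- igraph::as_edgelist(g, names = TRUE)
    } else {
      el <- as.matrix(edges[, c("gene_a", "gene_b")])
      nodes <- sort(unique(as.vector(el)))
    }
    itypes <- sample(setdiff(INTERACTION_TYPES, "other"),
                     nrow(el), replace = TRUE)
    edge_list <- data.frame(gene_a = el[, 1], gene_b = el[, 2],
                            interaction_type = itypes,
                            system_type = "genetic",
                            stringsAsFactors = FALSE)
    class(edge_list) <- c("InteractionEdgeList", "data.frame")
    focal <- spec$focal_gene %||% nodes[1]
    net <- build_network(edge_list)
    shells <- bfs_shells(net, focal)
    in_shell <- shells$shells[[as.character(spec$enriched_shell)]] %||%
      character(0)
    rate <- ifelse(nodes %in% in_shell,
                   spec$annotation_rate_in_shell,
                   spec$annotation_rate_background)
    annotated <- nodes[runif(length(nodes)) < rate]
    ann <- annotation_map(annotated, rep("planted", length(annotated)))
    list(edges = edge_list, annotation = ann, shell_truth = shells)
  })
}

#' Simulate TF regulons with one planted enriched regulator
#'
#' Generates `n_tfs` regulons by random sampling of targets, plus a query
#' gene set in which the planted TF's targets are over-represented at the
#' requested overlap fraction. With `planted_overlap = 0` the query is a
#' uniform draw from the gene universe (the null used for false-positive
#' calibration).
#'
#' @param n_tfs number of transcription factors.
#' @param n_genes size of the gene universe.
#' @param planted_tf index (1..n_tfs) or name of the enriched TF.
#' @param planted_overlap fraction of the query drawn from the planted
#'   TF's regulon.
#' @param query_size query gene-set size (default 50).
#' @param regulon_size mean regulon size (default 40).
#' @param seed integer seed.
#' @return list with `regulons` (a `RegulonMap`), `gene_set` (character),
#'   `universe` (character) and `planted_tf` (name).
#' @export
simulate_regulons <- function(n_tfs = 40, n_genes = 1000, planted_tf = 1,
                              planted_overlap = 0.8, query_size = 50,
                              regulon_size = 40, seed = 1L) {
  if (!is_prob(planted_overlap)) abort_cf("planted_overlap must be in [0, 1]")
  tfs <- sprintf("TF%03d", seq_len(n_tfs))
  if (is.character(planted_tf)) {
    if (!planted_tf %in% tfs) abort_cf("planted_tf not among the %d TFs", n_tfs)
  } else {
    if (!is_count(planted_tf) || planted_tf > n_tfs) {
      abort_cf("planted_tf not among the %d TFs", n_tfs)
    }
    planted_tf <- tfs[planted_tf]
  }
  withr::with_seed(seed, {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    regulons <- lapply(tfs, function(tf) {
      sort(sample(genes, min(regulon_size, n_genes)))
    })
    names(regulons) <- tfs
    class(regulons) <- "RegulonMap"
    q <- min(query_size, n_genes)
    n_from <- round(q * planted_overlap)
    pool <- regulons[[planted_tf]]
    from_regulon <- sample(pool, min(n_from, length(pool)))
    rest_pool <- if (n_from > 0) setdiff(genes, pool) else genes
    rest <- sample(rest_pool, q - length(from_regulon))
    list(regulons = regulons, gene_set = sort(c(from_regulon, rest)),
         universe = genes, planted_tf = planted_tf)
  })
}

#' Specification for a synthetic qPCR Cq table
#'
#' The generator is the algebraic inverse of the 2^-ddCt method: for a
#' target gene with intended fold change FC (deletant vs reference at a
#' given copper level), the deletant Cq is shifted by `-log2(FC)` cycles
#' relative to the reference. Housekeeping genes sit at a stable Cq with
#' optional jitter.
#'
#' @param targets named list: gene -> named numeric of intended fold
#'   changes per copper level, e.g. `list(SIC1 = c(DEFICIENT = 1.84))`
#'   interpreted as deletant vs reference.
#' @param housekeeping character vector of housekeeping gene names.
#' @param jitter_sd Cq jitter sd (cycles) applied to every measurement.
#' @param base_cq baseline target Cq (default 20).
#' @param housekeeping_cq baseline housekeeping Cq (default 15).
#' @param replicates technical replicates (default 2).
#' @param seed integer seed.
#' @return list of class `CqSimSpec`.
#' @export
cq_sim_spec <- function(targets, housekeeping = c("ARF1", "TDH3", "FBA1"),
                        jitter_sd = 0, base_cq = 20, housekeeping_cq = 15,
                        replicates = 2L, seed = 1L) {
  fcs <- unlist(targets)
  if (any(!is.finite(fcs)) || any(fcs <= 0)) {
    abort_cf("intended fold changes must be positive")
  }
  structure(list(
    targets = targets, housekeeping = toupper(housekeeping),
    jitter_sd = jitter_sd, base_cq = base_cq,
    housekeeping_cq = housekeeping_cq,
    replicates = as.integer(replicates), seed = as.integer(seed)
  ), class = "CqSimSpec")
}

#' Simulate a qPCR Cq table consistent with intended fold changes
#'
#' @param spec a [cq_sim_spec()].
#' @return a `CqTable` data.frame covering both strains at every copper
#'   level named in the intended fold changes.
#' @export
simulate_cq_table <- function(spec) {
  stopifnot(inherits(spec, "CqSimSpec"))
  withr::with_seed(spec$seed, {
    coppers <- unique(unlist(lapply(spec$targets, names)))
    rows <- list()
    for (strain in STRAIN_LEVELS) for (cu in coppers) {
      sample_id <- paste(strain, cu, sep = "_")
      for (gene in names(spec$targets)) {
        fc <- spec$targets[[gene]][[cu]]
        cq0 <- spec$base_cq + if (strain == "DEL") -log2(fc) else 0
        for (rep_i in seq_len(spec$replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, strain = strain, copper = cu,
            gene = toupper(gene), replicate = rep_i,
            cq = cq0 + rnorm(1, sd = spec$jitter_sd),
            stringsAsFactors = FALSE)
        }
      }
      for (gene in spec$housekeeping) {
        for (rep_i in seq_len(spec$replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sample_id, strain = strain, copper = cu,
            gene = gene, replicate = rep_i,
            cq = spec$housekeeping_cq + rnorm(1, sd = spec$jitter_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    out$cq <- pmin(pmax(out$cq, 0), 45)
    class(out) <- c("CqTable", "data.frame")
    out
  })
}
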