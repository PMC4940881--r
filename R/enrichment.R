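# Hypergeometric over-representation machinery shared by GO-term,
# TF-regulon and network-shell analyses.

#' Upper-tail hypergeometric probability
#'
#' Exact tail probability for drawing `k` annotated items in a sample of
#' `n` from a population of `N` containing `K` annotated items, computed
#' by log-gamma summation over the tail. The default is the standard
#' over-representation p-value P(X >= k), which includes the observed
#' count. `include_observed = FALSE` gives the strictly-greater tail
#' P(X > k), the convention of legacy `1 - cdf(k)` implementations found
#' in some published analyses.
#'
#' @param k observed annotated count in the sample.
#' @param n sample size.
#' @param K annotated count in the population.
#' @param N population size.
#' @param include_observed include P(X = k) in the tail (default TRUE).
#' @return tail probability in [0, 1].
#' @export
hypergeom_upper_tail <- function(k, n, K, N, include_observed = TRUE) {
  vals <- c(k = k, n = n, K = K, N = N)
  if (any(!is.finite(vals)) || any(vals != floor(vals))) {
    abort_cf("k, n, K, N must be integers")
  }
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > n) {
    abort_cf("bounds violated: need 0 <= K <= N, 0 <= n <= N, 0 <= k <= n")
  }
  lo <- if (include_observed) k else k + 1
  hi <- min(n, K)
  if (lo > hi) return(0)
  j <- lo:hi
  lp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  # sum on the log scale from the largest term for accuracy
  m <- max(lp)
  p <- exp(m) * sum(exp(lp - m))
  min(p, 1)
}

new_enrichment_result <- function(term, k, n, K, N, p, m_tests,
                                  correction, alpha) {
  if (!length(term)) {
    k <- K <- n <- N <- integer(0)
    p <- numeric(0)
  }
  p_adj <- if (correction == "bonferroni") pmin(1, m_tests * p) else p
  out <- data.frame(
    term = term, k = k, n = n, K = K, N = N,
    p = p, p_adj = p_adj, significant = p_adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentResult", "data.frame")
  out
}

#' Term over-representation in a gene set (flat annotation map)
#'
#' One hypergeometric upper-tail test per term with at least one annotated
#' gene in the query set; the universe defaults to all genes supplied.
#' Query genes outside the universe are dropped (their count is recorded
#' in the `"n_dropped"` attribute). No ontology structure is used: the map
#' is flat, so parent terms are only tested if annotated directly.
#'
#' @param gene_set character vector of query genes.
#' @param annotation named list gene -> terms (an `AnnotationMap`).
#' @param universe character vector defining the population.
#' @param correction `"bonferroni"` (m = number of terms tested) or
#'   `"none"`.
#' @param alpha significance level applied to adjusted p-values.
#' @return `EnrichmentResult` data.frame sorted by p (ties by term).
#' @export
enrich_annotation <- function(gene_set, annotation, universe,
                              correction = c("bonferroni", "none"),
                              alpha = 0.05) {
  correction <- match.arg(correction)
  if (!length(universe)) abort_cf("empty universe")
  universe <- unique(toupper(universe))
  gene_set <- unique(toupper(gene_set))
  dropped <- sum(!gene_set %in% universe)
  if (dropped) {
    warning(sprintf("%d query gene(s) outside the universe dropped", dropped))
  }
  gene_set <- intersect(gene_set, universe)
  ann <- annotation[names(annotation) %in% universe]
  if (!length(ann) || !length(gene_set)) {
    out <- new_enrichment_result(character(0), integer(0), integer(0),
                                 integer(0), integer(0), numeric(0), 0L,
                                 correction, alpha)
    attr(out, "n_dropped") <- dropped
    return(out)
  }
  term_genes <- split(rep(names(ann), lengths(ann)),
                      unlist(ann, use.names = FALSE))
  in_set <- lapply(term_genes, intersect, gene_set)
  keep <- lengths(in_set) >= 1L
  terms <- names(term_genes)[keep]
  N <- length(universe); n <- length(gene_set)
  K <- lengths(term_genes)[keep]
  k <- lengths(in_set)[keep]
  p <- vapply(seq_along(k), function(i) {
    hypergeom_upper_tail(k[i], n, K[i], N)
  }, numeric(1))
  out <- new_enrichment_result(terms, unname(k), n, unname(K), N,
                               unname(p), length(terms), correction, alpha)
  attr(out, "n_dropped") <- dropped
  out
}

#' Transcription-factor regulon over-representation
#'
#' The population is restricted to genes with at least one documented
#' regulator (the convention of regulatory-network enrichment): N = such
#' genes within `universe`, n = query genes among them, K and k = each
#' TF's target counts in population and query. TFs with no target in the
#' population are excluded from both the results and the Bonferroni
#' factor m.
#'
#' @param gene_set character vector of query genes.
#' @param regulons named list TF -> target genes (a `RegulonMap`).
#' @param universe transcriptome universe (default: union of all targets).
#' @param alpha Bonferroni-corrected significance level (default 1e-4).
#' @return `EnrichmentResult` data.frame, one row per TF tested.
#' @export
enrich_tfs <- function(gene_set, regulons, universe = NULL, alpha = 1e-4) {
  if (!length(regulons)) abort_cf("empty regulon map")
  regulated <- unique(toupper(unlist(regulons, use.names = FALSE)))
  universe <- if (is.null(universe)) regulated else
    unique(toupper(universe))
  population <- intersect(regulated, universe)
  query <- intersect(unique(toupper(gene_set)), population)
  if (!length(query)) {
    abort_cf("no query gene has a documented regulator in the universe")
  }
  targets_pop <- lapply(regulons, intersect, population)
  keep <- lengths(targets_pop) >= 1L
  targets_pop <- targets_pop[keep]
  N <- length(population); n <- length(query)
  K <- lengths(targets_pop)
  k <- vapply(targets_pop, function(t) length(intersect(t, query)), 1L)
  p <- vapply(seq_along(k), function(i) {
    hypergeom_upper_tail(k[i], n, K[i], N)
  }, numeric(1))
  new_enrichment_result(names(targets_pop), unname(k), n, unname(K), N,
                        unname(p), sum(keep), "bonferroni", alpha)
}

#' Write an enrichment result table as TSV
#' @param res an `EnrichmentResult`.
#' @param path output path.
#' @export
write_enrichment_table <- function(res, path) {
  write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
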