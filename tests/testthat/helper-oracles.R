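# Independent brute-force oracles used to validate the fast
# implementations, plus small fixture builders. Oracles deliberately use
# different algorithms from the code they check.

# all-pairs shortest path lengths by Floyd-Warshall on an adjacency matrix
oracle_floyd_warshall <- function(nodes, edges) {
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a != b) d[a, b] <- d[b, a] <- 1
  }
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

# exhaustive DFS enumeration of all simple paths, filtered to minimal length
oracle_all_shortest_paths <- function(adj, source, target) {
  best <- list(len = Inf, paths = list())
  walk <- function(path) {
    v <- path[length(path)]
    if (length(path) - 1 > best$len) return()
    if (v == target) {
      len <- length(path) - 1
      if (len < best$len) best <<- list(len = len, paths = list(path))
      else if (len == best$len) {
        best$paths[[length(best$paths) + 1]] <<- path
      }
      return()
    }
    for (w in adj[[v]]) {
      if (!w %in% path) walk(c(path, w))
    }
  }
  walk(source)
  best$paths[order(vapply(best$paths, paste, "", collapse = "\r"))]
}

adjacency_list <- function(nodes, edges) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$gene_a[i]; b <- edges$gene_b[i]
    if (a != b) {
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

random_edge_df <- function(n_nodes, p, seed) {
  withr::with_seed(seed, {
    nodes <- sprintf("N%02d", seq_len(n_nodes))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < p
    data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
               stringsAsFactors = FALSE)
  })
}

# explicit balanced 2x2 sum-of-squares decomposition, one gene at a time
oracle_anova_gene <- function(y, strain, copper) {
  cell <- interaction(strain, copper)
  cm <- tapply(y, cell, mean)
  r <- length(y) / 4
  ms <- tapply(y, strain, mean); mc <- tapply(y, copper, mean)
  g <- mean(y)
  ss_s <- 2 * r * sum((ms - g)^2)
  ss_c <- 2 * r * sum((mc - g)^2)
  ss_t <- sum((y - g)^2)
  ss_e <- sum((y - cm[cell])^2)
  ss_i <- ss_t - ss_s - ss_c - ss_e
  df_e <- 4 * (r - 1)
  list(F = c(ss_s, ss_c, ss_i) / (ss_e / df_e),
       p = pf(c(ss_s, ss_c, ss_i) / (ss_e / df_e), 1, df_e,
              lower.tail = FALSE))
}

# adjusted Rand index between two partitions
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# six well-separated interaction archetype profiles over the 4 design cells
archetype_profiles <- function(per_archetype = 20, sd = 0.05, seed = 5) {
  arch <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(1, -1, -1, 1),
                c(-1, 1, 1, -1), c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  withr::with_seed(seed, {
    X <- arch[rep(1:6, each = per_archetype), ] +
      matrix(rnorm(6 * per_archetype * 4, sd = sd), 6 * per_archetype)
    rownames(X) <- sprintf("g%03d", seq_len(nrow(X)))
    list(profiles = X, truth = rep(1:6, each = per_archetype))
  })
}

# a tiny balanced 2x2 ExpressionMatrix from explicit per-cell values
# cells: list(RD=, DD=, RH=, DH=) each a genes x r matrix (linear scale)
matrix_from_cells <- function(cells, genes = NULL) {
  r <- ncol(cells$RD)
  genes <- genes %||% sprintf("G%d", seq_len(nrow(cells$RD)))
  vals <- cbind(cells$RD, cells$DD, cells$RH, cells$DH)
  meta <- data.frame(
    sample_id = c(paste0("REF_DEFICIENT_", 1:r), paste0("DEL_DEFICIENT_", 1:r),
                  paste0("REF_HIGH_", 1:r), paste0("DEL_HIGH_", 1:r)),
    strain = rep(c("REF", "DEL", "REF", "DEL"), each = r),
    copper = rep(c("DEFICIENT", "DEFICIENT", "HIGH", "HIGH"), each = r),
    replicate = rep(1:r, 4), stringsAsFactors = FALSE)
  colnames(vals) <- meta$sample_id
  rownames(vals) <- genes
  expression_matrix(vals, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
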