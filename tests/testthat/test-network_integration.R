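# Graph machinery against brute-force oracles: duplicate-edge merging,
# induced subgraphs, components, BFS shells, shortest-path enumeration.

test_that("network construction merges duplicates and drops self-loops", {
  edges <- data.frame(
    gene_a = c("a", "b", "c"), gene_b = c("b", "a", "c"),
    interaction_type = c("negative genetic", "synthetic lethal",
                         "positive genetic"),
    stringsAsFactors = FALSE)
  g <- build_network(edges)
  expect_equal(igraph::gsize(g), 1)           # one A-B edge
  expect_true("C" %in% igraph::V(g)$name)          # loop node retained
  expect_identical(igraph::E(g)$types,
                   "negative genetic;synthetic lethal")
})

test_that("edge count equals the number of distinct unordered pairs", {
  withr::with_seed(31, {
    nodes <- sprintf("N%02d", 1:15)
    a <- sample(nodes, 1000, replace = TRUE)
    b <- sample(nodes, 1000, replace = TRUE)
    edges <- data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
    g <- build_network(edges)
    keep <- a != b
    key <- unique(paste(pmin(toupper(a[keep]), toupper(b[keep])),
                        pmax(toupper(a[keep]), toupper(b[keep]))))
    expect_equal(igraph::gsize(g), length(key))
  })
})

test_that("induced subnetworks match a brute-force edge filter", {
  tri <- data.frame(gene_a = c("a", "b", "c"), gene_b = c("b", "c", "a"),
                    stringsAsFactors = FALSE)
  g <- build_network(tri)
  sub <- induce_subnetwork(g, c("a", "b"))
  expect_identical(sort(igraph::V(sub)$name), c("A", "B"))
  expect_equal(igraph::gsize(sub), 1)
  expect_equal(igraph::gsize(induce_subnetwork(g, "z")), 0)
  for (seed in 1:10) {
    edges <- random_edge_df(20, 0.2, seed)
    g <- build_network(edges)
    keep <- sprintf("N%02d", 1:10)
    sub <- induce_subnetwork(g, keep)
    manual <- edges[edges$gene_a %in% keep & edges$gene_b %in% keep, ]
    expect_equal(igraph::gsize(sub), nrow(manual))
  }
})

test_that("connected component isolates the focal gene's component", {
  two_tri <- data.frame(
    gene_a = c("a", "b", "c", "x", "y", "z"),
    gene_b = c("b", "c", "a", "y", "z", "x"), stringsAsFactors = FALSE)
  g <- build_network(two_tri)
  comp <- connected_component(g, "a")
  expect_setequal(igraph::V(comp)$name, c("A", "B", "C"))
  solo <- build_network(data.frame(gene_a = "q", gene_b = "q",
                                   stringsAsFactors = FALSE))
  comp1 <- connected_component(solo, "q")
  expect_identical(igraph::V(comp1)$name, "Q")
  expect_equal(igraph::gsize(comp1), 0)
  expect_error(connected_component(g, "nope"), "absent")
})

test_that("BFS shells match fixtures and Floyd-Warshall on random graphs", {
  path <- data.frame(gene_a = c("A", "B", "C"), gene_b = c("B", "C", "D"),
                     stringsAsFactors = FALSE)
  sh <- bfs_shells(build_network(path), "A")
  expect_identical(sh$shells, list(`1` = "B", `2` = "C", `3` = "D"))
  expect_identical(sh$eccentricity, 3L)
  star <- data.frame(gene_a = "HUB", gene_b = sprintf("L%d", 1:6),
                     stringsAsFactors = FALSE)
  sh2 <- bfs_shells(build_network(star), "HUB")
  expect_identical(sh2$eccentricity, 1L)
  expect_setequal(sh2$shells[["1"]], sprintf("L%d", 1:6))
  for (seed in 1:15) {
    edges <- random_edge_df(25, 0.12, seed)
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    g <- build_network(edges)
    fw <- oracle_floyd_warshall(nodes, edges)
    focal <- nodes[1]
    sh <- bfs_shells(g, focal)
    for (d in names(sh$shells)) {
      expect_setequal(sh$shells[[d]],
                      nodes[is.finite(fw[focal, ]) &
                              fw[focal, ] == as.numeric(d)])
    }
    expect_setequal(sh$unreachable, nodes[!is.finite(fw[focal, ])])
  }
})

test_that("shells partition the component and paths climb the shells", {
  sim <- simulate_interaction_network(
    network_sim_spec(n_nodes = 80, edge_density = 0.04, seed = 3))
  g <- build_network(sim$edges)
  sh <- bfs_shells(g, "NODE0001")
  all_nodes <- c(sh$focal, unlist(sh$shells, use.names = FALSE))
  expect_identical(anyDuplicated(all_nodes), 0L)
  expect_setequal(all_nodes, igraph::V(g)$name)  # connected by design
  far <- sh$shells[[as.character(sh$eccentricity)]][1]
  ps <- all_shortest_paths_between(g, "NODE0001", far)
  dist_of <- function(v) {
    if (v == sh$focal) 0L else {
      as.integer(names(which(vapply(sh$shells, function(s) v %in% s,
                                    logical(1))))[1])
    }
  }
  for (p in ps$paths) {
    expect_identical(length(p) - 1L, ps$length)
    expect_identical(vapply(p, dist_of, 0L, USE.NAMES = FALSE),
                     seq(0L, ps$length))
  }
})

test_that("shortest-path enumeration matches exhaustive DFS", {
  square <- data.frame(gene_a = c("A", "B", "C", "D"),
                       gene_b = c("B", "C", "D", "A"),
                       stringsAsFactors = FALSE)
  ps <- all_shortest_paths_between(build_network(square), "A", "C")
  expect_identical(ps$paths, list(c("A", "B", "C"), c("A", "D", "C")))
  tree <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "D"),
                     stringsAsFactors = FALSE)
  expect_identical(all_shortest_paths_between(build_network(tree),
                                              "A", "D")$paths,
                   list(c("A", "B", "D")))
  for (seed in 1:15) {
    edges <- random_edge_df(14, 0.25, seed)
    nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
    g <- build_network(edges)
    adj <- adjacency_list(nodes, edges)
    src <- nodes[1]
    reach <- names(which(is.finite(
      oracle_floyd_warshall(nodes, edges)[src, ])))
    tgt <- setdiff(reach, src)
    if (!length(tgt)) next
    tgt <- tgt[length(tgt)]
    expect_identical(all_shortest_paths_between(g, src, tgt)$paths,
                     oracle_all_shortest_paths(adj, src, tgt))
  }
})

test_that("unreachable targets are distinguished from absent ones", {
  two <- data.frame(gene_a = c("A", "X"), gene_b = c("B", "Y"),
                    stringsAsFactors = FALSE)
  g <- build_network(two)
  expect_error(all_shortest_paths_between(g, "A", "Z"), "absent")
  expect_error(all_shortest_paths_between(g, "A", "X"), "disconnected")
  ps <- all_shortest_paths_between(g, "A", "B", max_paths = 1)
  expect_false(ps$truncated)
})

test_that("shell enrichment reproduces the explicit-background recipe", {
  ann <- structure(setNames(lapply(1:50, function(i) "cc"),
                            sprintf("B%02d", 1:50)),
                   class = "AnnotationMap")
  background <- sprintf("B%02d", 1:100)  # 50 annotated of 100
  shell <- sprintf("B%02d", 1:20)        # 20 of them, all annotated
  res <- shell_enrichment(shell, background, ann, "cc")
  expect_identical(c(res$k, res$n, res$K, res$N), c(20L, 20L, 50L, 100L))
  expect_equal(res$p, phyper(19, 50, 50, 20, lower.tail = FALSE),
               tolerance = 1e-12)
  # zero annotated in the shell -> p = 1
  res0 <- shell_enrichment(sprintf("C%02d", 1:10), background, ann, "cc")
  expect_equal(res0$p, 1)
  expect_error(shell_enrichment(shell, character(0), ann, "cc"), "empty")
})

test_that("planted shell enrichment is detected across replicate seeds", {
  hits <- 0L
  for (seed in 1:100) {
    sim <- simulate_interaction_network(
      network_sim_spec(n_nodes = 500, edge_density = 0.008,
                       enriched_shell = 3, seed = seed))
    g <- build_network(sim$edges)
    sh <- sim$shell_truth
    shell3 <- sh$shells[["3"]] %||% character(0)
    if (length(shell3) < 5) next
    res <- shell_enrichment(shell3, igraph::V(g)$name, sim$annotation,
                            "planted")
    if (res$p < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("SIF export writes node-type-node triples", {
  tri <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                    interaction_type = c("negative genetic",
                                         "synthetic lethal"),
                    stringsAsFactors = FALSE)
  g <- build_network(tri)
  p <- tempfile(fileext = ".sif")
  write_sif(g, p)
  lines <- readLines(p)
  expect_identical(length(lines), 2L)
  expect_true(any(grepl("negative_genetic", lines)))
})
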