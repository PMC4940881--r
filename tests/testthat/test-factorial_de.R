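# ANOVA against explicit sums of squares and aov, fold-change closed
# forms, classification rules, baseline normalization, SOM behaviour.

test_that("baseline normalization equalizes sample medians", {
  sim <- simulate_factorial_expression(factorial_sim_spec(n_genes = 40,
                                                          seed = 12))
  m <- sim$matrix
  m$values <- sweep(m$values, 2, runif(8, 0.5, 2), `*`)  # distort scales
  norm <- normalize_to_baseline(m)
  meds <- apply(norm$values, 2, median)
  expect_equal(unname(meds), rep(unname(meds[1]), 8), tolerance = 1e-12)
  expect_true(attr(norm, "baseline_sample") %in% colnames(m$values))
  # an already-median-equal matrix is unchanged
  again <- normalize_to_baseline(norm)
  expect_equal(again$values, norm$values, tolerance = 1e-12)
})

test_that("two-way ANOVA matches the hand sum-of-squares fixture", {
  # log2 cells: REF = {10,12} at both copper levels, DEL = {6,8}
  cells <- list(RD = 2^rbind(c(10, 12)), DD = 2^rbind(c(6, 8)),
                RH = 2^rbind(c(10, 12)), DH = 2^rbind(c(6, 8)))
  m <- matrix_from_cells(cells)
  a <- two_way_anova(m)
  expect_equal(a$F_strain, 16, tolerance = 1e-9)
  expect_equal(a$F_copper, 0, tolerance = 1e-9)
  expect_equal(a$F_interaction, 0, tolerance = 1e-9)
  expect_identical(c(a$df1, a$df2), c(1L, 4L))
  expect_equal(a$p_strain, pf(16, 1, 4, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("two-way ANOVA equals independent oracles on random genes", {
  sim <- simulate_factorial_expression(factorial_sim_spec(n_genes = 30,
                                                          seed = 21))
  m <- sim$matrix
  a <- two_way_anova(m)
  lv <- log2(m$values)
  strain <- m$samples$strain; copper <- m$samples$copper
  for (i in seq_len(nrow(lv))) {
    oracle <- oracle_anova_gene(lv[i, ], strain, copper)
    expect_equal(c(a$F_strain[i], a$F_copper[i], a$F_interaction[i]),
                 oracle$F, tolerance = 1e-9)
    expect_equal(c(a$p_strain[i], a$p_copper[i], a$p_interaction[i]),
                 oracle$p, tolerance = 1e-9)
    # cross-check against stats::aov on the first genes
    if (i <= 5) {
      fit <- summary(aov(lv[i, ] ~ strain * copper))[[1]]
      rn <- trimws(rownames(fit))
      expect_equal(a$F_strain[i], fit[match("strain", rn), "F value"],
                   tolerance = 1e-9)
      expect_equal(a$F_interaction[i],
                   fit[match("strain:copper", rn), "F value"],
                   tolerance = 1e-9)
    }
  }
})

test_that("constant genes are flagged degenerate with p = 1", {
  cells <- list(RD = rbind(c(100, 100)), DD = rbind(c(100, 100)),
                RH = rbind(c(100, 100)), DH = rbind(c(100, 100)))
  a <- two_way_anova(matrix_from_cells(cells))
  expect_true(a$degenerate)
  expect_equal(c(a$p_strain, a$p_copper, a$p_interaction), c(1, 1, 1))
})

test_that("fold changes are ratios of linear cell means with direction", {
  cells <- list(RD = rbind(c(100, 100)), DD = rbind(c(50, 50)),
                RH = rbind(c(80, 80)), DH = rbind(c(80, 80)))
  fc <- compute_fold_changes(matrix_from_cells(cells))
  expect_equal(fc$fc_del_deficient, 2)
  expect_identical(fc$dir_del_deficient, "down")
  expect_equal(fc$fc_del_high, 1)
  expect_identical(fc$dir_del_high, "none")
  # zero-noise G2 gene with b = 1 log2: copper contrast (2, up) in both
  props <- c("NULL" = 0, G1 = 0, G2 = 1, G3.1 = 0, G3.2 = 0, G3.3 = 0,
             G3.4 = 0, G4 = 0)
  sim <- simulate_factorial_expression(
    factorial_sim_spec(n_genes = 1, class_proportions = props,
                       noise_sd_log2 = 0, seed = 2))
  fc2 <- compute_fold_changes(sim$matrix)
  expect_equal(fc2$fc_cu_ref, 2)
  expect_equal(fc2$fc_cu_del, 2)
  expect_identical(fc2$dir_cu_ref, fc2$dir_cu_del)
})

make_cls_inputs <- function(p, fcs) {
  anova <- data.frame(gene = "g", F_strain = 1, F_copper = 1,
                      F_interaction = 1, p_strain = p[1], p_copper = p[2],
                      p_interaction = p[3], df1 = 1L, df2 = 4L,
                      degenerate = FALSE, stringsAsFactors = FALSE)
  fc <- data.frame(
    gene = "g",
    fc_del_deficient = as.numeric(fcs[1]), dir_del_deficient = fcs[5],
    fc_del_high = as.numeric(fcs[2]), dir_del_high = fcs[6],
    fc_cu_ref = as.numeric(fcs[3]), dir_cu_ref = fcs[7],
    fc_cu_del = as.numeric(fcs[4]), dir_cu_del = fcs[8],
    stringsAsFactors = FALSE)
  list(anova = anova, fc = fc)
}

test_that("classification rules fire with the documented precedence", {
  # strain-only significant with a qualifying deletion contrast -> G1
  x <- make_cls_inputs(c(0.01, 0.5, 0.6),
                       c(1.8, 1.1, 1.0, 1.0, "down", "down", "none", "none"))
  expect_identical(classify_genes(x$anova, x$fc)$group, "G1")
  # both mains significant, deletion down / copper up -> G3.1
  x <- make_cls_inputs(c(0.01, 0.02, 0.7),
                       c(1.8, 1.6, 1.7, 1.9, "down", "down", "up", "up"))
  expect_identical(classify_genes(x$anova, x$fc)$group, "G3.1")
  # interaction significant beats everything when any contrast qualifies
  x <- make_cls_inputs(c(0.01, 0.02, 0.03),
                       c(1.8, 1.6, 1.7, 1.9, "down", "down", "up", "up"))
  expect_identical(classify_genes(x$anova, x$fc)$group, "G4")
  # significance without a qualifying contrast stays NS
  x <- make_cls_inputs(c(0.01, 0.5, 0.6),
                       c(1.2, 1.1, 1.0, 1.0, "down", "down", "none", "none"))
  expect_identical(classify_genes(x$anova, x$fc)$group, "NS")
  # strict both-levels G3 gate
  x <- make_cls_inputs(c(0.01, 0.02, 0.7),
                       c(1.8, 1.2, 1.7, 1.9, "down", "down", "up", "up"))
  expect_identical(classify_genes(x$anova, x$fc)$group, "G3.1")
  expect_identical(classify_genes(x$anova, x$fc, g3_gate = "both")$group,
                   "NS")
})

test_that("classification recovers every planted class without noise", {
  spec <- factorial_sim_spec(n_genes = 800, noise_sd_log2 = 0, seed = 42)
  sim <- simulate_factorial_expression(spec)
  cls <- classify_genes(two_way_anova(sim$matrix),
                        compute_fold_changes(sim$matrix))
  merged <- merge(sim$truth, cls, by = "gene")
  non_null <- merged$planted_class != "NULL"
  expect_true(all(merged$planted_class %in%
                    c("NULL", "G1", "G2", "G3.1", "G3.2", "G3.3", "G3.4",
                      "G4")))
  expect_identical(merged$group[non_null], merged$planted_class[non_null])
  expect_true(all(merged$group[!non_null] == "NS"))
})

test_that("groups are disjoint and exhaustive; G3 subgroups sum to G3", {
  sim <- simulate_factorial_expression(factorial_sim_spec(n_genes = 2000,
                                                          seed = 5))
  cls <- classify_genes(two_way_anova(sim$matrix),
                        compute_fold_changes(sim$matrix))
  expect_identical(anyDuplicated(cls$gene), 0L)
  groups <- c("G1", "G2", "G3.1", "G3.2", "G3.3", "G3.4", "G4", "NS")
  expect_true(all(cls$group %in% groups))
  counts <- table(factor(cls$group, levels = groups))
  expect_identical(sum(counts), 2000L)
  g3_total <- sum(counts[c("G3.1", "G3.2", "G3.3", "G3.4")])
  expect_identical(g3_total, sum(grepl("^G3", cls$group)))
})

test_that("SOM assignment is deterministic and groups identical profiles", {
  ap <- archetype_profiles()
  a1 <- som_cluster(ap$profiles, seed = 1)
  a2 <- som_cluster(ap$profiles, seed = 1)
  expect_identical(a1$cluster, a2$cluster)
  # two copies of one profile land in the same cluster
  X <- ap$profiles[c(1, 1, 21, 41, 61, 81, 101), ]
  rownames(X) <- sprintf("p%d", 1:7)
  cl <- som_cluster(X, seed = 2)$cluster
  expect_identical(cl[["p1"]], cl[["p2"]])
  expect_error(som_cluster(ap$profiles[1:4, ]), "smaller grid")
})

test_that("cluster profiles are per-gene z-scores of design-cell means", {
  sim <- simulate_factorial_expression(factorial_sim_spec(n_genes = 10,
                                                          seed = 3))
  pr <- cluster_profiles(sim$matrix)
  expect_equal(unname(rowMeans(pr)), rep(0, 10), tolerance = 1e-12)
  sds <- apply(pr, 1, sd)
  expect_equal(unname(sds), rep(1, 10), tolerance = 1e-12)
  expect_error(cluster_profiles(sim$matrix, "NOPE"), "absent")
})
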