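# Per-gene two-way ANOVA, fold-change contrasts, response-group
# classification, and SOM clustering of interaction-effect genes.

#' Rescale every array to a baseline array of median overall intensity
#'
#' The baseline is the sample whose overall median intensity is the median
#' of the per-sample medians (for an even sample count, the lower of the
#' two middle samples). Every other sample is rescaled multiplicatively so
#' that its median equals the baseline's median.
#'
#' @param x an `ExpressionMatrix`.
#' @return the rescaled `ExpressionMatrix`; attributes `baseline_sample`
#'   and `scale_factors` record what was done.
#' @export
normalize_to_baseline <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (ncol(x$values) < 2L) abort_cf("need >= 2 samples to normalize")
  meds <- apply(x$values, 2, median)
  if (any(meds <= 0)) {
    abort_cf("sample(s) with non-positive median intensity: %s",
             paste(colnames(x$values)[meds <= 0], collapse = ", "))
  }
  ord <- order(meds, colnames(x$values))
  baseline_idx <- ord[ceiling(length(ord) / 2)]  # lower middle when even
  target <- meds[baseline_idx]
  factors <- target / meds
  x$values <- sweep(x$values, 2, factors, `*`)
  attr(x, "baseline_sample") <- colnames(x$values)[baseline_idx]
  attr(x, "scale_factors") <- factors
  x
}

#' Per-gene two-way fixed-effects ANOVA on log2 expression
#'
#' Balanced 2x2 decomposition, vectorized across genes: with r replicates
#' per cell and cell means on log2 values, the strain, copper and
#' interaction sums of squares each carry 1 df and the residual 4(r-1) df;
#' F = MS_effect / MS_error with p from the upper tail of the F
#' distribution. Genes with zero within-cell variance cannot be tested and
#' are flagged degenerate with all p = 1.
#'
#' @param x an `ExpressionMatrix` (balanced, >= 2 replicates per cell).
#' @return data.frame with per-gene F and p for strain, copper and
#'   interaction, the df pair, and a `degenerate` flag.
#' @export
two_way_anova <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  r <- check_balanced(x)
  lv <- log2(x$values)
  n <- 4L * r
  cm <- design_cell_means(x, log2_scale = TRUE)
  m_rd <- cm[, "REF.DEFICIENT"]; m_dd <- cm[, "DEL.DEFICIENT"]
  m_rh <- cm[, "REF.HIGH"];      m_dh <- cm[, "DEL.HIGH"]
  d_strain <- (m_dd + m_dh) / 2 - (m_rd + m_rh) / 2
  d_copper <- (m_rh + m_dh) / 2 - (m_rd + m_dd) / 2
  inter    <- m_dh - m_dd - m_rh + m_rd
  ss_strain <- n * d_strain^2 / 4
  ss_copper <- n * d_copper^2 / 4
  ss_inter  <- r * inter^2 / 4
  # residual: sum over cells of within-cell squared deviations
  fitted <- matrix(0, nrow(lv), ncol(lv))
  cells <- design_cells()
  for (i in seq_len(nrow(cells))) {
    cols <- cell_columns(x, cells$strain[i], cells$copper[i])
    fitted[, cols] <- cm[, paste(cells$strain[i], cells$copper[i], sep = ".")]
  }
  ss_err <- rowSums((lv - fitted)^2)
  df_err <- 4L * (r - 1L)
  ms_err <- ss_err / df_err
  scale2 <- pmax(1, rowMeans(lv)^2)
  degenerate <- ms_err <= .Machine$double.eps * scale2
  # exact closed-form limit for noiseless genes: an effect with positive
  # sum of squares is infinitely significant, one with zero SS is absent
  tol_ss <- 1e-9 * scale2
  f_of <- function(ss) {
    ifelse(degenerate, ifelse(ss > tol_ss, Inf, 0), ss / ms_err)
  }
  p_of <- function(f) {
    ifelse(is.infinite(f), 0,
           ifelse(degenerate, 1, pf(f, 1, df_err, lower.tail = FALSE)))
  }
  f_strain <- f_of(ss_strain); f_copper <- f_of(ss_copper)
  f_inter <- f_of(ss_inter)
  out <- data.frame(
    gene = rownames(lv),
    F_strain = f_strain, F_copper = f_copper, F_interaction = f_inter,
    p_strain = p_of(f_strain), p_copper = p_of(f_copper),
    p_interaction = p_of(f_inter),
    df1 = 1L, df2 = df_err, degenerate = degenerate,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("AnovaResult", "data.frame")
  out
}

#' Four signed fold-change contrasts per gene
#'
#' Ratios of linear-scale design-cell means: deletant vs reference at each
#' copper level, and high vs deficient copper within each strain. Each
#' contrast is stored as a magnitude >= 1 plus the direction of the
#' numerator condition (`up` when the deletant / high-copper mean is
#' larger, `down` when smaller, `none` at exact equality).
#'
#' @param x an `ExpressionMatrix`.
#' @return data.frame with `fc_*` magnitude and `dir_*` direction columns
#'   for the four contrasts.
#' @export
compute_fold_changes <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  check_balanced(x)
  cm <- design_cell_means(x, log2_scale = FALSE)
  if (any(cm <= 0)) abort_cf("non-positive cell mean; sanitize inputs first")
  contrast <- function(num, den) {
    ratio <- num / den
    list(fc = pmax(ratio, 1 / ratio),
         dir = ifelse(ratio > 1, "up", ifelse(ratio < 1, "down", "none")))
  }
  dd <- contrast(cm[, "DEL.DEFICIENT"], cm[, "REF.DEFICIENT"])
  dh <- contrast(cm[, "DEL.HIGH"], cm[, "REF.HIGH"])
  cr <- contrast(cm[, "REF.HIGH"], cm[, "REF.DEFICIENT"])
  cd <- contrast(cm[, "DEL.HIGH"], cm[, "DEL.DEFICIENT"])
  out <- data.frame(
    gene = rownames(cm),
    fc_del_deficient = dd$fc, dir_del_deficient = dd$dir,
    fc_del_high = dh$fc, dir_del_high = dh$dir,
    fc_cu_ref = cr$fc, dir_cu_ref = cr$dir,
    fc_cu_del = cd$fc, dir_cu_del = cd$dir,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("FoldChangeTable", "data.frame")
  out
}

signed_log2 <- function(fc, dir) {
  ifelse(dir == "down", -log2(fc), ifelse(dir == "up", log2(fc), 0))
}

#' Classify genes into factorial response groups
#'
#' Precedence (each gate requires both a significant ANOVA effect and a
#' qualifying fold-change contrast at `fc_threshold`):
#' 1. `G4` — significant interaction and any of the four contrasts at
#'    threshold;
#' 2. `G3` — both main effects significant (interaction not), with a
#'    deletion contrast and a copper contrast at threshold; sub-labelled
#'    by the (deletion, copper) direction pattern: (down,up) G3.1,
#'    (down,down) G3.2, (up,up) G3.3, (up,down) G3.4;
#' 3. `G1` — strain effect only, a deletion contrast at threshold;
#' 4. `G2` — copper effect only, a copper contrast at threshold;
#' 5. otherwise `NS`.
#'
#' Per-factor direction is the sign of the mean of the two same-factor
#' log2 ratios; genes whose two same-factor contrasts disagree in
#' direction are flagged `direction_inconsistent`.
#'
#' @param anova an `AnovaResult`.
#' @param fc a `FoldChangeTable` over the same genes.
#' @param alpha ANOVA significance threshold (default 0.05).
#' @param fc_threshold fold-change gate (default 1.5).
#' @param g3_gate `"either"` (default) lets one qualifying contrast per
#'   factor open the G3 gate; `"both"` requires both copper levels /
#'   both strains.
#' @return data.frame of class `GeneClassification` with `group`,
#'   per-factor directions, `direction_inconsistent` flag and a rationale
#'   string naming the gates that fired.
#' @export
classify_genes <- function(anova, fc, alpha = 0.05, fc_threshold = 1.5,
                           g3_gate = c("either", "both")) {
  g3_gate <- match.arg(g3_gate)
  stopifnot(inherits(anova, "data.frame"), inherits(fc, "data.frame"))
  if (!setequal(anova$gene, fc$gene)) {
    abort_cf("ANOVA and fold-change tables cover different gene sets")
  }
  fc <- fc[match(anova$gene, fc$gene), , drop = FALSE]
  sig_s <- anova$p_strain < alpha
  sig_c <- anova$p_copper < alpha
  sig_i <- anova$p_interaction < alpha

  del_hit <- cbind(fc$fc_del_deficient >= fc_threshold,
                   fc$fc_del_high >= fc_threshold)
  cu_hit <- cbind(fc$fc_cu_ref >= fc_threshold,
                  fc$fc_cu_del >= fc_threshold)
  del_gate <- if (g3_gate == "both") rowSums(del_hit) == 2 else
    rowSums(del_hit) >= 1
  cu_gate <- if (g3_gate == "both") rowSums(cu_hit) == 2 else
    rowSums(cu_hit) >= 1
  any_gate <- rowSums(del_hit) + rowSums(cu_hit) >= 1

  del_lfc <- (signed_log2(fc$fc_del_deficient, fc$dir_del_deficient) +
                signed_log2(fc$fc_del_high, fc$dir_del_high)) / 2
  cu_lfc <- (signed_log2(fc$fc_cu_ref, fc$dir_cu_ref) +
               signed_log2(fc$fc_cu_del, fc$dir_cu_del)) / 2
  del_dir <- ifelse(del_lfc > 0, "up", ifelse(del_lfc < 0, "down", "none"))
  cu_dir <- ifelse(cu_lfc > 0, "up", ifelse(cu_lfc < 0, "down", "none"))
  inconsistent <-
    (fc$dir_del_deficient != fc$dir_del_high &
       fc$dir_del_deficient != "none" & fc$dir_del_high != "none") |
    (fc$dir_cu_ref != fc$dir_cu_del &
       fc$dir_cu_ref != "none" & fc$dir_cu_del != "none")

  group <- rep("NS", nrow(anova))
  rationale <- rep("no gate fired", nrow(anova))

  is_g4 <- sig_i & any_gate
  is_g3 <- !is_g4 & sig_s & sig_c & !sig_i & del_gate & cu_gate
  is_g1 <- !is_g4 & !is_g3 & sig_s & !sig_c & del_gate
  is_g2 <- !is_g4 & !is_g3 & !sig_s & sig_c & cu_gate

  group[is_g4] <- "G4"
  sub <- paste(del_dir, cu_dir, sep = "/")
  g3_label <- c("down/up" = "G3.1", "down/down" = "G3.2",
                "up/up" = "G3.3", "up/down" = "G3.4")[sub]
  g3_label[is.na(g3_label)] <- "G3.1"  # unreachable with nonzero lfc
  group[is_g3] <- g3_label[is_g3]
  group[is_g1] <- "G1"
  group[is_g2] <- "G2"
  rationale[is_g4] <- "interaction significant + contrast gate"
  rationale[is_g3] <- "both main effects significant + both factor gates"
  rationale[is_g1] <- "strain effect only + deletion contrast gate"
  rationale[is_g2] <- "copper effect only + copper contrast gate"

  out <- data.frame(
    gene = anova$gene, group = group,
    del_direction = del_dir, cu_direction = cu_dir,
    direction_inconsistent = inconsistent,
    rationale = rationale,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("GeneClassification", "data.frame")
  out
}

#' Z-scored design-cell profiles for clustering
#'
#' Per-gene profile over the four design-cell means of log2 expression,
#' z-scored within gene (constant profiles map to the zero vector).
#'
#' @param x an `ExpressionMatrix`.
#' @param genes optional subset of gene ids.
#' @return genes x 4 numeric matrix.
#' @export
cluster_profiles <- function(x, genes = NULL) {
  cm <- design_cell_means(x, log2_scale = TRUE)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(cm))
    if (length(missing)) {
      abort_cf("genes absent from matrix: %s",
               paste(head(missing, 5), collapse = ", "))
    }
    cm <- cm[genes, , drop = FALSE]
  }
  mu <- rowMeans(cm)
  sdv <- apply(cm, 1, sd)
  z <- (cm - mu) / ifelse(sdv > 0, sdv, 1)
  z[sdv == 0, ] <- 0
  z
}

#' Self-organizing-map clustering of expression profiles
#'
#' Classic online Kohonen SOM on a rectangular grid: prototype vectors are
#' initialized from randomly sampled data rows, then updated by presenting
#' profiles in random order; the learning rate decays linearly from
#' `learning_rate` to near zero and the Gaussian neighborhood radius
#' shrinks linearly from `radius` to near zero over the epochs. Cluster
#' ids (0-based) are best-matching units under Euclidean distance.
#' Deterministic given the seed.
#'
#' @param profiles numeric matrix (genes x features), e.g.
#'   [cluster_profiles()] of the interaction-group genes.
#' @param grid SOM grid dimensions (default `c(2, 3)` = 6 clusters).
#' @param epochs training epochs (default 500).
#' @param learning_rate initial learning rate (default 0.5).
#' @param radius initial neighborhood radius (default 1.5 grid units).
#' @param seed integer seed.
#' @return list of class `ClusterAssignment`: `cluster` (named integer,
#'   0-based), `centroids` (units x features), `grid`.
#' @export
som_cluster <- function(profiles, grid = c(2, 3), epochs = 500,
                        learning_rate = 0.5, radius = 1.5, seed = 1L) {
  stopifnot(is.matrix(profiles), is.numeric(profiles))
  n_units <- prod(grid)
  if (nrow(profiles) < n_units) {
    abort_cf(paste0("need >= %d profiles for a %dx%d grid; ",
                    "configure a smaller grid"),
             n_units, grid[1], grid[2])
  }
  pos <- as.matrix(expand.grid(row = seq_len(grid[1]),
                               col = seq_len(grid[2])))
  grid_d2 <- as.matrix(dist(pos))^2
  withr::with_seed(seed, {
    w <- profiles[sample.int(nrow(profiles), n_units), , drop = FALSE]
    rownames(w) <- NULL
    total <- epochs * nrow(profiles)
    step <- 0L
    for (ep in seq_len(epochs)) {
      for (i in sample.int(nrow(profiles))) {
        frac <- step / total
        lr <- learning_rate * (1 - frac)
        sigma <- max(radius * (1 - frac), 0.05)
        xi <- profiles[i, ]
        d2 <- rowSums(sweep(w, 2, xi)^2)
        bmu <- which.min(d2)
        h <- exp(-grid_d2[bmu, ] / (2 * sigma^2))
        w <- w + (lr * h) * sweep(-w, 2, xi, `+`)
        step <- step + 1L
      }
    }
    d <- outer(rowSums(profiles^2), rowSums(w^2), `+`) -
      2 * profiles %*% t(w)
    cluster <- max.col(-d, ties.method = "first") - 1L
    names(cluster) <- rownames(profiles)
    structure(list(cluster = cluster, centroids = w, grid = grid),
              class = "ClusterAssignment")
  })
}
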