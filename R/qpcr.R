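# Housekeeping-gene stability ranking and 2^-ddCt relative quantification.

#' Rank candidate housekeeping genes by expression stability
#'
#' Stability score is the coefficient of variation (sd/mean) of
#' linear-scale expression across all arrays; candidates are ranked
#' ascending (most stable first), ties broken lexicographically.
#'
#' @param x an `ExpressionMatrix`.
#' @param candidates character vector of candidate gene ids.
#' @return data.frame of class `StabilityRanking` with `gene` and `cv`,
#'   ordered most stable first.
#' @export
rank_housekeeping_stability <- function(x, candidates) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  candidates <- unique(toupper(candidates))
  missing <- setdiff(candidates, gene_ids(x))
  if (length(missing)) {
    abort_cf("candidate gene(s) absent from matrix: %s",
             paste(missing, collapse = ", "))
  }
  v <- x$values[candidates, , drop = FALSE]
  cv <- apply(v, 1, sd) / rowMeans(v)
  out <- data.frame(gene = candidates, cv = unname(cv),
                    stringsAsFactors = FALSE)
  out <- out[order(out$cv, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("StabilityRanking", "data.frame")
  out
}

condition_label <- function(cond) {
  paste(toupper(cond[["strain"]]), toupper(cond[["copper"]]), sep = ":")
}

mean_cq <- function(cq, gene, cond) {
  rows <- cq[cq$gene == gene &
               cq$strain == toupper(cond[["strain"]]) &
               cq$copper == toupper(cond[["copper"]]), , drop = FALSE]
  if (!nrow(rows)) {
    abort_cf("no Cq measurement for gene %s in condition %s",
             gene, condition_label(cond))
  }
  # technical replicates averaged arithmetically on the Cq scale first,
  # then mean-of-means across biological samples
  per_sample <- tapply(rows$cq, rows$sample, mean)
  mean(per_sample)
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per condition, the target Cq is normalized against the geometric mean
#' of the housekeeping-gene Cq values (`dCq = Cq_target -
#' geomean(Cq_housekeeping)`); the contrast is `ddCq = dCq(A) - dCq(B)`
#' and the fold change `2^-ddCq`, reported with condition A as numerator.
#' Technical replicates are averaged arithmetically on the Cq scale
#' before any delta is formed.
#'
#' @param cq a `CqTable`.
#' @param target_gene gene of interest.
#' @param housekeeping character vector of housekeeping genes.
#' @param condition_a,condition_b named vectors/lists with `strain` and
#'   `copper`, e.g. `c(strain = "DEL", copper = "DEFICIENT")`.
#' @return list of class `QpcrFoldChange`: `gene`, `contrast`,
#'   `delta_cq_a`, `delta_cq_b`, `delta_delta_cq`, `fold_change`.
#' @export
delta_delta_ct <- function(cq, target_gene, housekeeping,
                           condition_a, condition_b) {
  stopifnot(is.data.frame(cq))
  target_gene <- toupper(target_gene)
  housekeeping <- toupper(housekeeping)
  dcq <- function(cond) {
    hk <- vapply(housekeeping, function(g) mean_cq(cq, g, cond), 0)
    if (any(hk <= 0)) {
      abort_cf("non-positive housekeeping Cq breaks the geometric mean")
    }
    geo <- exp(mean(log(hk)))
    mean_cq(cq, target_gene, cond) - geo
  }
  da <- dcq(condition_a)
  db <- dcq(condition_b)
  ddcq <- da - db
  structure(list(
    gene = target_gene,
    contrast = paste(condition_label(condition_a), "vs",
                     condition_label(condition_b)),
    delta_cq_a = da, delta_cq_b = db,
    delta_delta_cq = ddcq,
    fold_change = 2^(-ddcq)
  ), class = "QpcrFoldChange")
}

#' @export
print.QpcrFoldChange <- function(x, ...) {
  cat(sprintf("%s  %s  ddCq = %.3f  FC = %.3f\n",
              x$gene, x$contrast, x$delta_delta_cq, x$fold_change))
  invisible(x)
}
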