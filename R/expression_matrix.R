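#' Expression matrix with 2x2 factorial sample metadata
#'
#' The central container of the pipeline: a gene x sample matrix of
#' linear-scale expression values together with per-sample factorial
#' metadata (strain: reference `REF` vs deletant `DEL`; copper level:
#' `DEFICIENT` vs `HIGH`; replicate index). Values at or below the
#' sanitization floor (1.0 linear units) are clipped to the floor, and the
#' number of clipped cells is recorded in the `"n_clipped"` attribute; model
#' fitting happens on log2 of these values, so non-positive summaries must
#' be removed up front.
#'
#' @param values numeric matrix, genes in rows (rownames = gene identifiers,
#'   uppercased), samples in columns (colnames = sample identifiers).
#' @param samples data.frame with columns `sample_id`, `strain`, `copper`,
#'   `replicate`, one row per column of `values` (matched by `sample_id`).
#' @param clip sanitization floor on the linear scale (default 1.0).
#' @return an object of class `ExpressionMatrix`: list with elements
#'   `values` and `samples`, attribute `n_clipped`.
#' @export
expression_matrix <- function(values, samples, clip = 1.0) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_cf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort_cf("`values` must carry gene rownames and sample colnames")
  }
  rownames(values) <- toupper(rownames(values))
  if (anyDuplicated(rownames(values))) {
    abort_cf("duplicate gene ids: %s",
             paste(unique(rownames(values)[duplicated(rownames(values))]),
                   collapse = ", "))
  }
  req <- c("sample_id", "strain", "copper", "replicate")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    abort_cf("`samples` must be a data.frame with columns %s",
             paste(req, collapse = ", "))
  }
  samples$sample_id <- as.character(samples$sample_id)
  missing_meta <- setdiff(colnames(values), samples$sample_id)
  if (length(missing_meta)) {
    abort_cf("no metadata for sample(s): %s",
             paste(missing_meta, collapse = ", "))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  samples$strain <- toupper(as.character(samples$strain))
  samples$copper <- toupper(as.character(samples$copper))
  if (!all(samples$strain %in% STRAIN_LEVELS)) {
    abort_cf("strain must be one of %s", paste(STRAIN_LEVELS, collapse = "/"))
  }
  if (!all(samples$copper %in% COPPER_LEVELS)) {
    abort_cf("copper must be one of %s", paste(COPPER_LEVELS, collapse = "/"))
  }
  if (anyNA(values)) abort_cf("`values` contains missing entries")
  n_clipped <- sum(values < clip)
  values[values < clip] <- clip
  out <- structure(
    list(values = values, samples = samples),
    class = "ExpressionMatrix",
    n_clipped = n_clipped
  )
  out
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$samples$strain, x$samples$copper)
  print(tab)
  nc <- attr(x, "n_clipped")
  if (!is.null(nc) && nc > 0) cat(sprintf("%d value(s) clipped to floor\n", nc))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(x) rownames(x$values)

design_cells <- function() {
  expand.grid(strain = STRAIN_LEVELS, copper = COPPER_LEVELS,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

cell_columns <- function(x, strain, copper) {
  which(x$samples$strain == strain & x$samples$copper == copper)
}

check_balanced <- function(x, min_reps = 2L) {
  cells <- design_cells()
  ns <- mapply(function(s, cu) length(cell_columns(x, s, cu)),
               cells$strain, cells$copper)
  if (length(unique(ns)) != 1L) {
    abort_cf("unbalanced design: replicate counts %s across cells",
             paste(ns, collapse = "/"))
  }
  if (ns[1] < min_reps) {
    abort_cf("need >= %d replicates per design cell, found %d", min_reps, ns[1])
  }
  as.integer(ns[1])
}

#' Per-gene design-cell means
#'
#' Means of expression over replicates within each of the four design cells,
#' either on the linear scale (for fold changes) or on log2 (for ANOVA and
#' clustering profiles).
#'
#' @param x an `ExpressionMatrix`.
#' @param log2_scale average log2-transformed values instead of linear.
#' @return genes x 4 matrix with columns `REF.DEFICIENT`, `DEL.DEFICIENT`,
#'   `REF.HIGH`, `DEL.HIGH`.
#' @export
design_cell_means <- function(x, log2_scale = FALSE) {
  cells <- design_cells()
  v <- x$values
  if (log2_scale) v <- log2(v)
  out <- sapply(seq_len(nrow(cells)), function(i) {
    cols <- cell_columns(x, cells$strain[i], cells$copper[i])
    rowMeans(v[, cols, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(v),
                dimnames = list(rownames(v),
                                paste(cells$strain, cells$copper, sep = ".")))
  out
}
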