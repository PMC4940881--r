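# Readers/writers for every external format the pipeline touches.
# All readers normalize gene identifiers to uppercase and tolerate CRLF
# line endings and trailing whitespace; all writers are bit-stable.

read_lines_clean <- function(path) {
  x <- readLines(path, warn = FALSE)
  sub("[\r[:space:]]+$", "", x)
}

#' Read a gene x sample expression table
#'
#' Tab-delimited, gene identifier in the first column, one column per
#' sample. Sample metadata comes either from a sidecar TSV (columns
#' `sample_id`, `strain`, `copper`, `replicate`) or, when `metadata` is
#' `NULL`, from sample names following the `STRAIN_COPPER_REP` convention
#' (e.g. `REF_DEFICIENT_1`).
#'
#' @param path expression TSV path.
#' @param metadata optional sidecar TSV path.
#' @return an [expression_matrix()]; values below 1.0 linear units are
#'   clipped and counted in the `"n_clipped"` attribute.
#' @export
read_expression_table <- function(path, metadata = NULL) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 2L) abort_cf("expression table needs >= 1 sample column")
  genes <- toupper(trimws(df[[1]]))
  if (anyDuplicated(genes)) {
    abort_cf("duplicate gene ids in %s: %s", path,
             paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  sample_ids <- names(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort_cf("non-numeric value at gene %s, sample %s",
             genes[bad[1]], sample_ids[bad[2]])
  }
  dimnames(num) <- list(genes, sample_ids)
  if (is.null(metadata)) {
    meta <- parse_sample_names(sample_ids)
  } else {
    meta <- read.delim(metadata, sep = "\t", check.names = FALSE,
                       stringsAsFactors = FALSE, strip.white = TRUE)
  }
  expression_matrix(num, meta)
}

parse_sample_names <- function(sample_ids) {
  parts <- strsplit(sample_ids, "_", fixed = TRUE)
  bad <- sample_ids[vapply(parts, length, 1L) != 3L]
  if (length(bad)) {
    abort_cf("sample(s) lacking metadata (expected STRAIN_COPPER_REP): %s",
             paste(bad, collapse = ", "))
  }
  data.frame(
    sample_id = sample_ids,
    strain = toupper(vapply(parts, `[`, "", 1L)),
    copper = toupper(vapply(parts, `[`, "", 2L)),
    replicate = as.integer(vapply(parts, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

#' Write an expression table (and metadata sidecar)
#' @param x an `ExpressionMatrix`.
#' @param path output TSV path.
#' @param metadata_path optional sidecar TSV path for the sample table.
#' @export
write_expression_table <- function(x, path, metadata_path = NULL) {
  df <- data.frame(gene_id = gene_ids(x), x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

# ---- BioGRID genetic-interaction tables -------------------------------

BIOGRID_SYSTEM_MAP <- c(
  "negative genetic"        = "negative genetic",
  "positive genetic"        = "positive genetic",
  "synthetic lethality"     = "synthetic lethal",
  "synthetic lethal"        = "synthetic lethal",
  "synthetic growth defect" = "synthetic growth defect",
  "dosage lethality"        = "dosage lethality",
  "synthetic rescue"        = "synthetic rescue"
)

biogrid_find_col <- function(nms, candidates) {
  hit <- match(tolower(candidates), tolower(nms))
  hit <- hit[!is.na(hit)]
  if (length(hit)) nms[hit[1]] else NA_character_
}

#' Read a BioGRID TAB 2.0/3.0 interaction table
#'
#' Dialect is detected from header names, not column positions (column
#' order differs between TAB versions). Interactor identifiers prefer the
#' systematic name when present, falling back to the official symbol.
#' Experimental-system strings are case-folded onto the controlled
#' genetic-interaction vocabulary; unknown systems map to `"other"`.
#'
#' @param path BioGRID TAB file.
#' @param organism_filter optional organism (taxid or name); rows where
#'   either interactor fails the filter are dropped.
#' @param genetic_only keep only rows with experimental system type
#'   `"genetic"` (default TRUE).
#' @return data.frame of class `InteractionEdgeList` with columns
#'   `gene_a`, `gene_b`, `interaction_type`, `system_type`.
#' @export
read_biogrid_tab <- function(path, organism_filter = NULL,
                             genetic_only = TRUE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   comment.char = "", stringsAsFactors = FALSE,
                   strip.white = TRUE)
  names(df) <- sub("^#", "", names(df))
  nms <- names(df)
  sys_a <- biogrid_find_col(nms, c("Systematic Name Interactor A"))
  sys_b <- biogrid_find_col(nms, c("Systematic Name Interactor B"))
  sym_a <- biogrid_find_col(nms, c("Official Symbol Interactor A"))
  sym_b <- biogrid_find_col(nms, c("Official Symbol Interactor B"))
  esys  <- biogrid_find_col(nms, c("Experimental System"))
  etype <- biogrid_find_col(nms, c("Experimental System Type"))
  if (is.na(esys) || is.na(etype) ||
      (is.na(sys_a) && is.na(sym_a)) || (is.na(sys_b) && is.na(sym_b))) {
    abort_cf(paste0(
      "unrecognized BioGRID dialect in %s; expected TAB 2.0/3.0 headers ",
      "(Official Symbol/Systematic Name Interactor A/B, Experimental ",
      "System, Experimental System Type)"), path)
  }
  pick_id <- function(sys_col, sym_col) {
    sysv <- if (!is.na(sys_col)) as.character(df[[sys_col]]) else
      rep("-", nrow(df))
    symv <- if (!is.na(sym_col)) as.character(df[[sym_col]]) else
      rep("-", nrow(df))
    out <- ifelse(!is.na(sysv) & nzchar(sysv) & sysv != "-", sysv, symv)
    toupper(trimws(out))
  }
  a <- pick_id(sys_a, sym_a)
  b <- pick_id(sys_b, sym_b)
  keep <- nzchar(a) & nzchar(b) & a != "-" & b != "-"
  if (!is.null(organism_filter)) {
    of <- tolower(as.character(organism_filter))
    org_cols_a <- nms[grepl("^Organism .*A$", nms)]
    org_cols_b <- nms[grepl("^Organism .*B$", nms)]
    org_ok <- function(cols) {
      if (!length(cols)) return(rep(TRUE, nrow(df)))
      Reduce(`|`, lapply(cols, function(cc) {
        tolower(as.character(df[[cc]])) == of
      }))
    }
    keep <- keep & org_ok(org_cols_a) & org_ok(org_cols_b)
  }
  system_type <- tolower(trimws(as.character(df[[etype]])))
  if (genetic_only) keep <- keep & system_type == "genetic"
  sys_str <- tolower(trimws(as.character(df[[esys]])))
  itype <- unname(BIOGRID_SYSTEM_MAP[sys_str])
  itype[is.na(itype)] <- "other"
  out <- data.frame(
    gene_a = a[keep], gene_b = b[keep],
    interaction_type = itype[keep],
    system_type = system_type[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("InteractionEdgeList", "data.frame")
  out
}

#' Write an interaction edge list as TSV
#' @param edges an `InteractionEdgeList` (or compatible data.frame).
#' @param path output path.
#' @export
write_edge_table <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- gene -> term flat maps ------------------------------------------

#' Read a two-column gene-to-term TSV into an annotation map
#'
#' @param path TSV with columns gene, term (no header required; a header
#'   line `gene<TAB>term` is tolerated).
#' @return named list mapping uppercased gene id -> character vector of
#'   terms; genes with no non-empty terms are absent.
#' @export
read_gene_term_map <- function(path) {
  lines <- read_lines_clean(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) && tolower(lines[1]) %in% c("gene\tterm")) {
    lines <- lines[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 1L)
  genes <- toupper(trimws(vapply(parts, `[`, "", 1L)))
  terms <- trimws(vapply(parts, function(p) p[2] %||% NA_character_, ""))
  malformed <- which(!nzchar(genes))
  if (length(malformed)) {
    abort_cf("malformed gene-term row at line %d", malformed[1])
  }
  keep <- !is.na(terms) & nzchar(terms)
  annotation_map(genes[keep], terms[keep])
}

annotation_map <- function(genes, terms) {
  if (!length(genes)) return(structure(list(), class = "AnnotationMap"))
  m <- lapply(split(terms, genes), function(x) sort(unique(x)))
  structure(m[order(names(m))], class = "AnnotationMap")
}

#' Write an annotation map as two-column TSV
#' @param map named list gene -> terms.
#' @param path output path.
#' @export
write_gene_term_map <- function(map, path) {
  genes <- rep(names(map), lengths(map))
  terms <- unlist(map, use.names = FALSE)
  writeLines(paste(genes, terms, sep = "\t"), path)
  invisible(path)
}

# ---- TF -> target regulon tables -------------------------------------

#' Read a transcription-factor target table into a regulon map
#'
#' Accepts tab- or semicolon-separated rows `tf<SEP>target<SEP>evidence`.
#' When `documented_only` is TRUE only pairs whose evidence flag marks
#' documented regulation are retained.
#'
#' @param path input path.
#' @param documented_only keep only documented pairs (default TRUE).
#' @return named list of class `RegulonMap`: TF -> character vector of
#'   target genes (uppercased).
#' @export
read_tf_target_table <- function(path, documented_only = TRUE) {
  lines <- read_lines_clean(path)
  lines <- lines[nzchar(lines)]
  sep <- if (length(lines) && !grepl("\t", lines[1]) &&
             grepl(";", lines[1])) ";" else "\t"
  if (length(lines) && grepl("^tf[;\t]", tolower(lines[1]))) lines <- lines[-1]
  parts <- strsplit(lines, sep, fixed = TRUE)
  nfield <- vapply(parts, length, 1L)
  if (any(nfield < 2L)) {
    abort_cf("malformed TF-target row at line %d", which(nfield < 2L)[1])
  }
  tf <- toupper(trimws(vapply(parts, `[`, "", 1L)))
  target <- toupper(trimws(vapply(parts, `[`, "", 2L)))
  evidence <- tolower(trimws(vapply(parts, function(p) p[3] %||% "", "")))
  documented <- evidence %in% c("documented", "direct", "yes", "true", "1")
  if (documented_only) {
    tf <- tf[documented]; target <- target[documented]
  }
  if (!length(tf)) return(structure(list(), class = "RegulonMap"))
  m <- lapply(split(target, tf), function(x) sort(unique(x)))
  structure(m[order(names(m))], class = "RegulonMap")
}

#' Write a regulon map as a TSV of documented TF-target pairs
#' @param regulons named list TF -> targets.
#' @param path output path.
#' @export
write_tf_target_table <- function(regulons, path) {
  tf <- rep(names(regulons), lengths(regulons))
  target <- unlist(regulons, use.names = FALSE)
  writeLines(c("tf\ttarget\tevidence",
               paste(tf, target, "documented", sep = "\t")), path)
  invisible(path)
}

# ---- qPCR Cq tables ---------------------------------------------------

#' Read a qPCR quantification-cycle (Cq) table
#'
#' CSV with columns `sample`, `strain`, `copper`, `gene`, `replicate`,
#' `cq`. Cq values outside [0, 45] are rejected with the offending line
#' number.
#'
#' @param path CSV path.
#' @return data.frame of class `CqTable`.
#' @export
read_cq_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  req <- c("sample", "strain", "copper", "gene", "replicate", "cq")
  if (!all(req %in% names(df))) {
    abort_cf("Cq table must have columns %s", paste(req, collapse = ", "))
  }
  df$gene <- toupper(df$gene)
  df$strain <- toupper(df$strain)
  df$copper <- toupper(df$copper)
  df$cq <- as.numeric(df$cq)
  bad <- which(is.na(df$cq) | df$cq < 0 | df$cq > 45)
  if (length(bad)) {
    abort_cf("Cq outside [0, 45] at line %d of %s", bad[1] + 1L, path)
  }
  class(df) <- c("CqTable", "data.frame")
  df
}

#' Write a Cq table as CSV
#' @param cq a `CqTable`.
#' @param path output path.
#' @export
write_cq_table <- function(cq, path) {
  utils::write.csv(cq, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
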