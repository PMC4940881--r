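# End-to-end orchestration: normalize -> ANOVA/FC -> classify -> SOM on
# the interaction group -> enrichment -> network shells/paths -> TF
# enrichment -> optional qPCR. Every stage's table is written to disk so
# stages are independently re-runnable; a JSON manifest records config,
# seed and checksums for provenance.

#' Assemble and validate a pipeline configuration
#'
#' Inputs come either from files (`expression`, plus optional
#' `expression_metadata`, `network`, `annotation`, `regulons`, `cq`) or
#' from the seeded synthetic generators (`simulation = TRUE`, using
#' `sim_spec`). Thresholds default to the conventional factorial gates:
#' ANOVA alpha 0.05, fold-change 1.5, GO alpha 0.05, TF Bonferroni alpha
#' 1e-4.
#'
#' @param out_dir output directory for the report bundle.
#' @param seed global seed; all stage seeds derive from it.
#' @param simulation generate all inputs synthetically.
#' @param sim_spec a [factorial_sim_spec()] (defaults to
#'   `factorial_sim_spec(seed = derive_seed(seed, "expression"))`).
#' @param expression,expression_metadata,network,annotation,regulons,cq
#'   input file paths (see the io readers).
#' @param alpha,fc_threshold,g3_gate classification gates, see
#'   [classify_genes()].
#' @param go_alpha,tf_alpha enrichment significance levels.
#' @param som_grid,som_epochs SOM settings, see [som_cluster()].
#' @param focal_gene focal gene for the network stage (default: first
#'   node of the responsive subnetwork's largest component).
#' @return list of class `PipelineConfig`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulation = FALSE,
                            sim_spec = NULL, expression = NULL,
                            expression_metadata = NULL, network = NULL,
                            annotation = NULL, regulons = NULL, cq = NULL,
                            alpha = 0.05, fc_threshold = 1.5,
                            g3_gate = "either", go_alpha = 0.05,
                            tf_alpha = 1e-4, som_grid = c(2, 3),
                            som_epochs = 500, focal_gene = NULL) {
  if (!is_prob(alpha) || alpha <= 0 || alpha >= 1) {
    abort_cf("alpha must lie in (0, 1)")
  }
  if (!is.numeric(fc_threshold) || fc_threshold < 1) {
    abort_cf("fc_threshold must be >= 1")
  }
  if (!simulation && is.null(expression)) {
    abort_cf("either simulation = TRUE or an expression path is required")
  }
  for (p in c(expression, expression_metadata, network, annotation,
              regulons, cq)) {
    if (!is.null(p) && !file.exists(p)) abort_cf("input file not found: %s", p)
  }
  structure(list(
    out_dir = out_dir, seed = as.integer(seed), simulation = simulation,
    sim_spec = sim_spec, expression = expression,
    expression_metadata = expression_metadata, network = network,
    annotation = annotation, regulons = regulons, cq = cq,
    alpha = alpha, fc_threshold = fc_threshold, g3_gate = g3_gate,
    go_alpha = go_alpha, tf_alpha = tf_alpha, som_grid = som_grid,
    som_epochs = som_epochs, focal_gene = focal_gene
  ), class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @param ... overrides taking precedence over the file.
#' @return a `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, ...) {
  cfg <- yaml::read_yaml(path)
  cfg <- modifyList(cfg, list(...))
  do.call(pipeline_config, cfg)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort_cf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full factorial analysis pipeline
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the stage objects and the summary; the
#'   report bundle (TSVs, SIF, `summary.json`, `manifest.json`) is
#'   written to `config$out_dir`. On any stage error the partially
#'   written bundle is removed.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  staging <- file.path(tempfile("bundle"))
  dir.create(staging, recursive = TRUE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)

  truth <- NULL
  mat <- run_stage("input", {
    if (config$simulation) {
      spec <- config$sim_spec %||%
        factorial_sim_spec(seed = derive_seed(config$seed, "expression"))
      sim <- simulate_factorial_expression(spec)
      truth <- sim$truth
      sim$matrix
    } else {
      read_expression_table(config$expression, config$expression_metadata)
    }
  })
  mat <- run_stage("normalize", normalize_to_baseline(mat))
  aov_res <- run_stage("anova", two_way_anova(mat))
  fc <- run_stage("fold_change", compute_fold_changes(mat))
  cls <- run_stage("classify", classify_genes(
    aov_res, fc, alpha = config$alpha, fc_threshold = config$fc_threshold,
    g3_gate = config$g3_gate))

  groups <- split(cls$gene, cls$group)
  g4_genes <- groups[["G4"]] %||% character(0)
  som <- NULL
  if (length(g4_genes) >= prod(config$som_grid)) {
    som <- run_stage("som", som_cluster(
      cluster_profiles(mat, g4_genes), grid = config$som_grid,
      epochs = config$som_epochs, seed = derive_seed(config$seed, "som")))
  }

  responsive <- sort(unlist(groups[setdiff(names(groups), c("NS", "G2"))],
                            use.names = FALSE))

  annotation <- NULL
  if (!is.null(config$annotation)) {
    annotation <- run_stage("annotation", read_gene_term_map(config$annotation))
  }

  net_report <- NULL
  if (!is.null(config$network) ||
      (config$simulation && length(responsive) >= 10)) {
    net_report <- run_stage("network", {
      if (!is.null(config$network)) {
        edges <- read_biogrid_tab(config$network, genetic_only = TRUE)
        net_ann <- annotation
      } else {
        nspec <- network_sim_spec(
          n_nodes = length(responsive),
          enriched_shell = min(3L, max(1L, length(responsive) - 1L)),
          seed = derive_seed(config$seed, "network"))
        nsim <- simulate_interaction_network(nspec, node_names = responsive)
        edges <- nsim$edges
        net_ann <- nsim$annotation
      }
      net <- build_network(edges)
      sub <- induce_subnetwork(net, responsive)
      focal <- toupper(config$focal_gene %||%
                         sort(igraph::V(sub)$name)[1])
      comp <- connected_component(sub, focal)
      shells <- bfs_shells(comp, focal)
      paths <- NULL
      if (shells$eccentricity >= 1) {
        far <- shells$shells[[as.character(shells$eccentricity)]][1]
        paths <- all_shortest_paths_between(comp, focal, far)
      }
      shell_enr <- NULL
      if (!is.null(net_ann) && length(shells$shells)) {
        terms <- unique(unlist(net_ann, use.names = FALSE))
        background <- igraph::V(net)$name
        shell_enr <- do.call(rbind, lapply(names(shells$shells), function(d) {
          res <- shell_enrichment(shells$shells[[d]], background, net_ann,
                                  terms[1])
          res$shell <- as.integer(d)
          res
        }))
      }
      list(network = net, subnetwork = comp, shells = shells,
           paths = paths, shell_enrichment = shell_enr, focal = focal)
    })
  }

  go_enr <- NULL
  if (!is.null(annotation)) {
    go_enr <- run_stage("go_enrichment", {
      universe <- gene_ids(mat)
      do.call(rbind, lapply(names(groups)[names(groups) != "NS"],
                            function(gname) {
        res <- enrich_annotation(groups[[gname]], annotation, universe,
                                 alpha = config$go_alpha)
        if (nrow(res)) res$group <- gname
        res
      }))
    })
  }

  tf_enr <- NULL
  if (!is.null(config$regulons) ||
      (config$simulation && length(responsive) >= 5)) {
    tf_enr <- run_stage("tf_enrichment", {
      regs <- if (!is.null(config$regulons)) {
        read_tf_target_table(config$regulons, documented_only = TRUE)
      } else {
        # simulated regulons share the GENE##### universe of the
        # simulated expression matrix
        simulate_regulons(
          n_genes = nrow(mat$values),
          seed = derive_seed(config$seed, "regulons"))$regulons
      }
      enrich_tfs(responsive, regs, universe = gene_ids(mat),
                 alpha = config$tf_alpha)
    })
  }

  qpcr_report <- NULL
  if (!is.null(config$cq)) {
    qpcr_report <- run_stage("qpcr", {
      cqt <- read_cq_table(config$cq)
      hk <- intersect(c("ARF1", "TDH3", "FBA1"), unique(cqt$gene))
      targets <- setdiff(unique(cqt$gene), hk)
      do.call(rbind, lapply(targets, function(g) {
        r <- delta_delta_ct(cqt, g, hk,
                            c(strain = "DEL", copper = "DEFICIENT"),
                            c(strain = "REF", copper = "DEFICIENT"))
        data.frame(gene = g, contrast = r$contrast,
                   delta_delta_cq = r$delta_delta_cq,
                   fold_change = r$fold_change, stringsAsFactors = FALSE)
      }))
    })
  }

  # ---- write bundle ----------------------------------------------------
  hdr <- sprintf("# alpha=%g fc_threshold=%g seed=%d",
                 config$alpha, config$fc_threshold, config$seed)
  write_tsv_c <- function(df, name) {
    path <- file.path(staging, name)
    con <- file(path, "w")
    writeLines(hdr, con)
    close(con)
    suppressWarnings(
      write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  append = TRUE))
    path
  }
  gene_table <- Reduce(function(a, b) merge(a, b, by = "gene"),
                       list(aov_res, fc, cls))
  gene_table <- gene_table[order(gene_table$gene), , drop = FALSE]
  write_tsv_c(gene_table, "gene_results.tsv")
  if (!is.null(som)) {
    write_tsv_c(data.frame(gene = names(som$cluster),
                           cluster = unname(som$cluster),
                           stringsAsFactors = FALSE), "som_clusters.tsv")
    write_tsv_c(data.frame(unit = seq_len(nrow(som$centroids)) - 1L,
                           som$centroids), "som_centroids.tsv")
  }
  if (!is.null(go_enr) && NROW(go_enr)) write_tsv_c(go_enr, "go_enrichment.tsv")
  if (!is.null(tf_enr) && NROW(tf_enr)) write_tsv_c(tf_enr, "tf_enrichment.tsv")
  if (!is.null(net_report)) {
    write_sif(net_report$subnetwork, file.path(staging, "subnetwork.sif"))
    sh <- net_report$shells
    write_tsv_c(data.frame(
      distance = rep(as.integer(names(sh$shells)), lengths(sh$shells)),
      gene = unlist(sh$shells, use.names = FALSE),
      stringsAsFactors = FALSE), "shells.tsv")
    if (!is.null(net_report$shell_enrichment)) {
      write_tsv_c(net_report$shell_enrichment, "shell_enrichment.tsv")
    }
    if (!is.null(net_report$paths)) {
      write_tsv_c(data.frame(
        path = vapply(net_report$paths$paths, paste, "", collapse = "->"),
        stringsAsFactors = FALSE), "paths.tsv")
    }
  }
  if (!is.null(qpcr_report)) write_tsv_c(qpcr_report, "qpcr.tsv")

  group_levels <- c("G1", "G2", "G3.1", "G3.2", "G3.3", "G3.4", "G4", "NS")
  group_counts <- vapply(group_levels,
                         function(g) sum(cls$group == g), 0L)
  summary <- list(
    seed = config$seed,
    thresholds = list(alpha = config$alpha,
                      fc_threshold = config$fc_threshold),
    n_genes = nrow(mat$values),
    group_counts = as.list(group_counts),
    som_cluster_sizes = if (!is.null(som)) {
      as.list(setNames(tabulate(som$cluster + 1L, prod(config$som_grid)),
                       paste0("cluster", seq_len(prod(config$som_grid)) - 1L)))
    },
    shell_sizes = if (!is.null(net_report)) {
      as.list(setNames(lengths(net_report$shells$shells),
                       paste0("d", names(net_report$shells$shells))))
    },
    eccentricity = if (!is.null(net_report)) {
      net_report$shells$eccentricity
    },
    n_significant_tfs = if (!is.null(tf_enr)) sum(tf_enr$significant)
  )
  if (!is.null(truth)) {
    merged <- merge(truth, cls, by = "gene")
    non_null <- merged$planted_class != "NULL"
    summary$planted_recovery <-
      mean(merged$group[non_null] == merged$planted_class[non_null])
  }
  jsonlite::write_json(summary, file.path(staging, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  files <- sort(setdiff(list.files(staging), "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cufactor")),
    seed = config$seed,
    config = config[setdiff(names(config), c("sim_spec"))],
    output_checksums = as.list(tools::md5sum(file.path(staging, files)))
  )
  names(manifest$output_checksums) <- files
  jsonlite::write_json(manifest, file.path(staging, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (f in list.files(staging)) {
    file.copy(file.path(staging, f), file.path(config$out_dir, f),
              overwrite = TRUE)
  }
  invisible(list(matrix = mat, anova = aov_res, fold_changes = fc,
                 classification = cls, som = som, network = net_report,
                 go_enrichment = go_enr, tf_enrichment = tf_enr,
                 qpcr = qpcr_report, truth = truth, summary = summary))
}
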