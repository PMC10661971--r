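# End-to-end pipeline driver: read the five inputs, compute pathway
# activity, fit differential regulation, build/import and mask the
# co-expression network, cluster, and prioritize miRNAs per cluster.
# All stage outputs are written as TSV with a header comment recording
# version, seed and parameters; identical config + seed gives
# byte-identical tables.

#' Pipeline run configuration
#'
#' Validates and bundles input paths and stage parameters. Either
#' `network_path` (a precomputed edge list) or `reference_path` (an
#' expression compendium from which a network is built) must be given.
#'
#' @param expression_path,annotation_path,pathways_path,interactions_path
#'   Paths to the expression matrix, sample annotation, GMT collection and
#'   miRNA-target table.
#' @param network_path Optional path to a pathway co-expression edge list.
#' @param reference_path Optional path to a reference expression compendium.
#' @param output_dir Output directory.
#' @param condition,case_level,covariates Differential-model settings.
#' @param min_size,max_size Pathway size filter for activity scoring.
#' @param normalization `"zscore"` or `"none"`.
#' @param moderated Use empirical-Bayes variance moderation.
#' @param select_mode,select_value Top-pathway selection (`"top_k"` with k,
#'   or `"fdr_threshold"` with alpha).
#' @param corr_method,min_abs_weight,max_edge_p Network-building thresholds.
#' @param algorithm,min_cluster_size,edge_weight_mode Clustering settings.
#' @param mirna_column,gene_column Column names in the interaction table.
#' @param B,gaussian_threshold,hits_fdr,epsilon Prioritization settings
#'   (see [prioritization_config()]).
#' @param seed Master seed; per-stage seeds are derived deterministically.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(expression_path, annotation_path, pathways_path,
                       interactions_path, network_path = NULL,
                       reference_path = NULL, output_dir = "pacmir_out",
                       condition = "condition", case_level = NULL,
                       covariates = character(),
                       min_size = 5, max_size = 500,
                       normalization = "zscore", moderated = FALSE,
                       select_mode = "fdr_threshold", select_value = 0.01,
                       corr_method = "pearson", min_abs_weight = 0.3,
                       max_edge_p = 0.05,
                       algorithm = "louvain", min_cluster_size = 5,
                       edge_weight_mode = "absolute",
                       mirna_column = "mirna", gene_column = "gene",
                       B = 1000, gaussian_threshold = 30, hits_fdr = 0.25,
                       epsilon = 1e-15, seed = 1L) {
  cfg <- as.list(environment())
  for (p in c("expression_path", "annotation_path", "pathways_path",
              "interactions_path")) {
    if (!file.exists(cfg[[p]])) stop("input not found: ", cfg[[p]])
  }
  if (is.null(network_path) && is.null(reference_path)) {
    stop("one of network_path or reference_path is required")
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; relative input paths are
#' resolved against the YAML file's directory.
#'
#' @param path Path to a YAML config.
#' @param overrides Named list of values overriding the file's.
#' @return A validated `"run_config"`.
#' @export
read_run_config <- function(path, overrides = list()) {
  raw <- yaml::read_yaml(path)
  raw[names(overrides)] <- overrides
  base <- dirname(normalizePath(path))
  for (p in grep("_path$", names(raw), value = TRUE)) {
    if (!is.null(raw[[p]]) && !file.exists(raw[[p]])) {
      cand <- file.path(base, raw[[p]])
      if (file.exists(cand)) raw[[p]] <- cand
    }
  }
  do.call(run_config, raw)
}

write_stage_tsv <- function(df, path, cfg, extra = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# pacmir %s seed=%d %s",
                     as.character(utils::packageVersion("pacmir")),
                     cfg$seed, extra %||% ""), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes activity scoring, differential regulation, network masking,
#' clustering and miRNA prioritization, writing every stage output plus a
#' run log and the serialized configuration into `output_dir`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`activity`, `differential`, `selected`, `network`, `clusters`,
#'   `targeting`) and `output_dir`.
#' @export
run_full <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), ...))
  }
  stage <- function(name, expr) {
    note("stage ", name, " started")
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        note("stage ", name, " FAILED: ", conditionMessage(e))
        writeLines(log_lines, logf)
        stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        note("stage ", name, " warning: ", conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        note("stage ", name, ": ", trimws(conditionMessage(m)))
        invokeRestart("muffleMessage")
      }
    )
  }
  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "run_config.yaml"))

  inputs <- stage("load", {
    list(expr = read_expression_table(cfg$expression_path),
         ann = read_annotation(cfg$annotation_path),
         pathways = read_gmt(cfg$pathways_path),
         interactions = read_interactions(cfg$interactions_path,
                                          cfg$mirna_column,
                                          cfg$gene_column))
  })

  act <- stage("activity", {
    a <- activity_scores(inputs$expr, inputs$pathways,
                         min_size = cfg$min_size, max_size = cfg$max_size)
    if (cfg$normalization == "zscore") normalize_activity(a, "zscore") else a
  })
  write_activity(act, file.path(cfg$output_dir, "activity.tsv"))

  diff_tbl <- stage("diffreg", {
    fit_differential(act, inputs$ann, condition = cfg$condition,
                     case_level = cfg$case_level,
                     covariates = cfg$covariates,
                     moderated = cfg$moderated)
  })
  write_stage_tsv(diff_tbl, file.path(cfg$output_dir, "differential.tsv"),
                  cfg)
  selected <- select_top_pathways(diff_tbl, cfg$select_mode,
                                  cfg$select_value)
  note("selected ", length(selected), " differentially regulated pathways")

  net <- stage("network", {
    full <- if (!is.null(cfg$network_path)) {
      read_network_edges(cfg$network_path)
    } else {
      ref <- read_expression_table(cfg$reference_path)
      ref_act <- activity_scores(ref, inputs$pathways,
                                 min_size = cfg$min_size,
                                 max_size = cfg$max_size)
      build_reference_network(ref_act, corr_method = cfg$corr_method,
                              min_abs_weight = cfg$min_abs_weight,
                              max_edge_p = cfg$max_edge_p)
    }
    mask_network(full, selected)
  })
  write_network_edges(net, file.path(cfg$output_dir, "network_masked.tsv"))

  clusters <- stage("cluster", {
    cluster_pathways(net, algorithm = cfg$algorithm,
                     seed = derive_seed(cfg$seed, 101L),
                     min_cluster_size = cfg$min_cluster_size,
                     edge_weight_mode = cfg$edge_weight_mode)
  })
  cl_df <- data.frame(
    pathway = unlist(clusters, use.names = FALSE),
    cluster = rep(names(clusters), lengths(clusters))
  )
  write_stage_tsv(cl_df, file.path(cfg$output_dir, "clusters.tsv"), cfg,
                  extra = paste0("algorithm=", cfg$algorithm))

  targeting <- stage("prioritize", {
    background <- rownames(inputs$expr)
    pcfg <- prioritization_config(B = cfg$B,
                                  gaussian_threshold = cfg$gaussian_threshold,
                                  seed = derive_seed(cfg$seed, 202L),
                                  hits_fdr = cfg$hits_fdr,
                                  epsilon = cfg$epsilon)
    prioritize(inputs$interactions, inputs$pathways, clusters, background,
               cfg = pcfg)
  })
  for (cl in unique(targeting$cluster)) {
    write_stage_tsv(targeting[targeting$cluster == cl, , drop = FALSE],
                    file.path(cfg$output_dir,
                              paste0("targeting_", cl, ".tsv")),
                    cfg, extra = paste0("cluster=", cl))
  }
  writeLines(log_lines, logf)
  invisible(list(activity = act, differential = diff_tbl,
                 selected = selected, network = net, clusters = clusters,
                 targeting = targeting, output_dir = cfg$output_dir))
}
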