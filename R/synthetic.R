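# Synthetic-data generators for every pipeline input, with plantable
# signal: pathways sampled from a gene universe, case/control expression
# with shifted member genes for planted pathways, miRNA-target tables with
# a planted cluster-covering miRNA, and a latent-block reference
# compendium whose pathway activities correlate within blocks.
#
# Every generator is a pure function of its arguments and seed. Expression
# is Gaussian: the activity score depends only on within-sample ranks, so
# the marginal distribution is immaterial to the method under test.

#' Synthetic study specification
#'
#' Bundles the generator parameters used by [simulate_inputs()] and the
#' pipeline driver. Defaults describe a modest two-group study: 2000
#' genes, 100 pathways of 20-60 genes, 30 cases vs 30 controls, unit noise,
#' one planted upregulated block targeted by one planted miRNA among 50
#' decoys at 30% coverage.
#'
#' @param n_genes Gene universe size.
#' @param n_pathways Number of pathways.
#' @param pathway_size Length-2 range of pathway sizes.
#' @param n_case,n_control Sample counts per group.
#' @param effect Shift (in noise-sd units) applied to member genes of
#'   planted pathways in case samples.
#' @param noise_sd Per-gene noise standard deviation.
#' @param n_planted_up,n_planted_down Numbers of planted up/down pathways;
#'   `NULL` for `n_planted_up` plants the whole first latent block (the
#'   default), so the differential, clustering and targeting stages carry
#'   one coherent planted signal.
#' @param n_decoys Decoy miRNA count.
#' @param target_size Length-2 range of decoy target-set sizes.
#' @param coverage Fraction of each planted-cluster pathway's genes forced
#'   into the planted miRNA's target set.
#' @param ref_samples Reference compendium sample count.
#' @param n_blocks Latent co-expression blocks in the compendium.
#' @param factor_sd Latent factor standard deviation.
#' @param seed Master seed.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_genes = 2000, n_pathways = 100,
                           pathway_size = c(20, 60),
                           n_case = 30, n_control = 30,
                           effect = 1.0, noise_sd = 1.0,
                           n_planted_up = NULL, n_planted_down = 0,
                           n_decoys = 50, target_size = c(100, 500),
                           coverage = 0.3,
                           ref_samples = 100, n_blocks = 3,
                           factor_sd = 1.0, seed = 1L) {
  stopifnot(n_genes > 0, n_pathways > 0, length(pathway_size) == 2L,
            pathway_size[2] <= n_genes, coverage > 0, coverage <= 1,
            n_case > 0, n_control > 0)
  structure(as.list(environment()), class = "synthetic_spec")
}

#' Generate a random pathway collection
#'
#' Samples `n_pathways` gene sets uniformly from the universe; sizes drawn
#' uniformly from the range.
#'
#' @param n_genes Gene universe size (genes named g0001, ...).
#' @param n_pathways Number of pathways (named PW001, ...).
#' @param size_range Length-2 size range.
#' @param seed Integer RNG seed.
#' @return Named list of gene-identifier vectors.
#' @export
make_pathways <- function(n_genes, n_pathways, size_range = c(20, 60),
                          seed = 1L) {
  stopifnot(size_range[1] >= 1, size_range[2] <= n_genes)
  genes <- gene_names(n_genes)
  set.seed(seed)
  sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("PW%03d", seq_len(n_pathways))
  sets
}

gene_names <- function(n) sprintf("g%05d", seq_len(n))

#' Relabel pathway genes by a global permutation
#'
#' Applies one random permutation of the gene universe to every pathway,
#' preserving all set sizes and pairwise overlap cardinalities — the
#' randomized-pathway control used to assess specificity.
#'
#' @param pathways Named list of gene vectors.
#' @param universe Character vector of all gene identifiers.
#' @param seed Integer RNG seed.
#' @return Relabeled pathway collection.
#' @export
permute_pathway_labels <- function(pathways, universe, seed = 1L) {
  set.seed(seed)
  perm <- stats::setNames(sample(universe), universe)
  lapply(pathways, function(g) unname(perm[g]))
}

#' Generate a case/control expression matrix with planted pathway shifts
#'
#' Baseline expression is i.i.d. Normal(0, `noise_sd`) per gene and sample;
#' member genes of planted-up pathways are shifted by +`effect` in case
#' samples, planted-down by -`effect`.
#'
#' @param pathways Named list of gene vectors.
#' @param planted_up,planted_down Names of planted pathways.
#' @param n_genes Gene universe size.
#' @param n_case,n_control Sample counts.
#' @param effect Shift size in sd units.
#' @param noise_sd Noise standard deviation.
#' @param seed Integer RNG seed.
#' @return List with `expression` (genes-by-samples matrix) and
#'   `annotation` (data.frame sample_id, condition with levels
#'   control/case).
#' @export
make_expression <- function(pathways, planted_up = character(),
                            planted_down = character(),
                            n_genes = 2000, n_case = 30, n_control = 30,
                            effect = 1.0, noise_sd = 1.0, seed = 1L) {
  stopifnot(all(c(planted_up, planted_down) %in% names(pathways)))
  genes <- gene_names(n_genes)
  samples <- c(sprintf("case%03d", seq_len(n_case)),
               sprintf("ctrl%03d", seq_len(n_control)))
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * length(samples), sd = noise_sd),
              nrow = n_genes, dimnames = list(genes, samples))
  case_cols <- seq_len(n_case)
  up_genes <- unique(unlist(pathways[planted_up]))
  down_genes <- unique(unlist(pathways[planted_down]))
  if (length(up_genes) > 0L) {
    m[up_genes, case_cols] <- m[up_genes, case_cols] + effect * noise_sd
  }
  if (length(down_genes) > 0L) {
    m[down_genes, case_cols] <- m[down_genes, case_cols] - effect * noise_sd
  }
  ann <- data.frame(
    sample_id = samples,
    condition = rep(c("case", "control"), c(n_case, n_control)),
    stringsAsFactors = FALSE
  )
  list(expression = m, annotation = ann)
}

#' Generate a miRNA-target interaction table with a planted cluster-targeter
#'
#' Decoy miRNAs receive uniform random target sets with sizes drawn from
#' `size_range`. Each planted miRNA's target set contains
#' `ceiling(coverage * |pathway|)` genes from every pathway of its assigned
#' cluster, plus random fill genes drawn outside the cluster's gene union
#' up to its nominal size (increased with a warning if the forced genes
#' already exceed it).
#'
#' @param pathways Named list of gene vectors.
#' @param background Character vector of candidate target genes.
#' @param n_decoys Number of decoy miRNAs.
#' @param size_range Length-2 range of nominal target-set sizes.
#' @param planted Named list: planted miRNA name -> character vector of its
#'   assigned cluster's pathway names.
#' @param coverage Fraction of each assigned pathway forced into the
#'   planted target set.
#' @param seed Integer RNG seed.
#' @return Named list: miRNA -> target gene vector.
#' @export
make_interactions <- function(pathways, background, n_decoys = 50,
                              size_range = c(100, 500),
                              planted = list(), coverage = 0.3,
                              seed = 1L) {
  stopifnot(coverage > 0, coverage <= 1,
            size_range[1] >= 1, size_range[2] <= length(background))
  set.seed(seed)
  db <- list()
  for (nm in names(planted)) {
    cl <- planted[[nm]]
    stopifnot(all(cl %in% names(pathways)))
    forced <- unique(unlist(lapply(pathways[cl], function(g) {
      g <- intersect(g, background)
      sample(g, ceiling(coverage * length(g)))
    })))
    nominal <- sample(size_range[1]:size_range[2], 1L)
    if (nominal < length(forced)) {
      warning("planted miRNA ", nm, ": nominal size ", nominal,
              " below forced gene count ", length(forced), "; increased")
      nominal <- length(forced)
    }
    pool <- setdiff(background, unique(unlist(pathways[cl])))
    fill <- sample(pool, min(nominal - length(forced), length(pool)))
    db[[nm]] <- unique(c(forced, fill))
  }
  for (i in seq_len(n_decoys)) {
    sz <- sample(size_range[1]:size_range[2], 1L)
    db[[sprintf("dec-miR-%03d", i)]] <- sample(background, sz)
  }
  db
}

#' Generate a latent-block reference expression compendium
#'
#' Pathways are assigned round-robin to `n_blocks` latent factors; every
#' gene belonging to a pathway of block b loads on factor b, so activity
#' profiles of same-block pathways correlate across compendium samples,
#' giving [build_reference_network()] a modular graph.
#'
#' @param pathways Named list of gene vectors.
#' @param n_genes Gene universe size.
#' @param n_samples Compendium sample count.
#' @param n_blocks Number of latent blocks.
#' @param factor_sd Latent factor standard deviation (0 = no shared
#'   structure).
#' @param noise_sd Per-gene noise standard deviation.
#' @param seed Integer RNG seed.
#' @return List with `expression` (genes-by-samples matrix) and `blocks`
#'   (named list: block id -> pathway names).
#' @export
make_reference_compendium <- function(pathways, n_genes = 2000,
                                      n_samples = 100, n_blocks = 3,
                                      factor_sd = 1.0, noise_sd = 1.0,
                                      seed = 1L) {
  stopifnot(n_blocks >= 1, n_samples >= 3)
  genes <- gene_names(n_genes)
  block_of <- rep(seq_len(n_blocks), length.out = length(pathways))
  blocks <- split(names(pathways), block_of)
  names(blocks) <- paste0("block", names(blocks))
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
              nrow = n_genes,
              dimnames = list(genes, sprintf("ref%04d", seq_len(n_samples))))
  for (b in seq_len(n_blocks)) {
    f <- stats::rnorm(n_samples, sd = factor_sd)
    bg <- unique(unlist(pathways[blocks[[b]]]))
    bg <- intersect(bg, genes)
    if (length(bg) > 0L && factor_sd > 0) {
      m[bg, ] <- m[bg, ] + matrix(f, length(bg), n_samples, byrow = TRUE)
    }
  }
  list(expression = m, blocks = blocks)
}

#' Generate all five pipeline inputs from one specification
#'
#' Convenience wrapper: pathways, case/control expression + annotation,
#' interactions with a planted miRNA covering the first compendium block,
#' and the reference compendium. The planted-up pathways are the first
#' block's, so the differential, clustering and targeting stages all carry
#' the same planted signal.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `pathways`, `expression`, `annotation`,
#'   `interactions`, `reference`, `blocks`, `planted_mirna`,
#'   `planted_up`, `planted_down`.
#' @export
simulate_inputs <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  pw <- make_pathways(spec$n_genes, spec$n_pathways, spec$pathway_size,
                      seed = derive_seed(spec$seed, 1L))
  ref <- make_reference_compendium(pw, n_genes = spec$n_genes,
                                   n_samples = spec$ref_samples,
                                   n_blocks = spec$n_blocks,
                                   factor_sd = spec$factor_sd,
                                   noise_sd = spec$noise_sd,
                                   seed = derive_seed(spec$seed, 2L))
  blocks <- ref$blocks
  planted_up <- if (is.null(spec$n_planted_up)) blocks[[1]] else {
    utils::head(blocks[[1]], max(spec$n_planted_up, 0))
  }
  if (spec$effect == 0) planted_up <- character(0)
  planted_down <- if (spec$n_planted_down > 0 && length(blocks) >= 2) {
    utils::head(blocks[[2]], spec$n_planted_down)
  } else character(0)
  ex <- make_expression(pw, planted_up = planted_up,
                        planted_down = planted_down,
                        n_genes = spec$n_genes,
                        n_case = spec$n_case, n_control = spec$n_control,
                        effect = spec$effect, noise_sd = spec$noise_sd,
                        seed = derive_seed(spec$seed, 3L))
  planted <- if (spec$effect > 0 && length(blocks[[1]]) > 0) {
    list("planted-miR-1" = blocks[[1]])
  } else list()
  db <- make_interactions(pw, background = gene_names(spec$n_genes),
                          n_decoys = spec$n_decoys,
                          size_range = spec$target_size,
                          planted = planted, coverage = spec$coverage,
                          seed = derive_seed(spec$seed, 4L))
  list(pathways = pw,
       expression = ex$expression,
       annotation = ex$annotation,
       interactions = db,
       reference = ref$expression,
       blocks = blocks,
       planted_mirna = names(planted),
       planted_up = planted_up,
       planted_down = planted_down)
}

#' Write simulated inputs to disk in the pipeline's external formats
#'
#' Writes the pathway GMT, expression and annotation TSVs, interaction
#' table, reference compendium TSV, and a YAML manifest recording the
#' specification and seed.
#'
#' @param sim Output of [simulate_inputs()].
#' @param dir Output directory (created if needed).
#' @param spec The [synthetic_spec()] used (recorded in the manifest).
#' @return Invisibly, a named vector of file paths.
#' @export
write_simulated_inputs <- function(sim, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    pathways = file.path(dir, "pathways.gmt"),
    expression = file.path(dir, "expression.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    interactions = file.path(dir, "interactions.tsv"),
    reference = file.path(dir, "reference.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_gmt(sim$pathways, paths[["pathways"]])
  write_matrix_tsv(sim$expression, "gene", paths[["expression"]])
  utils::write.table(sim$annotation, paths[["annotation"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  inter <- data.frame(
    mirna = rep(names(sim$interactions), lengths(sim$interactions)),
    gene = unlist(sim$interactions, use.names = FALSE)
  )
  utils::write.table(inter, paths[["interactions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_matrix_tsv(sim$reference, "gene", paths[["reference"]])
  manifest <- list(planted_mirna = sim$planted_mirna,
                   planted_up = sim$planted_up,
                   planted_down = sim$planted_down,
                   blocks = sim$blocks)
  if (!is.null(spec)) manifest$spec <- unclass(spec)
  yaml::write_yaml(manifest, paths[["manifest"]])
  invisible(paths)
}

write_matrix_tsv <- function(m, id_col, path) {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
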