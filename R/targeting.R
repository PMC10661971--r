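# miRNA prioritization within pathway clusters.
#
# For each miRNA x and pathway y, a one-sided Fisher exact (hypergeometric)
# p-value P_xy measures overrepresentation of the miRNA's targets among the
# pathway's member genes, against a background of expressed genes. The
# cluster-targeting score of miRNA x for cluster C is the Stouffer-type
# aggregate
#
#     S = (1 / |C|) * sum_{y in C} qnorm(1 - P_xy)
#
# Its significance is assessed against an empirical null built by
# resampling same-sized random pathway sets and recomputing S; for large
# clusters (> 30 pathways) a Gaussian tail approximation from the null's
# mean and sd replaces the exceedance count.

#' One-sided overrepresentation p-value for a target/pathway overlap
#'
#' Hypergeometric upper-tail probability P(X >= observed overlap) with the
#' gene universe equal to the background set. Both the target set and the
#' pathway are intersected with the background first.
#'
#' @param targets Character vector of a miRNA's target genes.
#' @param pathway_genes Character vector of pathway member genes.
#' @param background Character vector of background (expressed) genes.
#' @return A p-value in (0, 1].
#' @export
overlap_pvalue <- function(targets, pathway_genes, background) {
  if (length(background) == 0L) stop("empty background gene set")
  bg <- unique(background)
  t_eff <- intersect(unique(targets), bg)
  p_eff <- intersect(unique(pathway_genes), bg)
  if (length(t_eff) == 0L) {
    warning("no target gene in background; p = 1")
    return(1)
  }
  k <- length(intersect(t_eff, p_eff))
  stats::phyper(k - 1, length(p_eff), length(bg) - length(p_eff),
                length(t_eff), lower.tail = FALSE)
}

#' Full miRNA-by-pathway overlap p-value matrix
#'
#' Computes [overlap_pvalue()] for every miRNA/pathway pair against one
#' fixed background. miRNAs with no target in the background are excluded
#' (with a message).
#'
#' @param interactions Named list: miRNA -> target gene vector.
#' @param pathways Named list: pathway -> member gene vector (already
#'   size-filtered).
#' @param background Character vector of background genes.
#' @return Numeric miRNA-by-pathway matrix with attribute `n_targets`
#'   (effective target counts) and `background_size`.
#' @export
overlap_matrix <- function(interactions, pathways, background) {
  if (length(background) == 0L) stop("empty background gene set")
  bg <- unique(background)
  N <- length(bg)
  jj <- match(unlist(interactions), bg)
  ii <- rep(seq_along(interactions), lengths(interactions))
  ok <- !is.na(jj)  # target genes outside the background do not count
  T_ind <- Matrix::sparseMatrix(i = ii[ok], j = jj[ok], x = 1,
                                dims = c(length(interactions), N),
                                dimnames = list(names(interactions), NULL),
                                use.last.ij = TRUE)
  n_targets <- Matrix::rowSums(T_ind)
  if (any(n_targets == 0)) {
    message("excluded ", sum(n_targets == 0),
            " miRNA(s) with no target in background")
  }
  keep <- n_targets > 0
  T_ind <- T_ind[keep, , drop = FALSE]
  n_targets <- n_targets[keep]
  if (nrow(T_ind) == 0L) stop("no miRNA has targets in the background")
  members <- lapply(pathways, function(g) intersect(unique(g), bg))
  P_ind <- Matrix::sparseMatrix(
    i = rep(seq_along(members), lengths(members)),
    j = unlist(lapply(members, match, bg)),
    x = 1, dims = c(length(members), N),
    dimnames = list(names(members), NULL)
  )
  K <- Matrix::rowSums(P_ind)                    # pathway sizes
  overlap <- as.matrix(T_ind %*% Matrix::t(P_ind))
  Kmat <- matrix(K, nrow(overlap), ncol(overlap), byrow = TRUE)
  nmat <- matrix(n_targets, nrow(overlap), ncol(overlap))
  p <- stats::phyper(overlap - 1, Kmat, N - Kmat, nmat, lower.tail = FALSE)
  dimnames(p) <- list(rownames(T_ind), names(members))
  structure(p, n_targets = stats::setNames(n_targets, rownames(T_ind)),
            background_size = N)
}

#' Cluster-targeting score of one miRNA
#'
#' Mean over the cluster's member pathways of the inverse-normal transform
#' qnorm(1 - P_xy); p-values are clipped into \[epsilon, 1 - epsilon\]
#' before the transform.
#'
#' @param p_row Named p-value vector (one miRNA's row of the overlap
#'   matrix).
#' @param cluster Character vector of pathway names.
#' @param epsilon Clipping constant (default 1e-15).
#' @return The score S (dimensionless).
#' @export
cluster_targeting_score <- function(p_row, cluster, epsilon = 1e-15) {
  stopifnot(length(cluster) > 0L)
  miss <- setdiff(cluster, names(p_row))
  if (length(miss) > 0L) {
    stop("cluster member(s) missing from the overlap matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  mean(stats::qnorm(1 - clip_pvalues(p_row[cluster], epsilon)))
}

# Draw B index sets of size k from n_universe without replacement.
# Consumes the current RNG state; callers set the seed.
draw_null_sets <- function(n_universe, k, B) {
  stopifnot(n_universe >= k, B >= 1)
  matrix(vapply(seq_len(B), function(i) sample.int(n_universe, k),
                integer(k)), nrow = k)
}

#' Bootstrap null distribution of cluster-targeting scores
#'
#' Resamples `B` uniform random pathway sets of size `cluster_size` (without
#' replacement within a draw) from the universe and recomputes the
#' targeting score of the miRNA's own p-value row on each.
#'
#' @param p_row Named p-value vector over the universe pathways.
#' @param cluster_size Number of pathways per resampled set.
#' @param universe Character vector of pathway names to sample from.
#' @param B Number of null draws (>= 100).
#' @param seed Integer RNG seed.
#' @param epsilon Clipping constant for the inverse-normal transform.
#' @return Numeric vector of B null scores.
#' @export
bootstrap_null <- function(p_row, cluster_size, universe, B = 1000,
                           seed = 1L, epsilon = 1e-15) {
  stopifnot(B >= 100)
  if (length(universe) < cluster_size) {
    stop("universe (", length(universe), ") smaller than cluster size (",
         cluster_size, ")")
  }
  miss <- setdiff(universe, names(p_row))
  if (length(miss) > 0L) stop("universe pathway(s) missing from p_row")
  z <- stats::qnorm(1 - clip_pvalues(p_row[universe], epsilon))
  set.seed(seed)
  idx <- draw_null_sets(length(universe), cluster_size, B)
  colMeans(matrix(z[idx], nrow = cluster_size))
}

# Vectorized null: one shared set of draws evaluated on every miRNA's
# z-row. Marginally identical per miRNA to independent draws; the shared
# draws make B = 1e5 across hundreds of miRNAs tractable.
null_score_matrix <- function(Z, universe_idx, cluster_size, B, seed) {
  set.seed(seed)
  idx <- draw_null_sets(length(universe_idx), cluster_size, B)
  Ind <- Matrix::sparseMatrix(i = as.vector(idx),
                              j = rep(seq_len(B), each = cluster_size),
                              x = 1,
                              dims = c(length(universe_idx), B))
  as.matrix(Z[, universe_idx, drop = FALSE] %*% Ind) / cluster_size
}

#' Empirical p-value from a null score vector
#'
#' Add-one exceedance formula (1 + #\{null >= observed\}) / (B + 1); the
#' smallest attainable value is 1 / (B + 1), never 0.
#'
#' @param S_obs Observed score.
#' @param null_scores Numeric vector of null scores.
#' @return Empirical p-value.
#' @export
empirical_pvalue <- function(S_obs, null_scores) {
  stopifnot(length(null_scores) > 0L)
  (1 + sum(null_scores >= S_obs)) / (length(null_scores) + 1)
}

#' Gaussian tail p-value from a null score sample
#'
#' Normal upper-tail probability of the observed score under a Gaussian
#' fitted to the null sample's mean and standard deviation (n - 1
#' denominator).
#'
#' @param S_obs Observed score.
#' @param null_scores Numeric vector of at least 30 null scores.
#' @return Tail p-value 1 - pnorm((S_obs - mean) / sd).
#' @export
gaussian_pvalue <- function(S_obs, null_scores) {
  stopifnot(length(null_scores) >= 30L)
  m <- mean(null_scores)
  s <- stats::sd(null_scores)
  if (s == 0) {
    warning("zero null standard deviation")
    return(if (S_obs <= m) 1 else .Machine$double.xmin)
  }
  stats::pnorm(S_obs, mean = m, sd = s, lower.tail = FALSE)
}

#' Prioritization configuration
#'
#' @param B Null draws per miRNA/cluster (default 1000).
#' @param gaussian_threshold Cluster size above which the Gaussian
#'   approximation replaces the exceedance count (default 30, strict
#'   greater-than).
#' @param universe `"matrix"` samples null pathway sets from all pathways
#'   in the overlap matrix (the default, correcting annotation bias);
#'   `"custom"` uses `universe_pathways`.
#' @param universe_pathways Pathway names when `universe = "custom"`.
#' @param seed Integer RNG seed.
#' @param hits_fdr BH threshold for counting enriched member pathways
#'   (default 0.25).
#' @param epsilon Clipping constant in (0, 1e-6] (default 1e-15).
#' @return A list of class `"prioritization_config"`.
#' @export
prioritization_config <- function(B = 1000, gaussian_threshold = 30,
                                  universe = c("matrix", "custom"),
                                  universe_pathways = NULL,
                                  seed = 1L, hits_fdr = 0.25,
                                  epsilon = 1e-15) {
  universe <- match.arg(universe)
  stopifnot(B >= 100, epsilon > 0, epsilon <= 1e-6,
            hits_fdr > 0, hits_fdr < 1)
  structure(list(B = as.integer(B),
                 gaussian_threshold = gaussian_threshold,
                 universe = universe,
                 universe_pathways = universe_pathways,
                 seed = as.integer(seed),
                 hits_fdr = hits_fdr,
                 epsilon = epsilon),
            class = "prioritization_config")
}

#' Prioritize miRNAs for each pathway cluster
#'
#' For every cluster and miRNA: computes the cluster-targeting score, an
#' empirical p-value against the resampling null (bootstrap exceedance for
#' clusters up to `gaussian_threshold` pathways, Gaussian tail above it),
#' a BH-adjusted p within the cluster's miRNA list, and the count of member
#' pathways individually enriched at the configured FDR.
#'
#' @param interactions Named list: miRNA -> target gene vector.
#' @param pathways Named list: pathway -> member gene vector.
#' @param clusters Named list of pathway-name vectors (a cluster set).
#' @param background Character vector of background (expressed) genes.
#' @param cfg A [prioritization_config()].
#' @param pmat Optional precomputed [overlap_matrix()]; computed if `NULL`.
#' @return data.frame with columns mirna, cluster, score, p_value,
#'   adjusted_p, method, hits, n_targets, sorted within cluster by
#'   adjusted p, then p, then miRNA name.
#' @export
prioritize <- function(interactions, pathways, clusters, background,
                       cfg = prioritization_config(), pmat = NULL) {
  stopifnot(inherits(cfg, "prioritization_config"), length(clusters) > 0L)
  if (is.null(pmat)) pmat <- overlap_matrix(interactions, pathways, background)
  n_targets <- attr(pmat, "n_targets")
  Z <- stats::qnorm(1 - clip_pvalues(unclass(pmat), cfg$epsilon))
  universe <- if (cfg$universe == "matrix") colnames(pmat) else {
    u <- intersect(cfg$universe_pathways, colnames(pmat))
    if (length(u) == 0L) stop("custom universe has no pathway in the matrix")
    u
  }
  out <- list()
  for (ci in seq_along(clusters)) {
    cl_name <- names(clusters)[ci]
    members <- intersect(clusters[[ci]], colnames(pmat))
    if (length(members) == 0L) {
      warning("cluster ", cl_name, " has no pathway in the matrix; skipped")
      next
    }
    k <- length(members)
    S_obs <- rowMeans(Z[, members, drop = FALSE])
    nulls <- null_score_matrix(Z, match(universe, colnames(pmat)), k,
                               cfg$B, derive_seed(cfg$seed, ci))
    use_gauss <- k > cfg$gaussian_threshold
    if (use_gauss) {
      m <- rowMeans(nulls)
      s <- apply(nulls, 1L, stats::sd)
      pv <- ifelse(s > 0,
                   stats::pnorm(S_obs, m, s, lower.tail = FALSE),
                   ifelse(S_obs <= m, 1, .Machine$double.xmin))
    } else {
      pv <- (1 + rowSums(nulls >= S_obs)) / (cfg$B + 1)
    }
    hits <- apply(unclass(pmat)[, members, drop = FALSE], 1L, function(p) {
      sum(stats::p.adjust(p, method = "BH") < cfg$hits_fdr)
    })
    df <- data.frame(mirna = rownames(pmat),
                     cluster = cl_name,
                     score = unname(S_obs),
                     p_value = unname(pv),
                     adjusted_p = stats::p.adjust(pv, method = "BH"),
                     method = if (use_gauss) "gaussian" else "bootstrap",
                     hits = unname(hits),
                     n_targets = unname(n_targets[rownames(pmat)]),
                     stringsAsFactors = FALSE)
    df <- df[order(df$adjusted_p, df$p_value, df$mirna), , drop = FALSE]
    out[[cl_name]] <- df
  }
  if (length(out) == 0L) stop("no cluster could be scored")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Jackknife stability of targeting p-values
#'
#' Leaves out one cluster pathway at a time, recomputes every miRNA's
#' targeting score and p-value on the reduced cluster (null cluster size
#' reduced by one), and reports the Spearman correlation between the mean
#' jackknifed p-values and the original ones across miRNAs.
#'
#' @param pmat An [overlap_matrix()] (or named p-value matrix).
#' @param cluster Character vector of >= 2 pathway names.
#' @param cfg A [prioritization_config()].
#' @return List with `original_p`, `jackknife_p` (miRNA-by-left-out-pathway
#'   matrix), `mean_jackknife_p`, and `spearman`.
#' @export
jackknife_pvalues <- function(pmat, cluster, cfg = prioritization_config()) {
  if (length(cluster) < 2L) stop("jackknife needs a cluster of size >= 2")
  miss <- setdiff(cluster, colnames(pmat))
  if (length(miss) > 0L) stop("cluster member(s) missing from matrix")
  Z <- stats::qnorm(1 - clip_pvalues(unclass(pmat), cfg$epsilon))
  universe_idx <- seq_len(ncol(pmat))
  p_for <- function(members, seed_offset) {
    k <- length(members)
    S_obs <- rowMeans(Z[, members, drop = FALSE])
    nulls <- null_score_matrix(Z, universe_idx, k, cfg$B,
                               derive_seed(cfg$seed, seed_offset))
    if (k > cfg$gaussian_threshold) {
      m <- rowMeans(nulls)
      s <- apply(nulls, 1L, stats::sd)
      stats::pnorm(S_obs, m, s, lower.tail = FALSE)
    } else {
      (1 + rowSums(nulls >= S_obs)) / (cfg$B + 1)
    }
  }
  orig <- p_for(cluster, 0L)
  jk <- vapply(seq_along(cluster), function(j) {
    p_for(cluster[-j], j)
  }, numeric(nrow(pmat)))
  colnames(jk) <- cluster
  rownames(jk) <- rownames(pmat)
  mean_jk <- rowMeans(jk)
  # degenerate (all-tied) p-vectors have no defined rank correlation
  rho <- if (stats::sd(mean_jk) == 0 || stats::sd(orig) == 0) NA_real_ else {
    stats::cor(mean_jk, orig, method = "spearman")
  }
  list(original_p = stats::setNames(orig, rownames(pmat)),
       jackknife_p = jk,
       mean_jackknife_p = mean_jk,
       spearman = rho)
}

#' Combine per-pathway enrichment p-values (comparison baseline)
#'
#' Fisher's method (chi-squared on 2|C| df) or Stouffer's method (equal
#' weights) over a miRNA's p-values across the cluster's member pathways.
#' These baselines are provided for comparison; unlike the resampling null
#' they are sensitive to a miRNA's target-set size.
#'
#' @param p_row Named p-value vector.
#' @param cluster Character vector of pathway names.
#' @param method `"fisher"` or `"stouffer"`.
#' @param epsilon Clipping constant applied before logs/transforms.
#' @return Combined p-value.
#' @export
aggregate_pvalues <- function(p_row, cluster,
                              method = c("fisher", "stouffer"),
                              epsilon = 1e-15) {
  method <- match.arg(method)
  miss <- setdiff(cluster, names(p_row))
  if (length(miss) > 0L) stop("cluster member(s) missing from p_row")
  p <- clip_pvalues(p_row[cluster], epsilon)
  if (method == "fisher") {
    stat <- -2 * sum(log(p))
    stats::pchisq(stat, df = 2 * length(p), lower.tail = FALSE)
  } else {
    z <- sum(stats::qnorm(1 - p)) / sqrt(length(p))
    stats::pnorm(z, lower.tail = FALSE)
  }
}

#' Count individually enriched member pathways (comparison baseline)
#'
#' BH-adjusts one miRNA's overlap p-values across a cluster's member
#' pathways and counts those below the threshold ("miRNA hits").
#'
#' @param p_row Named p-value vector.
#' @param cluster Character vector of pathway names.
#' @param fdr_threshold BH threshold in (0, 1) (default 0.25).
#' @return Integer hit count.
#' @export
count_enriched_pathways <- function(p_row, cluster, fdr_threshold = 0.25) {
  stopifnot(fdr_threshold > 0, fdr_threshold < 1)
  miss <- setdiff(cluster, names(p_row))
  if (length(miss) > 0L) stop("cluster member(s) missing from p_row")
  sum(stats::p.adjust(p_row[cluster], method = "BH") < fdr_threshold)
}
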