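# Rank-based per-sample pathway activity scores.
#
# For each sample, genes are ranked so the highest-expressed gene receives
# the largest rank (ties averaged); the activity of a pathway in a sample is
# the mean of the squared ranks of its member genes. Ranks are computed over
# all loaded genes, then the sum is restricted to pathway members, so scores
# are invariant to any strictly increasing per-sample transformation of the
# expression values.

#' Rank genes within one sample
#'
#' @param sample_expression Numeric vector of expression values for one
#'   sample (all loaded genes).
#' @param tie_policy Tie handling; only `"average"` is supported (average of
#'   spanned ranks, preserving the rank-sum invariant G(G+1)/2).
#' @return Numeric rank vector: the largest expression value gets rank G.
#' @export
rank_genes <- function(sample_expression, tie_policy = "average") {
  tie_policy <- match.arg(tie_policy, "average")
  if (!is.numeric(sample_expression) || length(sample_expression) < 1L) {
    stop("expression must be a non-empty numeric vector")
  }
  if (any(!is.finite(sample_expression))) {
    stop("non-finite expression value at position ",
         which(!is.finite(sample_expression))[1])
  }
  rank(sample_expression, ties.method = "average")
}

#' Per-sample pathway activity scores
#'
#' Computes, for every retained pathway and sample, the mean squared
#' within-sample rank of the pathway's member genes present in the matrix.
#' Pathways whose effective size (members present in the expression matrix)
#' falls outside `[min_size, max_size]` are excluded.
#'
#' @param expr Numeric genes-by-samples matrix with gene rownames.
#' @param pathways Named list of gene-identifier vectors.
#' @param min_size,max_size Effective pathway size filter (defaults 5, 500).
#' @return A pathways-by-samples numeric matrix of class
#'   `"pathway_activity"` with attributes `n_genes` (G), `n_members`
#'   (effective sizes), `tie_policy` and `normalized`.
#' @export
activity_scores <- function(expr, pathways, min_size = 5, max_size = 500) {
  stopifnot(is.matrix(expr), is.numeric(expr), !is.null(rownames(expr)))
  if (any(!is.finite(expr))) stop("expression matrix has non-finite values")
  if (length(pathways) == 0L) stop("empty pathway collection")
  G <- nrow(expr)
  members <- lapply(pathways, function(g) intersect(unique(g), rownames(expr)))
  sizes <- lengths(members)
  keep <- sizes >= min_size & sizes <= max_size
  if (!all(keep)) {
    message("excluded ", sum(!keep), " pathway(s) outside size range [",
            min_size, ", ", max_size, "]")
  }
  if (!any(keep)) stop("no pathway survives the size filter")
  members <- members[keep]
  # squared ranks per sample; sparse membership indicator gives all scores
  # in one product
  R2 <- apply(expr, 2L, function(x) rank(x, ties.method = "average"))^2
  idx <- lapply(members, function(g) match(g, rownames(expr)))
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(idx), lengths(idx)),
    j = unlist(idx),
    x = 1,
    dims = c(length(idx), G),
    dimnames = list(names(members), rownames(expr))
  )
  act <- as.matrix(M %*% R2) / lengths(members)
  colnames(act) <- colnames(expr)
  structure(act,
            class = c("pathway_activity", "matrix", "array"),
            n_genes = G,
            n_members = stats::setNames(lengths(members), names(members)),
            tie_policy = "average",
            normalized = FALSE)
}

#' Normalize pathway activity profiles across samples
#'
#' @param act A `"pathway_activity"` matrix (or plain pathways-by-samples
#'   matrix).
#' @param method `"zscore"` centers and scales each pathway row by its
#'   sample standard deviation (constant rows become all-zero with a
#'   warning); `"none"` returns the input unchanged.
#' @return Matrix of the same shape, `normalized` attribute updated.
#' @export
normalize_activity <- function(act, method = c("zscore", "none")) {
  method <- match.arg(method)
  if (method == "none") return(act)
  if (ncol(act) < 2L) stop("z-score normalization needs >= 2 samples")
  mu <- rowMeans(act)
  sdv <- apply(act, 1L, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning(sum(const), " constant pathway row(s) set to all-zero")
    sdv[const] <- 1
  }
  out <- (unclass(act) - mu) / sdv
  attributes(out) <- attributes(act)
  attr(out, "normalized") <- TRUE
  out
}

#' Write an activity matrix as TSV with a metadata header
#'
#' @param act Activity matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_activity <- function(act, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_genes=%s tie_policy=%s normalized=%s",
                     attr(act, "n_genes") %||% NA,
                     attr(act, "tie_policy") %||% "average",
                     isTRUE(attr(act, "normalized"))), con)
  df <- data.frame(pathway = rownames(act), unclass(act),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
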