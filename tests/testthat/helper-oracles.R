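# Independent oracles and tiny fixture builders shared across the suite.

# Brute-force BH: adjusted p_i = min over j >= i (sorted) of m * p_(j) / j,
# capped at 1, mapped back to input order.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force activity score: explicit sort-based ranks, squared, averaged.
activity_brute <- function(expr, members) {
  sapply(seq_len(ncol(expr)), function(j) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    mean(r[rownames(expr) %in% members]^2)
  })
}

# Enumerate all set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, next_label) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (lab in seq_len(next_label)) {
      rec(c(assign, lab), max(next_label, lab + 1L))
    }
  }
  rec(integer(0), 1L)
  out
}

# Modularity-maximizing partition by exhaustive enumeration.
best_modularity_partition <- function(g) {
  parts <- all_partitions(igraph::vcount(g))
  scores <- vapply(parts, function(p) igraph::modularity(g, p), 0)
  parts[[which.max(scores)]]
}

# Mean best-match Jaccard of reference groups against found clusters.
best_match_jaccard <- function(reference, found) {
  mean(sapply(reference, function(b) {
    max(sapply(found, function(cl) {
      length(intersect(b, cl)) / length(union(b, cl))
    }))
  }))
}

# Write a small GMT file; returns the path.
write_tmp_gmt <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "sets.gmt")
  writeLines(lines, path)
  path
}

# Small deterministic expression fixture: distinct values, named genes.
tiny_expr <- function(n_genes = 10, n_samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * n_samples), n_genes,
              dimnames = list(sprintf("g%02d", 1:n_genes),
                              sprintf("s%d", 1:n_samples)))
  m
}
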