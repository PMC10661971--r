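# Readers and writers for the external formats the pipeline touches:
# GMT gene-set files, expression/annotation tables, miRNA-mRNA interaction
# tables, and pathway co-expression network edge lists. All gene matching
# downstream is exact string match after whitespace trimming; identifier
# conversion is the user's responsibility.

trim_ids <- function(x) trimws(as.character(x))

detect_delimiter <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) return("\t")
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "\t"
}

#' Read a GMT pathway collection
#'
#' Parses the standard tab-separated GMT format (one gene set per line:
#' name, description, then member genes). Duplicate genes within a set are
#' collapsed; pathway order is preserved.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of gene identifiers, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty GMT file: ", path)
    return(structure(list(), descriptions = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    stop("GMT parse error, line ", bad[1], ": fewer than 3 fields")
  }
  names_ <- trim_ids(vapply(fields, `[[`, "", 1L))
  if (anyDuplicated(names_)) {
    stop("duplicate pathway name in GMT: ",
         names_[duplicated(names_)][1])
  }
  desc <- vapply(fields, `[[`, "", 2L)
  sets <- lapply(fields, function(f) unique(trim_ids(f[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  if (any(lengths(sets) == 0L)) {
    stop("GMT pathway with no genes: ", names_[lengths(sets) == 0L][1])
  }
  names(sets) <- names_
  structure(sets, descriptions = stats::setNames(desc, names_))
}

#' Write a pathway collection to GMT
#'
#' @param pathways Named list of character vectors.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(pathways, path) {
  desc <- attr(pathways, "descriptions") %||%
    stats::setNames(rep("", length(pathways)), names(pathways))
  lines <- vapply(names(pathways), function(nm) {
    paste(c(nm, desc[[nm]] %||% "", pathways[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a genes-by-samples expression table
#'
#' First row holds sample identifiers, first column gene identifiers.
#' Rows containing missing values are dropped (with a message); duplicated
#' gene identifiers are resolved by keeping the row with the highest mean.
#'
#' @param path Path to a TSV/CSV table.
#' @param delimiter Field delimiter; `NULL` auto-detects tab vs comma.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_table <- function(path, delimiter = NULL) {
  stopifnot(file.exists(path))
  delimiter <- delimiter %||% detect_delimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "\"")
  if (ncol(df) < 3L) stop("expression table needs >= 2 sample columns")
  sample_ids <- trim_ids(colnames(df)[-1])
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample ID: ", sample_ids[duplicated(sample_ids)][1])
  }
  gene_ids <- trim_ids(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      suppressWarnings(num <- as.numeric(vals[[j]]))
      bad <- which(is.na(num) & !is.na(vals[[j]]) &
                     !vals[[j]] %in% c("NA", ""))
      if (length(bad) > 0L) {
        stop("non-numeric cell at row ", bad[1], ", column ",
             sample_ids[j], ": '", vals[[j]][bad[1]], "'")
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- gene_ids
  drop <- rowSums(is.na(m)) > 0L
  if (any(drop)) {
    message("dropped ", sum(drop), " gene row(s) with missing values")
    m <- m[!drop, , drop = FALSE]
  }
  if (anyDuplicated(rownames(m))) {
    means <- rowMeans(m)
    ord <- order(-means)  # highest-mean row first, so !duplicated keeps it
    m <- m[ord, , drop = FALSE]
    ndup <- sum(duplicated(rownames(m)))
    m <- m[!duplicated(rownames(m)), , drop = FALSE]
    m <- m[order(match(rownames(m), gene_ids)), , drop = FALSE]
    message("collapsed ", ndup,
            " duplicated gene row(s), keeping highest-mean rows")
  }
  if (ncol(m) < 2L) stop("fewer than 2 samples after loading")
  m
}

#' Read a sample annotation table
#'
#' @param path Path to a TSV/CSV with a `sample_id` column (or first column
#'   used as sample IDs) plus condition and covariate columns.
#' @param delimiter Field delimiter; `NULL` auto-detects.
#' @return A data.frame with a `sample_id` character column.
#' @export
read_annotation <- function(path, delimiter = NULL) {
  stopifnot(file.exists(path))
  delimiter <- delimiter %||% detect_delimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE, quote = "\"")
  if (!"sample_id" %in% colnames(df)) colnames(df)[1] <- "sample_id"
  df$sample_id <- trim_ids(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in annotation")
  df
}

#' Read a miRNA-mRNA interaction table
#'
#' Accepts any delimited table with one miRNA column and one target-gene
#' column (TarBase- and TargetScan-style exports after column mapping).
#' Duplicate pairs are collapsed.
#'
#' @param path Path to the table.
#' @param mirna_column,gene_column Column names holding miRNA and target
#'   gene identifiers.
#' @param delimiter Field delimiter; `NULL` auto-detects.
#' @return Named list: miRNA identifier -> character vector of target genes.
#' @export
read_interactions <- function(path, mirna_column = "mirna",
                              gene_column = "gene", delimiter = NULL) {
  stopifnot(file.exists(path))
  delimiter <- delimiter %||% detect_delimiter(path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE, quote = "\"")
  missing_cols <- setdiff(c(mirna_column, gene_column), colnames(df))
  if (length(missing_cols) > 0L) {
    stop("column(s) not found: ", paste(missing_cols, collapse = ", "),
         "; available: ", paste(colnames(df), collapse = ", "))
  }
  mir <- trim_ids(df[[mirna_column]])
  gene <- trim_ids(df[[gene_column]])
  keep <- nzchar(mir) & nzchar(gene)
  mir <- mir[keep]; gene <- gene[keep]
  if (length(mir) == 0L) stop("no interactions parsed from ", path)
  lapply(split(gene, mir), unique)
}

#' Read a pathway co-expression network edge list
#'
#' Expects columns `pathway_a`, `pathway_b`, `weight` and optionally
#' `p_value`. Self-loops are dropped with a warning; reciprocal duplicate
#' edges are collapsed keeping the first occurrence.
#'
#' @param path Path to a TSV edge list.
#' @return An undirected [igraph::graph] with `weight` (and `p_value`)
#'   edge attributes.
#' @export
read_network_edges <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("pathway_a", "pathway_b", "weight")
  if (!all(need %in% colnames(df))) {
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  }
  df$pathway_a <- trim_ids(df$pathway_a)
  df$pathway_b <- trim_ids(df$pathway_b)
  if (any(!is.finite(df$weight)) || any(abs(df$weight) > 1)) {
    stop("edge weight outside [-1, 1]")
  }
  self <- df$pathway_a == df$pathway_b
  if (any(self)) {
    warning("dropped ", sum(self), " self-loop edge(s)")
    df <- df[!self, , drop = FALSE]
  }
  key <- ifelse(df$pathway_a < df$pathway_b,
                paste(df$pathway_a, df$pathway_b, sep = "\r"),
                paste(df$pathway_b, df$pathway_a, sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) {
    message("collapsed ", sum(dup),
            " reciprocal/duplicate edge(s), keeping first occurrence")
    df <- df[!dup, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g
}

#' Write a network as an edge-list TSV
#'
#' @param net An igraph network with a `weight` edge attribute.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_network_edges <- function(net, path) {
  el <- igraph::as_data_frame(net, what = "edges")
  colnames(el)[1:2] <- c("pathway_a", "pathway_b")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
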