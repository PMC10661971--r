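# Two-group differential regulation of pathway activity profiles with
# covariate adjustment. The default is ordinary least squares on each
# pathway row with a classical two-sided t test on the condition
# coefficient; an optional empirical-Bayes variance-moderation mode
# (limma) shrinks residual variances toward a pooled prior.

control_synonyms <- c("control", "controls", "ctrl", "normal", "reference",
                      "ref", "wt", "wildtype", "baseline", "healthy")

build_design <- function(ann, condition, case_level, covariates) {
  cond <- factor(ann[[condition]])
  if (nlevels(cond) != 2L) {
    stop("condition column '", condition, "' must have exactly 2 levels ",
         "among used samples (found ", nlevels(cond), ")")
  }
  if (is.null(case_level)) {
    is_ctrl <- tolower(levels(cond)) %in% control_synonyms
    case_level <- if (sum(is_ctrl) == 1L) levels(cond)[!is_ctrl] else {
      levels(cond)[2]
    }
    message("case level not given; using '", case_level, "'")
  }
  if (!case_level %in% levels(cond)) {
    stop("case level '", case_level, "' not a level of '", condition, "'")
  }
  cond <- stats::relevel(cond, ref = setdiff(levels(cond), case_level))
  if (min(table(cond)) < 2L) stop("each condition level needs >= 2 samples")
  df <- data.frame(.group = cond)
  for (cv in covariates) {
    if (!cv %in% colnames(ann)) stop("covariate '", cv, "' not in annotation")
    v <- ann[[cv]]
    df[[cv]] <- if (is.numeric(v)) v else factor(v)
  }
  X <- stats::model.matrix(~ ., data = df)
  colnames(X)[2] <- "group"
  X
}

#' Fit per-pathway differential-regulation linear models
#'
#' Regresses each pathway's activity profile on a case/control indicator
#' plus optional covariates (categorical covariates are one-hot encoded
#' dropping one level). The reported effect is the case-minus-control
#' coefficient; p-values come from two-sided t tests on that coefficient and
#' are BH-adjusted across all retained pathways.
#'
#' @param act Pathways-by-samples activity matrix (column names are sample
#'   IDs).
#' @param ann Annotation data.frame with a `sample_id` column.
#' @param condition Name of the two-level condition column.
#' @param case_level Level of `condition` treated as case. If `NULL`, the
#'   level that is not a recognized control synonym (control, ctrl,
#'   normal, reference, wt, baseline, healthy, ...) is used when exactly
#'   one level matches, else the second factor level; the choice is
#'   reported with a message.
#' @param covariates Character vector of covariate column names.
#' @param moderated If `TRUE`, use empirical-Bayes variance moderation
#'   (limma) instead of classical per-pathway t tests.
#' @return data.frame with columns pathway, effect, t, p_value, adjusted_p,
#'   direction (UP iff effect > 0), sorted by p (ties: larger |t| first,
#'   then pathway name).
#' @export
fit_differential <- function(act, ann, condition = "condition",
                             case_level = NULL, covariates = character(),
                             moderated = FALSE) {
  stopifnot(is.matrix(act) || inherits(act, "pathway_activity"))
  if (!"sample_id" %in% colnames(ann)) stop("annotation needs sample_id")
  use <- intersect(colnames(act), ann$sample_id)
  if (length(use) < 4L) stop("fewer than 4 annotated samples in the matrix")
  ann <- ann[match(use, ann$sample_id), , drop = FALSE]
  Y <- unclass(act)[, use, drop = FALSE]
  X <- build_design(ann, condition, case_level, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  df_res <- nrow(X) - ncol(X)
  if (df_res < 3L) stop("fewer than 3 residual degrees of freedom")
  if (moderated) {
    fit <- limma::eBayes(limma::lmFit(Y, X))
    effect <- fit$coefficients[, "group"]
    tval <- fit$t[, "group"]
    pval <- fit$p.value[, "group"]
  } else {
    coefs <- qr.coef(qrX, t(Y))
    res <- t(Y) - X %*% coefs
    sigma2 <- colSums(res^2) / df_res
    XtXinv_gg <- chol2inv(chol(crossprod(X)))[2, 2]
    effect <- coefs["group", ]
    se <- sqrt(sigma2 * XtXinv_gg)
    tval <- effect / se
    pval <- 2 * stats::pt(-abs(tval), df_res)
  }
  out <- data.frame(pathway = rownames(Y),
                    effect = unname(effect),
                    t = unname(tval),
                    p_value = unname(pval),
                    adjusted_p = adjust_fdr(unname(pval)),
                    direction = ifelse(effect > 0, "UP", "DOWN"),
                    stringsAsFactors = FALSE)
  out[order(out$p_value, -abs(out$t), out$pathway), , drop = FALSE]
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, capped at 1, returned in the original input
#' order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
adjust_fdr <- function(p_values) {
  check_pvalues(p_values)
  stats::p.adjust(p_values, method = "BH")
}

#' Select top differentially regulated pathways
#'
#' @param table Output of [fit_differential()].
#' @param mode `"top_k"` (k smallest p; ties broken by |t| then name) or
#'   `"fdr_threshold"` (all rows with adjusted p below the threshold).
#' @param k_or_alpha Integer k, or significance threshold alpha.
#' @return Character vector of pathway names, ordered by significance.
#' @export
select_top_pathways <- function(table, mode = c("top_k", "fdr_threshold"),
                                k_or_alpha) {
  mode <- match.arg(mode)
  tbl <- table[order(table$p_value, -abs(table$t), table$pathway), ,
               drop = FALSE]
  if (mode == "top_k") {
    k <- as.integer(k_or_alpha)
    if (k == 0L) {
      warning("k = 0: returning no pathways")
      return(character(0))
    }
    if (k > nrow(tbl)) {
      warning("k (", k, ") exceeds table size (", nrow(tbl),
              "); returning all pathways")
      k <- nrow(tbl)
    }
    tbl$pathway[seq_len(k)]
  } else {
    tbl$pathway[tbl$adjusted_p < k_or_alpha]
  }
}
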