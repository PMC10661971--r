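# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clip p-values away from 0 and 1 before inverse-normal or log transforms
#' @noRd
clip_pvalues <- function(p, epsilon = 1e-15) {
  stopifnot(is.numeric(p), epsilon > 0, epsilon <= 1e-6)
  pmin(pmax(p, epsilon), 1 - epsilon)
}

#' Validate a vector of p-values lies in [0, 1]
#' @noRd
check_pvalues <- function(p, what = "p-values") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(what, " must be numeric in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Derive a stage seed from a master seed, staying within 32-bit range
#' @noRd
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) * 1000003 + offset) %% 2147483647L)
}
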