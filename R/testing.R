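#' Likelihood-ratio test of nested codon models
#'
#' `stat = max(0, 2 (lnL_alt - lnL_null))`, referred to the upper tail of a
#' chi-square distribution with one degree of freedom.  Small negative
#' differences (optimiser noise in nested fits) are clamped to 0.  With
#' `mixture = TRUE` the boundary-respecting 50:50 mixture of a point mass
#' at 0 and chi-square df = 1 is used instead.
#'
#' @param lnL_null,lnL_alt log-likelihoods of the null and alternative fits.
#' @param mixture logical, default FALSE (plain chi-square df = 1).
#' @return list with `stat` and `p`.
#' @examples
#' lrt(-1000, -998.0793)  # stat ~3.84, p ~0.05
#' @export
lrt <- function(lnL_null, lnL_alt, mixture = FALSE) {
  if (!is.finite(lnL_null) || !is.finite(lnL_alt)) {
    stop("log-likelihoods must be finite")
  }
  stat <- max(0, 2 * (lnL_alt - lnL_null))
  p <- if (stat == 0) 1 else stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (mixture && stat > 0) p <- p / 2
  list(stat = stat, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment; input order is preserved in the output.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Consensus of per-gene results across alignment methods
#'
#' The screening runs every gene through two independent alignment builds;
#' a gene is called only when it is significant under every method (the
#' intersection rule).
#'
#' @param results named list (one entry per alignment method) of data frames
#'   with columns `gene_id` and the threshold field (`q` or `p`).
#' @param alpha significance threshold (default 0.05).
#' @param field which column to threshold, `"q"` (default) or `"p"`.
#' @return character vector of gene ids significant under all methods.
#' @export
consensus <- function(results, alpha = 0.05, field = c("q", "p")) {
  field <- match.arg(field)
  if (length(results) == 0) stop("need at least one result set")
  sets <- lapply(results, function(df) {
    if (nrow(df) == 0) return(character(0))
    df$gene_id[df[[field]] < alpha]
  })
  Reduce(intersect, sets)
}
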