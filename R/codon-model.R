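#' Empirical codon equilibrium frequencies (F61)
#'
#' Estimates the 61-vector of sense-codon equilibrium frequencies from the
#' observed codon table of an alignment, the empirical-frequency model used
#' for all likelihood computations in this package.  Gap and ambiguous
#' codons are ignored in the counts.  A pseudocount keeps every frequency
#' strictly positive, so the resulting rate matrix stays irreducible even on
#' short genes where some codons are unobserved.
#'
#' @param alignment a [codon_alignment] object.
#' @param pseudocount non-negative count added to every sense codon before
#'   normalisation (default 1e-6).
#' @return numeric(61) of frequencies summing to 1, named by codon.
#' @export
estimate_codon_frequencies <- function(alignment, pseudocount = 1e-6) {
  stopifnot(inherits(alignment, "codon_alignment"))
  st <- alignment$states
  counts <- tabulate(st[st >= 1L & st <= .NSTATE], nbins = .NSTATE)
  if (sum(counts) == 0) {
    stop("alignment contains no countable (unambiguous, non-gap) codons")
  }
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  if (pseudocount == 0 && any(counts == 0)) {
    stop("some sense codons are unobserved; a positive pseudocount is ",
         "required to avoid zero equilibrium frequencies")
  }
  pi <- counts + pseudocount
  pi <- pi / sum(pi)
  names(pi) <- .hearsel_code$sense
  pi
}

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61x61 instantaneous rate matrix of the Goldman-Yang codon
#' model.  For codon pairs differing at exactly one nucleotide,
#' `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]`; pairs
#' differing at more than one position have rate 0.  The matrix is rescaled
#' so the expected number of substitutions per codon per unit time is 1
#' (`-sum(pi_i q_ii) = 1`), making branch lengths expected substitutions per
#' codon.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param pi numeric(61) equilibrium codon frequencies (positive, sum 1).
#' @return an object of class `codon_rate_matrix`: list with `Q` (scaled
#'   61x61 matrix), `kappa`, `omega`, `pi`, and `scale` (the pre-scaling
#'   mean rate).
#' @examples
#' pi <- rep(1 / 61, 61)
#' Q <- codon_rate_matrix(kappa = 2, omega = 0.5, pi = pi)
#' max(abs(rowSums(Q$Q)))  # rows sum to zero
#' @export
codon_rate_matrix <- function(kappa, omega, pi) {
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) {
    stop("kappa must be a single positive number")
  }
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega < 0) {
    stop("omega must be a single non-negative number")
  }
  pi <- validate_pi(pi)
  m <- .hearsel_masks
  q <- pi[m$pair_col]
  q[m$pair_ts] <- q[m$pair_ts] * kappa
  q[m$pair_ns] <- q[m$pair_ns] * omega
  Q <- matrix(0, .NSTATE, .NSTATE)
  Q[m$pair_pos] <- q
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix: zero mean rate")
  Q <- Q / scale
  structure(list(Q = Q, kappa = kappa, omega = omega, pi = pi,
                 scale = scale),
            class = "codon_rate_matrix")
}

validate_pi <- function(pi) {
  if (length(pi) != .NSTATE || any(!is.finite(pi)) || any(pi <= 0)) {
    stop("pi must be a vector of 61 strictly positive frequencies")
  }
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  unname(pi) / sum(pi)
}

#' Symmetric eigendecomposition of a reversible codon rate matrix
#'
#' Decomposes `D^{1/2} Q D^{-1/2}` (symmetric because the Goldman-Yang chain
#' is reversible with stationary distribution `pi`), so that transition
#' matrices for any set of branch lengths come from one decomposition.
#'
#' @param Q a `codon_rate_matrix`.
#' @return list with `V` (orthogonal eigenvectors), `lambda` (eigenvalues),
#'   `sqrtpi`.
#' @keywords internal
decompose_rate_matrix <- function(Q) {
  stopifnot(inherits(Q, "codon_rate_matrix"))
  sq <- sqrt(Q$pi)
  S <- Q$Q * (sq %o% (1 / sq))
  S <- (S + t(S)) / 2  # symmetrise away rounding noise
  e <- eigen(S, symmetric = TRUE)
  list(V = e$vectors, lambda = e$values, sqrtpi = sq)
}

#' Codon transition probability matrix P(t) = exp(Qt)
#'
#' @param Q a `codon_rate_matrix`.
#' @param t branch length(s), expected substitutions per codon (>= 0).
#' @param decomp optional precomputed [decompose_rate_matrix()] result.
#' @return for scalar `t` a 61x61 stochastic matrix; for vector `t` a
#'   61 x 61 x length(t) array.
#' @examples
#' Q <- codon_rate_matrix(2, 0.5, rep(1 / 61, 61))
#' P <- transition_matrix(Q, 0.1)
#' range(rowSums(P))
#' @export
transition_matrix <- function(Q, t, decomp = NULL) {
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("branch lengths must be finite and non-negative")
  }
  if (is.null(decomp)) decomp <- decompose_rate_matrix(Q)
  P <- cpp_transition_matrices(decomp$V, decomp$lambda, decomp$sqrtpi,
                               as.numeric(t))
  if (length(t) == 1L) P[, , 1L] else P
}
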