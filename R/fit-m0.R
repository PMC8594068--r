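#' Fit the one-ratio (M0) codon model
#'
#' Maximum-likelihood fit of the Goldman-Yang one-ratio model: a single
#' dN/dS ratio `omega` and transition/transversion ratio `kappa` shared by
#' all branches and sites, with all branch lengths free.  This is the first
#' step of the two-step branch-site procedure: the estimated branch lengths
#' are subsequently frozen and passed to [fit_branch_site()].
#'
#' Optimisation is bounded quasi-Newton (`nlminb`) on log-transformed
#' parameters; bounds are `kappa` in \[0.01, 100\], `omega` in \[1e-4, 20\],
#' branch lengths in \[1e-6, 20\].
#'
#' @param alignment a [codon_alignment].
#' @param ltree a [labeled_tree]; input branch lengths, when positive, seed
#'   the optimisation.
#' @param pi codon frequencies; default [estimate_codon_frequencies()] of
#'   the alignment (F61, empirical codon table).
#' @param init optional named list with `kappa`, `omega` start values.
#' @param control passed to [stats::nlminb()] (`iter.max`, `rel.tol`...).
#' @return object of class `m0_fit`: list with `kappa`, `omega`, `tree`
#'   (a [labeled_tree] carrying the estimated branch lengths), `logLik`,
#'   `pi`, `convergence`, `n_sites`, `n_taxa`.
#' @examples
#' \donttest{
#' tr <- read_labeled_tree(text = "((A:0.2,B:0.2):0.1,C:0.3);")
#' sim <- simulate_alignment(tr, model = "M0",
#'                           params = list(kappa = 2, omega = 0.3),
#'                           n_sites = 100, seed = 1)
#' fit <- fit_m0(sim$alignment, tr)
#' coef(fit)
#' }
#' @export
fit_m0 <- function(alignment, ltree, pi = NULL, init = list(),
                   control = list()) {
  ctx <- .lik_context(alignment, ltree)
  if (ctx$ntip < 2) stop("M0 fit needs at least 2 taxa")
  if (is.null(pi)) pi <- estimate_codon_frequencies(alignment)
  pi <- validate_pi(pi)

  tol <- if (!is.null(control$tol)) control$tol else 1e-7
  max_outer <- if (!is.null(control$max_outer)) control$max_outer else 15
  nedge <- nrow(ctx$edge)
  len <- ctx$len
  len[!is.finite(len) | len < 1e-4] <- 0.1
  kappa <- if (!is.null(init$kappa)) init$kappa else 2
  omega <- if (!is.null(init$omega)) init$omega else 0.4

  full_ll <- function(kappa, omega, len) {
    dec <- decompose_rate_matrix(codon_rate_matrix(kappa, omega, pi))
    P <- .edge_P_cube(ctx, list(dec), rep(1L, nedge), len = len)
    sum(ctx$weights * .prune_patterns(ctx, P, pi))
  }

  # alternate joint (kappa, omega) refinement with per-edge branch-length
  # sweeps; each phase is monotone in the likelihood up to sweep staleness,
  # so the best visited state is tracked explicitly
  lb <- c(log(0.01), log(1e-4)); ub <- c(log(100), log(20))
  ll <- full_ll(kappa, omega, len)
  best <- list(kappa = kappa, omega = omega, len = len, ll = ll)
  converged <- FALSE
  for (outer in seq_len(max_outer)) {
    ll_prev <- ll
    negko <- function(x) {
      v <- -full_ll(exp(x[1]), exp(x[2]), len)
      if (!is.finite(v)) 1e10 else v
    }
    opt <- stats::nlminb(c(log(kappa), log(omega)), negko, lower = lb,
                         upper = ub,
                         control = list(iter.max = if (outer == 1) 30
                                        else 8))
    kappa <- exp(opt$par[1]); omega <- exp(opt$par[2])
    dec <- decompose_rate_matrix(codon_rate_matrix(kappa, omega, pi))
    len <- .optimize_lengths(ctx, dec, pi, len)
    ll <- full_ll(kappa, omega, len)
    if (ll > best$ll) best <- list(kappa = kappa, omega = omega,
                                   len = len, ll = ll)
    if (abs(ll - ll_prev) < tol) { converged <- TRUE; break }
  }

  newlen <- numeric(nedge)
  newlen[ctx$ord] <- best$len  # back to original edge order
  tree <- ltree$tree
  tree$edge.length <- newlen
  out <- list(kappa = best$kappa, omega = best$omega,
              tree = labeled_tree(tree, ltree$foreground),
              logLik = best$ll, pi = pi,
              convergence = if (converged) 0L else 1L,
              n_sites = ncol(alignment$states), n_taxa = ctx$ntip)
  class(out) <- "m0_fit"
  out
}

#' @export
print.m0_fit <- function(x, ...) {
  cat("One-ratio (M0) codon model fit\n")
  cat(sprintf("  kappa = %.4f   omega = %.4f   lnL = %.4f\n",
              x$kappa, x$omega, x$logLik))
  cat(sprintf("  %d taxa, %d codon sites, tree length %.4f\n",
              x$n_taxa, x$n_sites, sum(x$tree$tree$edge.length)))
  invisible(x)
}

#' @export
coef.m0_fit <- function(object, ...) {
  c(kappa = object$kappa, omega = object$omega)
}

#' @export
logLik.m0_fit <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- 2L + nrow(object$tree$tree$edge)
  attr(val, "nobs") <- object$n_sites
  class(val) <- "logLik"
  val
}

#' @export
summary.m0_fit <- function(object, ...) {
  print(object)
  cat("  branch lengths:\n")
  print(summary(object$tree$tree$edge.length))
  invisible(object)
}

#' @rdname simulate_alignment
#' @param object an `m0_fit`.
#' @param nsim number of simulated alignments.
#' @param seed integer seed.
#' @param ... ignored.
#' @export
simulate.m0_fit <- function(object, nsim = 1, seed = 1, ...) {
  out <- lapply(seq_len(nsim), function(i) {
    simulate_alignment(object$tree, model = "M0",
                       params = list(kappa = object$kappa,
                                     omega = object$omega, pi = object$pi),
                       n_sites = object$n_sites, seed = seed + i - 1L)
  })
  if (nsim == 1) out[[1]] else out
}
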