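#' Bayes empirical Bayes site-class posteriors
#'
#' Posterior probability that each codon site belongs to the positively
#' selected classes (2a + 2b) of branch-site Model A, integrating the
#' mixture parameters `(p0, p1, omega0, omega2)` over a uniform grid while
#' holding `kappa` and the branch lengths at their maximum-likelihood
#' estimates.  Each retained grid cell receives equal prior mass (cells
#' with `p0 + p1 > 1` are dropped).  A site is called positively selected
#' (PSS) when its posterior exceeds `threshold`.
#'
#' Because the prior factorises over the proportion grid and the omega
#' grid, the posterior for class k is the product of the prior-averaged
#' class proportion and the grid-averaged class likelihood; this equals the
#' full sum over the product grid exactly.
#'
#' @param alignment a [codon_alignment].
#' @param ltree a [labeled_tree] with the (fixed) branch lengths used in
#'   the fit and a non-empty foreground.
#' @param mle a [branch_site_params] from the alternative-model fit.
#' @param grid_points grid resolution per free parameter (default 10;
#'   >= 2 except via an explicit `grid`).
#' @param threshold PSS posterior cutoff (default 0.95).
#' @param grid optional list with numeric vectors `p0`, `p1`, `omega0`,
#'   `omega2` giving explicit grid values (overrides `grid_points`);
#'   passing the MLE values collapses the integration to naive empirical
#'   Bayes.
#' @param omega2_max upper edge of the `omega2` grid (default 11).
#' @param reference_taxon optional taxon name; adds 1-based codon positions
#'   on that taxon's ungapped sequence (NA where the taxon has a gap).
#' @return data.frame, one row per alignment codon site: `site`,
#'   `ref_site` (if requested), class posteriors `p_class0`, `p_class1`,
#'   `p_class2a`, `p_class2b`, `p_positive`, `is_pss`.
#' @export
beb_posteriors <- function(alignment, ltree, mle, grid_points = 10,
                           threshold = 0.95, grid = NULL, omega2_max = 11,
                           reference_taxon = NULL) {
  stopifnot(inherits(mle, "branch_site_params"))
  ctx <- .lik_context(alignment, ltree)
  if (!any(ctx$fg)) stop("BEB requires a non-empty foreground")
  pi <- mle$pi
  if (is.null(grid)) {
    if (grid_points < 2) stop("grid_points must be >= 2")
    mid <- (seq_len(grid_points) - 0.5) / grid_points
    grid <- list(p0 = mid, p1 = mid, omega0 = mid,
                 omega2 = 1 + mid * (omega2_max - 1))
  }

  # proportion part: prior-averaged class proportions over the (p0, p1)
  # cells with p0 + p1 <= 1
  pp <- expand.grid(p0 = grid$p0, p1 = grid$p1)
  pp <- pp[pp$p0 + pp$p1 <= 1 + 1e-12, , drop = FALSE]
  if (nrow(pp) == 0) stop("empty proportion grid")
  prop <- t(apply(pp, 1, function(r) {
    rest <- max(0, 1 - r[1] - r[2])
    c(r[1], r[2], rest * r[1] / (r[1] + r[2]), rest * r[2] / (r[1] + r[2]))
  }))
  A <- colMeans(prop)  # equal mass per retained cell

  # the common rate scale of the mixture is held at its MLE value, like
  # kappa and the branch lengths; grid omegas get their relative rates
  rate_of <- function(w) codon_rate_matrix(mle$kappa, w, pi)$scale
  R <- (mle$p0 + mle$p2a) * rate_of(mle$omega0) +
    (mle$p1 + mle$p2b) * rate_of(1)
  fg_idx <- which(ctx$fg)
  nedge <- nrow(ctx$edge)

  # likelihood part: per-class pattern log-likelihoods on the omega grid
  n_pat <- length(ctx$weights)
  g0 <- length(grid$omega0); g2 <- length(grid$omega2)
  ls0 <- matrix(0, n_pat, g0)          # class 0: depends on omega0
  ls2a <- array(0, c(n_pat, g0, g2))   # class 2a: omega0 x omega2
  ls2b <- matrix(0, n_pat, g2)         # class 2b: omega2
  dec1 <- decompose_rate_matrix(codon_rate_matrix(mle$kappa, 1, pi))
  rho1 <- rate_of(1) / R
  P1 <- .edge_P_cube(ctx, list(dec1), rep(1L, nedge),
                     len = ctx$len * rho1)
  ls1 <- .prune_patterns(ctx, P1, pi)
  P2fg <- lapply(grid$omega2, function(w) {
    dec2 <- decompose_rate_matrix(codon_rate_matrix(mle$kappa, w, pi))
    cpp_transition_matrices(dec2$V, dec2$lambda, dec2$sqrtpi,
                            ctx$len[fg_idx] * rate_of(w) / R)
  })
  for (j in seq_len(g2)) {
    Pb <- P1; Pb[, , fg_idx] <- P2fg[[j]]
    ls2b[, j] <- .prune_patterns(ctx, Pb, pi)
  }
  for (i in seq_len(g0)) {
    dec0 <- decompose_rate_matrix(codon_rate_matrix(mle$kappa,
                                                    grid$omega0[i], pi))
    P0 <- .edge_P_cube(ctx, list(dec0), rep(1L, nedge),
                       len = ctx$len * rate_of(grid$omega0[i]) / R)
    ls0[, i] <- .prune_patterns(ctx, P0, pi)
    for (j in seq_len(g2)) {
      Pa <- P0; Pa[, , fg_idx] <- P2fg[[j]]
      ls2a[, i, j] <- .prune_patterns(ctx, Pa, pi)
    }
  }

  # per-pattern scaling before exponentiation
  M <- pmax(apply(ls0, 1, max), ls1, apply(ls2b, 1, max),
            apply(ls2a, 1, function(v) max(v)))
  B <- cbind(rowMeans(exp(ls0 - M)),
             exp(ls1 - M),
             apply(exp(sweep(ls2a, 1, M, "-")), 1, mean),
             rowMeans(exp(ls2b - M)))
  num <- sweep(B, 2, A, "*")
  tot <- rowSums(num)
  if (any(tot <= 0 | !is.finite(tot))) {
    bad <- which(ctx$map %in% which(tot <= 0 | !is.finite(tot)))[1]
    stop("integrated likelihood is zero at site ", bad)
  }
  post <- num / tot

  post_sites <- post[ctx$map, , drop = FALSE]
  out <- data.frame(site = seq_len(nrow(post_sites)),
                    p_class0 = post_sites[, 1], p_class1 = post_sites[, 2],
                    p_class2a = post_sites[, 3], p_class2b = post_sites[, 4])
  out$p_positive <- out$p_class2a + out$p_class2b
  out$is_pss <- out$p_positive > threshold
  if (!is.null(reference_taxon)) {
    if (!reference_taxon %in% alignment$taxa) {
      stop("reference taxon ", reference_taxon, " not in alignment")
    }
    gap <- alignment$states[reference_taxon, ] == 0L
    ref <- cumsum(!gap)
    ref[gap] <- NA_integer_
    out <- cbind(out[, "site", drop = FALSE], ref_site = ref,
                 out[, -1, drop = FALSE])
  }
  out
}
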