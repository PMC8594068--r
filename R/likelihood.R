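# Likelihood plumbing shared by the M0 and branch-site fits: a precomputed
# "context" (postorder traversal, tip partial cube, site-pattern
# compression) and thin wrappers over the C++ pruning kernel.

# Build the reusable likelihood context for one alignment/tree pair.
.lik_context <- function(alignment, ltree) {
  stopifnot(inherits(alignment, "codon_alignment"),
            inherits(ltree, "labeled_tree"))
  tree <- ltree$tree
  if (!setequal(tree$tip.label, alignment$taxa)) {
    stop("tree tips and alignment taxa differ: tree-only {",
         paste(setdiff(tree$tip.label, alignment$taxa), collapse = ","),
         "}, alignment-only {",
         paste(setdiff(alignment$taxa, tree$tip.label), collapse = ","), "}")
  }
  ord <- if (nrow(tree$edge) <= 1L) {
    seq_len(nrow(tree$edge))  # trivial tree; reorder() chokes on 1 tip
  } else {
    ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  }
  edge <- tree$edge[ord, , drop = FALSE]
  len <- tree$edge.length[ord]
  fg <- (seq_len(nrow(tree$edge)) %in% ltree$foreground)[ord]

  st <- alignment$states[tree$tip.label, , drop = FALSE]
  key <- apply(st, 2, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  weights <- tabulate(map, nbins = sum(first))

  tips_full <- tip_partials(alignment, taxa = tree$tip.label)
  tips <- tips_full[, first, , drop = FALSE]

  ntip <- length(tree$tip.label)
  root <- setdiff(unique(edge[, 1]), edge[, 2])
  kids <- split(seq_len(nrow(edge)), edge[, 1])  # child edges per node
  list(edge = edge, len = len, fg = fg, tips = tips, weights = weights,
       map = map, root = as.integer(root[1]), ntip = ntip,
       nnode = ntip + tree$Nnode, ord = ord, kids = kids)
}

# Transition-matrix cube for one edge->decomposition assignment.
# decomps: list of decompose_rate_matrix() results; assign: integer per edge.
.edge_P_cube <- function(ctx, decomps, assign, len = ctx$len) {
  P <- array(0, dim = c(.NSTATE, .NSTATE, nrow(ctx$edge)))
  for (d in unique(assign)) {
    idx <- which(assign == d)
    dec <- decomps[[d]]
    P[, , idx] <- cpp_transition_matrices(dec$V, dec$lambda, dec$sqrtpi,
                                          len[idx])
  }
  P
}

# Per-pattern log-likelihood under a single rate-matrix assignment.
.prune_patterns <- function(ctx, P, pi) {
  cpp_prune_loglik(ctx$edge, ctx$tips, P, pi, ctx$nnode, ctx$root)
}

#' Per-site log-likelihoods by Felsenstein pruning
#'
#' Computes the log-likelihood of every codon site given an alignment, a
#' tree, and one transition probability matrix per branch, by postorder
#' pruning with per-node log scaling.  Root states are combined with the
#' equilibrium frequencies `pi`.  Sites that are entirely missing (gaps in
#' all taxa) have log-likelihood 0.
#'
#' @param alignment a [codon_alignment].
#' @param ltree a [labeled_tree] whose tips match the alignment taxa.
#' @param P 61 x 61 x nedge array: slice `i` is the transition matrix for
#'   row `i` of `ltree$tree$edge`.
#' @param pi numeric(61) root/equilibrium codon frequencies.
#' @return numeric(nsites) of per-site log-likelihoods.
#' @export
site_log_likelihood <- function(alignment, ltree, P, pi) {
  ctx <- .lik_context(alignment, ltree)
  pi <- validate_pi(pi)
  if (!identical(dim(P)[3], nrow(ltree$tree$edge)) &&
      dim(P)[3] != nrow(ltree$tree$edge)) {
    stop("need one transition matrix per edge")
  }
  Ppo <- P[, , ctx$ord, drop = FALSE]
  ls <- .prune_patterns(ctx, Ppo, pi)
  as.numeric(ls[ctx$map])
}

# Unscaled mean substitution rates r(omega) for the three omega values of
# Model A; the common scale factor R = (p0 + p2a) r(omega0) +
# (p1 + p2b) r(1) makes a branch length the expected number of
# substitutions per codon averaged over site classes on the background,
# so site classes keep their relative rates (class 2 sites really do
# evolve faster on the foreground, rather than merely shifting the
# synonymous/nonsynonymous composition).
.modelA_rates <- function(kappa, omega0, omega2, pi) {
  c(r0 = codon_rate_matrix(kappa, omega0, pi)$scale,
    r1 = codon_rate_matrix(kappa, 1, pi)$scale,
    r2 = codon_rate_matrix(kappa, omega2, pi)$scale)
}

# Branch-site Model A per-pattern, per-class log-likelihoods.
# Classes: 1 = (bg w0, fg w0); 2 = (bg 1, fg 1); 3 = (bg w0, fg w2);
# 4 = (bg 1, fg w2).  `rho` gives the branch-length multiplier for each of
# the three omega values (r(omega)/R under the common-scale convention).
# Returns npattern x 4 matrix.  Transition matrices are shared across
# classes: one full cube per background omega, plus foreground-edge slices
# for omega2.
.modelA_class_logliks <- function(ctx, kappa, omega0, omega2, pi,
                                  rho = c(1, 1, 1)) {
  dec0 <- decompose_rate_matrix(codon_rate_matrix(kappa, omega0, pi))
  dec1 <- decompose_rate_matrix(codon_rate_matrix(kappa, 1, pi))
  null_equal <- omega2 == 1 && rho[3] == rho[2]
  dec2 <- if (null_equal) dec1 else
    decompose_rate_matrix(codon_rate_matrix(kappa, omega2, pi))
  fg_idx <- which(ctx$fg)
  cpp_modelA_logliks(ctx$edge, ctx$tips,
                     dec0$V, dec0$lambda, dec1$V, dec1$lambda,
                     dec2$V, dec2$lambda, dec0$sqrtpi,
                     ctx$len, as.numeric(rho), as.integer(fg_idx), pi,
                     ctx$nnode, ctx$root, null_equal)
}

# One exact coordinate-ascent sweep over branch lengths for a fixed rate
# matrix.  Each edge is optimised by Brent against its outside (root-side)
# and inside (subtree) partials, recomputed from the current lengths before
# every edge, so each 1-D step is an exact profile of the full likelihood
# and the sweep is monotone.  A single Brent evaluation costs one 61 x 61
# matrix product instead of a full pruning pass.
.optimize_lengths <- function(ctx, dec, pi, len, min_bl = 1e-6,
                              max_bl = 20, tol = 1e-7) {
  nedge <- nrow(ctx$edge)
  npat <- length(ctx$weights)
  w <- ctx$weights
  kids <- ctx$kids
  # edge leading to each node (0 for the root)
  parent_edge <- integer(ctx$nnode)
  parent_edge[ctx$edge[, 2]] <- seq_len(nedge)
  P <- .edge_P_cube(ctx, list(dec), rep(1L, nedge), len = len)

  # outside partial at the parent of edge e, given fresh up-pass results
  outside_at <- function(e, up) {
    u <- ctx$edge[e, 1]
    chain <- integer(0)
    while (u != ctx$root) {
      pe <- parent_edge[u]
      chain <- c(pe, chain)
      u <- ctx$edge[pe, 1]
    }
    A <- matrix(pi, .NSTATE, npat)
    lsA <- numeric(npat)
    walk <- c(chain, e)
    for (k in seq_along(walk)) {
      ee <- walk[k]
      uu <- ctx$edge[ee, 1]
      for (e2 in setdiff(kids[[as.character(uu)]], ee)) {
        A <- A * up$contrib[, , e2]
        lsA <- lsA + up$ls_in[ctx$edge[e2, 2], ]
      }
      m <- apply(A, 2, max)
      m[m <= 0] <- 1
      A <- sweep(A, 2, m, "/")
      lsA <- lsA + log(m)
      if (k < length(walk)) {  # transport through edge ee to its child
        A <- crossprod(P[, , ee], A)
      }
    }
    list(A = A, ls = lsA)
  }

  for (e in rev(seq_len(nedge))) {
    up <- cpp_prune_all(ctx$edge, ctx$tips, P, pi, ctx$nnode, ctx$root)
    os <- outside_at(e, up)
    v <- ctx$edge[e, 2]
    B <- up$inhat[, , v]
    ls <- os$ls + up$ls_in[v, ]
    f <- function(t) {
      Pt <- cpp_transition_matrices(dec$V, dec$lambda, dec$sqrtpi,
                                    t)[, , 1]
      cpp_edge_loglik(os$A, B, Pt, ls, w)
    }
    opt <- stats::optimize(f, c(min_bl, max_bl), maximum = TRUE,
                           tol = tol)
    if (opt$objective > f(len[e])) {
      len[e] <- opt$maximum
      P[, , e] <- cpp_transition_matrices(dec$V, dec$lambda, dec$sqrtpi,
                                          len[e])[, , 1]
    }
  }
  len
}

# log of the mixture likelihood given per-class pattern log-likelihoods
# (npattern x K) and class proportions p (K), summed over patterns with
# multiplicity weights.
.mixture_loglik <- function(class_ls, p, weights) {
  lp <- sweep(class_ls, 2, log(p), "+")
  m <- apply(lp, 1, max)
  ll <- m + log(rowSums(exp(lp - m)))
  sum(weights * ll)
}
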