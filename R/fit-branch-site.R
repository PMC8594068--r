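#' Branch-site Model A parameter vector
#'
#' The parameters of the branch-site Model A mixture.  Sites fall into four
#' classes: class 0 (proportion `p0`) evolves with `omega0 <= 1` on all
#' branches; class 1 (`p1`) is neutral (`omega = 1`) everywhere; classes 2a
#' and 2b take `omega2 >= 1` on the foreground branches while keeping
#' `omega0` (2a) or 1 (2b) on the background.  Their proportions derive
#' from `p0`, `p1`:
#' `p2a = (1 - p0 - p1) p0 / (p0 + p1)`, `p2b = (1 - p0 - p1) p1 / (p0 + p1)`.
#'
#' @param kappa transition/transversion ratio.
#' @param omega0 background/purifying dN/dS, in (0, 1].
#' @param omega2 foreground positive-selection dN/dS, >= 1.
#' @param p0,p1 class-0 and class-1 proportions, with `p0 + p1 <= 1`.
#' @param pi numeric(61) codon frequencies.
#' @return object of class `branch_site_params` with the inputs plus `p2a`,
#'   `p2b` and the 4-vector `proportions`.
#' @export
branch_site_params <- function(kappa, omega0, omega2, p0, p1, pi) {
  if (omega0 <= 0 || omega0 > 1) stop("omega0 must be in (0, 1]")
  if (omega2 < 1) stop("omega2 must be >= 1")
  if (p0 < 0 || p1 < 0 || p0 + p1 > 1 + 1e-12) {
    stop("need p0, p1 >= 0 with p0 + p1 <= 1")
  }
  if (p0 + p1 <= 0) stop("p0 + p1 must be positive")
  pi <- validate_pi(pi)
  rest <- max(0, 1 - p0 - p1)
  p2a <- rest * p0 / (p0 + p1)
  p2b <- rest * p1 / (p0 + p1)
  structure(list(kappa = kappa, omega0 = omega0, omega2 = omega2,
                 p0 = p0, p1 = p1, p2a = p2a, p2b = p2b,
                 proportions = c(p0 = p0, p1 = p1, p2a = p2a, p2b = p2b),
                 pi = pi),
            class = "branch_site_params")
}

#' @export
print.branch_site_params <- function(x, ...) {
  cat("Branch-site Model A parameters\n")
  cat(sprintf("  kappa = %.4f  omega0 = %.4f  omega2 = %.4f\n",
              x$kappa, x$omega0, x$omega2))
  cat(sprintf("  p0 = %.4f  p1 = %.4f  p2a = %.4f  p2b = %.4f\n",
              x$p0, x$p1, x$p2a, x$p2b))
  invisible(x)
}

# fixed deterministic multi-start points on (s1 = p0+p1, s2 = p0/(p0+p1),
# omega0, kappa, omega2); local-minimum insurance for the mixture fit
.bs_starts <- list(
  list(s1 = 0.85, s2 = 0.75, omega0 = 0.2, kappa = 2.0, omega2 = 2.5),
  list(s1 = 0.60, s2 = 0.50, omega0 = 0.5, kappa = 2.0, omega2 = 5.0),
  list(s1 = 0.95, s2 = 0.40, omega0 = 0.05, kappa = 1.0, omega2 = 1.2))

.logit <- function(p) log(p / (1 - p))
.invlogit <- function(x) 1 / (1 + exp(-x))

#' Fit branch-site Model A (alternative or null)
#'
#' Maximum-likelihood fit of branch-site Model A over a tree whose branch
#' lengths are held fixed (the two-step procedure: estimate lengths with
#' [fit_m0()] first).  The alternative model frees `kappa`, `omega0`,
#' `omega2` and the class proportions; the null model of branch-site test 2
#' fixes `omega2 = 1`, so positive selection on the foreground is not
#' allowed but the four-class structure is retained.
#'
#' Optimisation uses `nlminb` on transformed parameters (logit for the
#' proportion simplex, log for `kappa` and `omega0`, log for `omega2 - 1`)
#' with bounds `kappa` in \[0.01, 100\], `omega0` in \[1e-4, 1\], `omega2` in
#' \[1, 50\], and takes the best of `n_starts` fixed deterministic starts
#' (plus any user-supplied `init`).
#'
#' @param alignment a [codon_alignment].
#' @param ltree a [labeled_tree] with fixed branch lengths and a non-empty
#'   foreground set.
#' @param null logical; fix `omega2 = 1` (the test-2 null)?
#' @param pi codon frequencies (default empirical F61 from the alignment).
#' @param init optional `branch_site_params` (or plain list) used as an
#'   additional start point.
#' @param n_starts number of fixed starts to use (1..3, default 3).
#' @param control passed to [stats::nlminb()].
#' @return object of class `branch_site_fit`: list with `params`
#'   (a [branch_site_params]), `logLik`, `null`, `convergence`,
#'   `n_sites`, `n_taxa`.
#' @export
fit_branch_site <- function(alignment, ltree, null = FALSE, pi = NULL,
                            init = NULL, n_starts = 3,
                            control = list(iter.max = 60, eval.max = 400,
                                           rel.tol = 1e-8)) {
  ctx <- .lik_context(alignment, ltree)
  if (!any(ctx$fg)) stop("branch-site fit requires a non-empty foreground")
  if (is.null(pi)) pi <- estimate_codon_frequencies(alignment)
  pi <- validate_pi(pi)

  # The class proportions enter the likelihood only through the (cheap)
  # mixture over precomputed class likelihoods, so they are profiled out:
  # the outer optimiser runs on [log kappa, log omega0, log(omega2 - 1)]
  # (last term absent under the null) and every outer evaluation maximises
  # over (p0, p1) on the logit-transformed simplex, warm-started from the
  # previous evaluation.
  lb <- c(log(0.01), log(1e-4), log(1e-8))
  ub <- c(log(100), 0, log(49))
  npar <- if (null) 2L else 3L
  lb <- lb[seq_len(npar)]; ub <- ub[seq_len(npar)]

  # Profile the class proportions out by EM.  The Model A proportions
  # factorise as a product of two binaries, (s2, 1-s2) x (s1, 1-s1), so the
  # M-step is closed-form and every iteration is monotone; the best of a
  # fixed set of deterministic starts is returned.  The class
  # log-likelihoods are fixed here, so each EM pass costs only O(npat).
  w <- ctx$weights
  sw <- sum(w)
  profile_ll <- function(cls, extra_start = NULL) {
    M <- apply(cls, 1, max)
    E <- exp(cls - M)
    wM <- sum(w * M)
    negp <- function(z) {
      s1 <- .invlogit(z[1]); s2 <- .invlogit(z[2])
      p <- c(s1 * s2, s1 * (1 - s2), (1 - s1) * s2, (1 - s1) * (1 - s2))
      v <- -(sum(w * log(as.vector(E %*% p))) + wM)
      if (is.finite(v)) v else 1e10
    }
    emrun <- function(s1, s2) {
      ll <- -Inf
      for (i in 1:60) {
        p <- c(s1 * s2, s1 * (1 - s2), (1 - s1) * s2, (1 - s1) * (1 - s2))
        tot <- as.vector(E %*% p)
        ll_new <- sum(w * log(tot)) + wM
        if (ll_new - ll < 1e-8) { ll <- ll_new; break }
        ll <- ll_new
        g <- p * as.vector(crossprod(E, w / tot)) / sw
        s1 <- min(max(g[1] + g[2], 1e-8), 1 - 1e-8)
        s2 <- min(max(g[1] + g[3], 1e-8), 1 - 1e-8)
      }
      # quasi-Newton polish of the (cheap) profiled surface
      po <- stats::nlminb(c(.logit(s1), .logit(s2)), negp,
                          lower = c(-18.4, -18.4), upper = c(18.4, 18.4))
      list(s1 = .invlogit(po$par[1]), s2 = .invlogit(po$par[2]),
           ll = -po$objective)
    }
    starts <- list(c(0.85, 0.75), c(0.5, 0.5), c(0.98, 0.5))
    if (!is.null(extra_start)) starts <- c(list(extra_start), starts)
    best <- NULL
    for (s in starts) {
      r <- emrun(s[1], s[2])
      if (is.null(best) || r$ll > best$ll) best <- r
    }
    best
  }

  # The common scale R couples the proportions to the expensive pruning
  # step.  Each outer run holds the proportions inside R fixed, so the
  # outer objective is smooth and deterministic; a few outer rounds then
  # update those proportions to self-consistency.
  make_obj <- function(p_scale, em_start) {
    function(y) {
      kappa <- exp(y[1]); omega0 <- exp(y[2])
      omega2 <- if (null) 1 else 1 + exp(y[3])
      r <- .modelA_rates(kappa, omega0, omega2, pi)
      R <- (p_scale[1] + p_scale[3]) * r[1] +
        (p_scale[2] + p_scale[4]) * r[2]
      cls <- .modelA_class_logliks(ctx, kappa, omega0, omega2, pi,
                                   rho = r / R)
      -profile_ll(cls, em_start)$ll
    }
  }
  recover <- function(y, p_scale, em_start) {
    kappa <- exp(y[1]); omega0 <- exp(y[2])
    omega2 <- if (null) 1 else 1 + exp(y[3])
    r <- .modelA_rates(kappa, omega0, omega2, pi)
    R <- (p_scale[1] + p_scale[3]) * r[1] +
      (p_scale[2] + p_scale[4]) * r[2]
    cls <- .modelA_class_logliks(ctx, kappa, omega0, omega2, pi,
                                 rho = r / R)
    em <- profile_ll(cls, em_start)
    list(kappa = kappa, omega0 = omega0, omega2 = omega2, em = em, R = R,
         p = c(em$s1 * em$s2, em$s1 * (1 - em$s2),
               (1 - em$s1) * em$s2, (1 - em$s1) * (1 - em$s2)))
  }

  to_start <- function(st) {
    list(y = pmin(pmax(c(log(st$kappa), log(st$omega0),
                         log(max(st$omega2 - 1, 1e-8)))[seq_len(npar)],
                       lb), ub),
         s = c(st$s1, st$s2))
  }
  starts <- lapply(.bs_starts[seq_len(max(1, min(n_starts, 3)))], to_start)
  if (!is.null(init)) {
    s1 <- min(max(init$p0 + init$p1, 1e-6), 1 - 1e-6)
    starts <- c(starts, list(to_start(list(
      s1 = s1, s2 = min(max(init$p0 / s1, 1e-6), 1 - 1e-6),
      omega0 = init$omega0, kappa = init$kappa,
      omega2 = max(init$omega2, 1 + 1e-6)))))
  }

  best <- NULL
  for (st in starts) {
    s1 <- st$s[1]; s2 <- st$s[2]
    p_scale <- c(s1 * s2, s1 * (1 - s2), (1 - s1) * s2,
                 (1 - s1) * (1 - s2))
    y_cur <- st$y
    em_start <- st$s
    obj_prev <- Inf
    fin <- NULL
    opt <- NULL
    for (round in 1:2) {
      obj <- make_obj(p_scale, em_start)
      ctl <- control
      if (round > 1) ctl$iter.max <- 12  # warm-started refinement
      opt <- stats::nlminb(y_cur, obj, lower = lb, upper = ub,
                           control = ctl)
      fin <- recover(opt$par, p_scale, em_start)
      y_cur <- opt$par
      em_start <- c(fin$em$s1, fin$em$s2)
      p_scale <- fin$p
      if (abs(opt$objective - obj_prev) < 1e-5) break
      obj_prev <- opt$objective
    }
    cand <- list(fin = fin, objective = -fin$em$ll,
                 convergence = opt$convergence, message = opt$message)
    if (is.null(best) || cand$objective < best$objective) best <- cand
  }
  # Canonical likelihood: the common scale computed from the candidate's
  # own proportions, so every fit (null or alternative, any search path)
  # is scored by the same well-defined function of the parameters.
  canonical <- function(kappa, omega0, omega2, p) {
    r <- .modelA_rates(kappa, omega0, omega2, pi)
    R <- (p[1] + p[3]) * r[1] + (p[2] + p[4]) * r[2]
    cls <- .modelA_class_logliks(ctx, kappa, omega0, omega2, pi,
                                 rho = r / R)
    list(ll = .mixture_loglik(cls, pmax(p, 1e-300), w), R = R)
  }
  fin <- best$fin
  cand <- list(kappa = fin$kappa, omega0 = fin$omega0,
               omega2 = fin$omega2, p = fin$p)
  sc <- canonical(cand$kappa, cand$omega0, cand$omega2, cand$p)
  if (!is.null(init)) {
    # the caller's start (typically the null optimum) is kept as a
    # candidate, which makes nested fits monotone by construction
    p_init <- c(init$p0, init$p1, init$p2a, init$p2b)
    w2_init <- if (null) 1 else max(init$omega2, 1)
    sc0 <- canonical(init$kappa, init$omega0, w2_init, p_init)
    if (sc0$ll > sc$ll) {
      cand <- list(kappa = init$kappa, omega0 = init$omega0,
                   omega2 = w2_init, p = p_init)
      sc <- sc0
    }
  }
  params <- branch_site_params(
    kappa = cand$kappa, omega0 = cand$omega0, omega2 = cand$omega2,
    p0 = cand$p[1], p1 = cand$p[2], pi = pi)
  structure(list(params = params, logLik = sc$ll, null = null,
                 scale = sc$R, convergence = best$convergence,
                 message = best$message,
                 n_sites = ncol(alignment$states), n_taxa = ctx$ntip),
            class = "branch_site_fit")
}

#' @export
print.branch_site_fit <- function(x, ...) {
  cat(sprintf("Branch-site Model A fit (%s)\n",
              if (x$null) "null: omega2 = 1" else "alternative"))
  cat(sprintf("  lnL = %.4f\n", x$logLik))
  print(x$params)
  invisible(x)
}

#' @export
coef.branch_site_fit <- function(object, ...) {
  p <- object$params
  c(kappa = p$kappa, omega0 = p$omega0, omega2 = p$omega2,
    p0 = p$p0, p1 = p$p1)
}

#' @export
logLik.branch_site_fit <- function(object, ...) {
  val <- object$logLik
  attr(val, "df") <- if (object$null) 4L else 5L
  attr(val, "nobs") <- object$n_sites
  class(val) <- "logLik"
  val
}

#' Branch-site test of positive selection for one gene
#'
#' The package's headline procedure: the branch-site Model A test 2 of
#' positive selection on a labelled foreground branch, run as the two-step
#' scheme used for the screening.  Branch lengths are first estimated under
#' the one-ratio M0 model and then frozen; the Model A alternative
#' (`omega2 >= 1` free) and null (`omega2 = 1`) are fitted on the fixed
#' tree; twice the log-likelihood difference is referred to a chi-square
#' distribution with 1 degree of freedom.  The alternative fit always
#' includes the null optimum among its start points, so the nesting
#' `lnL_alt >= lnL_null` holds by construction.
#'
#' @param alignment a [codon_alignment].
#' @param ltree a [labeled_tree] with a non-empty foreground.
#' @param gene_id identifier carried into the result (default "gene").
#' @param pi codon frequencies (default empirical F61).
#' @param n_starts multi-start count for the Model A fits.
#' @param mixture use the 50:50 point-mass/chi-square boundary mixture for
#'   the p-value instead of plain chi-square df = 1 (default FALSE).
#' @param beb also compute Bayes empirical Bayes site posteriors from the
#'   alternative fit (default FALSE); see [beb_posteriors()].
#' @param ... further arguments passed to [beb_posteriors()].
#' @return object of class `branch_site_test`: list with `gene_id`,
#'   `m0`, `fit_null`, `fit_alt`, `lnL_null`, `lnL_alt`, `lrt_stat`,
#'   `p_value`, `n_sites`, `n_taxa`, and optionally `sites` (BEB table).
#' @examples
#' \donttest{
#' tr <- read_labeled_tree(text = "((A:0.3,B:0.3)#1:0.1,(C:0.3,D:0.3):0.1);")
#' sim <- simulate_alignment(tr, model = "MODEL_A",
#'   params = list(kappa = 2, omega0 = 0.2, omega2 = 4, p0 = 0.6, p1 = 0.3),
#'   n_sites = 150, seed = 7)
#' bst <- branch_site_test(sim$alignment, tr, gene_id = "toy")
#' bst
#' }
#' @export
branch_site_test <- function(alignment, ltree, gene_id = "gene", pi = NULL,
                             n_starts = 3, mixture = FALSE, beb = FALSE,
                             ...) {
  if (is.null(pi)) pi <- estimate_codon_frequencies(alignment)
  m0 <- fit_m0(alignment, ltree, pi = pi)
  fixed <- m0$tree
  fit0 <- fit_branch_site(alignment, fixed, null = TRUE, pi = pi,
                          n_starts = n_starts)
  fit1 <- fit_branch_site(alignment, fixed, null = FALSE, pi = pi,
                          init = fit0$params, n_starts = n_starts)
  test <- lrt(fit0$logLik, fit1$logLik, mixture = mixture)
  out <- list(gene_id = gene_id, m0 = m0, fit_null = fit0, fit_alt = fit1,
              lnL_null = fit0$logLik, lnL_alt = fit1$logLik,
              lrt_stat = test$stat, p_value = test$p,
              n_sites = ncol(alignment$states),
              n_taxa = length(alignment$taxa))
  if (beb) {
    out$sites <- beb_posteriors(alignment, fixed, fit1$params, ...)
  }
  class(out) <- "branch_site_test"
  out
}

#' @export
print.branch_site_test <- function(x, ...) {
  cat("Branch-site test of positive selection (Model A, test 2)\n")
  cat(sprintf("  gene: %s  (%d taxa, %d codon sites)\n",
              x$gene_id, x$n_taxa, x$n_sites))
  cat(sprintf("  lnL null = %.4f   lnL alt = %.4f\n",
              x$lnL_null, x$lnL_alt))
  cat(sprintf("  2*dlnL = %.4f   p (chi-sq, df = 1) = %.4g\n",
              x$lrt_stat, x$p_value))
  cat(sprintf("  omega2 = %.3f on %.1f%% of sites (classes 2a + 2b)\n",
              x$fit_alt$params$omega2,
              100 * (x$fit_alt$params$p2a + x$fit_alt$params$p2b)))
  if (!is.null(x$sites)) {
    cat(sprintf("  positively selected sites (BEB): %d\n",
                sum(x$sites$is_pss)))
  }
  invisible(x)
}

#' @export
summary.branch_site_test <- function(object, ...) {
  print(object)
  cat("\nAlternative-model parameters:\n")
  print(object$fit_alt$params)
  invisible(object)
}

#' @export
coef.branch_site_test <- function(object, ...) coef(object$fit_alt)

#' Flatten branch-site test results into a per-gene record
#'
#' @param tests list of `branch_site_test` objects.
#' @return data.frame with one row per gene (lnL pair, LRT statistic, p,
#'   parameter estimates), without multiplicity correction; see [bh_fdr()].
#' @export
gene_test_table <- function(tests) {
  do.call(rbind, lapply(tests, function(x) {
    p <- x$fit_alt$params
    data.frame(gene_id = x$gene_id, lnL_null = x$lnL_null,
               lnL_alt = x$lnL_alt, lrt_stat = x$lrt_stat,
               p = x$p_value, kappa = p$kappa, omega0 = p$omega0,
               omega2 = p$omega2, p0 = p$p0, p1 = p$p1,
               n_sites = x$n_sites, n_taxa = x$n_taxa,
               stringsAsFactors = FALSE)
  }))
}
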