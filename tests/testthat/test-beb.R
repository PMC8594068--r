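test_that("grid posteriors equal exhaustive summation on a toy problem", {
  tr <- read_labeled_tree(text = "((A:0.3,B:0.4):0.1 #1,C:0.5);")
  aln <- codon_alignment(c(A = "ATGCGT", B = "ATGAGA", C = "ATGCGC"))
  pi <- rep(1 / 61, 61)
  mle <- branch_site_params(kappa = 2, omega0 = 0.2, omega2 = 4,
                            p0 = 0.6, p1 = 0.3, pi = pi)
  grid <- list(p0 = c(0.25, 0.75), p1 = c(0.25, 0.75),
               omega0 = c(0.25, 0.75), omega2 = c(2, 6))
  post <- beb_posteriors(aln, tr, mle, grid = grid)
  oracle <- beb_oracle(aln, tr, mle, grid)
  got <- as.matrix(post[, c("p_class0", "p_class1", "p_class2a",
                            "p_class2b")])
  dimnames(got) <- NULL
  expect_equal(got, oracle, tolerance = 1e-10)
  expect_equal(rowSums(got), rep(1, nrow(got)), tolerance = 1e-10)
})

test_that("a flat likelihood returns the grid-averaged prior proportions", {
  tr <- read_labeled_tree(text = "((A:1e-8,B:1e-8):1e-8 #1,C:1e-8);")
  aln <- codon_alignment(c(A = "ATGATG", B = "ATGATG", C = "ATGATG"))
  pi <- rep(1 / 61, 61)
  mle <- branch_site_params(2, 0.2, 4, 0.6, 0.3, pi)
  g <- 4
  post <- beb_posteriors(aln, tr, mle, grid_points = g)
  mid <- (seq_len(g) - 0.5) / g
  cells <- expand.grid(p0 = mid, p1 = mid)
  cells <- cells[cells$p0 + cells$p1 <= 1, ]
  A <- colMeans(t(apply(cells, 1, function(r) {
    rest <- 1 - r[1] - r[2]
    c(r[1], r[2], rest * r[1] / (r[1] + r[2]), rest * r[2] / (r[1] + r[2]))
  })))
  expect_equal(unname(unlist(post[1, c("p_class0", "p_class1", "p_class2a",
                                       "p_class2b")])),
               unname(A), tolerance = 1e-6)
})

test_that("collapsing the grid to the MLE gives naive empirical Bayes", {
  tr <- tree_6tx_fg()
  sim <- simulate_alignment(
    tr, "MODEL_A", list(kappa = 2, omega0 = 0.2, omega2 = 5,
                        p0 = 0.6, p1 = 0.3),
    n_sites = 40, seed = 61)
  aln <- sim$alignment
  pi <- rep(1 / 61, 61)
  mle <- branch_site_params(2, 0.2, 5, 0.6, 0.3, pi)
  post <- beb_posteriors(aln, tr, mle,
                         grid = list(p0 = mle$p0, p1 = mle$p1,
                                     omega0 = mle$omega0,
                                     omega2 = mle$omega2))
  # naive EB from the MLE mixture
  ctx <- hearsel:::.lik_context(aln, tr)
  r <- hearsel:::.modelA_rates(2, 0.2, 5, pi)
  R <- (mle$p0 + mle$p2a) * r[1] + (mle$p1 + mle$p2b) * r[2]
  cls <- hearsel:::.modelA_class_logliks(ctx, 2, 0.2, 5, pi, rho = r / R)
  lik <- exp(cls[ctx$map, , drop = FALSE])
  naive <- sweep(lik, 2, mle$proportions, "*")
  naive <- naive / rowSums(naive)
  got <- as.matrix(post[, c("p_class0", "p_class1", "p_class2a",
                            "p_class2b")])
  dimnames(got) <- NULL
  dimnames(naive) <- NULL
  expect_equal(got, naive, tolerance = 1e-10)
})

test_that("raising the PSS threshold never adds sites, permutation is clean", {
  tr <- tree_6tx_fg()
  sim <- simulate_alignment(
    tr, "MODEL_A", list(kappa = 2, omega0 = 0.1, omega2 = 8,
                        p0 = 0.5, p1 = 0.3),
    n_sites = 60, seed = 71)
  aln <- sim$alignment
  mle <- branch_site_params(2, 0.1, 8, 0.5, 0.3, rep(1 / 61, 61))
  p90 <- beb_posteriors(aln, tr, mle, grid_points = 4, threshold = 0.90)
  p95 <- beb_posteriors(aln, tr, mle, grid_points = 4, threshold = 0.95)
  p99 <- beb_posteriors(aln, tr, mle, grid_points = 4, threshold = 0.99)
  expect_gte(sum(p90$is_pss), sum(p95$is_pss))
  expect_gte(sum(p95$is_pss), sum(p99$is_pss))
  expect_equal(p95$p_positive, p95$p_class2a + p95$p_class2b)
  # permuting alignment columns permutes posteriors identically
  perm <- sample(ncol(aln$states))
  seqs <- apply(aln$codons[, perm, drop = FALSE], 1, paste0, collapse = "")
  alnp <- codon_alignment(seqs)
  pp <- beb_posteriors(alnp, tr, mle, grid_points = 4)
  expect_equal(pp$p_positive, p95$p_positive[perm], tolerance = 1e-12)
})

test_that("reference-taxon site numbering skips reference gaps", {
  tr <- tree_3tx()
  aln <- codon_alignment(c(A = "ATG---AAA", B = "ATGCCCAAA",
                           C = "ATGCCCAAG"))
  mle <- branch_site_params(2, 0.2, 2, 0.6, 0.3, rep(1 / 61, 61))
  # foreground needed: mark branch to C
  tr2 <- read_labeled_tree(text = "((A:0.1,B:0.2):0.1,C#1:0.3);")
  post <- beb_posteriors(aln, tr2, mle, grid_points = 2,
                         reference_taxon = "A")
  expect_equal(post$ref_site, c(1L, NA_integer_, 2L))
  expect_error(beb_posteriors(aln, tr2, mle, grid_points = 2,
                              reference_taxon = "Z"), "not in alignment")
})
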