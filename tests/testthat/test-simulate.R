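test_that("alignment simulation is deterministic and respects the tree", {
  tr <- tree_6tx_fg()
  s1 <- simulate_alignment(tr, "M0", list(kappa = 2, omega = 0.3), 50,
                           seed = 5)
  s2 <- simulate_alignment(tr, "M0", list(kappa = 2, omega = 0.3), 50,
                           seed = 5)
  expect_identical(s1$alignment$codons, s2$alignment$codons)
  s3 <- simulate_alignment(tr, "M0", list(kappa = 2, omega = 0.3), 50,
                           seed = 6)
  expect_false(identical(s1$alignment$codons, s3$alignment$codons))
  # zero branch lengths: all sequences identical
  tr0 <- read_labeled_tree(text = "((A:0,B:0):0,C:0);")
  s0 <- simulate_alignment(tr0, "M0", list(kappa = 2, omega = 0.3), 30,
                           seed = 1)
  expect_equal(s0$alignment$codons["A", ], s0$alignment$codons["B", ],
               ignore_attr = TRUE)
  expect_equal(s0$alignment$codons["A", ], s0$alignment$codons["C", ],
               ignore_attr = TRUE)
})

test_that("long simulations preserve the stationary codon distribution", {
  tr <- default_species_tree()
  pi <- random_pi()
  sim <- simulate_alignment(tr, "M0",
                            list(kappa = 2, omega = 0.3, pi = pi),
                            n_sites = 50000, seed = 8)
  est <- estimate_codon_frequencies(sim$alignment, pseudocount = 0.5)
  n <- 14 * 50000
  se <- sqrt(pi * (1 - pi) / n)
  # sequences are phylogenetically correlated, so allow a generous
  # multiple of the iid sampling error
  expect_true(all(abs(est - pi) < 12 * se + 5e-4))
})

test_that("planted positive-selection sites accumulate foreground changes", {
  tr <- read_labeled_tree(text = "(A:0.05,B#1:0.8);")
  sim <- simulate_alignment(
    tr, "MODEL_A", list(kappa = 2, omega0 = 0.05, omega2 = 8,
                        p0 = 0.45, p1 = 0.1),
    n_sites = 1500, seed = 12)
  gc <- genetic_code()
  aa <- matrix(gc$aa[sim$alignment$codons], 2)
  diffs <- aa[1, ] != aa[2, ]
  cl <- sim$truth$site_classes
  expect_gt(mean(diffs[cl %in% c("2a", "2b")]), mean(diffs[cl == "0"]))
  expect_equal(sort(unique(cl)), c("0", "1", "2a", "2b"))
  # proportions roughly match the Model A mixing weights
  bsp <- sim$truth$parameters
  expect_equal(mean(cl == "0"), bsp$p0, tolerance = 0.06)
  # model/parameter mismatches error
  expect_error(simulate_alignment(tr, "MODEL_A",
                                  list(kappa = 2, omega0 = 0.2), 10, 1),
               "omega2|needs")
  expect_error(simulate_alignment(tree_3tx(), "MODEL_A",
                                  list(kappa = 2, omega0 = 0.2, omega2 = 4,
                                       p0 = 0.6, p1 = 0.3), 10, 1),
               "foreground")
})

test_that("ortholog-table simulation plants exactly the requested defects", {
  sim <- simulate_ortholog_table(50, planted_missing = 6, planted_multi = 4,
                                 planted_noref = 3,
                                 planted_substitutable = 5, seed = 2)
  expect_equal(nrow(sim$truth), 50L)
  expect_equal(as.vector(table(sim$truth$category)[c("MISSING", "MULTI",
                                                     "NOREF",
                                                     "SUBSTITUTABLE")]),
               c(6L, 4L, 3L, 5L))
  expect_length(sim$no_reference, 3L)
  # reproducibility and feasibility check
  sim2 <- simulate_ortholog_table(50, planted_missing = 6,
                                  planted_multi = 4, planted_noref = 3,
                                  planted_substitutable = 5, seed = 2)
  expect_identical(sim$table, sim2$table)
  expect_error(simulate_ortholog_table(5, planted_missing = 10),
               "at most n_genes")
})

test_that("annotation simulation achieves its planted counts exactly", {
  plan <- list(coding = 5, intronic = 7, domain_only = 4, tad_only = 3,
               outside = 3)
  sim <- simulate_annotation(4, plan, seed = 3)
  expect_equal(nrow(sim$regions), 22L)
  expect_equal(as.vector(table(sim$truth$category)[names(plan)]),
               c(5L, 7L, 4L, 3L, 3L))
  # recovery through the annotation operations
  cls <- classify_coding(sim$regions, sim$exons)
  expect_equal(sum(cls$coding_class == "CODING"), 5L)
  gb <- assign_gene_body(cls, sim$units, sim$exons, noncoding_only = TRUE)
  expect_equal(sort(unique(gb$region_id)),
               sort(sim$truth$region_id[sim$truth$category == "intronic"]))
  dom <- build_regulatory_domains(sim$units)
  rd <- assign_reg_domain(cls, dom)
  want_rd <- sim$truth$region_id[sim$truth$category %in%
                                   c("coding", "intronic", "domain_only")]
  expect_setequal(unique(rd$region_id), want_rd)
  td <- assign_tad(cls, sim$units, sim$tads)
  want_tad <- sim$truth$region_id[sim$truth$category != "outside"]
  expect_setequal(unique(td$region_id), want_tad)
  # per-region gene agreement for the TAD-only plants
  tonly <- sim$truth[sim$truth$category == "tad_only", ]
  got <- td[td$region_id %in% tonly$region_id, ]
  expect_equal(got$gene_id[order(got$region_id)],
               tonly$gene_id[order(tonly$region_id)])
  # determinism: byte-identical BED output
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_bed(sim$regions, f1)
  write_bed(simulate_annotation(4, plan, seed = 3)$regions, f2)
  expect_identical(readLines(f1), readLines(f2))
  # degenerate and infeasible specs
  empty <- simulate_annotation(2, list(), seed = 1)
  expect_equal(nrow(empty$regions), 0L)
  expect_error(simulate_annotation(0, list(coding = 1), seed = 1),
               "at least one gene")
  expect_error(simulate_annotation(2, list(coding = -1), seed = 1),
               "non-negative")
})

test_that("simulate() on an M0 fit round-trips the fitted model", {
  tr <- tree_3tx()
  sim <- simulate_alignment(tr, "M0", list(kappa = 2, omega = 0.4), 60,
                            seed = 9)
  fit <- fit_m0(sim$alignment, tr)
  re <- simulate(fit, seed = 10)
  expect_s3_class(re$alignment, "codon_alignment")
  expect_equal(dim(re$alignment), dim(sim$alignment))
  expect_equal(re$truth$parameters$kappa, fit$kappa)
})
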