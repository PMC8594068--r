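test_that("gene-list union respects inclusion-exclusion", {
  a <- paste0("g", 1:115)
  b <- c(paste0("g", 1:14), paste0("h", 1:316))  # overlap exactly 14
  m <- merge_gene_lists(list(NSHL = a, IMPC = b))
  expect_equal(nrow(m$union), 431L)
  expect_equal(m$overlap["NSHL", "IMPC"], 14L)
  # disjoint and identical lists
  expect_equal(nrow(merge_gene_lists(list(x = paste0("a", 1:3),
                                          y = paste0("b", 1:4)))$union), 7L)
  m2 <- merge_gene_lists(list(x = a, y = a))
  expect_equal(nrow(m2$union), length(a))
  expect_equal(m2$overlap["x", "y"], length(a))
  # property: |union| = |A| + |B| - |A . B| on random lists
  set.seed(42)
  for (i in 1:20) {
    A <- sample(paste0("g", 1:60), sample(5:40, 1))
    B <- sample(paste0("g", 1:60), sample(5:40, 1))
    mm <- merge_gene_lists(list(A = A, B = B))
    expect_equal(nrow(mm$union),
                 length(A) + length(B) - mm$overlap["A", "B"])
  }
})

test_that("synonym normalisation happens before the union", {
  m <- merge_gene_lists(list(x = c("DFNB31", "GJB2"), y = c("WHRN")),
                        synonym_map = c(DFNB31 = "WHRN"))
  expect_equal(sort(m$union$gene), c("GJB2", "WHRN"))
  expect_equal(m$overlap["x", "y"], 1L)
  expect_match(m$union$sources[m$union$gene == "WHRN"], "x,y")
})

test_that("orthology filtering implements the screening rules", {
  sim <- simulate_ortholog_table(20, planted_missing = 3, planted_multi = 2,
                                 planted_noref = 1,
                                 planted_substitutable = 2, seed = 7)
  roster <- default_species_roster()$roster$species
  tab <- substitute_species(sim$table, roster)
  led <- filter_orthology(tab, sim$genes, max_missing = 1,
                          no_reference = sim$no_reference, roster = roster)
  expect_equal(sum(led$disposition == "EXCLUDED_ORTHOLOGY"), 5L)  # 3 + 2
  expect_equal(sum(led$disposition == "EXCLUDED_NO_REFERENCE"), 1L)
  expect_equal(sum(led$disposition == "ANALYZED"), 14L)
  # dispositions partition the genes and the run is idempotent
  expect_setequal(led$gene, sim$genes)
  led2 <- filter_orthology(tab, sim$genes, max_missing = 1,
                           no_reference = sim$no_reference, roster = roster)
  expect_identical(led, led2)
  # substitutable genes were rescued by the same-taxon pool
  resc <- sim$truth$gene[sim$truth$category == "SUBSTITUTABLE"]
  expect_true(all(led$disposition[led$gene %in% resc] == "ANALYZED"))
  expect_true(all(!is.na(tab$substituted_from[tab$gene %in% resc &
                                                tab$status == "ONE2ONE" &
                                                !is.na(tab$substituted_from)])))
})

test_that("single-cell rules: ONE2ONE passes, MANY2MANY excludes", {
  d <- default_species_roster()
  tab <- expand.grid(gene = "g1", species = d$roster$species,
                     stringsAsFactors = FALSE)
  tab$status <- "ONE2ONE"
  tab$taxon_group <- d$roster$taxon_group
  led <- filter_orthology(tab, "g1")
  expect_equal(led$disposition, "ANALYZED")
  tab$status[3] <- "MANY2MANY"
  expect_equal(filter_orthology(tab, "g1")$disposition,
               "EXCLUDED_ORTHOLOGY")
  expect_error(filter_orthology(tab, "g2"), "not present")
  # duplicated cell
  expect_error(filter_orthology(rbind(tab, tab[1, ]), "g1"), "exactly")
})

test_that("species substitution only upgrades MISSING cells", {
  d <- default_species_roster()
  tab <- data.frame(gene = "g1",
                    species = c("cow", "goat", "dog"),
                    status = c("MISSING", "ONE2ONE", "ONE2MANY"),
                    taxon_group = c("artiodactyla", "artiodactyla",
                                    "carnivora"),
                    stringsAsFactors = FALSE)
  out <- substitute_species(tab, roster = c("cow", "dog"))
  expect_equal(out$status[out$species == "cow"], "ONE2ONE")
  expect_equal(out$substituted_from[out$species == "cow"], "goat")
  expect_equal(out$status[out$species == "dog"], "ONE2MANY")  # untouched
  # no same-taxon donor: stays MISSING
  tab2 <- tab
  tab2$taxon_group[2] <- "rodents"
  out2 <- substitute_species(tab2, roster = c("cow", "dog"))
  expect_equal(out2$status[out2$species == "cow"], "MISSING")
  # no MISSING cells: identity up to the provenance column
  tab3 <- tab
  tab3$status[1] <- "ONE2ONE"
  out3 <- substitute_species(tab3, roster = c("cow", "dog"))
  expect_equal(out3$status, tab3$status)
  expect_true(all(is.na(out3$substituted_from)))
})
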