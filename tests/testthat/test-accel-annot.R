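units_df <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df
}

test_that("coding classification uses half-open >= 1 bp overlap", {
  ex <- units_df(gene_id = "G1", chrom = "chr1", start = 150, end = 250)
  r1 <- units_df(chrom = "chr1", start = 100, end = 200, id = "R1")
  r2 <- units_df(chrom = "chr1", start = 100, end = 150, id = "R2")
  out <- classify_coding(rbind(r1, r2), ex)
  expect_equal(out$coding_class, c("CODING", "NONCODING"))
  # adjacency [100,200) vs [200,300) is not overlap
  ex2 <- units_df(gene_id = "G1", chrom = "chr1", start = 200, end = 300)
  expect_equal(classify_coding(r1, ex2)$coding_class, "NONCODING")
  # minimum-overlap fraction knob
  expect_equal(classify_coding(r1, ex, min_overlap = 51)$coding_class,
               "NONCODING")
  expect_equal(classify_coding(r1, ex, min_overlap = 50)$coding_class,
               "CODING")
})

test_that("random regions classify exactly like the per-base oracle", {
  set.seed(5)
  n <- 150
  regions <- units_df(chrom = sample(c("c1", "c2"), n, TRUE),
                      start = sample(0:2000, n, TRUE))
  regions$end <- regions$start + sample(1:120, n, TRUE)
  regions$id <- paste0("R", seq_len(n))
  ex <- units_df(gene_id = paste0("G", 1:30),
                 chrom = sample(c("c1", "c2"), 30, TRUE),
                 start = sample(0:2000, 30, TRUE))
  ex$end <- ex$start + sample(20:200, 30, TRUE)
  got <- classify_coding(regions, ex)$coding_class
  expect_equal(got, oracle_coding(regions, ex))
})

test_that("gene-body assignment honours the non-exonic requirement", {
  units <- units_df(gene_id = c("G1", "G2"), chrom = "chr1",
                    start = c(1000, 1500), end = c(3000, 2500),
                    strand = "+")
  exons <- units_df(gene_id = c("G1", "G1"), chrom = "chr1",
                    start = c(1000, 2800), end = c(1200, 3000))
  # intronic region inside G1, inside G2's body too
  reg <- units_df(chrom = "chr1", start = 1900, end = 2000, id = "R1")
  asg <- assign_gene_body(reg, units, exons, noncoding_only = TRUE)
  expect_setequal(asg$gene_id, c("G1", "G2"))
  # region entirely inside a G1 exon: dropped for G1 when noncoding_only
  reg2 <- units_df(chrom = "chr1", start = 1050, end = 1100, id = "R2")
  asg2 <- assign_gene_body(reg2, units, exons, noncoding_only = TRUE)
  expect_equal(nrow(asg2), 0L)
  expect_equal(assign_gene_body(reg2, units)$gene_id, "G1")
})

test_that("randomised gene-body assignment matches the per-base oracle", {
  set.seed(17)
  units <- units_df(gene_id = paste0("G", 1:12), chrom = "c1",
                    start = sample(0:3000, 12))
  units$end <- units$start + sample(100:800, 12, TRUE)
  units$strand <- sample(c("+", "-"), 12, TRUE)
  exons <- do.call(rbind, lapply(1:12, function(i) {
    s <- units$start[i] + sample(0:50, 2)
    units_df(gene_id = units$gene_id[i], chrom = "c1", start = s,
             end = pmin(s + sample(30:100, 2, TRUE), units$end[i]))
  }))
  regions <- units_df(chrom = "c1", start = sample(0:3500, 120, TRUE))
  regions$end <- regions$start + sample(1:150, 120, TRUE)
  regions$id <- paste0("R", seq_len(120))
  for (nc in c(FALSE, TRUE)) {
    got <- assign_gene_body(regions, units, exons, noncoding_only = nc)
    want <- oracle_gene_body(regions, units, exons, noncoding_only = nc)
    expect_equal(sorted_pairs(got), sorted_pairs(want), info = nc)
  }
})

test_that("regulatory domains reproduce the worked basal-extension cases", {
  # single + strand gene, far from everything
  u <- units_df(gene_id = "G1", chrom = "chr1", start = 2e6,
                end = 2e6 + 2e4, strand = "+")
  d <- build_regulatory_domains(u, basal_up = 5000, basal_down = 1000,
                                max_extension = 1e6)
  expect_equal(d$basal_start, 1995000)
  expect_equal(d$basal_end, 2001000)
  expect_equal(d$start, 1e6)
  expect_equal(d$end, 3e6)
  # two + strand genes limit each other at their basal boundaries
  u2 <- units_df(gene_id = c("A", "B"), chrom = "chr1",
                 start = c(1e5, 3e5), end = c(1e5, 3e5) + 1e4,
                 strand = "+")
  d2 <- build_regulatory_domains(u2, 5000, 1000, 1e6)
  expect_equal(d2$end[1], 295000)   # A's right edge = B's basal start
  expect_equal(d2$start[2], 101000) # B's left edge = A's basal end
  expect_equal(d2$start[1], 0)      # clipped at the chromosome origin
  expect_equal(d2$end[2], 3e5 + 1e6)
  # zero extension: extended = basal
  d0 <- build_regulatory_domains(u2, 5000, 1000, 0)
  expect_equal(d0$start, d0$basal_start)
  expect_equal(d0$end, d0$basal_end)
  # minus-strand basal is mirrored around the TSS (end - 1)
  um <- units_df(gene_id = "M", chrom = "chr1", start = 5e5,
                 end = 5e5 + 1e4, strand = "-")
  dm <- build_regulatory_domains(um, 5000, 1000, 0)
  tss <- 5e5 + 1e4 - 1
  expect_equal(dm$basal_start, tss - 1000 + 1)
  expect_equal(dm$basal_end, tss + 5000 + 1)
  expect_equal(dm$basal_end - dm$basal_start, 6000)
})

test_that("TAD assignment uses any-base membership of the region", {
  units <- units_df(gene_id = c("G1", "G2"), chrom = "chr1",
                    start = c(100, 5000), end = c(600, 5600),
                    strand = "+")
  tads <- units_df(chrom = "chr1", start = c(0, 4000),
                   end = c(4000, 9000))
  r_in <- units_df(chrom = "chr1", start = 1000, end = 1200, id = "R1")
  expect_equal(assign_tad(r_in, units, tads)$gene_id, "G1")
  r_other <- units_df(chrom = "chr1", start = 4500, end = 4600, id = "R2")
  expect_equal(assign_tad(r_other, units, tads)$gene_id, "G2")
  # straddling the boundary reaches genes in both TADs
  r_span <- units_df(chrom = "chr1", start = 3900, end = 4100, id = "R3")
  expect_setequal(assign_tad(r_span, units, tads)$gene_id, c("G1", "G2"))
  # outside all TADs: nothing
  r_out <- units_df(chrom = "chr1", start = 9500, end = 9600, id = "R4")
  expect_equal(nrow(assign_tad(r_out, units, tads)), 0L)
  expect_error(assign_tad(r_in, units,
                          units_df(chrom = "chr1", start = c(0, 100),
                                   end = c(200, 300))), "overlap")
})

test_that("randomised TAD assignment matches the per-base oracle", {
  set.seed(29)
  units <- units_df(gene_id = paste0("G", 1:8), chrom = "c1",
                    start = sample(seq(0, 4000, 10), 8))
  units$end <- units$start + 200
  units$strand <- sample(c("+", "-"), 8, TRUE)
  starts <- sort(sample(seq(0, 4500, 100), 5))
  tads <- units_df(chrom = "c1", start = starts,
                   end = starts + c(diff(starts), 400) - 10)
  regions <- units_df(chrom = "c1", start = sample(0:4600, 80, TRUE))
  regions$end <- regions$start + sample(1:300, 80, TRUE)
  regions$id <- paste0("R", 1:80)
  got <- assign_tad(regions, units, tads)
  want <- oracle_tad(regions, units, tads)
  expect_equal(sorted_pairs(got), sorted_pairs(want))
})

test_that("summaries count regions, genes and the coding split", {
  regions <- units_df(chrom = "c1", start = c(0, 100, 200, 300),
                      end = c(50, 150, 250, 350),
                      id = paste0("R", 1:4),
                      lineage = c("MAMMAL_TSAR", "MAMMAL_TSAR",
                                  "MAMMAL_TSAR", "HUMAN_HAR"),
                      coding_class = c("NONCODING", "NONCODING",
                                       "NONCODING", "CODING"))
  asg <- units_df(region_id = c("R1", "R2", "R3", "R4"),
                  gene_id = c("EX1", "EX1", "EX1", "EX2"),
                  mode = c("GENE_BODY", "GENE_BODY", "GENE_BODY", "TAD"))
  s <- summarize_assignments(regions, asg)
  top <- s$gene_ranking[s$gene_ranking$mode == "GENE_BODY", ]
  expect_equal(top$gene_id[1], "EX1")
  expect_equal(top$n_regions[1], 3L)
  bm <- s$by_mode[s$by_mode$mode == "GENE_BODY", ]
  expect_equal(bm$n_regions, 3L)
  expect_equal(bm$n_genes, 1L)
  cs <- s$coding_split
  expect_equal(cs$n_regions[cs$lineage == "MAMMAL_TSAR" &
                              cs$coding_class == "NONCODING"], 3L)
  # empty assignments
  s0 <- summarize_assignments(regions, asg[0, ])
  expect_equal(nrow(s0$by_mode), 0L)
})
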