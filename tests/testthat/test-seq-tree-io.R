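test_that("FASTA codon alignments parse with correct states", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">A", "ATGAAA", ">B", "ATGAAG"), f)
  aln <- read_codon_alignment(f)
  expect_equal(dim(aln), c(2L, 2L))
  expect_equal(aln$taxa, c("A", "B"))
  expect_true(all(aln$states > 0))
  gc <- genetic_code()
  expect_equal(gc$sense[aln$states["A", ]], c("ATG", "AAA"))
})

test_that("gap and ambiguity conventions hold", {
  aln <- codon_alignment(c(A = "ATG---", B = "ATGAAA"))
  expect_identical(unname(aln$states["A", 2]), 0L)
  # IUPAC ambiguity expands to a non-empty subset of sense codons
  aln2 <- codon_alignment(c(A = "ATGAAN", B = "ATGAAA"))
  st <- aln2$states["A", 2]
  expect_true(st < 0)
  set <- aln2$ambig[[-st]]
  expect_true(length(set) >= 1 && all(set >= 1 & set <= 61))
  gc <- genetic_code()
  expect_setequal(gc$sense[set], c("AAA", "AAC", "AAG", "AAT"))
  # mixed case accepted
  expect_silent(codon_alignment(c(A = "atgAAA", B = "ATGaaa")))
})

test_that("stop-codon rules: internal errors, terminal stripped", {
  expect_error(codon_alignment(c(A = "ATGTAAAAA", B = "ATGAAAAAA")),
               "stop codon.*A.*site 2")
  # terminal stops silently removed
  aln <- codon_alignment(c(A = "ATGAAATAA", B = "ATGAAATGA"))
  expect_equal(ncol(aln$states), 2L)
  # terminal stop in one taxon only becomes a gap
  aln2 <- codon_alignment(c(A = "ATGAAATAA", B = "ATGAAAAAA"))
  expect_equal(ncol(aln2$states), 3L)
  expect_equal(unname(aln2$states["A", 3]), 0L)
})

test_that("malformed alignments are rejected with informative errors", {
  expect_error(codon_alignment(c(A = "ATGAA", B = "ATGAA")), "divisible")
  expect_error(codon_alignment(c(A = "ATGAAA", B = "ATG")), "aligned")
  expect_error(codon_alignment(c(A = "ATGAAA", A = "ATGAAA")), "duplicate")
})

test_that("sequential PHYLIP parses and round-trips with FASTA", {
  f <- withr::local_tempfile(fileext = ".phy")
  writeLines(c(" 2 9", "taxon_one ATGAAACCC", "taxon_two ATGAAAGGG"), f)
  aln <- read_codon_alignment(f)
  expect_equal(aln$taxa, c("taxon_one", "taxon_two"))
  expect_equal(ncol(aln$states), 3L)
  # read -> write -> read identity, both formats
  for (fmt in c("fasta", "phylip")) {
    out <- withr::local_tempfile()
    write_codon_alignment(aln, out, format = fmt)
    back <- read_codon_alignment(out)
    expect_identical(back$codons, aln$codons)
  }
  # wrapped sequence lines
  f2 <- withr::local_tempfile()
  writeLines(c("2 9", "A ATGAAA", "CCC", "B ATGAAAGGG"), f2)
  expect_equal(unname(read_codon_alignment(f2)$codons["A", 3]), "CCC")
})

test_that("Newick foreground marks are parsed and written back", {
  tr <- read_labeled_tree(text = "((A:0.1,B:0.1):0.05 #1,C:0.2);")
  expect_equal(length(tr$foreground), 1L)
  fg_child <- tr$tree$edge[tr$foreground, 2]
  expect_true(fg_child > length(tr$tree$tip.label))  # internal branch
  expect_equal(length(read_labeled_tree(text = "(A:0.1,B:0.1);")$foreground),
               0L)
  # tip-level mark
  tr2 <- read_labeled_tree(text = "(A:0.1,B#1:0.2);")
  expect_equal(tr2$tree$edge[tr2$foreground, 2],
               which(tr2$tree$tip.label == "B"))
  # 14-leaf default roster round-trips through write -> read
  tr14 <- default_species_tree()
  expect_equal(length(tr14$tree$tip.label), 14L)
  txt <- write_labeled_tree(tr14)
  back <- read_labeled_tree(text = txt)
  expect_setequal(back$tree$tip.label, tr14$tree$tip.label)
  expect_equal(sort(back$tree$edge.length), sort(tr14$tree$edge.length))
  fg_tips <- function(t) sort(ape::extract.clade(
    t$tree, t$tree$edge[t$foreground, 2])$tip.label)
  expect_equal(fg_tips(back), fg_tips(tr14))
})

test_that("missing branch lengths become zero with a flag", {
  tr <- read_labeled_tree(text = "((A,B),C);")
  expect_true(tr$missing_lengths)
  expect_true(all(tr$tree$edge.length == 0))
})

test_that("malformed Newick reports a character offset", {
  expect_error(read_labeled_tree(text = "((A:0.1,B:0.1):0.05"),
               "character [0-9]+")
})

test_that("BED parsing follows half-open semantics and flags bad records", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\tR1", "chr2\t5\t50", "chr1\t0\t10"), f)
  bed <- read_bed(f)
  expect_equal(nrow(bed), 3L)
  expect_equal(bed$chrom, c("chr1", "chr2", "chr1"))  # order preserved
  expect_equal(bed$start[1], 100)
  expect_equal(bed$end[1], 200)
  expect_equal(bed$id[1], "R1")
  f2 <- withr::local_tempfile()
  writeLines("chr1\t200\t200", f2)
  expect_error(read_bed(f2), "line 1")
  # round trip
  out <- withr::local_tempfile()
  write_bed(bed, out)
  expect_equal(read_bed(out)[, c("chrom", "start", "end")],
               bed[, c("chrom", "start", "end")])
})

test_that("gene lists read one id per line with comments", {
  f <- withr::local_tempfile()
  writeLines(c("# header", "GJB2", "MYO7A  # alias", "", "GJB2"), f)
  expect_equal(read_gene_list(f), c("GJB2", "MYO7A"))
})
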