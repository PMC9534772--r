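test_that("GTF exons map onto the genome with 1-based closed coordinates", {
  genome <- c(chrT = random_dna(400, 7))
  gtf <- write_toy_gtf(
    data.frame(chr = "chrT", gene = "geneA", tx = c("t1", "t1", "t2"),
               start = c(1, 201, 1), end = c(100, 300, 150),
               strand = "+"),
    withr::local_tempfile(fileext = ".gtf"))
  models <- read_gene_models(gtf, genome)
  expect_length(models, 1)
  g <- models$geneA
  expect_s3_class(g, "gene_model")
  expect_length(g$isoforms, 2)
  # a start=1,end=100 exon covers exactly the first 100 reference bases
  ex1 <- g$isoforms$t1[1]
  expect_equal(IRanges::start(ex1), 1)
  expect_equal(IRanges::end(ex1), 100)
  expect_equal(IRanges::width(ex1), 100)
  regions <- consensus_exonic_regions(g, genome)
  expect_equal(regions$sequence[1], substr(genome[["chrT"]], 1, 100))
})

test_that("missing references, out-of-bounds exons and zero-exon transcripts error", {
  genome <- c(chrT = random_dna(200, 8))
  gtf <- write_toy_gtf(
    data.frame(chr = "chrMISSING", gene = "geneA", tx = "t1",
               start = 1, end = 100, strand = "+"),
    withr::local_tempfile(fileext = ".gtf"))
  expect_error(read_gene_models(gtf, genome), "chrMISSING")

  gtf2 <- write_toy_gtf(
    data.frame(chr = "chrT", gene = "geneA", tx = "t1",
               start = 150, end = 500, strand = "+"),
    withr::local_tempfile(fileext = ".gtf"))
  expect_error(read_gene_models(gtf2, genome), "bounds")

  expect_error(
    gene_model("geneA", "+", "chrT", list(t1 = IRanges::IRanges())),
    "zero exons")
})

test_that("consensus is the interval intersection across isoforms", {
  genome <- c(chr1 = random_dna(500, 9))
  # isoform1 {[1,100],[201,300]}, isoform2 {[1,150],[251,300]}
  g <- gene_model("gX", "+", "chr1", list(
    t1 = IRanges::IRanges(c(1, 201), c(100, 300)),
    t2 = IRanges::IRanges(c(1, 251), c(150, 300))))
  cons <- consensus_exonic_regions(g, genome)
  expect_equal(cons$start, c(1, 251))
  expect_equal(cons$end, c(100, 300))

  # single isoform: identity
  g1 <- gene_model("gY", "+", "chr1",
                   list(t1 = IRanges::IRanges(11, 50)))
  cons1 <- consensus_exonic_regions(g1, genome)
  expect_equal(cons1$start, 11)
  expect_equal(cons1$end, 50)

  # disjoint isoforms: empty consensus, not an error
  g0 <- gene_model("gZ", "+", "chr1", list(
    t1 = IRanges::IRanges(1, 100), t2 = IRanges::IRanges(101, 200)))
  expect_equal(nrow(consensus_exonic_regions(g0, genome)), 0)
})

test_that("consensus is permutation-invariant and covered by every isoform", {
  genome <- c(chr1 = random_dna(1200, 10))
  iso <- list(
    t1 = IRanges::IRanges(c(1, 301, 701), c(200, 500, 1000)),
    t2 = IRanges::IRanges(c(51, 301, 701), c(200, 600, 900)),
    t3 = IRanges::IRanges(c(1, 501), c(450, 950)))
  g12 <- gene_model("g", "+", "chr1", iso)
  g21 <- gene_model("g", "+", "chr1", iso[c(3, 1, 2)])
  c1 <- consensus_exonic_regions(g12, genome)
  c2 <- consensus_exonic_regions(g21, genome)
  expect_equal(c1, c2)

  # per-base check: every consensus base is exonic in every isoform
  cons_pos <- unlist(mapply(seq, c1$start, c1$end, SIMPLIFY = FALSE))
  for (ex in iso) {
    iso_pos <- unlist(mapply(seq, IRanges::start(ex), IRanges::end(ex),
                             SIMPLIFY = FALSE))
    expect_true(all(cons_pos %in% iso_pos))
  }
})

test_that("intron union matches a brute-force per-base oracle", {
  genome <- c(chr1 = random_dna(500, 11))
  # introns [101,200] and [101,250] -> union [101,250]
  g <- gene_model("g", "+", "chr1", list(
    t1 = IRanges::IRanges(c(1, 201), c(100, 300)),
    t2 = IRanges::IRanges(c(1, 251), c(100, 300))))
  exp <- expansion_regions(g, genome)
  introns <- exp[exp$source == "intron", ]
  # oracle: per-base union of per-isoform gap positions
  gap_of <- function(starts, ends) {
    span <- min(starts):max(ends)
    exonic <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
    setdiff(span, exonic)
  }
  oracle <- sort(union(gap_of(c(1, 201), c(100, 300)),
                       gap_of(c(1, 251), c(100, 300))))
  got <- unlist(mapply(seq, introns$start, introns$end, SIMPLIFY = FALSE))
  expect_equal(sort(got), oracle)

  # single-exon gene, no UTR: no expansion regions
  g1 <- gene_model("g1", "+", "chr1", list(t1 = IRanges::IRanges(1, 400)))
  expect_equal(nrow(expansion_regions(g1, genome)), 0)

  # exons {[1,100],[201,300]} -> one intron [101,200]
  g2 <- gene_model("g2", "+", "chr1",
                   list(t1 = IRanges::IRanges(c(1, 201), c(100, 300))))
  i2 <- expansion_regions(g2, genome)
  expect_equal(i2$start, 101)
  expect_equal(i2$end, 200)

  # consensus and intron union never share a base
  cons <- consensus_exonic_regions(g, genome)
  cons_pos <- unlist(mapply(seq, cons$start, cons$end, SIMPLIFY = FALSE))
  expect_length(intersect(cons_pos, got), 0)
})

test_that("minus-strand regions are mRNA-sense and lengths are consistent", {
  genome <- c(chr1 = random_dna(300, 12))
  g <- gene_model("g", "-", "chr1", list(t1 = IRanges::IRanges(51, 150)))
  cons <- consensus_exonic_regions(g, genome)
  expect_equal(cons$sequence,
               revcomp(substr(genome[["chr1"]], 51, 150)))
  expect_equal(nchar(cons$sequence), cons$end - cons$start + 1)
})

test_that("soft-masked bases survive region extraction", {
  chrom <- random_dna(200, 13)
  substr(chrom, 50, 69) <- tolower(substr(chrom, 50, 69))
  genome <- c(chr1 = chrom)
  g <- gene_model("g", "+", "chr1", list(t1 = IRanges::IRanges(1, 200)))
  cons <- consensus_exonic_regions(g, genome)
  expect_true(grepl("[a-z]", cons$sequence))
  expect_equal(substr(cons$sequence, 50, 69), substr(chrom, 50, 69))
})

test_that("pre-extracted target FASTA round-trips through the header scheme", {
  tf <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">geneQ|exon_consensus|10-49", random_dna(40, 14)), tf)
  tr <- read_target_regions(tf)
  expect_equal(tr$gene_id, "geneQ")
  expect_equal(tr$source, "exon_consensus")
  expect_equal(tr$start, 10)
  expect_equal(tr$end, 49)
  expect_equal(nchar(tr$sequence), 40)
})
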