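test_that("generation is byte-identical per seed and records structure faithfully", {
  spec <- synthetic_spec(seed = 201, n_genes = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  tx1 <- generate_transcriptome(spec, d1)
  tx2 <- generate_transcriptome(spec, d2)
  expect_identical(readLines(tx1$fasta), readLines(tx2$fasta))
  expect_identical(readLines(tx1$gtf), readLines(tx2$gtf))

  # the annotation parses back into models matching the manifest
  genome <- read_genome_fasta(tx1$fasta)
  models <- read_gene_models(tx1$gtf, genome)
  man <- tx1$manifest_data
  expect_equal(length(models), length(man$genes))
  for (g in man$genes) {
    m <- models[[g$gene_id]]
    expect_equal(m$strand, g$strand)
    expect_equal(length(m$isoforms), length(g$isoforms))
    # consensus exons announced by the generator equal the computed ones
    cons <- consensus_exonic_regions(m, genome)
    exp_iv <- do.call(rbind, g$exons[g$consensus_exons])
    expect_equal(cons$start, unname(exp_iv[, 1]))
    expect_equal(cons$end, unname(exp_iv[, 2]))
  }
})

test_that("generated base composition tracks the requested GC", {
  spec <- synthetic_spec(seed = 202, n_genes = 6, base_gc = 60,
                         exon_length = c(300, 500))
  tx <- generate_transcriptome(spec, withr::local_tempdir())
  genome <- read_genome_fasta(tx$fasta)
  expect_gt(nchar(genome[[1]]), 10000)
  expect_lt(abs(gc_percent(genome[[1]]) - 60), 3)
})

test_that("planted homopolymers knock out every covering window", {
  spec <- synthetic_spec(
    seed = 203, n_genes = 2, isoforms_per_gene = c(1, 1),
    plants = list(list(type = "homopolymer", gene = 1, base = "G",
                       run_length = 6)))
  tx <- generate_transcriptome(spec, withr::local_tempdir())
  plant <- tx$manifest_data$plants[[1]]
  genome <- read_genome_fasta(tx$fasta)
  expect_equal(substr(genome[[1]], plant$start, plant$end), "GGGGGG")
  models <- read_gene_models(tx$gtf, genome)
  g <- models[[plant$gene]]
  cand <- extract_candidates(consensus_exonic_regions(g, genome), 35)
  hp <- !homopolymer_filter(cand)
  expect_true(any(hp))
  # oracle from manifest coordinates: expand the planted run over any
  # chance same-base neighbours, then every window overlapping it by >= 5
  # bases must fail
  run_lo <- plant$start
  run_hi <- plant$end
  while (run_lo > 1 &&
           substr(genome[[1]], run_lo - 1, run_lo - 1) == plant$base)
    run_lo <- run_lo - 1
  while (run_hi < nchar(genome[[1]]) &&
           substr(genome[[1]], run_hi + 1, run_hi + 1) == plant$base)
    run_hi <- run_hi + 1
  covering <- vapply(seq_len(nrow(cand)), function(i) {
    lo <- if (g$strand == "+") cand$region_start[i] + cand$start[i] - 1L
          else cand$region_end[i] - (cand$start[i] + 34L) + 1L
    hi <- lo + 34L
    min(hi, run_hi) - max(lo, run_lo) + 1L >= 5L
  }, logical(1))
  expect_true(any(covering))
  expect_true(all(hp[covering]))
})

test_that("a fully soft-masked gene yields zero probes", {
  spec <- synthetic_spec(
    seed = 204, n_genes = 2, isoforms_per_gene = c(1, 1),
    n_exons = c(1, 1), exon_length = c(300, 300),
    plants = list(list(type = "softmask", gene = 1, length = 300)))
  tx <- generate_transcriptome(spec, withr::local_tempdir())
  genome <- read_genome_fasta(tx$fasta)
  models <- read_gene_models(tx$gtf, genome)
  design <- design_probes(models, genome, design_config())
  masked_gene <- tx$manifest_data$plants[[1]]$gene
  expect_equal(design$counts$final[design$counts$gene_id == masked_gene], 0)
})

test_that("planted shared substrings are recoverable as off-target hits", {
  spec <- synthetic_spec(
    seed = 205, n_genes = 2, isoforms_per_gene = c(1, 1),
    plants = list(list(type = "shared_substring", gene_a = 1, gene_b = 2,
                       length = 20, compartment = "exon")))
  tx <- generate_transcriptome(spec, withr::local_tempdir())
  plant <- tx$manifest_data$plants[[1]]
  genome <- read_genome_fasta(tx$fasta)
  models <- read_gene_models(tx$gtf, genome)
  idx <- build_offtarget_index(models, genome, k = 15)
  g <- models[[plant$gene_a]]
  cand <- extract_candidates(consensus_exonic_regions(g, genome), 35)
  fails <- vapply(seq_len(nrow(cand)), function(i) {
    !screen_candidate(cand$target_window[i], plant$gene_a, idx)$pass
  }, logical(1))
  expect_true(any(fails))
  # oracle from the manifest: the shared region is the plant plus any
  # chance extension where the two loci's flanking bases happen to agree
  chrom <- genome[[1]]
  ext_l <- 0L
  while (substr(chrom, plant$start_a - ext_l - 1, plant$start_a - ext_l - 1) ==
           substr(chrom, plant$start_b - ext_l - 1, plant$start_b - ext_l - 1))
    ext_l <- ext_l + 1L
  ext_r <- 0L
  while (substr(chrom, plant$end_a + ext_r + 1, plant$end_a + ext_r + 1) ==
           substr(chrom, plant$end_b + ext_r + 1, plant$end_b + ext_r + 1))
    ext_r <- ext_r + 1L
  sh_lo <- plant$start_a - ext_l
  sh_hi <- plant$end_a + ext_r
  spans_plant <- vapply(seq_len(nrow(cand)), function(i) {
    lo <- if (g$strand == "+") cand$region_start[i] + cand$start[i] - 1L
          else cand$region_end[i] - (cand$start[i] + 34L) + 1L
    hi <- lo + 34L
    min(hi, sh_hi) - max(lo, sh_lo) + 1L >= 15L
  }, logical(1))
  expect_equal(fails, spans_plant)
})

test_that("infeasible plants fail at generation time", {
  spec <- synthetic_spec(
    seed = 206, n_genes = 1, isoforms_per_gene = c(1, 1),
    n_exons = c(1, 1), exon_length = c(100, 100),
    plants = list(list(type = "homopolymer", gene = 1, base = "A",
                       run_length = 150)))
  expect_error(generate_transcriptome(spec, withr::local_tempdir()),
               "infeasible plant")
})

test_that("the brute-force oracle agrees with the pipeline end to end", {
  spec <- synthetic_spec(seed = 207, n_genes = 5)
  tx <- generate_transcriptome(spec, withr::local_tempdir())
  genome <- read_genome_fasta(tx$fasta)
  models <- read_gene_models(tx$gtf, genome)
  cfg <- design_config()
  design <- design_probes(models, genome, cfg)
  oracle <- expected_survivors(tx, cfg)
  got <- design$counts[order(design$counts$gene_id),
                       c("gene_id", "final")]
  want <- oracle[order(oracle$gene_id), ]
  expect_equal(got$final, want$expected)
})
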