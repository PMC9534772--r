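test_that("index contents match brute-force k-mer sets", {
  tx50 <- random_dna(50, 31)
  idx <- kmer_index(c(s1 = tx50), owners = "gA", k = 15)
  expect_equal(length(ls(idx$map)), length(unique(
    substring(tx50, 1:36, 15:50))))
  # 36 positions indexed for a 50-nt sequence
  expect_equal(sum(vapply(ls(idx$map), function(w)
    length(idx$map[[w]]), integer(1))), 36)

  # toy k=3: an intron "ACGTT" enters the database as its literal reversal
  genome <- c(chr1 = paste0("AAAAAAAAAA", "GGG", "ACGTT", "CCC",
                            "TTTTTTTTTT"))
  g <- gene_model("g", "+", "chr1",
                  list(t1 = IRanges::IRanges(c(11, 19), c(13, 21))))
  idx3 <- build_offtarget_index(list(g), genome, k = 3)
  comp <- idx3$db_composition
  expect_true("reversed_intron" %in% comp$kind)
  rev_intron <- "TTGCA"  # literal reversal of ACGTT
  for (w in substring(rev_intron, 1:3, 3:5)) {
    expect_true(!is.null(idx3$map[[w]]), label = paste("kmer", w))
  }

  # a 20-mer planted in two genes: its six 15-mers map to both gene ids
  shared <- random_dna(20, 32)
  idx2 <- kmer_index(c(a = paste0(random_dna(30, 33), shared),
                       b = paste0(shared, random_dna(30, 34))),
                     owners = c("gA", "gB"), k = 15)
  for (w in substring(shared, 1:6, 15:20)) {
    owners <- unique(idx2$owner[idx2$map[[w]]])
    expect_setequal(owners, c("gA", "gB"))
  }
})

test_that("candidate screening applies the 15-nt cutoff with own-gene exemption", {
  backbone <- random_dna(300, 35)
  plant15 <- random_dna(15, 36)
  other <- paste0(random_dna(100, 37), plant15, random_dna(100, 38))
  idx <- kmer_index(c(own = backbone, other = other),
                    owners = c("gA", "gB"), k = 15)

  # candidate fully inside its own gene, no shared sequence: passes
  cand_own <- substr(backbone, 50, 84)
  expect_true(screen_candidate(cand_own, "gA", idx)$pass)
  # sanity: brute-force longest-common-substring with the other gene < 15
  expect_lt(lcs_length(cand_own, other), 15)

  # candidate carrying the planted 15-mer fails against the other gene
  cand_bad <- paste0(random_dna(10, 39), plant15,
                     substr(random_dna(10, 40), 1, 10))
  expect_equal(nchar(cand_bad), 35)
  res <- screen_candidate(cand_bad, "gA", idx)
  expect_false(res$pass)
  expect_true(all(res$hits$hit_gene == "gB"))
  # but the same window is fine for gB itself (own-gene exemption)
  expect_true(screen_candidate(cand_bad, "gB", idx)$pass)

  # 14-nt longest shared substring does not trigger rejection; flanking
  # bases are chosen explicitly so the match cannot extend to 15
  plant14 <- substr(plant15, 1, 14)
  other14 <- paste0(random_dna(100, 41), "A", plant14, "A",
                    random_dna(100, 42))
  idx14 <- kmer_index(c(own = backbone, other = other14),
                      owners = c("gA", "gB"), k = 15)
  cand14 <- paste0(substr(random_dna(12, 43), 1, 10), "C", plant14, "C",
                   substr(random_dna(12, 44), 1, 9))
  expect_equal(nchar(cand14), 35)
  expect_equal(lcs_length(cand14, other14), 14)
  expect_true(screen_candidate(cand14, "gA", idx14)$pass)
})

test_that("screening is equivalent to the longest-common-substring oracle", {
  # small two-gene system; check every candidate window both ways
  sys <- toy_system(seed = 105)
  genome <- sys$genome
  genes <- sys$genes
  idx <- build_offtarget_index(genes, genome, k = 15)
  regions <- consensus_exonic_regions(genes$geneA, genome)
  cand <- extract_candidates(regions, 35)
  cand <- cand[seq(1, nrow(cand), by = 17), ]  # thin for speed
  # oracle route: longest common substring between the window (either
  # orientation) and the other gene's database sequence (geneB is
  # single-exon, so its spliced mRNA is its only database entry)
  gb <- genes$geneB
  mrna_b <- revcomp(substr(genome[["chr1"]], 1501, 2300))
  for (i in seq_len(nrow(cand))) {
    w <- toupper(cand$target_window[i])
    oracle_fail <- max(lcs_length(w, mrna_b),
                       lcs_length(revcomp(w), mrna_b)) >= 15
    got <- screen_candidate(w, "geneA", idx)$pass
    expect_equal(!got, oracle_fail, label = paste("candidate", i))
  }
})

test_that("bulk screening equals per-candidate screening", {
  sys <- toy_system(seed = 106)
  idx <- build_offtarget_index(sys$genes, sys$genome, k = 15)
  regions <- consensus_exonic_regions(sys$genes$geneA, sys$genome)
  cand <- extract_candidates(regions, 35)
  cfg <- design_config()
  bulk <- fishprobes:::screen_candidates_bulk(cand, regions, idx, cfg)
  single <- vapply(seq_len(nrow(cand)), function(i) {
    screen_candidate(cand$target_window[i], "geneA", idx)$pass
  }, logical(1))
  expect_equal(bulk, single)
})

test_that("adding database sequences can only turn pass into fail", {
  win <- random_dna(35, 45)
  idx_small <- kmer_index(c(a = random_dna(200, 46)), owners = "gB", k = 15)
  idx_big <- kmer_index(c(a = random_dna(200, 46),
                          b = paste0(random_dna(50, 47), win)),
                        owners = c("gB", "gC"), k = 15)
  p_small <- screen_candidate(win, "gA", idx_small)$pass
  p_big <- screen_candidate(win, "gA", idx_big)$pass
  expect_true(p_small)
  expect_false(p_big)  # its own sequence is now owned by another gene
})

test_that("readout screening has no own-gene exemption and a 14-nt boundary", {
  ro <- random_dna(20, 48)
  # empty index: everything passes
  idx0 <- kmer_index(character(0), owners = character(0), k = 15)
  expect_true(screen_readout(ro, idx0, 14))

  # a 15-mer of the readout present anywhere in the database: fail
  idx15 <- kmer_index(
    c(tx = paste0(random_dna(60, 49), substr(ro, 3, 17),
                  random_dna(60, 50))),
    owners = "gQ", k = 15)
  expect_false(screen_readout(ro, idx15, 14))

  # longest shared substring exactly 14: accepted. Flank the planted
  # 14-mer with bases that differ from the readout's own neighbours so the
  # match cannot extend.
  block <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  tx14 <- paste0(random_dna(60, 51), block(substr(ro, 2, 2)),
                 substr(ro, 3, 16), block(substr(ro, 17, 17)),
                 random_dna(60, 52))
  expect_equal(max(lcs_length(ro, tx14), lcs_length(revcomp(ro), tx14)), 14)
  idx14 <- kmer_index(c(tx = tx14), owners = "gQ", k = 15)
  expect_true(screen_readout(ro, idx14, 14))

  # reverse-complement matches are caught too
  idxrc <- kmer_index(c(tx = revcomp(paste0(substr(ro, 1, 15),
                                            random_dna(40, 53)))),
                      owners = "gQ", k = 15)
  expect_false(screen_readout(ro, idxrc, 14))

  # index k must match the screening threshold
  idxk <- kmer_index(c(tx = random_dna(60, 54)), owners = "gQ", k = 12)
  expect_error(screen_readout(ro, idxk, 14), "configuration error")
  expect_error(screen_candidate(random_dna(35, 55), "gA", idxk, k = 15),
               "configuration error")
})
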