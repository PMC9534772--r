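# Shared fixtures and independent oracles, all built in code.

# Deterministic random DNA without touching the global RNG stream the tests
# may be using elsewhere.
random_dna <- function(n, seed, gc = 50) {
  withr::with_seed(seed, {
    p <- gc / 100
    paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
                 prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
          collapse = "")
  })
}

# A 35-mer with an exact number of G/C bases and no homopolymer run over 2.
window_with_gc <- function(n_gc, len = 35L) {
  gcs <- rep(c("G", "C"), length.out = n_gc)
  ats <- rep(c("A", "T"), length.out = len - n_gc)
  out <- character(len)
  # interleave so no long runs form
  idx <- order(c(seq_along(gcs) * (len / max(n_gc, 1)),
                 seq_along(ats) * (len / max(len - n_gc, 1))))
  out <- c(gcs, ats)[idx]
  paste(out, collapse = "")
}

# Longest common substring length between two strings (naive dynamic
# programming) -- the independent oracle for off-target match-length
# questions.
lcs_length <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    for (j in seq_along(y)) {
      if (x[i] == y[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

# Two-gene toy system on one reference: geneA (2 isoforms sharing exons 1+3,
# isoform 2 skips exon 2) and geneB (single exon, minus strand).
toy_system <- function(seed = 101) {
  chrom <- random_dna(3000, seed)
  genome <- c(chr1 = chrom)
  geneA <- gene_model(
    "geneA", "+", "chr1",
    list(
      tA1 = IRanges::IRanges(start = c(101, 501, 901),
                             end = c(400, 700, 1200)),
      tA2 = IRanges::IRanges(start = c(101, 901), end = c(400, 1200))))
  geneB <- gene_model(
    "geneB", "-", "chr1",
    list(tB1 = IRanges::IRanges(start = 1501, end = 2300)))
  list(genome = genome, genes = list(geneA = geneA, geneB = geneB))
}

# Write a tiny GTF from exon coordinate rows (gene, tx, start, end, strand).
write_toy_gtf <- function(rows, path) {
  lines <- sprintf(
    "%s\ttest\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
    rows$chr, rows$start, rows$end, rows$strand, rows$gene, rows$tx)
  writeLines(lines, path)
  path
}
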