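#' Reverse complement preserving case
#'
#' Case-preserving reverse complement for character vectors of nucleotide
#' sequences. Lowercase (soft-masked) bases stay lowercase so that masking
#' information survives strand flips; \code{N}/\code{n} map to themselves.
#' IUPAC ambiguity codes are complemented as well.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTacgtN")  # "NacgtACGT"
revcomp <- function(x) {
  comp <- chartr(
    "ACGTacgtNnRYSWKMBDHVryswkmbdhv",
    "TGCAtgcaNnYRSWMKVHDByrswmkvhdb", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Percent GC content
#'
#' GC is counted over G/C (either case) and divided by the full sequence
#' length, so ambiguous or masked bases dilute rather than inflate the value.
#'
#' @param x character vector of sequences.
#' @return numeric vector, percent in [0, 100].
#' @export
gc_percent <- function(x) {
  n <- nchar(x)
  gc <- n - nchar(gsub("[GCgc]", "", x))
  ifelse(n == 0, NA_real_, 100 * gc / n)
}

#' Read a genome FASTA preserving soft-masking
#'
#' Reads a (multi-)FASTA into a named character vector, one element per
#' reference sequence. Lowercase soft-masked stretches are preserved, which
#' the candidate mask filter relies on.
#'
#' @param path path to a FASTA file.
#' @return named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  out <- vapply(recs, function(r) as.character(r)[1], character(1))
  names(out) <- names(recs)
  out
}

# Write a named character vector as FASTA with fixed 60-column wrapping.
# Deterministic byte-for-byte (no timestamps), unlike some exporters.
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    n <- nchar(s)
    if (n > 0L) {
      starts <- seq(1L, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
    }
  }
  invisible(path)
}

# All k-mers of a string as a character vector (empty if too short).
kmers_of <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(character(0))
  substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L)
}

# stopifnot with a formatted message
fail_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)
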