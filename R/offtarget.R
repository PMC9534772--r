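#' Build a k-mer index over arbitrary sequences
#'
#' Low-level constructor for the off-target index: a hash from every k-mer
#' (uppercased; k-mers containing non-ACGT letters are skipped) to the
#' sequences containing it, plus a sequence-to-gene ownership map. Most
#' users will call \code{\link{build_offtarget_index}} instead.
#'
#' @param seqs named character vector of database sequences.
#' @param owners character vector, the owning gene id of each sequence.
#' @param kinds character vector labelling each sequence (e.g. \code{"mrna"},
#'   \code{"reversed_intron"}).
#' @param k word length.
#' @return an object of class \code{"offtarget_index"}.
#' @export
kmer_index <- function(seqs, owners, kinds = rep("mrna", length(seqs)),
                       k = 15L) {
  fail_if(k < 1L, "k must be >= 1")
  fail_if(length(owners) != length(seqs) || length(kinds) != length(seqs),
          "owners and kinds must parallel seqs")
  map <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    km <- kmers_of(toupper(seqs[[i]]), k)
    km <- unique(km[!grepl("[^ACGT]", km)])
    for (w in km) map[[w]] <- c(map[[w]], i)
  }
  structure(
    list(k = as.integer(k), map = map,
         owner = as.character(owners),
         seq_ids = names(seqs),
         db_composition = data.frame(
           seq_id = names(seqs), gene_id = as.character(owners),
           kind = as.character(kinds),
           length = nchar(as.character(seqs)),
           stringsAsFactors = FALSE)),
    class = "offtarget_index")
}

#' Build the transcriptome off-target index
#'
#' Constructs the off-target sequence database the way the screening
#' protocol specifies: every spliced mRNA of every gene, plus every intron
#' sequence reversed (literal string reversal by default; reverse
#' complement if \code{intron_reversal_mode = "revcomp"}). All k-mers of
#' these sequences are indexed with gene ownership, so that candidate
#' screening can exempt the target gene's own transcripts.
#'
#' @param genes list of \code{\link{gene_model}} objects.
#' @param genome named character vector of reference sequences.
#' @param k exact-match word length.
#' @param intron_reversal_mode \code{"reverse"} or \code{"revcomp"}.
#' @return an \code{offtarget_index}.
#' @export
build_offtarget_index <- function(genes, genome, k = 15L,
                                  intron_reversal_mode = "reverse") {
  seqs <- character(0); owners <- character(0); kinds <- character(0)
  for (g in genes) {
    for (tx in names(g$isoforms)) {
      s <- region_sequence(g$isoforms[[tx]], g, genome)
      seqs[[paste0(g$gene_id, "|", tx, "|mrna")]] <- s
      owners <- c(owners, g$gene_id); kinds <- c(kinds, "mrna")
    }
    introns <- expansion_regions(g, genome)
    introns <- introns[introns$source == "intron", , drop = FALSE]
    if (nrow(introns) > 0L) {
      for (i in seq_len(nrow(introns))) {
        s <- introns$sequence[i]
        s <- if (intron_reversal_mode == "revcomp") revcomp(s)
             else paste(rev(strsplit(s, "", fixed = TRUE)[[1]]),
                        collapse = "")
        seqs[[paste0(g$gene_id, "|intron", i, "|reversed_intron")]] <- s
        owners <- c(owners, g$gene_id); kinds <- c(kinds, "reversed_intron")
      }
    }
  }
  kmer_index(seqs, owners, kinds, k)
}

# Look up one k-mer; returns integer indices of db sequences containing it.
lookup_kmer <- function(idx, w) {
  v <- idx$map[[w]]
  if (is.null(v)) integer(0) else v
}

#' Screen one candidate window against the off-target index
#'
#' A candidate fails if any k-mer of its target window, or of the window's
#' reverse complement (both orientations are screened, as blastn would), is
#' found on a database sequence owned by a different gene. Sharing an exact
#' k-mer with k equal to the match cutoff is equivalent to sharing a
#' contiguous exact match of at least k nt. Matches to the candidate's own
#' gene (any isoform) are never hits.
#'
#' @param x a candidate window (character) or a 1-row candidate data.frame.
#' @param gene_id the candidate's own gene (taken from the data.frame if
#'   omitted).
#' @param idx an \code{offtarget_index}.
#' @param k expected word length; must equal \code{idx$k}.
#' @return list with \code{pass} (logical) and \code{hits} (data.frame:
#'   \code{candidate_gene}, \code{seq_id}, \code{hit_gene}, \code{kmer},
#'   \code{orientation}).
#' @export
screen_candidate <- function(x, gene_id = NULL, idx, k = idx$k) {
  fail_if(idx$k != k, "off-target index built with k = ", idx$k,
          " but screening requested k = ", k, " (configuration error)")
  if (is.data.frame(x)) {
    if (is.null(gene_id)) gene_id <- x$gene_id[1]
    x <- x$target_window[1]
  }
  win <- toupper(x)
  qs <- list(same = kmers_of(win, idx$k),
             revcomp = kmers_of(revcomp(win), idx$k))
  hits <- list()
  for (ori in names(qs)) {
    for (w in unique(qs[[ori]])) {
      if (grepl("[^ACGT]", w)) next
      ids <- lookup_kmer(idx, w)
      ids <- ids[idx$owner[ids] != gene_id]
      if (length(ids) > 0L) {
        hits[[length(hits) + 1L]] <- data.frame(
          candidate_gene = gene_id, seq_id = idx$seq_ids[ids],
          hit_gene = idx$owner[ids], kmer = w, orientation = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(hits) > 0L) do.call(rbind, hits) else
    data.frame(candidate_gene = character(0), seq_id = character(0),
               hit_gene = character(0), kmer = character(0),
               orientation = character(0), stringsAsFactors = FALSE)
  list(pass = nrow(hits) == 0L, hits = hits)
}

#' Screen a readout sequence for transcriptome homology
#'
#' Readout probes must be orthogonal to the entire transcriptome: the
#' sequence fails if it (or its reverse complement) shares any contiguous
#' exact match longer than \code{max_homology} nt — i.e. any
#' \code{(max_homology + 1)}-mer — with \emph{any} indexed sequence. There
#' is no own-gene exemption.
#'
#' @param seq nucleotide string.
#' @param idx an \code{offtarget_index} built with
#'   \code{k = max_homology + 1}.
#' @param max_homology longest tolerated contiguous homology, nt.
#' @return logical: \code{TRUE} if the sequence passes.
#' @export
screen_readout <- function(seq, idx, max_homology = 14L) {
  fail_if(idx$k != max_homology + 1L,
          "off-target index built with k = ", idx$k,
          " but readout screening requires k = max_homology + 1 = ",
          max_homology + 1L, " (configuration error)")
  win <- toupper(seq)
  for (q in c(win, revcomp(win))) {
    for (w in unique(kmers_of(q, idx$k))) {
      if (grepl("[^ACGT]", w)) next
      if (length(lookup_kmer(idx, w)) > 0L) return(FALSE)
    }
  }
  TRUE
}

# Positions (1-based k-mer start offsets within `seq`) whose k-mer, in either
# orientation, occurs in the index on a sequence owned by a gene other than
# `gene_id` (or on any sequence when gene_id is NULL). Vectorized bulk form
# of screen_candidate used by the pipeline; equivalence is asserted in the
# test suite.
offtarget_bad_positions <- function(seq, gene_id, idx) {
  u <- toupper(seq)
  L <- nchar(u)
  k <- idx$k
  if (L < k) return(integer(0))
  hit_positions <- function(kms) {
    uq <- unique(kms[!grepl("[^ACGT]", kms)])
    if (length(uq) == 0L) return(integer(0))
    is_hit <- vapply(uq, function(w) {
      ids <- lookup_kmer(idx, w)
      if (is.null(gene_id)) length(ids) > 0L
      else any(idx$owner[ids] != gene_id)
    }, logical(1))
    which(kms %in% uq[is_hit])
  }
  p1 <- hit_positions(kmers_of(u, k))
  # k-mer j of the reverse complement covers original positions
  # (L - j - k + 2) .. (L - j + 1), i.e. starts at L - j - k + 2.
  p2rc <- hit_positions(kmers_of(revcomp(u), k))
  p2 <- L - p2rc - k + 2L
  sort(unique(c(p1, p2)))
}

#' @export
print.offtarget_index <- function(x, ...) {
  comp <- table(x$db_composition$kind)
  cat(sprintf("off-target k-mer index (k = %d): %d sequences (%s), %d genes\n",
              x$k, nrow(x$db_composition),
              paste(sprintf("%s: %d", names(comp), comp), collapse = ", "),
              length(unique(x$owner))))
  invisible(x)
}
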