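#' Construct a gene model
#'
#' A gene model holds the per-isoform exon intervals of one gene on a shared
#' reference coordinate system (1-based, closed, the native R/Bioconductor
#' convention), plus any annotated 5' UTR intervals. Exons within an isoform
#' must be sorted and pairwise non-overlapping.
#'
#' @param gene_id gene identifier.
#' @param strand \code{"+"} or \code{"-"}.
#' @param reference_name name of the reference sequence the intervals live on.
#' @param isoforms named list (by transcript id) of \code{IRanges} of exons.
#' @param utr5 optional \code{IRanges} of annotated 5' UTR intervals.
#' @return an object of class \code{"gene_model"}.
#' @export
gene_model <- function(gene_id, strand, reference_name, isoforms,
                       utr5 = IRanges::IRanges()) {
  fail_if(!strand %in% c("+", "-"), "gene ", gene_id,
          ": strand must be '+' or '-'")
  fail_if(length(isoforms) < 1L, "gene ", gene_id, ": no isoforms")
  fail_if(is.null(names(isoforms)) || anyDuplicated(names(isoforms)) > 0L,
          "gene ", gene_id, ": isoforms must be uniquely named by transcript")
  tx_ids <- names(isoforms)
  isoforms <- lapply(tx_ids, function(tx) {
    ex <- isoforms[[tx]]
    fail_if(length(ex) == 0L,
            "gene ", gene_id, ": transcript ", tx, " has zero exons")
    ex <- BiocGenerics::sort(ex)
    fail_if(length(IRanges::reduce(ex)) != length(ex) ||
              any(IRanges::width(ex) < 1L),
            "gene ", gene_id, ": transcript ", tx,
            " has overlapping or empty exons")
    ex
  })
  names(isoforms) <- tx_ids
  structure(
    list(gene_id = gene_id, strand = strand,
         reference_name = reference_name,
         isoforms = isoforms, utr5 = utr5),
    class = "gene_model")
}

#' Read gene models from a GTF annotation
#'
#' Parses exon (and optional \code{five_prime_utr}) features from a GTF
#' subset into one \code{\link{gene_model}} per gene, checking every exon
#' against the genome's reference sequences and lengths. Output is ordered
#' by \code{gene_id} so downstream processing is deterministic.
#'
#' @param annotation_path path to a GTF file whose exon features carry
#'   \code{gene_id} and \code{transcript_id} attributes.
#' @param genome a named character vector of reference sequences (from
#'   \code{\link{read_genome_fasta}}) or a path to a genome FASTA.
#' @return list of \code{gene_model} objects, sorted by gene id.
#' @export
read_gene_models <- function(annotation_path, genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome)))
    genome <- read_genome_fasta(genome)
  gtf <- rtracklayer::import(annotation_path, format = "gtf")
  ex <- gtf[gtf$type == "exon"]
  fail_if(length(ex) == 0L, "no exon features in ", annotation_path)
  fail_if(is.null(ex$gene_id) || is.null(ex$transcript_id) ||
            anyNA(ex$gene_id) || anyNA(ex$transcript_id),
          "exon features must carry gene_id and transcript_id attributes")
  utr <- gtf[gtf$type == "five_prime_utr"]

  ref_len <- nchar(genome)
  gene_ids <- sort(unique(ex$gene_id))
  models <- lapply(gene_ids, function(g) {
    exg <- ex[ex$gene_id == g]
    chr <- as.character(unique(GenomicRanges::seqnames(exg)))
    fail_if(length(chr) != 1L, "gene ", g, " spans multiple references")
    fail_if(!chr %in% names(genome),
            "reference sequence '", chr, "' (gene ", g,
            ") not present in the genome FASTA")
    std <- as.character(unique(GenomicRanges::strand(exg)))
    fail_if(length(std) != 1L || !std %in% c("+", "-"),
            "gene ", g, " has missing or mixed strand")
    fail_if(max(GenomicRanges::end(exg)) > ref_len[[chr]] ||
              min(GenomicRanges::start(exg)) < 1L,
            "gene ", g, " has exons outside the bounds of '", chr, "'")
    isoforms <- lapply(split(GenomicRanges::ranges(exg), exg$transcript_id),
                       identity)
    u5 <- utr[!is.na(utr$gene_id) & utr$gene_id == g]
    gene_model(g, std, chr, isoforms,
               utr5 = IRanges::reduce(BiocGenerics::sort(GenomicRanges::ranges(u5))))
  })
  names(models) <- gene_ids
  models
}

# mRNA-sense sequence of a set of reference intervals: slice in coordinate
# order, then reverse-complement the concatenation for minus-strand genes.
region_sequence <- function(ranges, gene, genome) {
  ref <- genome[[gene$reference_name]]
  s <- paste(substring(ref, IRanges::start(ranges), IRanges::end(ranges)),
             collapse = "")
  if (gene$strand == "-") revcomp(s) else s
}

# Build the target-region table for a set of intervals. Each interval becomes
# one row with its own mRNA-sense sequence.
as_target_regions <- function(ranges, gene, genome, source) {
  if (length(ranges) == 0L) {
    return(data.frame(gene_id = character(0), source = character(0),
                      start = integer(0), end = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  seqs <- vapply(seq_along(ranges), function(i) {
    region_sequence(ranges[i], gene, genome)
  }, character(1))
  data.frame(gene_id = gene$gene_id, source = source,
             start = IRanges::start(ranges), end = IRanges::end(ranges),
             sequence = seqs, stringsAsFactors = FALSE)
}

#' Isoform-consensus exonic target regions
#'
#' The consensus is the per-base intersection of exon coverage across all
#' isoforms of the gene, reported as maximal disjoint intervals sorted by
#' coordinate. A probe placed in a consensus region hybridizes to every
#' spliced isoform. A single-isoform gene returns its own exons; genes whose
#' isoforms share no exonic base return an empty table.
#'
#' @param gene a \code{\link{gene_model}}.
#' @param genome named character vector of reference sequences.
#' @return data.frame of target regions (\code{gene_id}, \code{source},
#'   \code{start}, \code{end}, \code{sequence}); sequences are mRNA-sense and
#'   preserve soft-masking case.
#' @export
consensus_exonic_regions <- function(gene, genome) {
  cons <- Reduce(IRanges::intersect,
                 lapply(gene$isoforms, IRanges::reduce))
  as_target_regions(cons, gene, genome, "exon_consensus")
}

#' Intron and 5' UTR expansion regions
#'
#' For genes that do not yield enough exonic-consensus targets, probe design
#' expands into intronic sequence (the union, across isoforms, of the gaps
#' between consecutive exons) and, where the annotation provides
#' \code{five_prime_utr} features, the 5' UTR.
#'
#' @inheritParams consensus_exonic_regions
#' @return data.frame of target regions with \code{source} \code{"intron"}
#'   or \code{"utr5"}; may be empty.
#' @export
expansion_regions <- function(gene, genome) {
  introns_per_iso <- lapply(gene$isoforms, function(ex) {
    if (length(ex) < 2L) return(IRanges::IRanges())
    span <- IRanges::IRanges(min(IRanges::start(ex)),
                             max(IRanges::end(ex)))
    IRanges::setdiff(span, ex)
  })
  introns <- IRanges::reduce(BiocGenerics::sort(do.call(c, unname(introns_per_iso))))
  out <- as_target_regions(introns, gene, genome, "intron")
  if (length(gene$utr5) > 0L) {
    out <- rbind(out, as_target_regions(gene$utr5, gene, genome, "utr5"))
  }
  out
}

#' Read pre-extracted target regions from FASTA
#'
#' Alternative direct input: a per-gene target FASTA whose headers follow
#' \code{gene_id|source|start-end}.
#'
#' @param path path to the FASTA file.
#' @return data.frame of target regions as in
#'   \code{\link{consensus_exonic_regions}}.
#' @export
read_target_regions <- function(path) {
  seqs <- read_genome_fasta(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 3L
  fail_if(any(bad), "target FASTA headers must be gene_id|source|start-end")
  coords <- strsplit(vapply(parts, `[[`, character(1), 3L), "-", fixed = TRUE)
  data.frame(
    gene_id = vapply(parts, `[[`, character(1), 1L),
    source = vapply(parts, `[[`, character(1), 2L),
    start = as.integer(vapply(coords, `[[`, character(1), 1L)),
    end = as.integer(vapply(coords, `[[`, character(1), 2L)),
    sequence = unname(seqs), stringsAsFactors = FALSE)
}
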