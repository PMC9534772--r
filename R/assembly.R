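#' Assemble a full-length primary probe
#'
#' Builds the orderable oligo from a binding site and six readout sites
#' following the linker grammar
#' \preformatted{R'-AA-R'-AA-R'-TAAT-B-TAAT-R'-AA-R'-AA-R'}
#' where each \code{R'} is the reverse complement of a readout site (so that
#' fluorophore-bearing readout oligos hybridize to the assembled probe) and
#' \code{B} is the binding site. Total length is
#' \code{6 * site_len + 16 + nchar(binding_site)}; with the default 15-nt
#' sites and a 35-nt binding site this is the published 141 nt. In
#' sequential mode all six slots carry the same readout site.
#'
#' @param binding_site probe-sense binding site (uppercase ACGT).
#' @param readout_sites character vector of 6 readout site sequences, or a
#'   single site to repeat in all slots.
#' @param site_len expected readout-site length.
#' @return list of class \code{"primary_probe"}: \code{binding_site},
#'   \code{readout_sites}, \code{site_len}, \code{full_sequence},
#'   \code{length}.
#' @export
assemble_primary_probe <- function(binding_site, readout_sites,
                                   site_len = 15L) {
  if (length(readout_sites) == 1L) readout_sites <- rep(readout_sites, 6L)
  fail_if(length(readout_sites) != 6L,
          "exactly 6 readout sites are required (or 1 to repeat)")
  fail_if(any(nchar(readout_sites) != site_len),
          "readout site length mismatch: expected ", site_len, " nt")
  fail_if(grepl("[^ACGT]", binding_site),
          "binding site contains non-ACGT characters")
  fail_if(any(grepl("[^ACGT]", readout_sites)),
          "readout sites contain non-ACGT characters")
  slots <- revcomp(readout_sites)
  full <- paste0(slots[1], "AA", slots[2], "AA", slots[3], "TAAT",
                 binding_site, "TAAT",
                 slots[4], "AA", slots[5], "AA", slots[6])
  structure(
    list(binding_site = binding_site, readout_sites = readout_sites,
         site_len = as.integer(site_len), full_sequence = full,
         length = nchar(full)),
    class = "primary_probe")
}

#' Parse an assembled primary probe back into its parts
#'
#' Inverse of \code{\link{assemble_primary_probe}}: recovers the binding
#' site and the six readout sites from a full-length sequence, verifying the
#' AA/TAAT linkers and the total length along the way.
#'
#' @param full_sequence assembled probe sequence.
#' @param site_len readout-site length used at assembly.
#' @param binding_len binding-site length used at assembly.
#' @return list with \code{binding_site} and \code{readout_sites}.
#' @export
parse_primary_probe <- function(full_sequence, site_len = 15L,
                                binding_len = 35L) {
  expect_len <- 6L * site_len + 16L + binding_len
  fail_if(nchar(full_sequence) != expect_len,
          "sequence length ", nchar(full_sequence),
          " does not match the grammar (expected ", expect_len, ")")
  pos <- 1L
  take <- function(n) {
    out <- substr(full_sequence, pos, pos + n - 1L)
    pos <<- pos + n
    out
  }
  slots <- character(6)
  slots[1] <- take(site_len)
  fail_if(take(2L) != "AA", "malformed probe: expected AA linker")
  slots[2] <- take(site_len)
  fail_if(take(2L) != "AA", "malformed probe: expected AA linker")
  slots[3] <- take(site_len)
  fail_if(take(4L) != "TAAT", "malformed probe: expected TAAT linker")
  binding <- take(binding_len)
  fail_if(take(4L) != "TAAT", "malformed probe: expected TAAT linker")
  slots[4] <- take(site_len)
  fail_if(take(2L) != "AA", "malformed probe: expected AA linker")
  slots[5] <- take(site_len)
  fail_if(take(2L) != "AA", "malformed probe: expected AA linker")
  slots[6] <- take(site_len)
  list(binding_site = binding, readout_sites = revcomp(slots))
}

#' Assign one readout identity per gene
#'
#' Sequential smFISH reads one gene per readout: the codebook maps each gene
#' to a distinct readout in input order, carrying along the readout's
#' fluorophore when assigned.
#'
#' @param genes character vector of gene ids.
#' @param readouts readout data.frame (\code{\link{generate_readouts}}).
#' @return data.frame: \code{gene_id}, \code{readout_id},
#'   \code{fluorophore}.
#' @export
build_codebook <- function(genes, readouts) {
  fail_if(length(genes) < 1L, "no genes to encode")
  fail_if(nrow(readouts) < length(genes),
          "insufficient readouts: ", nrow(readouts), " for ",
          length(genes), " genes (readout reuse is not supported)")
  data.frame(gene_id = as.character(genes),
             readout_id = readouts$readout_id[seq_along(genes)],
             fluorophore = readouts$fluorophore[seq_along(genes)],
             stringsAsFactors = FALSE)
}

#' Schedule hybridization rounds across fluorophore channels
#'
#' Fills genes into (round, channel) cells. When readouts carry fixed
#' fluorophores, each gene is placed in its readout's channel at the next
#' free round of that channel; otherwise genes are filled round-major. Each
#' gene appears exactly once and no two genes share a cell; under the
#' default round-robin fluorophore assignment the number of rounds is
#' \code{ceiling(#genes / #channels)}.
#'
#' @param codebook data.frame from \code{\link{build_codebook}}.
#' @param channels character vector of channel labels.
#' @return list of class \code{"hyb_schedule"}: \code{entries} (data.frame
#'   \code{gene_id}, \code{readout_id}, \code{round}, \code{channel}),
#'   \code{n_rounds}, \code{channels}.
#' @export
schedule_hybridizations <- function(codebook,
                                    channels = c("AF647", "AF488", "AF546")) {
  fail_if(nrow(codebook) < 1L, "empty codebook")
  fail_if(length(channels) < 1L, "channels must be non-empty")
  n <- nrow(codebook)
  fixed <- !is.null(codebook$fluorophore) && !anyNA(codebook$fluorophore)
  if (fixed) {
    bad <- setdiff(unique(codebook$fluorophore), channels)
    fail_if(length(bad) > 0L,
            "gene(s) ", paste(
              codebook$gene_id[codebook$fluorophore %in% bad][1],
              collapse = ", "),
            " require channel(s) ", paste(bad, collapse = ", "),
            " absent from the channel set")
    next_round <- stats::setNames(rep(1L, length(channels)), channels)
    rounds <- integer(n); chans <- character(n)
    for (i in seq_len(n)) {
      ch <- codebook$fluorophore[i]
      rounds[i] <- next_round[[ch]]
      chans[i] <- ch
      next_round[[ch]] <- next_round[[ch]] + 1L
    }
  } else {
    rounds <- (seq_len(n) - 1L) %/% length(channels) + 1L
    chans <- channels[(seq_len(n) - 1L) %% length(channels) + 1L]
  }
  entries <- data.frame(gene_id = codebook$gene_id,
                        readout_id = codebook$readout_id,
                        round = rounds, channel = chans,
                        stringsAsFactors = FALSE)
  structure(list(entries = entries, n_rounds = max(rounds),
                 channels = channels),
            class = "hyb_schedule")
}

#' @export
print.hyb_schedule <- function(x, ...) {
  cat(sprintf("hybridization schedule: %d genes over %d round(s) x %d channel(s)\n",
              nrow(x$entries), x$n_rounds, length(x$channels)))
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Write order-ready design outputs
#'
#' Emits the complete, byte-stable set of run artifacts into \code{out_dir}:
#' \itemize{
#'   \item \code{primary_probes.fasta} — assembled probes, headers
#'     \code{gene_id|probe_index|start|source};
#'   \item \code{order_sheet.tsv} — name, full sequence, 5'-phosphate
#'     modification for the oligo pool order;
#'   \item \code{readouts.tsv} / \code{readouts.fasta} — readout sequences
#'     with fluorophore and 5'-modification labels;
#'   \item \code{design.json} — per-gene codebook entry (readout, round,
#'     channel);
#'   \item \code{config.json} — full configuration snapshot;
#'   \item \code{run_log.txt} — per-gene, per-stage candidate counts.
#' }
#'
#' @param probes data.frame of assembled probes (from
#'   \code{\link{run_pipeline}}/\code{\link{assemble_probe_table}}).
#' @param readouts readout data.frame.
#' @param schedule a \code{hyb_schedule}.
#' @param cfg the \code{design_config} used.
#' @param counts per-gene stage-count data.frame.
#' @param out_dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
write_outputs <- function(probes, readouts, schedule, cfg, counts, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                          showWarnings = FALSE)
  fail_if(!ok || file.access(out_dir, 2L) != 0L,
          "cannot write to output directory: ", out_dir)
  paths <- character(0)

  fa <- file.path(out_dir, "primary_probes.fasta")
  if (nrow(probes) > 0L) {
    headers <- sprintf("%s|%d|%d|%s", probes$gene_id, probes$probe_index,
                       probes$start, probes$source)
    write_fasta(stats::setNames(as.list(probes$full_sequence), headers), fa)
  } else {
    write_fasta(list(), fa)
  }
  paths <- c(paths, fa)

  sheet <- data.frame(
    name = if (nrow(probes) > 0L)
      sprintf("%s_probe%03d", probes$gene_id, probes$probe_index)
    else character(0),
    sequence = probes$full_sequence,
    modification = rep("5'-phosphate", nrow(probes)),
    stringsAsFactors = FALSE)
  p <- file.path(out_dir, "order_sheet.tsv")
  utils::write.table(sheet, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)

  ro <- readouts
  ro$modification <- paste0("5'-", ro$fluorophore)
  p <- file.path(out_dir, "readouts.tsv")
  utils::write.table(
    ro[, c("readout_id", "sequence", "fluorophore", "modification")],
    p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "readouts.fasta")
  write_fasta(stats::setNames(as.list(readouts$sequence),
                              readouts$readout_id), p)
  paths <- c(paths, p)

  design <- lapply(seq_len(nrow(schedule$entries)), function(i) {
    e <- schedule$entries[i, ]
    list(readout = e$readout_id, round = e$round, channel = e$channel)
  })
  names(design) <- schedule$entries$gene_id
  p <- file.path(out_dir, "design.json")
  jsonlite::write_json(design, p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)

  p <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, pretty = TRUE)
  paths <- c(paths, p)

  log_lines <- c("fishprobes run log",
                 sprintf("genes: %d; probes: %d; readouts: %d; rounds: %d",
                         length(unique(counts$gene_id)), nrow(probes),
                         nrow(readouts), schedule$n_rounds))
  if (nrow(probes) == 0L)
    log_lines <- c(log_lines, "WARNING: empty probe set")
  log_lines <- c(log_lines, "", "per-gene stage counts:",
                 utils::capture.output(print(counts, row.names = FALSE)))
  p <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, p)
  paths <- c(paths, p)

  invisible(paths)
}
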