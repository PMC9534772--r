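#' Design primary-probe binding sites for a set of genes
#'
#' Runs the per-gene design stages: extract candidate windows from the
#' isoform-consensus exonic regions, apply the composition filters (GC,
#' homopolymer, masked bases), screen survivors against the off-target
#' index, resolve overlaps greedily toward the GC target, expand into
#' introns/5' UTRs when the gene did not yield strictly more than
#' \code{expansion_threshold} probes, and trim to \code{max_probes} probes
#' closest to the GC target. Exon-consensus probes are never displaced by
#' expansion probes; expansion only appends.
#'
#' @param genes list of \code{\link{gene_model}} objects.
#' @param genome named character vector of reference sequences.
#' @param cfg a \code{\link{design_config}}.
#' @param idx optional pre-built \code{offtarget_index}; built from
#'   \code{genes} when omitted.
#' @return object of class \code{"probe_design"}: \code{probes} (data.frame
#'   with \code{gene_id}, \code{probe_index}, \code{source},
#'   \code{region_start}, \code{start}, \code{target_window},
#'   \code{binding_site}, \code{gc_percent}), \code{counts} (per-gene,
#'   per-stage counts), \code{config}, \code{index}.
#' @export
design_probes <- function(genes, genome, cfg = design_config(), idx = NULL) {
  validate_config(cfg)
  if (is.null(idx))
    idx <- build_offtarget_index(genes, genome, k = cfg$offtarget_k,
                                 intron_reversal_mode =
                                   cfg$intron_reversal_mode)
  fail_if(idx$k != cfg$offtarget_k,
          "off-target index built with k = ", idx$k,
          " but config requests offtarget_k = ", cfg$offtarget_k,
          " (configuration error)")

  stage_one <- function(regions, gene_id) {
    cand <- extract_candidates(regions, cfg$window, cfg$step)
    cand <- apply_composition_filters(cand, cfg)
    surv <- cand[cand$pass_composition, , drop = FALSE]
    surv$pass_offtarget <- screen_candidates_bulk(surv, regions, idx, cfg)
    kept <- surv[surv$pass_offtarget, , drop = FALSE]
    resolved <- resolve_overlaps(kept, cfg$gc_target, cfg$window)
    list(extracted = nrow(cand), composition_passed = nrow(surv),
         offtarget_passed = nrow(kept), resolved = resolved)
  }

  all_probes <- list()
  all_counts <- list()
  for (g in genes) {
    cons <- consensus_exonic_regions(g, genome)
    s1 <- stage_one(cons, g$gene_id)
    probes <- s1$resolved
    expanded <- needs_expansion(nrow(probes), cfg$expansion_threshold)
    s2 <- NULL
    if (expanded) {
      exp_regions <- expansion_regions(g, genome)
      s2 <- stage_one(exp_regions, g$gene_id)
      probes <- rbind(probes, s2$resolved)
    }
    final <- trim_to_max(probes, cfg$max_probes, cfg$gc_target)
    all_probes[[g$gene_id]] <- final
    all_counts[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id,
      extracted = s1$extracted + if (is.null(s2)) 0L else s2$extracted,
      composition_passed = s1$composition_passed +
        if (is.null(s2)) 0L else s2$composition_passed,
      offtarget_passed = s1$offtarget_passed +
        if (is.null(s2)) 0L else s2$offtarget_passed,
      overlap_resolved = nrow(probes),
      expansion_used = expanded,
      trimmed = isTRUE(attr(final, "trimmed")),
      final = nrow(final),
      stringsAsFactors = FALSE)
  }
  probes <- do.call(rbind, unname(all_probes))
  if (is.null(probes) || nrow(probes) == 0L) {
    probes <- extract_candidates(
      data.frame(gene_id = character(0), source = character(0),
                 start = integer(0), end = integer(0),
                 sequence = character(0), stringsAsFactors = FALSE),
      cfg$window)
    probes$probe_index <- integer(0)
  } else {
    probes$probe_index <- stats::ave(seq_len(nrow(probes)), probes$gene_id,
                                     FUN = seq_along)
  }
  rownames(probes) <- NULL
  structure(
    list(probes = probes, counts = do.call(rbind, unname(all_counts)),
         config = cfg, index = idx),
    class = "probe_design")
}

# Bulk off-target screening for one gene's composition survivors: computes
# per-region bad k-mer start positions once and derives each candidate's
# fate from them. Equivalent to calling screen_candidate per row (asserted
# in the test suite), but linear in region length rather than in
# candidates x window.
screen_candidates_bulk <- function(candidates, regions, idx, cfg) {
  if (nrow(candidates) == 0L) return(logical(0))
  pass <- logical(nrow(candidates))
  key <- paste(candidates$source, candidates$region_start)
  for (i in seq_len(nrow(regions))) {
    rk <- paste(regions$source[i], regions$start[i])
    rows <- which(key == rk)
    if (length(rows) == 0L) next
    bad <- offtarget_bad_positions(regions$sequence[i],
                                   regions$gene_id[i], idx)
    if (length(bad) == 0L) { pass[rows] <- TRUE; next }
    # candidate at offset s fails iff a bad k-mer starts in
    # [s, s + window - k]
    L <- nchar(regions$sequence[i])
    badvec <- logical(max(L - idx$k + 1L, 0L))
    badvec[bad] <- TRUE
    cb <- c(0L, cumsum(badvec))
    s <- candidates$start[rows]
    hi <- pmin(s + cfg$window - idx$k, length(badvec))
    nbad <- cb[hi + 1L] - cb[s]
    pass[rows] <- nbad == 0L
  }
  pass
}

#' Assemble the final probe table
#'
#' Joins designed binding sites with the codebook: each probe's six readout
#' slots carry the (reverse complement of the) readout site assigned to its
#' gene, following the AA/TAAT linker grammar.
#'
#' @param design a \code{probe_design}.
#' @param codebook data.frame from \code{\link{build_codebook}}.
#' @param readouts readout data.frame.
#' @param cfg the \code{design_config}.
#' @return the design's probe data.frame with a \code{full_sequence} column.
#' @export
assemble_probe_table <- function(design, codebook, readouts, cfg) {
  probes <- design$probes
  if (nrow(probes) == 0L) {
    probes$full_sequence <- character(0)
    return(probes)
  }
  site_of <- stats::setNames(readouts$site_sequence, readouts$readout_id)
  ro_of <- stats::setNames(codebook$readout_id, codebook$gene_id)
  probes$full_sequence <- vapply(seq_len(nrow(probes)), function(i) {
    site <- site_of[[ro_of[[probes$gene_id[i]]]]]
    assemble_primary_probe(toupper(probes$binding_site[i]), site,
                           cfg$readout_site_len)$full_sequence
  }, character(1))
  probes
}

#' Run the complete probe-design pipeline
#'
#' End-to-end driver: read gene models, design binding sites
#' (\code{\link{design_probes}}), generate one readout per gene
#' (\code{\link{generate_readouts}} seeded from the config), assign
#' fluorophores, build the codebook and hybridization schedule, assemble
#' full-length primary probes, and write all order-ready outputs. Identical
#' inputs and configuration produce byte-identical outputs.
#'
#' @param annotation_path GTF path (or \code{NULL} if \code{genes} given).
#' @param genome_path genome FASTA path (or a named character vector).
#' @param out_dir output directory.
#' @param cfg a \code{\link{design_config}}.
#' @param genes optional pre-built list of \code{gene_model}s (overrides
#'   \code{annotation_path}).
#' @return invisible list of class \code{"fishprobes_run"}: \code{design},
#'   \code{readouts}, \code{codebook}, \code{schedule}, \code{probes},
#'   \code{files}.
#' @export
run_pipeline <- function(annotation_path = NULL, genome_path, out_dir,
                         cfg = design_config(), genes = NULL) {
  validate_config(cfg)
  genome <- if (is.character(genome_path) && length(genome_path) == 1L &&
                  is.null(names(genome_path)))
    read_genome_fasta(genome_path) else genome_path
  if (is.null(genes)) {
    fail_if(is.null(annotation_path),
            "either annotation_path or genes must be supplied")
    genes <- read_gene_models(annotation_path, genome)
  }
  design <- design_probes(genes, genome, cfg)
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  readouts <- generate_readouts(
    n = length(gene_ids), idx = design$index, seed = cfg$seed,
    length = cfg$readout_length, gc_min = cfg$readout_gc_min,
    gc_max = cfg$readout_gc_max, max_homology = cfg$readout_max_homology,
    site_len = cfg$readout_site_len, cross_check = cfg$cross_check,
    ortho_k = cfg$ortho_k)
  readouts <- assign_fluorophores(readouts, cfg$channels)
  codebook <- build_codebook(gene_ids, readouts)
  schedule <- schedule_hybridizations(codebook, cfg$channels)
  probes <- assemble_probe_table(design, codebook, readouts, cfg)
  files <- write_outputs(probes, readouts, schedule, cfg, design$counts,
                         out_dir)
  invisible(structure(
    list(design = design, readouts = readouts, codebook = codebook,
         schedule = schedule, probes = probes, files = files),
    class = "fishprobes_run"))
}

#' Validate an emitted probe design
#'
#' Re-reads the artifacts written by \code{\link{run_pipeline}} and
#' re-checks the structural invariants: every probe FASTA record parses
#' under the linker grammar with the configured site and binding lengths,
#' binding sites are pure ACGT of the configured window length, every gene
#' in the design appears in the schedule exactly once, and no two genes
#' share a (round, channel) cell.
#'
#' @param out_dir directory written by \code{run_pipeline}.
#' @return \code{TRUE} invisibly if everything checks out; otherwise an
#'   error describing the first violation.
#' @export
validate_run <- function(out_dir) {
  cfgp <- file.path(out_dir, "config.json")
  fail_if(!file.exists(cfgp), "no config.json in ", out_dir)
  cfg <- jsonlite::read_json(cfgp, simplifyVector = TRUE)
  fa <- file.path(out_dir, "primary_probes.fasta")
  fail_if(!file.exists(fa), "no primary_probes.fasta in ", out_dir)
  seqs <- read_genome_fasta(fa)
  for (nm in names(seqs)) {
    parts <- parse_primary_probe(seqs[[nm]], cfg$readout_site_len,
                                 cfg$window)
    fail_if(nchar(parts$binding_site) != cfg$window,
            "probe ", nm, ": binding site is not ", cfg$window, " nt")
    fail_if(grepl("[^ACGT]", seqs[[nm]]),
            "probe ", nm, ": non-ACGT characters")
  }
  dj <- jsonlite::read_json(file.path(out_dir, "design.json"),
                            simplifyVector = FALSE)
  cells <- vapply(dj, function(e) paste(e$round, e$channel), character(1))
  fail_if(anyDuplicated(cells) > 0L,
          "schedule places two genes in the same round/channel cell")
  probe_genes <- unique(sub("\\|.*$", "", names(seqs)))
  fail_if(!all(probe_genes %in% names(dj)),
          "probe FASTA contains genes absent from design.json")
  invisible(TRUE)
}

#' @export
print.probe_design <- function(x, ...) {
  cat(sprintf("probe design: %d probes across %d gene(s)\n",
              nrow(x$probes), nrow(x$counts)))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

#' @export
summary.probe_design <- function(object, ...) {
  cnt <- object$counts
  cat(sprintf("genes: %d; final probes: %d (mean %.1f/gene)\n",
              nrow(cnt), sum(cnt$final), mean(cnt$final)))
  cat(sprintf("expansion used for %d gene(s); trimming for %d gene(s)\n",
              sum(cnt$expansion_used), sum(cnt$trimmed)))
  if (nrow(object$probes) > 0L)
    cat(sprintf("binding-site GC: %.1f-%.1f%% (median %.1f%%)\n",
                min(object$probes$gc_percent),
                max(object$probes$gc_percent),
                stats::median(object$probes$gc_percent)))
  invisible(object)
}

#' @export
print.fishprobes_run <- function(x, ...) {
  cat(sprintf("fishprobes run: %d probes, %d readouts, %d round(s)\n",
              nrow(x$probes), nrow(x$readouts), x$schedule$n_rounds))
  cat("files:\n")
  for (f in x$files) cat("  ", f, "\n", sep = "")
  invisible(x)
}
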