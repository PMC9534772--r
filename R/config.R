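#' Probe-design configuration
#'
#' Collects every tunable parameter of the design pipeline with defaults
#' matching the published sequential-smFISH protocol: 35-nt binding sites
#' with 45--75% GC, homopolymer runs of 5 or more disallowed, a 15-nt exact
#' off-target match cutoff, expansion into introns/5'UTRs for genes that do
#' not yield more than 40 targets, trimming to at most 40 probes closest to
#' 55% GC, random 20-nt readouts at 45--60% GC screened at >14-nt contiguous
#' homology, 15-nt readout sites embedded in a 141-nt primary probe, and
#' three fluorophore channels.
#'
#' @param window binding-site length, nt.
#' @param gc_min,gc_max inclusive GC bounds for binding-site candidates,
#'   percent.
#' @param max_homopolymer_run longest tolerated run of identical bases; a run
#'   of \code{max_homopolymer_run + 1} disqualifies a candidate.
#' @param offtarget_k exact-match word length for off-target screening, nt.
#'   A shared k-mer with k equal to the match cutoff is equivalent to a
#'   contiguous exact match of at least that length.
#' @param expansion_threshold genes with this many or fewer probes after the
#'   exonic-consensus stage are expanded into introns/5'UTRs (the protocol
#'   requires strictly more than 40 targets).
#' @param max_probes per-gene probe cap after trimming.
#' @param gc_target GC content that trimming preserves probes closest to,
#'   percent.
#' @param readout_length readout probe length, nt.
#' @param readout_gc_min,readout_gc_max inclusive GC bounds for readouts.
#' @param readout_max_homology longest contiguous transcriptome homology a
#'   readout may have; anything longer is rejected.
#' @param readout_site_len length of the readout-site prefix embedded (as
#'   reverse complement) in primary probes. The default 15 together with the
#'   35-nt binding site and AA/TAAT linkers gives the published 141-nt probe.
#' @param channels fluorophore channel labels, in assignment order.
#' @param seed integer seed controlling every random draw.
#' @param intron_reversal_mode how intron sequences enter the off-target
#'   database: \code{"reverse"} (literal string reversal, the default) or
#'   \code{"revcomp"}.
#' @param cross_check also require accepted readouts to be mutually
#'   orthogonal at word length \code{ortho_k}.
#' @param ortho_k word length for readout-vs-readout orthogonality.
#' @param step candidate window step, nt (1 = maximally dense tiling).
#' @return an object of class \code{"design_config"} (a validated list).
#' @export
design_config <- function(window = 35L,
                          gc_min = 45, gc_max = 75,
                          max_homopolymer_run = 4L,
                          offtarget_k = 15L,
                          expansion_threshold = 40L,
                          max_probes = 40L,
                          gc_target = 55,
                          readout_length = 20L,
                          readout_gc_min = 45, readout_gc_max = 60,
                          readout_max_homology = 14L,
                          readout_site_len = 15L,
                          channels = c("AF647", "AF488", "AF546"),
                          seed = 1L,
                          intron_reversal_mode = c("reverse", "revcomp"),
                          cross_check = FALSE,
                          ortho_k = 12L,
                          step = 1L) {
  intron_reversal_mode <- match.arg(intron_reversal_mode)
  cfg <- list(
    window = as.integer(window),
    gc_min = as.numeric(gc_min), gc_max = as.numeric(gc_max),
    max_homopolymer_run = as.integer(max_homopolymer_run),
    offtarget_k = as.integer(offtarget_k),
    expansion_threshold = as.integer(expansion_threshold),
    max_probes = as.integer(max_probes),
    gc_target = as.numeric(gc_target),
    readout_length = as.integer(readout_length),
    readout_gc_min = as.numeric(readout_gc_min),
    readout_gc_max = as.numeric(readout_gc_max),
    readout_max_homology = as.integer(readout_max_homology),
    readout_site_len = as.integer(readout_site_len),
    channels = as.character(channels),
    seed = as.integer(seed),
    intron_reversal_mode = intron_reversal_mode,
    cross_check = isTRUE(cross_check),
    ortho_k = as.integer(ortho_k),
    step = as.integer(step)
  )
  class(cfg) <- "design_config"
  validate_config(cfg)
  cfg
}

#' Validate a design configuration
#'
#' Checks the internal consistency of a \code{\link{design_config}}; errors
#' name the offending field(s).
#'
#' @param cfg a \code{design_config}.
#' @return the config, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  fail_if(!inherits(cfg, "design_config"), "not a design_config object")
  fail_if(cfg$gc_min > cfg$gc_max,
          "invalid config: gc_min (", cfg$gc_min,
          ") exceeds gc_max (", cfg$gc_max, ")")
  fail_if(cfg$gc_target < cfg$gc_min || cfg$gc_target > cfg$gc_max,
          "invalid config: gc_target must lie within [gc_min, gc_max]")
  fail_if(cfg$readout_gc_min > cfg$readout_gc_max,
          "invalid config: readout_gc_min exceeds readout_gc_max")
  for (f in c("window", "offtarget_k", "max_probes", "readout_length",
              "readout_site_len", "step", "ortho_k")) {
    fail_if(cfg[[f]] < 1L, "invalid config: ", f, " must be positive")
  }
  fail_if(cfg$max_homopolymer_run < 1L,
          "invalid config: max_homopolymer_run must be positive")
  fail_if(cfg$readout_site_len > cfg$readout_length,
          "invalid config: readout_site_len exceeds readout_length")
  fail_if(length(cfg$channels) < 1L,
          "invalid config: channels must be non-empty")
  fail_if(cfg$offtarget_k != cfg$readout_max_homology + 1L,
          "invalid config: offtarget_k (", cfg$offtarget_k,
          ") must equal readout_max_homology + 1 (",
          cfg$readout_max_homology + 1L, ")")
  invisible(cfg)
}

#' @export
print.design_config <- function(x, ...) {
  cat("smFISH probe design configuration\n")
  cat(sprintf("  binding site: %d nt, GC %g-%g%%, homopolymer run <= %d\n",
              x$window, x$gc_min, x$gc_max, x$max_homopolymer_run))
  cat(sprintf("  off-target: exact %d-mer match vs mRNA + %s introns\n",
              x$offtarget_k,
              if (x$intron_reversal_mode == "reverse") "reversed"
              else "reverse-complemented"))
  cat(sprintf("  selection: expand if <= %d probes, cap %d, GC target %g%%\n",
              x$expansion_threshold, x$max_probes, x$gc_target))
  cat(sprintf("  readouts: %d nt, GC %g-%g%%, homology <= %d nt, site %d nt\n",
              x$readout_length, x$readout_gc_min, x$readout_gc_max,
              x$readout_max_homology, x$readout_site_len))
  cat(sprintf("  channels: %s; seed %d\n",
              paste(x$channels, collapse = ", "), x$seed))
  invisible(x)
}
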