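#' Tile binding-site candidate windows over target regions
#'
#' Slides a fixed-length window over each target region at the given step
#' and records, per window, the target-sense sequence, the probe-sense
#' binding site (its exact reverse complement) and the GC content. No
#' filtering is applied here; composition filters and off-target screening
#' annotate the table afterwards.
#'
#' @param regions data.frame of target regions
#'   (\code{\link{consensus_exonic_regions}} /
#'   \code{\link{expansion_regions}}).
#' @param window window length, nt.
#' @param step offset between consecutive windows, nt.
#' @return data.frame with one row per candidate: \code{gene_id},
#'   \code{source}, \code{region_start}, \code{region_end}, \code{start}
#'   (1-based offset within the region), \code{target_window},
#'   \code{binding_site}, \code{gc_percent}. Regions shorter than the window
#'   contribute no rows.
#' @export
extract_candidates <- function(regions, window = 35L, step = 1L) {
  fail_if(window < 1L, "window must be >= 1")
  fail_if(step < 1L, "step must be >= 1")
  empty <- data.frame(gene_id = character(0), source = character(0),
                      region_start = integer(0), region_end = integer(0),
                      start = integer(0), target_window = character(0),
                      binding_site = character(0), gc_percent = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(regions) == 0L) return(empty)
  per_region <- lapply(seq_len(nrow(regions)), function(i) {
    s <- regions$sequence[i]
    L <- nchar(s)
    if (L < window) return(empty)
    starts <- seq(1L, L - window + 1L, by = step)
    win <- substring(s, starts, starts + window - 1L)
    # GC via prefix sums over the region: one pass instead of per-window
    # counting.
    isgc <- cumsum(strsplit(s, "", fixed = TRUE)[[1]] %in%
                     c("G", "C", "g", "c"))
    gc <- 100 * (isgc[starts + window - 1L] -
                   c(0L, isgc)[starts]) / window
    data.frame(gene_id = regions$gene_id[i], source = regions$source[i],
               region_start = regions$start[i], region_end = regions$end[i],
               start = starts, target_window = win,
               binding_site = revcomp(win), gc_percent = gc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, per_region)
}

#' GC-content filter
#'
#' Passes candidates whose GC content lies within the inclusive band
#' \code{[gc_min, gc_max]}.
#'
#' @param x candidate data.frame (with a \code{gc_percent} column) or a
#'   numeric vector of GC percentages.
#' @param gc_min,gc_max inclusive bounds, percent.
#' @return logical vector, \code{TRUE} = pass.
#' @export
gc_filter <- function(x, gc_min = 45, gc_max = 75) {
  gc <- if (is.data.frame(x)) x$gc_percent else as.numeric(x)
  gc >= gc_min & gc <= gc_max
}

#' Homopolymer filter
#'
#' Fails any window containing a run of more than \code{max_run} identical
#' bases (default: runs of 5+ fail, runs of 4 pass). Run detection is
#' case-insensitive so soft-masked stretches count toward runs.
#'
#' @param x candidate data.frame (with a \code{target_window} column) or a
#'   character vector of windows.
#' @param max_run longest tolerated run.
#' @return logical vector, \code{TRUE} = pass.
#' @export
homopolymer_filter <- function(x, max_run = 4L) {
  win <- if (is.data.frame(x)) x$target_window else as.character(x)
  pat <- sprintf("([acgt])\\1{%d,}", max_run)
  !grepl(pat, win, perl = TRUE, ignore.case = TRUE)
}

#' Masked/ambiguous-base filter
#'
#' Fails any window containing a base other than uppercase A, C, G, T:
#' lowercase (soft-masked) bases, N, and other IUPAC ambiguity codes all
#' disqualify, since such windows either fall in repeat-masked sequence or
#' are not synthesizable as stated.
#'
#' @param x candidate data.frame or character vector of windows.
#' @return logical vector, \code{TRUE} = pass.
#' @export
mask_filter <- function(x) {
  win <- if (is.data.frame(x)) x$target_window else as.character(x)
  !grepl("[^ACGT]", win)
}

#' Apply all composition filters to a candidate table
#'
#' Annotates the table with per-filter pass columns (\code{pass_gc},
#' \code{pass_homopolymer}, \code{pass_mask}) and their conjunction
#' \code{pass_composition}. The filters are independent predicates, so the
#' surviving set does not depend on application order.
#'
#' @param candidates candidate data.frame from
#'   \code{\link{extract_candidates}}.
#' @param cfg a \code{\link{design_config}}.
#' @return the annotated data.frame.
#' @export
apply_composition_filters <- function(candidates, cfg = design_config()) {
  candidates$pass_gc <- gc_filter(candidates, cfg$gc_min, cfg$gc_max)
  candidates$pass_homopolymer <-
    homopolymer_filter(candidates, cfg$max_homopolymer_run)
  candidates$pass_mask <- mask_filter(candidates)
  candidates$pass_composition <- candidates$pass_gc &
    candidates$pass_homopolymer & candidates$pass_mask
  candidates
}
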