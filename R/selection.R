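#' Resolve overlapping candidates greedily by GC closeness
#'
#' Among filter-passing candidates of one gene, repeatedly accepts the
#' candidate whose GC content is closest to the target (ties: smaller start,
#' then lexicographically smaller window) and discards every candidate whose
#' window overlaps an accepted one within the same target region. The result
#' is a maximal set of non-overlapping probes biased toward the GC target,
#' sorted by region and start, and independent of input row order.
#'
#' @param candidates data.frame of candidates from one gene (all filters
#'   passed).
#' @param gc_target GC content to prefer, percent.
#' @param window window length (inferred from the sequences if omitted).
#' @return the accepted subset, sorted by region then start.
#' @export
resolve_overlaps <- function(candidates, gc_target = 55, window = NULL) {
  n <- nrow(candidates)
  if (n == 0L) return(candidates)
  if (is.null(window)) window <- nchar(candidates$target_window[1])
  region_key <- paste(candidates$gene_id, candidates$source,
                      candidates$region_start)
  dist <- abs(candidates$gc_percent - gc_target)
  ord <- order(dist, candidates$region_start, candidates$start,
               candidates$target_window)
  accepted <- logical(n)
  blocked <- logical(n)
  for (i in ord) {
    if (blocked[i]) next
    accepted[i] <- TRUE
    ov <- region_key == region_key[i] &
      candidates$start < candidates$start[i] + window &
      candidates$start + window > candidates$start[i]
    blocked[ov] <- TRUE
  }
  out <- candidates[accepted, , drop = FALSE]
  out[order(out$region_start, out$start), , drop = FALSE]
}

#' Does a gene need target-space expansion?
#'
#' The protocol expands into introns and 5' UTRs for genes that did not
#' yield enough targets — strictly more than the threshold — from their
#' exonic consensus regions alone. A gene with exactly \code{threshold}
#' probes therefore still expands.
#'
#' @param candidate_count number of probes after all filters and overlap
#'   resolution on exon-consensus regions only.
#' @param threshold the "enough targets" cutoff.
#' @return logical.
#' @export
needs_expansion <- function(candidate_count, threshold = 40L) {
  candidate_count <= threshold
}

#' Trim a probe set to the per-gene maximum
#'
#' While the set exceeds \code{max_probes}, removes the probe whose GC
#' content lies furthest from \code{gc_target}; ties are broken by removing
#' the larger start first (preserving 5'-most probes). The result carries a
#' \code{trimmed} attribute recording whether any probe was removed.
#'
#' @param probes overlap-resolved probe data.frame for one gene.
#' @param max_probes maximum probes to keep.
#' @param gc_target GC content whose neighbourhood is preserved, percent.
#' @return the trimmed data.frame, sorted by region then start, with
#'   attribute \code{"trimmed"}.
#' @export
trim_to_max <- function(probes, max_probes = 40L, gc_target = 55) {
  trimmed <- FALSE
  while (nrow(probes) > max_probes) {
    dist <- abs(probes$gc_percent - gc_target)
    worst <- which(dist == max(dist))
    if (length(worst) > 1L) {
      w <- worst[order(-probes$start[worst], -probes$region_start[worst])]
      worst <- w[1]
    }
    probes <- probes[-worst, , drop = FALSE]
    trimmed <- TRUE
  }
  probes <- probes[order(probes$region_start, probes$start), , drop = FALSE]
  attr(probes, "trimmed") <- trimmed
  probes
}
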