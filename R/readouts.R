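#' Generate transcriptome-orthogonal readout probes
#'
#' Draws random fixed-length sequences uniformly over \{A,C,G,T\} from a
#' seeded stream and accepts each draw iff (a) its GC content lies in the
#' inclusive band, (b) it shares no contiguous exact match longer than
#' \code{max_homology} nt with the indexed transcriptome in either
#' orientation (\code{\link{screen_readout}}), and (c), optionally, it shares
#' no \code{ortho_k}-mer with any previously accepted readout. Rejection
#' sampling continues until \code{n} readouts are accepted or
#' \code{max_attempts} draws are exhausted; the result is deterministic for
#' a fixed seed, configuration and index.
#'
#' @param n number of readouts to generate.
#' @param idx an \code{offtarget_index} (may index nothing; \code{NULL}
#'   skips the transcriptome screen).
#' @param seed integer seed for the draw stream.
#' @param length readout length, nt.
#' @param gc_min,gc_max inclusive GC bounds, percent.
#' @param max_homology longest tolerated contiguous transcriptome homology.
#' @param site_len length of the 5' prefix used as the primary-probe readout
#'   site.
#' @param cross_check require mutual orthogonality between accepted readouts
#'   at word length \code{ortho_k} (off by default).
#' @param ortho_k word length for the mutual-orthogonality check.
#' @param max_attempts draw budget before giving up.
#' @return data.frame: \code{readout_id}, \code{sequence},
#'   \code{gc_percent}, \code{site_sequence}, \code{fluorophore}
#'   (\code{NA} until \code{\link{assign_fluorophores}}).
#' @export
generate_readouts <- function(n, idx = NULL, seed, length = 20L,
                              gc_min = 45, gc_max = 60,
                              max_homology = 14L, site_len = 15L,
                              cross_check = FALSE, ortho_k = 12L,
                              max_attempts = 10000L * n) {
  fail_if(n < 1L, "n must be >= 1")
  fail_if(site_len > length, "site_len exceeds the readout length")
  if (!is.null(idx))
    fail_if(idx$k != max_homology + 1L,
            "off-target index built with k = ", idx$k,
            " but readout screening requires k = ", max_homology + 1L,
            " (configuration error)")
  # Draw from a private RNG state so callers' streams are untouched.
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)

  accepted <- character(0)
  gcs <- numeric(0)
  ortho <- new.env(hash = TRUE, parent = emptyenv())
  attempts <- 0L
  while (length(accepted) < n) {
    if (attempts >= max_attempts) {
      stop("readout generation exhausted ", max_attempts, " attempts with ",
           length(accepted), "/", n, " accepted (acceptance rate ",
           sprintf("%.3f", length(accepted) / attempts), ")", call. = FALSE)
    }
    attempts <- attempts + 1L
    s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
    gc <- gc_percent(s)
    if (gc < gc_min || gc > gc_max) next
    if (!is.null(idx) && !screen_readout(s, idx, max_homology)) next
    if (cross_check) {
      words <- unique(c(kmers_of(s, ortho_k), kmers_of(revcomp(s), ortho_k)))
      if (any(vapply(words, function(w) !is.null(ortho[[w]]), logical(1))))
        next
      for (w in words) ortho[[w]] <- TRUE
    }
    accepted <- c(accepted, s)
    gcs <- c(gcs, gc)
  }
  data.frame(
    readout_id = sprintf("RO%03d", seq_len(n)),
    sequence = accepted,
    gc_percent = gcs,
    site_sequence = substr(accepted, 1L, site_len),
    fluorophore = NA_character_,
    stringsAsFactors = FALSE)
}

#' Assign fluorophores to readouts round-robin
#'
#' Readout \code{i} receives \code{channels[(i - 1) \%\% length(channels) + 1]};
#' the assignment is stable and deterministic.
#'
#' @param readouts data.frame from \code{\link{generate_readouts}}.
#' @param channels character vector of channel labels.
#' @return the readout data.frame with \code{fluorophore} filled in.
#' @export
assign_fluorophores <- function(readouts,
                                channels = c("AF647", "AF488", "AF546")) {
  fail_if(length(channels) < 1L, "channels must be non-empty")
  readouts$fluorophore <-
    channels[(seq_len(nrow(readouts)) - 1L) %% length(channels) + 1L]
  readouts
}
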