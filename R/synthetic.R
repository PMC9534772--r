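#' Specification for a synthetic transcriptome
#'
#' Describes a small seeded transcriptome used to exercise every filter and
#' rule of the design pipeline with analytically known ground truth: genes
#' with multiple isoforms that differ only by skipped internal exons (so the
#' isoform consensus is known by construction), tunable base composition,
#' and planted features — exact substrings shared between gene pairs,
#' homopolymer runs, soft-masked stretches and GC-extreme genes — recorded
#' with exact coordinates in the run manifest.
#'
#' @param seed integer; fixes every random draw.
#' @param n_genes number of genes.
#' @param isoforms_per_gene integer range \code{c(lo, hi)}.
#' @param n_exons integer range for exons per gene.
#' @param exon_length,intron_length integer ranges, nt.
#' @param base_gc mean GC of generated sequence, percent.
#' @param intergenic spacer length between gene blocks, nt.
#' @param plants list of planted features; each element is a list with a
#'   \code{type} of \code{"shared_substring"} (\code{gene_a}, \code{gene_b},
#'   \code{length}, \code{compartment} = \code{"exon"} or \code{"intron"}),
#'   \code{"homopolymer"} (\code{gene}, \code{base}, \code{run_length}),
#'   \code{"softmask"} (\code{gene}, \code{length}) or \code{"gc_extreme"}
#'   (\code{gene}, \code{region_gc}). Gene references are 1-based indices.
#' @return object of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(seed, n_genes = 10L,
                           isoforms_per_gene = c(1L, 3L),
                           n_exons = c(2L, 5L),
                           exon_length = c(150L, 400L),
                           intron_length = c(80L, 200L),
                           base_gc = 50, intergenic = 200L,
                           plants = list()) {
  for (rng in list(isoforms_per_gene, n_exons, exon_length, intron_length)) {
    fail_if(length(rng) != 2L || any(rng < 1L) || rng[1] > rng[2],
            "ranges must be c(lo, hi) with 1 <= lo <= hi")
  }
  fail_if(n_genes < 1L, "n_genes must be >= 1")
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         isoforms_per_gene = as.integer(isoforms_per_gene),
         n_exons = as.integer(n_exons),
         exon_length = as.integer(exon_length),
         intron_length = as.integer(intron_length),
         base_gc = as.numeric(base_gc),
         intergenic = as.integer(intergenic),
         plants = plants),
    class = "synthetic_spec")
}

sample_range <- function(rng, n = 1L) {
  if (rng[1] == rng[2]) rep(rng[1], n)
  else sample(seq(rng[1], rng[2]), n, replace = TRUE)
}

random_seq <- function(n, gc) {
  p <- gc / 100
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
        collapse = "")
}

#' Generate a synthetic transcriptome
#'
#' Materializes a \code{\link{synthetic_spec}} into a genome FASTA, a GTF
#' annotation (exon features) and a JSON manifest recording gene structure
#' and the exact coordinates of every planted feature. Isoform 1 of each
#' gene carries all exons; each additional isoform skips one distinct
#' internal exon, so the isoform-consensus exons are exactly those skipped
#' by no isoform. Deterministic per seed, byte for byte.
#'
#' @param spec a \code{synthetic_spec}.
#' @param dir output directory (created if needed).
#' @return invisible list: \code{fasta}, \code{gtf}, \code{manifest}
#'   (paths), \code{manifest_data} (the parsed manifest structure).
#' @export
generate_transcriptome <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(spec$seed)

  gc_override <- rep(NA_real_, spec$n_genes)
  for (p in spec$plants) {
    if (identical(p$type, "gc_extreme")) gc_override[p$gene] <- p$region_gc
  }

  chrom_parts <- character(0)
  offset <- 0L
  genes <- list()
  for (i in seq_len(spec$n_genes)) {
    gid <- sprintf("g%02d", i)
    n_iso <- sample_range(spec$isoforms_per_gene)
    min_ex <- if (n_iso > 1L) n_iso + 1L else spec$n_exons[1]
    n_ex <- max(sample_range(spec$n_exons), min_ex)
    ex_len <- sample_range(spec$exon_length, n_ex)
    in_len <- if (n_ex > 1L) sample_range(spec$intron_length, n_ex - 1L)
              else integer(0)
    gc <- if (is.na(gc_override[i])) spec$base_gc else gc_override[i]
    strand <- sample(c("+", "-"), 1L)

    spacer <- random_seq(spec$intergenic, spec$base_gc)
    chrom_parts <- c(chrom_parts, spacer)
    offset <- offset + spec$intergenic

    block_start <- offset + 1L
    exon_coords <- matrix(0L, nrow = n_ex, ncol = 2L)
    block_parts <- character(0)
    pos <- offset
    for (e in seq_len(n_ex)) {
      exon_coords[e, ] <- c(pos + 1L, pos + ex_len[e])
      block_parts <- c(block_parts, random_seq(ex_len[e], gc))
      pos <- pos + ex_len[e]
      if (e < n_ex) {
        block_parts <- c(block_parts, random_seq(in_len[e], gc))
        pos <- pos + in_len[e]
      }
    }
    chrom_parts <- c(chrom_parts, block_parts)
    offset <- pos

    internal <- seq(2L, n_ex - 1L)
    skipped <- if (n_iso > 1L)
      sort(internal[sample.int(length(internal), n_iso - 1L)])
    else integer(0)
    isoforms <- list()
    isoforms[[paste0(gid, ".t1")]] <- seq_len(n_ex)
    if (n_iso > 1L) {
      for (j in seq_len(n_iso - 1L)) {
        isoforms[[sprintf("%s.t%d", gid, j + 1L)]] <-
          setdiff(seq_len(n_ex), skipped[j])
      }
    }
    genes[[gid]] <- list(
      gene_id = gid, strand = strand, block = c(block_start, offset),
      exons = exon_coords, isoforms = isoforms,
      consensus_exons = setdiff(seq_len(n_ex), skipped))
  }
  chrom_parts <- c(chrom_parts, random_seq(spec$intergenic, spec$base_gc))
  chrom <- paste(chrom_parts, collapse = "")

  # -- planted features ------------------------------------------------
  used <- list()  # per-gene list of planted reference intervals
  reserve <- function(gid, lo, hi) {
    iv <- used[[gid]]
    if (!is.null(iv)) {
      for (u in iv) if (lo <= u[2] && hi >= u[1]) return(FALSE)
    }
    used[[gid]] <<- c(iv, list(c(lo, hi)))
    TRUE
  }
  pick_site <- function(gid, intervals, len, what) {
    wide <- intervals[intervals[, 2] - intervals[, 1] + 1L >= len, ,
                      drop = FALSE]
    fail_if(nrow(wide) == 0L, "infeasible plant: ", what, " of length ",
            len, " does not fit any eligible interval of ", gid)
    for (try in seq_len(200L)) {
      r <- wide[sample(nrow(wide), 1L), ]
      lo <- r[1] + sample(r[2] - r[1] + 2L - len, 1L) - 1L
      if (reserve(gid, lo, lo + len - 1L)) return(lo)
    }
    stop("infeasible plant: could not place ", what, " in ", gid,
         " without overlapping other plants", call. = FALSE)
  }
  cons_intervals <- function(g) {
    g$exons[g$consensus_exons, , drop = FALSE]
  }
  intron_intervals <- function(g) {
    n_ex <- nrow(g$exons)
    if (n_ex < 2L) return(matrix(0L, 0L, 2L))
    cbind(g$exons[-n_ex, 2] + 1L, g$exons[-1L, 1] - 1L)
  }
  plant_records <- list()
  for (p in spec$plants) {
    if (identical(p$type, "gc_extreme")) {
      plant_records[[length(plant_records) + 1L]] <-
        list(type = "gc_extreme", gene = genes[[p$gene]]$gene_id,
             region_gc = p$region_gc)
    } else if (identical(p$type, "homopolymer")) {
      g <- genes[[p$gene]]
      lo <- pick_site(g$gene_id, cons_intervals(g), p$run_length,
                      "homopolymer")
      substr(chrom, lo, lo + p$run_length - 1L) <-
        strrep(p$base, p$run_length)
      plant_records[[length(plant_records) + 1L]] <-
        list(type = "homopolymer", gene = g$gene_id, base = p$base,
             run_length = p$run_length, start = lo,
             end = lo + p$run_length - 1L)
    } else if (identical(p$type, "softmask")) {
      g <- genes[[p$gene]]
      lo <- pick_site(g$gene_id, cons_intervals(g), p$length, "softmask")
      substr(chrom, lo, lo + p$length - 1L) <-
        tolower(substr(chrom, lo, lo + p$length - 1L))
      plant_records[[length(plant_records) + 1L]] <-
        list(type = "softmask", gene = g$gene_id, length = p$length,
             start = lo, end = lo + p$length - 1L)
    } else if (identical(p$type, "shared_substring")) {
      ga <- genes[[p$gene_a]]; gb <- genes[[p$gene_b]]
      comp <- if (is.null(p$compartment)) "exon" else p$compartment
      ivs_a <- if (comp == "exon") cons_intervals(ga)
               else intron_intervals(ga)
      ivs_b <- if (comp == "exon") cons_intervals(gb)
               else intron_intervals(gb)
      plant_seq <- random_seq(p$length, 55)
      lo_a <- pick_site(ga$gene_id, ivs_a, p$length, "shared substring")
      lo_b <- pick_site(gb$gene_id, ivs_b, p$length, "shared substring")
      substr(chrom, lo_a, lo_a + p$length - 1L) <- plant_seq
      substr(chrom, lo_b, lo_b + p$length - 1L) <- plant_seq
      # the planted length must be the true shared length: where the two
      # loci's flanking bases happen to coincide, retype the copy-b flank
      # so the exact match cannot extend beyond the plant
      for (fl in list(c(lo_a - 1L, lo_b - 1L),
                      c(lo_a + p$length, lo_b + p$length))) {
        if (all(fl >= 1L) && all(fl <= nchar(chrom)) &&
              substr(chrom, fl[1], fl[1]) == substr(chrom, fl[2], fl[2])) {
          substr(chrom, fl[2], fl[2]) <-
            setdiff(c("A", "C", "G", "T"),
                    toupper(substr(chrom, fl[1], fl[1])))[1]
        }
      }
      plant_records[[length(plant_records) + 1L]] <-
        list(type = "shared_substring", gene_a = ga$gene_id,
             gene_b = gb$gene_id, length = p$length, compartment = comp,
             sequence = plant_seq,
             start_a = lo_a, end_a = lo_a + p$length - 1L,
             start_b = lo_b, end_b = lo_b + p$length - 1L)
    } else {
      stop("unknown plant type: ", p$type, call. = FALSE)
    }
  }

  # -- write artifacts -------------------------------------------------
  fasta <- file.path(dir, "genome.fa")
  write_fasta(list(chrS = chrom), fasta)

  gtf_lines <- character(0)
  for (g in genes) {
    for (tx in names(g$isoforms)) {
      for (e in g$isoforms[[tx]]) {
        gtf_lines <- c(gtf_lines, sprintf(
          "chrS\tfishprobes_synth\texon\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\";",
          g$exons[e, 1], g$exons[e, 2], g$strand, g$gene_id, tx))
      }
    }
  }
  gtf <- file.path(dir, "annotation.gtf")
  writeLines(gtf_lines, gtf)

  manifest_data <- list(
    seed = spec$seed,
    parameters = unclass(spec)[setdiff(names(unclass(spec)), "plants")],
    reference_name = "chrS", reference_length = nchar(chrom),
    genes = lapply(genes, function(g) {
      list(gene_id = g$gene_id, strand = g$strand, block = g$block,
           exons = lapply(seq_len(nrow(g$exons)),
                          function(e) g$exons[e, ]),
           isoforms = g$isoforms,
           consensus_exons = g$consensus_exons)
    }),
    plants = plant_records)
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest_data, manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(fasta = fasta, gtf = gtf, manifest = manifest,
                 manifest_data = manifest_data))
}

#' Brute-force expected final probe counts
#'
#' Independent oracle for end-to-end tests: recomputes, from the generated
#' FASTA and manifest alone, the expected final probe count per gene by
#' full window enumeration, naive per-base consensus computation, exact
#' substring search for off-target matches (\code{grepl} over the other
#' genes' database sequences rather than a k-mer index), and literal
#' simulation of the greedy overlap, expansion and trimming rules.
#'
#' @param tx result of \code{\link{generate_transcriptome}} (or a directory
#'   containing its outputs).
#' @param cfg a \code{\link{design_config}}.
#' @return data.frame: \code{gene_id}, \code{expected}.
#' @export
expected_survivors <- function(tx, cfg = design_config()) {
  if (is.character(tx)) {
    tx <- list(fasta = file.path(tx, "genome.fa"),
               manifest = file.path(tx, "manifest.json"))
  }
  chrom <- read_genome_fasta(tx$fasta)[[1]]
  man <- jsonlite::read_json(tx$manifest, simplifyVector = FALSE)
  genes <- man$genes

  exon_mat <- function(g) {
    do.call(rbind, lapply(g$exons, function(e) unlist(e)))
  }
  # per-base consensus of isoform exon coverage -> maximal run intervals
  consensus_ivs <- function(g) {
    ex <- exon_mat(g)
    span <- c(min(ex[, 1]), max(ex[, 2]))
    n <- span[2] - span[1] + 1L
    cov <- rep(TRUE, n)
    for (iso in g$isoforms) {
      v <- rep(FALSE, n)
      for (e in unlist(iso)) {
        v[(ex[e, 1]:ex[e, 2]) - span[1] + 1L] <- TRUE
      }
      cov <- cov & v
    }
    runs_to_ivs(cov, span[1])
  }
  intron_ivs <- function(g) {
    ex <- exon_mat(g)
    span <- c(min(ex[, 1]), max(ex[, 2]))
    n <- span[2] - span[1] + 1L
    gap <- rep(FALSE, n)
    for (iso in g$isoforms) {
      idx <- unlist(iso)
      v <- rep(TRUE, n)
      lo <- min(ex[idx, 1]); hi <- max(ex[idx, 2])
      v[seq_len(n) + span[1] - 1L < lo] <- FALSE
      v[seq_len(n) + span[1] - 1L > hi] <- FALSE
      for (e in idx) v[(ex[e, 1]:ex[e, 2]) - span[1] + 1L] <- FALSE
      gap <- gap | v
    }
    runs_to_ivs(gap, span[1])
  }
  runs_to_ivs <- function(v, base) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values] + base - 1L, ends[r$values] + base - 1L)
  }
  region_seq <- function(iv, strand) {
    s <- substr(chrom, iv[1], iv[2])
    if (strand == "-") revcomp(s) else s
  }
  mrna_of <- function(g, iso) {
    ex <- exon_mat(g)
    s <- paste(vapply(unlist(iso), function(e)
      substr(chrom, ex[e, 1], ex[e, 2]), character(1)), collapse = "")
    if (g$strand == "-") revcomp(s) else s
  }

  # off-target database per gene: spliced mRNAs + reversed introns
  db_of <- function(g) {
    mr <- vapply(g$isoforms, function(iso) mrna_of(g, iso), character(1))
    iv <- intron_ivs(g)
    intr <- if (nrow(iv) > 0L)
      vapply(seq_len(nrow(iv)), function(i) {
        s <- region_seq(iv[i, ], g$strand)
        if (cfg$intron_reversal_mode == "revcomp") revcomp(s)
        else paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
      }, character(1)) else character(0)
    toupper(c(mr, intr))
  }
  dbs <- lapply(genes, db_of)
  names(dbs) <- vapply(genes, `[[`, character(1), "gene_id")

  k <- cfg$offtarget_k
  w <- cfg$window
  out <- data.frame(gene_id = character(0), expected = integer(0),
                    stringsAsFactors = FALSE)
  for (g in genes) {
    others <- paste(unlist(dbs[setdiff(names(dbs), g$gene_id)]),
                    collapse = "#")
    memo <- new.env(hash = TRUE, parent = emptyenv())
    km_hit <- function(km) {
      v <- memo[[km]]
      if (is.null(v)) {
        v <- grepl(km, others, fixed = TRUE) ||
          grepl(revcomp(km), others, fixed = TRUE)
        memo[[km]] <- v
      }
      v
    }
    survivors_in <- function(ivs) {
      rows <- list()
      if (nrow(ivs) > 0L) for (i in seq_len(nrow(ivs))) {
        s <- region_seq(ivs[i, ], g$strand)
        L <- nchar(s)
        if (L < w) next
        for (st in seq(1L, L - w + 1L, by = cfg$step)) {
          win <- substr(s, st, st + w - 1L)
          ch <- strsplit(win, "", fixed = TRUE)[[1]]
          if (any(!ch %in% c("A", "C", "G", "T"))) next
          gc <- 100 * sum(ch %in% c("G", "C")) / w
          if (gc < cfg$gc_min || gc > cfg$gc_max) next
          if (max(rle(ch)$lengths) > cfg$max_homopolymer_run) next
          bad <- FALSE
          for (p in seq_len(w - k + 1L)) {
            if (km_hit(substr(win, p, p + k - 1L))) { bad <- TRUE; break }
          }
          if (bad) next
          rows[[length(rows) + 1L]] <-
            list(region_start = ivs[i, 1], start = st, win = win, gc = gc)
        }
      }
      rows
    }
    greedy <- function(rows) {
      picked <- list()
      while (length(rows) > 0L) {
        dist <- vapply(rows, function(r) abs(r$gc - cfg$gc_target),
                       numeric(1))
        rs <- vapply(rows, function(r) r$region_start, numeric(1))
        st <- vapply(rows, function(r) r$start, numeric(1))
        wn <- vapply(rows, function(r) r$win, character(1))
        best <- order(dist, rs, st, wn)[1]
        b <- rows[[best]]
        picked[[length(picked) + 1L]] <- b
        keep <- vapply(rows, function(r) {
          !(r$region_start == b$region_start &&
              r$start < b$start + w && r$start + w > b$start)
        }, logical(1))
        rows <- rows[keep]
      }
      picked
    }
    probes <- greedy(survivors_in(consensus_ivs(g)))
    if (length(probes) <= cfg$expansion_threshold) {
      probes <- c(probes, greedy(survivors_in(intron_ivs(g))))
    }
    while (length(probes) > cfg$max_probes) {
      dist <- vapply(probes, function(r) abs(r$gc - cfg$gc_target),
                     numeric(1))
      worst <- which(dist == max(dist))
      if (length(worst) > 1L) {
        st <- vapply(probes[worst], function(r) r$start, numeric(1))
        rs <- vapply(probes[worst], function(r) r$region_start, numeric(1))
        worst <- worst[order(-st, -rs)][1]
      }
      probes <- probes[-worst]
    }
    out <- rbind(out, data.frame(gene_id = g$gene_id,
                                 expected = length(probes),
                                 stringsAsFactors = FALSE))
  }
  out
}
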