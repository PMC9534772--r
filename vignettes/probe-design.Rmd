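---
title: "Designing sequential smFISH probe sets with fishprobes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sequential smFISH probe sets with fishprobes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishprobes)
```

## The design problem

Sequential single-molecule FISH reads out one set of genes per
hybridization round: long *primary probes* tile each target mRNA and
present single-stranded overhangs, and short fluorophore-conjugated
*readout probes* bind those overhangs, are imaged, stripped, and exchanged
for the next round's readouts. The computational task is to turn gene
models into an orderable oligo pool: for each gene, a set of up to 40
specific 35-nt binding sites; a panel of orthogonal 20-nt readouts; and
the assembled 141-nt primary probes with their round/channel schedule.

`fishprobes` implements this as a deterministic pipeline:

1. **Target regions.** Probes are placed in the *isoform consensus* —
   the per-base intersection of exon coverage across all annotated
   isoforms — so every probe detects every splice form. Where the
   annotation is ambiguous about what "consensus" means, intersection is
   the strictest reading and the one we adopt: it can only lose targets,
   never mis-target an isoform. Genes that do not yield strictly more
   than 40 probes from consensus exons are expanded into intronic
   sequence (the union of per-isoform exon gaps) and, when annotated,
   the 5' UTR. UTRs are accepted only from explicit `five_prime_utr`
   features: they cannot be inferred from exon lines alone.
2. **Candidate windows.** A 35-nt window slides at step 1 (maximally
   dense tiling; spacing is resolved later) over each target region.
   Each window must have 45–75% GC (inclusive at both bounds), no run of
   5 or more identical bases (case-insensitive), and no base other than
   uppercase A/C/G/T — lowercase soft-masked stretches, N, and IUPAC
   ambiguity codes all disqualify a window, which emulates design on a
   repeat-masked genome without destroying the input sequence.
3. **Off-target screening.** The off-target database holds every spliced
   mRNA plus every intron sequence *reversed* (literal string reversal by
   default, switchable to reverse complement via
   `intron_reversal_mode`). A candidate is dropped if it shares any
   exact 15-mer, in either orientation, with a sequence owned by another
   gene. Sharing a 15-mer is exactly equivalent to sharing a contiguous
   exact match of ≥ 15 nt, so the word-lookup implements the stated
   match-length cutoff deterministically; near-matches below 100%
   identity that a local aligner might additionally flag are out of
   scope. All isoforms of the target gene itself are exempt.
4. **Selection.** Overlaps among surviving candidates are resolved
   greedily: repeatedly accept the candidate closest to 55% GC (ties:
   smaller start, then lexicographically smaller window) and discard
   everything overlapping it. The protocol does not state a spacing
   rule; this greedy rule is our construction, chosen because it is
   deterministic, independent of input order, and biases the set toward
   the stated 55% GC optimum. Probe sets larger than 40 are then trimmed
   by repeatedly removing the probe farthest from 55% GC, ties removing
   the larger start first so 5'-most probes survive. Expansion probes
   are only ever appended after consensus probes; they never displace
   them. Trimming happens last, after any expansion.
5. **Readouts and assembly.** Readouts are drawn uniformly over
   {A,C,G,T}^20 by seeded rejection sampling and accepted at 45–60% GC
   if they share no contiguous match longer than 14 nt with the indexed
   transcriptome in either orientation (no own-gene exemption — readouts
   must be orthogonal to everything). A hard attempt cap converts a
   mis-specified configuration into a clear error, reporting the
   acceptance rate, instead of an endless loop. Primary probes follow
   the linker grammar

   ```
   R'-AA-R'-AA-R'-TAAT-[binding site]-TAAT-R'-AA-R'-AA-R'
   ```

   where each `R'` is the reverse complement of a readout site, so the
   total length is `6 * site_len + 16 + 35`. With full 20-nt readout
   sites this grammar gives 171 nt, which contradicts the published
   141-nt total; embedding the 15-nt 5' prefix of each readout
   reconciles the arithmetic exactly (`6*15 + 16 + 35 = 141`), so
   `readout_site_len = 15` is the default and the site length is
   configurable. In sequential mode all six slots carry the same
   readout, amplifying one gene's signal per probe.
6. **Scheduling.** Each gene maps to one readout (injective, in input
   order); readouts get fluorophores round-robin over the channel set
   (AF647, AF488, AF546 by default); genes are imaged in their readout's
   channel at that channel's next free round. With `G` genes and `C`
   channels this fills `ceiling(G/C)` rounds — e.g. 33 genes on 3
   channels need 11 rounds.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `window` | 35 nt | binding-site length |
| `gc_min`, `gc_max` | 45, 75 % | inclusive candidate GC band |
| `max_homopolymer_run` | 4 | runs of 5+ identical bases fail |
| `offtarget_k` | 15 nt | exact-match cutoff vs other genes |
| `expansion_threshold` | 40 | expand unless > 40 consensus probes |
| `max_probes` | 40 | per-gene cap after trimming |
| `gc_target` | 55 % | GC preserved by overlap resolution and trimming |
| `readout_length` | 20 nt | readout probe length |
| `readout_gc_min/max` | 45, 60 % | readout GC band |
| `readout_max_homology` | 14 nt | longest tolerated transcriptome match |
| `readout_site_len` | 15 nt | readout prefix embedded in primaries |

`validate_config()` enforces the internal couplings, most importantly
`offtarget_k == readout_max_homology + 1`: the k-mer index implements
"longer than 14 nt fails" only when its word length is 15.

## The synthetic study system

`synthetic_spec()` / `generate_transcriptome()` build a small seeded
transcriptome in which every rule has computable ground truth:

- Isoforms differ only by skipped internal exons, so the consensus exons
  are known exactly at generation time and recorded in the manifest.
- Planted features — shared substrings between gene pairs, homopolymer
  runs, soft-masked stretches, GC-extreme genes — are embedded at
  manifest-recorded coordinates. For shared substrings the generator
  additionally retypes any flanking base that happens to coincide
  between the two loci, so the planted length *is* the true maximal
  shared length; without this, roughly 44% of plants would extend by
  chance and the manifest would misstate the ground truth.
- The default scale is 10 genes of roughly 2 kb (a few tens of kb of
  genome), chosen so that a full design plus the brute-force oracle run
  in a few seconds; end-to-end validation uses 20 such transcriptomes.

`expected_survivors()` is the independent oracle: it recomputes final
per-gene probe counts from the FASTA and manifest alone, using per-base
coverage vectors for the consensus, full window enumeration, character
counting for GC, run-length encoding for homopolymers, fixed-string
search (`grepl`) over the other genes' database sequences for
off-target matches, and literal simulation of the greedy selection and
trimming loops. The pipeline must match it exactly, per gene, on every
generated transcriptome.

What the generator does *not* emulate: realistic repeat families (its
soft-masking is a planted block, not RepeatMasker output), alternative
transcription starts/ends, expression levels, and sequencing-scale
genomes. Passing tests therefore demonstrate that the rules are
implemented exactly as stated, not that probe yields on a real
mammalian transcriptome will match any particular distribution.

## Numerical and degenerate-input choices

- Intervals are 1-based closed (`IRanges`) throughout, with GTF input
  mapping directly; candidate `start` offsets are 1-based within their
  region. GC values are exact rationals of the form `100*k/35` compared
  with `>=`/`<=`, so the inclusive bounds are exact at the boundary.
- Empty consensus (isoforms sharing no exonic base) is an empty result,
  not an error; regions shorter than the window yield no candidates; a
  fully masked gene legitimately finalizes at 0 probes, with a warning
  in the run log when a whole design is empty.
- Strand "−" sequences are stored mRNA-sense at extraction so all
  downstream windowing is strand-agnostic; soft-mask case survives the
  reverse complement.
- All tie-breaks (overlap resolution, trimming) are documented fixed
  rules, so identical inputs and configuration reproduce outputs byte
  for byte; no timestamps enter any output file.
- k-mers containing non-ACGT characters are never indexed and never
  queried; masked or ambiguous windows are already rejected upstream.

## A worked example

```{r example, eval = FALSE}
spec <- synthetic_spec(seed = 42, n_genes = 4,
  plants = list(list(type = "shared_substring", gene_a = 1, gene_b = 2,
                     length = 18, compartment = "exon")))
tx <- generate_transcriptome(spec, "tx")
run <- run_pipeline(tx$gtf, tx$fasta, "design_out",
                    design_config(seed = 7))
summary(run$design)
validate_run("design_out")
expected_survivors(tx)  # brute-force cross-check of run$design$counts
```

## Known limitations

- Off-target rejection is exact-match only; thermodynamic models (Tm,
  secondary structure, hybridization energy) are deliberately absent,
  matching the protocol being reproduced.
- Readout reuse across rounds is not implemented: panels need at least
  as many readouts as genes.
- Whether "reversed introns" in the original database meant literal
  reversal or reverse complement is not decidable from the protocol
  text; both are supported and literal reversal is the default.
- The GTF reader covers the exon/`five_prime_utr` subset the pipeline
  needs, not the full GTF specification.
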