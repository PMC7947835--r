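# mitoaudit

Codon-aware auditing of mitochondrial initiation codons and gene-order
conservation for metazoan mitogenomes.

## The problem

Metazoan mitochondrial genomes carry 13 protein-coding genes (PCGs), 2
rRNAs and 22 tRNAs on a compact circle, translated under lineage-specific
genetic codes (NCBI translation tables: 1 standard, 5 invertebrate
mitochondrial, 9 echinoderm/flatworm mitochondrial). Annotation pipelines
frequently misplace CDS 5′ boundaries, because mitochondrial initiation is
not restricted to ATG: table 5 admits six initiation codons, and in
echinoderms comparative evidence supports ATT, ATC and possibly TTG beyond
the accepted ATG/GTG pair. A start codon placed one codon off silently
corrupts every downstream alignment and phylogenetic matrix built from the
gene.

`mitoaudit` formalizes the comparative curation that careful mitogenome
studies perform by eye:

* **Genetic codes** — full 64-codon definitions of tables 1/5/9 with their
  initiation-codon sets, plus an *extended* echinoderm start set
  `{ATT, ATC, TTG}` for audit use (ATA is deliberately excluded, so
  ATA-initiated annotations remain correction targets).
* **I/O** — GenBank flat files (read/write, circular coordinates,
  origin-spanning `join()` locations, partial markers) and FASTA+GFF3;
  gene-name normalization across annotation conventions (COX1 = COI,
  NAD1 = ND1, rrnL = 16S, ...).
* **Ortholog extraction** — per-gene cross-taxon sets; duplicate and
  partial-copy resolution; pooling of conspecific records into one
  terminal.
* **The codon audit** — per gene: translate annotated CDSs, build a
  center-star protein alignment (Needleman–Wunsch–Gotoh pairwise steps,
  BLOSUM62, affine gaps), measure each taxon's 5′ offset against the
  cohort consensus, scan a ±`window` codon neighborhood of the annotated
  start for in-frame, stop-free candidates, and call each annotation
  `confirmed`, `corrected` (with a signed codon shift), `novel_candidate`
  (an unrecognized codon sitting exactly at the consensus offset) or
  `unresolved`. `audit_cohort()` iterates audit → apply corrections →
  re-audit, which untangles neighboring misannotations that block each
  other's candidate scans.
* **Gene order** — arrangements as normalized signed circular
  permutations; breakpoint distances, maximal conserved blocks, and
  detection of a single two-block interchange (the kind of minimal
  rearrangement that separates deeply diverged echinoderm classes).
* **Simulator** — circular mitogenomes with the full 37-gene complement,
  planted start codons, strands, spacers and ground-truth sidecars, plus
  perturbation operators (annotation shifts, block transposition /
  inversion / interchange), so the whole pipeline is testable offline.

## Worked example

Simulate a 6-taxon cohort from one ancestral genome (5% divergence),
misannotate a quarter of the PCG start coordinates by ±1–2 codons, then
audit:

```r
library(mitoaudit)

spec    <- genome_spec(seed = 7)      # 37-gene circular mitogenome blueprint
cohort  <- simulate_cohort(spec, n_taxa = 6, divergence = 0.05, seed = 7)
cohort  <- perturb_annotations(cohort, shift_fraction = 0.25,
                               shift_range = 2, seed = 7)
records <- lapply(cohort, `[[`, "record")
records[[1]]
#> <mitogenome_record> synthotaxon_01 SYN000001: 15777 nt (circular), 37 features
#>    PCG: 13, rRNA: 2, tRNA: 22

calls <- audit_cohort(records, get_table(9, extended = TRUE))
table(calls$verdict)
#> confirmed corrected
#>        58        20
```

All 20 perturbed annotations come back `corrected`, each with the signed
shift (in codons, downstream positive) that restores the planted start:

```r
subset(calls, verdict == "corrected",
       select = c(taxon, gene_label, annotated_codon, shift_codons, final_codon))
#>             taxon gene_label annotated_codon shift_codons final_codon
#> 1  synthotaxon_01        ND1             GAA           -2         ATG
#> 4  synthotaxon_04        ND1             ATG           -1         ATG
#> 44 synthotaxon_02        ND3             TTT           -2         ATT
#> 50 synthotaxon_02       ND4L             GAG           -2         ATC
#> ...
```

Row 4 is the instructive case: the misannotated CDS happens to *begin*
with ATG, but its translation is one codon short against the cohort
alignment, so positional evidence still moves the boundary. The usage
matrix recovers the planted codons — ATG everywhere except ND3 (ATT) and
ND4L (ATC), the two genes where alternative initiation is characteristic:

```r
codon_usage(calls)
#> <codon_usage_matrix> 6 taxa x 13 genes
#>   ND1   ATG:6
#>   ...
#>   ND3   ATT:6
#>   ND4L  ATC:6
```

Gene orders are identical across the cohort, as simulated:

```r
orders <- lapply(records, order_from_record)
format_gene_order(orders[[1]])
#> "+COI +ND4L +COII +ATP8 +ATP6 +COIII +ND3 +ND4 +ND5 -ND6 +CYTB +12S +16S +ND1 +ND2"
max(order_distance_matrix(orders))
#> 0
```

`detect_interchange()` names the swapped blocks when two arrangements
differ by exactly one two-block interchange, e.g. the ND1 ↔ 16S swap:
`apply_rearrangement(spec, "interchange", list(block1 = "ND1", block2 = "16S"))`
yields an order at breakpoint distance 3 from the original, and the
detector reports `(ND1, 16S)`.

A thin command-line wrapper lives at `inst/scripts/mitoaudit.R`
(`simulate`, `perturb`, `audit` subcommands); see the methods vignette
(`vignettes/start-codon-audit.Rmd`) for the model, parameter and design
discussion.

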