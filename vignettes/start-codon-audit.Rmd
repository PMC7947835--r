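---
title: "Auditing mitochondrial initiation codons by comparative alignment"
author: "mitoaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing mitochondrial initiation codons by comparative alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoaudit)
```

## The scientific setting

Metazoan mitochondria translate their 13 protein-coding genes (PCGs) under
genetic codes that deviate from the standard code, and the deviations are
concentrated where annotation errors hurt most: the initiation codon. The
invertebrate mitochondrial code (NCBI table 5) accepts six initiation
codons; the echinoderm/flatworm code (table 9) officially accepts only ATG
and GTG, yet comparative evidence in asteroid mitogenomes supports ATT and
ATC as genuine starts (most prominently in ND3 and ND4L) and TTG as a
provisional fourth candidate. Annotation software regularly either forces
an ATG where none initiates — shifting the CDS boundary by a few codons —
or takes an alternative codon at face value when the true start is the
standard ATG a codon away.

The reliable way to arbitrate is comparative: align each gene's
translation across many taxa and ask whether a sequence is in frame and
flush with its relatives at the 5′ end. Published studies do this by
visual inspection. `mitoaudit` encodes that inspection as a deterministic,
testable procedure.

## The audit model

For one gene across $n$ taxa, let $s_i$ be the annotated CDS of taxon $i$
and $a_i$ its translation under the chosen table. The audit:

1. **Aligns** $\{a_i\}$ with a center-star multiple alignment: the center
   is the member maximizing the summed pairwise global alignment scores
   (Needleman–Wunsch–Gotoh, BLOSUM62, gap open 10 / extend 1), and the
   pairwise alignments are merged under *once a gap, always a gap*.
   Mitochondrial PCGs are short (55–615 codons) and highly conserved, so
   this desk-scale heuristic is fully adequate; determinism comes from
   sorting members by taxon first and breaking center ties toward the
   alphabetically first taxon.
2. **Measures 5′ offsets.** Each row's offset (in codons; positive = the
   row starts downstream of the cohort, i.e. a shorter 5′ end) is read at
   an *anchor column*: the first sustained run (10 columns, or the longest
   available) of alignment columns in which every row has a residue. The
   modal residue count reaching the anchor, with ties toward the longer 5′
   end, defines the consensus. The naive alternative — each row's first
   non-gap column — is biased: under realistic divergence the optimizer
   sometimes pays a mismatch to align the first residue of a shifted
   sequence and opens its gap one column later, which silently zeroes the
   offset. Reading codon counts at a fully-occupied anchor column is
   immune to this gap-placement wobble. The modal first non-gap column is
   still reported as `consensus_start_col` for display.
3. **Enumerates candidates.** In-frame codons at shifts
   $s \in [-w, +w]$ from the annotated start ($w$ = `window`, default 5
   codons). Upstream candidates are retrieved with circular wrap;
   candidates are discarded if the codon is a stop, the resulting ORF
   contains an internal stop, or the upstream extension crosses another
   annotated PCG/rRNA/tRNA feature. On linear (partial) records the
   window is clipped at the contig edge and noted.
4. **Calls a verdict.** A *recognized* start is any member of the table's
   canonical or extended start sets. Because the offset fixes a unique
   shift, at most one candidate attains consensus offset 0:
   * a recognized start at offset 0 → `confirmed` (if it is the annotated
     position) or `corrected` (with the signed shift onto it);
   * otherwise, if the *annotated* codon itself sits at offset 0 but is
     not recognized → `novel_candidate` when `allow_novel` is set (the
     audit flags, never asserts, novel codons — and never proposes
     *moving* a boundary onto an unrecognized codon, so an upstream
     non-start codon such as AAT can never be nominated);
   * otherwise, if the annotated codon is recognized but no start attains
     offset 0 (a gene genuinely shorter at the 5′ end, e.g. one codon
     short relative to the cohort) → `confirmed`, with the offset noted;
   * otherwise → `unresolved`.

   Among several recognized candidates the fixed preference
   ATG > GTG > ATT > ATC > TTG and then the smaller |shift| break ties;
   with offset-0 uniqueness these keys are rarely exercised, but they make
   the procedure total and deterministic.

### Why the audit iterates

`audit_cohort()` applies all `corrected` calls and re-audits until a pass
proposes nothing (bounded by `max_passes = 3`). One pass is insufficient
in exactly one geometry: two genes whose 5′ ends face each other across a
short spacer (typical for a minus-strand gene followed by a plus-strand
gene), where one annotation was extended across the neighbor's true start
while the neighbor's was shifted downstream. The neighbor's upstream scan
is then blocked by the inflated annotation and its call is `unresolved`;
after the first pass corrects the blocker, the second pass recovers the
neighbor. The facing-ends geometry cannot deadlock mutually (two
downstream-shifted annotations retreat from their shared junction, each
freeing the other's scan path), so two passes settle it; the third is
margin. Calls are always reported against the *original* annotations with
cumulative shifts, and a re-audit of fully corrected records confirms
everything (idempotence, asserted in the tests).

### The extended start set

`get_table(9, extended = TRUE)` attaches `{ATT, ATC, TTG}` to table 9 as
audit-recognized starts. ATA is deliberately excluded: it is a table-5
start but the comparative evidence in echinoderms argues against it, and
excluding it keeps ATA-initiated annotations as correction targets (the
audit then relocates them onto the nearby ATG the alignment supports).
Users can assign any codon set to `table$extended_starts` before auditing;
classification of stop codons as starts is structurally impossible.

## Gene-order analytics

Arrangements are signed circular permutations over normalized gene labels,
canonicalized by rotating COI first and reflecting so COI is on the plus
strand — so rotation of the sequence record and reading-direction choices
cannot masquerade as rearrangements (asserted under randomized rotations
and reflections). Three statistics cover the claims such comparisons need:

* `breakpoint_distance()` — oriented adjacencies of one order absent from
  the other, on the circle; an adjacency equals its reverse-complement
  reading. A single transposed gene costs 3 breakpoints.
* `conserved_blocks()` — maximal runs of elements consecutive, in the same
  relative orientation, in both circles (a block also counts when it
  appears whole in the opposite reading direction).
* `detect_interchange()` — decides whether two orders differ by exactly
  one swap of two disjoint contiguous blocks, and names the smallest such
  pair. Label uniqueness forces the block boundaries once a rotation and
  the mismatch span are fixed, giving an $O(n^2)$ decision rather than a
  search over all block pairs.

Full rearrangement-distance inference (sorting by inversions and
transpositions) is deliberately not implemented; breakpoints, blocks and
the single-interchange test carry the comparisons this package targets.
Both distance and blocks are verified against independent brute-force
oracles over *all* signed circular permutations up to $n = 6$ and 200
random $n = 12$ cases. By default orders include PCGs and rRNAs only
(15 elements) — the granularity at which single-interchange claims are
made; `include_trnas = TRUE` gives the 37-element view appropriate for
lineages with tRNA-heavy rearrangements.

## The simulator and what it does (not) emulate

`genome_spec()` describes one circular blueprint; its defaults are the
study conditions the tests run under: the full 37-gene complement
(13 PCGs with typical lengths of 55–615 codons, 2 rRNAs of 900/1500 nt,
22 tRNAs of 65–75 nt), intergenic spacers of 2–25 nt, table 9, starts ATG
everywhere except ND3 = ATT and ND4L = ATC (the two genes where
alternative initiation is characteristically observed), and a
predominantly plus-strand arrangement with ND6 and several tRNAs on the
minus strand. `simulate_cohort()` then derives a star cohort: every taxon
is the same ancestral genome with independent site-uniform substitutions
at the requested per-site probability (default studies use 0.05), with
any change that would destroy a planted start, a terminal stop, or create
an internal PCG stop re-drawn or skipped. Substitution counts are asserted
to sit within 3σ of the binomial expectation.

Perturbation operators create the scenarios the audit must detect:
`perturb_annotations()` shifts a chosen fraction of start coordinates by
whole codons without touching the sequence (never past a neighboring
feature), `apply_rearrangement()` edits the blueprint's gene order, and
the `trim_5prime` / `start_override` knobs of `simulate_cohort()` plant a
genuinely shorter 5′ end with its own start codon — the pattern that
distinguishes a misannotation from a real length difference.

Deliberate non-features, and hence limits on what passing tests show about
real data: no indels (alignment raggedness beyond the 5′ region is not
exercised), no tRNA/rRNA secondary structure, no phylogenetic tree shape
(star cohort only), no transition/transversion or codon-position bias
beyond stop rejection, and spacer content is uniform random — so the
upstream codon context of a shifted annotation is arbitrary, not selected.
Real cohorts also bring heterogeneous annotation vocabularies and partial
records; the loaders normalize names through a synonym table and honor
partial flags, but the simulator does not generate fragmented assemblies.

## Numerical and design choices

| Parameter | Default | Why |
|---|---|---|
| `window` | 5 codons | documented misannotations are 1–3 codons; 5 gives margin without scanning deep into neighbors |
| gap open / extend | 10 / 1 (half-bit) | standard protein-alignment regime for BLOSUM62 |
| anchor run length | 10 columns | longer than any plausible gap-wobble island, shorter than any PCG |
| `divergence` bound | ≤ 0.3 | beyond this, mitochondrial PCG alignments stop being trustworthy at the 5′ end |
| `max_passes` | 3 | facing-ends geometry settles in 2; one pass of margin |
| spacer range | 2–25 nt | compact metazoan mitogenome spacing |

Degenerate inputs: ambiguity codes translate to `X` and can never match a
start or stop set, so the audit cannot hallucinate starts from Ns; U is
normalized to T on input; incomplete 3′ stop codons (CDS length ≢ 0 mod 3,
completed by polyadenylation) are tolerated at extraction and excluded
from internal-stop screening at the final partial codon; a single-member
ortholog set audits trivially against itself with a warning; members
pooled from partial conspecific records carry sequence but no genome
context and are audited at their annotated position only.

Problem sizes in the shipped tests are chosen for a desk run: unit tests
use a shortened blueprint (~40–85 codon PCGs), while the acceptance-grade
checks run the full-size default blueprint with 12 taxa — the scale of a
published asteroid cohort — and complete in well under a minute per audit.

## Known limitations

* Evidence is purely comparative-positional; the audit cannot distinguish
  a genuinely novel initiation codon from a conserved misannotation shared
  by the whole cohort, and accordingly only ever *flags* novel candidates.
* Ortholog grouping is annotation-label-driven (synonym-normalized), not
  homology-searched; a gene mislabeled beyond the synonym table is
  excluded rather than rescued.
* `detect_interchange()` answers only the single-interchange question;
  arrangements differing by composite rearrangements return `NULL` rather
  than a parsimony path.
* The center-star alignment is a heuristic; its pairwise steps are exact,
  and its scores are oracle-checked, but no optimality claim attaches to
  the multiple alignment itself.
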