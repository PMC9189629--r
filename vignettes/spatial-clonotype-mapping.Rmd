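---
title: "Mapping T cell clonotypes to Visium capture spots: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping T cell clonotypes to Visium capture spots: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrspot)
```

## The problem

Targeted TCRβ amplification of Visium spatial gene-expression cDNA yields a
paired-end library in which read 1 carries a 16-nt spot barcode followed by a
12-nt unique molecular identifier (UMI), and read 2 carries the amplified
TCRβ V(D)J region. Because the constant region lies 3′ of CDR3, amplification
uses a pool of TRBV gene-specific primers (45 for the human β locus, pooled
equimolar — at 10 µM total each primer sits at 10/45 ≈ 0.22 µM), so every
read 2 begins at a known V primer. `tcrspot` turns such a library into a
spot-by-clone UMI count matrix plus repertoire statistics, and ships a
simulator that generates the complete input set with ground truth, so every
stage is testable without sequencing data.

## The procedure

1. **Clonotype calling** (`call_clonotypes()`). Each read 2 is assigned a V
   segment by the best ungapped placement of each primer-anchored query
   (primer plus the V 3′ region) over start offsets 0–10 (the partial read-2
   tail precedes the primer); a call requires a mismatch fraction ≤ 0.1 over
   the aligned span. A J segment is then placed 3′ of the V alignment,
   accepted at ≤ 2 mismatches over ≥ 20 aligned nt. The CDR3 spans the
   conserved V cysteine codon through the conserved J phenylalanine codon
   (FGXG motif), both projected through the ungapped alignments. Reads
   sharing the exact (V gene, J gene, CDR3 nucleotide) key form a clonotype;
   clones are numbered by descending read support. Alternatively,
   `import_mixcr()` ingests a MiXCR-style clones table plus per-clone
   `reads_cln<N>.fastq.gz` files as the front end.
2. **Spatial linkage** (`link_reads()`). Every clone-supporting read is
   paired to its read 1 by normalised read id (not file order, because
   per-clone exports scramble order), the barcode (bases 1–16) and UMI
   (bases 17–28) are extracted — read 1 shorter than 28 nt is a hard error,
   mirroring the protocol's minimum cycle count — and the barcode is matched
   against the tissue-positions whitelist.
3. **Deduplication** (`deduplicate()`). Each (barcode, UMI) combination is
   used once. Within a pair claimed by several clones the majority clone
   wins; ties discard the pair.
4. **Matrix and statistics** (`build_matrix()`, `repertoire_stats()`). Rows
   are all in-tissue spots in positions-file order, columns the clones with
   at least one in-tissue UMI. Off-tissue UMIs go to a side table. Summary
   statistics: total reads, TCR UMIs, clone count, Shannon diversity
   H = −Σ pᵢ ln pᵢ, sequencing saturation, UMIs per in-tissue spot, the
   fraction of clone-supporting reads under tissue, and the count of flagged
   non-TRB clones.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `max_hamming` | 0 | No barcode error correction by default; the original combine-counts analysis gives no evidence of correction. With 1, a barcode is corrected only to a *unique* whitelist neighbour. |
| `max_mismatch_frac` (V) | 0.1 | Tolerates sequencing error over a ~60–80 nt anchor without letting random sequence through (a random alignment has ≈ 75% mismatches). |
| `max_mismatch` (J) | 2 over ≥ 20 nt | J segments are short (45–60 nt); an absolute cap is more stable than a fraction. |
| `min_read1_len` | 28 | 16-nt barcode + 12-nt UMI; validated, never silently truncated. |
| Shannon log base | e | Natural-log units keep H ≤ ln K; the base is exposed for bit-based reporting. |
| `dedup_policy` | majority, ties discarded | "Used once" fixes the constraint but not the winner; majority voting is conservative and a tie carries no evidence either way. |

## Saturation definition

No closed formula accompanies the reported per-sample saturation values, so
the package uses the 10x-style definition: saturation = 1 − (unique UMIs) /
(barcode-matched clone-supporting reads, pre-deduplication). Under the
simulator's duplication model (each molecule read 1 + Poisson(µ−1) times)
its expectation is ≈ 1 − 1/µ, which the test suite checks by simulation
against the closed form. Published per-sample values cannot be reproduced
without the deposited reads and the original denominator; the definition is
documented here rather than asserted as theirs.

## What the simulator emulates — and what it does not

`simulate_dataset()` generates: a V/J segment reference (V 250–300 nt with
the cysteine anchor within 10 nt of the 3′ end; J 45–60 nt with an FGXG
motif), a primer pool (20-mers upstream of CDR3, shared read-2 tail), a
tissue-positions file (v1 dialect, gem-group suffixes), a placed repertoire,
and paired FASTQ with complete truth tables. Defaults are the package's
reference study condition: 50 spots, 80% under tissue, 20 clones placed on
4 spots each, 2,000 molecules, PCR duplication mean 3, substitution rate
10⁻³ (a typical Illumina figure; exact-recovery checks set it to 0, which is
the condition under which exactness is the correct expectation). Total
molecule count is controlled directly (`n_molecules`) and split over clones
by uniform or geometric weights, then multinomially over each clone's spots
— an equivalent but simpler control surface than per-clone-spot UMI counts.

Deliberately not modelled: indels (the caller is ungapped; its guarantees
are stated for substitution-only error), quality-score profiles (qualities
are constant placeholders and no quality filtering is applied), ambient
diffusion gradients, full transcriptomes, and real locus sequence homology
(decoy "BCR-like" segments at 70% identity to a TRBV stand in for
cross-priming). Passing tests therefore demonstrate algorithmic correctness
under controlled noise, not end-to-end performance on real tissue.

## Numerical and degenerate-input choices

- Alignment score is matches − mismatches; score ties break to the
  lexicographically smallest segment name, offset ties to the smallest
  offset, making calls deterministic.
- Barcodes containing N never match; an N in the UMI is kept and treated as
  a literal symbol during deduplication.
- Nonproductive clonotypes (out of frame, internal stop, or missing C/F
  anchors) are retained and flagged, never dropped.
- Reads with a V but no J call are counted in the drop log, not assigned.
- An empty repertoire yields a zero-column matrix and header-only TSV;
  off-tissue-only data yields a populated side table.
- All randomness flows from a single integer seed; identical configuration
  gives byte-identical outputs, including gzip streams.

## Problem sizes used in the checks

The bundled verification uses 50-spot / 20-clone / ~2,000-molecule datasets
for exact-recovery checks, ~10,000 reads for the error-tolerance check at
10⁻³, and 500 engineered records for the deduplication oracle — sizes at
which every property is decisive while a full run stays in the seconds
range.

## Known limitations

- Exact clone keys: no fuzzy CDR3 clustering or UMI-network collapsing, so
  a substitution inside CDR3 creates a (flagged, low-support) satellite
  clone rather than being absorbed.
- Chain classification is by V-gene name prefix (TRBV vs other); it flags
  cross-primed non-TRB hits but is not an immunoglobulin annotator.
- The ungapped aligner does not recover reads with indels in the V anchor
  or J region.
- `clone_overlap()` compares against an external clone-key list only; it
  does not process single-cell V(D)J output itself.
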