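---
title: "Methods: joint annotation of co-occurring variants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint annotation of co-occurring variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(jointvar)
```

## The model

`jointvar` treats variant annotation as a transcript-level, not a
variant-level, problem. The pipeline has five stages, each a pure function
from tibbles to tibbles:

1. **Decomposition.** A raw record `(chrom, pos, ref, alt)` is decomposed by
   comparing the first `min(|ref|, |alt|)` bases position by position. Each
   mismatch yields one SNV. If `|ref| > |alt|`, the unmatched REF tail
   becomes a single deletion whose first deleted base sits at
   `pos + |alt|`; if `|alt| > |ref|`, the unmatched ALT tail becomes a
   single insertion anchored *after* `pos + |ref| - 1`. The contract is a
   round trip: re-applying the components to REF reconstructs ALT exactly.
   A record therefore emits any number of SNVs but at most one indel.

2. **Assignment.** Each transcript defines an annotation window
   `[min(exon starts) - F, max(exon ends) + F]` with flank `F = 2` bp — just
   wide enough to include the splice dinucleotides of terminal introns'
   neighbours and variants abutting the coding span. Component variants are
   matched to windows by interval overlap (`GenomicRanges`), using each
   component's genomic span: a point for SNVs, `pos .. pos + len - 1` for
   deletions, and the two anchor-gap flanking bases `pos .. pos + 1` for
   insertions. When a deletion's span swallows a later variant, the later
   variant is dropped with a warning (first-come, coordinate order), so the
   surviving set is always jointly applicable.

3. **Classification.** For an SNV, splice dinucleotide windows (the first
   and last two bases of each intron, donor/acceptor by strand) take
   precedence; otherwise the SNV's coding offset selects a codon, and *all
   co-occurring SNVs of the same transcript falling in that codon are
   applied simultaneously* before translating. This joint codon is what
   distinguishes `CTG → TTG` (synonymous when the first SNV is considered
   alone) from `CTG → TCG` (leucine → serine) when a second same-codon SNV
   co-occurs. Missense calls are graded by Grantham distance; stop gain and
   loss are read off the translated codons. For an indel, splice-window
   overlap again takes precedence; otherwise the category follows the net
   coding-length change `delta`: `frameshift_variant` when
   `delta %% 3 != 0`, `inframe_variant` when `delta != 0`, `silent_mutation`
   when the indel does not change the coding sequence at all. Inserted bases
   count toward `delta` only when the anchor gap lies strictly *inside* a
   coding exon — an insertion anchored immediately before or after an exon
   lands in intron or flank, so edge-anchored insertions never produce
   frameshifts. Deleted bases count only where the deletion intersects
   coding exons.

4. **Reconstruction.** All surviving variants of a transcript are applied
   to its exon sequences in descending genomic order (so positions stay
   valid), spliced, reverse-complemented on the minus strand, and
   translated in full (no early termination at stop codons, ambiguous
   codons become `X`). An *internal* stop is a `*` strictly before the final
   residue; its position is reported as
   `100 * index / nchar(reference protein)`.

5. **ORF status.** `FULLY_DELETED` if a single deletion covers the whole
   transcript span; otherwise `ORF_DISRUPTED` if any splice dinucleotide was
   hit or the variant protein contains an internal stop where the reference
   protein had none; otherwise `ORF_PRESERVED` if any variant was assigned;
   otherwise `ORF_INTACT`. Two consequences of this definition are worth
   spelling out. First, frame-restoring indel pairs (deltas summing to
   0 mod 3) are `ORF_PRESERVED` provided the transiently shifted stretch
   contains no stop codon — the defining "joint" behaviour. Second,
   transcripts whose *reference* annotation is already stop-interrupted
   (pseudogene-like models) are exempt from the stop criterion, since a new
   stop cannot be distinguished meaningfully from an already-broken frame.

```{r}
genome <- c(c1 = "ATGCTGGGGTAA")
exons <- tibble::tibble(transcript_id = "t1", chrom = "c1",
                        start = 1L, end = 12L, strand = "+")
both <- tibble::tibble(chrom = "c1", pos = c(4L, 5L),
                       ref = c("C", "T"), alt = c("T", "C"))
jv_annotate(both, genome, exons)$annotations$category
jv_annotate(both[1, ], genome, exons)$annotations$category
```

## Parameters and conventions

- **Coordinates** are 1-based inclusive everywhere; insertions are anchored
  after their `pos`.
- **Flank** `F = 2` bp (the annotation-window margin). Exactly the width of
  a splice dinucleotide; it determines only which variants are *reported*
  against a transcript, not their category.
- **Grantham bins**: 0–50 `CONSERVATIVE`, 51–100 `MODERATELY_CONSERVATIVE`
  (both → `conservative_missense_codon`), 101–150 `MODERATELY_RADICAL`,
  >150 `RADICAL` (both → `non_conservative_missense_codon`). The shipped
  matrix is the published 20×20 table; it is symmetric and integer-valued,
  and can be replaced via `read_grantham_matrix()`.
- **Codon table**: the standard genetic code by default
  (`default_codon_table()`), replaceable by any 64-entry table.
- **First ALT only**: multi-allelic VCF records contribute their first
  alternative allele; symbolic/breakend ALTs are skipped and counted.
- **Splice model**: only the canonical donor/acceptor dinucleotides are
  considered; any SNV inside, or any indel intersecting (deletions) or
  strictly straddled by (insertions), a dinucleotide window is a splice
  variant, which takes precedence over the coding category.

## The fixture generator and its realism

`generate_fixture(scenario, seed)` produces nine deterministic scenarios
(`FIXTURE_SCENARIOS`) with recorded expected outcomes. The generator aims
for *adversarial minimality*, not biological realism: transcripts are
30–50 codons with 30 bp flanks, introns are `GT…AG` with random interiors,
and random codon bodies exclude stop codons so that planted effects are the
only effects. Two design points matter for trusting the truths:

- `frame_restore` plants a run of 4–7 `GCC` codons and puts a 1-bp deletion
  and a 1-bp `C` insertion inside it. The transiently shifted stretch is
  all G/C, which cannot spell `TAA`/`TAG`/`TGA`, so `ORF_PRESERVED` is
  guaranteed *by construction*, for every seed, rather than checked after
  the fact.
- `frameshift_stop` plants `GCC ATA ACC` at codon index `i` and deletes the
  `G`: the shifted frame reads `CCA TAA …`, creating an internal stop at
  codon `i + 1` whose reported location `100 * (i + 2) / n_codons` is known
  in closed form.

The randomised property fixtures used by the test suite (not shipped) are
separate: 160-bp chromosomes with 1–4 exons and variants spaced ≥ 8 bp so
that deletion-conflict resolution never triggers, compared against
independent oracles (per-base whole-chromosome editing, all-pairs overlap
scans, a from-scratch single-SNV classifier).

## Numerical choices

There is essentially no floating-point numerics in the method; the two
deliberate choices are:

- Stop positions are reported as percentages of the *reference* protein
  length (`100 * index / nchar(ref_protein)`), kept as doubles and only
  rounded (2 digits) at file-writing time.
- Grantham distances are stored and compared as integers; class boundaries
  are closed on the left bin (`<= 50`, `<= 100`, `<= 150`), so boundary
  scores are deterministic.

Determinism: `generate_fixture()` seeds R's RNG locally and restores the
caller's RNG state, and all output writers order records explicitly
(chromosome, position, kind), so repeated runs are byte-identical.

## Limitations

- Only coding exons (CDS) are modelled: no UTRs, no promoter/regulatory
  annotation, and `silent_mutation` covers everything in the window that is
  neither coding nor splice-dinucleotide.
- Splice assessment is dinucleotide-only; branch points, polypyrimidine
  tracts and splice-strength scoring are out of scope.
- Co-occurrence is treated at the transcript level without phasing input:
  all variants assigned to a transcript are assumed to lie on the same
  haplotype. Unphased heterozygous variants are therefore evaluated as if
  co-occurring.
- One deletion swallowing later variants resolves conflicts by coordinate
  order; no attempt is made to re-normalise overlapping indel
  representations.
- `stop_lost` at the terminal codon does not by itself disrupt the ORF
  (there is no stop-readthrough extension model); the reconstructed protein
  simply lacks its terminal `*`.
- Multi-allelic records beyond the first ALT and symbolic/structural
  alleles are skipped (with counts), not annotated.
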