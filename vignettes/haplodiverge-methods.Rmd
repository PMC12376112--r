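---
title: "Haplotig purging and inter-haplotype divergence: models and methods"
author: "HaploDiverge authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotig purging and inter-haplotype divergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Long-read assemblies of highly heterozygous diploid genomes — outbreeding
forage grasses are an extreme case, with heterozygosity above 3% — routinely
assemble both alleles of a locus as separate contigs. The shorter,
redundant copy (a *haplotig*) inflates the assembly and corrupts
completeness and duplication statistics, so it must be identified and
removed before scaffolding. Once two clean haplotype assemblies exist, the
obvious next question is how different they actually are, beyond the SNP
rate: small INDELs and large presence/absence variants (PAVs) can drive
local sequence identity far below what per-base heterozygosity suggests.

HaploDiverge implements both stages as a tested library plus a thin CLI,
and ships a truth-labelled diploid simulator so that every stage can be
exercised — and its accuracy measured — without any external data.

# Haplotig purging

Contigs are paired on three independent evidence channels, and a contig is
declared a haplotig of a *longer* contig if it fulfils **any one** of:

1. **Alignment coverage** — more than 70% of the shorter contig is covered
   (union of aligned intervals) by alignments to the longer contig;
2. **Micro-synteny** — the pair shares a collinear block of at least five
   genes;
3. **Shared markers** — at least one single-copy complete
   completeness-marker gene (BUSCO-style) occurs exactly once on each of
   the two contigs.

The thresholds live in `purgeConfig()`: coverage is a strict `>` (0.70),
the count thresholds are inclusive `>=` (5 genes, 1 marker), following the
"greater than" versus "at least" wording of the criteria. All three
defaults are the standard values used in published haplotig-purging
pipelines for grass genomes.

Design choices that the criteria themselves leave open, and how this
package resolves them:

* **Coverage denominator.** Coverage is measured on the *shorter* contig
  of a pair — the fraction of the putative haplotig that aligns — matching
  the semantics of read-depth-based purge tools. Alignments of both
  orientations are pooled into one interval union; a MAPQ floor is
  available (`min_mapq`) but off by default.
* **Collinear chaining.** Matched gene anchors are ranked along each
  contig by start coordinate; a block is the longest chain strictly
  monotone in both rank orders (increasing, or decreasing for inverted
  blocks) with consecutive rank gaps of at most `max_anchor_gap` (default
  10) on both contigs. Inverted blocks count toward criterion 2: allelic
  contigs frequently assemble in opposite orientation. The implementation
  is an O(n²) chaining DP; tests verify it against an independent
  longest-common-monotone-subsequence oracle computed by adjacency-matrix
  relaxation.
* **"Single-copy" is judged per contig.** A marker duplicated genome-wide
  but complete exactly once on each member of a pair links the pair —
  allelic duplication is precisely the signal the criterion exploits.
* **Chains of haplotigs.** Contigs are processed in decreasing length; a
  contig purged into a partner that was itself purged is still removed,
  and its partner is reported as found. The output therefore stays a pure
  partition of the input: `primary bp + haplotig bp == input bp` on every
  run.
* **Equal-length pairs.** The lexicographically larger id may be purged
  into the smaller; ties are deterministic and logged on the result
  object.
* **Best partner.** When several longer contigs qualify, the recorded
  partner is the one triggering the most criteria, then the highest
  coverage, then the most collinear genes, then the lexicographically
  smallest id.

Raising `min_coverage` with the other thresholds fixed can only shrink the
purged set; this monotonicity is asserted in the test suite at 0.5 / 0.7 /
0.9.

# Inter-haplotype divergence

## Variant extraction from whole-genome alignment

Variants are read directly from `=`/`X`/`I`/`D` CIGAR runs of a
whole-genome alignment PAF (the format minimap2 emits with `--eqx`;
ambiguous `M` runs are rejected with a pointer to `--eqx`). An `X` run of
length *k* decomposes into *k* single-base SNPs, so SNP counts always match
per-base masking. Insertions/deletions shorter than 50 bp are small
INDELs; runs of 50 bp or more are PAVs — the conventional boundary between
small and structural variation. The complement of all target-aligned
intervals forms the *unaligned* mask track.

## Concordance between two callsets

Only variants detected by both the whole-genome-alignment callset and an
independent read-based callset are trusted:

* **SNPs and INDELs** are common iff a variant of the same class in the
  other callset shares the **exact start position**. Allele agreement is
  not required (an optional `strict` mode compares alleles where both
  sides carry them).
* **PAVs** are common iff their reference spans overlap, or the start of
  one lies within **10 bp downstream** of the end of the other — applied
  in both directions, since read-based SV callers place breakpoints
  imprecisely. With half-open spans this is exactly a gap of at most 10
  bases, implemented as an `IRanges::findOverlaps(maxgap = 10)`.
* PAVs whose span contains at least one assembly-gap base (`N` run) are
  filtered out; a PAV merely abutting a gap is kept.

Common variants are represented by the WGA-side record: the whole-genome
alignment is the coordinate authority on the reference haplotype, the read
callset corroborates.

## Windowed sequence identity

Each reference sequence is tiled into 100-kb windows (the last window of a
sequence may be shorter). Per window,

$$\mathrm{identity} = \frac{W_\mathrm{eff} - \mathrm{masked}}{W_\mathrm{eff}},$$

where *masked* is the **union** of common-variant reference spans, N-gap
intervals and unaligned intervals clipped to the window. Counting the
union (never the sum) guarantees `masked <= W_eff` and identity in
`[0, 1]` even when categories overlap. Accounting conventions the formula
does not itself fix:

* a variant masks its *reference-span* length; an insertion masks only the
  single reference base it is anchored on (the window lives on the
  reference axis, so inserted length has no home there);
* gaps subtracted are reference-haplotype gaps; query-side gaps enter only
  through the gap-PAV filter;
* per-category columns (`variant_bp`, `gap_bp`, `unaligned_bp`) are each
  clipped unions, while `masked_bp` is the union over all categories, so
  the columns need not sum to `masked_bp`.

# The simulator

`simulateDiploid()` generates the study conditions end to end:

1. a uniform-random haplotype 1 (default 5 Mb over 2 chromosomes);
2. haplotype 2 by planting non-overlapping events: substitutions at
   **0.0343 per bp** — the heterozygosity level reported for highly
   heterozygous forage grasses, i.e. three to four SNPs per 100 bp — plus
   small
   INDELs at 0.00283 per bp and PAVs at 0.00082 per bp. The two latter
   rates are not directly reported anywhere; they were fixed once to
   reproduce the ~12:1 SNP:INDEL and ~42:1 SNP:PAV count ratios observed
   in such genomes, and are freely configurable. INDEL lengths are uniform
   on [1, 49] bp, PAV lengths uniform on [50, 500] bp, insertion and
   deletion equiprobable;
3. 40 primary contigs tiling haplotype 1 at event-free breakpoints, plus
   25 haplotigs sampled from haplotype 2, each a strictly shorter
   sub-interval of exactly one primary's allelic region (40–100 kb);
4. 30 gene anchors per primary, copied in order (inverted for roughly one
   haplotig in five) onto the haplotig; 3 single-copy complete markers per
   allelic pair plus one unpaired marker per primary;
5. exact PAF alignments with `=`/`X` CIGARs, both haplotig-vs-primary and
   whole-haplotype, derived from the planted events — not from a separate
   aligner;
6. two noisy callsets: truth minus independent Bernoulli dropouts at
   `callset_fnr` per callset, with read-callset PAV positions jittered
   uniformly by up to `pav_jitter_bp`.

Numerical and structural choices:

* **Non-overlapping events** (rejection sampling with per-class binomial
  counts) keep truth masking additive and make
  `applyVariants(h1, truth) == h2` an exact string identity. Wide events
  are placed before narrow ones — SNPs would otherwise pepper the sequence
  and starve PAV spans. Deletions reserve one spacer base after their
  span so two deletions can never abut and fuse into a single alignment
  run.
* **Seed hierarchy.** One global seed feeds named substreams (genome,
  mutate, fragment, genes, callsets), so changing one stage's parameters
  does not perturb another stage's draws. Identical parameters give
  byte-identical output files.
* **Noise knobs for robustness scenes.** `anchor_dropout` thins haplotig
  gene copies; `aln_trim_frac` trims the haplotig alignments (split
  between both ends, re-snapped to event-free boundaries), degrading the
  coverage channel.

What the simulator does *not* emulate — and hence what passing tests do
not show about real data: sequencing error and read-level artifacts,
repeat-induced spurious alignments between non-allelic contigs, phase-
switch mosaics within a contig, assembly base errors, N-gaps inside
simulated sequence (gap handling is exercised by dedicated unit fixtures
instead), and biologically clustered rather than uniform variant
placement. Real purge decisions face harder negatives than the simulated
scene provides; the simulation establishes correctness of the decision
procedure, not its field accuracy.

# Verification strategy and problem sizes

The test suite checks, among others:

* union lengths and pair coverage against a per-base membership oracle
  (100 random instances each);
* chain sizes against the independent relaxation oracle on 200 random
  permutations of up to 15 genes;
* exact truth recovery of purging on the noise-free 5-Mb scene
  (precision = recall = 1) and mean F1 ≥ 0.9 over ten noisy seeds;
* exact reproduction of all planted variants (class, position, length)
  from the emitted CIGARs, and window identity equal to
  `1 - truth_masked/W_eff` to machine precision;
* concordance counts within four standard deviations of
  `(1 - fnr)^2 · |truth|` pooled over 20 seeds, and SNP counts binomial
  around `genome_bp · 0.0343`;
* base conservation (`primary + haplotig == input`), byte-identical
  reruns, and coverage-threshold monotonicity.

Unit tests run on a 600-kb two-chromosome scene; the end-to-end property
checks use the full 5-Mb default scene, and the statistical checks use
twenty 1-Mb mutate-only scenes. These sizes keep the full suite around
three minutes while leaving every rate at its defaults.

`scripts/acceptance.R` re-runs the same computations from scratch against
the installed package and writes the resulting quantities as JSON; see the
README for how to invoke it.

# Known limitations

* The purge stage consumes alignment, anchor and marker *tables*; it does
  not run an aligner, a gene mapper or a BUSCO search.
* Divergence assumes a single reference axis (haplotype 1); inversion
  interiors are whatever the upstream aligner made of them — if it emitted
  no alignment there, they surface in the unaligned mask.
* The VCF emitter writes simple biallelic records (symbolic `<INS>`/`<DEL>`
  with `SVTYPE`/`SVLEN`/`END` for structural alleles); multi-allelic sites
  and breakend notation are out of scope.
* `readPaf()` keeps whole files in memory; at chromosome-scale inputs with
  per-base CIGARs this is a few GB, adequate for the intended desk-scale
  use.
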