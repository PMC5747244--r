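---
title: "Methods: characterising transcription in GWAS haploblocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterising transcription in GWAS haploblocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplotx)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data tests do and do
not establish about real data.

## Coordinates and interval arithmetic

All coordinates are 0-based half-open internally; BED I/O passes through
unchanged and GTF I/O converts from 1-based inclusive at the file boundary.
Region-level operations (`merge_intervals()`, `subtract_intervals()`,
`overlap_bases()`) are strand-agnostic — enrichment statistics count
nucleotides, not stranded features — and strand is consulted only where the
biology demands it: 5' ends, promoter windows, and bidirectionality.
Overlapping annotation features are single-counted via merge before any
base counting; chromosome names are matched verbatim, since silent "chr"
aliasing turns mismatched inputs into wrong zero-overlaps rather than
errors. The interval engine is delegated to IRanges/GenomicRanges behind
the tibble surface, and the test suite holds it to exact agreement with a
literal per-base boolean-mask oracle on randomised fixtures.

## LD-block delineation

A haploblock around an index GWAS SNP is delimited by the decay of linkage
disequilibrium. Under the **main** rules, each boundary is first placed at
the most distant proxy SNP with r² > 0.5 on that side, clipped to ±500 kb
of the index SNP. A side is then *insufficient* when no proxy on it (within
the cap) has r² < 0.6 — LD never decays below threshold, so the boundary
cannot be located — and such a side is extended to the nearest
recombination hotspot beyond the current boundary. Under the **pilot**
rules both proxy-extent boundaries are always extended to the nearest
hotspots, and the total block length is capped at 1 Mb. The block's end
coordinate is the outermost retained SNP position + 1, so the boundary SNP
base is included.

Open points resolved as package policy:

- *Sufficiency scope.* Whether proxies beyond the 500-kb cap participate in
  the sufficiency test is unspecified; they are excluded, since a boundary
  that cannot legally be placed there cannot be informed by them. An empty
  side counts as insufficient.
- *Total-cap distribution (pilot).* How the 1-Mb cap is shared between
  sides is unspecified; each side is trimmed proportionally to its overhang
  beyond 500 kb from the index SNP — the least surprising rule, and the
  block always keeps its index SNP. The cap is applied after hotspot
  extension.
- *Hotspot geometry.* Hotspots are points; interval input is reduced to a
  point by `read_hotspots()`. "Nearest" means the smallest extension beyond
  the current boundary moving away from the index; a side that needs
  extension but has no hotspot keeps its proxy-extent boundary and is
  flagged rather than silently accepted.

Every boundary records its provenance (`proxy_extent`, `hotspot`, `cap`),
and construction is verified against an exhaustive per-SNP scan oracle on
randomised panels, including cap-clipping and hotspot-extension cases.

## Capture space and controls

Blocks that touch a coding exon by even one base, or are under 3 kb, are
excluded; survivors are collapsed into non-redundant regions (retaining the
map from region to contributing index SNPs), and the exons of
`protein_coding` and `lincRNA` genes — the union across all transcripts of
those genes — are subtracted to give the target regions. Intronic controls
take one random intron per expressed locus and draw a subregion with
length uniform in [200, 1000] nt and uniform placement (the range is
prescribed, the sampling law is not; uniform is the minimal assumption).
"Repeat content" is interpreted as the repeat-covered *base fraction*, and
candidates above 0.75 are rejected in favour of another intron of the same
locus; selection is reproducible under a seed.

## Expression, filtering, occupancy

Size factors use the classical median-of-ratios estimator: the per-column
median of counts divided by the row-wise geometric mean, over transcripts
positive in every condition. FPKM is
`(count/sf) / ((length/10³)·(normalised column total/10⁶))`, invariant to
consistently rescaling a condition's counts and factor. A transcript is
retained iff it is multi-exonic (spliced), reaches FPKM > 1 in at least one
condition, overlaps the capture space by ≥ 1 exonic base, and contributes
> 1% of its locus's expression. The isoform share is evaluated in the
condition where the locus is maximally expressed — a tissue-agnostic
reading that avoids averaging artifacts; loci are formed by transitive
clustering of same-strand transcripts sharing exonic bases, mirroring
assembler locus merging. Expression tiers are tertiles of maximal FPKM
(no published cutoffs exist; ties go to the lower tier so the assignment is
monotone). A block is *occupied* when at least one retained transcript
above the expression threshold has an exonic base inside it. FPKM is
evaluated after size-factor normalisation (the order is unspecified
upstream; normalising first is the conservative choice).

## Enrichment statistics

For a region set R and annotation A, the 2×2 table is a = overlap bases,
b = bases of A outside a, c = bases of R without A, d = the remaining
genomic bases; exclusion zones are removed from R, A and the genome total
before counting, so the cells always sum to the effective genome size.
The odds ratio is (a/b)/(c/d); the CI is `log OR ± 1.96·SE` with
`SE = √(1/a+1/b+1/c+1/d)`; p-values come from the χ² test with Yates
continuity correction (the default of the standard R test; a flag disables
it). Zero cells are an error unless the Haldane–Anscombe +0.5 correction is
enabled — applied to the OR and CI only, never to the χ². The one-sided
"greater" alternative used for element enrichment halves the two-sided χ²
p directionally (p/2 when log OR > 0, 1 − p/2 otherwise), since the χ²
test itself is sign-blind. SNP-level tables count SNPs as single events
inside element base sets, with introns as the reference class and
Benjamini–Hochberg adjustment across classes.

Randomised controls re-place the region intervals uniformly at random —
length-preserving, same chromosome (a flag allows cross-chromosome),
outside the exclusions, with gaps chosen with probability proportional to
the number of admissible start positions — and recompute the enrichment
under a seed. TSS enrichment takes strand-aware 5'-end windows of ±500 bp
as the region, and excludes reference promoters ±500 bp and reference
exons ±200 bp from all terms; one shared placement scheme serves both the
TSS analysis and the aggregate-profile negative controls. The reference
promoter width is the same ±500 bp as the exclusion rule, absent any other
definition.

A note on calibration: the analytic SE treats bases as independent, which
is adequate for SNP-scale (point) events but optimistic for long contiguous
intervals, whose overlap is lumpy; the log OR of interval-scale null
placements also carries a small-sample (Jensen) bias. The calibration tests
therefore check the χ² rejection rate and the centring of the
randomised-control mean at point scale, where the estimator's sampling
theory actually applies; interval-scale results should lean on the
randomised controls rather than the analytic CI alone.

## Tissue specificity

Tau is `τ = Σᵢ(1 − x̂ᵢ)/(n − 1)` with `x̂ᵢ = xᵢ/max(x)`: 0 for uniform
expression, 1 for single-condition expression, `(n−k)/(n−1)` for k equal
positive entries — closed forms the tests verify for all k, along with
scale invariance to 10⁻¹². Expression is transformed as
`log2(normalised count + 1)`, a monotone variance-damping transform chosen
in place of a model-based variance-stabilising transform; this affects
absolute τ values slightly but not the formula, the ordering, or the
planted-profile recovery (single-condition profiles give τ = 1 under any
monotone transform fixing 0). All-zero transcripts are flagged
`computed = FALSE` rather than scored. The τ-component matrix
(`1 − x̂ᵢ`, 0 at the maximal condition) is exported for external
clustering; cluster significance testing is out of scope. The specific set
uses a strict threshold (τ > 0.8 by default).

## Aggregate profiles and bidirectionality

Profiles count peak elements — not tags — by midpoint into fixed bins
(default 100 bp over ±5 kb) of strand-oriented offset from each included
transcript's 5' end, then divide by the number of transcripts, so
`normalised count × n` recovers the integer raw count in every bin
(a conservation law the tests enforce exactly). Midpoint assignment avoids
double-counting wide peaks across bins. Transcripts enter a profile when
their FPKM in the track's tissue exceeds the floor (default 0). Promoter
occupancy is the fraction of TSS ±500 bp windows touching ≥ 1 peak.
Positive controls are candidates (e.g. annotated lncRNAs) ranked by
distance of their median expression from the analysed set's median, taken
to matching size. A transcript is bidirectional when its span, extended
500 bp at the 5' end, overlaps the extended span of an opposite-strand
transcript — a symmetric relation by construction.

## Allelic imbalance

Given heterozygous-site read counts, SNPs need ≥ 30 reads (inclusive);
per-SNP two-sided exact binomial p-values against a configurable null
ratio (default 0.5; supply a bias-adjusted value if reference-mapping bias
was estimated upstream) are combined per transcript with Fisher's method
(−2Σlog p ~ χ²₂ₖ); q-values are Benjamini–Hochberg across transcripts with
flagging at q < 0.1; the imbalance measure is |0.5 − median ratio| ∈
[0, 0.5]. This is a deliberately simplified stand-in for a full
genotyping + phased meta-analysis workflow: phase is ignored (per-SNP
independence), and "median allelic expression" is read as the median
reference-allele ratio. Transcripts losing all SNPs to the depth filter
are omitted with a log message rather than scored.

## The synthetic study

The generator emulates the pipeline's inputs with controllable truth on a
deliberately small genome (2 chromosomes × 2 Mb — large enough for 200
blocks, small enough for per-base oracles). Defaults are the regimes the
pipeline is meant to characterise: 20 index SNPs with proxy r² following
`exp(−d/20 kb)` plus ±0.05 uniform noise, hotspots every 50 kb with
jitter, 5 tissues, block occupancy 0.85, 80% single-tissue transcripts at
mean count 200, promoter-mark fraction 0.6 over a 2×10⁻⁶/bp Poisson peak
background, a planted element odds ratio of 2 for 300 GWAS vs 3000 common
SNPs, and 30% of transcripts allelically imbalanced at allele fraction 0.8
with 5 SNPs of mean depth 50.

Planting is Bernoulli per block, so measured occupancy is compared to the
realised draw and to the exact binomial interval around the planted rate.
Decoys are designed to be removed *deterministically* by the filter under
test: unoccupied blocks receive single-exon transcripts (multi-exonic
filter), occupied loci may receive an isoform whose counts are a fixed
0.5% of the dominant isoform's (share filter) — expression-threshold
decoys are avoided because FPKM depends on library totals, which would
make planted truth probabilistic. Three broadly expressed housekeeping
transcripts outside the blocks guarantee median-of-ratios size factors are
computable in every configuration (including 100% tissue-specific
planting); they fall outside the capture space and never enter the
retained set. LD truth blocks are computed by an exhaustive per-SNP scan
emitted alongside the panel. Parameter-recovery experiments use one
isoform per locus so that promoters are distinct and the promoter-mark
fraction is identifiable from transcript-level occupancy.

What passing these tests shows — and does not. They establish that the
implementation computes its stated definitions exactly (oracle
equivalence), that its statistics are calibrated where their sampling
theory applies, and that planted parameters are recovered at the stated
scale. The generator does not emulate sequence content, assembly noise,
mapping bias, LD structure beyond monotone decay, or correlated expression
across tissues; conclusions about real CaptureSeq data still depend on the
upstream assembly and quantification being sound.

## Problem sizes and reproducibility

Test and acceptance runs use: 100 random interval fixtures on ≤ 50-kb
genomes, 50 random SNP panels of ≤ 200 SNPs, 400 point-scale null
enrichment simulations plus 100 randomised placements, 50 generator seeds
× 200 blocks for occupancy/promoter recovery, 500 null and 100 × 10
planted transcripts for allelic calibration and power, and one full
pipeline run on the default study — sizes chosen so every check rests on
enough replication to be meaningful while the whole suite stays quick on a
single CPU. Every stochastic step takes an explicit seed, and all of
`scripts/acceptance.R`'s randomness derives from its `--seed` argument.
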