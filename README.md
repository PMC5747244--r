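# haplotx

Most trait- and disease-associated variants found by genome-wide association
studies (GWAS) fall in intronic or intergenic haplotype blocks with no
annotated genes, yet many of those blocks are quietly transcribed.
Targeted RNA capture (CaptureSeq) of such regions across a tissue panel can
reveal rare, tissue-specific multi-exonic transcripts — but turning the raw
regions and assemblies into defensible biology takes a chain of bespoke
genomic computations. **haplotx** implements that chain as a tested, tidy R
toolkit:

- **LD-block delineation** around index GWAS SNPs from proxy-SNP r²
  tables and recombination hotspots, under two rule sets: extension to the
  most distant proxy with r² > 0.5 clipped at ±500 kb, with hotspot
  extension for sides where LD never decays below 0.6 (*main*), or
  always-extend-to-hotspot with a 1-Mb total cap (*pilot*);
- **capture-space construction**: blocks containing coding exons or under
  3 kb are excluded, the survivors are collapsed into non-redundant regions,
  and `protein_coding`/`lincRNA` exons are subtracted; intronic control
  regions (200 nt–1 kb, repeat content ≤ 75%) are drawn per expressed locus;
- **transcript filtering**: median-of-ratios size factors, FPKM, and the
  retention rule *multi-exonic ∧ FPKM > 1 in ≥ 1 tissue ∧ overlaps the
  capture space ∧ isoform share > 1% of locus expression*, plus
  low/medium/high expression tiers and per-block **occupancy**;
- **enrichment statistics** at nucleotide or SNP resolution: the 2×2 table
  (a = overlap bases, b = annotation-only, c = region-only, d = rest),
  OR = (a/b)/(c/d), Wald CI `log OR ± 1.96·√(1/a+1/b+1/c+1/d)`,
  Yates-corrected χ² p-values, exclusion zones, seeded randomised-placement
  controls, and GWAS-vs-common SNP enrichment in transcript elements
  relative to introns;
- **tissue specificity** via the Tau index
  `τ = Σᵢ(1 − xᵢ/max(x))/(n − 1)` on log-transformed normalised counts;
- **aggregate metaplots** of CAGE/histone-mark peaks in ±5 kb around
  transcript 5' ends (counts normalised by transcript number),
  promoter-occupancy fractions, and **bidirectional-promoter** calling
  (5' extension by 500 bp, opposite-strand overlap);
- **allelic imbalance**: per-SNP exact binomial tests (≥ 30 reads) combined
  per transcript with Fisher's method, Benjamini–Hochberg FDR < 0.1, and the
  imbalance measure |0.5 − median allelic ratio|;
- a **seeded synthetic-study generator** that emulates every input with
  controllable ground truth (planted occupancy, specificity profiles,
  promoter-mark fractions, element odds ratios, allelic effects), so the
  whole pipeline is testable at desk scale.

Everything takes and returns tibbles and composes with the pipe; result
objects have `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
figures.

## Worked example

```r
library(haplotx)

cfg <- sim_config(seed = 42)            # 2 x 2-Mb genome, 20 index SNPs, 5 tissues
sim <- simulate_ld_panel(cfg)
blocks <- build_haploblocks(sim$proxies, sim$hotspots, main_rules())
head(blocks[, c("chrom", "start", "end", "index_snp_id", "left_rule", "right_rule")], 4)
#>   chrom  start    end index_snp_id left_rule    right_rule
#> 1 chr1  177003 198864 rs0001       proxy_extent proxy_extent
#> 2 chr1  357319 383765 rs0002       proxy_extent proxy_extent
#> 3 chr1  543231 559277 rs0003       proxy_extent proxy_extent
#> 4 chr1  718162 738977 rs0004       proxy_extent proxy_extent
```

Each block records how every boundary was set (`proxy_extent`, `hotspot`,
or `cap`). `run_pipeline()` chains all stages on the same synthetic study:

```r
res <- run_pipeline(cfg, n_rand = 10)
nrow(res$kept_blocks)                     # 18 blocks survive exclusion
covered_bases(res$capture) / 1e3          # 421 kb of capture space
nrow(res$retained)                        # 34 retained isoforms in 17 loci
res$occupancy$fraction_occupied           # 0.944 of blocks transcribed
res$specific$fraction                     # 0.706 of transcripts with tau > 0.8
res$promoter_occupancy$fraction           # 0.824 promoters with a CAGE peak

glance(res$tss_enrichment$result)
#>   odds_ratio log_or p_value alternative haldane
#> 1       360.   5.89       0 two.sided   FALSE

res$snp_enrichment[, c("class", "odds_ratio", "ci_low", "ci_high", "p_adj")]
#>   class     odds_ratio   ci_low ci_high  p_adj
#> 1 promoters       1.51 -0.00611   0.826 0.0342
#> 2 exons           1.91  0.142     1.15  0.0168
```

The TSS log OR of 5.89 recovers the planted CAGE signal (peaks at 60% of
transcript 5' ends against a sparse background); the element table shows
GWAS SNPs planted at two-fold odds in promoters/exons relative to introns,
with BH-adjusted one-sided χ² p-values. Allelic-imbalance calls live in
`res$allelic` (`ai_measure`, `q_value`, `imbalanced`), e.g. a planted
transcript with median ratio 0.771 gets ai_measure 0.271 at q ≈ 9e-15.

`autoplot(res$tau)`, `autoplot(res$profile)` and
`plot_enrichment(res$snp_enrichment)` draw the standard figures.

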