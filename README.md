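# mhcpop

Population-level analysis of MHC class IIB variation genotyped by
**pooled, population-tagged amplicon sequencing**, for studies asking
whether immune-gene polymorphism tracks local pathogen communities.

The package targets the common survey design in which DNA from 18–20
individuals per population is pooled, amplified with 5-bp
population-tagged primers over exon 2 of duplicated MHC class IIB loci,
and pyrosequenced alongside 16S rDNA of the local bacterial community,
with dominant neutral markers (AFLP-style) providing the neutral
baseline. Because pools lose individual genotypes, every downstream
analysis works on *presence–absence of true variants per population*.

## What it computes

1. **True-variant calling** (`filter_amplicons()`): demultiplexing by
   exact tag + near-exact primer match, truncation to a common read
   length (default 220 bp), collapse to unique variants, removal of
   artifactual variants — singletons, variants seen in fewer than two
   populations, frameshifted variants (any indel run whose length is not
   a multiple of 3 after global alignment to the reference exon), and
   unalignable sequences — yielding a populations × variants 0/1 matrix.
2. **Codon-level diversity and selection** (`site_diversity()`,
   `z_test_selection()`): per-codon amino-acid diversity
   `D = 1 / (20 Σ pᵢ²)` (0.05 = conserved, 1 = maximally diverse),
   percent polymorphic codons, and Nei–Gojobori pathway-counting
   dN/dS with Jukes–Cantor correction and a codon-bootstrap Z-test of
   positive selection, all partitioned into peptide-binding-region
   (PBR) versus non-PBR codons.
3. **Differentiation and isolation by distance** (`mantel_test()`,
   `partial_mantel_test()`, `dominant_fst()`,
   `neutral_slope_envelope()`): Euclidean presence–absence distances
   standardized to (d−d_min)/(d_max−d_min), Mantel and partial Mantel
   permutation tests with outlier-pair masking, Hardy–Weinberg Fst for
   dominant markers, and a resampled neutral envelope of IBD slopes.
4. **Community ecology** (`filter_records()`, `richness()`,
   `permanova()`): QC filtering of classified 16S records, pathogen
   flagging (Austin & Austin style list), species richness, and
   one-factor PERMANOVA.
5. **Association** (`fit_assoc()`, `assoc_grid()`): linear models of
   percent polymorphism against richness with ANOVA F-tests over the
   locus × codon-partition × richness-partition grid.
6. **Synthetic data with ground truth** (`sim_config()`,
   `simulate_allele_pool()`, `simulate_pool_reads()`,
   `simulate_aflp()`, `simulate_communities()`): a seeded generator
   emulating the whole design — selection-shaped allele pools,
   tag+primer reads with substitution/homopolymer/chimera errors,
   IBD-structured dominant markers, pathogen-bearing communities with a
   programmable richness–polymorphism coupling — so every step can be
   validated against known truth.

`run_pipeline()` chains all stages from one (YAML-able) seeded
configuration and writes a checksummed run manifest.

## Worked example

```r
library(mhcpop)

cfg     <- sim_config(seed = 1)                 # 9 pools x 19 fish, 20 alleles
alleles <- simulate_allele_pool(cfg)
sim     <- simulate_pool_reads(cfg, alleles)
ref     <- substr(sim$templates[[1]], 21, 20 + 3 * cfg$n_codons)

flt <- filter_amplicons(sim$reads, sim$pools, ref)
flt
#> Amplicon filtering result
#>   reads: 7200 (7200 assigned, 0 unassigned, 0 short)
#>   variants: 3676 -> 73 retained
#>   removed: singleton=3272, single_population=65, frameshift=177,
#>            unalignable=0, duplicate_after_trim=89

mask <- pbr_mask("locus1", cfg$n_codons, cfg$pbr_mask)
sel  <- selection_table(flt$alignment, mask, n_boot = 1000, seed = 7)
sel[, c("partition", "n_codons", "dN", "dS", "ratio", "Z", "P")]
#>   partition n_codons     dN     dS ratio     Z        P
#> 1   non-PBR       45 0.0610 0.3345 0.182 -6.46 1.00e+00
#> 2       PBR       10 0.2301 0.0343 6.709  3.86 5.67e-05
#> 3       all       55 0.0883 0.2703 0.327 -4.30 1.00e+00
```

The filter recovers every simulated true allele present in at least two
pools (3,676 raw variants shrink to 73 retained), and the Z-test flags
diversifying selection only at the PBR codons — exactly the structure
the generator programs (`omega_pbr = 5`, `omega_nonpbr = 0.2`): dN/dS
is 6.7 and highly significant at PBR codons, 0.18 (purifying) outside
them. Exact numbers vary with the seed.

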