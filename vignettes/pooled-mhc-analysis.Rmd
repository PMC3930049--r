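---
title: "Methods: pooled-amplicon MHC genotyping and pathogen-association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled-amplicon MHC genotyping and pathogen-association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, filtering rules, numerical choices
and known limitations behind `mhcpop`. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The study design the package models

The target design pools genomic DNA of 18–20 individuals per population
(nine populations by default), amplifies exon 2 of duplicated MHC class
IIB loci (55 or 58 codons) with population-specific 5-bp tagged primers,
and pyrosequences the pools together with 16S rDNA amplicons of the
local bacterial communities. Dominant neutral markers (AFLP-style 0/1
bands per individual) provide the neutral baseline for differentiation.
Pooling destroys individual genotypes and read counts are only
semi-quantitative, so every population-genetic statistic downstream of
filtering is computed on *presence–absence of variants per population*,
never on allele frequencies.

## True-variant calling (`filter_amplicons()`)

Stages, in order, with removal reasons recorded per variant:

1. **Demultiplexing.** A read is assigned to the unique pool whose tag
   matches the first five bases exactly and whose forward or reverse
   primer matches immediately downstream within `max_primer_mismatch`
   (default 1). Tags tolerate no mismatches: with 5-bp tags a single
   mismatch can reach another tag, so exact matching is the only safe
   rule. Reverse-primer hits are reverse-complemented into forward
   orientation before collapse.
2. **Truncation** to `L = 220` bases (shorter reads discarded, counted):
   equal lengths make exact string identity a well-defined variant
   relation.
3. **Collapse**: any single-base or indel difference separates variants;
   ids are assigned by total count (descending), then sequence
   (lexicographic), making the table deterministic.
4. **Abundance filter**: variants appearing only once (`singleton`) or
   in fewer than two populations (`single_population`) are removed as
   putative PCR/sequencing artifacts. "Appearing only once" is read
   globally — total count ≤ 1 across all pools — so one read in each of
   two pools is retained; the stricter per-pool reading (a count ≥ 2 in
   at least one pool) is available via `singleton_scope = "per_pool"`.
   Both reasons are logged, making the choice auditable.
5. **Frameshift screen**: each survivor is globally aligned to the
   in-frame reference exon (reference fully covered, variant flanks
   trimmed — this is where partial intron-like sequence is removed).
   Scoring: match +1, mismatch −1, a gap of length $L$ costs
   $4 + (L-1)$. Variants scoring below half the maximum attainable
   score are `unalignable`; variants with any indel run of length
   $\not\equiv 0 \pmod 3$ are `frameshift`. Survivors become a
   reference-anchored codon alignment (gap codons for 3k deletions;
   in-frame insertions are trimmed out of the projection).
6. **Post-trim deduplication.** Flank trimming can make distinct
   truncated variants identical within the exon (e.g. a homopolymer
   indel in the flank). Duplicates are merged into the highest-count
   representative (`duplicate_after_trim`), so retained true variants
   are unique exon sequences. Without this step, recurrent flank-indel
   classes would survive the abundance filter as spurious extra
   variants.

The reconstruction of exon trimming (reference-anchored pairwise
alignment) is a design decision: the original workflow aligned variants
in a multiple alignment before applying the frameshift rule, but left
its trimming procedure unspecified.

## Codon-level diversity and selection

**Per-site amino-acid diversity.** For each codon column,
$D = 1/(20\sum_i p_i^2)$ over the observed amino-acid frequencies
(gap codons excluded), so $D \in [0.05, 1]$. Because published non-PBR
means in this literature can fall below the statistic's floor of 0.05,
the package also emits $D_{\mathrm{rescaled}} = (D - 0.05)/0.95$, and
both scales are reported rather than silently choosing one.

**Nei–Gojobori dN/dS.** Potential synonymous sites per codon are the
per-position fractions of synonymous one-step changes (denominator 3;
changes to stop codons are never synonymous), averaged between the two
sequences of a pair. Observed synonymous/nonsynonymous differences are
averaged over all minimal mutational pathways between differing codons;
pathways through stop codons are excluded (if every pathway is blocked,
all are counted with stop steps scored nonsynonymous — a rare corner
retained for totality). Proportions receive the Jukes–Cantor correction
$d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$, undefined (flagged
saturated) at $p \ge 3/4$. Pairwise values are averaged over unordered
sequence pairs with equal weight; gap codons are skipped
pairwise-complete. The implementation is checked against an independent
exhaustive-pathway oracle to 1e-12 in the test suite.

**Z-test of selection.** $Z = (d_N - d_S)/SE$ per codon partition
(PBR / non-PBR / all), with $SE$ from a seeded codon bootstrap
(default 1000 resamples; the variance method of the original analysis
tool is unstated, and the codon bootstrap is that tool's default
approach). The p-value is the upper normal tail (one-tailed for
positive selection). Identical sequences yield $Z = 0$, $P = 1$;
partitions under 3 codons are refused as bootstrap-degenerate.

**Polymorphism.** A codon is polymorphic iff ≥ 2 distinct amino acids
occur — amino acids, not codons, consistent with "polymorphic amino
acid sites". Per-population values restrict the alignment to the
variants present in that population (the published per-population
ranges imply this subsetting without stating it).

## Differentiation and isolation by distance

Euclidean distances between population presence–absence profiles are
standardized by $(d - d_{\min})/(d_{\max} - d_{\min})$ over the
off-diagonal cells, so the endpoints 0 and 1 are attained exactly and
the map is idempotent.

The Mantel statistic is the Pearson correlation over the
$n(n-1)/2$ pairs; the null permutes rows/columns of the first matrix
simultaneously; p-values use the add-one convention
$(\#\{R^\ast \ge R\} + 1)/(n_{\mathrm{perm}} + 1)$ (never exactly
zero), one-tailed for positive association by default (the directional
IBD usage), two-tailed by flag. The partial Mantel uses the first-order
partial-correlation formula with permutation of the first matrix (the
named test has several variants; a residual-permutation alternative is
provided). Outlier population pairs can be masked (`drop_pairs()`);
masked cells are excluded from the statistic, and permutations are
evaluated over the same fixed cell positions — an approximation chosen
for determinism, since the original handling of removed pairs under
permutation is not described.

**Dominant-marker Fst.** Under Hardy–Weinberg equilibrium the
band-absence allele has frequency $\hat q = \sqrt{1 - f}$ with $f$ the
band frequency. Per locus, pairwise Fst is the between-population
variance of $\hat q$ over $\bar q(1 - \bar q)$; multilocus Fst is the
ratio of averages across loci, truncated at 0. No estimator is
prescribed for dominant data in the emulated analysis; this Nei-style
choice keeps the fixation case (band frequencies 0 vs 1) at exactly 1.

**Neutral slope envelope.** Repeated random subsets of loci (size a
required argument — the original subset size is unstated) yield a
distribution of Fst-versus-distance regression slopes and $R^2$;
`envelope_verdict()` flags whether an observed MHC slope or $R^2$ lies
inside. Degenerate draws are discarded, logged, and redrawn.

*Known bias:* at weak differentiation the $\sqrt{\cdot}$ transform and
finite sampling (≈19 individuals per population) inflate estimated
slopes slightly upward relative to the truth-frequency slope, so at the
generator's weak default slope the envelope can sit just above the
realized value; at clearly non-zero programmed slopes the envelope
brackets the realized slope in ≥ 90% of seeds (verified in the test
suite at 100 subsets × 200 loci over 50 seeds).

## Community ecology and association

16S records are kept if read length ≥ 200 bases (the value used for the
published classification results; the 250-bp expected amplicon size is
available by argument — both thresholds appear in the source analysis,
so both are supported and documented) and assignment bootstrap ≥ 0.5.
"Unclassified X" taxa are distinct units keyed by their lowest assigned
rank. Pathogens are flagged by case-insensitive exact match against a
configurable list defaulting to the seven-taxon fish-pathogen set
(Austin & Austin style). Richness is the count of present taxa per
population and partition.

PERMANOVA uses the distance-based one-factor decomposition
($SS_T = \sum d^2/N$ over pairs) with pseudo-F
$(SS_B/(a-1))/(SS_W/(N-a))$ and label permutation; Bray–Curtis is the
default dissimilarity (the source analysis names none; Euclidean and
Jaccard are selectable through `community_dissimilarity()`). The
replication unit is generic over samples: with one community sample per
population a populations-as-factor test is degenerate (within-group df
0) and is refused rather than faked.

Association tests are ordinary simple regressions of percent
polymorphism on richness with ANOVA F (df 1 and $n-2$), reported over
the full locus × codon-partition × richness-partition grid. No
multiple-testing correction is applied across cells, matching the
customary presentation; a Bonferroni column is emitted for
transparency.

## The synthetic-data generator

The generator exists so that every pipeline stage can be validated
against known truth; its defaults are fixed once to the emulated study
conditions and are not tuned per test.

* **Alleles.** `n_alleles_global = 20` alleles arise from a common
  stop-free ancestor by codon mutation events
  (Poisson, `mut_per_codon = 0.4` per allele lineage). A proposed
  single-nucleotide change is rejected if it creates a stop; otherwise
  a nonsynonymous proposal is accepted with probability
  $\min(1, \omega)$ and a synonymous one with $\min(1, 1/\omega)$,
  where $\omega$ is `omega_pbr` (default 5) inside the PBR mask and
  `omega_nonpbr` (default 0.2) outside. $\omega = 1$ is exactly
  neutral; $\omega = 0$ freezes a partition entirely (with both
  partitions frozen all alleles equal the ancestor — a degenerate
  control, for which uniqueness is not enforced). This acceptance
  scheme is the package's own construction: it yields the required
  PBR/non-PBR diversity contrast, a neutral $\omega = 1$ calibration
  point, and a literal frozen control.
* **Reads.** 800 reads per pool (≈ 7,200 total, the scale of the
  emulated survey; ≈ 40 reads per allele per pool, comfortably above
  the ≥ 30 reads/allele condition the recovery guarantees assume).
  Templates are 276-bp inserts — 20-bp 5′ flank, exon, 3′ flank —
  behind a 5-bp tag and 20-bp primer, so truncation to 220 keeps the
  full exon plus partial intron-like flank. Errors: substitutions at
  0.002/base, one-base indels at 0.01 per homopolymer run (length ≥ 2,
  the dominant 454 error mode), chimeras at 0.01 (5′ of one allele
  joined to 3′ of another at a uniform breakpoint). These rates are
  design choices (no rates are published for the emulated run), set so
  artifact variants are overwhelmingly singletons, which is what makes
  the singleton filter meaningful and testable.
* **Pools.** Each population gets a symmetric-Dirichlet frequency
  vector over the global allele pool; 19 individuals draw 2 alleles
  each; reads sample the pooled copies. Only pool-level truth is
  guaranteed, as in the real design.
* **AFLP.** 500 dominant loci (the spec-scale example size; the real
  survey's 1,665 is a scale, not a requirement). Per-locus recessive
  frequencies receive a spatially autocorrelated Gaussian deviation
  (exponential covariance, range 50 km) whose scale is solved from
  `ibd_slope_target` (default 5e-4 Fst/km, a weak but realistic
  riverine cline); individuals are sampled under HWE. The truth records
  the realized slope computed from the true frequencies.
* **Communities.** 80 taxa, 9% pathogenic — seven pathogen taxa, named
  after the default pathogen list so the community filter flags them
  directly. Pathogen richness per population follows
  $S_i = \mathrm{clamp}(\mathrm{round}(1.5 + b\,z_i + \varepsilon_i),
  0, n_{\mathrm{path}})$ with $\varepsilon \sim N(0,1)$, so
  `assoc_effect` $b$ programs a latent population
  $R^2 = b^2/(b^2+1)$ ($b = 2 \Rightarrow R^2 = 0.8$) and $b = 0$ gives
  exact independence. The defaults span pathogen richness ≈ 0–3, the
  range of the emulated survey. Nonpathogen taxa follow an
  occupancy/abundance model independent of the covariate.
* **Determinism.** One master seed; every generator derives a fixed
  per-operation sub-stream, so a seed fixes every output byte and
  stage-level re-runs reproduce pipeline-level results.

### What passing tests do and do not show

The generator emulates the *statistical structure* of the design:
selection-shaped codon diversity, tag/primer read anatomy, the three
454-typical error modes, spatially structured neutral markers, sparse
pathogen communities. It does not emulate flowgram-level 454 noise,
quality scores, primer-binding biases, within-individual copy-number
variation, PCR abundance distortions beyond the semiquantitative
caveat, or real taxonomic assignment uncertainty. Recovery and
calibration results on synthetic data therefore validate the
*algorithms* under the stated error model, not the wet-lab performance
of any particular sequencing run. One realistic limitation is visible
in the tests: a one-base indel within ~2 bases of the exon boundary can
be absorbed by the aligner as terminal mismatches rather than a gap,
letting rare recurrent indel classes masquerade as substitution
variants — exactly the kind of artifact that pooled designs cannot
fully exclude.

## Problem sizes used in the automated checks

The test suite and acceptance script run the full default study scale
(9 pools × 800 reads) once, and use reduced scales elsewhere (fewer
pools/alleles, 99–999 permutations, 100–300 bootstrap resamples,
10–100 envelope subsets) chosen as the smallest sizes at which the
checked properties are stable; calibration checks use 200–1000
replicates as stated in each test.
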