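---
title: "Methods: mapping a young sex-linked region and its pericentromeric context"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping a young sex-linked region and its pericentromeric context}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`slrscape` maps a *young* sex-linked region (SLR) — one whose X and Y are
still ~99% identical — and characterizes the pericentromeric heterochromatin
(PCH) it sits in. This vignette is the package's own account of the models
and procedures, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
choices and limitations a maintainer should know about. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The inference problem

In an XY system that stopped recombining only recently, the Y has not
degenerated: gene content, order, and even sequence are nearly identical to
the X. What distinguishes the non-recombining region is *co-segregation with
sex*: every variant fixed on the Y since recombination stopped is carried
heterozygously by every male and by no female. The package's mapping logic
builds on that signature and corroborates it with population
differentiation, X–Y divergence, satellite/centromere context, chromatin
state, and gonadal expression.

## Sex-linkage scanning

**Sex-specific SNPs.** `call_sex_specific_snps()` keeps a site when every
non-missing male is heterozygous and every non-missing female is homozygous
for the same allele (the female-specific mode is symmetric for ZW systems).
The "all" quantifier is deliberate: with 10 + 10 individuals, requiring full
penetrance reduces the background acceptance probability of a
Hardy–Weinberg site to at most `(2pq)^10 (p^20 + q^20)` (≈ 9.6e-7 at
p = 0.5), so false positives are isolated single windows, handled by the
demarcation step. Sites with more than 20% missing genotypes are excluded.

**Windowing and demarcation.** Selected sites are counted in 50-kb tiling
windows; `demarcate_slr()` marks windows with at least `min_count = 3` sites
and merges marked runs across gaps of at most `max_gap_windows = 5`,
reporting the longest merged run as the SLR and its chromosome complement as
pseudoautosomal. Neither constant is a published value: at the generator's
~1 SNP/kb design density a true SLR window carries ~50 sites and a
background window essentially none, so the call is insensitive to both
constants over a wide range (3 keeps isolated false positives out; 5
bridges the occasional window diluted by missingness or assembly gaps).

**F<sub>ST</sub> and association.** `window_fst()` computes a Hudson-type
ratio of averages per window, `1 − mean(H_w)/mean(H_b)`, with
sample-size-corrected within-sex heterozygosities (`2pq · 2n/(2n−1)`) and
`H_b = p_m(1−p_f) + p_f(1−p_m)`; windows with fewer than 40 variants are
missing, mirroring the filter used for the published windowed
F<sub>ST</sub>. Ratio-of-averages (rather than average-of-ratios) keeps the
estimator stable in windows containing low-frequency variants. Note that at
a male-specific site p_m = 0.5 and p_f = 0, so windowed F<sub>ST</sub>
plateaus near 0.5 inside an XY SLR — maximal differentiation (1.0) only
arises at fixed differences between groups. `assoc_scan()` replaces
mixed-model association machinery with a two-sided exact hypergeometric test
on the per-site 2×2 allele-count table. This is a deliberate design
decision: the scan's only role here is to localize a fully penetrant region,
synthetic data have no population structure or kinship to correct for, and
the exact test has a closed-form null that the test suite verifies against
an independent enumeration oracle to 1e-9.

## X–Y divergence and evolutionary strata

`xy_window_similarity()` assumes coordinate-matched, collinear haplotypes
(no aligner, no indel handling; for real data a whole-genome alignment must
be applied first — the synthetic haplotypes are collinear by construction,
as are the published ones, which show no large-scale inversions). Similarity
is computed per 100-kb window over intron-masked positions only; windows
with under 1 kb of compared intronic bases are missing. Introns are the
natural comparison set: coding positions are shaped by selection, and
intergenic sequence in these regions is repeat-dense.

`segment_strata()` performs an exhaustive single-changepoint search over the
SLR's windowed divergence (1 − similarity), minimizing the pooled
within-segment sum of squared deviations with a two-window minimum segment.
The two segments are compared with a two-sided Wilcoxon rank-sum test
(exact for small samples without ties, normal approximation with tie
correction otherwise).

A numerical-soundness choice worth explaining: because the changepoint is
itself chosen to maximize the between-segment contrast, the raw Wilcoxon p
is anti-conservative under a constant-divergence null — in 200 null
simulations the naive rule "two strata iff Wilcoxon p < 0.05" fired 33.5% of
the time. `segment_strata()` therefore also computes `selection_p`, a
permutation calibration: window values are permuted 500 times (fixed
internal seed; the caller's RNG stream is untouched), the changepoint search
is re-run on each permutation, and `selection_p` is the fraction of
permutations whose optimized Wilcoxon p is at least as extreme. Two strata
are reported only when both the raw Wilcoxon p (the conventional quantity,
still reported) and `selection_p` fall below `alpha = 0.05`. Under the null
this brings the false-positive rate to the nominal level (~3% measured over
100 seeds); with the planted 1.2%/0.8% contrast the decision is unambiguous
(p ≈ 1e-16).

## Satellite detection and karyotype

`find_tandem_arrays()` is a self-contained reimplementation of
tandem-repeat detection: for each candidate period *p* (default 10–2000 bp,
the cap mirroring the published repeat-finder parameter string) the sequence
is compared with itself shifted by *p*; window starts whose *p*-wide
mismatch fraction is ≤ `max_mismatch = 0.2` are marked, marked starts with
overlapping 2*p* spans are coalesced, and each stretch is trimmed until its
overall mismatch fraction meets the tolerance. Ascending period order plus a
coverage check (skip a candidate if >50% covered by an accepted
smaller-period array) suppresses harmonics, so a period-*k* array is
reported at its fundamental period. Arrays shorter than
`max(2 periods, min_len = 50 bp)` are suppressed: the 50-bp floor plays the
role of a minimum alignment score — without it, two-copy matches at short
periods arise by chance in random sequence at ~4e-4 per position.
The detector is quadratic in (sequence length × period range); it is meant
for assembled chromosomes and was validated against a brute-force
all-period oracle on short sequences.

Monomers are canonicalized as the lexicographic minimum over all rotations
of the monomer and of its reverse complement, making family assignment
invariant to array phase and strand. `build_families()` merges arrays whose
canonical monomers are within 10% in length and ≥80% identical over
rotations, ranking families by total genomic span. `classify_families()`
then labels a family **centromeric** when on ≥70% of the chromosomes
carrying it the family forms exactly one cluster (loci merged across gaps
≤ 500 kb) and that cluster is interior (>200 kb from both ends) on at least
one metacentric/submetacentric chromosome, and **telomere-associated** when
≥90% of its clusters lie within 200 kb of a chromosome end. The thresholds
are this package's own — published results describe the patterns
qualitatively ("a single locus per chromosome", "exclusively at the ends")
— and all four constants are exposed as arguments; the margins should be
scaled down together with chromosome size on small test genomes.
Centromeres are the span of the centromeric family's single cluster per
chromosome (largest cluster on ties, flagged; chromosomes without a cluster
flagged unresolved, as expected for incompletely assembled centromeres).
Morphology follows the Levan arm-ratio convention collapsed to three
classes: metacentric (long/short ≤ 1.7), submetacentric (≤ 3.0, boundary
inclusive), telocentric (> 3.0), with the short arm floored at 1 bp so a
terminal centromere gives a finite ratio.

## k-mer genome profiling

`count_kmers()` counts canonical k-mers (the lexicographic minimum of a
k-mer and its reverse complement) across all read windows, using a 2-bit
packed code per window computed by a moving weighted sum; k ≤ 26 keeps
codes exact in doubles. `fit_spectrum()` models the multiplicity histogram
`h(m)` as an error component below a valley plus a homozygous-coverage
peak: the valley is the first local minimum of the 3-point-smoothed
histogram, the error mass is `E = Σ_{m<valley} m·h(m)`, and

* `error_rate = 1 − (1 − E/T)^(1/k)` (a k-mer instance is error-free iff
  all k bases are correct), and
* `genome_size = (T − E) / hom_coverage`.

The homozygous coverage is located robustly: the mode `m0` of the smoothed
`m·h(m)` above the valley seeds a window `[valley, 2·m0]`, and
`hom_coverage` is the mean multiplicity over that window. On a clean
spectrum this equals the peak position exactly (the package's worked
examples are unchanged), but it is far more stable on desk-scale
simulations, where coverage is correlated over read-length blocks and the
histogram shape has only ~(genome/read length) effective degrees of freedom:
a raw argmax wanders several bins and biases the genome size by 5–10%,
while the windowed mean lands within ~1%. The upper cut at `2·m0` keeps
high-multiplicity repeat k-mers (satellite arrays) out of the mean.
Heterozygosity is *not* modeled — the estimator targets the homozygous peak
of haploid (or effectively homozygous) input — and k = 21 is used
throughout the tests instead of the very large k the published analysis
could afford; all formulas are k-parametric.

## PCH, peaks and Hi-C

`repeat_content_track()` reports the fraction of bases covered by ≥1 repeat
interval per 50-kb window (overlaps collapsed via `IRanges`).
`call_pch()` marks windows strictly above `threshold = 0.40` — the only
explicit per-window rule in the source material; the >50% vs <16% contrast
is used as a generator calibration, not a calling rule — and merges marked
runs across ≤5-window gaps into blocks annotated with centromere
containment. `peak_enrichment()` filters peaks at −log10 p strictly greater
than 8, then contrasts the fraction of surviving peak *midpoints* inside
PCH with the PCH fraction of the genome (peak counts, not bp; membership by
midpoint).

`balance_matrix()` uses symmetric iterative proportional scaling
(`A ← D A D`, `d_i = sqrt(target/rowsum_i)`) after masking zero-sum bins;
for positive matrices this has the same doubly-stochastic-up-to-scale fixed
point as Knight–Ruiz balancing and is simpler to reason about and test
(tolerance 1e-6 on relative row sums, 1000-iteration cap with a warning and
flag on non-convergence). `oe_pearson_pc1()` aggregates the balanced matrix
to 250-kb bins, divides each entry by its diagonal (distance) mean — the
expected-value model is the per-diagonal mean with no smoothing, the
simplest consistent choice — computes the Pearson correlation matrix of the
O/E columns, and takes the leading eigenvector of the column-centered
correlation matrix by power iteration (tolerance 1e-8, deterministic ramp
start; verified against a dense eigendecomposition at cosine ≥ 0.999). The
unit eigenvector is scaled by the PC1 standard deviation so that
structureless matrices produce near-zero entries, and its sign is oriented
so PC1 correlates positively with gene density: positive = active A
compartment, negative = silenced B. Constant or empty O/E columns are
excluded and reported as missing.

`distance_stratified_contacts()` keeps bin pairs with balanced counts
strictly above 10, classifies them PCH–PCH or nonPCH–nonPCH by bin-midpoint
membership (mixed pairs dropped), reports mean contact per log2-distance
stratum and class, and pools a two-sided Wilcoxon rank-sum test over the
strata where both classes are populated — distance-matched pooling, since
contact frequency is dominated by distance. `pch_size_correlation()` is a
plain Pearson correlation (two-sided t test) between per-chromosome PCH bp
and chromosome length.

## Expression

`tpm()` is the standard within-sample length-normalized unit (columns sum
to 1e6 exactly). `tau()` uses the standard tissue-specificity definition on
group means of `log2(TPM+1)`; the log damping is the common convention and
keeps tau stable when one group is extreme. `screen_candidates()` encodes
the two patterns of interest: *testis-exclusive* (group mean TPM > 1 in
testis, ≤ 1 everywhere else) and *testis + early-intersex with ovary
depletion* (expressed in both, each ≥ 4× the ovary mean, testis and early
intersex within 2-fold of each other). The 4-fold and 2-fold constants are
this package's quantification of a qualitative description ("much lower
level", "similar level") and are arguments. Early intersex means stages
I1–I3 when stage labels exist, else the whole intersex group.
`pch_expression_compare()` contrasts PCH and non-PCH genes (midpoint
membership) on proportion expressed (TPM > 1), median TPM and median tau,
with two-sided Wilcoxon tests.

## The synthetic generator: what it emulates, and what it does not

`gen_genome()` plants, with recorded truth: a karyotype in the study's
5:3:16 morphology proportions; one centromeric satellite array per
chromosome (interior on meta/submetacentrics, terminal on telocentrics;
100 × 524-bp copies ≈ 52 kb, matching the ~50-kb scale of assembled
centromeres); telomere-associated arrays at chromosome ends (50 × 190-bp
copies — kept modest because the real arrays are largely unassembled, and
much larger planted arrays would create subtelomeric repeat blocks the
assembly-based analysis does not show) plus (TTAGGG)n termini; PCH blocks
~ Normal(4.2 Mb, 0.5 Mb) truncated above 1 Mb, centered on the centromere
and shifted to fit; an alternating repeat/gap renewal process hitting 55%
repeat coverage inside PCH and 15% outside (renewal rather than Poisson
placement, so window-level coverage concentrates tightly on the target);
and gene models at ~1 gene per 50 kb with 3–8 exons. On the sex chromosome
the Y haplotype is the X with per-base substitutions at 1.2% (17–20 Mb) and
0.8% (20–24 Mb); the ends are untouched, so both PARs fall out by
construction, and the centromere sits inside the SLR at 35% of its span so
the higher-divergence stratum contains it.

Gene spacing is uniform along the chromosome: the gene-rich stratum of the
real system carries ~1 gene per 45 kb *despite* spanning the
centromere/PCH, and uniform spacing keeps 100-kb similarity windows
populated on both sides of the strata boundary. The generator therefore
does **not** emulate the lower gene density of autosomal PCH — a known
limitation that matters only for the missingness pattern of similarity
windows and for PCH-gene counts in the expression contrast.

`gen_population_genotypes()` makes every genotypable planted X–Y site
heterozygous in all males and homozygous-reference in all females, and
draws background sites under Hardy–Weinberg at p ~ U(0.05, 0.95) with ~1
site/kb. In sequence mode the genotypable sites are *all* realized X–Y
substitutions; in track-only mode they are drawn at `snp_density` (1/kb, a
configurable placeholder — the real data's SNP density is not published).
`gen_kmer_reads()` samples forward-strand reads uniformly with i.i.d.
substitution errors (canonical k-mer counting is strand-symmetric, so
simulating strands would only exercise the canonicalizer twice).
`gen_epigenome()` places peaks at a 4:1 density ratio inside vs outside PCH
and builds contact matrices as `base · (d+1)^(−1)` with a 2× multiplicative
elevation for PCH–PCH pairs, an alternating-block compartment checkerboard
(±30%) outside PCH, and Poisson noise (a `noise = "none"` mode exposes the
exact expectations for closed-form tests). `gen_expression()` draws
negative-binomial counts whose expectations scale with exonic length (so
TPM recovers planted levels), silences ~30% of genes, plants one
testis-exclusive and one testis+early-intersex SLR gene, and optionally
elevates PCH genes (the null `pch_boost = 1` makes the classes
exchangeable for calibration tests).

What passing tests on this generator do **not** show about real data:
no indels or structural variants (the similarity module is coordinate-matched
by design), no population structure or kinship (the exact association test
is sufficient here; it is not a general GWAS replacement), no read-level
Hi-C simulation (matrices are drawn at the binned level), no
sequencing-quality modeling, and satellite monomers are random sequences
with the published lengths, not the published consensus sequences (which
are not reproduced in the text).

## Problem sizes, determinism and degenerate inputs

Everything is deterministic given a seed: the generator consumes a single
seeded stream per bundle, per-module offsets separate the genotype,
epigenome and expression draws, and the permutation calibration inside
`segment_strata()` runs under a temporarily swapped RNG state so callers'
streams are unaffected. The test suite runs the full-scale acceptance
checks (27.9-Mb chromosome scans, a 1-Mb/40× k-mer simulation, the
24-chromosome ~600-Mb track-only genome) once each, and exercises
multi-seed invariants at reduced sizes chosen for a fast default test run
(0.5-Mb k-mer genomes over 3 seeds, 2 seeds of the chromosome-scale SLR
scan, 20-seed null calibrations on small tracks); the sizes are the
package's own choice of desk-scale problem and are stated in the tests.

Degenerate inputs are handled explicitly: unimodal k-mer histograms raise
an error directing to `error_free = TRUE`; empty repeat sets, peak sets
below the score filter, all-missing genotype sites, monomorphic windows,
zero-sum Hi-C bins, constant O/E columns, silent genes and empty PCH/non-PCH
classes all produce missing values or skip notes rather than failures; ties
in centromere clusters pick the larger span and raise a flag; and the
morphology boundary at arm ratio 3.0 is submetacentric (inclusive).

## Orchestration

`run_pipeline()` runs simulate → sexscan → strata → satellites → k-mer →
PCH/Hi-C → expression on a single `generator_config`, skipping
sequence-dependent stages with a note on track-only input. Every stage
threshold can be overridden through a module-qualified `params` list (one
auditable place for every constant), outputs land under `outdir` in the
standard formats (FASTA, GFF3, BED/bedGraph, VCF v4.2, 3-column contact
text + JSON sidecar, TSV, JSON report), and rerunning a config reproduces
the report exactly. The package's interface is its R functions plus
`scripts/acceptance.R`; no shell entry point is shipped.
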