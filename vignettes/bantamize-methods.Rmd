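---
title: "Mapping a crossbred dwarf phenotype: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a crossbred dwarf phenotype: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`bantamize` reconstructs the inference chain used to dissect the bantam
(dwarf) phenotype in crossbred chicken populations: group-stratified
mixed-model association scans, a fixed-effects meta-analysis with
heterogeneity testing, windowed Weir–Cockerham $F_{ST}$, relative
identity-by-descent (rIBD) introgression mapping, and haplotype-level
phylogenetics. Because the original whole-genome panels are not required
to exercise the methods, the package ships a forward simulator of the
*bantamization* crossbreeding design whose output feeds every downstream
stage. This vignette documents the models, the tunable parameters, and
the design decisions that were genuinely open.

## The crossbreeding design and its simulator

A *neo-bantam* breed is created by crossing a normal-sized breed (the
*counterpart*) with an existing true-bantam breed (the *source*), then
repeatedly backcrossing carriers of the dwarf phenotype to the
counterpart while selecting for bantam stature, and finally breeding the
miniature line within itself. The simulator reproduces this pedigree
explicitly, per group of (source, counterpart, neo-bantam) breeds:

1. **Founders.** Per site, an ancestral allele frequency $p$ is drawn
   from a Beta distribution (default Beta(0.5, 0.5), favouring
   intermediate spectra after the MAF filter). Each breed's frequency is
   drawn from the Balding–Nichols distribution
   $\mathrm{Beta}\!\left(p\frac{1-F}{F},\,(1-p)\frac{1-F}{F}\right)$
   with per-breed drift $F$ (default 0.2, which yields pairwise
   $F_{ST}$ between unrelated breeds in the 0.1–0.25 range typical of
   traditional fancy breeds). Founder haplotypes are independent
   Bernoulli draws at the breed frequency.
2. **Causal loci.** Each group selects at one bi-allelic locus; groups 1
   and 2 share the same position and allele, group 3 carries a private
   locus on another chromosome. The causal allele is planted at
   frequency 1 in the source and 0 in the counterpart. Within a
   *sweep radius* (default 50 kb) every source haplotype is replaced by
   a copy of one founder haplotype. This local monomorphism is the
   imprint historical selection leaves around a breed-defining allele —
   without it a founder model with site-independent draws has no
   within-breed haplotype sharing at all, and no IBD-based statistic
   could see introgression. The ancestral frequency at causal sites is
   pinned at 1/2 so breeds outside the target group stay polymorphic
   there, keeping all three studies informative at every causal locus.
3. **Cross.** F1 = source × counterpart; each of $g$ backcross
   generations (default 4) mates causal-allele carriers to counterpart
   founders; selection is truncation on the causal genotype, which under
   a fully penetrant major locus is equivalent to the breeder's
   phenotypic selection. Two final generations of carrier-by-carrier
   intercrossing emulate the within-line matings that consolidated the
   neo-bantam breeds; the cohort is drawn homozygote-first
   (`selection_mode = "homozygote_preferred"`) because a recognised
   breed is (nearly) true-breeding for its defining allele. The
   intercross stage leaves the expected neutral source-genome fraction
   at $(1/2)^{g+1}$.
4. **Meiosis.** Haldane model: crossover counts are Poisson with mean
   the map length in Morgans, positions uniform in cM, no interference.
   The default map is a constant 3 cM/Mb; a user map file with
   (bp, cM) knots is accepted with linear interpolation. Chromosomes
   are 5 Mb — microchromosome-sized, but the macrochromosome-typical
   rate is retained so that hitchhiking around the selected locus
   behaves like a real macrochromosome interval. (Raising the rate to
   microchromosome levels fragments the introgressed block itself and
   is scientifically defensible only with correspondingly denser maps.)
5. **Truth tracks.** Every neo-bantam haplotype carries an ancestry
   interval list (source vs counterpart, 0-based half-open, tiling each
   chromosome exactly), emitted as BED; it is the reference for
   validating the rIBD scan and the ancestry-dilution expectation.

The crossed parents are the *sampled* founder cohorts themselves: breed
pools are small and the birds used for bantamization were birds of those
breeds. This matters — it is what makes neo-bantam haplotypes exact
mosaics of sampled source/counterpart haplotypes, so the IBD detector
can trace them.

What the simulator deliberately does not model: coalescent founder
genealogies (within-breed background haplotype sharing exists *only* at
swept regions), sequencing errors and genotype uncertainty, mutation,
polygenic background for stature (a liability phenotype model is
provided but off by default), and overlapping generations. Tests passing
on these data therefore demonstrate correctness of the statistical
machinery and recoverability of the designed signal, not robustness to
every artefact of real sequence data.

## Quality control

The QC cascade masks genotypes with depth outside [3, 100], then drops
sites with quality ≤ 10, call rate ≤ 0.8 (recomputed after masking),
mean depth outside [3, 100], and finally minor allele frequency
< 0.05 on non-missing alleles (a MAF of exactly 0.05 survives).
Genotype-depth masking precedes the call-rate computation, mirroring
VCFtools semantics where per-genotype filters feed site filters. The
report attributes each dropped site to the first rule it violates in
cascade order; a site that fails call rate only because of masking is
attributed to the genotype-depth rule, which keeps the per-rule counts
causally meaningful. Multi-allelic records are split into one record per
alternative allele, each with a distinct identifier, genotypes recoded
with other alternatives counted as reference-class.

## Mixed-model association

Each group is a case-control panel (bantam-sized = 1), analysed as a
quantitative trait in
$y = W\alpha + x\beta + u + \varepsilon$, $u \sim N(0, \sigma_g^2 K)$,
with $K$ the IBS similarity matrix — the same matrix later converted to
the 1-IBS distances for trees, so relatedness enters every analysis on
one scale. $K$ is eigendecomposed once; the restricted likelihood is
profiled over the variance ratio $\lambda = \sigma_g^2/\sigma_e^2$ on a
log-spaced grid over $[10^{-5}, 10^5]$ with golden-section refinement,
ties resolved toward the smaller ratio. Per-variant tests reuse the null
ratio by default (the EMMAX-style approximation; an `"exact"` mode
re-profiles per variant) and refer the Wald statistic $(\beta/se)^2$ to
$\chi^2_1$. Missing dosages are mean-imputed; monomorphic variants are
reported `NA` with a reason. The residual variance is floored at
$10^{-12}$ of the phenotypic scale so an exactly phenotype-collinear
variant yields a finite, extreme statistic instead of a zero standard
error — at desk scale, fully penetrant major loci otherwise produce
degenerate rows that would silently drop out of the meta-analysis.
Genomic control is
$\lambda_{GC} = \mathrm{median}(\chi^2_{obs}) / 0.4549$.

## Meta-analysis

Classical inverse-variance fixed effects: $w_i = 1/se_i^2$,
$\hat\beta = \sum w_i\beta_i/\sum w_i$, $\hat{se} = (\sum w_i)^{-1/2}$,
two-sided normal $p$. Genomic control is applied per input study (and
only when $\lambda_{GC} > 1$), not to the combined statistic — the
documented behaviour of the standard meta-analysis tools this follows.
Variants are matched on position with allele alignment; a ref/alt swap
flips the effect sign, anything else is excluded. Heterogeneity is
Cochran's $Q = \sum w_i(\beta_i - \hat\beta)^2$ on $k-1$ df with
$I^2 = \max(0, (Q - (k-1))/Q)$ and a per-study direction string.
Single-study variants are reported but excluded from the shared-variant
heterogeneity summary.

## $F_{ST}$ and rIBD

Per-site Weir–Cockerham variance components $a$, $b$, $c$ are computed
with the full unequal-sample-size corrections; windows of 10 kb
(0-based half-open, anchored at 0) aggregate by the ratio of sums
$\sum a / \sum(a+b+c)$ over informative sites — exactly the weighted
windowed estimator VCFtools reports, and distinct from averaging
per-site ratios.

IBD detection is a deterministic identity-run scan: for every
inter-cohort haplotype pair, maximal runs of allele identity containing
at most one mismatch are reported when their genetic length reaches a
threshold. The probabilistic LOD machinery of phased-panel detectors is
intentionally not re-implemented: the downstream statistic consumes
segments, not detector internals, and segment files from external
detectors are accepted directly. The default length threshold is
0.03 cM (appropriate at sequence density); the simulation study passes
0.15 cM because at its ~2 kb site spacing shorter runs arise by chance.

Per 10-kb window and cohort pair $X \leftrightarrow N$ (neo-bantams),
cIBD counts haplotype pairs sharing at least one segment overlapping
the window (pair-counting bounds nIBD = cIBD/tIBD at 1, which
segment-counting would not guarantee), tIBD $= 4 n_X n_N$, and
$\mathrm{rIBD} = \mathrm{nIBD}_{source,neo} -
\mathrm{nIBD}_{counterpart,neo}$: positive where neo-bantam haplotypes
resemble the bantam source more than their own normal-sized
counterpart. Windows partially overlapped by a segment count as
overlapped. When a causal region is *completely* introgressed the
neo-vs-source comparison can be monomorphic and identical throughout —
no informative site — which the study summaries report as zero
differentiation rather than missing.

## Haplotype phylogenetics

Blocks of ±1 kb (configurable) around a lead variant are extracted from
phased haplotypes; $r^2$ against the lead is computed from haplotype
frequencies, not genotype correlations. Haplotype and sample trees are
neighbor-joining on 1-IBS distances (negative branch lengths clamped to
zero), and the "PhyloGWAS" view — PCA and NJ restricted to significant
variants — tests whether samples cluster by phenotype rather than by
overall relatedness, using the same variant scaling
$\sqrt{2p(1-p)}$ as the genome-wide PCA.

## Annotation

Positional only: a variant is assigned to every gene whose interval
extended by 1 kb on both sides contains it; the flank is
strand-symmetric because a fixed promoter-sized window is applied on
both sides. Consequence prediction (missense classes etc.) is out of
scope. Overlap summaries count elements shared by exactly/at least $k$
of the named analyses; a gene is "hit" when at least one significant
variant is assigned to it.

## The simulation study and its problem sizes

The packaged study (`bantam_replicate_study()`) runs 20 independent
replicates of: 3 groups × (10 source + 10 counterpart + 10 neo-bantam),
genome of 3 × 5 Mb with 2400 sites per chromosome, $g = 4$ backcrosses,
2 intercross generations, causal loci at the chr1 midpoint (groups 1–2,
shared) and chr2 midpoint (group 3, private). Each replicate runs the
three group scans, the meta-analysis, and the per-group F_ST and rIBD
scans, and records: whether every scan's minimal-$p$ variant lies
within 50 kb of its causal locus; whether the meta $p$ at the shared
locus is at most the smallest per-group $p$; whether heterogeneity
$p < 0.05$ at the private locus; whether mean rIBD in the 100-kb causal
region is positive and at or above the genome-wide 99th percentile of
window rIBD; and whether genome-wide mean
$F_{ST}(\text{neo},\text{counterpart}) <
F_{ST}(\text{neo},\text{source})$ with the inequality reversed inside
the causal region. These sizes keep one replicate near twenty seconds
on a single core while leaving every statistic comfortably powered.

Two deviations from obvious alternatives deserve a note. First, the
ancestry-dilution check $(1/2)^{g+1}$ excludes the whole causal
chromosome rather than a ±2 cM window: at 15 cM per chromosome,
selection's hitchhiking flank extends far beyond 2 cM, and only the
non-causal chromosomes are genuinely neutral. Second, the
number of backcross generations used by historical breeders is not
recorded anywhere; $g$ is a configuration knob and 4 is a deliberate
middle ground — enough dilution to make introgressed regions stand out,
few enough generations that carrier lineages never bottleneck out.

## Known limitations

- The founder model has no linkage disequilibrium outside swept
  regions, so LD-profile decay on simulated data is steeper than in
  real breeds.
- The IBD detector's mismatch allowance is a count per segment, not a
  rate per cM; very long segments on dense data may fragment earlier
  than a probabilistic detector would report.
- Binary phenotypes are fitted on the observed 0/1 scale; no
  liability-threshold transformation of effect sizes is attempted.
- With case status confounded with breed membership, the kinship
  random effect absorbs part of the true signal; genomic-control
  lambdas on such scans can fall below 1. This is a property of the
  design, not a calibration fault — permuted-phenotype scans are
  calibrated.
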