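---
title: "Methods: cohort variant statistics, constraint enrichment and SV consensus"
author: "felcohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort variant statistics, constraint enrichment and SV consensus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(felcohort)
```

## Scope

felcohort reimplements, as reusable functions, the cohort-scale analyses of
a small diverse mammalian resequencing study (the motivating case is a
~50-cat whole-genome cohort): per-sample variant statistics, kinship-based
selection of an unrelated analysis set, constraint-group enrichment and
depletion of coding SNVs, loss-of-function singleton prioritization,
dual-caller structural-variant (SV) consensus, and segregation tests for a
dominant disease allele whose homozygote is inviable. Because such cohorts
are built from controlled-access sequence data, the package ships a
synthetic-cohort generator that emits every input the pipeline consumes
(multi-sample VCF, impact annotations, gene/pLI tables, SV call sets,
genotyping panels), with the statistical structure the analyses assume.

## The synthetic cohort model

`generate_genes()` draws genes with lognormal coding lengths (default
median 1.5 kb, sdlog 0.5 — the scale of mammalian coding sequences) and
assigns pLI constraint groups in fixed proportions
(weak/moderate/strong = 0.620/0.197/0.183, the ratio of group sizes in a
typical pLI-annotated ortholog set) using largest-remainder rounding, so
small gene sets hit the proportions exactly.

`generate_cohort()` plants SNVs per gene *g* and impact *I* as

$$N_{gI} \sim \mathrm{Poisson}\!\left(\frac{C_g}{1000}\, d_I\, m_{G(g),I}\right),$$

where $C_g$ is the coding length in bp, $d_I$ the per-impact baseline
density per kb and $m_{G,I}$ a positive depletion multiplier per
(constraint group, impact) cell. Depletion multiplies the Poisson rate
(thinning) rather than deleting variants after the fact, which keeps site
labels exchangeable and therefore the permutation null exact. Each SNV gets
a population frequency from a Beta(0.3, 3) model truncated to (0, 0.5]
(rare-skewed, as cohort site-frequency spectra are), and per-sample
genotypes are Hardy–Weinberg draws conditioned on the site segregating in
the sample (allele count ≥ 1), so realized densities match the configured
rates and the VCF holds no monomorphic records. Defaults
$d = (6, 3.5, 0.3)$ per kb for synonymous/missense/LoF keep the
synonymous-to-missense ratio of real annotation sets while raising the LoF
rate above the empirically tiny per-cohort value, so that every
group-by-impact cell holds enough sites to be informative in desk-scale
cohorts of a few hundred to a few thousand genes; the absolute LoF rate
cancels from every observed/expected contrast, so this choice affects
Monte-Carlo precision, not the statistics under test.

Singleton enrichment factors $e_{G,I}$ act on the probability that a site
is a singleton (allele count exactly 1). The baseline singleton probability
$s_0 = P(AC=1 \mid AC \ge 1)$ is computed by numeric integration of the
binomial sampling distribution over the MAF model; a site in an enriched
cell is then forced into (or re-drawn out of) the singleton configuration
with the mixture probability that multiplies $s_0$ by exactly $e_{G,I}$.
Transitions occur with probability 0.709, giving a Ts/Tv ratio near 2.44.
Two annotation sources are emulated with a 0.9 concordance default, to
exercise the dual-annotation candidate filter.

What the generator does *not* emulate: linkage disequilibrium, mutation-rate
heterogeneity along the genome, genotyping error, missingness (the loader
handles missing genotypes; the generator does not produce them by default)
and pedigree structure beyond what the kinship tests construct explicitly.
Passing tests therefore demonstrate the correctness and calibration of the
statistical machinery under its stated assumptions, not robustness to every
artefact of real sequence data.

`generate_dual_caller_svs()` spaces true SVs ≥ 2 kb apart with span sizes
of 1–10 kb, then reports each through two emulated callers with uniform
breakpoint jitter (default half-width 25 bp), size jitter (250 bp) and
per-caller dropout (0.1). With these bounds, two independently jittered
reports of one SV always satisfy the 50 bp / 500 bp / 50%-reciprocal merge
criteria, and calls of different origin never do — so dual-reported SVs are
recoverable at 100% recall by construction. Jitter of 50 bp or more is
allowed but warned about, since recovery is then no longer guaranteed.

## Per-sample statistics

`per_sample_stats()` counts, per sample, biallelic sites carrying at least
one alternate allele and private singletons. The inbreeding coefficient is
the method-of-moments estimate

$$F = \frac{O_{hom} - E_{hom}}{N - E_{hom}},$$

with $E_{hom}$ from cohort allele frequencies at each polymorphic site,
using the $2N/(2N-1)$ small-sample correction on expected heterozygosity
(the convention of the standard `--het` implementations); without the
correction $F$ is biased upward at cohort sizes in the tens. Cohort
contrasts (breed vs random bred, in the motivating study) use the two-sided
Wilcoxon rank-sum test.

## Kinship and pruning

`kinship_matrix()` implements the KING-robust within-pair estimator

$$\phi_{ij} = \frac{N_{het,het} - 2\,N_{hom,hom'}}{N_{het}^{(i)} + N_{het}^{(j)}}$$

over sites genotyped in both samples, where $N_{hom,hom'}$ counts
opposite-homozygote configurations. It uses only genotype configurations,
so it is invariant to site order and allele relabelling, and it needs no
external allele frequencies. Duplicates give 0.5; parent–offspring and
full sibs 0.25; unrelated pairs 0. Pairs with no heterozygous sites have
undefined $\phi$ (returned as NA), and pairs with fewer than 1,000
overlapping sites are flagged low-confidence.

`prune_related()` builds the graph of pairs with $\phi$ strictly above the
0.15 threshold and repeatedly removes the vertex of maximum degree — the
sample with the most relatives — until no edge remains. Ties are broken by
removing the lexicographically smallest sample ID; the paper-style rule
("remove the most-connected individual iteratively") does not determine a
unique order, and determinism is required for reproducible analysis sets.

## Constraint-group enrichment

Genes are binned by pLI: weak < 0.1, strong > 0.9, moderate otherwise. The
boundary values 0.1 and 0.9 are folded into moderate: strict inequalities
on both published cutpoints would leave them unassigned, and folding them
inward keeps the weak and strong bins pure. For each group $G$ and coding
impact $I$ (synonymous, missense, LoF; "other" never enters the universe):

- observed density $Y_{GI} = X_{GI}/C_G \times 1000$ per kb,
- expected density $E_{GI} = X_G\,(X_I/X)/C_G \times 1000$,
- observed singleton fraction $Y^F_{GI} = X_{GIP}/X_{GI}$,
- expected singleton fraction $E^F = X_P/X$,

with $X$ counts of SNVs, $P$ marking singletons and $C_G$ the summed coding
length of all assigned genes in the group. Results are reported as percent
differences $100\,(Y-E)/E$.

The 95% confidence intervals are the 2.5th/97.5th percentiles of the
statistic under the permutation null that shuffles the impact label
multiset (or the singleton-status multiset) across all coding variant
sites, gene assignments fixed. Since only the cell counts of the
group-by-impact (or cell-by-singleton) table matter, the permutation
distribution is the uniform distribution over contingency tables with fixed
margins; `stats::r2dtable` samples it directly, which is mathematically
identical to permuting labels and removes the per-permutation relabelling
cost. The permutation mean of each cell equals the closed-form expectation
(the identity $\mathbb{E}[X_{GI}] = X_G X_I / X$ under sampling without
replacement), which the test suite verifies to Monte-Carlo error. The
default 10,000 permutations reproduce the precision commonly reported for
such CIs; the calibration suite uses 2,000 per cohort across 200 cohorts of
800 genes and 20 samples — sized so the smallest cell (strong × LoF) holds
~70 sites and the permutation distribution is close to continuous — and
observes 95% ± 3% empirical coverage.

Pairwise group contrasts use the Fisher exact test. In counts mode the
table opposes SNV sites of one impact to the remaining coding nucleotides
of each group ($[X_{AI}, C_A - X_{AI}]$ vs $[X_{BI}, C_B - X_{BI}]$); in
singletons mode, singletons to non-singletons of the same impact. The
two-sided p sums all hypergeometric probabilities not exceeding the
observed table's (with the conventional $1+10^{-7}$ tie tolerance), and the
odds ratio is the sample cross-product. Raw p-values are flagged at 0.05
and 0.001; no multiplicity correction is applied, matching the two-star
convention of the figures this reproduces.

Candidate prioritization returns LoF singletons in strong-constraint genes,
flagged by annotation-source concordance (LoF in every source vs at least
one) and sorted by concordance then pLI. One impact per variant per source
is used — the most severe consequence (LoF > missense > synonymous >
other) — since the collapsing rule across transcripts is otherwise
unspecified; when sources disagree, a configurable primary source (default:
first listed) supplies the impact used in enrichment.

### Effect recovery

With a programmed 50% LoF depletion in strong genes, the recovered percent
difference centres near −44, not −50: the expectation $E$ is itself
computed from depleted margins ($X_G$ and $X_I$ both shrink), pulling the
contrast toward zero by a factor of roughly $1/(1 - f_s/2)$ with $f_s$ the
strong-group length share. The recovery suite (50 replicates of 2,000
genes × 50 samples) asserts the replicate mean in [−60, −40] and a
significant strong-vs-weak Fisher depletion (OR < 1, p < 0.05) in ≥ 90% of
replicates.

## SV consensus

`merge_callsets()` requires, for span types, the conjunction of the
proximity/size rules (start within 50 bp, size within 500 bp, type and
strand agreement) and 50% reciprocal overlap — the only reading consistent
with both published formulations of the merge; a flag relaxes to the
proximity rules alone. Matching is one-to-one and greedy by smallest start
distance (ties: smallest size difference), implemented with a windowed
candidate search and verified in tests against brute-force all-pairs
matching. Insertions come only from the designated authoritative caller
and must be carried by more than two individuals; unmerged span calls are
retained and tagged single-caller, and the consensus set can be summarized
with or without them. Consensus breakpoints are taken from the primary
caller (by default the insertion-authoritative one), since the merged
record must keep one coordinate system. Population frequency counts
carrier individuals, not alleles; SVs above 90% frequency are flagged as
likely reference-minor sites. Region annotation multi-labels each SV by
≥ 1 bp overlap with exons, introns (gene bodies minus exons) and 5 kb
strand-aware flanks, with `intergenic` reserved for SVs touching none;
label fractions can therefore sum above 100% while every SV has at least
one label.

## Segregation tests

`hwe_chisq()` is the three-class Hardy–Weinberg goodness-of-fit statistic
with the allele frequency estimated from the panel, df = 1 and no
continuity correction — on the motivating panel's counts (40 hom-ref,
69 het, 0 hom-alt) the uncorrected statistic is 23.4. `recessive_lethal_test()`
uses an exact two-sided binomial test of the het share among viable
offspring of two carriers against 2/3; at the panel sizes where this
question arises (n ≈ 11) the chi-square approximation would be
inappropriate. `candidate_sv_filter()` applies the discovery-design rule
exactly: an SV must overlap the critical region and be carried by every
affected, and no unaffected, discovery sample; dominant concordance treats
het and hom-alt both as carriers, with hom-alt additionally flagged as
violating the lethal model.

## Numerical and design choices

- Coordinates are 1-based inclusive internally and in VCF; BED exports are
  0-based half-open.
- Degenerate statistics return NA markers (Ts/Tv with no transversions,
  $\phi$ with no heterozygous sites, densities of zero-length groups,
  singleton fractions of empty cells) rather than infinities, with
  warnings where the condition is unexpected.
- Monomorphic panels give $\chi^2 = 0$, p = 1; zero-margin Fisher tables
  give p = 1 with an undefined odds ratio.
- All generators are deterministic functions of their configuration
  (including the seed); the pipeline derives per-stage seeds from the one
  global seed by fixed offsets and records them in its outputs.
- Problem sizes used by the verification suites — 200 null cohorts of 800
  genes × 20 samples at 2,000 permutations; 50 recovery replicates of
  2,000 genes × 50 samples; 50,000-site gene-drop kinship simulations; 100
  random call-set pairs of up to 1,000 calls — were chosen to make
  Monte-Carlo error small relative to the tested tolerances.

## Known limitations

The generator's independence assumptions (no LD, no rate heterogeneity)
make the permutation null exactly correct by construction; on real data the
same permutation scheme is standard but approximate. The KING-robust
estimator is accurate for the close-relative range used here (φ ≥ 0.125)
and degrades in strongly structured cohorts. SV genotype concordance
between callers is not modelled (carriers are taken as reported), so the
union genotype rule is exercised only through carrier-set merging.
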