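---
title: "Evaluating a reduced SNP panel against dense genotypes: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating a reduced SNP panel against dense genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

Breeding programs increasingly genotype animals on fixed mid-density SNP
panels (tens of thousands of markers) instead of whole-genome sequencing
(millions of markers). Panels are cheaper and analytically stable, but their
markers are *ascertained* — selected for common polymorphism — so every
downstream statistic is computed on a biased subsample of the genome. The
practical question for a breeding geneticist is not whether the two platforms
give identical numbers (they cannot), but whether the *inferences* agree:
does the panel recover the same population structure, the same ranking of
lines by genetic diversity, and the same candidate regions under selection?

`chipconcord` implements that evaluation as a reusable, tested pipeline. Both
platforms are pushed through identical quality control and analysis stages,
and agreement is quantified per analysis: sign-aligned Pearson correlation of
principal-component scores, rank concordance of per-line diversity, Jaccard
overlap of merged candidate regions, and permutation-minimal RMSE between
ancestry matrices. Because real paired chip/WGS datasets of this kind are
rarely public, the package ships a seeded simulator that emulates the study
design the pipeline targets: four parental breeding lines from two commercial
breeds, genotyped densely and on a MAF-ascertained subset of the same
individuals.

## The simulation model

Genotypes are simulated under the Balding–Nichols model. Each marker has an
ancestral allele frequency drawn Uniform(0.05, 0.95). A population unit with
drift parameter $F \in (0,1)$ draws its frequency from

$$p' \sim \mathrm{Beta}\!\left(p\frac{1-F}{F},\; (1-p)\frac{1-F}{F}\right),$$

so $\mathbb{E}[p'] = p$, $\mathrm{Var}[p'] = F\,p(1-p)$, and $F$ equals the
expected fixation index of the unit against its parent frequency vector.
Dosages are Binomial(2, $p'$) per individual; optional admixed individuals
draw each allele copy from a line chosen by their ancestry proportions.

The default scenario (`paper_like_scenario()`) uses a two-level hierarchy:
two breed pools (each $F = 0.15$ from the ancestral vector) and four lines —
A ($n=20$) and B ($n=34$) *sharing one* frequency vector drawn from the first
pool, and C ($n=34$, $F=0.10$) and D ($n=40$, $F=0.03$) drifting
independently from the second. These values were fixed once, before any
downstream result was computed, to reproduce the qualitative structure the
pipeline is meant to detect: one breed pair that is nearly undifferentiated,
one clearly diverged pair, highest within-line diversity in D and lowest in C
(weaker drift keeps allele frequencies intermediate, which raises expected
heterozygosity), and breed separation dominating the leading axis of
variation. The dense panel holds 60,000 markers on five 40-Mb chromosomes
with 0.5% uniform missingness; the chip panel is 5,000 of those markers drawn
uniformly among sites with pooled minor allele frequency at least 0.05, on
the same individuals — so platform differences downstream are purely
ascertainment, mirroring designs in which one DNA sample is run on both
platforms.

What the simulator deliberately does **not** model: linkage disequilibrium
(markers are exchangeable given line frequencies), genotyping error beyond
uniform missingness, sex chromosomes, and the marker-spacing rules of real
array design (uniform thinning stands in for them). Passing tests therefore
demonstrate correctness of the statistics and the direction and rough
magnitude of ascertainment effects — not calibration against any real chip.
The LD-pruning stage is exercised instead with constructed correlated
columns, and real-data LD would make pruning remove more sites than it does
here. Selection sweeps are emulated as deterministic frequency shifts toward
the nearer fixation point inside a declared interval of one focal line, so
truth regions for the selection scans are known exactly.

All randomness flows from one integer seed through named sub-streams
(deterministic hashes of stage names), so any stage can be regenerated
independently and whole runs are bit-reproducible.

## Quality control

Filters mirror standard chip/WGS comparability practice and are applied
identically to both platforms, in a fixed order: non-autosomal sites first,
then sites with missing rate strictly above 1%, then samples with missing
rate strictly above 5% (all thresholds configurable). The order matters —
removing samples changes per-site missing rates — so it is fixed and
documented: marker filters precede the individual filter. Boundary cases are
retained ("greater than" is strict). The autosome list is a configuration
value defaulting to chicken (GRCg7b) names "1"–"39", because chromosome
naming dialects vary too much for safe inference.

LD pruning uses a 50-SNP window advanced by 5 SNPs with an $r^2$ cutoff of
0.2. $r^2$ is the squared Pearson correlation of dosage vectors over
pairwise-complete samples; this is simpler than PLINK's composite-haplotype
measure and is a deliberate simplification, since pruning here only thins
markers for the structure stages. Two further deterministic conventions:
the *earlier* (left-most) site of a correlated pair is always kept (PLINK
prefers the less-missing site), and zero-variance sites are treated as
uncorrelated. Passes repeat until stable, so the retained set is a
deterministic function of the input order. Whether windowed diversity and
selection statistics should also run on pruned data is genuinely ambiguous
in common practice; the pipeline exposes a per-stage flag and defaults to
pruned input for PCA/tree/admixture and unpruned input for windowed
$\pi$/$F_{ST}$/LSBL, since window statistics already aggregate over sites
and pruning would discard signal.

## Diversity and selection statistics

Per line and site (over called genotypes): $H_o$ is the heterozygote
fraction, $H_e = 2p(1-p)$, MAF $= \min(p, 1-p)$. Line-level values are
unweighted means over sites with at least one called genotype. $H_e$ uses no
small-sample correction by default — a $2n/(2n-1)$ flag exists but is off —
because the uncorrected form is the simplest defensible choice and the
evaluation compares platforms, not absolute levels.

Windowed nucleotide diversity uses the unbiased per-site term
$2c(n-c)/(n(n-1))$ ($c$ alternate-allele count, $n$ called allele count)
summed per window and divided by the window *span in bp* — the convention of
windowed-diversity tools that treat unobserved positions as invariant. This
choice matters: dividing by variant count instead changes values by orders
of magnitude, and the span convention is what makes chip-derived $\pi$
(sparse markers) orders of magnitude smaller than dense-panel $\pi$, as seen
when comparing platforms of very different marker density. Windows are
1-based inclusive, anchored at position 1, advanced by the step (100 kb /
30 kb by default), with terminal partial windows kept and normalized by
their actual span. Genome-wide $\pi$ is the length-weighted mean over the
non-overlapping 100-kb grid (whether such summaries should be window means
or whole-genome sums is usually unstated in applied work; the length-weighted
window mean is used and documented here).

$F_{ST}$ uses the Weir–Cockerham (1984) variance components $a$, $b$, $c$
per site, combined per window as $\sum a / \sum (a+b+c)$ (ratio of sums).
Sites where either line has fewer than two called genotypes are skipped;
windows with a zero denominator report `NA` rather than being dropped;
negative estimates are reported as computed, never clamped, and empirical
quantiles operate on raw values.

The locus-specific branch length for focal population $X$ against references
$Y, Z$ is

$$\mathrm{LSBL}_X = \tfrac{1}{2}\left(F_{ST}(X,Y) + F_{ST}(X,Z) - F_{ST}(Y,Z)\right),$$

computed on a shared grid of non-overlapping 100-kb windows. In the default
pipeline the focal "population" pools the two sister lines of the first
breed, matching the design where branch-specific selection on one breed is
contrasted against the two lines of the other.

Candidate regions are the top 5% of the empirical distribution: the
threshold is the $\lceil 0.05 N \rceil$-th largest non-missing value and
ties at the threshold are all included (deterministic, possibly more than
$\lceil 0.05 N\rceil$ windows). The joint scan between a line pair flags
windows that are simultaneously in the top 5% of $F_{ST}$ and in either 2.5%
tail of $\log_2(\pi_X/\pi_Y)$, labeling each flagged window with the line of
reduced diversity. "Elevated" and "extreme" are vague in applied usage, so
both fractions are configuration values; 5% and 2.5% per tail are the
defaults. Windows with zero diversity in either line have an undefined log
ratio; they are excluded from quantile estimation and reported separately,
because on sparse chip grids they are marker-density artifacts rather than
evidence of selection.

## Structure inference

**PCA.** Missing dosages are mean-imputed per site, then each site is
centered by $2\hat p$ and scaled by $\sqrt{\hat p(1-\hat p)}$ (Patterson
scaling). Scores are left singular vectors scaled by singular values. Signs
are fixed by making each component's largest-magnitude loading positive, so
output is reproducible; cross-platform comparison additionally re-aligns
signs pairwise, since sign conventions cannot agree across different marker
sets.

**Trees.** The pairwise distance is the allele-sharing distance
$d(i,j) = \mathrm{mean}\,|g_i - g_j|/2$ over pairwise-complete sites (the
distance metric feeding neighbor-joining is rarely stated in applied
reports; allele sharing is the simplest choice defined directly on dosages).
Neighbor joining and bootstrap bipartition counting are delegated to `ape`;
negative NJ branch lengths are clamped to zero with a message. Bootstrap
resamples sites with replacement; support is the percentage of replicate
trees containing each internal bipartition of the point-estimate tree. The
package default is 1,000 replicates; the simulated pipeline default is 100,
chosen as this package's desk-scale setting (support on simulated line
splits saturates at far fewer replicates).

**Admixture.** The model: genotypes Binomial(2, $f_{ij}$) with
$f = QP$, $Q$ rows on the simplex, $P \in [10^{-6}, 1-10^{-6}]$. The
optimizer is the classical EM on per-allele ancestry assignments with a
simultaneous closed-form M-step for $Q$ and $P$ — monotone in
log-likelihood by construction (and asserted in tests), initialized from
seeded uniform noise, stopping at a log-likelihood gain below `tol`
(default $10^{-4}$) or `max_iter` (default 2,000). This is deliberately not
the quasi-Newton block relaxation of the ADMIXTURE program: at the scales
this package targets (hundreds of samples, thousands of pruned markers) the
EM is adequate and much simpler to verify. Two consequences are documented
rather than hidden: EM approaches boundary optima ($Q \to 0/1$) slowly, and
$Q$ columns are identifiable only up to permutation, so all comparisons go
through exhaustive best-permutation matching (`q_matrix_agreement`, $K \le 8$).

**Choosing K.** Cross-validation masks non-missing genotype *entries* in
`n_folds` seeded folds, refits on the rest, predicts held-out entries as
$2f_{ij}$, and scores the root-mean-square deviation; the reported optimum
is the argmin over K. This RMSE-on-masked-entries criterion is a declared
deviation from ADMIXTURE's deviance-based CV — only the argmin is treated as
comparable between the two, never the error values. CV fits default to
`max_iter = 300`: model selection needs relative fold errors, which
stabilize long before the slow EM tail, and the cap is configuration, not a
statement about convergence of the final fit (the final fit at the chosen K
uses the full default budget).

A note on parameter-recovery precision, because it drives one test scale:
for an unadmixed individual the MLE $\hat q$ has sampling standard error of
roughly $1/\sqrt{2M \cdot \bar F}$ with $M$ markers and between-population
drift $\bar F$; at $M = 2{,}000$ and $F = 0.1$ that is $\approx 0.035$, so
the *maximum* deviation over 60 individuals is expected near 0.09 even at
the exact optimum — no optimizer can beat it. The recovery test therefore
uses $M = 10{,}000$ markers, where the expected maximum deviation
($\approx 2.6 \times 0.016$) sits safely under the 0.05 bound being
asserted. This is an information-content requirement of the assertion, not
a tuning of the generator.

## Concordance measures

Per component, Pearson $r$ of paired per-sample scores after choosing the
sign that maximizes $r$ (no Procrustes rotation by default — raw
per-component scores are what applied platform comparisons correlate; a
rotation would hide genuine axis swaps). Diversity agreement is reported as
Spearman $\rho$ over lines for $H_e$ and $\pi$ plus an exact-ordering flag;
with only four lines the flag is the primary criterion and $\rho$ is
reported for completeness. Candidate-region agreement merges
adjacent/overlapping flagged windows into maximal regions first (so
overlapping sliding-window grids do not inflate counts), then reports
Jaccard (overlap bp / union bp, 1-based inclusive arithmetic) and reciprocal
hit counts. Ancestry agreement is the RMSE between $Q$ matrices minimized
over column permutations.

## Problem sizes and numerical conventions

The default simulated evaluation uses 60,000 dense markers, 5,000 chip
markers, 128 individuals, $K \in \{1,\dots,6\}$ with 5 folds, and 100
bootstrap replicates — sizes chosen as this package's standard desk-scale
configuration; every one of them is a config field and scales up without
code changes (real studies test K up to 10 and 1,000 bootstrap replicates).
Degenerate inputs are handled explicitly: empty windows report $\pi = 0$ and
$n_{sites} = 0$; windows without usable sites report `NA` $F_{ST}$ and
missingness propagates through LSBL; monomorphic sites are dropped by PCA
scaling and treated as uncorrelated by pruning; samples with no shared
called sites make the distance matrix error rather than guess; CV fold
partitions that would blank out a sample or site are redrawn a bounded
number of times. Ties are broken deterministically everywhere (earlier site
kept in pruning, inclusive thresholds in quantile rules, smallest-index
joins inside `ape::nj`), so fixed-seed runs are bit-reproducible, which the
test suite asserts.

## Known limitations

Without LD or genotyping error, the simulator cannot probe pruning efficacy
or error robustness on realistic data. Chip ascertainment by a pooled-MAF
floor plus uniform thinning omits spacing constraints and
reference-panel-specific bias of real array design. The Weir–Cockerham
implementation covers two populations (all scans here are pairwise);
haplotype-based selection statistics (iHS, XP-EHH) and significance testing
of concordance measures are out of scope. Hudson-style $F_{ST}$ appears only
as an independent oracle inside the test suite, never as the implementation.
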