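---
title: "Models and methods behind the cashmere pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the cashmere pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains the statistical models the package implements, the
choices made where the design was genuinely open, what the synthetic-data
generators emulate (and what they do not), and the numerical details a
user extending or auditing the package needs.

## Codon models and selection tests

Sequences evolve under a Goldman–Yang (GY94) codon model on the 61 sense
codons of the standard code. The generator entry for codons $i \to j$
differing at one nucleotide is $q_{ij} = \pi_j\,\kappa^{[\text{ts}]}\,
\omega^{[\text{nonsyn}]}$, zero for multi-nucleotide changes, with rows
summing to zero and the matrix rescaled to one expected substitution per
codon at equilibrium — branch lengths are therefore expected
substitutions per codon site. Codon frequencies are F1×4 (products of
position-independent nucleotide frequencies, renormalized over sense
codons), estimated from the observed alignment composition. F1×4 was
chosen over F3×4 or empirical-61 to keep nuisance parameters few at desk
scale; the frequency vector used is always available from the fit object.

The likelihood is a Felsenstein pruning sum over the rooted input tree,
computed per site and per site-pattern (identical columns are collapsed
with multiplicity weights). The transition matrices come from an
eigendecomposition of the similarity-transformed symmetric generator, so
$P(t)$ for any branch length is a single matrix congruence. Partial
likelihoods are rescaled every 16 merges; on trees of a few dozen tips
this keeps values far from underflow while avoiding per-column max
operations in the hot loop.

**Branch-length treatment.** Per-gene fits do not re-estimate every
branch length; they keep the input tree's relative lengths and estimate
one free rate scalar per gene alongside $\kappa$ and the $\omega$
parameters. This mirrors how a genome-scale analysis holds the species
tree fixed, removes $2n-3$ nuisance parameters per gene, and is the main
reason a 200-gene null calibration finishes in minutes.

**Models.** `one_ratio` (single $\omega$), `two_ratio` (separate
foreground $\omega$ — the branch model behind REG calls), `free_ratio`
(per-branch $\omega$), and a branch-site pair. The branch-site model is a
three-class site mixture: class 0 evolves at $\omega_0 \in (0,1)$
everywhere, class 1 at $\omega = 1$ everywhere, and class 2 at
$\omega_2$ on the foreground branch with $\omega = 1$ elsewhere. The null
fixes $\omega_2 = 1$ (collapsing class 2 into class 1), the alternative
frees $\omega_2 \ge 1$ (capped at 1000), giving one extra identifiable
parameter and a $\chi^2_1$ likelihood-ratio test. The p-value uses the
plain chi-square reference; `boundary_mix = TRUE` switches to the 50:50
point-mass/chi-square boundary mixture, which is the statistically
stricter option.

**Optimization.** Nelder–Mead on unconstrained transformed scales (log
for rates, logit for proportions, softmax for class weights). Branch and
one-ratio fits use a single start — their likelihoods are unimodal in
practice and the nested alternative is warm-started from the null
optimum, with one escape restart if it lands below the null. Branch-site
alternatives are multimodal in $(p_2, \omega_2)$, so they use three
starts fanned out from the null optimum at $\omega_2 \approx 2, 4, 47$.
In the branch-site fits $\kappa$ and the rate scalar are profiled out at
their one-ratio estimates: both hypotheses share the constraint, the
mixture parameters are the ones the test is about, and per-class site
log-likelihood caching then makes the constant $\omega=1$ class free.

**REG direction.** "Rapidly evolving" is read as *elevated* foreground
$\omega$: the candidate verdict requires $p < 0.05$ and
$\hat\omega_{fg} > \hat\omega_{bg}$. A `direction` column preserves the
directionless reading for users who want a pure rate-difference test.

**Counting estimator.** `counting_omega_per_branch` provides a
Nei–Gojobori-style per-branch dN/dS from ancestral codon states: observed
nonsynonymous/synonymous differences between branch-endpoint codons
(averaged over minimal single-step paths for multi-hit codons, paths
through stops excluded) normalized by NG86 site counts of the parent
sequence. $\omega$ is flagged undefined when $dS = 0$ rather than forced
to a value.

**Missing data.** Columns containing any gap/ambiguous/stop codon are
dropped gene-wide before fitting (complete-case sites); the dropped count
is carried on the fit object. This is the simplest defensible treatment
and keeps the likelihood comparable across nested fits.

## Ancestral reconstruction and convergence

Protein ancestral states use marginal reconstruction: an up–down pruning
pass under a Poisson-type replacement model whose exchangeabilities are
uniform and whose stationary frequencies are the alignment-wide observed
amino-acid frequencies (pseudocount 0.5). At the shallow divergences this
pipeline targets, reconstruction is frequency-dominated and an empirical
matrix (JTT/WAG) changes little; a hook accepts any user 20×20
exchangeability matrix. Reported states are posterior argmaxes with ties
broken toward the residue seen in more leaves, then alphabetically —
determinism matters more than the tie itself, which is measure-zero on
real data.

A site is a convergent substitution between two focal branches when both
child states differ from their respective parent states and the two child
(derived) states are identical. Sites where the two parent states are
identical are *parallel* substitutions; they satisfy the rule and are
reported with a `parallel` flag rather than excluded, since derived-state
identity plus change-from-parent is the criterion. All four states
(two parents, two children) must reach a posterior gate, default 0.8 —
the literature filters "to reduce false positives" without a numeric
cutoff, so the gate is explicit and configurable.

The conservative-site (CCS) filter then requires that every valid
non-focal leaf carry one single residue, different from the focal derived
residue, and that every focal-clade leaf carry the derived residue — the
"only in the two convergent lineages" condition. By construction CCS
sites are a subset of convergent sites, which are a subset of sites
substituting on both focal branches; this filtration chain is asserted in
the tests. Genes pass the upstream validity filter when at least 75% of
alignment cells are canonical residues (≥ semantics at the boundary).

Fitch parsimony state sets are implemented alongside as a brute-force
cross-check; on zero-homoplasy columns Fitch and marginal ML must agree
at every unambiguous node, and they do in the test battery.

## Selective-sweep scan

Sites are filtered to biallelic SNPs with overall minor-allele frequency
≥ 0.05 and genotype call rate ≥ 0.9 (at most 10% missing). Missing
genotypes are never imputed; they shrink the called-allele denominator.

Per-site differentiation uses the Weir–Cockerham (1984) diploid variance
components $a$ (among populations), $b$ (among individuals) and $c$
(within individuals) from per-population allele counts, frequencies and
observed heterozygote proportions. Window Fst over 50 kb windows stepped
by 20 kb is the ratio of sums $\sum a / \sum(a+b+c)$ — not a mean of
per-site ratios, which is biased by low-information sites; a two-site toy
in the tests demonstrates the difference. Negative window values are kept
for ranking (a clamped copy is reported) so the upper-tail quantile is
not distorted.

Nucleotide diversity per site is $2 c_{ref} c_{alt} / (n(n-1))$ on called
alleles; window $\pi$ divides the per-site sum by the window length in
bp. The $\pi$-ratio is reference-population $\pi$ over selected
("cashmere") population $\pi$, so diversity loss in the selected
population pushes windows into the upper tail; the orientation is an
argument, and the degenerate cases (both $\pi$ zero → missing; only the
denominator zero → capped) are explicit.

Top-window calling uses the k-th largest order statistic with
$k = \lceil f \cdot n \rceil$ and keeps ties, so exactly $k$ windows are
flagged in the absence of ties and the reported threshold can be quoted
alongside the flags. Candidate regions are the interval intersection of
the two methods' flagged windows (merged bookended runs); genes annotate
to each method by ≥ 1 bp overlap and the final candidate list is the
intersection of the two per-method gene lists. Both the window-overlap
count and the merged-region count are reported, since "common regions"
can reasonably mean either.

## Coexpression core

The network analysis follows the WGCNA recipe on a normalized expression
matrix: genes with sample SD < 0.5 removed; average-linkage sample
clustering as an outlier screen (report-only by default — dropping
samples is a decision the analyst should make by inspecting the
dendrogram); unsigned adjacency $|cor|^\beta$ with $\beta$ the smallest
power whose scale-free fit index reaches 0.85. The fit index is the
$R^2$ of $\log_{10}(\text{freq})$ on $\log_{10}(\bar k)$ over 10
connectivity bins, signed by $-\text{sign}(\text{slope})$ so that a
proper scale-free (decreasing) degree distribution scores positively. A
signed-network switch is provided; unsigned is the default the study
description implies.

The topological overlap matrix is
$TOM_{ij} = (l_{ij} + a_{ij}) / (\min(k_i,k_j) + 1 - a_{ij})$ with
$l_{ij} = \sum_{u \ne i,j} a_{iu}a_{uj}$, unit diagonal. Modules come
from average-linkage clustering of $1 - TOM$ with a *static* cut at 99%
of the maximum merge height, keeping branches of at least 30 genes
(label 0 otherwise, labels ordered by decreasing size). This is a
deliberate simplification of the dynamic hybrid tree cut: it is
deterministic, has one interpretable parameter, and recovers
block-structured truth exactly (adjusted Rand index 1 in the test
battery). It will fragment modules with strongly nested correlation
structure, which the full dynamic algorithm handles better — the main
known limitation of this module.

Module eigengenes are first principal components of the per-gene
z-scored module submatrix, sign-aligned to the module's mean profile and
unit-variance. Modules whose eigengene dissimilarity $1 - cor$ falls
below 0.25 are merged iteratively to a fixed point (the merge is
idempotent by test). Module–trait relationships use Pearson correlation
against four binary stage indicators (anagen, catagen, telogen,
late-telogen), with two-sided p from $t = r\sqrt{n-2}/\sqrt{1-r^2}$, raw
(heatmap convention, no multiplicity correction). Hub genes are genes of
the key module(s) with $|GS| > 0.2$ and $|MM| > 0.8$, where GS is the
gene–trait correlation and MM the gene–own-eigengene correlation.

## Differential expression

Counts are normalized by median-of-ratios size factors (geometric-mean
reference over genes positive in all samples; total-count fallback with a
warning). Dispersion is per-gene method-of-moments on the normalized
scale, $\alpha = \max((s^2-\mu)/\mu^2, 10^{-8})$, without shrinkage — a
transparent choice whose cost is noisier $\alpha$ for weak genes; the
planted-truth acceptance checks are the arbiter, not parity with any
specific tool (an NB-GLM cross-check against an established fitter runs
in the suite and tracks estimates closely). Each gene gets a
two-coefficient NB GLM (intercept, group indicator) with log size-factor
offsets, solved by Fisher scoring with closed-form 2×2 updates; the Wald
z uses the SE from the observed information. Separation (one group all
zero) caps the effect at ±10 log2 units and flags it. All-zero genes are
excluded from testing *and* from the BH denominator. DEGs require
$|log2FC| > 1$ and BH-FDR $< 0.05$, both strict, with up/down counted
relative to the second group level.

## Enrichment and integration

Gene sets from all stages live in a ledger over one declared gene
universe (deduplicated, provenance-tagged). Pathway enrichment is the
hypergeometric upper tail $P[X \ge k]$ with BH q-values across pathways;
the significance flag follows the raw $p < 0.05$ convention with q
reported alongside. The default universe is the full annotation rather
than only tested genes — explicit beats implicit, and a switch covers the
other convention. The gene–pathway bipartite edge list exports exactly
the overlap members of significant pathways.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, each with
recorded truth:

* **Codon alignments** evolve root-to-tips under the same GY94 code path
  the estimator uses (no simulator/estimator mismatch), with optional
  foreground-branch $\omega$ shifts, on trees of 6–8 taxa and genes of
  100–2000 codons. Convergent sites are planted by overwriting columns so
  both focal clades carry a derived residue absent from their parents;
  conservative planting additionally fixes all background leaves to one
  residue. Sites already substituting on a focal branch are resampled and
  logged.
* **Variant panels** draw per-site ancestral frequencies from a symmetric
  Beta(0.8, 0.8) with Balding–Nichols jitter (background differentiation
  0.02) and binomial diploid genotypes; planted sweep windows shrink the
  selected population's heterozygosity by a factor (default 0.1) and push
  frequencies toward fixation (divergence 0.6). Sites are independent:
  there is no linkage or coalescent history, which is sufficient because
  every downstream statistic is a per-site or per-window moment. Default
  scale: two populations of 20 diploids, 5 Mb, SNP density 0.002/bp,
  2% missingness — a desk-scale stand-in for a resequencing cohort.
* **Expression data**: modules are latent stage-linked factors times
  per-gene loadings (with $E[\text{loading}^2]$ equal to the target
  within-module correlation 0.8) plus noise, a weak shared sample factor
  supplying the low-correlation background real data shows; counts are
  negative binomial with dispersion 0.2 and planted ±2 log2 fold-changes
  in 60 genes across two 10-sample breed groups. Four 15-sample stages
  (60 samples) cover the hair-follicle cycle with months drawn within
  each stage's calendar range.
* **Annotation/pathways**: genes tile the chromosome; one gene is
  relocated into each sweep window; one pathway is loaded with the
  planted sweep genes.

Passing tests on these data demonstrate *internal correctness* — the
statistics recover what was planted under their own model assumptions.
They do not demonstrate robustness to model violations real data carry:
alignment error, recombination and linkage, dispersion trends over mean
expression, batch effects, or reference bias. The problem sizes above are
the package's defaults for the test suite and the acceptance script and
were chosen once as realistic desk-scale analogs.

## Numerical choices, degenerate inputs and tie-breaks

* LRT statistics are clamped at 0; nested fits are asserted to respect
  $\text{lnL}_{alt} \ge \text{lnL}_{null} - 10^{-6}$.
* Optimizer tolerance $10^{-6}$ on lnL (Nelder–Mead reltol $10^{-7}$);
  non-convergent genes carry a flag, are excluded from candidate verdicts
  and from BH denominators.
* Eigen-based $P(t)$ clips tiny negative entries to 0; $t = 0$ returns
  the identity.
* Reconstruction tie-breaks: leaf support, then alphabet. Quantile
  tie-breaks: ties kept, with a warning when all values tie.
* All genomic coordinates are 0-based half-open internally; VCF and GFF3
  conversion happens only at the file boundary.
* Identical seed and configuration give byte-identical outputs; the
  coexpression stage contains no randomness at all.
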