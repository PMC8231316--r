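---
title: "Genetic diversity and population structure of inbred SNP panels: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic diversity and population structure of inbred SNP panels: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popdiv)
```

popdiv implements the standard diversity workflow used for advanced plant
breeding panels genotyped at biallelic SNPs (typically by
genotyping-by-sequencing): quality control, per-marker statistics,
admixture-model structure inference with Evanno's delta-K, PCA and
complete-linkage dendrograms, one-level AMOVA with PhiPT and the haploid
migrant number Nm, and per-subpopulation allelic-pattern indices. This
vignette explains the models and the numerical choices; it states no result
that the package's tests do not themselves compute.

## Data model and quality control

A panel is a `genotype_matrix`: lines x markers minor-allele dosages in
{0, 1, 2, NA} with chromosome/position/allele metadata. Polarity is fixed at
read time from observed frequencies; a locus at exactly MAF 0.5 takes the
alphabetically smaller base as its minor allele, so polarity is
deterministic and `read_hapmap(write_hapmap(x))` is an exact inverse.
Positions are stored in base pairs (the HapMap/VCF native unit) and
converted to Mb only in reports; a HapMap file whose positions are plainly
megabase-scale (all below 1e4, or fractional) is rescaled with a message.

QC follows the usual GBS filter statement read literally: sample call rate
*strictly greater than* 0.8, SNP call rate strictly greater than 0.7, MAF
*at least* 0.05. Samples are filtered first; marker MAF and call rate are
then recomputed on the retained samples. Filtering acts on observed
(pre-imputation) calls. The bundled imputer is deliberately naive — locus
modal dosage, ties toward the lower dosage — and exists only so that the
EM, PCA and distance stages can demand a complete matrix; haplotype-aware
imputation is out of scope and results on sparse panels should be read
accordingly.

## Marker statistics

For minor allele frequency $q$, the biallelic polymorphism information
content is
$$\mathrm{PIC} = 1 - \left(q^2 + (1-q)^2\right) - 2q^2(1-q)^2,$$
which rises monotonically from 0 at $q = 0$ to its biallelic maximum 0.375
at $q = 0.5$. (Some published tables cap PIC at 0.25, which corresponds to
a different approximation; this package evaluates the formula above
exactly.) Observed heterozygosity is the fraction of dosage-1 calls, per
marker and per line; in advanced inbred material the per-line value doubles
as a residual-segregation / outcrossing flag.

Chromosome distribution reports count, first/last position (Mb, 3
decimals), coverage = last − first, mean spacing = coverage / count, and
density = count / coverage, with roll-ups over the three wheat subgenomes
(A/B/D) and homoeologous groups 1–7. Mean spacing is defined as
coverage/count — not coverage/(count − 1) — because that is the convention
the reference tables this report mirrors actually use. A chromosome with
one marker has coverage 0 and undefined (NA) spacing and density rather
than a division error.

## Structure inference

The admixture model treats each line's two allele copies at locus $l$ as
draws from $K$ latent subpopulations: with mixing proportions $q_i$ (rows
of Q summing to 1) and subpopulation minor-allele frequencies $p_{kl}$, the
dosage is Binomial$(2, \sum_k q_{ik} p_{kl})$. The package maximizes the
log-likelihood by the classic EM block updates, which are monotone in the
log-likelihood (asserted in tests at every iteration). This is a
maximum-likelihood point-estimate surrogate for the Bayesian MCMC samplers
commonly used for this model: those are used in practice only to produce
per-K likelihoods and Q plots, and the EM reproduces both deterministically
per seed. The likelihood spread that Evanno's statistic needs comes from
replicate random restarts (replicate $r$ seeds `base_seed + r - 1`) instead
of posterior spread — it plays the same role in the statistic.

Numerical choices: subpopulation frequencies are clamped to
$[10^{-6}, 1-10^{-6}]$ to avoid $\log 0$; Q rows are renormalized each
iteration against floating-point drift; convergence is declared when the
per-iteration log-likelihood gain falls below
$\mathrm{tol}\cdot(1 + |\log L|)$ with tol = 1e-6 — a relative criterion,
because panel-scale likelihoods are order $10^5$ and an absolute 1e-6
plateau is unreachable in bounded iterations. K = 1 is a closed form
(pooled frequencies), not an EM run.

Evanno's table takes replicate log-likelihoods per K and computes
$\Delta K = |L''(K)| / \mathrm{sd}(L(K))$, defined for interior K only;
best K is the arg max over defined values, with zero-sd K excluded (and
warned about) and ties resolved to the smallest K. Deterministic EM
restarts can make sd tiny, inflating delta-K; since only the arg max is
interpreted, this does not affect model choice.

PCA is covariance-based (the dosage scale is already common across loci;
a correlation option is not provided because up-weighting rare alleles is
not wanted here), computed by SVD of the column-centred matrix. Each
component's sign is fixed so its largest-magnitude loading is positive,
making scores deterministic. Dendrograms are complete-linkage agglomeration
on Euclidean distances in the space of the first 3 PCs by default — three
components being what structure scatter plots conventionally show —
configurable via `n_components`; trees are exported as Newick via ape.
Hard subgroup labels are the Q arg max with ties to the lower index.

## AMOVA, PhiPT and Nm

Distances are squared Euclidean on dosages,
$d^2_{ij} = \sum_l (x_{il}-x_{jl})^2$, the codominant-genotypic convention.
With $N$ lines in $k$ groups of sizes $n_g$:
$$SS_{tot} = \tfrac1N \sum_{i<j} d^2_{ij},\qquad
  SS_{w} = \sum_g \tfrac1{n_g} \sum_{i<j \in g} d^2_{ij},\qquad
  SS_{a} = SS_{tot} - SS_{w},$$
mean squares from $df_a = k-1$, $df_w = N-k$, the average sample-size
coefficient $n_0 = (N - \sum_g n_g^2/N)/(k-1)$ (never assumed balanced),
$V_a = \max(0, (MS_a - MS_w)/n_0)$ truncated at zero so PhiPT stays in
[0, 1], $V_w = MS_w$, and $\Phi_{PT} = V_a/(V_a+V_w)$. The p-value permutes
whole-individual labels (999 by default) and is
$(\#\{\Phi^{perm} \ge \Phi\} + 1)/(n_{perm}+1)$. The haploid migrant number
is
$$N_m = \left[\frac{1}{V_a/(V_a+V_w)} - 1\right]\Big/2 = \frac{V_w}{2V_a},$$
reported as "unbounded" when $V_a = 0$.

For equal-sized groups on 1-D embeddings this decomposition coincides with
classical one-way ANOVA sums of squares, which the tests verify against a
brute-force oracle (and against an independent PERMANOVA implementation).

## Diversity indices

Per subpopulation and locus, allele frequencies use the haploid convention
appropriate to inbred lines: a residual heterozygote contributes half a
count to each allele, so $f = \sum_i x_{il} / (2 n)$. Indices per locus:
Na (direct allele count, optionally restricted to frequency >= 5%),
$N_e = 1/(1-h)$, Shannon's $I = -\sum p \ln p$ (0 ln 0 = 0),
$h = 1 - \sum p^2$, and $uh = \frac{n}{n-1} h$ with the per-locus
non-missing $n$. Each is averaged across loci with standard errors
$sd/\sqrt{L}$; the report's Mean column is the arithmetic mean of the
per-subpopulation values. An allele is private to a subpopulation when its
frequency is positive there and zero everywhere else; the per-line count is
the number of loci at which a line carries at least one copy of an allele
private to its own subpopulation.

## The synthetic panel generator

`simulate_panel()` draws Balding–Nichols panels: ancestral minor
frequencies Uniform(maf_floor, 1 − maf_floor), subpopulation frequencies
Beta$(p(1-F)/F,\,(1-p)(1-F)/F)$, inbred-line genotypes that are
heterozygous with a small residual probability and otherwise homozygous
with probability $p_{kl}$, i.i.d. missingness, and a 21-chromosome
wheat-like layout with A/B/D marker shares 0.41/0.51/0.09. The defaults are
the regime of an advanced-breeding-line panel: 141 lines in two groups
(70 + 71), 14,563 loci, F = 0.006 (weak differentiation), residual
heterozygosity 0.015, MAF floor 0.05, and no missing data — the panel
stands in for a post-imputation call set, which is also why missingness
defaults to zero. No linkage is simulated: no analysis stage here uses LD,
so positions are cosmetic beyond the distribution report.

`realized_fst()` summarizes the truth as a variance-component FST:
per locus $s^2/(s^2 + \bar h_w)$, where $s^2$ is the across-subpopulation
sample variance of the true frequencies (k − 1 divisor) and $\bar h_w$ the
mean within-subpopulation gene diversity. This convention is chosen
deliberately: it sits on the same scale as the Balding–Nichols parameter F
and as the AMOVA PhiPT estimator, so recovery tests compare like with like.
The Nei population-variance convention ($(H_T-H_S)/H_T$ with a k divisor)
reads a factor of about $(k-1)/k$ lower — roughly half, for two
subpopulations — and would make "PhiPT recovers the simulated FST"
structurally false rather than a property of the estimator.

What passing tests show — and what they do not: the generator emulates
allele-frequency structure, residual heterozygosity, missingness and
chromosome layout, but not linkage disequilibrium, genotyping error biases,
family structure within subpopulations, or site-frequency spectra of real
GBS discovery. Recovery results on these panels therefore validate the
estimators' algebra and statistical behaviour, not their robustness to
those real-data features.

## Problem sizes used by the test suite

The property suite exercises the estimators at panel scales chosen to make
their sampling noise small relative to the tolerances tested: PhiPT
recovery on 140-line, 2000-locus panels at F in {0.01, 0.05, 0.1} over 10
seeds (tolerance ±0.02); Evanno delta-K recovery on 100-line, 2000-locus
panels at F = 0.05 over 10 seeds with 3 replicate restarts per K in 1..4
(EM tolerance 1e-5, at most 500 iterations); study-regime emulation checks
on a 141 x 2000 panel. Loci counts are scaled down from the 14,563 of a
full GBS panel since every statistic here concentrates at rate
$1/\sqrt{L}$; the distribution report and the layout chi-square test use
the full 14,563.

## Known limitations

* The EM surrogate reports a point estimate; it does not quantify
  uncertainty in Q, and with highly admixed panels replicate restarts can
  converge to distinct local optima (visible as large sd in the Evanno
  table).
* Label switching across replicates is not aligned; only likelihoods and
  the best run's Q are consumed downstream.
* The naive imputer biases toward major alleles at low call rates; filter
  first, and treat diversity indices from heavily imputed panels with
  caution.
* Multi-allelic loci are out of scope throughout (VCF records with two or
  more ALT alleles are skipped).
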