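# popdiv

SNP-based genetic diversity and population structure analysis for panels of
inbred lines — the workflow used to characterize advanced breeding material
in crops such as bread wheat before association studies or genomic
selection. Given a biallelic genotype table (TASSEL HapMap or VCF), popdiv
answers the questions a breeder asks of a new panel: how are the markers
distributed across the genome, how informative are they, how many latent
subpopulations are there, how differentiated are they, and how much
diversity does each subgroup hold.

## What it computes

* **Genotype IO and QC** — HapMap/VCF parsing to a minor-allele dosage
  matrix (0/1/2/NA), with the standard filters: sample call rate > 0.8,
  SNP call rate > 0.7, MAF ≥ 0.05, plus a naive locus-mode imputer for
  completeness-demanding stages.
* **Marker statistics** — per-SNP MAF, observed heterozygosity and
  polymorphism information content
  `PIC = 1 − (q² + (1−q)²) − 2q²(1−q)²` (maximum 0.375 at q = 0.5);
  chromosome-wise distribution tables with subgenome (A/B/D) and
  homoeologous-group roll-ups.
* **Population structure** — maximum-likelihood admixture model
  (dosage ~ Binomial(2, Σₖ q·p)) fitted by EM over a range of K with
  replicate random restarts, Evanno ΔK = |L″(K)|/sd(L) model selection,
  covariance PCA, and complete-linkage dendrograms in PC space (Newick
  export).
* **AMOVA** — one-level partition of squared-Euclidean dosage distances
  into among/within components with unequal-group-size correction,
  ΦPT = Va/(Va+Vw), whole-individual permutation p-values, and the haploid
  migrant number `Nm = [1/ΦPT − 1]/2 = Vw/(2Va)`.
* **Diversity indices** — per-subpopulation Na, Na(freq ≥ 5%),
  Ne = 1/(1−h), Shannon's I = −Σ p ln p, h = 1 − Σp², uh = n/(n−1)·h, and
  private-allele statistics (per-population mean, per-line counts, ranges).
* **Synthetic panels** — a Balding–Nichols generator of wheat-like inbred
  panels with known subpopulation labels and frequencies, so every stage
  can be validated against ground truth.

## Worked example

Simulate a 60-line panel with two weakly differentiated subpopulations
(F = 0.05) and run the full workflow:

```r
library(popdiv)
sim <- simulate_panel(sim_config(n_per_group = c(30, 30), n_loci = 800,
                                 fst = 0.05, missing_rate = 0.02, seed = 42))
qc  <- apply_qc(sim$gm)            # call-rate + MAF filters
gmc <- impute_naive(qc$gm)         # complete matrix for EM/PCA/AMOVA

scan <- run_k_scan(gmc$calls, k_min = 1, k_max = 4, replicates = 5,
                   base_seed = 42, tol = 1e-5, max_iter = 500)
(ev <- evanno_delta_k(scan))
#> Evanno delta-K table (best K = 2 )
#>  K n_rep   mean_L     sd_L      L1   L2_abs   delta_K
#>  1     5 -49744.4  0.00000      NA       NA        NA
#>  2     5 -47673.8  5.30578 2070.56 989.5981 186.51330
#>  3     5 -46592.9 31.15592 1080.96  59.8764   1.92183
#>  4     5 -45571.8 75.67033 1021.08       NA        NA

fit    <- admixture_em(gmc$calls, K = attr(ev, "best_K"), seed = 42)
groups <- assign_subgroups(fit)
amova_one_level(squared_distance_matrix(gmc$calls), groups$group,
                n_perm = 999, seed = 42)
#> AMOVA (2 groups, sizes 30/30)
#>       Source df        SS       MS Est.Var.    %    Nm
#>   Among Pops  1  1424.983 1424.983   29.540   5% 9.120
#>  Within Pops 58 31250.100  538.795  538.795  95%
#>        Total 59 32675.083       NA  568.334 100%
#> PhiPT = 0.0520  (P = 0.001, 999 permutations)
```

The ΔK column peaks sharply at K = 2 (the simulated truth), the AMOVA
recovers ΦPT = 0.052 against a realized simulated FST of 0.047, and the
low Nm ≈ 9 reflects the moderate differentiation (for a panel with
ΦPT ≈ 0.006, Nm rises to ~86: weak structure reads as massive effective
gene flow). `diversity_report(gmc, groups$group)` then tabulates Na, Ne, I,
h, uh and private alleles per subgroup with an arithmetic Mean column, and
`run_pipeline()` wires all stages together and writes the complete report
bundle (filter report, distribution/AMOVA/diversity tables, Evanno table,
Q matrix, Newick dendrogram, JSON manifest).

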