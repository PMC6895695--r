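# cardiofate

Variability across human iPSC lines means that nominally identical directed
cardiac differentiations end very differently: some lines yield almost pure
cardiomyocytes (CMs), others yield mostly epicardium-derived cells (EPDCs),
and some never form a beating syncytium at all. `cardiofate` implements, as
a tested and reusable R package, the computational chain that links iPSC
transcriptomes to that differentiation outcome:

1. **Deconvolution** — estimate per-sample CM/EPDC/stem-cell fractions from
   bulk RNA-seq by nonnegative least squares on a marker-gene signature
   matrix (top-N overexpressed genes per population), with validation
   against an orthogonal purity measure (%cTnT).
2. **Fate threshold sweep** — dichotomise lines into CM-fated vs EPDC-fated
   at each candidate CM:EPDC ratio (0:100 … 90:10), count differentially
   expressed genes (Welch t on log2(TPM+1), Storey q < 0.1) at each, pick
   the ratio maximising the count, and calibrate it against a
   class-size-preserving label-permutation null.
3. **Signature models** — per-gene GLMs of outcome on expression (identity
   or logit link, pseudo-R²) and an L1-penalised (LASSO) joint model with
   10-fold cross-validation for the total variance in fate explained.
4. **X-chromosome allelic imbalance** — per-gene allelic imbalance
   fractions AIF = max(ref, alt)/(ref+alt) ∈ [0.5, 1], pseudoautosomal
   region masking (PAR1 60,001–2,699,520; PAR2 154,931,044–155,260,560),
   and Mann-Whitney comparisons of X-inactivation state between fate groups
   and along chrX intervals.
5. **Enrichment, association, replication** — gene-set tests on the
   normalised fate contrast; logistic covariate models (sex, age,
   ethnicity, passage) with a Firth fallback; a vectorised genotype-dosage
   scan with genomic-inflation diagnostics; clone/twin outcome concordance;
   and cross-cohort signature replication with Fisher enrichment against an
   empirical background.

Everything runs on a built-in synthetic cohort generator
(`simulate_ipsc_cohort()` and friends) that plants known fractions,
signature effects, X-inactivation states and genetic effects, so every
stage is testable without access to restricted cohort data.

## Worked example

```r
library(cardiofate)

cohort    <- simulate_ipsc_cohort(seed = 1)           # 184 lines, 91 planted genes
cohort_b  <- simulate_ipsc_cohort(n_lines = 39, n_terminated = 24,
                                  profiles = cohort$profiles, seed = 1001)
genotypes <- simulate_genotypes(n_lines = 184, n_variants = 5000, seed = 2001)

res <- run_pipeline(cohort, cardiofate_config(seed = 1),
                    genotypes = genotypes, cohort_b = cohort_b)
```

which prints, stage by stage:

```
[cardiofate] deconvolution: 150 markers, 147 samples, r(cTnT) = 0.986
[cardiofate] fate sweep: best threshold 0.30, 46 DE genes, 46 signature genes
[cardiofate] signature model: 46 per-gene fits, joint CV R2 = 0.576
[cardiofate] AIF: 14680 gene-sample values, 0 PAR-masked, CM vs EPDC p = 1.3e-184
[cardiofate] association: sex p = 0.00745 (Z test), scan lambda = 1.003
[cardiofate] replication: 2/46 signature genes, fold 1.60, Fisher p = 0.361
```

Reading the numbers: the 150-marker signature (50 per population)
reconstructs cell fractions that correlate at r = 0.986 with the simulated
%cTnT purity; the sweep recovers the planted 30:70 CM/EPDC optimum with 46
genes at q < 0.1 (far outside its permutation null); the LASSO joint model
explains ~58% of fate variance out of sample; CM-fated female lines show
markedly lower allelic imbalance on chrX (X reactivation); female sex
predisposes to the CM fate; the null genotype scan is calibrated
(λ_GC ≈ 1.00); and signature replication in an independent cohort with its
own (different) planted signature is, correctly, indistinguishable from
background. Individual stages are available as plain functions
(`estimate_fractions()`, `threshold_sweep()`, `joint_lasso_cv()`,
`compute_aif()`, `variant_scan()`, `contrast_replication()`, …) returning
classed objects with `print()`/`plot()` methods.

## Acceptance script

`scripts/acceptance.R` re-runs the entire chain from scratch — cohort
generation, deconvolution, threshold sweep, signature models, allelic
imbalance, association scan and cross-cohort replication — and writes its
JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`.

## Documentation

The methods vignette (`vignettes/cardiofate-methods.Rmd`) describes the
statistical model of each stage, the synthetic cohort's generative
assumptions and their limits, the default parameters and where they come
from, and the numerical choices (solver, tie-breaks, boundary conventions).
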