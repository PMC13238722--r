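# stromasig

Stromal co-expression signatures of PTEN protein loss in prostate cancer.

PTEN protein loss is common in prostate tumors and activates PI3K–AKT–mTOR
signaling, but protein-level assessment by immunohistochemistry (IHC) says
nothing about the remodeling of the tumor microenvironment that accompanies
it. `stromasig` implements, as tested and reusable R functions, the full
inference chain from pathology scores to a prognostic transcriptional
signature:

1. **IHC scoring** — per-core quality control (tumor present, stromal PTEN
   positive as internal control), the H-score
   `H = 3·%strong + 2·%moderate + 1·%weak ∈ [0, 300]`, per-patient mean
   aggregation, and calibration of the PTEN-loss cutoff by scanning
   candidate thresholds for the split that best discriminates a
   PI3K–AKT–mTOR activity signature (two-sided Wilcoxon rank-sum).
2. **Expression preprocessing** — low-count filtering, TMM normalization
   factors, log-CPM, and an approximate variance-stabilizing transform.
3. **Differential expression** — per-gene linear models with voom-style
   precision weights, empirical-Bayes moderated t statistics, BH FDR, and
   DEG calling at `|log2FC| > 0` (human) or `> 1` (mouse), FDR < 0.05.
4. **Signed co-expression network** — biweight midcorrelation with outlier
   capping, signed adjacency `((1+r)/2)^β` (β = 14 human, 18 mouse),
   topological overlap `TOM_ij = (ℓ_ij + a_ij)/(min(k_i,k_j) + 1 − a_ij)`,
   average-linkage module detection with eigengene merging, module–trait
   association (|r| > 0.2, FDR < 0.05), kME and connectivity statistics.
5. **Signature engine** — module × DEG intersection scored by Jaccard
   index, derivation of the module signature (DEG ∩ module), per-sample
   scoring as mean z-scored expression, GMT I/O, homolog mapping.
6. **Survival stratification** — Kaplan–Meier, log-rank, Cox
   proportional-hazards by Newton–Raphson on the Efron partial likelihood
   (hand-rolled, cross-checked against `survival`), likelihood-ratio
   comparison of nested models, Harrell's concordance, quartile (Q1 vs Q4)
   and median-risk-score stratification, including the PTEN-loss-subset
   sub-stratification.
7. **Synthetic cohort** — negative-binomial counts over planted latent
   modules, a zero-inflated H-score distribution with loss effects planted
   exactly in H = 0 patients, per-core QC failures, and censored survival
   with a planted hazard ratio of 0.68 per SD of the stromal signature, so
   every stage is testable without patient data.

## Worked example

Simulate a cohort at the study scale and run the whole chain:

```r
library(stromasig)

cfg <- simConfig(n_patients = 197, n_genes = 1000, seed = 1)
sim <- simulateCohort(cfg)

disc <- runDiscovery(sim$cores, sim$clinical, sim$counts,
                     sim$truth$pi3k_genes, profile = "human",
                     max_genes = 1000)
c(included = sum(disc$patients$included), threshold = disc$threshold,
  degs = sum(disc$de$significant), signature = length(disc$signature))
#> included threshold      degs signature
#>      153         0       228       128

m  <- filterGenes(sim$counts, 5, 0.70)
lc <- logCPM(m, tmmFactors(m))
strat <- runStratification(sim$clinical, lc, disc$signature,
            pten_status = setNames(ifelse(sim$truth$loss_status, "loss",
                                          "presence"),
                                   names(sim$truth$loss_status)))
hr <- hazardRatios(strat$cox_full)
round(c(HR = hr$HR[hr$term == "signature"], lr_p = strat$lr$p_value,
        cindex = concordanceIndex(strat$cox_full)), 3)
#>     HR   lr_p cindex
#>  0.691  0.024  0.606
```

Reading the numbers: 153 of 197 synthetic patients had at least one core
passing QC; the threshold scan recovered the planted cutoff H = 0; the
discovery stage called 228 DEGs and derived a 128-gene module signature
containing the planted 75-gene stromal program; on the survival side each
SD of the signature multiplies the recurrence hazard by 0.69 (planted:
0.68), and adding the signature to PSA + Gleason significantly improves
the Cox model (likelihood-ratio p = 0.024).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end on a freshly simulated cohort at the
given seed — IHC scoring, threshold calibration, normalization,
differential expression, network and module detection, signature
derivation and survival stratification — logging the recovered quantities
to stderr and writing the acceptance JSON to `--out`.

## Layout

```
R/                     implementation (S4 classes: ModuleSet, ThresholdScan,
                       SignatureScores, CoxPHFit)
tests/testthat/        unit, property and acceptance suites
scripts/acceptance.R   end-to-end acceptance runner
vignettes/             methods vignette (models, parameters, limitations)
```
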