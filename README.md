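# hybridsig

Hybrid prognostic signatures and random-signature benchmarks for censored
survival outcomes.

## What problem does this solve?

Prognostic gene-expression signatures for ER-positive / HER2-negative
breast cancer are routinely validated by statistical significance in a
Cox model. That criterion is nearly vacuous: because a large fraction of
the breast-cancer transcriptome is correlated with proliferation — which
carries genuine prognostic information — a *random* set of 15 genes is
almost always significantly associated with outcome on a cohort of a few
hundred patients. Two questions follow for anyone building or buying a
signature:

1. Can clinicopathological information and molecular information be
   combined in a data-driven way? `hybridsig` builds a **hybrid
   signature** by running iterative sure independence screening (SIS) for
   Cox models over all gene expressions *plus the Nottingham Prognostic
   Index (NPI) treated as a pseudo-gene*, so the clinical index competes
   with — and is selected alongside — individual genes.
2. Is a given signature actually better than random gene sets?
   `hybridsig` evaluates any signature with a full censored-data metric
   suite and scores it against an explicit random-signature null via the
   **Signature Skill Score**

   `SSS = (⟨BS⟩_random − BS) / ⟨BS⟩_random`,

   the relative improvement of the signature's
   inverse-probability-of-censoring-weighted (IPCW) Brier score over the
   mean Brier score of seeded random same-size signatures.

The evaluation suite comprises Harrell's C-index (pair formula
`c = ((C−D)/(C+D+T_x)+1)/2`), IPCW cumulative/dynamic time-dependent
AUC(t) and its trapezoidal integral (IAUC) with paired signed-rank
comparisons, the logrank statistic `χ² = Σ (O−E)²/E`, Nagelkerke's pseudo
R² `1 − exp{−(2/n)(l_β − l_0)}`, calibration curves with MAE and Q(0.9),
variance inflation factors, permutation-significance recursive
partitioning of hazard scores into risk groups, and intersections of
best-prognosis groups across multiple signatures (the
chemotherapy-omission analysis). A synthetic cohort generator with a
latent proliferation factor, planted prognostic genes and an NPI-like
clinical score makes every stage testable end-to-end without access to
controlled-access patient data. Built-in rosters ship the gene lists of
the EndoPredict and OncotypeDx assays (gene lists only — not their
proprietary scores), a fixed Random negative control, NPI+Random, and the
hybrid 14-gene + NPI list.

## Worked example

Build a hybrid signature on a synthetic cohort, evaluate it on held-out
patients, score it against random signatures, and stratify patients into
risk groups:

```r
library(hybridsig)

cfg <- syntheticConfig(nPatients = 800, nGenes = 1000, seed = 42)
g <- generateCohort(cfg)
g$cohort
#> SignatureCohort: 1000 genes x 800 samples
#>   endpoint: disease_specific; events: 348/800 (43.5%)
#>   clinical columns: er, her2, chemo, age, tumor_size_cm, node_stage, grade, npi

parts <- splitCohort(g$cohort, 0.7, seed = 1)
outTrain <- survOutcome(parts$train, horizon = 10)
outTest  <- survOutcome(parts$test,  horizon = 10)

# screen all genes + the NPI pseudo-feature on the training set
full <- assembleDesignMatrix(parts$train,
  geneSignature("all", rownames(parts$train), includesNPI = TRUE))
scr <- sisSelect(full, outTrain, targetSize = 15, seed = 1)
scr
#> ScreeningResult (vanilla, 2 iterations): 15 features selected
#> GeneSignature 'SIS': 14 genes + NPI
#>   G00213, G00305, G00383, G00141, G00273, G00263, G00387, G00004, ...

# fit on training, evaluate on test with training standardization
dTrain <- assembleDesignMatrix(parts$train, scr@selected)
fit <- fitCox(dTrain, outTrain)
dTest <- assembleDesignMatrix(parts$test, scr@selected,
                              standardization = dTrain)
evaluateSignature(fit, dTest, outTest)
#> MetricReport (horizon 10y): C = 0.818, IAUC = 0.859, Brier = 0.057, SSS = NA
#>   logrank chi2 = 50.40 (p = 1.25e-12), R2 = NA, cal MAE = 0.083

# Signature Skill Score against 25 seeded random 15-gene signatures
ref <- randomReference(parts$train, parts$test, k = 15, nRandom = 25,
                       seed = 9)
signatureSkillScore(evaluateSignature(fit, dTest, outTest)@brier,
                    ref$brier)
#> [1] 0.3862831

# risk groups by permutation-significance recursive partitioning
pred <- predictRisk(fit, dTest, timeGrid = 10)
partitionRiskGroups(pred@relativeHazard, outTest, seed = 3)
#> RiskStratification: 4 risk groups
#>   Node 1: n = 83, events = 1
#>   Node 2: n = 72, events = 14
#>   Node 3: n = 65, events = 37
#>   Node 4: n = 20, events = 18
#>   thresholds: 0.5224, 1.812, 8.711
```

Reading the output: the screened signature keeps the NPI (the clinical
index survives against 1000 genes, including true prognostic ones like
`G00004`), the hybrid model discriminates well out of sample (C = 0.82),
its Brier score improves on the random-signature mean by 39%
(SSS = 0.386), and the test cohort splits into four risk groups whose
event fractions rise from 1/83 in the best-prognosis group (Node 1) to
18/20 in the worst.

The NPI-only signature, the built-in assay gene lists, and the whole
orchestration (screen, fit, evaluate, stratify, intersect best groups,
random reference) are available through `builtinSignatures()` and
`runPipeline(pipelineConfig(...))`; see the vignette in
`vignettes/hybrid-signatures.Rmd` for the methods.

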