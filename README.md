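# pairsig

Prognostic signatures from the **relative ordering of immune-related
lncRNA pairs** in tumor expression profiles.

Absolute expression levels are fragile across sequencing platforms and
normalization pipelines. `pairsig` instead encodes, for every ordered
gene pair (a, b) and sample s, the binary indicator

```
P_ab(s) = 1  if expression(a, s) > expression(b, s),  else 0
```

which depends only on the within-sample ranking of the two genes and is
therefore invariant to any strictly increasing per-sample transform — no
cross-sample normalization is required. A patient's risk score is the
coefficient-weighted sum over the pairs of a fitted signature,

```
score(s) = Σ_i  β_i · P_i(s)
```

with the β_i estimated by multivariate Cox proportional-hazards
regression. The package implements the full workflow for building and
validating such signatures on a tumor/normal expression cohort with
survival follow-up:

1. **screen** lncRNAs co-expressed with immune genes
   (|r| > 0.4, p < 0.001 on log2(x+1) values);
2. **differential expression** of the screened lncRNAs
   (limma moderated-t, BH FDR < 0.05, |log2FC| > 1.5);
3. **pairing** — all n(n−1)/2 pair indicators, keeping pairs whose
   one-frequency lies strictly inside (0.20, 0.80);
4. **selection** — univariate Cox (Wald p < 0.01) → repeated
   cross-validated LASSO-Cox (`lambda.min`) → backward stepwise
   elimination by AIC;
5. **risk dichotomization** at the AIC-optimal cutoff, and **validation**
   by time-dependent ROC/AUC (Kaplan–Meier censoring weights),
   Kaplan–Meier/log-rank, independence from clinical covariates,
   stratified analysis, and association with immune-infiltration,
   drug-response and qRT-PCR ΔCt tables.

A seeded synthetic-cohort generator (`simulation_spec()` /
`simulate_cohort()`) produces tumor/normal cohorts with planted
immune-correlated, differentially expressed lncRNAs and survival drawn
from a proportional-hazards model on planted pair indicators, so every
stage can be checked against ground truth.

Intended users: computational biologists building rank-based prognostic
models from bulk RNA-seq cohorts with survival follow-up, and method
developers who need a tested reference implementation of the pair-matrix
/ LASSO-Cox / AIC-cutoff chain.

## Worked example

```r
library(pairsig)

spec   <- simulation_spec(seed = 1)        # 500 tumors, 50 normals,
cohort <- simulate_cohort(spec)            # 3 planted pairs, 30% censoring
run    <- run_pipeline(cohort$expr, cohort$surv, pipeline_config(seed = 1))
print(run)
```

```
Pair-signature pipeline run
  funnel: 300 lncRNA -> 40 irlncRNA -> 20 DE -> 190 pairs -> 70 valid -> 17 Cox -> 11 LASSO -> 6 signature
  cutoff -0.1430; log-rank p 2.86e-24; AUC: 1y=0.751, 2y=0.795, 3y=0.806
```

The funnel line counts survivors of each stage: of 300 lncRNAs, 40 pass
the immune co-expression screen, 20 are differentially expressed, their
190 pairs shrink to 70 with informative one-frequency, 17 are
prognostic univariately, 11 survive the LASSO, and backward AIC
elimination leaves a 6-pair signature. The signature recovers all three
planted pairs with coefficients close to truth:

```r
head(run$signature, 3)
#>           pair_id       beta        hr    ci_low   ci_high            p
#> 1 LNC0001|LNC0002  1.2088173 3.3495210 2.6085024 4.3010467 2.653043e-21
#> 3 LNC0003|LNC0004 -1.0997890 0.3329413 0.2580979 0.4294879 2.547220e-17
#> 6 LNC0005|LNC0006  0.5768669 1.7804513 1.3979183 2.2676623 2.947968e-06
cohort$truth$planted_pairs
#>    gene_a  gene_b beta
#> 1 LNC0001 LNC0002  1.2
#> 2 LNC0003 LNC0004 -0.9
#> 3 LNC0005 LNC0006  0.6
```

The log-rank p compares survival between the high/low risk groups split
at the AIC-optimal cutoff; the AUCs are cumulative/dynamic
time-dependent AUCs at 1/2/3 years. To score a new cohort with a fitted
signature (preserving each pair's fitted orientation) use
`score_cohort(run$signature, new_expr)`.

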