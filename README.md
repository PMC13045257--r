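# TCDtype

Tumours evade immune control not only by excluding T cells but by driving
the T cells they contain into dysfunctional states — exhaustion, senescence,
exclusion and a broader dysfunction programme. TCDtype quantifies how
strongly each of these four T cell dysfunction (TCD) states is engaged in
every tumour sample of a bulk expression cohort, groups tumours into
severity-ordered TCD subtypes, and carries the subtypes through the standard
downstream questions: which miRNAs and methylation probes track severity,
whether a small miRNA panel predicts survival, and whether the extreme
subtypes can be recognised from those panels. It is aimed at computational
oncology analysts working with FPKM-like expression matrices plus matched
miRNA, methylation and clinical tables.

## The statistic at the core

For tumour sample *j*, a gene is differentially expressed (DEG) when its
fold change against the averaged normal reference, FC = x / (mean normal +
pseudocount), satisfies FC > 2 or FC < 0.5. Each TCD signature is then
scored by the upper-tail hypergeometric probability of its DEG overlap:

    P(k; N, M, n) = C(M,k) C(N-M, n-k) / C(N,n),      p_j = P(X >= k)

with N genes in the universe, M DEGs in sample *j*, n signature genes, and
k DEGs inside the signature. The 4 x samples matrix of these p-values is
the **TCD profile**. Subtypes come from consensus clustering of the profile
(PAM, Manhattan distance, k = 2..8, delta-area model selection); severity
ordering ranks clusters by mean -log10(p). Prognosis uses the linear Cox
risk score f(X) = x'beta from a Breslow partial-likelihood fit over the
selected miRNAs, with a median split into high/low risk groups.

A synthetic cohort generator (`generate_cohort()`) plants all of this
structure — subtype shifts on the signatures, monotone miRNA effects,
methylation trends, severity-dependent hazards — so that every stage is
testable against known ground truth without any external download.

## Worked example

```r
library(TCDtype)

co <- generate_cohort(cohort_config(seed = 1))   # 4 x 50 tumours, 50 normals
normals <- names(co$sample_role)[co$sample_role == "normal"]

pr <- build_tcd_profile(co$expression, co$signatures, normals)
pr
#> TCD profile: 4 states x 200 tumour samples (universe 2000 genes)
#> median -log10(p) per state:
#>  exhaustion  senescence   exclusion dysfunction
#>       1.928       1.798      20.167       4.435

cc <- consensus_cluster(profile_matrix(pr), seed = 1)
cc
#> Consensus clustering over k = 2..8 (100 resamples, item fraction 0.80)
#> relative delta-areas:
#>    k2    k3    k4    k5    k6    k7    k8
#> 0.377 0.667 0.194 0.037 0.035 0.017 0.021
#> chosen k: 4

asg <- order_subtypes(pr, cc$labels$k4)
asg
#> Subtype assignment (severity-ordered):
#>     T-low  T-middle T-middle2    T-high
#>        56        44        50        50

lr <- logrank_test(co$clinical$os_time, co$clinical$os_event,
                   asg$subtype[co$clinical$sample_id])
sprintf("log-rank chisq = %.1f (df %d), p = %.3g", lr$chisq, lr$df, lr$p)
#> "log-rank chisq = 123.3 (df 3), p = 1.49e-26"
```

The profile medians show enrichment rising with signature size and planted
effect; the delta-area sequence flattens after k = 4, matching the four
planted subtypes (50 each, recovered here with a handful of boundary
samples swapped between the two weakest grades); and survival separates
sharply across severity because the generator ties the hazard to the grade.
`run_pipeline(pipeline_config(...))` chains all stages — profile, subtyping,
scores, differential miRNAs/DMPs, Cox risk model with held-out
stratification, and subtype classifiers — writing TSV/JSON artifacts and a
run report; `write_cohort()` emits the matching input files.

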