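# noduleTLR

Adaptive cross-domain transfer-learning radiomics for telling lung
granulomatous nodules (LGN) from solid lung adenocarcinoma (LAC) on
nodule-centred CT patches.

LGN is one of the great radiological mimickers of lung cancer: both
present as solitary pulmonary solid nodules (SPSNs, ≤ 30 mm) and share
lobulated shapes and spiculated signs on CT. `noduleTLR` implements the
full modelling stack for this differential diagnosis, runnable end to end
on synthetic data at desk scale:

* **Preprocessing** — lung-window (level −600 HU, width 1500 HU)
  nodule-centred 224 × 224 three-channel patches (`makePatch()`,
  `applyWindow()`).
* **Adaptive transfer learning** — a source network pretrained on a
  labelled source domain; the target network initialised from it and
  fine-tuned under a meta-network-gated source-feature-matching
  constraint (`pretrainSource()`, `trainTargetWithTransfer()`); 3904
  pooled convolutional features per patient (`extractFeatures()`), as a
  `SummarizedExperiment`.
* **Transfer learning signature (TLS)** — Mann–Whitney screening followed
  by a sparse Bayesian extreme learning machine: constructive
  fast-marginal-likelihood ARD logistic regression that selects a handful
  of features and scores each patient in [0, 1] (`buildTls()`,
  `fitSbelm()`, `tlsScore()`).
* **Source-domain ranking** — sliced 1-Wasserstein distance between
  source and target embeddings in a shared frozen feature space
  (`slicedW1()`, `rankSources()`); smaller distance = recommended source.
* **Fusion (TLRM)** — sparse-Bayes-LASSO logistic fusion of the TLS with
  clinical factors and subjective CT findings (`fitSparseBayesLasso()`,
  `tlrmScore()`), against a multivariable-logistic clinical comparator
  (`fitClinicalLogistic()`).
* **Evaluation** — AUC with DeLong CIs and tests, IDI, Hosmer–Lemeshow
  calibration, decision curves, stratified analysis (`delongTest()`,
  `idi()`, `hosmerLemeshow()`, `decisionCurve()`, `stratifiedAnalysis()`).
* **Synthetic fixtures** — a nodule renderer and cohort generator whose
  defaults encode a reference multicentre cohort summary (LAC older,
  larger, more lobulated/spiculated), plus source-domain generators with a
  `targetOverlap` similarity dial (`cohortSpec()`,
  `generateTargetCohort()`, `generateSourceDomain()`).
* **Orchestration** — `runPipeline()` drives the whole experiment from a
  validated (YAML-loadable) config with per-stage caching and a hash
  manifest; `transferBenchmark()` repeats it over seeds.

The model at the core: with per-channel gates
`g_c = σ(logit_c + slope_c · s̄_c)` and affine matching maps `M`, the
target network minimises

    CE(y, f(x)) + λ Σ_stages (1/C) Σ_c g_c ‖M(t)_c − s_c‖²

where `t` and `s` are pooled target- and source-network features of the
same patches; gates move first-order on validation data (channels no more
label-informative than noise are down-weighted) and the TLS/TLRM are ARD /
hierarchical-Laplace sparse Bayesian logistic models. See the methods
vignette (`vignettes/transfer-learning-radiomics.Rmd`) for assumptions,
defaults and limitations.

## Worked example

```r
library(noduleTLR)
co  <- generateTargetCohort(cohortSpec(n = 120, seed = 7))
src <- generateSourceDomain(sourceDomainSpec("wsi_like", nClasses = 4,
                                             n = 120, targetOverlap = 1,
                                             seed = 8))
cfg    <- networkConfig(widthScale = 0.25, epochs = 8)
srcNet <- pretrainSource(src, cfg, seed = 9, epochs = 3)$net
tr <- co$patches[1:60]; va <- co$patches[61:120]
fit <- trainTargetWithTransfer(tr, va, srcNet, lambda = 0.1, seed = 10)

fe <- extractFeatures(fit$net, tr)
fe
#> class: SummarizedExperiment
#> dim: 976 60
#> assays(1): features
#> rownames(976): tlf_s1_c001 tlf_s1_c002 ... tlf_s6_c479 tlf_s6_c480
#> colData names(4): patient_id cohort label provenance

tls <- buildTls(fe, patchLabels(tr))
tls$model
#> SbelmModel: 1/672 features retained (converged, 4 iterations)

sc <- tlsScore(tls$model, featureMatrix(extractFeatures(fit$net, va)))
delongCi(sc, patchLabels(va))
#> $auc    0.765625
#> $lower  0.6055034
#> $upper  0.9257466
```

At `widthScale = 0.25` the extractor emits 976 features (the default
full-width configuration emits exactly 3904); the screen passes 672 of
them and the SBELM keeps one dominant feature, whose validation AUC of
0.77 on these 60 held-out patients comes with the DeLong 95% interval
shown. A full experiment — three ranked source domains, the non-transfer
baseline, TLS, TLRM and clinical models with evaluation reports — is one
call: `runPipeline(defaultRunConfig(seed = 1), outDir = "out")`.

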