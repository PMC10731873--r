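# riskfilter

Online updating of logistic prognostic risk models by **direct particle
filtering**: the coefficient vector of the risk model is itself the only
state of a particle filter, so every newly observed patient outcome updates
the model a little — no drift detector, no scheduled retraining.

The motivating setting is postoperative survival risk after resection of
non-small cell lung cancer: a single-centre registry of ~1300 patients with
~70 mixed-type clinical features, a heavily imbalanced binary outcome
(death is the minority class), and a deployed logistic model whose accuracy
decays as practice shifts (concept drift / model decay).  The package
provides the full workflow around the filter: feature reduction, the
initial batch fit, the assimilation loop, before/after evaluation, and a
synthetic cohort generator with known ground truth so everything is
testable without private hospital data.

## The method in brief

With risk model
`ln(y/(1−y)) = θ₁x₁ + … + θ_d x_d + b` and flat parameter vector
`θ = (θ₁,…,θ_d, b)`, the filter assigns θ artificial pseudo-dynamics

```
θ_{k+1} = θ_k + ε_k,   ε_k ~ N(0, Q)
```

and treats each binary outcome as an indirect measurement of θ through the
integrated observation function

```
Y_k = sigmoid(θ·X_k) + ξ_k,   ξ_k ~ N(0, R).
```

Each cycle: jitter M weighted particles with `N(0, Q)`; reweight by the
Gaussian squared-error likelihood `exp(−(Y − Ŷ)²/2R)` of the new patient's
outcome; record the weighted posterior mean; resample (multinomial).  The
final parameter estimate is the mean of the last `estimate_window`
posterior means.  `Q` is built from the initial fit by "differentiation and
standardisation" (`build_q()`): normalised absolute parameter shares on the
diagonal, normalised absolute feature correlations off it, shrunk by 0.1
and repaired to positive semi-definite.  A deterministic dense-grid Bayes
filter (`grid_bayes_filter()`) serves as an independent reference
implementation for validating the particle filter on one-parameter models.

## Worked example

End-to-end pipeline on a synthetic cohort shaped like the target registry
(1288 patients, 70 raw features, 12% deaths):

```r
library(riskfilter)
cfg <- default_run_config()
cfg$seed <- 7
cfg$paths$output_dir <- "demo_run"
res <- cmd_run_all(cfg)
#> [simulate] wrote 1288 patients to demo_run/cohort.csv
#> [reduce] 70 -> 5 features
#> [fit] theta0 over 4 columns, cv accuracy 0.9200
#> [assimilate] 608 cycles, stability 4.097 (not stable)
#> [evaluate] accuracy batch 0.9000 -> filtered 0.9000
print(res$comparison)
#> == batch model ==
#> accuracy 0.9000  (n = 430)
#>             precision  recall      f1     n
#> survival       0.9227  0.9686  0.9451   382
#> death          0.5862  0.3542  0.4416    48
#> AUC 0.8702
#> == filtered model ==
#> accuracy 0.9000  (n = 430)
#> ...
```

The pipeline simulated a cohort, split it 2/3–1/3 (858 training rows = 250
initialisation + 608 filtering, 430 test), reduced 70 raw features to 5
(variance filter → correlation filter → cross-validated lasso →
random-forest importance screen), fitted the initial model θ₀ on the 250
initialisation rows, assimilated the 608-patient stream, and compared both
models on the held-out test set.  On this *static* stream the filtered
model preserves the batch model's discrimination (accuracy 0.90, AUC 0.87)
while its parameters keep exploring — the reported stability (max trailing
parameter range 4.1) quantifies that exploration.

The filter earns its keep when the data-generating process changes.
`drift_experiment()` flips the sign of the leading risk coefficient midway
through the stream, re-draws post-drift outcomes, and compares the frozen
batch model against the assimilated one on post-drift test data:

```r
dr <- drift_experiment(n_seeds = 10, seed = 1)
round(colMeans(dr), 3)
#> acc_frozen acc_filtered
#>      0.895        0.969
sum(dr$acc_filtered > dr$acc_frozen)
#> [1] 10
```

The assimilated model recovers 5–12 points of post-drift accuracy in every
replicate — without anyone noticing the drift, which is the point.

A thin command-line wrapper ships in `inst/scripts/riskfilter`
(`riskfilter simulate|run-all --config cfg.yaml --out DIR --seed N`).

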