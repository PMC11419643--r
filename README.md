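# strokerisk

An R package for stroke-risk prediction on tabular clinical cohorts in the
Kaggle stroke-prediction CSV dialect
(`id,gender,age,hypertension,heart_disease,ever_married,work_type,`
`Residence_type,avg_glucose_level,bmi,smoking_status,stroke`). It implements
a complete modelling chain for biostatisticians and ML practitioners who
want every stage — imputation through encrypted storage — reproducible,
testable and auditable on synthetic data:

1. **HKGA imputation** — hybrid k-means + genetic-algorithm clustering.
   Lloyd iterations seed a GA over assignment chromosomes that
   minimizes the within-cluster distance objective
   `f(C_1..C_k) = Σ_i Σ_{x∈C_i} ‖x − z_i‖`, with roulette selection on
   shifted goodness, uniform crossover, two-point resampling mutation and
   elitism; empty clusters are repaired. Masked cells are imputed with
   cluster means.
2. **Aggregation** — per-attribute mean, median, population SD (divisor
   `b`) and sample variance (divisor `b − 1`).
3. **ICA reduction** — whitening + fixed-point unmixing with the tanh
   contrast; components kept when mean |activation| > 0.1.
4. **T-test / Spearman filter + UD-GSRBEHO selection** — pooled two-sample
   statistics `τ = (x̄_a − x̄_b)/√(δ²(d_a+d_b)/(d_a d_b))` summarized by
   `λ = 1 − 6Στ²/(l(l²−1))`, then a wrapper selector: elephant herding
   optimization (clan updating/separating) hybridized with the gradient
   search rule, direction-of-movement term and a local escape operator,
   with the β schedule `β = β_min + (β_max − β_min)(1 − (m/M)³)²`
   (1.2 → 0.2) and Rand-index fitness against the labels.
5. **Fuzzy risk coding** — trapezoidal membership functions and a six-code
   comorbidity rule base over the diabetes/heart-disease class grid;
   centroid defuzzification yields a crisp value in [1, 6].
6. **AWBi-LSTM** — a from-scratch bidirectional LSTM (sigmoid gates, tanh
   candidate, concatenated final hidden states, softmax readout) trained
   by backpropagation through time under a three-branch mutation-selection
   scheme (square / absolute / Huber loss; the branch with the smallest
   batch loss is adopted).
7. **Metrics** — precision, recall/sensitivity, specificity, F-measure,
   accuracy, NPV `TN/(TN+FN)` and MCC, binary or macro-averaged.
8. **Secure storage** — MD5-salted EC-ElGamal over a prime-field curve:
   `E1 = R·B + S_kP`, `E2 = M + R·A + S_kP` with
   `S_k = MD5(encode(A)‖salt)` mapped into the group, Koblitz message
   embedding, and a JSON-lines ciphertext store.

A synthetic-cohort generator (`generate_cohort()`) reproduces the dialect's
structure — mixed types, MCAR missingness in `bmi`/`smoking_status`, class
imbalance, planted logistic effects — so the whole chain runs without any
external download. See `vignettes/strokerisk-methods.Rmd` for the full
methods account.

## Worked example

```r
library(strokerisk)

cfg <- pipeline_config(
  cohort = cohort_spec(n_records = 2000, seed = 1, preset = "separable"),
  seed = 11)
fit <- strokerisk(config = cfg)
print(fit)
#> Stroke-risk model (HKGA + ICA + UD-GSRBEHO + fuzzy + AWBi-LSTM)
#>   cohort: 2000 records, 10 predictors (72 imputed cells)
#>   selected features (4): age, heart_disease, avg_glucose_level, bmi
#>   target: stroke; held-out accuracy: 0.9675
```

The selector kept the attributes that actually drive the planted outcome
(the steep glucose effect dominates this regime, with age and heart disease
secondary), and the classifier recovers the planted signal on the held-out
20% split: accuracy 0.9675 against a logistic-oracle ceiling of ~0.985.
`summary(fit)` adds the full metric report, `plot(fit)` the training-loss
trace, and `predict(fit, newdata)` scores fresh cohorts. Predicted records
are encrypted with

```r
enc <- encrypt_predictions(fit, path = "ciphertext.jsonl", seed = 11)
decrypt_record(enc$records[[1]], enc$keys, enc$curve)
#> [1] "id:4;code:0"
```

A thin CLI wraps the same functions:

```sh
strokerisk simulate --config cfg.yaml --out out/
strokerisk run      --config cfg.yaml --out out/ --seed 11
```

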