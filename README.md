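# fittnet

Individualized FITT exercise prescriptions for older adults from a
Levenberg–Marquardt-trained neural network.

## The problem

Aerobic exercise programmes for older adults are usually prescribed from
one-size-fits-all guideline ranges, even though the dose needed to improve
cardiorespiratory fitness (CRF, measured as VO₂max in mL·kg⁻¹·min⁻¹) varies
strongly with age, sex, body composition and baseline fitness. `fittnet`
implements a data-driven alternative: a small multilayer perceptron that maps
a subject's basic characteristics and a target CRF improvement to the four
FITT prescription elements —

* **F**requency (sessions/week),
* **I**ntensity (% heart-rate reserve, %HRR),
* **T**ime (minutes/session),
* **V**olume (programme weeks),

trained on subject-level samples expanded from study-level summary
statistics of the aerobic-training literature. It is aimed at exercise
scientists and biostatisticians who want to build, validate and apply such
prescription models end to end.

## The model

The regressor is a 5–12–10–8–4 feed-forward network (tanh hidden layers,
linear output): inputs are age, sex (0 = female, 1 = male), BMI, baseline
VO₂max and the target relative improvement; outputs are the encoded FITT
elements, with intensity coded as `%HRR/100 − 0.5` so that 50 %HRR is the
coding origin (60 %HRR ↦ 0.1).

Weights are fit from scratch by a damped Gauss–Newton (Levenberg–Marquardt)
optimizer. With residual vector *e* and Jacobian *J = ∂e/∂w*, each update
solves

    Δw = (JᵀJ + λI)⁻¹ Jᵀe

with the damping factor λ decreased (×0.1) after accepted steps —
approaching Gauss–Newton — and increased (×10) after rejected ones —
approaching gradient descent. The loss is the L2-regularized MSE

    L = MSE + α Σⱼ wⱼ²

(biases unpenalized), treated exactly inside the normal equations, with
early stopping on validation loss (patience 10) and an error-precision goal
of 10⁻⁷. Hyperparameters (η, β, α) are selected by grid search inside a
nested 10×10 cross-validation; validation statistics include pooled
RMSE/MAE/R², prescription error ratios with a ±20 % tolerance band,
improvement hit rates within mean ± k·SD bands, Bland–Altman limits of
agreement and expected-versus-observed regression.

Because the subject-level training corpus is expanded from published group
summaries, the package also ships the corpus machinery: per-study Gaussian
augmentation of age/BMI/VO₂max around their mean ± SD (sex and improvement
held fixed), plus fully synthetic study tables and ground-truth response
surfaces for testing.

## Worked example

```r
library(fittnet)

# a synthetic literature table (12 studies, 360 subjects) and its
# Gaussian-augmented corpus
table  <- synth_study_table(12, seed = 1, n_total = 360)
corpus <- build_corpus(table, seed = 1)
corpus
#> Encoded corpus: 360 samples from 12 studies (seed 1)

# 10-segment split: 8 train, 1 validation (early stopping), 1 test
plan  <- make_splits(corpus, seed = 1)
roles <- split_roles(plan)

net <- init_network(seed = 42)                 # 5-12-10-8-4, tanh hidden
net <- attach_input_scaling(net, corpus$x)     # map inputs to [-1, 1]
fit <- train_network(net, corpus$x[roles$train, ], corpus$y[roles$train, ],
                     corpus$x[roles$validation, ], corpus$y[roles$validation, ],
                     config = train_config(max_epochs = 150))
fit
#> Trained network 5-12-10-8-4 (lm): 29 epochs, stopped on patience, best val MSE 6.791

metric_set(forward(fit$network, corpus$x[roles$test, ]),
           corpus$y[roles$test, ])
#> n=144  RMSE 2.1590  MAE 1.3288  MSE 4.6613  R2 0.9796  R 0.9901

# an individualized prescription: 68.5-year-old woman, BMI 24.6, baseline
# VO2max 11.9, targeting a 10% improvement
prescribe(fit, subject_profile(68.5, "F", 24.6, 11.9),
          target_improvement = 0.10)
#> FITT prescription: 3 d/wk, 63.7 %HRR (58.7-68.7), 27.86 min, 10.31 wk
```

The test-segment metrics read as usual: RMSE/MAE near zero and R² near one
mean the model reproduces the held-out studies' prescriptions on the encoded
scale (the pooled numbers are dominated by the minutes and weeks outputs,
which have the largest physical ranges). The prescription line is the
decoded model output: session frequency rounded to whole days/week, the
intensity midpoint with its default ±5 %HRR band, and session time and
programme length to two decimals. Batch prescription over a roster
(`batch_prescribe()`) summarizes each element as mean ± SD (min–max) per
group, and `nested_cv()` produces the per-round RMSE/MAE/R² table with its
Mean and Best rows.

A thin command-line front end over the same pipeline
(`simulate`, `train`, `cv`, `evaluate`, `prescribe`) is installed at
`system.file("cli", "fittnet", package = "fittnet")`.

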