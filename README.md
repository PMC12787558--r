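# treefusion

Joint urban-tree health grading and gas-exchange estimation from paired RGB
imagery and sensor records, in a single compact multi-task network — with
the full preprocessing pipeline, a reproducible CPU training loop, an
ablation harness, and a synthetic survey generator for desk-scale
experiments.

## Who this is for

Urban-forestry and ecological-monitoring groups who have (or plan to
collect) per-tree field photographs plus environmental/biometric sensor
tables, and want one model that simultaneously:

* classifies tree health into four ordinal grades
  (0 very poor, 1 poor, 2 fair, 3 good/healthy),
* estimates daily O₂ production, and
* estimates daily CO₂ absorption.

## The model

An MBConv image encoder with squeeze-and-excitation channel attention
(canonical compact seven-stage layout: stem 32ch; stages
(1,3,1,16,1), (6,3,2,24,2), (6,5,2,40,2), (6,3,2,80,3), (6,5,1,112,3),
(6,5,2,192,4), (6,3,1,320,1); 1×1 head to a 1280-wide pooled embedding),
fused by concatenation with a small sensor MLP (d → 64 → 32, SiLU):

    F_fusion = [ MLP(x_sensor) ∥ GAP(MBConv stack(x_image)) ]     (32 + 1280 = 1312)

Three architecturally decoupled heads branch from the fusion vector,
each FC → ReLU → FC: a 4-class softmax classifier and two linear gas
regressors on z-scored targets. Training minimizes the balanced multi-task
objective

    L_T = 0.4 · L_cls + 0.3 · L_O2 + 0.3 · L_CO2

with cross-entropy for the classifier and mean absolute error for the
regressions. The reference configuration holds **5,368,698 trainable
parameters (5.4 M)** and **0.386 G multiply–accumulates** at 224×224 —
small enough for edge deployment. Everything (forward, backward, Adam with
cosine annealing, gradient clipping, early stopping) is implemented in the
package with C++ kernels for the convolutions; no deep-learning framework
is required.

Because real paired survey data of this kind are typically institutional
and private, the package also ships a documented synthetic generator
(12-species mix, the standard 8-channel sensor suite plus 6 biometrics,
ordinal health classes, stoichiometrically coupled gas targets, procedural
background-suppressed tree images) whose ground-truth rule lets you measure
oracle ceilings for each modality. See the methods vignette
(`vignettes/treefusion-methods.Rmd`) for the generator's exact links and
the design rationale.

## Worked example

```r
library(treefusion)

# static profile of the reference architecture
cfg <- model_config(backbone = backbone_config("full"))
count_params(cfg)     # 5368698       -> 5.4 M
count_macs(cfg)       # 385894768     -> 0.39 G at 224x224

# synthetic survey: 800 trees, 80/20 stratified split, tiny profile, 96 px
gen <- generator_config(n_trees = 800, seed = 7)
exp <- prepare_experiment(gen)
model <- build_model(model_config(backbone = backbone_config("tiny"),
                                  sensor_dim = ncol(exp$train$x), seed = 7))
fit <- train_model(model, exp$train,
                   train_config(max_epochs = 30, patience = 12, seed = 7))
evaluate_model(fit$model, exp$test, exp$pipeline)
```

which prints (about five minutes on one CPU):

```
Test metrics (n = 160)
  accuracy  : 0.9125
  macro-F1  : 0.9125
  per-class F1: 0.921 0.867 0.897 0.964
  O2  MAE 0.529  RMSE 0.686
  CO2 MAE 0.708  RMSE 0.900
```

Read this against the generator's ceilings: an oracle that sees both
modalities' latents tops out near 0.96 accuracy (`oracle_accuracy()`), and
the injected gas noise has sd ≈ 0.52 (O₂) / 0.75 (CO₂) in original units,
so the trained model recovers most of the recoverable signal in both
tasks. `ablate()` reruns the same data through the no-SE, image-only and
sensor-only variants under identical splits; the single-modality variants
land far below the fused model by construction of the generator.

A thin command-line surface over the same functions lives at
`inst/cli/treefusion.R` (`synth`, `train`, `eval`, `ablate`, `profile`
subcommands).

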