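# flowfe — targeted free-energy estimation with normalizing-flow maps

Computing a reduced free-energy difference
`Δf_ij = f_j − f_i = −ln(Z_j/Z_i)` between metastable states whose
Boltzmann distributions do not overlap normally requires simulating a
chain of intermediate states.  Targeted reweighting removes the chain:
an invertible map per state transports each distribution onto one
common, easy reference, and the overlap needed by standard estimators
is created in that shared coordinate system.  `flowfe` is an R
implementation of this program for practitioners of free-energy
methods who want to understand — and diagnose — what the choice of
reweighting estimator does to accuracy and data efficiency when the
maps are *learned* from limited data.

The package provides, as first-class, tested components:

* **Spline-coupling normalizing flows** (monotone rational-quadratic
  splines, exact log-Jacobians both ways, hand-verified analytic
  backpropagation, Adam training) mapping a uniform base box onto each
  state, so the model density `ln q(r) = −D ln L + ln|det J_{r→z}|`
  is exactly normalized and cheap to sample.
* **The six standard estimators** built on the generalized work
  function `φ_i(r) = u_i(r) + ln q_i(r)`:

  | estimator | definition | samples |
  |---|---|---|
  | AVMD / AVBG | `⟨φ⟩` | physical / model |
  | EXPMD | `ln⟨e^{φ}⟩_p` | physical |
  | EXPBG | `−ln⟨e^{−φ}⟩_q` | model |
  | BAR | root of `Σ_n 1/(N_p + N_q e^{φ_n−f}) = 1` | both, pooled |
  | MBAR | K-state self-consistent solve on remapped potentials `u_{k→i} = u_i(T_{k→i}(r)) − ln γ` | physical, all states |

  each with analytic standard errors, and the configurational-entropy
  split `Δs_ij = C_ij − Δf_ij` with `C_ij = ⟨u_j⟩_{p_j} − ⟨u_i⟩_{p_i}`.
* **State restriction**: a deterministic cluster rule fixes each
  state's integration limits; out-of-state configurations are
  penalized (`u + 1e20`, handled as exactly zero weight), which
  measurably reduces estimator variance.
* **The training/evaluation protocol**: 50:50 train/validation split,
  estimator sweeps every 50 batches, optional mid-run split swap with
  parameter reset, and overfitting diagnostics that need no ground
  truth (argmax of `AVMD_V`, growth flags on validation error bars,
  train-vs-validation gaps).
* **Self-contained benchmark systems**: a 3D narrow-well toy potential
  (six harmonic wells grouped into three 2-modal states) with
  quadrature ground truth, cluster-restricted Metropolis samplers, and
  Gaussian-mixture systems with closed-form free energies.

## Worked example

Train a flow on one metastable state of the toy system and compare
estimators against quadrature truth:

```r
library(flowfe)

sys <- default_toy_system()
quadrature_free_energy(sys$pot, sys$assigner, state = 1, grid_n = 128)
#> [1] 4.878383        # ground truth f_1 (in k_B T)

train <- sample_state(sys, state = 1, n = 1000, seed = 1)
val   <- sample_state(sys, state = 1, n = 1000, seed = 2)
rp  <- restricted_potential(sys$pot, state = 1, sys$assigner)
cfg <- train_config(total_batches = 500, eval_stride = 250, seed = 3)
fit <- train_state_model(train, val, rp, cfg)
subset(fit$trace, batch == 500 & estimator %in% c("AVMD", "EXPBG", "BAR"))
#>    batch estimator split    value     stderr
#> 12   500      AVMD     T 5.067229 0.02342445
#> 13   500      AVMD     V 4.607210 0.02670900
#> 17   500     EXPBG       4.881990 0.02787828
#> 18   500       BAR     T 5.096609 0.01517054
#> 19   500       BAR     V 4.888227 0.01615527
```

After 500 batches on 1000 points the model is already overfitting:
the work-function averages disagree across splits by ~0.5 k_B T
(AVMD_T above truth, AVMD_V below — the KL-divergence bracket), and
BAR on the *training* split is 13 of its error bars above the truth,
while BAR on the *validation* split (4.888 ± 0.016) and EXPBG
(4.882 ± 0.028) sit on the quadrature value 4.878.  That contrast —
validation-side BAR/MBAR stay reliable under overfitting while
training-side estimates drift with misleadingly small error bars —
is the central phenomenon the package quantifies.

The full three-state study with swap-and-reset, MBAR through composed
maps, entropy decompositions and the diagnostics report is one call:

```r
res <- run_toy_study(study_config(seed = 1))   # ~10 min on one CPU
res$summary      # per-estimator coverage of truth, terminal bias
res$report       # early-stopping suggestions, error-bar growth flags
```

A thin CLI wraps the same functions:
`exec/flowfe sample|train|estimate|assess-toy|report --config cfg.json --seed 1 --out dir/`.

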