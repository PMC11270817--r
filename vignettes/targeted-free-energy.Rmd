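---
title: "Targeted free-energy estimation with flow maps: models, estimators, and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted free-energy estimation with flow maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Metastable states of a molecular system are regions of configuration
space with their own local equilibrium distributions
`p_i(r) = exp(-u_i(r)) / Z_i`, where `u_i` is the reduced potential
(energy over k_B T) and the partition function `Z_i` is unknown.  The
quantity of interest is the reduced free-energy difference
`Delta f_ij = f_j - f_i = -ln(Z_j / Z_i)` between states whose
distributions do not overlap.  Classical perturbative estimators need
overlap, which is usually bought with chains of intermediate states.
Targeted reweighting buys it differently: an invertible map
transports each state's distribution onto a common reference, and the
estimators operate in that shared coordinate system.

`flowfe` implements this program end to end with normalizing flows as
the maps.  One flow per state is trained by maximum likelihood on
locally ergodic samples of that state; the flow's normalized density

```
ln q_i(r) = -D ln L + ln |det J_{r->z}|(r)
```

is the image of a uniform base distribution on a box `[a, b]^D`
(`L = b - a`) under the learned transport.  Because `q_i` is exactly
normalized, reweighting against it yields *absolute* reduced free
energies; differences between states follow.

## The work function and the six estimators

Everything is organized around the generalized work function

```
phi_i(r) = u_i(r) + ln q_i(r).
```

From the identities `1 = <q/p>_p` and `1 = <p/q>_q`, with
`p = exp(f - u)`:

* `AVMD = <phi>_p`, `AVBG = <phi>_q` — plain averages; exact only
  when the map is perfect (then `phi` is constant and equals `f`).
  `AVMD` is biased below `f` by `KL(p||q)` and `AVBG` above by
  `KL(q||p)`, which is what makes their train/validation traces a
  useful model-quality readout.
* `EXPMD = ln <exp(phi)>_p` and `EXPBG = -ln <exp(-phi)>_q` — the
  one-directional exponential estimators, computed with log-sum-exp.
  They are consistent but heavy-tailed under poor overlap; with an
  under-covering model the finite-sample estimate sits above the true
  `f` (Jensen), shrinking as the sample grows.
* `BAR` — solves the two-state mixture identity
  `sum_n 1/(N_p + N_q exp(phi_n - f)) = 1` over the pooled physical
  and model samples.  The left side is strictly increasing in `f`, so
  the implementation brackets the root with the two EXP estimates and
  bisects to 1e-12.  The same estimator is the maximum-likelihood
  intercept of a logistic regression on work values, which the test
  suite uses (via `glm`) as an independent reference.
* `MBAR` — the K-state generalization, fed with *remapped* effective
  potentials `u_{k->i}(r) = u_i(T_{k->i}(r)) - ln gamma_{k->i}(r)`,
  where `T_{k->i}` composes state k's inverse map with state i's
  forward map through the base space and `gamma` is the composed
  Jacobian.  Only physical (MD-origin) samples enter by default; the
  solver runs damped self-consistent iteration, a BFGS polish on the
  convex objective, and final sweeps to a 1e-12 residual, with the
  gauge fixed at `f_1 = 0`.  The covariance is the standard
  asymptotic estimator built from the weight-matrix SVD; the test
  suite cross-checks it against a seeded bootstrap.

Estimates carry delta-method standard errors (AV, EXP) or the
asymptotic BAR/MBAR errors, a `T`/`V` split tag and the counts used.

### Integration limits

Each state is a region of one global potential surface, delimited by
a deterministic cluster rule fixed before estimation.  The
`restricted_potential` adds a large penalty (reported as `u + 1e20`)
to configurations assigned elsewhere; in the weighting arithmetic
those rows are treated symbolically as `+Inf`, so their Boltzmann
weight is exactly zero and no overflow can occur.  Restriction
confines every estimator to the state's own configuration integral;
without it, model samples straying into a neighboring state's well
acquire large importance weights and inflate the EXP variance (the
package's acceptance suite measures exactly this contrast on paired
seeds).

### Entropy decomposition

With `f_i = <u_i>_{p_i} - s_i`, differences split as
`Delta s_ij = C_ij - Delta f_ij` with
`C_ij = <u_j>_{p_j} - <u_i>_{p_i}` estimated directly from the
physical samples (independent of map quality).  The package
propagates the free-energy error and the two energy-mean errors in
quadrature.  Sign convention: `Delta f_ij` denotes `f_j - f_i`, so
`Delta s_ij = s_j - s_i`.

## The flow architecture

Coupling layers with monotone rational-quadratic splines transform
half of the coordinates conditioned on the other half, alternating
the mask between layers.  Defaults: 4 layers, 16 spline bins, a
two-hidden-layer tanh conditioner of width 64.  Specifics worth
knowing:

* The spline knots come from a row-wise softmax (widths/heights, with
  a 1e-3 minimum bin fraction for numerical safety) and a shifted
  softplus (interior derivatives); endpoint derivatives are fixed at
  1.  Zero raw parameters therefore give exactly the identity map,
  and the conditioner's last layer is zero-initialized so training
  starts from `q = p_0`, which makes early-training diagnostics
  interpretable.
* Density evaluation (`r -> z`) applies the analytic spline, so the
  maximum-likelihood loss and its exact gradient are cheap; sampling
  (`z -> r`) inverts each bin's quadratic in closed form with one
  Newton polish.  The whole log-density path is double precision.
* Backpropagation is exact: the in-bin partial derivatives of the
  transform and its log-derivative are generated symbolically (via
  `deriv`) and chained by hand through the softmax/cumulative-sum/
  softplus parameterization and the conditioner network.  The test
  suite verifies every stage against central finite differences.
* Configurations outside the domain box have `ln q = -Inf` (zero
  mass) rather than being clamped, preserving normalization and the
  zero-weight convention of the restricted potentials.

Training uses Adam at learning rate 0.001 on batches of 1000 drawn
without replacement (epoch-wise shuffling; partial final batches
dropped).  Every 50 batches, all estimators are evaluated on the
training split, the validation split, and 1000 fresh model samples.
Optionally, at a chosen batch the two equally sized splits are
swapped and the parameters reset to their stored initial values, so
the second half of the run repeats the protocol with the data roles
exchanged.  The evaluation event that coincides with the swap batch
measures the fully trained first-half model; the reset takes effect
from the next batch.  A non-finite training loss aborts with a
diagnostic rather than skipping the batch.

## Synthetic systems and what they do (not) emulate

The benchmark generator stands in for molecular-dynamics data sets:

* **Narrow-well toy system** — six isotropic harmonic wells on the
  unit cube, grouped into three 2-modal metastable states.  The
  default (`default_toy_system()`) uses stiffness 200 (local sd
  ~0.071, so wells at the default centers are separated by more than
  7 local standard deviations; construction refuses anything under
  5), depths `(0, 1, 0.5, 0.5, 2, 0)` giving distinct state free
  energies of order 5 k_B T with differences of 0.07-0.19 k_B T, and
  a nearest-well-center cluster rule (lowest index on ties) mapped
  through the well grouping.  Ground truth comes from midpoint-rule
  quadrature (default 128 points per dimension; the suite checks
  stability under doubling, and cycle closure is exact by
  construction of a joint quadrature).
* **Sampling** — `n` independent Metropolis walkers per state, 400
  steps each, proposal sd `1.1/sqrt(k)` (empirically ~40%
  acceptance), with moves rejected when the proposal leaves the
  state's cluster; a symmetric inter-well translation move (25% of
  proposals) equilibrates the two wells of a state, which plain local
  moves could not cross.  This gives locally ergodic data: thorough
  coverage within a state, none across states — the regime targeted
  reweighting is for.
* **Gaussian-mixture systems** — states with
  `u = -ln sum_k a_k N(mu_k, diag sd_k^2)`, hence closed-form
  `f = -ln sum_k a_k` and closed-form entropies for single-component
  states; used wherever an analytic oracle is wanted (diagonal
  covariances suffice for that purpose).

What the generator does not emulate: autocorrelated trajectories
(walkers are independent), force-field energetics and molecular
internal coordinates, roto-translational or permutation symmetries,
and biased (metadynamics) sampling.  Passing tests therefore
demonstrate the correctness of the estimation machinery and the
qualitative train/validation phenomenology, not robustness to
correlated or high-dimensional molecular data.

## The convergence study and its diagnostics

`run_toy_study()` reproduces the standard protocol at a scale chosen
to be informative on one CPU in roughly ten minutes: 1000 training
plus 1000 validation samples per state, 2000 batches with
swap-and-reset at 1000, evaluations every 50 batches (40 events).
With this little data the flows overfit visibly: training-side
estimates drift away from quadrature truth with misleadingly small
error bars, while the validation-side BAR and MBAR estimates stay
near the truth with honest error bars — the qualitative signature
the study is designed to exhibit.  Early in training the composed
maps may transport no mass between states; MBAR then has no overlap
and the event is recorded as NA rather than a number.

Three diagnostics usable without ground truth are reported: the
batch maximizing `AVMD_V` per state (an early-stopping suggestion),
a monotone-growth flag on the BAR/MBAR validation error bars (rank
correlation with progress > 0.6 and last-quarter median > 1.5x the
first-quarter median), and the train-minus-validation gap series.
For comparisons against truth, the first 10% of events are treated
as burn-in, and coverage counts events whose estimate lies within
twice its analytic standard error of the quadrature value.

Two caveats a user should know.  First, the validation split is
*fixed* across evaluation events, so an entire validation series
shares one finite-sample offset; the per-event analytic error bar
(which the suite bootstrap-verifies) does not include that
split-level variance, and coverage measured against a single split
can sit a little below its nominal level even for a well-behaved
estimator.  Second, with only-physical-sample MBAR the cross-state
information flows entirely through the composed maps, so MBAR
estimates inherit a small finite-N bias wherever map overlap in the
base space is imperfect; more data shrinks both effects.

## Numerical and design choices

* Domain and base box coincide (`[0, 1]^D` by default): the base is
  uniform with known `ln p_0 = -D ln L`.
* BAR bracket: the two EXP estimates (the root provably lies
  between them), widened until the residual changes sign; bisection
  to 1e-12.
* MBAR gauge `f_1 = 0`; pairwise differences and their errors come
  from one joint solve, so thermodynamic cycles close identically.
* Work-function rows that are non-finite (model samples outside the
  state or domain) are excluded from q-side averages with their
  count reported; p-side rows are finite by construction.
* Zero-sample states are allowed in the MBAR solver (evaluated
  perturbatively); a disconnected overlap graph is an error naming
  the components.
* All randomness derives from one master seed through a fixed
  splitting rule (`split_seed`), making every trace byte-for-byte
  reproducible.

## Limitations

The flows here are generic Cartesian spline-coupling maps; molecular
applications would add internal-coordinate layers and symmetry
handling.  Training data are assumed in-domain and locally ergodic;
no autocorrelation correction is applied to error bars.  Quadrature
ground truth is a low-dimensional facility (refused above 3D).  The
energy-based (KL) training objective is deliberately out of scope;
only maximum likelihood is implemented.
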