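---
title: "Modeling dissociation kinetics from residue interaction-energy fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling dissociation kinetics from residue interaction-energy fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(koffkit)
```

## The problem

Drug efficacy often tracks the *residence time* of a protein–ligand complex
(`tau = 1/koff`) better than equilibrium affinity. Measuring `koff` is slow;
simulating unbinding is expensive. The pragmatic middle ground implemented
here regresses `pkoff = -log10(koff)` on cheap descriptors computed from the
*equilibrium* complex geometry: the per-residue van der Waals and
electrostatic interaction energies between the ligand and each protein
residue (COMBINE-style analysis). This vignette records the modeling
choices, their assumptions, and what the test suite does and does not
establish.

## Energetics

For every (ligand atom i, protein atom j) pair at distance `r`:

- van der Waals: `eps_ij [ (Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6 ]` in the
  AMBER `Rmin/eps` convention, `Rmin_ij = Rmin_i/2 + Rmin_j/2`,
  `eps_ij = sqrt(eps_i eps_j)`. The minimum is `-eps_ij` at `r = Rmin_ij`.
- electrostatic: `k_e q_i q_j / (eps_r r)` with `k_e = 332.0522173`
  kcal·Å/(mol·e²) and a uniform dielectric `eps_r = 4`. A constant
  dielectric is a deliberately crude screening model; it is what the
  underlying methodology prescribes, and it keeps the descriptor linear in
  the ligand charges.

Per-residue sums of these terms give vectors `E^vdW` and `E^elec` of length
`n_p`; their concatenation over N complexes is the `N x 2 n_p` matrix **X**.
Summing a row of X reproduces the total intermolecular nonbonded energy
exactly (tested against an independently coded scalar double loop at 1e-9
relative tolerance). There is no distance cutoff by default — full pairwise
sums — and no intramolecular or 1-4 terms, since ligand and protein are
distinct molecules. Coincident atoms (`r = 0`) are an error, not a clamp: a
minimized structure should never contain them, so they indicate broken
input. Waters and ions are excluded from the residue list and flagged,
because the residue count `n_p` must mean "protein residues" for columns to
align across complexes.

## Pretreatment

The fixed order is truncation → SD filter → (optional) standardization →
PCA:

- **Truncation** replaces strictly positive energies by zero. Positive
  interaction energies in a minimized complex are force-field artifacts;
  zeroing them also makes the descriptors insensitive to exactly how
  repulsive an artifact is.
- **SD filter** (`std_threshold`, kcal/mol, default 0 = keep all): columns
  whose sample standard deviation (n−1 denominator; the convention is ours,
  the source is silent) falls below the threshold carry no between-ligand
  information.
- **Standardization** is off by default: the energy blocks share units, and
  scaling up near-constant columns amplifies noise. It is exposed because
  some datasets need it.
- **PCA** by SVD of the centered matrix. Component signs are fixed (largest
  |loading| positive) so results are reproducible across BLAS/LAPACK builds.
  `n_components` defaults to `min(n-1, retained columns)`; when labels are
  available, `select_n_components()` picks it by LOO-CV Q² instead, which is
  our stand-in for the per-dataset choices the methodology leaves open.

Everything is fitted on training rows only and frozen
(`pretreat_fit()` / `pretreat_transform()`), including inside every
cross-validation fold — otherwise Q² silently absorbs test information.

## The Bayesian neural network

A fully connected net (default one hidden layer of 16 sigmoid units) whose
weights and biases carry a fully factorized Gaussian variational posterior.
Training minimizes the negative evidence lower bound

```
-ELBO = -E_q[ log N(y | f_w(x), sigma_n^2) ] + KL( q || N(0, prior_std^2) )
```

by full-batch Adam (default learning rate 1e-2, 2000 epochs, one Monte
Carlo draw per step). The observation noise `sigma_n` is a single learnable
log-parameterized point parameter — it is required to form a Gaussian
likelihood at all, and it is what gives the posterior-predictive intervals
their width. Predictions draw `posterior_samples` (default 1000) weight
samples, evaluate the net, add likelihood noise, and report the draw mean
and the empirical 2.5/97.5% quantiles.

Numerical choices that mattered in practice (all are optimization aids; the
objective is untouched):

- **Local reparameterization**: hidden pre-activations are sampled from
  their induced Gaussians instead of sampling weights, which cuts the
  gradient variance of a one-draw ELBO estimate enormously.
- **Analytic output layer**: the final layer is linear-Gaussian, so its
  expectation is taken in closed form, `E[(y - Z)^2] = (y - M)^2 + V`.
- **Initialization**: hidden biases start spread (`N(0,1)`) so the sigmoid
  features are not collinear; the output layer starts at the ridge
  least-squares readout of the initial hidden features; posterior standard
  deviations start at 0.05.
- **Noise warm-up**: `sigma_n` is frozen for the first quarter of training.
  Otherwise the noise term can absorb still-unexplained signal early and
  trap the fit in a poor local optimum (initializing at a quarter of the
  label spread serves the same purpose).
- Targets are centered internally; the mean is restored at prediction.

One consequence worth knowing: at the variational optimum `sigma_n^2`
absorbs the posterior function variance, and predictive draws add both, so
the intervals are mildly conservative. On well-specified synthetic data we
observe 95%-interval coverage of 0.98–0.99 rather than 0.95; the acceptance
band [0.90, 0.99] reflects that.

Divergence (non-finite gradients) raises an error suggesting a smaller
learning rate rather than silently producing garbage.

## Baseline regressors

The methodology compares eight model families. The pre-installed R stack
offers none of the usual wrappers (no pls/e1071/randomForest/xgboost), so
compact textbook implementations live in-repo behind one
`regressor_spec()` / `fit_regressor()` / `predict()` contract:

- **PLSR** — univariate NIPALS; with full components it equals OLS (tested).
- **BR** — Bayesian ridge via evidence maximization (MacKay updates).
- **GPR** — RBF kernel, hyperparameters by L-BFGS-B on the exact marginal
  likelihood; Cholesky with escalating jitter guards the noise-free limit.
- **PCR** — SVD scores + least squares.
- **RF** — bagged exact-greedy variance-reduction trees, `mtry = p/3`.
- **SVM** — epsilon-SVR, RBF kernel, solved as the standard 2n-variable
  dual QP with `quadprog` (a small ridge keeps the PSD dual Hessian
  numerically positive definite).
- **XGBoost** — Newton boosting with the regularized leaf/gain formulas
  (for squared loss the Hessian is 1, so this is shrunken residual
  boosting on the same tree engine as the forest).
- **Mean** — a ninth, null kind predicting the training mean; it is the
  analytic reference point for Q² worked examples.

All stochastic kinds seed their own RNG and restore the caller's stream.
Models only ever see pretreatment scores, never raw X.

## Evaluation protocol

`ranked_split()` sorts by pkoff (stable, so ties keep input order — a
determinism choice) and holds out every fifth sample: `floor(N/5)` test
samples; 66 → 53/13 and 35 → 28/7. `loo_cv()` runs exactly n folds and
refits pretreatment + model per fold; Q² uses the full training-set mean as
its centering constant, matching the single mean in the determination
coefficient's definition (an interpretation we document rather than a
printed prescription). The Pearson `r` is the standard formula; the printed
source formula for `r` omits its squares (a typesetting defect, as the
literal expression is identically zero), so the standard definition is
implemented. A metrics call on a zero-variance vector errors instead of
returning NaN.

## Synthetic world

`make_toy_complexes()` builds one shared protein scaffold (residue centers
on a 6 Å shell, atoms jittered under a 1.5 Å minimum separation) and
per-ligand short chains near the origin, each atom 2.5–8 Å from the nearest
protein atom; charges |q| ≤ 1 e, `eps` in [0.05, 0.25] kcal/mol, `Rmin/2`
in [1.4, 2.0] Å. `plant_pkoff()` sets
`pkoff = g(truncate(X) w) + N(0, noise_sd^2)` — the plant lives on the
*truncated* descriptors, mirroring both the pipeline's first step and the
physical reading that only favorable contacts carry kinetic signal;
without this the truncation step would destroy planted signal by
construction. `g` is the identity or a gentle saturation `2 tanh(s/2)`
(there to let tests show nonlinear models matching or beating linear ones
on a nonlinear map, without claiming any real-data ranking). Planted
weights are rescaled so the noiseless signal has unit spread; the default
noise of 0.3 pkoff units is a realistic experimental log-scale spread, and
0.2 is used where the stated recovery checks prescribe it. Optional pKd
values are generated by inverting the BEP line and adding noise.

What a green suite establishes: the pipeline recovers signal it is
guaranteed to contain, finds nothing in null plants, and its statistics
match independent oracles. What it does not establish: force-field realism,
docking/minimization quality, or the published per-dataset metric values —
those depend on external datasets and unpublished hyperparameters, and are
deliberately out of scope.

## Known limitations

- The PDB writer keeps 3 decimals (format precision), so structure
  round-trips are exact only to 1e-3 Å; `r^-12` terms consequently move by
  ~0.1%.
- The run configuration is JSON, not TOML: the offline environment has no
  TOML parser and shipping one was not worth the surface area.
- The BNN posterior is mean-field; correlated-weight uncertainty and MCMC
  are out of scope, as are k-fold CV (k < n) and hyperparameter search
  beyond the LOO component-count utility.
- Baseline hyperparameter defaults are sensible textbook values, not tuned
  reconstructions of any published setting.
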