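---
title: "Adaptive discriminant analysis with hidden classes and extra variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive discriminant analysis with hidden classes and extra variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`damda` addresses a dataset-shift problem that standard discriminant
analysis cannot: the unlabelled test data may contain classes that were
never observed while training the classifier, and may be recorded on a
superset of the training variables. This vignette documents the model, the
estimation procedure, the tunable parameters, the synthetic-data designs
used to validate the package, and the numerical and design choices behind
the implementation.

## Model and estimation in two phases

### Learning phase

The training data are complete: `M` observations on `P` variables, each
carrying one of `K` class labels. Conditional on its class, an observation
is multivariate Gaussian, so the classifier reduces to per-class estimation
of means, covariances and class proportions. Covariances are constrained
through the eigenvalue decomposition `Sigma_k = lambda_k D_k A_k D_k'`
(EDDA): each of volume `lambda`, shape `A` and orientation `D` may be
common to all classes or class-specific, giving a ladder of models from
spherical-equal (`EII`) to unconstrained (`VVV`). `fit_edda()` fits every
requested family and keeps the one maximising

```
BIC = 2 L(X, labels) - eta log M ,
```

where `eta` counts `K * P` means, `K - 1` free proportions, and the
family-specific covariance parameters. Ties go to the family with fewer
parameters. The default candidate set comprises the eight
single-decomposition families with closed-form estimators (`EII`, `VII`,
`EEI`, `VEI`, `EVI`, `VVI`, `EEE`, `VVV`); the iterative families can be
requested explicitly. Per-family constrained estimation is delegated to
mclust's M-step routines, the standard implementation of this
parameterisation; everything around it (likelihood, parameter counting,
selection) is computed in-package, and one-dimensional fits use the obvious
closed forms directly.

After this phase the training data are discarded. Only the parameter
estimates travel to the discovery phase — the defining property of the
inductive approach, and what makes the method suitable for on-line use.

### Discovery phase

Given `N` unlabelled test observations on `R = P + Q` variables (matched to
the learned variables **by name**; file order is irrelevant) and a
candidate number `H` of hidden classes, the EM algorithm maximises the
test-data mixture log-likelihood over

* the `C = K + H` mixing proportions (re-estimated on the test data),
* means and covariances of the `H` hidden classes on all `R` variables,
* for each known class: the extra-variable mean `mu^Q_k`, the
  cross-covariance `C_k`, and the extra-block covariance `Sigma^Q_k`,

while the learned blocks `(mu_k, Sigma_k)` stay **fixed** — the package
inserts the learning-phase values unchanged at every iteration, and the
test suite asserts they remain bit-identical in the final model.

A naive weighted-moment update for the known-class blocks would ignore the
structure of the fixed `Sigma_k` (for instance a diagonal EDDA family) and
can produce an indefinite assembled covariance. Instead, the M-step uses
*inductive conditional estimation*: fix the marginal of the learned
variables, estimate the conditional distribution of the new variables given
the learned ones, and reassemble the joint. With the class scattering
matrix partitioned into `W` (learned block), `V` (cross) and `U` (extra
block), the closed forms are

```
C_hat = (Sigma^-1 W Sigma^-1)^-1 (Sigma^-1 V)
E_hat = [C_hat' Sigma^-1 W Sigma^-1 C_hat - 2 V' Sigma^-1 C_hat + U] / N_k
mu^Q  = ybar^Q - C_hat' Sigma^-1 (ybar^P - mu_k)
Sigma^Q = E_hat + C_hat' Sigma^-1 C_hat ,
```

and the assembled covariance is positive definite whenever the scatter is,
because its Schur complement with respect to the fixed block equals `E_hat`.
The tests verify, by brute-force numerical maximisation on small instances,
that these closed forms attain the optimum of the expected complete
log-likelihood term they are derived from, and that when the learned block
is itself the unconstrained weighted estimate the assembly collapses to the
ordinary weighted sample covariance.

### Hidden-class count, convergence, degenerate runs

`damda_fit()` fits every `H` in a range (default `0:5`) and maximises
`BIC_H = 2 L - eta_H log N`, where

```
eta_H = (H + K - 1) + 2 H R + H choose(R, 2) + 2 K Q + K P Q + K choose(Q, 2)
```

counts only the discovery-phase parameters. The EM stops when
`|L(t) - L(t-1)| / (1 + |L(t)|) < 1e-5` (configurable) or after 500
iterations. If a class's responsibility mass vanishes (below `1e-8`) or a
covariance degenerates mid-run, the fit restarts from a random partition,
up to 5 times, before failing; hierarchical initialisation makes restarts
rare in practice.

### Initialisation

The EM starts from a deterministic hierarchical partition of the test data
into `C` clusters: Ward linkage on standardised columns, a deliberately
simple, dependency-light stand-in for likelihood-based agglomeration — the
initialiser is exchangeable as long as it lands in a reasonable basin.
Clusters are matched one-to-one to the known classes by the Gaussian
Kullback–Leibler score

```
tr(S_g^-1 Sigma_k) + (m_g - mu_k)' S_g^-1 (m_g - mu_k) + log det(S_g)/det(Sigma_k)
```

solved as an **exact assignment problem** (minimum total divergence over
injections) rather than greedily: greedy matching is ambiguous when one
cluster is closest to two classes, and exact assignment is
order-independent. Matched clusters inherit the learned parameters on the
learned block and their own moments elsewhere; unmatched clusters seed the
hidden classes. Cluster covariances with fewer than `R + 2` members are
shrunk toward the pooled within-cluster covariance with weight proportional
to the deficiency, and all initial covariances get an eigenvalue floor of
`1e-8 * trace / R`. Cross blocks are scaled down geometrically if needed
until the assembled Schur complement is positive definite.

## Variable selection

For high-dimensional test data the package adapts a stepwise model-
comparison search. At each step, the proposal variable is either useful for
classification jointly with the currently selected set (`M1`) or
conditionally independent of the classes given a regression on a subset of
the selected variables (`M2`); the two are compared by

```
BIC_1 = BIC_class(selected + proposal)
BIC_2 = BIC_class(selected) + BIC_reg(proposal | subset of selected)
```

with the proposal accepted when `BIC_1 - BIC_2 > 0`. `BIC_class` is the
discovery-phase BIC maximised over the hidden-class range, so the number of
hidden classes is re-selected at every step (fits are cached per variable
set). `BIC_reg` comes from a bidirectional BIC-scored stepwise Gaussian
regression with the intercept-only model as a candidate. Design choices the
literature leaves open, resolved here:

* **Step order**: one best-addition pass then one best-removal pass per
  cycle, stopping when a full cycle changes nothing. Candidates within a
  pass are scored independently, so the accepted proposal is the argmax of
  the BIC difference regardless of enumeration order (and the pass is
  trivially parallelisable).
* **Removal rule**: the mirror image of the printed addition rule — remove
  when `BIC_class(selected - v) + BIC_reg(v | selected - v)` exceeds
  `BIC_class(selected)`.
* **Candidate pool**: extra (`Q`) variables are eligible from the first
  addition pass; there is no reason to privilege the training variables
  once the comparison is BIC-based.
* **Start set**: either all observed variables, or the top `S` (default 10)
  variables ranked by `max_g BIC(g-component univariate mixture) - BIC(single
  Gaussian)` for `g` in `2..G` (default `G = K + 3`) — variables with
  multimodal marginals are the most promising classifiers.

The inductive contract holds throughout: parameters of learned variables in
any candidate model are row/column slices of the learning-phase estimates.

## The synthetic-data generator

`sim_spec()` / `simulate_damda()` reproduce the three-type variable design
used to validate adaptive classification:

* **Gen** variables follow a mixture of `C` Gaussians (default 4). Class
  means sit at the vertices of a regular simplex, rotated into general
  position by a random orthogonal matrix so that *every* Gen coordinate
  carries class-mean signal, and scaled so the pairwise mean distance is
  the `separation` parameter (default 3). Class covariances are random SPD
  with condition number at most `cond_max` (default 10) and the largest
  eigenvalue anchored at 1, so `separation` reads directly in units of the
  largest within-class standard deviation.
* **Cor** variables are noisy linear combinations of 2 randomly chosen Gen
  variables (signed weights uniform on `[0.5, 1.5]`), with the noise
  variance set from the population mixture moments so that the correlation
  with the generating combination is `cor_target` (default 0.6). By
  construction they are informative about the classes only *through* Gen:
  conditionally on their linked Gen variables they are independent of the
  labels, which the tests verify via partial correlations.
* **Noi** variables are independent Gaussians.

A random subset of `K_obs` classes and `n_obs` variables is observed in
training (policies: all/half/a-fifth of the Gen variables plus random
Cor/Noi); the test set carries all classes and variables with ground truth.
Identical spec and seed reproduce identical matrices.

What the generator does *not* emulate: heavy tails, label noise, outliers,
non-Gaussian class shapes, and the strong smooth between-variable
dependence of real spectra. Passing the simulation suites therefore
demonstrates correctness of the estimation machinery under the model's own
assumptions, not robustness to their violation.

Evaluation metrics ship alongside: `ari()` (chance-corrected partition
agreement, label-permutation invariant) and `matched_error()`
(misclassification after optimal one-to-one matching of predicted to true
classes on the confusion matrix, solved exactly).

## Numerical choices

* All densities are computed in log scale through Cholesky factors
  (RcppArmadillo kernels); posteriors use log-sum-exp. Underflow is
  otherwise certain for large `R`.
* Positive definiteness is checked scale-free: smallest eigenvalue greater
  than `1e-10` times the largest.
* The within-class scatter `W` is inverted only while its condition number
  stays below `1e12`; beyond that the run stops and asks for the
  regularisation flag rather than silently pseudo-inverting.
* Regularisation (off by default) adds an inverse-Wishart-style prior
  scatter: `O_k + nu * Psi` with `N_k + nu` in the covariance divisions,
  defaults `Psi = diag` of pooled test variances and `nu = R + 2` — the
  weakest proper choice. Estimates shrink toward `Psi` as `nu` grows. It is
  needed whenever effective class sizes can drop below `R`. With the prior
  active the EM maximises a penalised likelihood, so the raw log-likelihood
  trace is no longer guaranteed monotone; the monotonicity contract applies
  to unregularised runs.
* Mixing proportions are re-estimated on the test data by default (class
  balance is allowed to drift); renormalising the learned proportions
  around the hidden mass is available as an option but known to bias the
  known-class proportions.
* BIC ties: fewer parameters win (families), smaller `H` wins (hidden-class
  count).
* Model files are versioned JSON documents with numerics written at 17
  significant digits, so a save/load round trip is bit-exact.

## Validation problem sizes

The test suite validates the machinery at the scales the method targets:
200 randomized discovery instances (`K <= 3`, `H <= 2`, `P <= 5`, `Q <= 3`,
`N` in 50–500) for EM monotonicity, termination, the fixed-block contract
and positive definiteness; 50 small instances against a brute-force
maximiser for the conditional closed forms; 50 seeds of the augmented
design (2 observed classes, 1 hidden, 4 learned + 2 extra variables, 4 SD
separation, `N = 600`) for hidden-class detection, ARI and mean recovery,
plus 50 null seeds for false-positive control; 20 seeds of a 40-variable
Gen/Cor/Noi design (`N = 400`) for variable selection; and exhaustive
enumeration for the assignment and parameter-count oracles.
`scripts/acceptance.R` recomputes a summary of these quantities end to end
from a single seed.

## Known limitations

* Hidden-class and extra-variable covariances are unconstrained; the
  parsimonious EDDA families apply to the learning phase only.
* Estimation is strictly inductive; there is no transductive refit of the
  learned parameters, by design.
* Training labels are assumed noise-free and classes Gaussian; no outlier
  handling.
* The exact-assignment matcher and matched-error metric enumerate
  injections, which is exact but intended for the small class counts
  (roughly up to 8) typical of this setting.
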