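---
title: "Partial correlation screening for sparse Gaussian graphical models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial correlation screening for sparse Gaussian graphical models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcsnet)
```

## The model

A Gaussian graphical model (GGM) represents a p-variate Gaussian vector
$X = (X_1, \ldots, X_p)$ as an undirected network: nodes are variables and
an edge joins $i$ and $j$ exactly when their partial correlation
$\rho_{ij|V\setminus\{i,j\}}$ — the correlation between $X_i$ and $X_j$
after removing the linear effect of all remaining variables — is non-zero.
Under Gaussianity a zero partial correlation is equivalent to conditional
independence, and the partial correlations are determined by the precision
matrix $\Omega = \Sigma^{-1}$ through
$\rho_{ij|V\setminus\{i,j\}} = -\omega_{ij}/\sqrt{\omega_{ii}\omega_{jj}}$.

Sparse estimation of this network is attractive whenever $n/p$ is modest,
but the workhorse $\ell_1$-penalized estimators share a known defect: the
regularization level that predicts well keeps too many spurious edges.
`pcsnet` implements a two-stage answer.  Stage one fits any of four
standard estimators with any of the usual tuning rules.  Stage two —
partial correlation screening (PCS) — removes the entries of the estimated
partial correlation matrix whose absolute value does not exceed a
threshold $\tau$ chosen by cross-validation, and refits the surviving
neighborhoods by ordinary least squares.  Screening can only delete edges,
so it trades a small amount of sensitivity for a large reduction in false
positives; networks that are already too sparse pass through unchanged.

## Stage one: estimators and tuning rules

All estimators operate on column-centered data (the objectives carry no
intercepts).  Columns are not rescaled to unit variance by default — the
objectives are stated on the raw scale — but every front-end accepts
`standardize = TRUE`, since the literature is silent on this point and
users may prefer scale-free fits.

**Graphical lasso** (`fit_glasso`) minimizes
$\mathrm{tr}(S\Omega) - \log\det\Omega + \lambda_1\sum_{i\neq j}|\omega_{ij}|$
by block coordinate descent over columns; the diagonal is unpenalized.
Tuning: 10-fold cross-validation of the held-out negative log-likelihood
(CV1) or of the summed nodewise prediction error (CV2), each with the
minimum or the one-standard-error rule; BIC; extended BIC.  The penalty
grid is 100 equidistant values from 0.001 (0.05 when $p \ge 100$) to
$\max|S|$, which always contains the empty model.

**Nodewise lasso** (`fit_nodewise_lasso`) solves the p regressions
$\tfrac12\|X_i - \sum_{j\neq i}\beta_{ij}X_j\|^2 + \lambda_2\sum_{j\ne i}|\beta_{ij}|$
(through glmnet, with the penalty rescaled by $1/n$ to match this unscaled
form) and reconciles the two weights per pair with the AND or OR rule.
Per-node tuning: cross-validation (min / one-standard-error), BIC, or the
closed-form finite-sample level.  The per-node grid mirrors glmnet's: 100
log-equidistant values descending from
$\lambda_{\max} = \max_j |X_j^\top X_i|$ to $10^{-4}\lambda_{\max}$
($10^{-2}$ when $n \le p$).

**SPACE** (`fit_space`) minimizes the joint objective
$\tfrac12\sum_i\|X_i - \sum_{j\neq i}\rho_{ij}\sqrt{\omega_{jj}/\omega_{ii}}X_j\|^2
 + \lambda_3\sum_{i<j}|\rho_{ij}|$
in which each $\rho_{ij}$ is shared by the two regressions it touches.  The
solver alternates coordinate descent on $\rho$ (each update a soft
threshold of a residual inner product aggregated over both regressions)
with $\omega_{ii}$ re-estimated as inverse mean residual variances,
starting from $\rho = 0$, $\omega_{ii} = 1/\mathrm{var}(X_i)$.  Because
the $\omega$ update is a heuristic re-estimation rather than a descent
step, the implementation tracks the objective across outer iterations and
returns the best iterate, so the reported objective sequence is
non-increasing.  The grid is 100 equidistant values between
$\sqrt{n}\,\Phi^{-1}(1 - 0.9/2p^2)$ and
$\sqrt{n}\,\Phi^{-1}(1 - 10^{-4}/2p^2)$; tuning by cross-validation
(min / one-standard-error), BIC, or the finite-sample level.

**Nodewise ridge** (`fit_ridge_nodewise`) solves
$\tfrac12\|X_i - \sum_{j \ne i}\delta_{ij}X_j\|^2 + \lambda_4\sum_{j\ne i}\delta_{ij}^2$
exactly, $\hat\delta_i = (X_{-i}^\top X_{-i} + 2\lambda_4 I)^{-1}X_{-i}^\top X_i$,
tuned per node by cross-validation.  Ridge weights are never exactly zero:
the unscreened ridge network is complete by construction (false positive
rate 1), and the estimator is useful precisely as a dense first stage for
screening.

Partial correlations for the regression-based estimators use the
geometric-mean relation
$\hat\rho_{ij} = \mathrm{sign}(\hat\beta_{ij})\sqrt{\hat\beta_{ij}\hat\beta_{ji}}$,
valid when the two weights agree in sign.  In finite samples the signs can
disagree, a case the asymptotic relation does not define; such entries are
set to zero, consistent with the sparsity goal.  This means an OR-rule
edge whose reverse weight is zero carries a zero partial correlation and
is therefore removed by any positive screening threshold.

## Stage two: the screening procedure

Given a first-stage estimate $\hat\Gamma$, the screened neighborhood of
node $i$ at threshold $\tau \in (0,1)$ is
$\hat{A}_{i,\tau} = \{j : |\hat\rho_{ij|V\setminus\{i,j\}}| > \tau\}$, the
screened edge set keeps the pairs exceeding $\tau$, and node $i$'s
regression is refit by OLS on $\hat{A}_{i,\tau}$.

The threshold is selected by a double loop.  The regularization penalty
$\lambda$ is chosen once, on the full sample.  The sample is then split
into K = 10 folds; on each set of K−1 retained folds the first stage is
re-estimated at that fixed $\lambda$, and for every $\tau$ in a grid of
100 equidistant values on [0.0001, 1] the screened neighborhoods are refit
on the training folds and scored by squared prediction error on the
held-out fold:
$\mathrm{CV}(\tau) = \sum_k \sum_i \|X_i^k - \sum_{j\in\hat{A}_{i,\tau}}\hat\theta_{ij,\tau}X_j^k\|^2$.
$\mathrm{CV}(\tau)$ is piecewise constant with breakpoints at the sorted
$|\hat\rho|$ values of the per-fold networks, so the implementation
evaluates one refit per distinct edge set rather than one per grid point;
a test verifies this against the naive per-$\tau$ evaluation.  Ties in the
argmin go to the largest $\tau$ (the sparser final network), mirroring the
most-regularized tie-break used for $\lambda$.  Two design points the
procedure's description leaves open were resolved as follows: the OLS
refit inside the loss is done on the training folds only (standard
cross-validation hygiene), and the final reported network carries the
screened first-stage $\hat\rho$ values rather than re-derived partial
correlations from the refit.  The same seeded fold assignment is reused
for $\lambda$- and $\tau$-selection unless overridden, and both seeds are
recorded in the run report.

Degenerate cases: an empty first-stage network is returned unchanged
(screening cannot repair false negatives); if every per-fold network is
empty at every threshold the smallest grid value is returned with a
warning; an over-saturated refit (neighborhood at or above the training
row count, possible for a dense ridge stage at tiny $\tau$) falls back to
the minimum-norm least-squares solution and is flagged.

## Tuning parameters at a glance

| Parameter | Default | Meaning |
|---|---|---|
| `folds` | 10 | cross-validation folds, for both $\lambda$ and $\tau$ |
| `gamma` | 0.5 | extended-BIC weight in $[0,1]$; 0 recovers classical BIC |
| `alpha` | 0.05 | finite-sample bound on expected false positives per neighborhood |
| `edge_tol` | 1e-8 | zero-detection floor for solver output (unitless) |
| `tau_grid_size` | 100 | number of candidate screening thresholds |
| `seed` | 1 | fold-assignment seed, recorded for reproducibility |

Two conventions deserve explicit mention because the literature is
ambiguous and they change results materially:

* **EBIC model size.** The extended BIC is computed as
  $-2\mathcal{L}(\hat\Omega) + \kappa\log n + 4\kappa\gamma\log p$ with
  $\mathcal{L} = (n/2)(\log\det\hat\Omega - \mathrm{tr}(S\hat\Omega))$ and
  $\kappa$ the number of *non-zero off-diagonal parameters* of
  $\hat\Omega$ — each edge contributes its two symmetric entries.
  Counting unordered edges instead halves the complexity penalty and, at
  $n = 100, p = 60$ on a chain graph, flips the selection from the empty
  network to a nearly complete recovery; the doubled count reproduces the
  strongly conservative extended-BIC behavior this estimator is known for
  in the benchmark designs the package targets.
* **Finite-sample level for the nodewise lasso.** The closed form
  $\lambda_2(\alpha) = (2/\sqrt{n})\,\Phi^{-1}(1-\alpha/2p^2)$ is stated
  for the conventional $(1/n)$-scaled per-node objective.
  `fsr_lambda()` returns that quantity verbatim; `estimate_network()`
  multiplies it by $n/2$ before handing it to the unscaled solver, which
  makes it equivalent to $\sqrt{n}\,\Phi^{-1}(1-\alpha/2p^2)$ — the same
  convention under which the SPACE grid and SPACE level are stated (those
  apply unchanged).  Without the rescaling the level is $\sim n/2$ times
  too weak and the "conservative" rule returns dense networks.

BIC for the nodewise and SPACE estimators is implemented in its literal
printed form $n\cdot\mathrm{RSS} + \kappa\log n$ with RSS the residual
*sum of squares*.  Because $n\cdot\mathrm{RSS}$ grows like $n^2$ while the
complexity term grows like $\log n$, this criterion is dominated by fit
and effectively selects the smallest grid penalty; the conventional
Gaussian form would use $n\log(\mathrm{RSS}/n)$.  The literal form is kept
deliberately — it is the documented criterion, and for SPACE the smallest
grid value is itself a strong finite-sample level ($\alpha = 0.9$), so
SPACE-BIC remains usefully regularized — but users wanting a conventional
BIC should prefer the cross-validated or extended-BIC rules.

## Synthetic benchmark models

`run_experiment()` replicates the standard simulation designs used to
benchmark sparse GGM estimators, with true/false positive rates computed
over all $p(p-1)/2$ pairs:

* **Chain graphs** (`chain_model`): partial correlations $-0.4$ on the
  first off-diagonal band and, optionally, $-0.2$ on the second
  ($p-1$, resp. $2p-3$ edges).  The precision matrix is built with unit
  diagonal and $\omega_{ij} = -\rho_{ij}$ — partial correlations are
  invariant to the diagonal scale of $\Omega$, so the unit-diagonal choice
  is canonical — and inverted for the sampling covariance.
* **Nearest-neighbor graphs** (`nearest_neighbor_model`): p points on the
  unit square, each linked to its two nearest neighbors.  The default
  keeps *mutual* nearest-neighbor pairs; the liberal `rule = "or"` keeps
  every directed relation.  The mutual rule is the default because it
  reproduces the realized edge counts of the published benchmark
  instances (about 14 / 42 / 141 edges at p = 20 / 60 / 200), whereas the
  OR graph has at least p edges and roughly 1.3p in practice.  Edge
  weights are drawn from $[-1,-0.5]\cup[0.5,1]$.
* **Random graphs** (`random_model`): each upper-triangular precision
  entry set to 0.3 with probability $\rho$ (0.1 / 0.01 / 0.001 are the
  conventional choices for p = 20 / 60 / 200).
* **Toy model** (`toy_model`): the fixed six-variable covariance whose
  implied network has five edges, all with partial correlation −0.45; one
  variable pair is marginally correlated yet conditionally independent,
  which makes it a sharp smoke test for partial-correlation logic.

For the nearest-neighbor and random models the precision diagonal before
repair is set to 1 (the construction leaves it unspecified), and positive
definiteness is enforced by the shift
$\Omega \mapsto \Omega + (|\lambda_{\min}(\Omega)| + 0.1)I$, applied
unconditionally, so the repaired matrix always has smallest eigenvalue at
least 0.1.  Partial correlations then follow by normalizing and flipping
the sign of the off-diagonal — exactly `precision_to_partial()`.  The
model generators are deterministic given their seed, and by default one
fixed realization is reused across all replicates of an experiment cell,
matching how the benchmark tables report a single realized edge count.

What the generator does *not* emulate: real data are rarely Gaussian,
rarely i.i.d. across rows, and their partial correlations are neither
homogeneous in magnitude nor bounded away from zero.  Passing the
benchmark cells therefore demonstrates correctness of the estimation
stack under its stated assumptions, not robustness to misspecification.
The rank-based `nonparanormal()` transform (truncated-Winsorized normal
scores, truncation level $\delta_n = 1/(4n^{1/4}\sqrt{\pi\log n})$,
midranks so ties map to identical scores) extends applicability to
monotone-non-Gaussian margins, but not to dependence misspecification.

## Numerical choices

* Graphical lasso: convergence when the mean absolute change of the
  covariance iterate falls below $10^{-6}\times$ the mean absolute
  off-diagonal of S, at most 500 sweeps; paths are fit from the largest
  penalty down with warm starts.  Optimality is certified in the test
  suite by a duality-gap bound (dual-feasible point obtained by clipping
  $\hat\Omega^{-1}$ into the box $|\theta_{ij} - s_{ij}| \le \lambda$).
* SPACE: relative objective-change tolerance $10^{-6}$, at most 50 outer
  alternations (200 in tight-tolerance tests); coordinate updates sweep
  all pairs.
* Ties: all argmin selections over penalty or threshold grids break
  toward the most regularized value.
* Held-out covariance in the likelihood loss CV1 is computed with
  fold-specific centering and $1/n_k$ normalization; the prediction-error
  losses use the once-centered full data.
* Constant columns are rejected at ingestion; missing values are refused
  rather than imputed.

## Scale of the shipped validation

The test suite exercises the full stack at desk scale: the toy model end
to end (exact recovery of the five-edge network after screening a
cross-validated graphical lasso, majority of five seeds), and 20-replicate
versions of four benchmark cells (chain graph, $p \in \{20, 60\}$,
$n \in \{100, 500\}$) chosen to pin down four qualitatively different
behaviors — perfect recovery by SPACE-BIC at large n, the exactly-complete
unscreened ridge network, empty extended-BIC networks in the
low-information regime, and the screened false positive rate of the
cross-validated graphical lasso.  These sizes are the package's chosen
validation scale; the full published factorial (100 replicates, up to
p = 200, nineteen variants) runs through the same `run_experiment()`
driver unchanged.

## Known limitations

* Undirected Gaussian models only: no directed/causal structure, no mixed
  discrete-continuous models.
* The screening threshold is a single global cutoff; heterogeneous signal
  strengths near the noise floor can lose weak true edges (visible in the
  benchmark chain model with band $-0.2$ at n = 100).
* SPACE's alternation is a heuristic fixed-point scheme inherited from
  its literature; it is not guaranteed to find the global joint minimum
  in $(\rho, \omega)$, only certified against a generic optimizer on
  small instances.
* For $p > n$ the graphical-lasso subproblems remain solvable for
  $\lambda > 0$, but path endpoints near zero penalty can be
  ill-conditioned; the grid's lower endpoint of 0.05 for $p \ge 100$
  exists for exactly this reason.
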