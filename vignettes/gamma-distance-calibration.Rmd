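---
title: "Gamma distances for proteins: model, calibration engine, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma distances for proteins: model, calibration engine, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Two aligned amino acid sequences separated by an evolutionary distance
$d$ (expected substitutions per site) differ at a proportion $p$ of
sites.  Because substitutions overwrite one another, $p$ saturates: under
a stationary reversible model with equilibrium frequencies $\pi$, the
expected $p$ climbs from $0$ toward the plateau $b = 1 - \sum_r \pi_r^2$
and never reaches it.  The gamma distance inverts an idealized form of
this relationship,

$$d = a\,b\left[(1 - p/b)^{-1/a} - 1\right],$$

with a model-specific shape constant $a>0$ capturing how heterogeneous
replacement rates are across residue pairs.  Setting $b = 1$ gives the
Poisson-correction (PC) variant; setting $b = 1-\sum_r\pi_r^2$ gives the
equal-input (EI) variant.  As $a \to \infty$ the formula degenerates to
the log form $-b\log(1-p/b)$, the exact inverse for an equal-input
(frequencies-only) process.

`protgamma` serves two audiences: users who just want fast corrected
distances (`distance_matrix()`, with bundled constants for 27 empirical
models via `published_constants()`), and users who want to see — or
extend — the calibration that produces such constants.

## The substitution model layer

An empirical model is a symmetric exchangeability matrix $S$ plus a
frequency vector $\pi$ over the residue alphabet `ARNDCQEGHILKMFPSTWYV`
(PAML row order, used everywhere in the package).  `read_paml_dat()`
parses the standard PAML file dialect: 19 rows of lower-triangular
exchangeabilities read row by row, then 20 frequencies.  Frequencies are
renormalized to sum to exactly 1 before any computation, since published
files carry rounding error at the last digit.

The generator is assembled as $Q_{ij} = S_{ij}\pi_j$ ($i \ne j$), with
the diagonal set so rows sum to zero and a global rescaling so that
$-\sum_i \pi_i Q_{ii} = 1$ — branch lengths are then expected
substitutions per site.  By reversibility
$\mathrm{diag}(\sqrt{\pi})\,Q\,\mathrm{diag}(1/\sqrt{\pi})$ is symmetric,
so a single symmetric eigendecomposition, computed once per model and
cached, yields $P(t) = e^{Qt}$ for any $t$ at the cost of one $20\times
20$ multiplication.  The numerically tiny null eigenvalue of the
generator is clamped to exactly zero so that $P(t)$ remains stable for
arbitrarily large $t$.  The expected divergence curve needs only the
diagonal of $P$:
$p(d) = 1 - \sum_k c_k e^{\lambda_k d}$ with $c_k = \sum_i \pi_i
U_{ik}^2$, a 20-term exponential sum that makes curve evaluation and
inversion essentially free.

Seventeen of the 27 models load with full definitions (the files are
read from phangorn's PAML-format collection); for the remaining ten
(WAG\*, PMB, cpREV64, gcpREV, stmtREV, AB, mtInv, mtMet, mtVer, DEN) no
definition file is redistributed in any package this installation can
draw on, so `load_model()` fails informatively while
`published_constants()` still serves their constants.  One known
discrepancy is documented rather than patched: the VT definition file
available here is a different release of that matrix than the one behind
the bundled constants — its frequency vector gives $b = 0.94095$ where
the constants table says $0.94092$, and its exchangeabilities produce a
visibly different divergence curve.  We deliberately do not adjust
vendored numbers to make such checks pass.

## Pairwise maximum-likelihood distances

`ml_pairwise_distance()` maximizes the standard pairwise likelihood
$\sum_{ij} n_{ij}\log(\pi_i P(t)_{ij})$ over $t \ge 0$, where $n_{ij}$
are site-pattern counts.  The likelihood is unimodal in $t$ but flat
across the saturation plateau, which occupies almost all of the search
interval $[10^{-9}, 1000]$ on a linear scale; golden-section probing on
that interval can land in the flat region and never see the optimum.
The implementation therefore runs Brent on $\log t$ first (geometric
probing) and refines the result with a linear Brent pass in a bracket
around the coarse optimum (tolerance $10^{-8}$).  Log arguments are
floored at $10^{-300}$; all-diagonal count matrices return exactly 0.

## The synthetic data generator

The calibration data are pairs of integer counts
$(p\cdot n_{\text{sites}},\; d\cdot n_{\text{sites}})$, rounded half
away from zero.  `simulate_pd_samples()` produces them natively:

1. `generate_tree_collection()` builds random topologies by uniform
   coalescent-style joins with i.i.d. exponential branch lengths, each
   tree rescaled so the collection's diameters spread evenly across a
   target range (default $[0.05, 20]$, matching the intended coverage of
   patristic distances up to 20 substitutions/site).  Taxon counts
   default to 25–30: at least 25 taxa mirrors the eligibility rule of
   the tree-selection procedure (`select_trees_by_diameter()`, whose
   default grid runs from 0.0001 to 20 in steps of 0.001, i.e. 20,000
   picks), and keeping the range narrow bounds per-tree cost.
2. `simulate_alignment()` draws a root sequence i.i.d. from $\pi$ and
   propagates it along every branch by sampling end states from the rows
   of $P(t)$.  Only endpoint states matter for observed differences, and
   $d$ comes from branch lengths, so no event-by-event simulation is
   needed.  Rates are homogeneous across sites and there are no indels.
3. For a capped random subset of sequence pairs per tree (default 150),
   the observed $p$ and the pairwise ML distance $d$ are recorded and
   scaled to integers.

This emulates the structure of calibration data derived from large
real-tree collections — a wide, roughly even spread of divergences, ML
re-estimated distances, integer storage — but not everything about real
data: real gene trees have heterogeneous taxon sampling and non-random
shape; real alignments have indels, alignment error and compositional
drift; and real pipelines refit branch lengths jointly on the whole tree
where we estimate per pair.  Passing calibration tests therefore
demonstrates internal consistency of the machinery at desk scale, not
robustness of the constants to real-data artifacts.

## The regression layer

`subsample_uniform_p()` approximates the "uniform over $[0, 0.9]$"
design: observations with $p > 0.9$ are discarded, the rest stratified
into equal-width $p$ bins (default 45), and an equal quota drawn from
each bin without replacement.  The precise uniformization algorithm is a
design choice of this package; any scheme with the same marginal target
would do.

`fit_gamma_a()` estimates $a$ (with $b$ always held fixed — $b$ is a
property of $\pi$, not a free parameter) by Gauss–Newton on the weighted
least-squares objective $\sum_i w_i\,(d_i - f(p_i; a))^2$ with relative
weights $w_i = d_i^{-2}$, analytic gradient, starting value $a = 2$,
step halving on divergent steps, and a relative-offset stopping rule of
$10^{-8}$ within at most 50 iterations.  Pairs with $d = 0$ are excluded
up front: their weight is undefined and an exactly-zero distance carries
no information about curvature.  Reported uncertainty follows the usual
asymptotics: $\mathrm{SE}(\hat a)$ from the weighted Jacobian with the
weighted residual variance, a 95% interval via the $t$ quantile at
$n-1$ degrees of freedom (indistinguishable from normal quantiles at
calibration sample sizes), and an MSE reported as the *unweighted* mean
squared residual at the estimate — the scale on which fit quality is
conventionally tabulated.  Whether to weight the MSE was genuinely open;
the unweighted choice is recorded here so the number is auditable.

Two calibration drivers sit on top:

* `calibrate_analytic()` — the deterministic route: 2,000 $p$ values
  evenly spaced on $(0, 0.9]$, each mapped to $d$ through the exact
  divergence curve (the infinite-sites limit of simulation), then the
  weighted fit.  An even grid is the natural analogue of the uniform-$p$
  design.  For models whose plateau lies below 0.9 the grid is clipped
  with a warning.
* `calibrate_simulated()` — the stochastic route: the full generator
  above, uniform-$p$ subsampling (default target 20,000 observations),
  then the same fit; fully reproducible from one integer seed.

The test suite ties the two routes to each other and to published
constants (analytic within 5%, simulated within 10% for reference
models), and pins the estimator itself to independent oracles: exact
recovery of noise-free constants to $10^{-6}$, agreement with a
brute-force one-dimensional minimizer of the identical objective to
$10^{-6}$, and agreement with `nls` (the same Gauss–Newton algorithm
implemented independently in base R) at its looser stopping rule.  One
degenerate regime is asserted rather than avoided: the uniform model's
EI curve *is* the $a\to\infty$ log form, so its fitted $a$ must diverge
upward or fail to converge.

Problem sizes used by the default test run — 200 trees of 25–30 taxa,
5,000 sites, at most 150 pairs per tree, 20,000 retained observations —
are the package's chosen desk-scale operating point: large enough that
binomial noise in $p$ is small against the curvature being estimated,
small enough to iterate on.

## Distances for users

`p_distance()` applies pairwise deletion: a site is compared only when
both residues are canonical (gaps, `B`, `Z`, `X`, `J`, `U`, `O`, `?`,
`.` are excluded), case-insensitively.  Simulated calibration data are
gap-free, so the gap policy is our choice, and pairwise deletion is the
conservative standard.  `gamma_distance()` is undefined at
$p \ge b$; such pairs are flagged as saturated, carried as `Inf` in
memory, and serialized in PHYLIP output as a configurable finite
placeholder (default 30) because downstream tree builders need finite
input.  The square-PHYLIP writer pads names to 10 characters and prints
six decimals; a long-format TSV writer carries the $p$, $d$ and
saturation flags together.

## Known limitations

* Ten models expose constants but no loadable matrices (above); VT's
  available matrix file does not match its constants.
* No among-site rate heterogeneity, invariant sites, or indel process in
  either the CTMC layer or the simulator.
* Pairwise ML distances, not joint tree-wide refitting; at high
  saturation the pairwise estimate is noisy where a tree-based estimate
  would borrow strength across taxa.
* The gamma formula itself is an approximation: even the analytic
  calibration has irreducible lack-of-fit (visible as its MSE), and fits
  restricted to different $p$ ranges give slightly different $a$.
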