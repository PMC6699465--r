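# protgamma

Fast pairwise evolutionary distances between aligned amino acid
sequences, via **gamma distances** calibrated for 27 empirical
substitution models — plus the calibration engine that derives those
constants from first principles.

## The problem

Given two aligned protein sequences, the quantity of interest is the
evolutionary distance *d*: the expected number of substitution events
per site that separate them.  What is observable is only the
*p*-distance — the proportion of sites at which the sequences differ —
which underestimates *d* increasingly badly as substitutions overwrite
each other.  Full maximum-likelihood correction under an empirical
amino acid model (Dayhoff, LG, WAG, ...) is accurate but slow.  A
long-standing shortcut is the gamma distance

```
d = a · b · [ (1 − p/b)^(−1/a) − 1 ]
```

where *b* is the saturation plateau of the expected p-distance and *a*
is a shape constant absorbing the heterogeneity of replacement rates
among residue pairs.  Two variants are in common use:

* **PC** (Poisson correction): `b = 1`;
* **EI** (equal input): `b = 1 − Σ π_r²`, with `π` the model's
  equilibrium residue frequencies.

With the right per-model constant *a*, this one-line formula tracks the
full model-based estimate remarkably well across the usable range of
*p*.  `protgamma` bundles published (a, b) constants for 27 empirical
models × both variants, applies them to alignments, and — the heart of
the package — re-derives them with a built-in calibration engine:

* a CTMC layer (normalized reversible generator `Q[i,j] = S[i,j]·π_j`,
  spectral transition matrices, exact divergence curves
  `p(d) = 1 − Σ_i π_i P(d)[i,i]`, pairwise ML distance estimation);
* a simulation layer (synthetic tree collections spanning a diameter
  grid, sequence evolution along trees, patristic distances, integer
  (p, d) count blocks);
* a regression layer (uniform-p subsampling; weighted Gauss–Newton
  estimation of *a* with relative `d⁻²` weights, starting value 2,
  asymptotic standard errors, 95% CIs and MSEs).

## Worked example

```r
library(protgamma)

aln <- as_alignment(c(
  human = "ARNDCQEGHILKMFPSTWYVARNDCQEGHILKMFPSTWYV",
  mouse = "ARNDCQEGHILKMFPSTWYVARNDCEEGHILKMFPSTWYV",
  yeast = "ARNECQEGHILKMFPSTWYVGRNDCEEGHILKMFPSTAYV"))
distance_matrix(aln, "LG", "EI")
#> Gamma distance matrix (LG, EI: a = 3.56820, b = 0.94051), 3 taxa
#>          human    mouse    yeast
#> human 0.000000 0.025434 0.107409
#> mouse 0.025434 0.000000 0.079077
#> yeast 0.107409 0.079077 0.000000
```

Each entry corrects the observed proportion of differences (e.g.
human–mouse: 1 difference over 40 sites, p = 0.025) into expected
substitutions per site under the LG equal-input curve; at such small
divergence the correction is minimal, and it grows sharply as p
approaches the plateau b.  Re-deriving the Dayhoff PC constant from the
model's exact divergence curve:

```r
calibrate_analytic("Dayhoff", "PC")
#> Gamma-distance calibration: Dayhoff [PC]
#>   a = 2.01674  (95% CI 2.00567..2.02780, SE 0.0056)
#>   b = 1.00000 (fixed), MSE = 0.011535, n = 2000, converged in 5 iteration(s)
published_constants("Dayhoff", "PC")
#> PC gamma constants for Dayhoff: a = 1.99924 [1.99850, 1.99997], b = 1.00000 (MSE 0.00121)
```

The analytic re-derivation lands within ~1% of the bundled constant;
`calibrate_simulated()` runs the full stochastic pipeline (trees →
sequences → pairwise ML distances → weighted regression) and lands
within a few percent at desk scale.

A command-line interface wraps the same functions:

```sh
exec/protgamma dist --in aln.fasta --model Dayhoff --variant pc --out dist.phy
exec/protgamma calibrate --mode analytic --model WAG --variant ei
exec/protgamma simulate --model LG --n-trees 5 --n-sites 1000 --seed 7 --out-prefix sim/run1
exec/protgamma list-models
```

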