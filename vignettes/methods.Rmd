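---
title: "Models and methods behind ornamass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ornamass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ornamass` tests for correlated evolution between a binary cranial
character (bony ornamentation) and continuous log body mass on dated
fossil phylogenies, and asks whether ornamented lineages evolve toward
giantism faster. This vignette is the package's own account of the
models, the numerical choices, and the limits of what its tests
demonstrate.

## Tree model and time-scaling

Trees are `ape` `"phylo"` objects carrying a `root.time` attribute (Ma
before present), so a non-ultrametric fossil tree has well-defined tip
ages `root_age - depth`. `timescale()` first applies "basic"
stratigraphic dating — each internal node takes the age of its oldest
descendant tip, tips at the midpoint (or a seeded uniform draw) of their
first/last-appearance interval — which necessarily leaves zero-length
branches along the oldest lineages. Three rules then redistribute time
(`vartime`, default 1 Ma):

* **ABA** adds `vartime` to every branch. Tips whose root path has
  fewer edges end up older than their stratigraphic date; this
  distortion is inherent to the rule and is documented rather than
  hidden. The tree is re-anchored so no tip becomes younger than dated.
* **MBL** raises every branch to at least `vartime` by pushing parent
  nodes older, i.e. debiting the immediate ancestral branch first and
  recursing rootward. Because basic dating always leaves a zero-length
  path to the oldest tip, a strict "never extend the root" rule would
  reject essentially every real input; the root is therefore pushed
  back by default, with `root.extend = FALSE` available for the strict
  behaviour.
* **Equal** first extends the root age by `vartime` (the root rule we
  chose for the underspecified extension amount; it guarantees a donor
  for zero-length runs directly below the root), then lets each
  zero-length branch borrow from the nearest rootward branch with
  positive length, spacing the intervening node ages evenly. Tip ages
  are preserved exactly by MBL and Equal.

`consensus_tree()` summarizes a calibration set by arithmetic per-edge
means on the shared topology (edges matched by subtended tip sets), the
common practice for calibration-uncertainty summaries.

## PGLS with Pagel transforms

The regression `y = Xβ + e`, `e ~ N(0, σ²C)` uses the shared-path
matrix **C** (Ma) and is fitted by Cholesky whitening — no explicit
inverse is ever formed. Transforms are applied in the order κ (every
branch length raised to κ, covariance rebuilt), δ (every matrix entry,
i.e. node depth, raised to δ), λ (off-diagonal multiplier). The loose
phrase "exponential transform" in the methods literature is resolved to
the standard Pagel power forms. Bounds: λ ∈ [0,1], κ ∈ [1e-4, 3],
δ ∈ (1e-4, 3].

**R²** is reported as `1 - RSS/TSS` in the whitened space, with TSS
from the GLS intercept-only model — bounded, reproducible, and invariant
to the taxon ordering; `epsilon` is the whitened residual standard
deviation. We do not claim either matches any particular legacy
implementation's definition; they are labelled for what they are.

`pgls_mcmc()` is Metropolis-within-Gibbs: element-wise random walks on
coefficients (uniform prior on (-100, 100), the conventional
non-assuming choice), log σ² (uniform on a wide log range), and two
transform parameters. A tree index is drawn uniformly per iteration, so
calibration uncertainty enters the posterior as prescribed by the
tree-set design; with one tree the index is constant. Proposal scales
adapt only during burn-in, preserving detailed balance afterwards. The
"phylogenetic ANOVA" is the same sampler with factor and interaction
columns (`Orna`, `Phylo`, `Orna:Phylo`) and the proportion-above-zero
readout; no separate machinery.

The ornamented-mass threshold is `exp(intercept + Orna coefficient)`,
the model's predicted mass for an ornamented taxon. PGLS prediction is a
generalization of the fitted model, not a forecast, and the function
attaches a note saying so.

## Threshold model

`threshbayes()` implements the liability model: the binary state is the
sign of a latent variable evolving as Brownian motion jointly with the
observed continuous trait, covariance `R ⊗ C` with the liability rate
fixed at 1 and the threshold at 0 (the standard identifiability
constraints). Liabilities are Gibbs-updated one tip at a time from
their exact conditional normals (computed from the precision
`R⁻¹ ⊗ C⁻¹` with rank-one cache updates), truncated to the side of zero
matching the observed state; truncated draws use the inverse CDF with
an exponential-tilted rejection fallback deep in the tails. σ², the
correlation *r* (uniform prior on [-1, 1], implemented as a bounded
random walk — the prior, not the parameterization, is what matters for
the posterior), and the two root means are Metropolis updates. One
"generation" is a full sweep. Reported summaries are the posterior mean
*r* and mean *r²*; the latter is the quantity comparable to a
"threshold-model mean R²" in the motivating analysis, without asserting
the two definitions coincide.

A thresholded deep-tree liability can be invariant across tips (all one
state) — such data carry no information about *r*, and the test-suite
generators re-draw (deterministically) until both states reach 20%
representation, mirroring the polymorphic empirical character
(38 ornamented of 111).

## Mk inference

`mk_loglik()` is Felsenstein pruning with per-node rescaling; 2×2
transition matrices use the closed form, 4×4 the `ape` matrix
exponential. Root partials are weighted by observed (empirical) state
frequencies by default — the convention of equating stationary and
empirical frequencies — with flat and stationary weightings available.
Polytomies are refused by likelihood operations (the motivating trees
are resolved); I/O accepts them.

`rjmcmc_binary()` samples over four binary rate models (shared rate,
two rates, either rate zeroed). Jumps are independence proposals: a
candidate model is drawn uniformly and its rates drawn fresh from the
exponential prior, so prior and proposal cancel and the acceptance is
the likelihood ratio — Jacobian-free by construction. Rates get
log-scale random walks under an Exp(mean *m*) prior with
*m* ~ U(0, 10) (the hyperprior scheme of the motivating analysis);
*m* has its own Metropolis update. Fixed-model mode ("equal"/"free")
disables jumps and supplies the log-likelihood traces for Bayes-factor
tests.

The dependent model uses 4 combined states `{00, 01, 10, 11}`
(ornament digit first), double transitions structurally zero, with 4
(independent) or 8 (dependent) free rates and the same hyperprior
sampler. The headline contrast is rate(giantism gain | ornamented) /
rate(giantism gain | unornamented). Per-draw ratios explode whenever
the denominator visits zero, so the pipeline reports the ratio of
average posterior rates — the same form in which the ×20 figure is
conventionally printed. One genuine identifiability limit surfaced in
calibration: giant-but-unornamented tips can arise either by gaining
mass before losing ornaments or after, which inflates the unornamented
gain rate on some simulated histories; recovery of the full contrast is
therefore a majority-of-replicates property, not a per-dataset
guarantee.

`fossilize_bf()` constrains ("fossilizes") an internal node to each
alternative state in two otherwise identical chains and reports
`2 × (log HM₁ - log HM₂)`; positive favours the first-listed state.
`stochastic_maps()` samples node states from pruning conditionals
(root first, preorder sweep) and branch histories by rejection sampling
with a uniformization fallback after 1,000 failed attempts; tip states
are honoured exactly on every map.

## Generalized Hansen models

`hansen_loglik()` builds the exact multivariate-normal moments of a
regime-painted OU/BM model segment by segment: means accumulate
`θ(1 - e^{-αt})` contributions discounted by downstream attraction;
variances accumulate `σ²(1 - e^{-2αt})/2α` (or `σ²t` on BM segments)
to the pairwise MRCA and are discounted into both descendants. Because
variance integrates only over each tip's actual lifespan, fossil
(non-ultrametric) tips need no special casing. The regime at a node is
the rootward end of its segment painting; the root takes the oldest
segment's state. `root_mode = "stationary"` replaces the free root
value with the root regime's stationary distribution (mean θ, variance
σ²/2α); `"estimated"` adds the root value as a parameter — both modes
of the motivating analysis.

Fitting is multi-start (default 5 seeded starts) bounded ML on log α,
log σ² and free means — multi-peak OU surfaces are multimodal enough
that single-start optima are untrustworthy. Standard errors come from
the numerical Hessian; a non-invertible Hessian yields absent SEs plus
a flag rather than fabricated numbers. `sanity_flags()` encodes the
known failure modes (α below 1e-6/Ma; θ beyond twice the data range
outside the observed values; SE(θ) exceeding |θ|), and
`hansen_model_set()` excludes flagged fits from AICc model averaging
(AICc with n = number of tips), reporting them separately. The
phylogenetic half-life is `ln 2 / α`, with its ratio to tree depth
attached.

## Synthetic data: what it does and does not emulate

The generators define the package's study conditions. The default
fixture (`fixture_config()`): 111 taxa from a birth–death simulation
(birth 0.065, death 0.035 /Ma — chosen to give Mesozoic-scale tree
depths near 100–130 Ma and a substantial fraction of extinct tips),
an ornament character under symmetric rates 0.008/Ma from an
unornamented root (re-drawn deterministically until the ornamented
count falls in [30, 46], bracketing the empirical 38/111), and log
mass under two-regime OU at the published estimates — optima 2.394 and
7.241 log_e kg, common α 0.131/Ma, rates 1.358 (unornamented) and
0.313 (ornamented). A clade of size closest to 54 is flagged as the
Maniraptoriformes analogue so the trimmed tree is a ~57-taxon
structural match.

What the fixture does **not** emulate: ornament states are independent
of the clade flag (real maniraptoriforms are almost all unornamented);
taxon sampling is neutral rather than preservation-biased; the mass
range is whatever the OU truth produces rather than the empirical
0.1–7,000 kg span; and tip dates are exact rather than interval-coded.
Passing recovery tests therefore demonstrates correctness of the
estimators under their own generative assumptions — not robustness to
the coding decisions, sampling biases and topological uncertainty of
real fossil data.

## Numerical and scale choices

* Harmonic-mean marginal likelihoods are retained as the method of
  record for Bayes factors despite their known instability; they are
  computed by log-sum-exp and carry a batch-means Monte Carlo standard
  error so unreliable BFs are visible.
* Natural logs everywhere; BFs on the 2×log scale with verdicts at 5
  ("strong") and 10 ("very strong").
* Published-scale chain lengths (≈10⁶–2×10⁶ iterations) are the
  `pipeline_config()` defaults divided by `scale_divisor`; the test
  suite and acceptance script run chains of 1,200–6,000 sweeps on trees
  of 57–200 tips, sizes at which every calibration in the suite was
  verified to be informative. Seeds are mandatory throughout; every
  posterior object records its draws, and report regeneration under the
  same seed is identical.
* Degenerate inputs fail loudly: missing branch lengths, unscored or
  mismatched taxa, singular designs and non-positive-definite
  covariances all raise errors naming the offender, never silent
  defaults.

## Known limitations

Hidden-rate (hidden Markov) discrete models, multistate characters,
measurement-error-aware regression, multivariate OU and
stepping-stone/thermodynamic marginal likelihoods are out of scope.
The harmonic-mean Bayes factor should be read with its Monte Carlo
error. The Equal root-extension amount and the MBL root rule are
documented choices where the field's descriptions are loose; both are
isolated in `timescale()` and easy to revisit.
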