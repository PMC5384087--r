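---
title: "Models and methods in chronodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in chronodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chronodiv)
```

chronodiv implements the comparative-phylogenetics chain used to study how a
montane Neotropical radiation — the model case is the clearwing butterfly
genus *Pteronymia*, whose species table ships with the package — assembled
its spatial, elevational and temporal diversity. All three stages run on an
ultrametric chronogram with branch lengths in millions of years (my):

1. **Historical biogeography**: a time-stratified
   Dispersal-Extinction-Cladogenesis (DEC) model over nine Neotropical areas.
2. **Elevational trait evolution**: Brownian motion with jointly estimated
   Pagel λ and δ branch-scaling parameters, likelihood-ratio tests, and
   δ/λ-rescaled ancestral reconstruction.
3. **Diversification through time**: six birth-death models with
   exponentially time-dependent rates, AIC selection, and a stepwise clade
   shift scan with a posterior-frequency significance rule.

A fourth module simulates all three data types so that every estimator can
be calibrated against its own generating process without any external data.

## Tree model

A chronogram is an `ape::phylo` object validated on entry: one root, unique
non-empty tip labels, non-negative branch lengths, and root-to-tip depths
equal to relative tolerance `1e-6` (configurable; dating software emits
floating-point jitter, so tip ages are snapped to zero after validation).
Polytomies are tolerated everywhere except where the likelihood genuinely
assumes binary cladogenesis (`branching_times()` and the DEC pruning), which
refuse them: how to resolve a polytomy is a caller decision.

## DEC biogeography

Ranges are subsets of an ordered area system (default: Central America A,
Western lowlands B, Western/Central Northern Andes C, Central Andes D,
Eastern Cordillera of Colombia and Venezuela E, Upper Amazon F, Lower
Amazon G, Atlantic Forest H, Guiana Shield I), capped at four areas — the
largest range observed among extant species. Along a branch, a range `S`
gains area `j` at rate `d * sum_{i in S} m[i, j]`, where `m` is the dispersal
multiplier matrix of the epoch the branch segment falls in, and loses an
occupied area at rate `e`; a single-area range that loses its area falls
into an absorbing null range. Epochs default to 11–8, 8–5 and 5–0 my;
branches older than the oldest boundary extend that epoch rather than
erroring.

The shipped default multipliers are a synthetic three-class scheme (adjacent
areas 1.0, two graph steps 0.5, long-distance 0.01, with Central America cut
off before 5 my and the Upper Amazon before 8 my, emulating the Isthmus of
Panama and the Pebas wetland system). They are deliberately simple,
reproducible placeholders: expert matrices for a real analysis should be
supplied via `dispersal_schedule()`.

**Cladogenesis.** At a node a single-area range is inherited by both
daughters (sympatry). A widespread range `S` divides through `2|S|`
scenarios — subset sympatry `({i}, S)` and vicariance `({i}, S \ {i})` for
each occupied area `i` — with equal weight `1/(2|S|)`, each scenario summed
over both daughter orderings. Under this law a two-area range at a cherry
with single-area daughters contributes exactly `2/4 = 1/2`, which is the
convention all likelihoods and the exhaustive-enumeration test oracle share.

**Inference.** Conditional range likelihoods are propagated by Felsenstein
pruning with per-branch transition matrices; each epoch rate matrix is
exponentiated through an eigendecomposition (validated against the rate
matrix and falling back to Padé scaling-and-squaring when nearly defective).
The root is summed under a flat weight over observable states, the classic
DEC default; the weight vector is configurable, and no survival conditioning
is applied (the biogeographic likelihood tools this mirrors do not condition
on survival either). `(d, e)` are maximized on the log scale over
`[1e-8, 10]^2` with five seeded starts. Marginal ancestral ranges come from
a full up-down pass (inside pruning vectors times outside partial
likelihoods), with ties in the most-probable state broken towards the lowest
state index (size, then lexicographic) for determinism.

Event counting is rule-based on most-probable states: a node is an *in-situ
speciation* within a focal region iff its range and both daughter ranges are
subsets of the focal set (all internal nodes form the denominator — the
uncertainty-filtered alternative is a caller-side subset); a *colonization*
of area X is a branch whose parent range excludes X and child range includes
X, dated to the branch's age interval.

## Elevational trait evolution

A species' elevational niche is summarized as the 2.5th–97.5th percentile
interval of its records plus the arithmetic mean (`elevational_summary()`,
linear-interpolation percentiles). Each summary statistic evolves by
Brownian motion with rate σ² (m²/my) around a root state, with two
branch-scaling parameters:

* **λ ∈ [0, 1]** multiplies off-diagonal phylogenetic covariance; 1 keeps
  the tree's covariance, 0 is a star phylogeny. λ is applied at the
  covariance level, never by editing branches, so no negative branch can
  arise.
* **δ > 0** exponentiates node depths: depth `x` becomes
  `x^δ · T^(1-δ)` with `T` the crown depth. The normalization preserves
  total depth so ages stay in my after rescaling; δ > 1 concentrates change
  near the present (species-specific adaptation), δ < 1 near the root
  (early burst). The default upper bound is 3 — boundary estimates near 3
  are reported with a flag — and is configurable.

σ² and the root state are profiled analytically (GLS) at every `(λ, δ)`, and
the two scaling parameters are maximized jointly (a 5×5 start grid refined
by bounded quasi-Newton from the best three corners). Likelihood-ratio tests
against δ = 1 and λ = 1 use the plain upper χ²₁ tail with one degree of
freedom and no boundary-mixture correction, matching how such tests are
conventionally reported for these scalings. Two independent likelihood
evaluators — dense multivariate normal and contrasts pruning on the
transformed tree — are kept in agreement to 1e-8 by the test suite.

**Reconstruction.** `rescale_and_reconstruct()` rescales the tree by the
fitted δ and λ and predicts node values by best linear unbiased prediction
under BM with the GLS root plugged in; prediction variances include the
root-estimation term `(1 - c'V⁻¹1)² / (1'V⁻¹1)`, so they are exactly zero at
tips and grow monotonically toward the root. By default a scaling parameter
is applied only when its LRT is significant at 0.05 — rescale-only-when-
supported workflows leave the decision of what counts as different from 1
open, and a significance gate is the reproducible choice — with
`apply = "always"` / `"never"` overrides. For a constant trait the profiled σ² is zero and the
reconstruction is an exact point mass.

## Time-dependent diversification

Rates are exponential in time measured backward from the present:
λ(t) = λ₀·e^{αt}, μ(t) = μ₀·e^{βt}; α > 0 means faster speciation in the
past. The six canonical models (BCST, BVAR, BCST-DCST, BVAR-DCST,
BCST-DVAR, BVAR-DVAR) have 1, 2, 2, 3, 3 and 4 free parameters.

The likelihood of the branching times is the crown-conditioned
reconstructed-tree likelihood with the root (crown) speciation term
excluded and sampling fraction f. Writing ρ(t) = ∫₀ᵗ (λ−μ) and
J(t) = ∫₀ᵗ λ(s)e^{ρ(s)} ds, a lineage alive at time t is represented by
exactly one sampled lineage with log-density
`log p₁(t) = ρ(t) − 2·log(1 + f·J(t)) + log f`, and

logL = 2·log p₁(t₁) + Σ_{i≥2} [log λ(tᵢ) + log p₁(tᵢ)]

over branching times t₁ > t₂ > … (crown first). Survival conditioning
(−2·log P(t₁)) is off by default and switchable. J has closed forms for
pure birth (`e^ρ − 1`) and constant rates; otherwise it is evaluated by
48-node Gauss–Legendre quadrature per branching time (the integrand is a
smooth exponential, and the quadrature is held to the adaptive
`stats::integrate` answer by tests), with `quadrature = "adaptive"`
available. Optimization is bounded multi-start quasi-Newton (λ₀ on the log
scale in [1e-4, 10], μ₀ in [0, 10], α and β in [−2, 2], eight seeded
starts), and every model is warm-started from its nested sub-models so a
superset never scores below a model it contains. The six-model table is
ranked by AIC = 2k − 2logL (the shift scan below uses AICc), with the best
model flagged supported only when every rival has ΔAIC > 2.

**Shift scan.** Per tree: fit one constant-rate birth-death model; for every
internal node whose clade and backbone both remain large enough (default
five tips), fit the clade and the clade-collapsed backbone separately
(two rates each, plus one parameter for the shift location, k = 5) and
accept the best shift if AICc improves by at least 4 units (configurable;
the stepwise tool this emulates derives its threshold from simulations we
do not reproduce); iterate on the remainder. Across a posterior sample of
trees, shift locations are matched by tip-set Jaccard similarity ≥ 0.9 —
posterior topologies differ, so exact matching would under-count — and a
location is significant only when present in ≥ 5% of trees. AICc sample
size is the number of branching times.

## Synthetic data

`simulate_bd_tree()` runs the birth-death process forward from a crown pair,
with thinning for time-varying rates; extinct lineages are pruned and
whole-clade extinctions trigger resimulation (up to 1000 attempts, counted
in an attribute; the induced conditioning-on-survival bias is accepted and
documented rather than corrected). Trees can be conditioned on crown age or,
for constant rates, on a tip count — in which case the present is placed
uniformly between the nth birth and the next event so that no pendant branch
has zero length. `simulate_bm_trait()` draws from the exact multivariate
normal of the λ/δ-transformed covariance. `simulate_dec_history()` runs
Gillespie anagenesis along branches with epoch-specific rates and samples
one cladogenesis scenario per node from the inheritance law; lineages that
fall to the null range are recorded as extirpated (or the history is
redrawn). One seed controls each simulator call and results are
bit-reproducible.

What the simulators deliberately do not emulate: phylogenetic uncertainty
from dating (a posterior sample is emulated by independent replicate
simulations, not by correlated draws), spatially autocorrelated occurrence
records behind the elevational summaries, and founder-event (jump)
dispersal. Passing calibration tests on these simulations therefore shows
estimator correctness under the model's own assumptions, not robustness to
their violation on real data.

## Numerical choices and problem sizes

* Matrix exponentials: eigendecomposition per epoch rate matrix with
  explicit reconstruction validation (tolerance 1e-9 relative) and Padé
  fallback; negative entries from roundoff are clamped to zero.
* Pruning vectors are renormalized at every node with accumulated log
  scale factors, so likelihoods of large trees cannot underflow.
* Optimizers are deterministic given their seed; reported multi-start
  tables let the user check that the optimum beat every start.
* The calibration suites run at sizes chosen to give stable Monte Carlo
  estimates while staying convenient on a laptop: 200-tip trees (40
  replicates) for δ recovery, 100-tip trees (400 replicates) for the
  δ-LRT type-I error, 200-tip constant-rate and crown-10-my decreasing-rate
  trees (50 seeds each) for model selection, 100 replicates for (λ₀, α)
  recovery, 40-tip trees (50 seeds) for shift-scan false positives and 30
  grafted-clade replicates for shift power. The dispersal-rate
  recovery harness uses a four-area system with 100-tip trees, where DEC
  state spaces stay small enough for many replicate ML fits.

## Known limitations

* DEC here is the classic ML variant: no founder-event (+J) parameter, no
  Bayesian range inference, and the across-tree extension is per-tree
  fitting plus frequency summaries rather than exact statistical DEC
  averaging.
* The shift scan's AICc threshold is a fixed default, not a
  simulation-calibrated function of tree size.
* LRTs for λ and δ use χ²₁ without boundary corrections; near-boundary
  nulls make them mildly conservative for λ.
* Elevational summaries treat records as exchangeable; sampling bias in
  the underlying records propagates untouched.
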