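---
title: "Models, conventions and numerical choices in phytraitsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, conventions and numerical choices in phytraitsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytraitsim)
```

## The model family

All eleven primary models are Gaussian processes on a rooted tree with
branch lengths in time units, expressible as multivariate normal tip
distributions

$$ y \sim N(\mu,\; \sigma^2 V_0(\theta)), $$

where $V_0$ is a deterministic transformation of the Brownian-motion
covariance $C$ ($C_{ij}$ = height of the MRCA of tips $i$ and $j$; the root
sits at height 0, the deepest tip at $T$). The rate $\sigma^2$ is **never**
baked into transformed branch lengths: transforms stay idempotent, and the
fitting code can profile $\sigma^2$ analytically.

With a branch spanning heights $[t_1, t_2]$:

| model  | parameter (domain)        | transformed branch length                                      |
|--------|---------------------------|----------------------------------------------------------------|
| BM     | —                         | $t_2 - t_1$ (identity)                                         |
| OU     | $\alpha > 0$              | $\tfrac{1}{2\alpha} e^{-2\alpha T}\,(e^{2\alpha t_2}-e^{2\alpha t_1})$ |
| EB     | $a \neq 0$                | $(e^{a t_2}-e^{a t_1})/a$                                      |
| lambda | $\lambda \in [0,1]$       | internal edges $\times\lambda$, terminals padded to keep tip heights |
| delta  | $\delta > 0$              | $t_2^\delta - t_1^\delta$ (node heights powered)               |
| kappa  | $\kappa \in [0,1]$        | each branch $b \mapsto b^\kappa$                               |
| trend  | slope $s$                 | $\int_{t_1}^{t_2} \max(0,\, 1+st)\,dt$                         |
| white  | —                         | no tree; $V_0 = I$                                             |
| depth  | depth $> 0$               | global rescale to the target depth                             |
| lrates | rate table                | clade-wise branch multipliers (stem included)                  |
| nrates | interval table            | time-interval branch multipliers                               |

Every transform with a tree representation is implemented twice: on the
tree (`rescaleTree` then `phyloVCV`) and directly on the covariance
(`closedFormVCV`, elementwise in the MRCA heights where the transform is a
monotone height map, edge-wise through an independent root-path incidence
matrix otherwise). The test suite holds the two paths to $10^{-8}$
relative agreement on random trees; the closed-form path also serves as the
fast likelihood kernel.

## Conventions the literature leaves open

Several choices are genuinely underdetermined by the model descriptions;
the package fixes them as follows, and uses the *same* convention in
simulation and fitting so the two sides are always internally consistent.

* **OU** is the root-fixed process on ultrametric trees:
  $V_{ij} = \tfrac{1}{2\alpha} e^{-2\alpha(T-s)}(1-e^{-2\alpha s})$ with
  $s$ the MRCA height. Non-ultrametric input is rejected rather than
  given an arbitrary fossil-tip convention. As $\alpha \to 0$ this
  collapses to BM; $e^{2\alpha T}$ overflow is caught with an explicit
  parameter-bound error.
* **delta** acts on node heights with *no* rescaling back to the original
  depth: $\delta$ changes total variance as well as its apportionment,
  which is the simplest self-consistent reading of a time-dependent rate.
* **trend** interprets the slope as a linear change of the diffusion
  *rate*, floored at zero: $r(t) = \max(0, 1+st)$. Samplers that draw
  slopes as large as $\pm 100$ otherwise produce negative branch lengths;
  the floor keeps lengths nonnegative and a warning reports when it
  engages.
* **kappa** maps zero-length branches to zero ($0^0 := 0$), preserving
  hard-polytomy semantics.
* **lambda** is defined by off-diagonal scaling of the covariance; the
  tree-space version (shrink internal edges, pad terminals) matches it and,
  because $\lambda \le 1$ is enforced, never needs negative padding.

## Stacking

A stacked model applies, in order: primary transform → local clade rates →
interval rates → covariance; ancestral mean shifts touch only the tip
expectation vector ($\mu_i$ = $z_0$ plus the shifts on tip $i$'s root
path), never the covariance. Clades are anchored by the MRCA of a named
tip set — portable across Newick readers, unlike node indices — and the
clade's stem branch is included in rate scaling. Interval coordinates
refer to the original tree's time axis; under a stacked primary transform,
boundaries are mapped through the primary's height map where one exists
(BM, OU, EB, delta, trend, depth) and by per-edge linear interpolation of
the transformed branch over its original time span for the edge-wise
transforms (lambda, kappa, lrates), where no global height map is defined.
When both overlays are present, clade rates apply before interval rates —
an arbitrary but documented and tested order. Shifts are treated as acting
on final tip means regardless of the primary model; under OU a real mean
jump would decay toward the optimum, so this is a declared simplification,
not a theorem.

## Simulation engine

Each replicate draws its parameters from per-parameter samplers (fixed,
uniform, exponential, gamma, normal, or a user list). Draws outside a
parameter's domain are hard errors: silently clamping or redrawing would
make the realized parameter distribution differ from the configured one.
Multi-trait data use the matrix-normal construction
$Y = M + L_C Z L_R^\top$ with lower Cholesky factors of $\sigma^2 V_0$ and
of the among-trait covariance $R$. If a factorization fails (numerically
semidefinite cases such as $\lambda = 0$), one jitter of
$10^{-10}\,\mathrm{tr}(V)/n$ is added to the diagonal before failing hard.
Measurement error is iid $N(0, v)$ added to every cell — a single scalar
variance per replicate; per-tip error vectors are an extension point, not
implemented.

Reproducibility uses counter-style RNG substreams keyed by (master seed,
replicate index, stage), so replicate $k$ is bit-identical no matter how
many other replicates run, and a manifest row (model, realized parameters,
seed materials) is sufficient to regenerate its data exactly.

## Output formats

Contrasts follow Felsenstein's pruning recursion; polytomies are rejected
rather than silently resolved, because random resolution changes contrast
values. PGLS whitening multiplies by the inverse lower Cholesky factor of
the tree covariance, uncentered by default (centering by the GLS root
estimate is a flag); the lower-triangular factor is deterministic and the
choice is recorded because other square roots would give numerically
different outputs. Whitening is linear but not idempotent — a second pass
uses the same factor again.

## Maximum-likelihood fitting

For a candidate model, $\hat z_0$ is the GLS root estimate and
$\hat\sigma^2 = r^\top V_0^{-1} r / n$ profiles analytically, leaving only
the shape parameter to a numeric search over fitContinuous-style bounds:
$\alpha \in [e^{-500}, e]$, $\lambda, \kappa \in [e^{-500}, 1]$,
$\delta \in [e^{-500}, 3]$, $a \in [-5/T, 10^{-6}]$ (note the tiny
*positive* upper end, so EB must accept positive $a$),
slope $\in [-100, 100]$. Because several ranges span $e^{-500}$, those are
searched on the log scale. The search evaluates five deterministic starts
at quantiles $\{0.05, 0.25, 0.5, 0.75, 0.95\}$ of the (transformed) range,
plus both endpoints and the BM-identity value, then refines by Brent search
in the bracket around the best start — fully reproducible, and the
endpoint/identity evaluations guarantee nesting relations such as
$\ln L(\hat\lambda) \ge \ln L(\mathrm{BM})$ exactly.

When measurement error is estimated it enters as the ratio
$\phi = v/\sigma^2$, so $V_0 + \phi I$ keeps $\sigma^2$ profiled; $\phi$ is
searched on $\log\phi \in [-20, 7]$ jointly with the shape parameter
(coarse deterministic grid, then Nelder–Mead clamped to the box). AIC is
$2k - 2\ln L$ with $k = 2$ (BM, white), 3 (shape models), $+1$ when error
is estimated; selection uses plain AIC by default, with small-sample AICc
behind a default-off flag.
Ties — including the degenerate constant-data case, where the profiled
variance collapses and the likelihood is unbounded for every candidate —
break by smaller $k$, then the fixed order BM, OU, EB, lambda, delta,
kappa, trend, white.

Bivariate BM/OU/EB use the matrix-normal likelihood
$V = R \otimes C(\theta)$ with a single shared shape parameter; given
$\theta$, the two root states and $R$ (rates folded into its diagonal) have
closed-form estimates, $k = 5$ (BM) or 6 (OU/EB). A numerically singular
$\hat R$ (e.g. duplicated traits) is flagged rather than silently accepted.

## The measurement-error case study

The demonstration pipeline simulates each of the seven focal univariate
models with the case-study samplers ($\sigma^2 \sim \mathrm{Exp}(1)$,
$z_0 \sim N(0,1)$, shapes uniform over the fitting bounds), then adds error
at three levels. "Moderate" and "high" are not standardized quantities
anywhere; this package *defines* them as error variance equal to $0.25$ and
$1.0$ times the replicate's realized $\sigma^2 \times$ mean tip depth —
i.e. a quarter of, and the whole of, the BM-scale phylogenetic variance —
and records the realized variance per replicate. White noise and depth
have no published sampler row; white noise reuses the BM samplers by
analogy, recorded as an assumption.

Documented problem sizes: the confusion-matrix property test runs 200
replicates per model on a 50-tip pure-birth tree (7 models × 3 error
levels × 2 estimation modes ≈ 59 000 model fits), chosen as the smallest
design where the qualitative effects — accuracy decaying with error, BM
favored when error is estimated — are stable across seeds. The acceptance
script uses 60 replicates on 30 tips for the same pipeline, plus
$10^4$–$2\times10^4$ Monte-Carlo replicates for distributional checks and
200 replicates on 100 tips for rate recovery.

## What the synthetic data do and do not show

The built-in pure-birth generator produces clean, ultrametric, bifurcating
trees with exponential waiting times — adequate for verifying the engine
and for power analyses on tree *size*, but free of the features that make
empirical trees hard: non-ultrametricity from fossil tips, extreme
imbalance, rate heterogeneity not matching any candidate model, and
non-Gaussian trait variation. Passing tests therefore certify the
mathematics of the simulator and fitter, not that model selection will
behave comparably on any particular empirical tree; the demo pipeline
accepts arbitrary user trees precisely so that question can be asked per
dataset. The trend model is a known weak point: with slopes sampled
across $[-100, 100]$ most draws floor the rate to zero almost immediately,
and recovery of "trend" as the generating model is accordingly poor —
manifests record each slope draw so the question remains investigable.

## Known limitations

* No multi-optimum or non-stationary OU, no Lévy/jump processes, no
  discrete traits, no within-species sampling models beyond additive
  Gaussian error.
* Mean shifts do not interact with OU attraction (see above).
* lrates/nrates/AncShift are simulation-side processes; the fitting module
  covers the seven focal models plus white noise only.
* PGLS whitening provides no regression machinery — whitening only.
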