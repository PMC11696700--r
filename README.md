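# phytraitsim

Large-scale simulation and maximum-likelihood model selection for
continuous trait evolution on phylogenies.

## The problem

Phylogenetic comparative methods model a continuous trait evolving along a
rooted, time-calibrated tree. Under Brownian motion (BM) with root state
*z₀* and rate *σ²*, tip values are multivariate normal:

    y ~ N(z₀·1, σ²·C),   C[i, j] = height of the MRCA of tips i and j.

The classical extensions of BM — Ornstein–Uhlenbeck (OU, attraction *α*
toward an optimum), early burst (EB, rate changing as *e^(a·t)*), Pagel's
λ/δ/κ, a linear rate trend, white noise, depth scaling, and clade- or
interval-specific rate shifts — can all be written as deterministic
transformations of the branch lengths (equivalently of *C*). This package
implements eleven such primary models, lets any of them be **stacked** with
local clade rates and/or instantaneous ancestral mean shifts, draws model
parameters afresh per replicate from user-chosen distributions, simulates
single or correlated multi-trait data via a matrix-normal model
(`vec(Y − M) ~ N(0, R ⊗ σ²C)`), adds Gaussian measurement error, and emits
five output formats: raw traits, phylogenetic independent contrasts (on the
input or unit-depth tree), and PGLS-whitened traits (likewise).

On the inference side it fits the candidate models by maximum likelihood
(root state and rate profiled analytically; shape parameters by bounded
deterministic multi-start search), selects among them with
AIC = 2k − 2 ln L — optionally estimating the measurement-error variance as
an extra parameter — fits bivariate BM/OU/EB, and summarises selection
accuracy as confusion matrices. It is intended for anyone studying the
power and pitfalls of evolutionary model selection: which models are
identifiable on *their* tree, at *their* noise level, before collecting
data.

## Worked example

```r
library(phytraitsim)

tree <- yuleTree(50, birth_rate = 1, seed = 7)   # ultrametric, 50 tips

sess <- simulationSession(
  tree, model = "OU", n_rep = 100,
  params = list(sigma2 = paramSampler("exponential", rate = 1),
                z0     = paramSampler("normal", mean = 0, sd = 1),
                alpha  = paramSampler("uniform", min = 0.1, max = 2)),
  outputs = c("raw", "pic"), seed = 42)
arch <- runSession(sess)
arch
#> Trait simulation archive: 100 replicate(s), model OU, 1 trait(s)
head(arch$manifest[, c("replicate", "model", "sigma2", "shape_value")], 3)
#>   replicate model    sigma2 shape_value
#> 1         1    OU 0.1157668   0.7139849
#> 2         2    OU 1.4179289   0.4400558
#> 3         3    OU 0.8282842   1.5458641

sel <- fitModelsAIC(tree, arch$traits[[2]][, 1])
sel
#> AIC model selection: selected OU
#>   model       lnL k      AIC      dAIC converged
#>      OU -54.14551 3 114.2910 0.0000000      TRUE
#>   delta -54.59971 3 115.1994 0.9083988      TRUE
#>   trend -55.29587 3 116.5917 2.3007219      TRUE
#>   kappa -55.61196 3 117.2239 2.9329000      TRUE
#>  lambda -56.05882 3 118.1176 3.8266096      TRUE
#>      BM -57.95956 2 119.9191 5.6280907      TRUE
#>      EB -57.95955 3 121.9191 7.6280810      TRUE
```

The replicate here was generated with a strong pull (α ≈ 0.44, drawn from
the sampler) so OU wins; BM, which ignores the pull, pays 5.6 AIC units.

The manifest row for a replicate (model, realized parameter draws, master
seed) is sufficient to regenerate it exactly; rerunning `runSession(sess)`
reproduces every table bit for bit. `modelSelectionDemo()` runs the full
simulate–perturb–fit–select pipeline across all seven focal models and
three measurement-error levels and returns row-normalized confusion
matrices:

```r
demo <- modelSelectionDemo(yuleTree(30, 1, seed = 1), n_rep = 60, seed = 3)
demo
#> Model-selection demo: 7 models x 60 replicates on 30 tips
#>   none_assumed_absent          mean diagonal 0.524
#>   none_estimated               mean diagonal 0.231
#>   moderate_assumed_absent      mean diagonal 0.183
#>   moderate_estimated           mean diagonal 0.157
#>   high_assumed_absent          mean diagonal 0.160
#>   high_estimated               mean diagonal 0.160
```

Accuracy collapses as error grows, and estimating the error parameter
pushes selections toward the simpler BM model — the package's reference
behavior for this kind of power analysis.

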