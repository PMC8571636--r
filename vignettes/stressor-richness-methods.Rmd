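---
title: "Methods: multiple-stressor simulations in competitive communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multiple-stressor simulations in competitive communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stresscomm)
```

## The question the package addresses

When a community faces many stressors at once, the number of stressors
(stressor richness, *s*) and the overall severity of stress (total stressor
intensity, TSI) are confounded: adding stressors normally adds intensity.
`stresscomm` implements a simulation design that severs this confound. The
core device is the TSI definition

$$\mathrm{TSI} = 1 - \prod_{i=1}^n \prod_{l=1}^s \varepsilon_{il},$$

over the $n \times s$ matrix $E$ of multiplicative stressor effects
$\varepsilon_{il} \in (0,1]$ on species' focal traits, together with the
power rescaling $\varepsilon'_{il} = \varepsilon_{il}^{\,k}$,
$k = \log d / \log \prod\prod \varepsilon_{il}$, which pins the product at
any target $d = 1-\mathrm{TSI}$ while preserving the relative pattern of
stressor action (`rescale_to_fixed_tsi()`). Experiments can then vary $s$
with TSI either floating or fixed.

## Models and assumptions

All dynamics are deterministic (no demographic or environmental
stochasticity), stressors are press perturbations acting multiplicatively on
one growth parameter per species, and only competitive interactions are
modeled.

* **Lotka–Volterra** — phenomenological; $dN_i/dt / N_i = \mu_i - \sum_j
  \alpha_{ij} N_j$; stressors act on $\mu_i$; carrying capacity
  $\mu_i/\alpha_{ii}$.
* **MacArthur consumer–resource** — resources are explicit. The resource
  equation is logistic supply with linear mass-action uptake,
  $dR_k/dt = r_k R_k (1 - R_k/K_k) - \sum_i c_{ik} N_i R_k$, paired with
  consumer growth $\sum_k w_i c_{ik} R_k - m_i$. The species-specific
  resource value $w_i$ (rather than the classical resource-specific form) is
  the stressed trait, which keeps the three models comparable. The logistic
  supply with mass-action uptake form is this package's choice for the
  resource dynamics and is stated prominently because other renewal forms
  (e.g. chemostat supply) would change quantitative outcomes.
* **Stomp light-spectrum competition** — at most four phytoplankton species
  coexist by absorbing different parts of the 400–700 nm spectrum. Per-capita
  growth is $(\phi_i/z)\int_0^z \gamma_i(z')\,dz' - l_i$ with
  $\gamma_i(z) = \int a_i(\lambda) I(\lambda,z)\, d\lambda$ and Beer–Lambert
  attenuation $I(\lambda,z) = I_{in}(\lambda)\exp\{-z(\sum_j a_j(\lambda)N_j
  + a_{bg}(\lambda))\}$. The optical defaults — a 31-point wavelength grid, a
  51-point depth grid, Gaussian absorption spectra with evenly spaced peaks
  (450–650 nm) and 50 nm width, peak absorption 2×10⁻³ per abundance per m,
  flat incident flux 40, background attenuation 0.2 m⁻¹, depth 10 m — are
  this package's parameterization, chosen to give monoculture equilibria of
  order 10²–10³ and feasible 4-species coexistence. Grid-doubling convergence
  of both quadratures is exercised in the test suite; both grids are
  user-configurable.

## Stressor algebra

Effects compose additively in log space; trait-level pairwise interactions
$\eta_{il_1l_2}$ (symmetric, zero diagonal — stressors do not interact with
themselves) enter as products of log effects:

$$\log\theta_i = \log\theta_{i,0} + \sum_l \log\varepsilon_{il}
 + \sum_{l_1}\sum_{l_2} \log(\varepsilon_{il_1})\log(\varepsilon_{il_2})\,
 \eta_{il_1l_2}.$$

Three conventions deserve explicit statement:

* **Log base.** The interaction term uses base-10 logarithms by default
  (matching the worked example where $\log 0.6 = -0.22$); with $\eta = 0$
  the base is irrelevant and the result is exactly
  $\theta_i = \theta_{i,0}\prod_l \varepsilon_{il}$. `log_base` is an
  argument of `apply_stressors()`.
* **Pair counting.** The double sum runs over ordered pairs as written, so a
  symmetric pair receives weight $2\eta\log\varepsilon_1\log\varepsilon_2$;
  `ordered_pairs = FALSE` counts each unordered pair once.
* **Rescaling and η.** The TSI rescaling operates on $E$ only; sampled
  interaction tensors are not themselves rescaled. SCV is computed on the
  matrix as experienced, i.e. after rescaling.

SCV — the coefficient of variation of the row products of $E$ — uses the
sample ($n-1$) standard deviation; a 1-species matrix returns 0 by
convention. Traits can become arbitrarily small under severe stress but
never non-positive; no floor is applied.

## Community generation (the synthetic-data stage)

Focal traits are sampled log-normal(meanlog 0, sdlog 0.25). The non-focal
defaults are reconstructions chosen for plausible unstressed coexistence and
should not be read as any empirical calibration:

* LV: $\alpha_{ii} = 1$, off-diagonal $\alpha \sim U(0.1, 0.9) \cdot 3/(n-1)$.
  The $3/(n-1)$ factor equals 1 at the 4-species baseline and scales the
  summed competitive load so that richer (8- and 16-species) random
  communities remain feasible; without it, random coexistence of 16 species
  is essentially impossible and the screening stage would never accept.
* MacArthur: one resource per species; own-resource uptake 1, shared uptake
  $U(0.05, 0.3)\cdot 3/(n-1)$ (same scaling rationale); resource rates and
  capacities 1; maintenance $m_i$ a $U(0.25, 0.45)$ fraction of
  resource-saturated growth $w_i \sum_k c_{ik} K_k$, so every monoculture is
  viable pre-stress but sufficiently severe stress can starve it.
* Stomp: losses $l_i$ a $U(0.25, 0.45)$ fraction of unshaded depth-averaged
  growth, mirroring the MacArthur construction.

Communities are screened (`screen_coexistence()`): the unstressed
equilibrium is solved and the community is accepted only if every species
sits at ≥ 1 % of its carrying capacity (monoculture equilibrium). Solver
failures count as rejections with a distinct status, never as silent drops.
Each sampling attempt uses seed `base_seed + attempt`, so any accepted
community is reproducible in isolation.

What the generator deliberately does **not** emulate: cotolerance
(correlated species sensitivities), stressors that increase growth, temporal
(pulse) stress, and trophic or mutualistic links. Passing tests therefore
demonstrate the internal logic of the richness/intensity decomposition, not
predictions for any particular natural community.

## Equilibria, pruning, numerics

Equilibria are roots of the per-capita rates of the extant set (equivalent
to rooting the full dynamics on the positive orthant, while avoiding the
trivial $N_i = 0$ roots), found with Broyden's quasi-Newton method
(`pracma::broyden`; a scalar secant iteration covers the univariate case,
which that routine does not accept). Numerical policy:

* residual tolerance 10⁻¹⁰ in max-norm, at most 200 iterations;
* warm starts: half carrying capacity for unstressed solves, the unstressed
  equilibrium for stressed solves;
* on failure, deterministic multiplicative restarts (×1, ×0.5, ×1.6, ×0.8,
  ×1.25, ×0.64) — no RNG inside the solver;
* a start that is already a root returns in 0 iterations;
* persistent failure returns `converged = FALSE` with diagnostics; it is
  never an exception.

`prune_extinctions()` iterates solve → remove species below 1 % of their
*unstressed* carrying capacity (negative or non-finite candidates count as
below threshold) → re-solve, until the survivor set is a fixed point;
rounds are capped at $n + r + 4$ to abort oscillating removal sets.
Resources driven to zero are deactivated and reactivated if their invasion
rate turns positive. Stability is not checked by eigenvalues; instead the
test suite cross-validates pruned solutions against stiff time integration
(`deSolve`) and, for 4-species LV, against the survivor-subset enumeration
implied by integration. This is a documented limitation: in the rare case of
alternative stable states the pruned root is the one reached from the warm
start.

## Metrics

Per replicate: yield ratio (stressed/unstressed total abundance),
persistence (count and fraction), Bray–Curtis similarity between stressed
and unstressed abundance vectors, SCV, and the Loreau–Hector partition
$\Delta Y = n\overline{\Delta RY}\,\overline{M} + n\,\mathrm{cov}(\Delta
RY, M)$ with population (1/n) covariance and expected relative yield $1/n$
(the two-species analytics use 1/2). Conventions:

* Monoculture yields $M_i$ are computed under the **stressed** traits (each
  species alone at its stressed monoculture equilibrium); an
  unstressed-monoculture variant can be obtained by passing unstressed
  capacities to `biodiversity_effects()` directly.
* Mixture-extinct species enter with observed yield 0 and keep their
  monoculture yield. Species whose *stressed monoculture* is infeasible
  ($M_i = 0$) cannot enter the partition; the pipeline computes the
  partition over the remaining species (with expected relative yield one
  over their number) and flags the record `NA` if fewer than two remain.
* Scaled effects divide by $\Delta Y$ and are `NA` when $\Delta Y = 0$;
  where defined they sum to exactly 1. For the two-species closed forms the
  scaled complementarity is implemented as $1 - S/\Delta Y$, which this sum
  constraint forces.

## The factorial experiment

`build_design()` crosses TSI level (10 %, 50 %, 90 %, unfixed) × stressor
richness (1–20) × model × initial richness (4, 8, 16; Stomp only at 4) ×
interactions (absent/present): 1120 cells, 1000 requested replicates each by
default. Replicate seeds derive deterministically from the base seed; failed
replicates (community generation or stressed solve) are replaced from a
fresh derived seed up to 5 times, with replacements counted in the output.
Aggregation reports means and 10th/90th percentiles (linear interpolation
between order statistics, `quantile` type 7), excluding undefined scaled
terms with counts.

The test suite exercises a scaled-down profile — 4-species Lotka–Volterra,
no interactions, $s \in \{1, 5, 10, 20\}$, TSI unfixed and fixed at 90 %,
200 replicates per cell; the two-species ρ experiment and the SCV sweep run
at 1000 iterations per richness level — sizes chosen as the smallest at
which the directional contrasts are decisively resolved. At this scale the
qualitative pattern is stable: with TSI floating, function, persistence and
compositional resistance all fall with richness while selection rises; with
TSI fixed, persistence and compositional resistance rise with richness,
complementarity rises and selection falls. Exact replication of the
full-scale 1 120 000-run experiment is out of scope: the original parameter
ranges for the non-focal parameters are not published, so only
direction-of-effect properties are asserted.

## Known limitations

* Non-focal sampling ranges are reconstructions; absolute metric values are
  not comparable to any published figure, only directions and the algebraic
  identities are.
* No stability analysis at equilibria (cross-checked by integration only at
  test scale).
* The Stomp model is restricted to ≤ 4 species and one fixed optical
  geometry per community.
* Press stressors only; no time-varying stress, no positive (growth-
  enhancing) environmental change, no stressor action on interaction
  coefficients.
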