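---
title: "Growth-defence trade-offs in phage-bacteria communities: model, solvers and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-defence trade-offs in phage-bacteria communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmphage)
```

## The model

`rmphage` simulates a well-mixed community of `n` bacterial strains, each
carrying a unique restriction-modification (RM) defence system, preyed on by
a single phage species. Because an RM system only destroys *unmethylated*
phage DNA, the phage population splits into `n` epigenetic variants: variant
`i` carries the methylation pattern that evades the RM system of strain `i`.
A variant that successfully infects a different host re-emerges carrying
*that* host's methylation pattern, so every infection of host `i` produces
variant-`i` progeny.

With `b_i` and `p_i` the strain and variant densities, `B` and `P` their
totals, the dynamics are

$$\dot b_i = \gamma_i b_i (1 - B/C) - \eta b_i p_i -
  \eta \omega_i b_i (P - p_i) - \alpha b_i,$$
$$\dot p_i = \eta \beta b_i p_i + \eta \omega_i \beta b_i (P - p_i) -
  \eta p_i B - \delta p_i.$$

Each strain is characterised by two numbers: its maximal growth rate
$\gamma_i$ and its RM *imperfection* $\omega_i$, the probability that an
unmethylated phage escapes restriction (so $1/\omega$ is the defence
strength; $\omega = 1$ means no defence). The shared constants are the
adsorption rate $\eta$, burst size $\beta$, phage decay rate $\delta$,
bacterial dilution rate $\alpha$, and carrying capacity $C$.

The scientific question is how a *trade-off* between $\gamma$ and $\omega$
(strong defence costs growth) reshapes the community. Without a trade-off,
coexisting diversity is capped near the burst size $\beta$; with one, the
cap can be exceeded severalfold, and a strain's steady-state biomass is
predicted almost perfectly by the ratio $\gamma'/\omega$ of its effective
growth rate $\gamma' = \gamma(1 - B/C) - \alpha$ to its imperfection.

## Parameters, units and defaults

Time is measured in units of the maximal growth-rate scale, so sampled
$\gamma \in [0, 1]$. Densities are individuals, with defaults

| parameter | default | meaning |
|---|---|---|
| `C` | $10^8$ | carrying capacity; sets the large-population limit |
| `eta` | $10^{-8}$ | adsorption rate, chosen so $\eta C = 1$ |
| `beta` | $100$ | burst size (progeny per lysis) |
| `delta` | $0.1$ | phage decay rate |
| `alpha` | $0.1$ | bacterial dilution rate |
| `T` | $10^4$ | time between strain invasions |
| `ext_threshold` | $1$ | extinction density: one individual |

The equations are invariant under measuring densities in units of `C` (and
$\eta \to \eta C$), so only the combination $\eta C$ matters; the explicit
$C = 10^8$ makes the one-individual extinction threshold concrete. The
closed form most useful for orientation: a lone strain with a perfect RM
system coexists with its phage at $B^\ast = \delta/(\eta(\beta-1))$, about
$1.01 \times 10^5$ individuals at the defaults — phage predation holds
bacteria three orders of magnitude below carrying capacity.

## The open-ecosystem protocol and its two engines

The community is assembled by repeated invasion: at times $T, 2T, \ldots$
every strain below one individual is removed (its phage variant with it;
a variant below threshold is zeroed while its host survives), then one new
$(\gamma, \omega)$ pair drawn from a configurable joint distribution is
introduced at a density of one individual (strain and matching variant),
and the system relaxes for another $T$.

Two engines implement this protocol:

* **`evolve_open_ecosystem()`** integrates the differential equations
  (deSolve's `lsodar` on a compiled right-hand side), stopping each round
  early once the largest relative rate of change falls below `steady_tol`
  (nothing changes between settling and the next invasion).
* **`iterative_evolution()`** replaces each round by its limit outcome:
  a newcomer is admitted iff its invasion fitness
  $f(\gamma, \omega) = \gamma(1 - B/C) - \alpha - \eta\omega P$ is
  positive at the ambient $(B, P)$, after which the coexistence steady
  state is re-solved analytically and newly infeasible residents are
  removed, smallest density first, until the survivor set is
  self-consistent. This is orders of magnitude faster and is exact in the
  limit of large `T`.

On shared invader sequences the two engines agree on the final diversity
and on $B$ and $P$ to many digits, which is the package's central
cross-validation (see the test suite's oracle-equivalence and
engine-agreement checks).

### The analytic steady state

Setting $\dot b_i = 0$ (with $b_i > 0$) gives
$p_i = f(\gamma_i, \omega_i) / (\eta (1 - \omega_i))$; setting
$\dot p_i = 0$ gives $b_i = (\eta B + \delta) p_i / (\beta \gamma_i')$.
Summing the first relation expresses $P$ explicitly in $B$; substituting
into $B = \sum_i b_i$ leaves one scalar equation in $B$, solved by
bracketed root finding on $(0, \min_i C(1 - \alpha/\gamma_i))$ — the
interval on which every effective growth rate is positive and the residual
is continuous. Numerical choices that matter:

* The residual can have several roots. The dynamically stable community
  (verified against long integrations) sits at the **largest root with all
  densities positive**; the scan is log-spaced because roots cluster many
  decades below the interval's upper end. Inside the assembly loop a local
  bracket around the previous $B$ is tried first.
* Strains with $\gamma \le \alpha$ are removed before solving: their
  negative effective growth rate flips the sign of the density formula and
  would corrupt the smallest-density removal ranking.
* When a strain set admits no joint fixed point at all, densities are
  evaluated at the quasi-equilibrium (the $B$ minimising the absolute
  residual) purely to decide which strain to remove next; when even a
  single strain cannot sustain phage, the phage-free logistic branch
  $B = C(1 - \alpha/\gamma_{\max})$, $P = 0$ applies (competitive
  exclusion).
* `prune_to_feasible()` additionally removes survivors whose analytic
  density falls below the extinction threshold, keeping the fast engine
  consistent with the dynamical protocol's culling; `enforce_threshold =
  FALSE` restores the strict $f > 0$ rule.

### Integrating boom-bust transients

A pioneer pair introduced at one individual into an empty system booms to
carrying capacity, triggers a phage explosion, and crashes — in the exact
equations to densities hundreds of orders of magnitude below one
individual, from which the flow later recovers. No floating-point
integration can follow that literally (the solver stalls near the denormal
range, or recovers from its own noise floor, irreproducibly). The
integrator therefore makes the refuge explicit and deterministic:

* the right-hand side evaluates densities clamped at zero, so
  tolerance-level negative excursions cannot feed the logistic term's
  finite-time blow-up;
* a constant influx `imm` ($10^{-6}$ individuals per time unit, six orders
  below the extinction threshold) bounds every density away from the
  denormal range; crashed populations sit near $10^{-7}$ individuals until
  conditions let them regrow, and anything still below one individual at a
  round boundary is culled as usual. For phage variants such regrowth is
  intrinsic to the model anyway (a variant at density zero is recreated by
  cross-infection of its host at rate $\eta \omega \beta b P$). The influx
  perturbs interior steady states (at $10^5$ individuals and more) by less
  than one part in $10^9$; `imm = 0` recovers the unmodified equations,
  backed by a root-function floor that zeroes a density exactly when it
  crosses $10^{-10}$;
* with `stop_at_steady`, a second root function ends the round when the
  largest relative rate of change drops below `steady_tol` ($10^{-8}$ by
  default; densities below one individual are scaled absolutely so strains
  decaying to extinction do not postpone termination).

Two further facts matter for verification work. The interior fixed points
are locally stable but *weakly* damped (slowest eigenvalues of order
$-10^{-3}$), and at the default `rtol` of $10^{-6}$ integration noise can
pump the weak mode indefinitely; comparisons against the analytic solver
should use `rtol` $10^{-9}$ or tighter. And violent starts (all strains at
high density, as in `batch_culture()`) can land on a large, extremely
slowly damping oscillation around the fixed point; the robust readout
there is the **time average** over a tail window, which pins the
fixed-point relations of the bacterial equations and matches the analytic
densities to a fraction of a per cent.

## The strain samplers

All four families share marginal expectations $\langle\gamma\rangle = 0.5$
and $\langle\log_{10}\omega\rangle = -2$ and supports
$\gamma \in [0,1]$, $\omega \in [10^{-4}, 1]$, so correlated and
uncorrelated ecosystems are compared at identical average cost and defence:

* `sample_uncorrelated()`: independent $\gamma \sim U(0,1)$,
  $\log_{10}\omega \sim U(-4, 0)$.
* `sample_correlated_product()`: a single uniform variate `u` sets the
  defence strength, $\log_{10}\omega = -4u$, and modulates the growth
  draw, $\gamma = \mu(u) + (v - \tfrac12)\,\mathrm{wid}(u)$ with
  $\mu(u) = \tfrac12 + k(\tfrac12 - u)$ and
  $\mathrm{wid}(u) = 1 - 2k|u - \tfrac12|$. The construction is
  mean-symmetric, so both normalisation constraints hold *exactly* for
  every steepness $k \in [0, 1]$, the support never leaves the box, and
  the least-squares slope of $\gamma$ on $\log_{10}\omega$ is exactly
  $k/4$. (A one-sided scaled product $\gamma = c\,v\,(1 - ku)$ resampled
  into $[0,1]$ cannot satisfy the mean constraint: any conditional law
  $U(0, \min(1, s(u)))$ has conditional mean at most $\tfrac12$, with
  equality only in the degenerate uncorrelated case — hence the symmetric
  construction.)
* `sample_steepness_scaled()`: the same family with $\gamma$ affinely
  contracted towards $\tfrac12$ until the fitted slope matches a target,
  for studying cheaper RM systems at unchanged correlation structure.
* `sample_truncated_bvn()`: $(\gamma, \log_{10}\omega)$ bivariate normal,
  means $(0.5, -2)$, standard deviations matching the uniform marginals
  ($1/\sqrt{12}$ and $4/\sqrt{12}$), correlation parameter $\rho$,
  truncated to the box. The box is symmetric about the means, so
  truncation preserves them; the realised Pearson correlation is
  attenuated by truncation, which is why the parameter is reported as
  $\rho$ and the realised association is measured with `fit_slope()`.
  $\rho = 1$ degenerates to the exact diagonal
  $\gamma = \tfrac12 + (\log_{10}\omega + 2)/4$.

**Default steepness.** The baseline trade-off `default_steepness() = 0.03`
is calibrated, once, so that the baseline correlated ecosystem assembled
over $10^5$ invasion rounds at the default parameters settles in the
reference high-diversity regime with roughly twice as many coexisting
strains as the burst size ($D/\beta \approx 2$), the regime against which
the package's acceptance checks compare. At this steepness the strongest
RM systems cost their carriers a few per cent of growth rate on average —
the magnitude competition experiments report for efficient RM systems.
Steeper trade-offs pack more diversity ($D/\beta \approx 3$ at $k = 0.1$,
$\approx 4$ at $k = 1/3$); the steepness is a single explicit knob, not a
hidden fit.

## What the simulations do and do not show

The generator emulates a community whose invaders' growth and defence
parameters are drawn from a fixed joint distribution. Real communities
violate several of its assumptions: invaders are not independent draws
(they descend from residents), RM phenotypes are not fixed (methylation
states and RM gene content change on ecological timescales), resources are
not a single logistic substrate, and the deterministic large-population
limit erases demographic noise that matters near the one-individual
threshold. Passing checks therefore validate the *model's* internal
machinery — the equivalence of its analytic and dynamical solvers, the
sampler normalisations, and the qualitative robustness of the
diversity-versus-trade-off phenomenon — not quantitative predictions about
any particular microbial system.

Two honest numerical findings are worth recording. First, with
uncorrelated strain parameters the assembled diversity saturates the
leaky-RM generalisation of the burst-size cap slightly *above* $\beta$
($D/\beta \approx 1.1$–$1.2$ at the defaults, sensitive to the phage decay
rate: $0.8$ at $\delta = 0.5$ up to $1.26$ at $\delta = 0.05$); the cap is
exactly $\beta$ only in the perfect-RM limit. Second, the burst-size bound
written in terms of the biomass-weighted mean imperfection
$S = \sum_i \omega_i b_i / B$,
$$D/\beta \le \frac{1 - S}{1 - \beta S},$$
is a per-variant propagation heuristic: at an exact fixed point only its
biomass-weighted average is pinned, and assembled communities overshoot
the bound by up to a few per cent. `assembly_checks()` reports both the
bound and the (exact) viability partition round by round.

## Reproducing the headline numbers

`scripts/acceptance.R` at the repository root re-runs the package's main
computations from scratch — sampler normalisations on $10^6$ draws, the
closed-form single-strain density by both engines, $10^5$-round assemblies
for the uncorrelated, baseline-correlated and fully correlated samplers,
the fitness-predictor correlations, engine agreement at reduced scale, and
the bound/viability property fractions — and writes them as a flat JSON
report. Problem sizes in the test suite are chosen so the whole suite runs
in well under half an hour on one core: $2 \times 10^5$-draw sampler
checks, $10^5$-round iterative assemblies, a $2 \times 10^3$-round
dynamical assembly for engine agreement, and twenty random 2-10-strain
oracle instances.
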