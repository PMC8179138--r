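---
title: "Thermodynamic profiling of ligand binding with ThermoFEP"
author: "ThermoFEP authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic profiling of ligand binding with ThermoFEP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ThermoFEP)
```

ThermoFEP dissects a relative binding free energy into its enthalpic and
entropic parts and traces the enthalpy to ligand and solvent contributions.
This vignette explains the models behind each stage, the parameters that
matter, what the built-in synthetic systems do and do not emulate, and the
numerical choices made where the design was open. Units throughout:
kcal/mol, Angstrom, Kelvin; the Boltzmann constant is
`r format(kBoltzmann(), digits = 8)` kcal/(mol K).

## Free energy perturbation and the thermodynamic cycle

The Zwanzig (exponential averaging) identity gives the free energy
difference between two Hamiltonians from samples of one:

$$\Delta F = -k_BT \,\ln\!\left\langle e^{-\Delta U / k_BT}\right\rangle_A .$$

A single step between two ligands is far too large for this average to
converge, so the transformation is split over a ladder of intermediate
states with linear coupling $U_\lambda = (1-\lambda)U_A + \lambda U_B$;
`lambdaLadder()` defaults to 84 evenly spaced windows, the intermediate-state
count typical of receptor-scale alchemical transformations. Soft-core
potentials are unnecessary here because no atoms vanish in the toy systems;
the coupling scheme is a package choice, stated rather than inherited.

Numerical points:

* the exponential average is evaluated with a log-sum-exp shift, so large
  positive $\Delta U$ cannot overflow;
* each window's standard error comes from block averaging with 10 blocks —
  a per-window diagnostic; production errors should come from independent
  replicates (`combineReplicates()`, three by default), which is also how
  `cycleCombine()` propagates errors when both legs carry replicates
  (mean and SEM of per-replicate differences);
* an overlap diagnostic reports the fraction of exponential weight carried
  by the top 5% of frames and warns above 50% — the signature of windows
  spaced too far apart.

The relative binding free energy is the difference of the alchemical legs
run in the bound and the unbound environment,
$\Delta\Delta G = \Delta G_{bound} - \Delta G_{unbound}$. Only the Zwanzig
estimator is provided; bridge-type estimators (BAR/MBAR) are out of scope by
design.

The validation system is a harmonic mutation $U_X = k_X|x - c_X|^2/2$, whose
transformation free energy is exact:
$\Delta F = (d\,k_BT/2)\ln(k_B/k_A)$, independent of the centers. For
$k: 1 \to 2$ at 300 K this is 0.2066 kcal/mol. The tests verify the
closed form against numerical quadrature of the two partition functions
before using it as the oracle, and require the 84-window estimate to agree
within three standard errors, forward and reverse.

## Computational van't Hoff analysis

With $\Delta G(T)$ measured at several temperatures,

$$\frac{\Delta G}{T} = \Delta H \cdot \frac{1}{T} - \Delta S$$

is a straight line when $\Delta C_p \approx 0$ over the range: the slope of
an ordinary least squares fit of $\Delta G/T$ on $1/T$ is
$\Delta\Delta H$, minus the intercept is $\Delta\Delta S$, and
$-T_{ref}\Delta\Delta S$ is reported at a 300 K reference. The default
temperature set is 280–315 K in 5 K steps — eight temperatures spanning a
range narrow enough for the linear model yet wide enough to condition the
slope. The fit is unweighted and uses replicate means; replicate scatter
feeds the bootstrap instead. These are package choices where the procedure
was genuinely open.

Uncertainty is the delicate part: the slope amplifies free energy noise by
roughly the inverse spread of $1/T$, so per-temperature noise of
0.2 kcal/mol becomes enthalpy noise of order 1 kcal/mol. `bootstrapProfile()`
resamples replicates within each temperature and reports percentile
intervals with two standard small-sample calibrations: resampled group means
are inflated by $\sqrt{n/(n-1)}$ (the bootstrap variance of a mean of $n$
values underestimates the sampling variance by $(n-1)/n$), and the interval
reads the bootstrap distribution at expanded t-quantile levels
(df $= \sum_g (n_g - 1)$) rather than 2.5/97.5%. Without these, intervals
from the typical three replicates per temperature undercover badly
(measured ~80% for a nominal 95%); with them, measured coverage over 400
independent synthetic tables is 94%. A single replicate per temperature
falls back to regression standard errors with a warning.

Exactness checks: a noiseless synthetic table is recovered to machine
precision, and the analytic harmonic free energy — purely entropic,
$\Delta F(T) \propto T$ — yields $\Delta\Delta H = 0$ exactly.

## Enthalpy decomposition

Neglecting the pressure–volume term, the relative binding enthalpy splits as
$\Delta\Delta H \approx \Delta\Delta U_L + \Delta\Delta U_S$. The ligand
term $\Delta\Delta U_L$ is computable by direct averaging over end-state
trajectories and itself decomposes into receptor–ligand interaction energy,
ligand internal (strain) energy — the bound-minus-unbound difference of the
intramolecular terms, so that solvent and receptor internal energies stay
with the surroundings — and desolvation, defined as the bound-state minus
unbound-state ligand–water interaction energy difference. The surroundings
term cannot be converged by direct averaging (it sums over every
solvent/receptor interaction), so it is obtained indirectly:
$\Delta\Delta U_S = \Delta\Delta H - \Delta\Delta U_L$, with errors added in
quadrature.

Two identities are enforced to $10^{-9}$ on every object: desolvation equals
the bound/unbound ligand–water difference, and $\Delta\Delta U_L$ equals the
sum of its three parts. Profile additivity
($\Delta\Delta G = \Delta\Delta H - T\Delta\Delta S$) is *not* an identity —
the free energy is measured independently — so `assembleProfile()` reports
the discrepancy and flags it when it exceeds the combined SEM.

The end-to-end conservation check runs the whole chain on the host–guest
benchmark: $\Delta\Delta H$ from van't Hoff over FEP at eight temperatures,
$\Delta\Delta U_L$ from tagged end-state averages, and their sum compared to
the directly measured total mean potential-energy difference between end
states. Agreement is required within three combined standard errors; the
residual systematic error is the (small) $\Delta C_p$ of the toy system over
the 35 K window.

## Hydration-site analysis

Water positions from all frames are pooled and clustered greedily: the
position whose 1.0 Å neighbourhood contains the most observations becomes a
site center, its observations are claimed, and the process repeats until the
best candidate's occupancy falls below 0.5 — site radius and occupancy
threshold following common hydration-site practice, both configurable.
Count ties are broken by the lexicographically smallest coordinate, a
deterministic rule that also makes the recovered centers invariant to frame
order.

Per site and averaged over occupied frames, `siteEnergies()` reports the
site water's total pair energy with all other waters ($E_{ww}$) and with the
solute ($E_{sw}$). The full pair energy is assigned to the site water — no
1/2 factor — a convention that differs between published implementations and
is therefore stated explicitly.

`siteEntropy()` estimates translational and orientational entropies relative
to bulk with k = 1 nearest-neighbour (Kozachenko–Leonenko) estimators
carrying the Euler–gamma log-correction: positions against a uniform fluid
at the stated bulk density, orientations on the unit sphere (geodesic
nearest-neighbour angles) against the uniform distribution with entropy
$\ln 4\pi$. Referencing to bulk cancels the estimator's additive constant;
both entropies are clamped at zero from above, since site ordering can only
reduce them. Closed forms serve as oracles: an isotropic Gaussian site of
spread $\sigma$ has $S_{trans}/k_B = \tfrac{3}{2}\ln(2\pi e\sigma^2) +
\ln\rho_{bulk}$, and a von Mises–Fisher orientation distribution of
concentration $\kappa$ has a known entropy deficit against $\ln 4\pi$.

`compareNetworks()` matches sites across two complexes one-to-one by
greedy closest-center pairing within 1.5 Å (the pairing rule and radius are
package choices); reference-network sites with no partner are flagged
displaced and contribute the loss of their full energies to the totals.
The water–water / solute–water split is additive by construction:
$\Delta E_{total} = \Delta E_{ww} + \Delta E_{pw}$ exactly.

## The synthetic systems: what they emulate, and what they do not

`generateWaterNetwork()` plants hydration sites with specified centers,
Gaussian positional spread, von Mises–Fisher orientational concentration and
Bernoulli occupancy over a uniform bulk background in a sphere — ground
truth for clustering recovery, occupancy calibration (binomial), and both
entropy estimators. The planted configurations are geometric, not
Boltzmann-sampled: waters may overlap, so pair *energies* on planted
networks are not meaningful, and the energy operations are validated instead
on fixed configurations (direct potential evaluation) and on sampled
host–guest trajectories. This is the main thing passing tests do *not* show:
estimator behaviour on correlated, physically packed solvent is only probed
by the host–guest system, which is itself far smaller than any receptor.

The host–guest benchmark is four fixed host particles forming a shallow
pocket, a two-particle bonded guest, and a dozen orientable single-site
pseudo-waters (Lennard-Jones plus a point-dipole term
$-\mu_i\mu_j(\hat u_i\!\cdot\!\hat u_j)/r^3$; solute dipoles couple to the
water dipole along the separation axis) in a 7 Å sphere with reflecting
boundaries. The A-to-B transformation deepens the guest's dispersion well,
strengthens its dipole and stretches its bond, shifting receptor–ligand,
ligand–water and strain energies at once. The bound-leg guest is held by a
soft positional restraint (10 kcal mol⁻¹ Å⁻², the analogue of restraining
heavy atoms to crystal coordinates); the restraint is independent of
$\lambda$ and cancels exactly in every perturbation energy. A
single-site water with one dipole vector was chosen over a rigid 3-site
model to keep every energy term analytically checkable by brute force.

Problem sizes used by the tests and the acceptance script are deliberate
package choices balancing estimator noise against runtime: 84 windows with
$10^5$ Metropolis steps for the harmonic ladder, 12 windows with 5000 sweeps
and 3 replicates per temperature for the host–guest cycle, $2\times10^4$
sweeps for end-state averages, $10^4$ frames for planted-network recovery,
and 100 seeded tables with 500–1000 bootstrap draws for coverage. At these
sizes the harmonic estimate lands within ~1 SEM of the closed form and the
conservation gap sits well inside its three-SEM band.

## Degenerate inputs and edge behaviour

Constant $\Delta U = c$ gives $\Delta F = c$ with zero SEM; identical end
states give identically zero series. Fewer than 10 retained frames, fewer
than 100 clustering frames, or fewer than 20 occupied frames for entropies
warn rather than fail. Fewer than three distinct temperatures, non-finite
energies, non-positive temperatures or $K_i$, percent-inhibition records
(which carry no free energy), mismatched leg temperatures, and unresolvable
config paths are errors raised before computation. Coincident water
positions contribute no log-distance information and are excluded from the
nearest-neighbour average rather than producing $-\infty$.

## Known limitations

* The Zwanzig estimator is one-directional; no bridge estimator cross-check
  is available in-package.
* The van't Hoff model assumes $\Delta C_p = 0$ across the temperature
  window; curvature shows up as enthalpy bias, not as a diagnostic.
* Nearest-neighbour entropies use k = 1 only, and the orientational
  estimator treats the sphere locally as flat — fine at the concentrations
  tested, biased for extremely peaked distributions.
* Hydration-site occupancy over a bulk background picks up a small positive
  bias (bulk waters wandering through a site's radius), visible only below
  the binomial noise floor at the tested densities.
* The toy systems share no force field with any production simulation; they
  validate estimators, not chemistry.
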