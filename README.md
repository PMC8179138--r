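# ThermoFEP

Thermodynamic profiling of ligand binding: alchemical free energy
perturbation, computational van't Hoff analysis, enthalpy decomposition and
hydration-site thermodynamics in one tested R package.

## The problem

Small chemical changes to a ligand can change its binding affinity by orders
of magnitude (an *activity cliff*), and the free energy difference alone says
little about why. The mechanism lives in the enthalpy/entropy split: does the
modified ligand bind tighter because it interacts better with the receptor,
because it pays less desolvation penalty, or because it reorganizes the
ordered water network in the binding site? ThermoFEP implements the
simulation-side analysis chain that answers this, for computational chemists
who already have (or can generate) per-window perturbation energies and
water trajectories:

1. **FEP / thermodynamic cycle** — per-window free energies by the Zwanzig
   (exponential averaging) estimator,

   ΔF = −k\_BT ln ⟨exp(−ΔU/k\_BT)⟩,

   accumulated along a ladder of intermediate states (84 windows by default)
   and combined across bound and unbound legs into a relative binding free
   energy ΔΔG = ΔG\_bound − ΔG\_unbound, with replicate statistics.
2. **Computational van't Hoff analysis** — ΔΔH and ΔΔS from the slope and
   intercept of an ordinary least squares regression of ΔG/T on 1/T over
   free energies computed at several temperatures (eight by default,
   280–315 K), with calibrated bootstrap confidence intervals.
3. **Enthalpy decomposition** — the ligand term ΔΔU\_L (receptor–ligand,
   ligand internal/strain, and desolvation from bound/unbound ligand–water
   energies) from trajectory averages, and the surroundings term obtained
   indirectly as ΔΔU\_S ≈ ΔΔH − ΔΔU\_L.
4. **Hydration-site analysis** — greedy density clustering of water
   positions across frames into sites; per-site occupancy, water–water and
   solute–water interaction energies, nearest-neighbour translational and
   orientational entropies relative to bulk (inhomogeneous solvation theory
   style), and one-to-one matching of sites across complexes with displaced
   sites flagged.
5. **Affinity conversion** — K\_i to standard-state binding free energy,
   ΔG = RT ln(K\_i / 1 M).

Because receptor-scale trajectories cannot ship with a package, every stage
is validated against analytically solvable synthetic systems built in: a
harmonic-oscillator mutation sampled by Metropolis Monte Carlo (closed-form
ΔF, ΔΔH = 0), a host–guest toy system with orientable pseudo-waters
(brute-force checkable energies, end-to-end enthalpy conservation), planted
hydration networks (known site centers, occupancies, spreads and
orientational concentrations) and exact-line van't Hoff tables.

## Worked example

```r
library(ThermoFEP)

## harmonic mutation k: 1 -> 2 kcal/(mol A^2) at 300 K, 84 windows
spec <- harmonicSpec(1, forceConstantA = 1, forceConstantB = 2)
leg  <- fepLeg(spec, "bound", lambdaLadder(84), nSteps = 1e5, seed = 42)
legDG(leg)                 # 0.206366  (analytic (kBT/2) ln 2 = 0.2066137)
leg@legSEM                 # 0.0003009

## van't Hoff on a replicated synthetic table
tab  <- generateVantHoffTable(syntheticVantHoffSpec(
          deltaH = -11.6, deltaS = -0.016, noiseSD = 0, seed = 1))
prof <- fitVantHoff(tab, Tref = 300)
ddH(prof)                  # -11.6 kcal/mol   (slope)
minusTddS(prof)            #   4.8 kcal/mol   (-300 K * ddS)

## enthalpy decomposition from measured component energies
comp <- ligandEnergyComponents(-3.6, -1.7, 1.0, 6.5)
comp@desolvation           # -5.5  (bound minus unbound ligand-water)
comp@ddUL                  # -10.8
surroundingsEnergy(-11.6, comp@ddUL)@ddUS   # -0.8 kcal/mol

## affinity conversion
ddgFromKi(affinityRecord("A", 45e-9), affinityRecord("B", 39e-6))  # -4.008
```

The numbers shown are what the code prints: the FEP estimate agrees with the
closed-form harmonic free energy within one standard error, the noiseless
van't Hoff fit is exact, and the decomposition identities hold to 1e-9.

A full pipeline driver is available through a YAML configuration
(`readRunConfig()` / `runPipeline()`); it writes a `results.json` with the
config hash and all seeds embedded, plus a human-readable report restating
the leg-sum, enthalpy-split and profile-additivity identities with
pass/fail flags.

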