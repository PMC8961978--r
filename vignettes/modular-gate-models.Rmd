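---
title: "Modular NOT-gate models: composition scheme, kinetics and numerics"
author: "circomp authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular NOT-gate models: composition scheme, kinetics and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circomp)
```

## The modeling problem

Synthetic gene circuits in yeast are naturally modular: each transcription
unit (promoter + coding sequence + terminator) makes one mRNA, each mRNA is
translated in a cytoplasmic pool, and shared machinery (a protease pool,
polymerases, ribosomes) serves several units at once. `circomp` models each
of these modules as an independent submodel with its own species and
reactions, and wires modules together the way the SBML Level 3 hierarchical
composition (`comp`) package does:

* a submodel exposes a species through a **port** named `port_<speciesId>`;
* two ports are never linked directly — a third copy of the species, the
  **connecting (helper) species**, is instantiated in the cell model;
* the helper carries one **replaced-by** link to the port of the submodel
  that produces the species, and one **replaced-element** link per
  consuming submodel's port;
* machinery species that no submodel produces (RNA polymerase II `PolII`,
  ribosomes `rib`, a hormone input `e`) live only in the cell model and
  carry replaced-element links only.

Hierarchy depth is fixed at one (cell → submodels): nested submodels are
not supported, which keeps flattening and validation trivially complete.
A circuit serializes to one XML file per submodel plus a main `cell.xml`
holding the external model definitions, the helper species and their
replacement links; `flattenCircuit()` resolves the hierarchy into a single
network in which every connected species occurs exactly once, carrying the
cell copy's identity, compartment and initial amount.

## The two case-study gates

Both catalog circuits are Boolean NOT gates built on the bacterial ClpXP
protease, which is orthogonal to the yeast proteome: ClpX recognizes the
ssrA degron on the fluorescent reporter, unfolds it, and feeds it into ClpP
for fast proteolysis. The reporter is expressed constitutively; the gate
input switches ClpX expression on, so output is high exactly when the input
is absent.

`buildGalactoseNotGate()` has 7 modules — three nuclear transcription units
(reporter, ClpP, ClpX), three cytoplasmic mRNA pools, one degradation pool
— six producer-linked helper species (three mRNAs, three proteins) and two
producer-less machinery species (`PolII` feeding the units, `rib` feeding
the pools). Galactose is **not** a species: its presence is a toggle on the
pGAL1 transcription-initiation rate inside `TU_ClpX` (`setGalactose()`),
with a basal:induced ratio defaulting to 1:100.

`buildEstradiolNotGate()` has 9 modules: a fourth transcription unit
expresses the chimeric activator LHV
(LexA DNA-binding domain — human estrogen-receptor hormone-binding domain —
VP64 activation domain). The hormone `e` is a constant cytoplasmic boundary
species consumed by `pool_mRNA_LHV`, where the single irreversible step
`LHV + e -> LHVe` lumps hormone binding and nuclear import; `LHVe` is the
one nuclear connecting species and activates ClpX transcription in
`TU_ClpX` through a non-cooperative Hill term. Every reaction touching
`LHVe` lives in those two modules. In this gate polymerases and ribosomes
are neglected — their constant Hill occupancies are folded into the
constitutive rates — so there are 9 connecting species, 8 cytoplasmic and 1
nuclear. Hsp90 sequestration of LHV is the biological mechanism keeping the
activator cytoplasmic without hormone, but it is not a model component:
absence of hormone simply yields no LHVe.

## Kinetics

Two rate forms cover every reaction:

* **mass action**, rate $k\prod_i x_i^{s_i}$ with total molecularity at
  most two (zero-order synthesis, first-order decay/dilution, bimolecular
  binding);
* **Hill activation without cooperativity**,
  $v = \left(k_\mathrm{basal} + k\,\frac{A}{K+A}\right)
  \cdot \left[\frac{A_2}{K_2+A_2}\right] \cdot [S]$,
  where $A$ is the activator (a transcription factor, `PolII`, or `rib`),
  the optional second Hill factor serves promoters depending on both an
  activator and polymerase, and the optional linear factor $S$ is the
  template of a translation reaction (the mRNA is a modifier, never
  consumed). The Hill coefficient is structurally fixed at $n = 1$; the
  slot exists as a documented extension point but any other value is
  rejected.

The $k_\mathrm{basal}$ term exists because the uninduced ClpX promoter is
leaky, not silent: an activated promoter still initiates at a small basal
rate. The Hill argument is the *total* (constant) polymerase/ribosome
amount, consistent with these being fixed boundary species — free-machinery
bookkeeping is deliberately out of scope.

The degradation pool implements, as reactions:
dimerization ClpP + ClpX ⇌ ClpXP (stored as a forward/backward pair of
irreversible reactions; the `reversible` flag is pure metadata),
irreversible target binding ClpXP + GFP → ClpXP_GFP, proteolysis
ClpXP_GFP → ClpXP (the protease acts catalytically; released peptides are
not tracked), and first-order dilution of both complexes by growth. Only
the target binding is stated to be irreversible by the underlying biology;
dimerization is modeled reversibly as the conservative choice, with the
backward rate exposed (set it to 0 for the irreversible variant, and the
dilution rate to 0 for a minimal model).

## Parameters

Units are molecule counts and seconds throughout; compartment sizes default
to 1 (dimensionless) because no volumes are specified anywhere in the
system being modeled. Defaults are order-of-magnitude choices for yeast,
set once and exposed via `galactoseDefaults()` / `estradiolDefaults()`:

| parameter | default | rationale |
|---|---|---|
| transcription initiation | 0.02–0.05 mRNA/s | weak reporter vs. strong constitutive promoter |
| pGAL1 induced : basal | 0.05 : 5e-4 /s | leaky inducible promoter, 1:100 |
| translation initiation | 0.05 /mRNA/s | times ribosome occupancy where modeled |
| mRNA decay | ln2/1200 /s | 20-min half-life |
| protein decay | ln2/7200 /s | 2-h half-life |
| PolII, K(PolII) | 100, 50 | occupancy ≈ 2/3 |
| rib, K(rib) | 1000, 500 | occupancy ≈ 2/3 |
| dimerization f/r | 1e-3 /molecule/s, 1e-3 /s | mid-range bimolecular binding |
| target binding | 1e-3 /molecule/s | irreversible capture |
| proteolysis | 0.1 /s | fast degradation |
| complex dilution | 1e-4 /s | growth dilution, near protein decay |
| hormone binding | 1e-4 /molecule/s | lumped binding + import |
| saturating hormone | 2000 molecules | deep saturation of the activator |

With these defaults, both circuits already behave as NOT gates
(ratio well above the functional threshold of 2) before any optimization;
the optimizer then explores the documented bounds in
`gateAnalysisSpec()` — transcription 1e-4–0.2, binding rates 1e-5–1e-2
(hormone binding down to 1e-6), proteolysis 1e-3–1, reporter decay
1e-5–1e-3 — which is how the reported optimized ratios are obtained.

## Numerics

* **ODE assembly.** $\dot{x} = S\,r(x)$ from the stoichiometry matrix and
  per-reaction rate closures; constant species get zero derivatives. State
  is clipped at 0 before rate evaluation so integrator undershoot cannot
  produce negative rates; reported trajectories clip undershoot (bounded by
  1e-9) to zero.
* **Integration.** `deSolve::lsoda` (stiff-capable, deterministic).
* **Steady states** are found by integrating in doubling time windows
  (initial window 2e5 s, matching the slowest default timescale) until the
  largest per-second relative state change falls below `tolRel`
  (default 1e-8), then polished by damped Newton iterations on the
  right-hand side over the non-constant species with a finite-difference
  Jacobian. The polish is accepted only if it reduces the residual below
  the convergence threshold, so closed-form comparisons in the test suite
  are limited by arithmetic rather than by integration depth. Steady-state
  search by long integration was chosen over root-finding from scratch
  because the degradation kinetics are stiff and multiple nonphysical roots
  exist at negative amounts; Newton is only ever started from an already
  nearly-converged trajectory point.
* **ON/OFF ratio** = steady-state reporter at input-absent divided by
  input-present; a zero denominator reports an infinite ratio with a
  warning.
* **Optimization** is seeded random multi-start (first start: the current
  parameterization clipped into bounds; further starts uniform in
  log-bound space) with L-BFGS-B refinement on $\log_{10}$ parameters,
  bounded, objective $-\log(\text{ratio})$ or
  $(\log \text{ratio} - \log r^*)^2$. Identical seeds give identical
  results; returned parameters never leave the bounds.

## Serialization choices

SBML Level 3 Version 1 with comp Version 1; substance units are items
(molecule counts) with `hasOnlySubstanceUnits="true"`. Replacement links
are attached to the cell-level species elements and reference remote ports
via `portRef`; the reader also accepts replacements placed on submodel
elements. External model definitions use relative paths (`<id>.xml`) so a
circuit directory is portable. Kinetic laws are written as standard MathML;
alongside it, a small tool-namespace annotation records the law structure,
the submodel kind and species roles, making round trips field-exact.
Foreign files without the annotation are read tolerantly: module kinds are
inferred from id conventions, roles from ports and net stoichiometry, and
bare-`k` local parameters as mass action; constructs outside the supported
subset (rules, events, function definitions, nested hierarchies) are
reported as warnings rather than silently dropped. Schema validation
against the SBML XSDs is not performed; well-formedness plus full
structural round-trip identity stand in for it.

## What the catalog circuits do and do not emulate

The catalog circuits *are* the study conditions: module inventories,
wiring, compartment assignments and input mechanisms match the two
experimental gates, and the counting utilities expose both per-file and
unique-species conventions so published totals can be checked against
model files under either. They do **not** emulate cell-to-cell
variability, fluorescence calibration, maturation of the reporter,
stochasticity at low copy number, the galactose regulon upstream of pGAL1,
or Hsp90 titration — so passing tests demonstrate correctness of the
composition, flattening and deterministic kinetics, not quantitative
agreement with flow-cytometry distributions. Measured quantities
(experimental ON/OFF ratios, promoter-strength fold changes) are outside
the model's reach and are deliberately not computed anywhere in the
package.

## Problem sizes used by the test suite

The suite exercises flat models of 2–16 species. Gate steady states solve
in well under a second; the 10-point input sweeps use exact steady states
per point. The optimizer runs used in tests and in
`scripts/acceptance.R` use 2 starts and an iteration cap of 8 on 5–6 free
parameters — enough for the monotone-dominated objectives here, where the
optimum sits on the bound of the most sensitive parameters.

## Known limitations

* One hierarchy level; no comp deletions, no port references to reactions
  or parameters.
* Mass action is capped at molecularity two; no Michaelis–Menten or
  stochastic propensity forms.
* The flattener targets the subset this package emits (plus tolerant
  reading); it is not a general-purpose comp flattener for arbitrary
  third-party SBML.
* Steady-state detection assumes the circuit settles; systems with
  sustained growth (zero decay everywhere) correctly error out of the
  search instead of returning a pseudo-steady state.
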