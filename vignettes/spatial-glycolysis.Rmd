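---
title: "Spatial agent-based simulation of glycolysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial agent-based simulation of glycolysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abmetab)
```

## The model

`abmetab` simulates a metabolic pathway as a population of autonomous
molecular agents in a cubic portion of cytoplasm. Every molecule — enzyme,
metabolite or enzyme–substrate complex — is a hard sphere that diffuses by
Brownian motion and, if it is an enzyme or a complex, can *perceive* and bind
cognate metabolites in its neighbourhood. The global behaviour of the pathway
(concentration changes, depletion, oscillations) is not prescribed by rate
equations; it emerges from these local interactions.

The default environment is a cube of side 1000 Å (one attolitre) with
reflecting walls, at $T = 298.15$ K and viscosity $\eta = 0.0011$ Pa·s,
advanced in ticks of $\Delta t = 10^{-4}$ s.

### Geometry and diffusion

A molecule of weight $M$ (g/mol) becomes a sphere of radius

$$ r = \left( \frac{3\,\bar v\, M}{4 \pi N_A} \right)^{1/3}, $$

with $\bar v = 0.73$ cm³/g, the standard partial specific volume of globular
proteins. We apply the same rule to metabolites: every molecule is a sphere
derived from its weight, which produces realistic crowding with a single
parameter. Its diffusion coefficient follows Stokes–Einstein,

$$ D = \frac{k_B T}{6 \pi \eta r}, $$

and each tick the molecule moves by a **fixed step modulus**
$L = \sqrt{2 D \Delta t}$ in an isotropic random direction
($\cos\theta \sim U[-1,1]$, $\phi \sim U[0, 2\pi)$). Using the
one-dimensional mean-squared-displacement form as a three-dimensional step
modulus is a deliberate fidelity choice; `msd = "3d"` switches to
$\sqrt{6 D \Delta t}$ and `gaussian_steps = TRUE` replaces the fixed modulus
by an isotropic Gaussian displacement with the same MSD, for sensitivity
studies. The `free_diffusion_msd()` harness verifies that the empirical MSD
of this walk is $2 D t$ to within statistical error.

With these defaults a small metabolite (a ~4 Å sphere) has a per-tick step of
roughly 3000 Å — longer than the box. Steps are folded back by repeated
specular reflection at the walls, which preserves the per-tick displacement
statistics and keeps the cost of a move O(1); an alternative would be to
sub-divide ticks into collision-checked sub-steps, which we document but do
not use by default. A consequence worth keeping in mind is that metabolite
positions decorrelate essentially completely between ticks, so the system is
closer to well-mixed per tick than a continuous-time Brownian picture would
be.

A monitor guarantees that no move ends inside another sphere: a proposed move
that lands on an occupied spot is re-aimed in a fresh random direction up to
`k_retries = 5` times, after which the agent stays put for that tick.
Touching spheres are legal; overlap means strictly smaller centre distance
than the radius sum. Agents are updated sequentially in a fresh random
permutation per phase per tick, which removes systematic first-mover bias
while keeping runs exactly reproducible per seed.

### Perception and binding

Each enzyme projects a perception sphere of radius $r + d$, where $d$ is the
**perception distance** — the simulator's abstraction of interaction range.
Three regimes are of interest: $d = 5$ Å (van der Waals-like contact forces),
$d = 10$ Å (electromagnetic forces capped by Debye screening) and
$d = 300$ Å (long-range electrodynamic forces between resonant oscillating
dipoles). One perception distance applies to the whole simulation.

A cognate metabolite at surface-to-surface separation $s \le d$ is bound with
probability $p(s)$. The default law is

$$ p(s) = \begin{cases} 1 & s \le 5\,\text{Å} \\ (5/s)^3 & s > 5\,\text{Å},
\end{cases} $$

truncated to zero beyond $d$: certainty of binding at contact range, and a
cubic decay that mirrors the $1/r^3$ shape of a resonant long-range
potential. The law is pluggable (`uniform` and `inv_six` alternatives ship
with the package) and the choice matters: any law with certainty at contact
keeps the contact regime reactive at a non-negligible rate, see *Known
limitations*.

Candidates are tried in uniformly random order (`mode = "random"`); the
optional `"specificity"` mode sorts them by the specificity constant
$k_{cat}/K_m$ first and requires $K_m$ values in the model.

### The reaction automaton

Binding creates a complex — a new agent at the enzyme's position whose radius
follows volume additivity, $r_c = (r_e^3 + \sum_i r_i^3)^{1/3}$, and whose
mobility is recomputed from that radius. A complex that still misses
substrates keeps moving and perceiving; the first bound metabolite fixes the
direction of a reversible reaction. Once the full substrate multiset of the
chosen direction is bound, the complex is saturated: it waits
$\max(1, \operatorname{round}((1/k_{cat})/\Delta t))$ ticks — the reciprocal
of the turnover number — and then releases the products at collision-free
positions adjacent to the enzyme surface (random directions on an expanding
shell; if the neighbourhood is packed the release is deferred one tick).
The enzyme returns free at its position. Saturated complexes are stationary
during the wait; partial complexes move like every other molecule.

Dissociation of partial complexes is **off by default**: a complex that
cannot find its remaining substrates keeps them sequestered indefinitely,
which is what produces the stalled partial-complex signature in contact-range
runs. An optional `unbind_timeout` (ticks) releases long-lived partial
complexes for exploratory runs.

Each tick runs three phases in order — move, perceive-and-bind (at most one
bind per enzyme per tick), then wait/release — followed by snapshot
recording. A single seeded RNG stream drives every draw, so identical
(model, config, seed) inputs give byte-identical trajectories.

## Model input and adaptation

Models enter either from SBML (species, initial concentrations, reactions,
modifiers as catalysts, `kcat` kinetic-law parameters — rate-law mathematics
is deliberately ignored) or from a versioned, human-readable native XML/YAML
format. Molecular weights are not part of SBML and online retrieval would
make builds network-dependent, so weights ship as a bundled table with an
override hook.

Converting a kinetic model to agent-based form applies three adaptations:

1. **Exclusions.** Bulk reactions without an explicit catalyst pool
   (adenylate kinase, ATPase, the UDP→UTP conversion, glucose transport) and
   the fermentation steps (pyruvate decarboxylases, alcohol dehydrogenases)
   are removed; pyruvate is the end product of interest. Orphaned metabolites
   are pruned with a log line.
2. **Irreversibility.** The three control points of glycolysis —
   hexokinase/glucokinase, phosphofructokinase, pyruvate kinase — are forced
   irreversible, in line with most of the literature.
3. **Concentration scaling.** Initial concentrations are scaled below
   1 mmol/l so the agent population stays computationally tractable. Purely
   proportional scaling would erase the rarest species (e.g. a species at
   0.0007 mmol/l rounds to zero particles in an attolitre), so the map is
   proportional scaling followed by flooring any positive species to the
   concentration of exactly one particle. The map is monotone, so the
   concentration ordering of species is preserved, and no positive species
   disappears.

Counts follow from concentrations as
$n = \operatorname{round}(c \cdot 10^{-3} N_A V)$; at $V = 10^{-18}$ l,
1 mmol/l is 602 molecules.

## The bundled glycolysis network

`glycolysis_model()` encodes the adapted yeast glycolysis: the main branch
GLC → G6P → F6P → F16bP → DHAP/GAP → BPG → 3PG → 2PG → PEP → PYR with one
reaction per isoenzyme (HXK1/HXK2/GLK1, TDH1/2/3, ENO1/2, …), plus the
glycerol branch (DHAP + NADH → G3P → glycerol), the trehalose branch
(G6P ↔ G1P → UDPG → T6P → trehalose) and glycogen synthesis from UDPG.
Three initial concentrations are published values and enter verbatim:
pyruvate 0.2, trehalose 0.015 and NADH 0.086 mmol/l. Every other initial
concentration, enzyme copy number and turnover number is a documented
order-of-magnitude approximation (flagged `approx = TRUE`, kcat in the
10–10³ s⁻¹ range typical of glycolytic enzymes), chosen once and overridable
from a user-supplied table. At full scale the fixture instantiates ~3500
molecules — thousands of agents, with sub-percent excluded volume.

`scale` multiplies all counts (floor one particle per non-zero species) for
desk-scale work. The package's own test battery runs the network at
`scale = 0.2` (~700 agents) for 0.2 simulated seconds, which is where the
regime comparison below is evaluated; full-scale 1-second runs are a matter
of hours on one CPU, not of days, but are deliberately not part of the test
suite.

## What the tests do and do not show

The test battery checks the simulator against independent oracles:
direct-evaluation physics formulas (to 1e-12), the $2Dt$ MSD law for free
diffusion, brute-force neighbour scans, an exact integer conservation ledger
over fuzzed random pathways, and the Michaelis–Menten $V_{max}$ limit — one
enzyme with saturating substrate and non-limiting binding produces products
at $k_{cat}$ within 10%.

On the glycolysis fixture the desk-scale regime comparison reproduces the
qualitative physics: mean glucose consumption orders as
300 Å > 10 Å > 5 Å over seed replicates, the contact regime keeps
hexokinase-family complexes continuously present, and ATP retention is
highest in the contact regime. These are emergent outcomes of the binding
geometry, not assertions wired into the engine.

What desk scale does **not** show: absolute end-point concentrations and
depletion times of second-long full-scale runs, and clean oscillation
spectra — at ~40 recorded samples the F16bP periodogram peak is a coarse
quantity. The observables (`depletion_time()`, `dominant_frequency()`,
`synchrony()`) are exact, pure functions of the recorded series; their
defaults (linear detrending, rectangular window, peak significance at 4x the
median periodogram power) are documented choices.

## Numerical choices and degenerate inputs

* Wait times round to the nearest tick with a floor of one tick, so
  $k_{cat} > 1/\Delta t$ still costs one tick per turnover.
* Reversible reactions reuse the forward kcat for the reverse direction
  unless the model provides `kcat_reverse`.
* Complexes whose release finds no free space defer by one tick and retry;
  the deferral count is reported in the series metadata.
* An enzyme catalysing several reactions chooses uniformly among the
  reactions its first-bound metabolite is compatible with (the glycolysis
  fixture has none of these after isoenzyme splitting).
* Zero-duration runs return only the initial snapshot; models with zero
  reactions simulate as pure diffusion; empty candidate sets, zero-radius
  queries and zero-length steps are all well-defined no-ops.
* Boundary handling is reflecting by default — the box is a portion of
  cytoplasm, not a torus, and reflection conserves molecule number without
  teleporting cognate partners; periodic boundaries are available in the
  spatial primitives for comparison.

## Known limitations

* **The contact-regime stall is comparative, not absolute.** With the
  default binding law (certainty at ≤ 5 Å) and per-tick position
  decorrelation, contact encounters remain frequent enough that ATP is
  consumed at a reduced but non-zero rate at $d = 5$ Å. The package
  therefore states the stall signature as persistent partial hexokinase
  complexes plus *maximal* ATP retention relative to the 10 Å and 300 Å
  regimes, rather than a strictly flat ATP curve. A binding law with a
  lower contact plateau, or sub-stepped movement, would sharpen the stall.
* Step folding preserves displacement statistics but lets fast metabolites
  cross the whole box within a tick; collision checks apply only at the
  landing position.
* No hydrodynamic interactions, no anisotropic shapes, no
  crowding-corrected viscosity, no allosteric regulation, no glucose
  transport, and no mixed perception distances within one run.
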