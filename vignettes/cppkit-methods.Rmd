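---
title: "Staged steered-pulling free energies and membrane-disruption metrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged steered-pulling free energies and membrane-disruption metrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cppkit)
```

## Scope

Cell-penetrating peptides (CPPs) cross lipid bilayers against free-energy
barriers far too high to sample with unbiased molecular dynamics. A
practical protocol steers the peptide across the membrane normal in
stages, estimates the potential of mean force (PMF) from the
nonequilibrium work of many replicas per stage, and then relaxes the
system to see whether the peptide stays in the lower leaflet, forms a
water pore, remains inserted, or returns. `cppkit` implements the
analysis side of that protocol — stage planning, Jarzynski free-energy
estimation with representative-replica hand-off, and the bilayer
disruption metrics — together with synthetic-data generators whose ground
truth is known exactly, so every estimator can be validated end to end.

The package deliberately does **not** attempt to reproduce absolute PMF
barriers or pore radii of real all-atom membrane simulations: those
require microseconds of solvated MD. Everything here runs at desk scale
on synthetic ensembles or on externally produced work logs and labelled
coarse trajectories.

## The staged pulling model

The reaction coordinate is the scalar separation `z` between the peptide
centre of mass and the lower-leaflet headgroup centre of mass, in
Angstrom. The span (canonically ~40 Å of membrane) is divided into
contiguous stages (canonically 8 stages of 5 Å); each stage runs `N`
replicas (canonically 25) of a steered pull at constant guide velocity
(canonically 1 Å/ns).

Free energies come from the Jarzynski equality,

$$\exp(-\beta \Delta F) = \langle \exp(-\beta W) \rangle, \qquad
\beta = \frac{1}{k_B T},$$

with `kB = 0.0019872041` kcal mol⁻¹ K⁻¹ and `T = 310.15` K by default.
A frequently seen slip writes β as "the Boltzmann constant multiplied by
the temperature"; the equality is only dimensionally consistent with
β = 1/(k_B·T), which is what `thermo_params()` implements.

After each stage the replica whose final work lies closest to the stage's
Jarzynski estimate is selected (`select_representative_replica()`, ties
broken deterministically by lowest replica id) and its final
configuration seeds every replica of the next stage. `run_asmd()`
re-anchors each stage's pointwise profile to the previous stage's end
value, so the assembled PMF is continuous at stage boundaries by
construction — this mirrors the "hand the last frame over" semantics of
the staged protocol.

Two estimator entry points are provided because staged protocols are
ambiguous on this point: `jarzynski_free_energy()` operates on final
works only, and `jarzynski_profile()` applies the estimator pointwise
along the guide position, interpolating each replica's work linearly
(traces are densely sampled; higher-order interpolation is unwarranted).

### Numerical safeguards

The exponential average is evaluated with a shifted-exponential
(log-sum-exp) scheme, so ensembles with large `βW` cannot underflow; the
implementation agrees with the naive form to 10⁻¹⁰ kcal/mol whenever the
naive form is representable, and respects two exact bounds on every
input: the Jensen bound `ΔF ≤ mean(W)` and `ΔF ≤ min(W) + ln(N)/β`.
Adding a constant to all works shifts the estimate by exactly that
constant.

## The synthetic pulling engine

`simulate_steered_pull()` integrates an overdamped Langevin particle
(Euler–Maruyama; no inertia) dragged by a harmonic guide across a known
sum-of-Gaussians landscape:

$$x_{t+\mathrm{d}t} = x_t + \frac{\mathrm{d}t}{\gamma}\left(-U'(x_t) +
k(\lambda_t - x_t)\right) + \sqrt{2 k_B T \,\mathrm{d}t/\gamma}\;\xi_t,$$

with external work accumulated in the stiff-spring convention
`dW = k (λ − x) dλ` and `W(0) = 0` exactly. The overdamped scheme is the
simplest integrator with a known steady state — the particle trails the
guide by `γ v / k` on a flat landscape and work accrues at `γ v²` — which
makes the simulator itself testable in closed form.

Parameters, units and defaults:

| parameter         | units              | default | rationale |
|-------------------|--------------------|---------|-----------|
| `spring_constant` | kcal mol⁻¹ Å⁻²     | 10      | stiff-spring guide; the staged protocol's "constant force of 10 kcal·mol⁻¹" is dimensionally a spring constant and is mapped here |
| `velocity`        | Å ns⁻¹             | 1       | the slow pulling speed the protocol settles on |
| `temperature`     | K                  | 310.15  | body temperature |
| `friction` (γ)    | kcal mol⁻¹ ns Å⁻²  | 0.05    | `D = k_B T / γ ≈ 12 Å²/ns`, a realistic diffusivity for a small solute in water |
| `timestep`        | ns                 | 10⁻³    | stability requires `dt < 2γ/k`; the default sits at 1/10 of the relaxation time `γ/k` |

The pulled span must be a whole number of integration steps so the guide
lands exactly on the stage end; stage widths used by the planner always
satisfy this. All randomness flows through R's RNG: a trace is
bit-reproducible from its seed, and replica `i` of an ensemble derives
its seed deterministically from `(seed, i)` with two distinct
multipliers, so nested derivations (stage, then replica) cannot collide
across indices.

### What the estimator can and cannot deliver

For near-equilibrium pulls the work variance obeys
`σ_W² ≈ 2 k_B T W_diss`, so the finite-`N` Jarzynski estimate carries a
statistical error of roughly `k_B T sqrt((e^{β σ_W²} − 1)/N)` per stage.
With 25 replicas and the default friction this is ~0.14 kcal/mol per
5 Å stage — small against barriers of several kcal/mol, but not against
1–2% of a stage's dissipated work. A single 25-replica estimate of a
flat landscape therefore lands within ~±0.5 kcal/mol of zero over a
full 8-stage span, while showing that the estimator is *unbiased* to
within a few percent of the dissipation requires averaging many
independent ensembles; the test suite does exactly that (50 independent
25-replica ensembles). Hysteresis between forward and backward staged
runs is assessed in the quasi-static regime (0.1 Å/ns), where estimator
noise, not protocol bias, dominates the residual.

## The synthetic bilayer generator

`generate_bilayer_trajectory()` emulates the features the metrics need,
with analytically known ground truth:

* two leaflets of lipids on a jittered lateral grid, headgroup beads at
  specified planes (default ±19.25 Å, i.e. 38.5 Å thickness), each lipid
  carrying one chain of tail beads tilted by a per-lipid random angle;
* species are labels only; names like `CHOL` become single-bead sterols;
* sparse bulk water slabs beyond each leaflet, and — optionally — a
  transmembrane water column sampled uniformly within a per-slab disk of
  a specified radius profile `r(z)`, with per-slab counts proportional
  to disk area, so the true bottleneck radius is known exactly;
* optionally a peptide bead chain at a controllable depth.

What it does **not** emulate: lipid diffusion and undulations, water
ordering, electrostatics, peptide conformational dynamics, or periodic
wrapping (fixtures are generated whole; readers refuse wrapped
molecules). Consequently, a passing metric validates the *estimator* on
geometry it claims to measure — it says nothing about force-field
realism on real trajectories.

## Membrane metrics

**Leaflets.** Lipids at or above the median headgroup z are "upper"
(`z ≥ median`, a deterministic tie rule).

**Order parameter.** `S = ⟨(3 cos²θ − 1)/2⟩` with θ against the membrane
normal, averaged over lipids and frames, bounded in [−0.5, 1]. The
coarse model has no hydrogens, so the pseudo-bonds are the
consecutive-bead vectors along each chain; a perfectly aligned chain
scores exactly 1, which keeps the formula testable without united-atom
reconstruction. `bond_order_parameter()` exposes the raw per-vector
form.

**Pore radius.** The membrane span is sliced into z slabs (default 1 Å:
sub-lipid resolution without empty-slab noise at fixture densities);
per slab the radius is the maximum lateral distance of slab waters to
the slab water centroid, an empty slab scores 0, and the frame value is
the minimum over slabs — the bottleneck of the water pathway. The
"maximum water extent per slab" notion admits a second reading (half the
maximum pairwise distance), available via `method = "pairwise"`. Means
are reported over the trailing analysis window (default 0.8 of frames,
matching relaxation analyses that keep the last 80 of 100 ns). Recovery
degrades for undersampled channels: below roughly 10 waters per slab the
min-over-slabs statistic biases low by more than the nominal
`max(0.5 Å, 2/√n)` sampling bound, so sparse channels should be read as
qualitative.

**Thickness and area per lipid.** Thickness is the difference of mean
headgroup z between leaflets, per frame. Area per lipid uses the
box-area method `Lx·Ly / n_lipids` per leaflet, so APL × leaflet count
equals the box area exactly; Voronoi tessellation is deliberately out of
scope. Both are exactly invariant under rigid translation.

**Fate classification.** The released peptide's trailing-window mean COM
z is mapped onto three bands: below `z_lower + margin` →
`lower_leaflet_equilibrium`; above `z_upper − margin` → `return`;
in between, `pore_formation` if the pore radius exceeds the threshold in
more than the persistence fraction of analyzed frames, else `insertion`.
The source protocol defines these outcomes only qualitatively, so the
margin (5 Å), pore threshold (1 Å) and persistence (0.5) are explicit,
config-exposed choices; the bands partition the axis (requiring
`2·margin` < plane separation), which makes the classifier total.

**Occupancy.** Per peptide residue, the percentage of analyzed frames
with any bead-to-bead contact within the cutoff against the selected
lipid group (headgroup by species, tails, sterols; unions via `+`),
under minimum-image distances. The cutoff default of 4.0 Å is a
conventional heavy-bead contact distance — the original analysis relied
on an external package's unstated default — and is always reported in
the output metadata. Occupancy is monotone in the cutoff, and a group
union can never score below its members.

## Peptide descriptors

GRAVY is the mean Kyte–Doolittle hydropathy over the sequence (scale
hard-coded from the original publication; rounding to two decimals only
at presentation). Net charge is the integer formal model at neutral pH:
+1 per K/R, −1 per D/E, histidine neutral, zwitterionic termini
cancelling — the only model consistent with all declared charges of the
bundled peptide set. The registry stores the five study peptides with
their declared values and recomputes both descriptors; the K-FGF entry
declares length 17 against a 16-residue printed sequence, and the
registry flags rather than repairs the discrepancy.

```{r registry}
peptide_registry()[, c("name", "sequence", "net_charge", "gravy",
                       "length_matches")]
```

## Problem sizes

The validation suite runs the full canonical protocol (8 × 5 Å stages,
25 replicas, 1 Å/ns) for the flat-landscape and barrier-recovery checks,
a 0.1 Å/ns variant for hysteresis, 50 × 25-replica ensembles for the
unbiasedness check, 10⁵ Gaussian works for the second-cumulant limit,
and bilayers of up to 150 lipids per leaflet over a handful of frames
for the composition and metric checks. These sizes were chosen so each
statistical assertion has the power it needs while the whole suite stays
comfortably interactive.

## Known limitations

* The pulling engine is one-dimensional by design: no membrane
  deformation feedback, no peptide internal degrees of freedom.
* Jarzynski estimates from 25 replicas carry irreducible noise of order
  0.1–0.2 kcal/mol per stage at the default conditions; treat sub-0.5
  kcal/mol features of an assembled PMF as within noise.
* Pore radii from channels with fewer than ~10 waters per slab are
  biased low.
* Readers accept only the documented bead-naming dialect and refuse
  wrapped molecules rather than attempting to unwrap them.
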