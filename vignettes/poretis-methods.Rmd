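---
title: "Path sampling of membrane pore formation: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Path sampling of membrane pore formation: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretis)
```

This vignette is the package's own account of its methods: the sampling
model and its assumptions, the membrane collective variables and their
conventions, the tunable parameters with their defaults and rationale,
the numerical choices made where the method descriptions in the
literature leave freedom, what the synthetic systems do and do not
emulate, and the known limitations. Nothing stated here goes beyond what
the test suite and the acceptance script themselves compute.

## 1. The sampling model

Two-state transition interface sampling describes a rare transition
A → B through a scalar order parameter λ. State A is λ < λ_A, state B
is λ > λ_B, and intermediate interfaces λ_A = λ_0 < … < λ_n = λ_B define
the path ensembles [0−], [0+], …, [(n−1)+]. A valid [i+] path starts in
A, crosses λ_i, keeps all interior frames inside [λ_A, λ_B] and ends in
a terminal state; a valid [0−] path has both endpoints at or above λ_A
and its interior inside A. The rate constant is the exact identity

$$k_{AB} = f_A \, P_A(\lambda_B\mid\lambda_A)
         = f_A \prod_{i=0}^{n-1} P_A(\lambda_{i+1}\mid\lambda_i),$$

with the flux $f_A = 1/(\langle t\rangle_{[0^-]} +
\langle t\rangle_{[0^+]})$ from weighted mean path durations. Both
factors depend on the placement of λ_A; their product does not, and the
test suite verifies this invariance on the toy system.

**Assumptions.** The dynamics backend must be Markovian and
time-reversible in distribution (Langevin dynamics qualifies; so does
overdamped Brownian dynamics). Equilibrium velocities must factorise
from positions, since shooting moves redraw them from the thermal
distribution. Orthorhombic periodic boxes only.

### Moves

*Shooting.* A stored frame is chosen uniformly, its velocities are fully
redrawn from the Maxwell–Boltzmann distribution, and the trajectory is
integrated backward and forward until a terminal state. With uniform
frame selection and full velocity redraw, the flexible-path-length
Metropolis factor is `min(1, N_old/N_new)` on the frame counts;
proposals exceeding the length cap (default 50× the initial path length)
are rejected, never truncated, to keep the ensemble unbiased.

*Wire fencing.* For the higher [i+] ensembles, `n_sub` (default 3)
subtrajectories are shot inside the fence between λ_i and a cap
interface, each cut at its first crossing of a fence boundary
("reflect-by-rejection") and accepted against the current subtrajectory
with the flexible-length factor on fence-frame counts; the final
subtrajectory is extended to the terminal states by free dynamics. The
weighting of accepted paths is the simplest one consistent with the
Metropolis structure — unit weights with rejected moves recounting the
current path — and its unbiasedness is not assumed but measured: the
test suite requires the wire-fencing estimate of a local crossing
probability to agree with the standard-shooting estimate within three
combined standard errors.

*Cap placement.* The default cap for [i+] is the interface midway in
index (a proxy for crossing-probability space under roughly equal local
probabilities) between λ_i and λ_B — but never closer than two
interfaces above λ_i. This floor is a deliberate design choice: a cap
sitting exactly at λ_{i+1} cuts subtrajectories at the very interface
whose crossing probability the ensemble estimates, and measurably
distorts that estimate, whereas a cap at λ_B coincides with the physical
path terminus and is harmless. Caps are exposed in the configuration.

*Point exchange.* The [0−]/[0+] swap continues dynamics determinately
through the shared λ_0 crossing: the new [0+] path continues forward
from the upward crossing ending the [0−] path, and the new [0−] path
integrates time-reversed from the A-side start of the [0+] path.

*Infinite swap.* With unit path weights, every assignment of replicas to
[i+] ensembles compatible with the validity matrix is equally probable
in the infinite-swap limit. The sampler draws a uniformly random valid
permutation each cycle (greedy most-restrictive-first for the nested
validity structure of interface ensembles, permanent-weighted sequential
sampling otherwise), and logs fractional occupancies computed from exact
matrix permanents (Ryser's formula, C++).

**Estimator bookkeeping.** Every move attempt, point-exchange attempt
and swap event counts the current path of each participating ensemble
exactly once, accepted or not. This uniformity matters: if swapped-in
paths were counted but unmoved ones not, paths valid in many ensembles
(high λ maxima) would be systematically overweighted in the low
ensembles. The archived weight of a path is therefore the number of
events it represented its ensemble.

## 2. Membrane collective variables

All CVs operate on a `bilayer_frame`: coordinates in nm, per-atom role
flags (polar heavy, phosphorus, water oxygen) and lipid membership.
Periodic centers of mass use the circular-mean construction followed by
an exact minimum-image average about it, which is translation invariant
and reduces exactly to the arithmetic mean for clusters spanning less
than half the box.

*Chain coordinate ξ_ch.* Cylinder radius 0.8 nm, 26 slices of 0.1 nm
(DMPC defaults; the POPC preset uses 30 slices), centred on the membrane
z center of mass. Fill rule: empty slice 0, single atom 0.75
(`partial_fill`, exposed), two or more atoms exactly 1 — a definite
convention so that equality tests are exact. One polar atom in every
slice therefore gives ξ_ch = 0.75, the threshold for a continuous polar
defect.

*Cylinder localisation.* The xy center is a fixed point: atoms inside
the current cylinder are grouped into z layers, each nonempty layer's
periodic xy center of mass is computed, and the new center is the
unweighted average of the layer centers (unweighted, so outer layers
cannot dominate). Iteration starts from the previous frame's center
along a path (continuity), else from the most central polar atoms, and
converges below 0.01 nm or stops at 50 sweeps, returning the candidate
with the largest ξ_ch and a non-convergence flag. With several separated
defect columns the fixed point is not unique and follows the initial
guess — a documented dependence, exercised in the tests.

*Pore expansion ξ_p.* Equals ξ_ch while any slice is empty. Once all
slices are occupied, ξ_p = max(ξ_ch, 1 + (N − N_ref)/N_ref) with N the
polar-atom count within an expansion radius of 1.5× the cylinder radius
and N_ref = 2 × n_slices, the count at which every slice is completely
filled. This variant is monotone under adding polar atoms, sits near 1
for a nascent continuous defect, and exceeds 2 for a wide pore (the
open-pore convention used for state definitions). The exact published
normalisation of the expansion term is defined in earlier work that this
package does not reproduce; the variant here is the package's documented
convention and is used consistently throughout.

*d_LLP.* The 12 lipids (`n_llp`, exposed) laterally closest to the
cylinder center are split into upper and lower sets by their phosphate z
offset from the membrane center of mass; if one set is empty the
selection extends by next-nearest lipids until both are populated;
d_LLP is the difference of the set means. Ties in the nearest-lipid
ordering break by lowest lipid index, for determinism.

*d1/d2 and d1\*/d2\*.* Lipids are z-sorted into equal halves; d1 is the
z separation of the cross-half pair minimising the 3D minimum-image
distance (d1\*: minimising |Δz| only), d2 the same after removing the
first pair. The z-sorted split makes both non-negative. The starred
variants dip spuriously under coherent membrane undulations (tilted
leaflets bring laterally distant lipids close in z) — the generator has
an undulation control precisely to reproduce this failure mode in a
test — so the Euclidean forms are preferred for new work, while the
starred forms remain because existing order-parameter schemes use them.

*d_CNT.* |N/2 − #{phosphorus above the bilayer z center of mass}|,
an integer. The membrane z center of mass uses the periodic form so a
bilayer straddling the z boundary stays well defined.

*Order-parameter schemes.* `"PF"`: λ = ξ_p − (d1\* + d2\*), coupling
pore formation to translocation bookkeeping; `"PC"`: λ = −ξ_p (progress
toward the closed state increases λ); `"XI_CH"`: λ = ξ_ch.

## 3. Synthetic systems: what they emulate

*Langevin toy engine.* A quartic double well along x, harmonic in y,
BAOAB-discretised underdamped Langevin dynamics (unit mass, k_B = 1).
BAOAB was chosen for its accurate configurational sampling at practical
time steps, and because its friction-zero limit is exactly velocity
Verlet — which gives a free symplecticity test. Defaults used across
the tests: barrier 5 kT, minima at ±1, dt = 0.02, friction 1,
temperature 1. A 5 kT barrier makes transitions rare enough that
interface sampling is meaningful (crossing probability ~2×10⁻²) yet
frequent enough that a multi-million-step direct simulation provides a
brute-force rate with ~100 events for the three-standard-error
comparison. All randomness flows through R's global RNG, so `set.seed`
reproduces entire sampling runs bitwise.

*Pseudo-bilayer generator.* Two leaflets of point-lipids (one phosphorus
head, three collinear tail beads at 0.35 nm spacing), waters as single
oxygen sites outside the hydrophobic slab, in a 6.2 × 6.2 × 7 nm box
with a 3.4 nm head-head thickness and 128 lipids / 5749 waters by
default — the geometry of a solvated DMPC patch. Controls: local
thinning (depth/radius about a center), a polar defect column with
per-slice atom counts, translocated lipids (leaflet split shifted by
`flipped_lipids`), coherent sinusoidal undulation, and Gaussian
positional jitter (0.04 nm default; tests that need exact values set it
to zero). Every requested feature is recorded in a ground-truth
attribute so tests can verify it from raw coordinates without the CV
code — the generator and the CVs cross-check each other.

The generator emulates the *geometric* features the CVs read: head
positions, polar columns, thinning, leaflet imbalance. It does not
emulate lipid conformational disorder, water structure, electrostatics
or realistic defect shapes. Passing CV tests therefore establishes that
the CV implementations compute their definitions correctly under
periodic boundaries — not that the CVs discriminate states well in real
bilayers, which is a property of the physics, not of this code.
Likewise, toy-engine agreement between path sampling and brute force
validates the sampling machinery, not any membrane-specific quantity.

## 4. Analyses: estimators and numerical choices

*Crossing curve.* Per-ensemble weighted survival functions of path
λ-maxima, scaled by the telescoped product of preceding local
probabilities; the telescoping identity holds exactly at interfaces, and
the assembled curve is clamped monotone.

*Flux and rate.* Durations are (frames − 1) × timestep. Standard errors
come from block averaging of the cycle-expanded series (each path
repeated by its weight), so move-to-move autocorrelation is absorbed;
relative errors propagate in quadrature through the rate identity.

*Free energy and committor projection.* Within an archive, endpoint
frames are dropped; the [0−] and [0+] interiors then tile the
equilibrium trajectory one-to-one (one path of each per crossing cycle),
so their histograms combine after per-ensemble weight normalisation with
no overlap fit. Higher [i+] histograms, restricted to their reliable
region λ ≥ λ_i, are matched sequentially by a multiplicative constant
fitted on log densities over overlapping bins and overwrite their own
region. Bins only partially covered by a restriction (the bin also holds
frames below λ_i) are excluded from fits and overwrites — truncated
straddle bins otherwise skew the constants; aligning bin edges with
interfaces avoids the issue entirely when projecting onto λ itself.
Forward and backward archives are combined by one multiplicative
constant fitted on their overlap, per the standard forward/backward
matching construction; for strongly asymmetric systems this single
constant is an approximation, noted as a limitation. Empty bins are NA,
never zero-filled. The committor label of a frame is whether its own
path ends, in physical time, in the product state — for interior frames
of interface paths this is exactly the frame's forward commitment, since
the path cannot touch a terminal state in between. Labels from one
archive alone carry the velocity bias of arrival conditioning; the
forward+backward combination restores the positional committor, which is
why the isocommittor-0.5 test uses both archives.

*Transmission coefficient.* Effective-positive-flux counting at a
dividing surface: the denominator sums positive-direction crossings
(sign of Δλ between stored frames) with path weights; the numerator
counts once per reactive A→B path (its first crossing arrives directly
from the reactant basin). λ is taken at full storage resolution; with
strided storage, recrossings within a stride are invisible and κ is
biased upward — the toy tests store every step. Product-side paths can
be included with their small rate-ratio weight; both conventions are
available because their difference is negligible at realistic ratios.

*Block errors.* Flyvbjerg–Petersen doubling blocks; the plateau is the
first block size whose standard error grows by less than 2% on doubling
(minimum 8 blocks), validated against the i.i.d. closed form (20%) and
the AR(1) effective-sample-size formula (25%). A running estimate can be
unwound to raw contributions by first differences.

*Inf-init.* Round 1 runs with the terminal interfaces only, seeded from
equilibrium configurations in state A. After each round, intermediate
interfaces are placed at weighted survival quantiles of the observed
path maxima at a target local probability of 0.3 (the customary 0.2–0.4
placement band), with terminals fixed; the ensemble count thus grows by
one interface per factor-of-0.3 of reached probability, a rule chosen
here since the published description leaves it open. Rounds are a fixed
number of cycles (default 20) rather than wall time, for
reproducibility. Degenerate maxima produce a single intermediate with a
warning; a zero budget is an immediate structured failure. The iteration
implemented here is a faithful-but-independent realisation of the
briefly published protocol.

## 5. Validation summary and problem sizes

The deterministic checks are exact: CV defining values (ξ_ch = 0.75,
d_CNT splits), brute-force pair-search and proximity oracles on 100
random generator frames, permutation-enumeration infinite-swap weights,
worked transmission-coefficient constructions (1/3, 1/2), and the
printed flux/probability/rate arithmetic identities. The stochastic
checks run at sizes chosen to keep the whole suite in the minutes range
while leaving clear statistical margins: pilot placement from 2000
direct excursions, production sampling of ~700 cycles over 4–7
interfaces, brute-force comparisons from 2–4 million Langevin steps
(~100+ events), and projections from two 500-cycle runs on 0.16-wide
bins. At these sizes the rate comparison is a ~3σ test with ~15%
relative errors on each side, and the projected free energy reproduces
the analytic double well to ~0.15 kT RMS against a 0.5 kT bound.

## 6. Known limitations

- The wire-fencing weighting is validated empirically on the toy system,
  not proven; exotic landscapes (broad flat barriers with long fence
  dwell times) could stress it.
- The single forward/backward matching constant is exact only up to the
  sampling symmetry of the two archives.
- ξ_p beyond 1 is a package convention, not the published normalisation.
- Odd lipid counts are rejected by the pair-distance CVs (documented
  limitation of the equal-half split).
- Triclinic boxes, biasing forces/differentiable CVs, multistate
  (three-state or more) variants and direct MD engine coupling are out
  of scope; external engines attach through the dynamics-backend
  interface.
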