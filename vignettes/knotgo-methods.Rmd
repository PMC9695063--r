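---
title: "knotgo: model, move sets and analysis methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{knotgo: model, move sets and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotgo)
```

## The model

`knotgo` simulates protein folding with a C-alpha structure-based (Go-type)
model. Each residue is a hard sphere of radius 1.7 Å (the van der Waals
radius of a C-alpha atom) centred on its C-alpha position; consecutive
beads are joined by rigid sticks whose lengths are the native C-alpha
distances (about 2.9 Å for cis peptide bonds, 3.8–3.9 Å for trans).
Conformational freedom lives entirely in the joint angles: every accepted
conformation reproduces the native bond lengths to within 10⁻⁹ Å, and no
two non-bonded beads (sequence separation ≥ 2) may approach closer than
twice the bead radius.

Two residues are in *native contact* when the smallest distance between
their heavy atoms in the native structure is at most 4.5 Å. Only native
contacts interact. The energy of a conformation $\{\vec r_i\}$ is

$$E = \varepsilon \sum_{i,\,j \ge i+2} \left[\left(\frac{|\vec r_i-\vec r_j| -
d^{\mathrm{nat}}_{ij}}{w}\right)^2 + 1\right]^{-1}
\left(\chi_{ij}\chi^{\mathrm{nat}}_{ij} + \chi_{ji}\chi^{\mathrm{nat}}_{ji} +
\tfrac12\right) \Delta^{\mathrm{nat}}_{ij},$$

with $\varepsilon = -1$ (reduced units, $k_B = 1$), an inverse-quadratic
well of half-width $w$, and a chirality factor built from the signed triple
products

$$\chi_{ij} = \Theta\!\big((\vec r_i-\vec r_j)\cdot[(\vec r_{j+1}-\vec r_j)
\times(\vec r_{j-1}-\vec r_j)]\big) - \tfrac12 .$$

The factor is 1 when both ordered chiralities match their native values,
1/2 when one matches, and 0 for the full mirror image, so the native fold
is favoured over its mirror and the low-temperature ensemble converges to
the native basin. Two conventions required decisions:

* **Heaviside at zero.** $\Theta(0)=0$, so exactly coplanar bead triples
  get $\chi=-1/2$. The step is epsilon-stabilised: a triple product with
  magnitude below 10⁻⁹ counts as non-positive. Without this, lattice-like
  geometries (whose triples are exactly zero) acquire a sign decided by
  floating-point noise after rigid rotations, which breaks incremental
  energy bookkeeping.
* **Terminal contacts.** $\chi_{ij}$ is undefined when $j$ is a chain
  terminus (one neighbour is missing). The corresponding product is
  replaced by $+1/4$, its native-matching value: terminal contacts are kept
  but never penalised, and the formula is unchanged everywhere it is
  defined.

The reaction coordinate is the fraction of native contacts, $Q$: a contact
counts as formed when its bead distance differs from the native distance by
*strictly less* than $w$.

### The well half-width

$w$ (Å) controls folding cooperativity: wider wells give broader, higher-
temperature transitions. The conventional calibration is to tune $w$ until
the FWHM/Tm ratio of the heat-capacity peak lands between 4 and 5%, the
experimental value for a well-characterised two-state folder. The package
default is $w = 1$ Å; the desk-scale knotted fixture is typically run at
$w = 0.5$ Å, where its small contact set still yields a clean two-state
transition.

## Move sets and linear topology preservation

One Monte Carlo step (mcs) proposes one elementary move per replica. The
move kind is drawn with probability 1/2 each:

* **crankshaft** — a contiguous internal window of $m$ beads rotates about
  the axis through its two flanking beads;
* **pivot** — the $m$ beads adjacent to a random terminus rotate about an
  axis through the bead at distance $m$ from that terminus. The paper-style
  construction leaves the pivot axis direction open; `knotgo` draws it
  isotropically, which keeps the proposal symmetric.

$m$ is uniform on $\{1, \dots, m_{\max}\}$ with $m_{\max}$ the largest
integer strictly smaller than $3N/4$; draws infeasible for the chain length
are redrawn.

The move can be applied two ways:

* **LTyP** (linear topology preserving): the rotation amplitude is limited
  to the *free rotation interval* — for every (moving bead, fixed bead)
  pair the clockwise and counter-clockwise contact angles are solved in
  closed form (a single-harmonic equation in the rotation angle), and the
  free interval is the intersection of all pairwise clash-free arcs
  containing zero. Rotating to an endpoint produces grazing contact, which
  is allowed. Because every bead pair is kept from overlapping *along the
  whole rotation path*, and because a bead radius of at least
  $(3.9/2)(\sqrt2/2) \approx 1.38$ Å makes two crossing bonded sticks force
  a bead overlap (`min_crossing_safe_radius()` finds this worst case
  numerically), the chain can never pass through itself: the 1.7 Å radius
  guarantees topology preservation with bead–bead screening alone.
* **non-LTyP**: the angle is uniform on $(-\pi, \pi]$ and only the final
  conformation is screened for clashes; the rotation path may take the
  chain across itself.

Both variants use symmetric proposals: the free arc containing the current
configuration is the same set of configurations seen from the trial state
(its length is invariant), so the plain Metropolis rule
$\min(1, e^{-\Delta E/T})$ satisfies detailed balance. A pair-pruning bound
(minimal orbit distance above contact distance) skips most pairs; tests
verify the pruned solver against a dense angular-scan oracle at 10⁻³ rad.

## Replica exchange

Production protocol: 64 temperatures (tests use 4–10), non-uniformly spaced
— `temperature_ladder()` uses geometric spacing with a three-fold denser
linear sub-grid on $[0.9, 1.1]\,\hat T_m$, the estimate coming from a short
pilot run (`estimate_tm()`). Exchange between temperature-adjacent slots is
attempted every 10³ mcs with the standard alternating even/odd pairing and
acceptance $\min(1, \exp[(1/T_i - 1/T_j)(E_i - E_j)])$. Conformations carry
tokens that travel with them through exchanges; `token_roundtrips()` counts
full bottom–top–bottom ladder traversals as a mixing diagnostic.

Samples (E, Q, topological state, token) are recorded every 10⁴ mcs after
the relaxation budget: runs shorter than two units (10⁹ mcs at production
scale, configurable for desk-scale work) equilibrate for their first half,
longer runs of $n$ units for $n-1$ units. Each replica owns a
splitmix64-seeded xoshiro256++ RNG stream, plus one stream for exchange
decisions, so runs are bit-reproducible from (seed, config) and an
interrupted run resumed from its checkpoint state is bit-identical to an
uninterrupted one. The energy after each move is updated incrementally —
a contact term can only change when its dependency set
$\{i-1..i+1, j-1..j+1\}$ straddles the moving block — and spot-asserts
periodically compare the cache against full recomputation (10⁻⁶
tolerance), bond lengths (10⁻⁶ Å) and the excluded-volume constraint.

## Knot analysis

The topological state of a conformation is determined in three steps:

1. **Closure.** An open chain must be closed before its knot type is
   well defined. The exposed `close_chain()` implements deterministic
   radial closure (termini extended radially from the centroid to a sphere
   at 10× the chain extent, joined by a great-circle arc). For *detection*,
   however, `knot_type()` and `is_knotted()` use the majority vote over a
   fixed quasi-uniform set of 15 parallel closure directions (both termini
   sent far out along the same direction). The reason is empirical: for
   loose open knots whose termini sit buried between the knot lobes —
   including the standard parametric trefoil arc truncated at its
   innermost point — the centroid-radial rays exit through exactly the
   wedge that unties the knot, and radial closure reports the unknot while
   the overwhelming majority of uniform closure directions report the
   trefoil. The direction set is fixed, so detection remains deterministic.
2. **Cyclic KMT reduction.** The closed loop is simplified by triangle
   elimination: a vertex is deleted whenever the triangle formed with its
   neighbours is pierced by no other segment (closure edges included), so
   every deletion is an isotopy of the *closed* curve and the knot type is
   provably preserved. The open-chain reducer `kmt_reduce()` (endpoints
   fixed, closure not considered) is also provided; note that on loose
   arcs open-chain reduction may slide the knot over the end gap — which
   is why detection closes first.
3. **Alexander invariants.** The reduced loop is projected onto a generic
   plane (deterministic pseudo-random rotations retry degenerate
   projections), the underpass presentation of the Alexander matrix is
   built from the crossings, and $|\Delta(-1)|$ together with the odd part
   of $|\Delta(-2)|$ (the determinant at $-2$ is defined only up to sign
   and powers of two) label the knot: unknot (1,1), 3₁ (3,7), 4₁ (5,11),
   5₁ (5,31), 5₂ (7,1), 6₁ (9,5); anything else, composites included, is
   `other`. The Alexander determinant cannot see chirality, so mirror
   knots share a label — which is the desired behaviour for knot *typing*
   (the energy function, not the knot detector, distinguishes mirrors).

`knotted_core()` trims residues from the N-terminus while the chain stays
knotted, then from the C-terminus, and reports the minimal knotted segment
in the source residue numbering; tails shorter than 15 residues on both
sides classify the knot as shallow, otherwise deep.

## WHAM thermodynamics

`wham_fit()` combines the per-temperature histograms over joint
(E, Q, knotted) bins by iterating the standard self-consistency equations

$$g(m) = \frac{\sum_k H_k(m)}{\sum_k n_k e^{f_k - E_m/T_k}}, \qquad
e^{-f_k} = \sum_m g(m)\, e^{-E_m/T_k}$$

in log space until the free energies move by less than 10⁻⁸ (at most 10⁵
iterations). Energy bins have width $\max(0.05, \mathrm{range}/400)$
reduced units; Q bins are one per contact count (Q is naturally discrete
with resolution $1/N_c$). Adjacent ladders without histogram overlap are
an error; overlap below 1% warns. From the density of states,
`thermo_curves()` evaluates $U(T)$ and
$C_V(T) = (\langle E^2\rangle - \langle E\rangle^2)/T^2$,
`melting_and_width()` locates the CV peak ($T_m$) and its interpolated
full width at half maximum, and `knotting_profiles()` projects the knot
indicator along $T$ and along $Q$ (at a reference temperature, default
$T_m$); empty Q bins are reported as `NA`, never as zero.

Direct per-temperature estimates (`thermo_direct()`) with block-bootstrap
errors (200 resamples, fixed sub-seed) back the equilibration cross-check
`check_equilibration()`: runs started from the native state and from a
denatured conformation, with either move set, must agree in $U(T)$ and
$C_V(T)$ within 3 combined standard errors at every ladder temperature —
the operational test that thermal equilibrium was reached. The bootstrap
is honest only when blocks are long compared to the correlation time of
the series, so the block count defaults to `min(50, n/10)`: at production
sample counts this is the conventional 50 blocks, while a desk-scale run
with a few hundred samples per temperature gets fewer, longer blocks
(50 blocks of 4 samples each would badly under-cover). Two further
desk-scale lessons are recorded here because they shaped the defaults:
the deviation statistic is a maximum over ~100 correlated comparisons and
therefore noisy (its null distribution sits near 3 SE), so the scaled-down
cross-check samples densely (every 2×10³ mcs) to stabilise the error
estimates; and a toy whose folding transition is too cooperative for its
mcs budget (the 15-bead lattice globule at its critical rung) fails the
check not for lack of equilibrium but for lack of self-averaging — the
check's own toy is therefore the 15-bead helix, whose broader transition
the 2×10⁶-mcs budget comfortably equilibrates.

## The synthetic world

All tests run without downloads, on fixtures built in code:

* `make_toy_topology()` — a planar hairpin (a stacked ladder whose
  contact map is exactly symmetric about the turn), a helix, and a
  compact lattice-meander globule, all with 3.8 Å bonds. Because the
  fixtures have no side chains, their contact maps use a C-alpha proxy
  (contact iff native C-alpha distance ≤ 6.5 Å, separation ≥ 2),
  recorded in the topology metadata so it is never confused with the
  heavy-atom rule used on real structures. The planar hairpin and the
  lattice globule have identically zero triple products on (some or all)
  contacts — their chirality is the $\Theta(0)=0$ convention value, not
  a defect — so the exact mirror-zero energy identity is checked on the
  knotted fixture restricted to contacts whose chirality is defined in
  both pair orders with comfortably nonzero triple products.
* `make_knotted_topology()` — an open trefoil. Two geometric choices were
  made once, for scientific reasons: the parametric curve is cut at an
  *outer* lobe (phase π), because cutting at the innermost point leaves a
  loose slip-knot whose termini are buried and whose detection is
  closure-ambiguous; and the lobe plane is compressed (×0.6) while the
  axis is stretched (×1.5), giving ~21 contacts at 35 beads instead of 10.
  With the sparse isotropic arc, conformations with $Q = 1$ are unknotted
  about half the time — the contact set simply does not pin the topology,
  and no knotting-probability statement survives. The tight variant is
  decisively knotted (all 15 closure directions agree) and shows
  $p_k \to 1$ at low temperature with a clean transition near
  $T \approx 0.25$ at $w = 0.5$.
* `synthetic_protein_trace()` — four stand-ins mirroring the benchmark
  topologies (a 109-residue deep trefoil with core 21–74 and tails 20/35;
  a 92-residue shallow trefoil with core 11–82 and tails 10/10; two
  unknotted chains of 90 and 98 residues). They are geometric
  constructions, not experimental structures; they exist so the chain
  loading, knot typing, core mapping and depth classification pipeline
  can be exercised offline end to end. Tests on them establish that the
  *machinery* recovers the constructed ground truth — they say nothing
  about real PDB entries, which the same pipeline reads when files are
  available.
* `generate_denatured()` — unfolds the native state by single-temperature
  non-LTyP MC above $T_m$, retrying with fresh sub-seeds until the result
  is unknotted with $Q < 0.2$.

What a green test establishes, and what it does not: the synthetic world
exercises every algorithmic path (potential, move sets, exchange, knot
analysis, WHAM) at desk scale — minutes, not the 10⁸–10¹⁰ mcs,
64-replica production runs. Cluster-scale reproduction of real-protein
thermodynamics is out of scope; the package provides the machinery and the
scaled-down evidence that equilibrium properties are move-set independent
while relaxation cost is not.

One scaled-down limit deserves emphasis: *topological* basin exchange on
the knotted fixture is far slower than desk budgets. Untying happens
readily at the hot end of the ladder, but a re-knotting event from the
denatured state was never observed within 4×10⁶ mcs, so a run's knotted
flag at low temperature reflects the basin the ensemble fell into, not a
converged average over both basins — the same orders-of-magnitude
relaxation burden that full-scale knotted proteins show. The claim that
the equilibrium low-temperature ensemble is knotted rests instead on
energetics: the knotted basin sits about 3.3 reduced units below the best
unknotted compact trap (a Boltzmann factor of e²² at T = 0.15), so the
knotting-probability checks start from the native state and sample the
knotted basin, which is the equilibrium one.

## Numerical choices

* Chirality step epsilon 10⁻⁹ (above); intersection predicates in the KMT
  reducer use 10⁻⁹ epsilons, and triangles sharing a vertex with a segment
  are not counted as pierced.
* Degenerate projections (near-parallel crossings, coincident passage
  parameters, unreliable determinants) are retried under deterministic
  pseudo-random rotations, up to 50 times.
* Grazing contacts in the free-interval solver (arccos argument outside
  $[-1,1]$ by < 10⁻¹²) are clamped; grazing counts as allowed.
* WHAM iterates in log space with max-shifted sums; convergence 10⁻⁸ on
  free energies, cap 10⁵ iterations.
* The two-level WHAM oracle, the Schottky closed form, the law-of-cosines
  contact angles, the dense angular scan, and the rejection sampler over
  clash-free freely jointed chains serve as independent cross-checks in
  the test suite.

## Known limitations

* Knot typing is determinant-based; knots sharing $|\Delta(-1)|$ and the
  odd part of $|\Delta(-2)|$ with a listed type would be mislabelled
  (none occur among prime knots up to 6 crossings).
* Open-chain knot state is closure-majority over 15 directions; chains
  whose closure spectrum is nearly balanced (very loose or very shallow
  knots) are classified by a thin margin and can flip under small
  deformations. This is a property of open-knot definitions, not of the
  implementation.
* The simulator is serial; the per-replica RNG streams make a parallel
  implementation bit-compatible in principle, but none is provided.
* The heavy-atom contact rule needs side-chain atoms; C-alpha-only inputs
  degenerate to a C-alpha distance rule at the same cutoff (4.5 Å), which
  finds essentially no contacts — topology work is unaffected, but
  energetics on C-alpha-only files are meaningless without a proxy cutoff
  such as the fixtures' 6.5 Å.
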