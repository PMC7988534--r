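---
title: "Event-driven square-well dynamics for amyloid peptide self-assembly: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-driven square-well dynamics for amyloid peptide self-assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdmd)
```

## The model

`pepdmd` simulates short peptides with a PRIME20-style coarse-grained
representation: each residue contributes three backbone beads (NH, CaH,
CO) and one sidechain bead (glycine has none).  All interactions are
discontinuous, so the dynamics is event-driven: beads fly ballistically
until an analytically predicted discontinuity crossing, at which point an
impulsive velocity update is applied.

Covalent geometry is maintained by hard-walled bonds and pseudobonds that
confine each pair to within ±2% of its nominal length.  The pseudobond
set (NH–CO within a residue; CaH–CaH, CaH–NH and CO–CaH across the
peptide unit; NH–SC and CO–SC bracing the sidechain arm) triangulates the
backbone into a nearly rigid, extended strand with free rotation of the
sidechain bead about the chain axis.  This is a deliberate idealization:
the heptapeptide Ac-KLVFFAE-NH2 (Abeta16-22) is short and strongly
beta-prone, and representing it as a semi-rigid extended strand removes
the intramolecular folding search while preserving the two processes the
model is built to study — diffusion-limited association and the
alignment/registry search of hydrogen-bonded strand pairs.

Nonbonded interactions are of two kinds:

* **Sidechain square wells.**  Each unordered residue pair has a hard
  core at the additive contact distance, a well width, and a well depth
  in units of the hydrogen-bond energy eps_HB (attractive wells have
  energy −depth inside the well).  The bundled default table
  (`inst/extdata/sw_params_v1.txt`, one `PAIR` record per unordered pair
  of the 20 residue types, 210 records) is an explicit approximation:
  hydrophobic residues attract with a geometric-mean rule scaled to
  0.30 eps_HB for Phe–Phe, oppositely charged residues (K/R with D/E)
  attract at 0.30 eps_HB, like-charge pairs are hard-sphere only, and all
  other pairs are zero.  The published parameter sets this scheme stands
  in for are not printed in the primary literature; the file format
  (`PAIR`/`GEOM`/`HB` records, versioned header) accepts any externally
  supplied table, and nothing in the engine assumes the default values.
* **Directional backbone hydrogen bonds.**  An NH and a CO bead on
  different chains (or at least three residues apart on one chain) may
  bond when they cross their square-well width of 5.0 Å moving inward,
  provided the four auxiliary beads — the CaH and preceding CO flanking
  the NH, and the CaH and following NH flanking the CO — are all farther
  than 4.6 Å from the partner bead.  This enforces local linearity of
  the bonded geometry, the discrete analogue of hydrogen-bond
  directionality.  A formed bond has depth 1.0 eps_HB by definition, a
  reduced NH–CO hard core of 2.6 Å, and one bond per donor and per
  acceptor.  Formation is attempted only at the inward crossing; a pair
  that fails the directionality test passes through freely and may try
  again on a later approach.

The hydrogen-bond constants (well 5.0 Å, core 2.6 Å, auxiliary distance
4.6 Å) were fixed together with the lattice geometry of the fixtures
module: an ideal beta-sheet with the experimental 4.9 Å strand spacing
places every in-register NH···CO pair just inside the well (4.90–4.95 Å)
with all auxiliary distances at 4.95 Å or more, while any misaligned
close approach puts an auxiliary bead inside the exclusion zone.
Geometry defaults (backbone bead diameters 3.3–3.7 Å, CaH–CaH spacing
3.8 Å along a strand, per-residue sidechain diameters and arm lengths)
live in one place, the `GEOM` block of the parameter table.  Intra-chain
pairs three or fewer covalent bonds apart that are not themselves walled
interact through a hard core scaled by 0.75, the usual near-chain
squeeze; sidechain wells and hydrogen bonds act only between chains or
between residues at least three positions apart.

Units: lengths in Å, energies in eps_HB (= 12.47 kJ/mol for reporting),
masses in Da; the reduced time unit tau follows as
Å·sqrt(Da/eps_HB).  The mapping of tau to nanoseconds is not computed by
the package; the reduced temperature T* = k_B T/eps_HB is the native
temperature scale, and the conventional annotation that T* = 0.193
corresponds to 326 K is carried as configuration metadata only.

## The event loop

The engine keeps a priority queue of future events keyed by time with a
deterministic tie-break (time, then kind, then bead ids).  Each bead
stores its position at its own last-update time, so free flight costs
nothing; cell lists with cells at least one interaction range wide prune
neighbour prediction, and cell-boundary crossings are themselves events
that re-anchor and re-wrap the bead.  Scheduling uses the classic
one-slot-per-particle scheme: whenever a bead's velocity (or cell)
changes, a counter invalidates its queued events and a single rescan
pushes only its earliest candidate; stale events trigger a rescan of the
beads whose slot they occupied when popped.  Event prediction solves
|r + v·t| = d for each discontinuity distance d in a numerically stable
form (no catastrophic cancellation; negative or complex roots mean no
event), with guards that treat a pair found marginally beyond a wall as
colliding immediately so that floating-point drift cannot wedge a pair
outside its constraints.

Square-well mechanics follow the standard impulsive rules: elastic
reflection at cores and walls; well entry adds the depth to the kinetic
energy along the line of centres; well exit succeeds only when the
radial kinetic energy exceeds the depth and otherwise reflects.  The
potential energy is bookkept (−1 per hydrogen bond, −depth per occupied
well) and audited against a from-scratch recomputation at a configurable
event interval, together with a hard-core overlap scan and a total
energy drift measure.  Between thermostat collisions the total energy is
conserved to floating-point roundoff (about 1e-18 eps_HB per event in
the test systems, far below the 1e-9 budget the suite asserts).

The Andersen thermostat arrives as a Poisson stream of ghost collisions:
at each ghost event one bead's velocity is resampled from the
Maxwell–Boltzmann distribution at T*.  The `simulation_config()` default
rate is 0.1 ghosts per bead per tau.  The package's own assembly runs
use a much weaker coupling, 0.002 (`assembly_proxy_config()`): at 0.1
the centre-of-mass motion of a whole chain decorrelates every few tau,
which makes inter-chain transport diffusive with a very small diffusion
constant and stretches the encounter stage of assembly far beyond any
practical event budget.  At 0.002 chains traverse the inter-chain
spacing nearly ballistically while the thermostat still holds the
time-averaged temperature at T* (the suite checks 2%).  This choice
trades thermostat stiffness for transport realism and is the single most
consequential run-condition decision in the package.

## System setup

`random_initial_configuration()` places chains in the extended reference
conformation with uniform random orientations and positions, rejecting
hard-core overlaps (minimum image) with a bounded retry budget, and
`init_velocities()` draws Maxwell–Boltzmann velocities, removes net
momentum and rescales to exactly T*.  Concentration and box edge
interconvert exactly through Avogadro's number: 192 chains in a 321.0 Å
cubic box are 9.64 mM, i.e. 10 mM at the precision usually quoted.

## Trajectory observables

*Hydrogen-bond map.*  The engine's live bond set, reported at residue
level; `hbond_geometry_ok()` audits each recorded bond against the
geometric criteria.

*Strand-pair classification.*  For a chain pair with at least two
hydrogen bonds, each bond gives a residue pairing (i on one chain, j on
the other).  Parallel pairs have constant j−i, antiparallel pairs
constant i+j; the orientation is whichever pattern has the smaller
variance (the pairing slope sign breaks exact ties).  The registry
offset is the median pairing offset — i+j−(n−1) for antiparallel, j−i
for parallel, 0-based — with half-integer medians truncated toward zero
so that edge fraying cannot flip an in-register pair.  Offset 0 is
in-register.

*Beta-sheet residue fraction.*  No residue-level secondary-structure
definition exists for this representation, so the package declares one:
a residue is beta iff its chain belongs to a classified pair (≥2 bonds)
and the residue lies within one sequence position of a residue donating
or accepting one of that pair's bonds.  This yields exactly 0% for a
monomer gas, ~100% for ideal lattices, and is insensitive to termini
conventions.  The published percentage-versus-time curves depend on the
(unstated) definition used there, so quantitative comparisons of
absolute percentages carry that caveat; trends and plateaus do not.

*Nearest sidechain contacts.*  For each chain, the nearest
other-chain sidechain bead to the focal residue's sidechain is counted
as a contact iff the pair sits inside its square well, falling back to
1.2× the contact distance for zero-depth pairs — wells are the
model-native notion of "contact".  In an ideal antiparallel in-register
lattice the modal partners are F19→F19 and F20→V18; parallel in-register
gives F20→F20.

*Clustering and layers.*  Chains sharing a hydrogen bond or an occupied
attractive sidechain well are joined; connected components are
oligomers.  A cluster's order parameter is the fraction of its
edge-connected chain pairs that are classified strand pairs.  Within a
cluster, the connected components of the hydrogen-bond-only subgraph are
the sheet layers (stacking contributes only sidechain-well edges), so a
four-layer fibril fixture reports exactly 4.

## The fixtures module

`build_sheet_fixture()` constructs ideal lattices in the four canonical
arrangements (parallel/antiparallel × in/out-of-register), with strands
4.9 Å apart, layers 9.9 Å apart (staggered 1.9 Å so aromatic sidechains
of adjacent layers share wells), and hydrogen-bond rungs alternating
sides along each strand so no donor or acceptor is used twice.  Each
fixture carries construction-time ground truth — per-pair orientation
and offset, per-residue beta labels, layer count, per-residue nearest
partners — which the analysis stage must reproduce exactly; this is the
primary oracle for the analysis code.  The lattices satisfy the engine's
bond walls and hydrogen-bond criteria by construction (spacing targets
are secondary), and a short low-temperature engine burst leaves their
bonds in place.

What the fixtures do **not** emulate: thermal disorder, partial registry
mixtures, amorphous aggregates, finite-temperature fraying.  Passing the
fixture oracle therefore certifies the classification logic, not the
realism of simulated ensembles.

The module also generates synthetic MS peak lists (theoretical fragments
plus seeded decoys and mass jitter) and synthetic ion-mobility calibrant
sets drawn from the power-law calibration relation, for the
interpretation layer below.

## Desk-scale assembly conditions

Full-scale runs (192 chains, 12 µs) are beyond a single-CPU desk budget,
so the package defines one scaled stand-in, `assembly_proxy_config()`:
24 chains of Ac-KLVFFAE-NH2 at 10 mM (box 158.5 Å) and T* = 0.193,
thermostat 0.002/bead/tau, 2.5e7 events (roughly 1.4e4 tau), snapshots
every 100 tau.  Two qualitative hallmarks of the full-scale kinetics are
checked on smoothed (10-snapshot block mean) series:

* `check_monotone_rise()` — the beta percentage starts below 5%, never
  drops more than 2 points between blocks, and rises by at least 15
  points overall;
* `check_two_phase_decay()` — the potential energy falls by at least
  10 eps_HB and the mean decay rate over the final quarter is below half
  the steepest block rate (fast collapse/nucleation, slow ordering).

The thresholds are package conventions chosen from the physics of a
~25-chain system (block noise of a few percentage points; a substantial
rise is tens of points), not fitted quantities.  Because nucleation at
this scale is stochastic, the suite requires 4 of 5 seeds to pass each
check rather than every seed.

## Cross-linking MS interpretation

The photo-induced cross-linking arm is pure arithmetic, kept exact:

* Masses come from element compositions (monoisotopic by default);
  every species' stored mass must match its composition to 1e-6 Da.
  The TFMD (trifluoromethyl-diazirine) modification adds C2N2F3 and
  removes one H; photolysis removes N2 per formed cross-link or water
  quench (+H2O).
* b/y fragments obey the complement identity b_k + y_(n−k) = M for
  every linear chain; for cross-linked dimers the fragment containing
  the link site carries the whole partner chain, and double
  fragmentation (one cleavage per chain) is enumerated with the two
  link-containing pieces joined.  Deeper fragmentation is combinatorial
  and not enumerated.
* Site assignment ranks candidate donor→acceptor pairs by explained
  peak count, then summed absolute error, at a ±0.2 Da matching
  tolerance.  The tolerance is deliberate: printed literature masses for
  these species sit ~0.15 Da above the theoretical monoisotopic values
  (their convention is unstated), so the package records exact
  theoretical masses and matches within the documented window rather
  than guessing the convention.
* The traveling-wave CCS calibration Ω = A·t_D^B·z·√(1/m_ion + 1/m_gas)
  is fitted by linear regression of log(Ω′) on log(t_D), with
  Ω′ = Ω/(z·√(1/m_ion + 1/m_gas)); drift times are assumed dead-time
  corrected upstream, and no instrument model is attempted.

## Numerical choices and degenerate inputs

Simultaneous events are ordered deterministically by (time, kind, bead
ids); identical seeds and configurations replay the event sequence
exactly.  Root finding uses the stable quadratic forms; a popped event
older than the clock by more than 1e-9 tau aborts the run as calendar
corruption.  A pair found marginally outside its outer wall (or inside
its inner wall) due to roundoff is scheduled for immediate reflection.
Wrong-sign executions (a "collision" with separating velocities, possible
only through roundoff) are no-ops that reschedule the pair.  Placement
failure after the retry cap, infeasible boxes, sub-minimal calibrant
sets, empty peak lists and inconsistent modification sites are all hard
errors with specific messages.

## Limitations

* The interaction table is an approximation with the documented
  qualitative structure; absolute rates and transition temperatures are
  not transferable to any published parameterization.
* Chains are semi-rigid extended strands; conformational entropy of the
  monomer is absent, which accelerates ordering relative to a flexible
  model.
* The beta-residue definition and contact cutoff are declared
  conventions; published curves using other definitions will differ in
  absolute values.
* The thermostat-rate choice trades Andersen stiffness for transport;
  dynamical observables (diffusion constants, absolute timescales)
  should not be interpreted quantitatively.
* No NPT ensemble, replica exchange, or real-temperature mapping.
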