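---
title: "Modelling the R1 spin-label side chain: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the R1 spin-label side chain: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the package models the MTSSL-labelled cysteine
(R1) side chain, why its defaults are what they are, and which parts of the
problem it deliberately does not model.

## The side-chain model

The R1 side chain is treated as rigid-geometry / flexible-dihedral: bond
lengths and angles are frozen at ideal values and only the five torsions
χ1–χ5 vary. This is the assumption both established prediction paradigms
make, and it is what allows a conformer to be identified with a point in
the 5-torus of χ angles. The internal-coordinate template lives in
`inst/extdata/r1a_topology.txt`: one line per atom beyond CB with its
reference triplet, bond length (Å), bond angle (°), and either a frozen
torsion or a `chi` marker. Atoms are placed by the standard
internal-to-Cartesian (NERF) step, and `measure_chi()` applies the same
sign convention (IUPAC: cis = 0°, positive clockwise viewed along the bond),
so build → measure round-trips are exact to numerical precision; the test
suite holds this to 1e-6° over a thousand random tuples.

Two conventions deserve explicit statement:

* **χ definitions.** χ1 = N-CA-CB-SG, χ2 = CA-CB-SG-SD, χ3 = CB-SG-SD-CE
  (the disulfide torsion), χ4 = SG-SD-CE-C3, χ5 = SD-CE-C3-C4. The fourth
  atom of χ5 differs between programs and libraries, so it is a parameter of
  `r1_topology()` and every ensemble, library and report carries the
  convention tag; `chi_deviation()` refuses to compare across mismatched
  tags.
* **Atom naming.** The side chain is written as residue `R1A` with atoms
  CB-SG-SD-CE linker and ring atoms C3, C4 (double bond), C5, N1, C9 with
  methyls C6/C7 on C5 and C8 on C9, and the N1-O1 nitroxide. This naming
  carries one methyl fewer than a fully tetramethylated pyrroline would; it
  is kept as the package's interchange contract, and since the label is
  heavy-atom rigid beyond the torsions it has no effect on χ measurement,
  clash statistics at the resolutions involved, or spin-center geometry.
  The planar five-ring's internal angles (116.3°, 100.9°, 110.1°) were
  solved once so that the implicit C9–C3 closure bond comes out at 1.51 Å.

## Clash model and the two predictors

Both predictors share one clash engine. A hard clash is a heavy-atom pair
closer than `scale` times the sum of Bondi-style van der Waals radii
(C 1.70, N 1.55, O 1.52, S 1.80, H 1.20, Cu 1.40 Å; overridable). The label
atoms entering the check are everything the torsions move (SG…O1); CB and
the backbone belong to the protein itself. The environment excludes the
labelled residue, hydrogens, and — by default — solvent and cryo-protectant
molecules, because neither prediction paradigm uses them; `include_solvent
= TRUE` restores them, which is exactly the kind of interaction (ordered
waters bridging the nitroxide to a neighbouring chain) that the contact
listing `contacts()` can reveal but the predictors ignore.

* **Accessible volume** (`sample_accessible_volume`): χ drawn uniformly on
  (−180, 180]⁵; a conformer is accepted if its clash count is at most
  `max_clashes` (default 5) at `scale = 0.75`. The loose scale plus a small
  clash allowance mirrors published accessible-volume practice: labelling a
  real protein perturbs the local side chains, so a zero-tolerance criterion
  would be too strict. Defaults: 200 accepted conformers, 50 000 trial
  budget. All accepted conformers carry equal weight; the acceptance
  fraction is recorded as the site's openness measure.
* **Rotamer placement** (`place_rotamers`): every library entry is built and
  reweighted by w_i = p_i · exp(−E_i / kT_eff). The soft clash energy is a
  quartic overlap penalty, E = Σ ε·max(0, scale·(r_i+r_j) − d)⁴ with
  ε = 1 kT_eff Å⁻⁴ — smooth, monotone in overlap, and zero exactly where
  the hard criterion sees no contact. The established tools do not publish
  a canonical functional form, so the package picks one and documents it;
  occupancies are relative, which is why kT_eff defaults to 1 arbitrary
  energy unit with `temperature_factor` as a pure scale. Entries whose hard
  clash count exceeds `hard_max_clashes` are discarded; the partition
  function is the sum of unnormalized weights over the survivors, equal to
  1 in the free-label limit (no environment ⇒ weights reproduce the priors
  exactly, which the tests assert).

Numerical edge cases are defined rather than left to chance: empty
ensembles (fully buried sites) are returned with a diagnostic instead of an
error so benchmark runs continue; ties in the zero-temperature limit go to
the whole minimum-energy shell (several rotamers are typically exactly
clash-free, so "the" minimum is a set); every ensemble records its seed,
and each sampling call owns a private RNG stream that leaves the caller's
`.Random.seed` untouched.

## Comparison metrics

All angle arithmetic is circular: differences are minimal signed
differences in (−180, 180], so 179° and −179° are 2° apart.
`chi_deviation()` ranks library entries by the max-over-angles circular
distance — the most conservative single-number summary, since one
badly-off torsion is enough to make a rotamer wrong.

The spin center is either the N1 atom or the N1–O1 midpoint; the midpoint
is the better stand-in for the delocalized unpaired electron and is the
default for prediction-vs-prediction comparisons, while N1 is the natural
choice against crystallographic coordinates (the deposited label's O1 is
sometimes less well ordered). One report always uses one rule, and names it.

`ensemble_distance()` returns both the distance between occupancy-weighted
mean positions (what the distance-vector analysis uses) and the full
weighted pair-distance histogram (weights w_i·w_j, default 0.5 Å bins) —
the PELDOR-like observable. `vector_angle_deviation()` quantifies the
finding that two predictions can agree on |r| while disagreeing
substantially on direction.

Surface areas use deterministic Shrake–Rupley quadrature: 960 golden-spiral
points per atom, probe 1.4 Å. Determinism was preferred over random point
sets so that areas are exactly reproducible; the suite checks the one- and
two-sphere analytic cases to better than 2 % and convergence (<1 % change on
doubling the point count) on a 40-atom fragment. Buried area is the
own-chain-context area minus the full-context area — the usual interface
bookkeeping, comparable to PISA's numbers only within ~10–15 % because
radii sets and algorithms differ.

## Crystal packing

In space group P1 the symmetry operators are the identity plus integer
lattice translations. `expand_packing()` converts to fractional
coordinates, enumerates translations out to a conservative bound from the
cell heights, and keeps every image chain with at least one atom within the
cutoff of the centre chain; image chains are tagged (`A+101`-style) and
deterministically remapped to single letters on writing. The benchmark
assembly builder runs this around every site, strips solvent (keeping metal
ions and R1 residues), and flags any site whose environment sphere
(default 10 Å) would include a lattice image that is *not* part of the
assembly — predictions at such truncated sites would see an artificially
open environment and are marked rather than silently reported.

## What the synthetic generator emulates — and what it does not

`make_helix()` builds ideal poly-alanine (φ = −57°, ψ = −47°, ω = 180°,
standard bond geometry, CB at the L-configuration improper of +122.5°); its
i→i+4 O…N distances land in the α-helical hydrogen-bonding band, which the
tests use as a geometric sanity check. `make_open_site()` plants an R1
conformer with known χ on the helix surface and guarantees it clash-free at
scale 0.9 — a deliberately stricter criterion than the predictors' 0.75, so
the planted truth is comfortably inside every acceptance region. The
default planted tuple (−60, 180, −60, 180, −90) sits at canonical rotamer
minima and was chosen once from the clash-free set of the canonical grid;
it is a feasibility choice of the generator, not a tuned quantity.

`make_tight_site()` adds a second helix by a deterministic grid search over
orientation (parallel or crossing), approach direction and outward offset;
candidate placements must approach the planted label to within
`occluder_gap` (default 3.5 Å, the closest approach that provably leaves
the planted conformer clash-free at 0.9) without touching it or
interpenetrating the first helix, and the search keeps the candidate that
sterically blocks the most conformers of the canonical χ grid. This is a
generator-internal score; the acceptance tests judge the result with the
independent brute-force clash oracle, so generator and oracle cannot share
a bug. The synthetic library (`make_synthetic_library`) draws χ1–χ3 from
von Mises mixtures at the canonical minima {−60, 60, 180}° (concentration
20 by default, ≈13° spread), and χ4/χ5 from broader mixtures
({−75, 75, 180}° at a quarter and {−90, 90}° at an eighth of the
concentration), with Dirichlet-uniform priors; the generating parameters
ride along in the metadata as planted ground truth.

What passing these tests shows: every pipeline stage — construction,
measurement, clash statistics, reweighting, distances, I/O — is internally
consistent and reproduces the qualitative regime distinction (tight sites
accept fewer random conformers, retain fewer rotamers, and defeat libraries
that lack the forced conformation). What it does not show: agreement with
any particular real protein. The helix has no tertiary structure, no
β-barrel, no copper site, no ordered solvent, and a single planted contact
instead of a real crystal form; quantitative claims about deposited
structures live exclusively in the acceptance checks that read the real
coordinate files.

## Numerical tolerances

* χ round trip pre-I/O: 1e-6° (pure float error).
* χ round trip through the PDB format: 0.2°, derived a priori from the
  fixed 3-decimal coordinate columns — ±5·10⁻⁴ Å per coordinate propagates
  to a worst-case ≈0.3° over the four atoms of a torsion with ~1.5 Å bonds,
  and the root-sum-square expectation is well under 0.1°.
* Kabsch RMSD vs the quaternion eigenvalue method: 1e-9 Å. The SVD
  implementation enforces a proper rotation (det = +1) and refuses
  underdetermined inputs (<3 points, collinear sets).
* SASA quadrature: <2 % against closed forms at 960 points/atom.

## Problem sizes

The shipped tests and the acceptance script run on 18–26-residue helices,
libraries of 25–200 entries (one 10 000-entry library for histogram-shape
checks), accessible-volume budgets of a few hundred to a few thousand
trials, and ten-seed replication for the open/tight ordering; these sizes
give stable statistics for every asserted property while keeping the whole
suite fast on a single core.

## Known limitations

* Only the R1 side chain; no RX/V1 or other label chemistries.
* No bond-length/angle relaxation, no hydrogen placement, no explicit
  solvent or cryo-protectant energetics — interactions with ordered waters
  are *observable* through `contacts()` but not modelled by either
  predictor, which is precisely the gap the benchmark design makes visible.
* General space-group operators are accepted from the input when present,
  but only P1 (identity + lattice translations) is exercised and required.
* Occupancies are relative; kT_eff has no absolute calibration.
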