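# spinlabelr

In silico spin labelling of protein structures with the MTSSL (R1) nitroxide
side chain, and a benchmark harness that asks the question practitioners
actually care about: not just *how far apart* two predicted labels are, but
whether the predicted **ensembles** resemble the conformations a label really
adopts in a crystalline protein environment.

## The problem

PELDOR/DEER spectroscopy measures nanometre distances between nitroxide spin
labels, but the R1 side chain dangles from the backbone through five
rotatable dihedrals (χ1–χ5), so converting a spin–spin distance into backbone
geometry requires predicting where the nitroxide sits. Two families of
predictors dominate:

* **accessible-volume approach** — draw χ1–χ5 uniformly at random, keep every
  sterically allowed conformer with equal weight;
* **rotamer approach** — place each member of a precomputed rotamer library
  (χ tuples with prior weights) and reweight by a Boltzmann factor of the
  clash energy with the environment,

  w_i = p_i · exp(−E_i / kT_eff),  Z = Σ w_i,

  where the partition function Z measures how much conformational freedom
  survives at a site.

Benchmarks keep finding that both deliver a similar ~3 Å distance error. This
package implements both paradigms over one clash engine, plus the full set of
comparison metrics — χ-angle statistics against a library (minimal circular
differences), occupancy-weighted mean spin positions, PELDOR-like pair
distance distributions, distance-vector angles, Shrake–Rupley
solvent-accessible and buried surface areas, and Ligplot-style contact
listings — so the ensemble-level reasons behind that plateau can be
reproduced and probed. A synthetic-data module generates idealized "open"
(solvent-exposed) and "tight" (crystal-contact) labelling sites with planted
ground-truth conformations, so the whole pipeline is testable without any
downloads.

## Worked example

```r
library(spinlabelr)

tight <- make_tight_site(seed = 1)        # helix + occluding second helix,
tight                                     # planted chi1..chi5 known exactly
#> synthetic tight site: chain A residue 9, planted chi (-60, 180, -60, 180, -90), occluder chain B

lib <- make_synthetic_library(200, seed = 2)
ens_av <- spin_label(tight$model, tight$site, "accessible_volume", seed = 1)
ens_av
#> label_ensemble [accessible_volume] at A/9: 200 conformer(s), p.f. 200, acceptance 0.292
ens_ro <- spin_label(tight$model, tight$site, "rotamer", library = lib)
ens_ro
#> label_ensemble [rotamer] at A/9: 54 conformer(s), p.f. 0.1962

chi_deviation(tight$planted_chi, lib)$max_abs_delta
#> 85.7   # degrees: no library rotamer is close to the environment-forced truth

ed <- ensemble_distance(ens_av, ens_ro)
ed$mean_position_distance                 # 1.25 A between the two methods' means
sasa(tight$model, list(chain = "A", resno = 9))
#> surface_report: total ASA 197.9 A^2, buried 89.1 A^2 (probe 1.4 A, 960 pts/atom)
```

Reading: at the tight site the sampler accepts only 29 % of random
conformers and the library loses three quarters of its rotamers (partition
function 0.20), yet the *nearest* surviving rotamer is still 86° away from
the planted truth in max-circular χ distance — the buried-conformation
failure mode in which a rotamer approach degenerates into an
accessible-volume approach. The two methods' occupancy-weighted mean spin
positions nevertheless agree to ~1 Å, illustrating how ensemble-level errors
can cancel in distance space.

`run_benchmark()` orchestrates the same analysis over many sites and
unordered site pairs (with optional P1 crystal-packing expansion via
`expand_packing()` to complete each label's environment) and writes
JSON + TSV reports. A command-line front end is installed as
`exec/spinlabelr` with subcommands `simulate`, `label`, `measure-chi`,
`distances` and `benchmark`.

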