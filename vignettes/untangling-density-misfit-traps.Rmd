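---
title: "Density-misfit barrier traps: the wE score, the toy refiner and the escape maneuvers"
author: "untangler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-misfit barrier traps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(untangler)
```

## The problem

A two-conformer (altloc) crystallographic model assigns each split atom's
two positions to conformer letters A and B. The average electron density is
blind to that assignment: exchanging the letters of any subset of split
groups leaves the model density unchanged. Geometry is not blind — cognate
bonds (A–A, B–B) connect atoms that move together, and a wrong assignment
leaves bonds strained. Yet refinement cannot repair a wrong assignment by
moving atoms, because the two alternate positions would have to pass
through each other, and the coincident intermediate fits the density badly.
The result is a *density-misfit barrier trap*: a local minimum of the joint
density-plus-geometry energy whose strain signature survives minimization.

`untangler` implements, at desk scale, the machinery this problem needs: a
weighted model-quality score (wE) that exposes traps, a real-space toy
refiner whose energy landscape actually contains them, four escape
maneuvers, and a synthetic fixture generator with a known ground truth
against which everything is validated.

## The statistical geometry energy and the wE score

Every geometry term is scored as a statistical energy
\[
E = \left(\frac{v - v_0}{\sigma}\right)^2,
\]
where $v$ is the value measured from the model, $v_0$ the library ideal and
$\sigma$ the spread observed in high-quality structures. Torsion
differences are wrapped to $(-180^\circ, 180^\circ]$ before division.
Restraint libraries are plain text (`inst/extdata/*.lib`); the bead-peptide
library defines the toy chemistry used by the generator, and a coarse
amino-acid library supplies topology and approximate ideals for real
residues.

The scalar score aggregates the absolute deviates $|d_i|$ of each
validation category (bonds, angles, torsions, clashes, and placeholders
for the remaining crystallographic categories) as
\[
wE \;=\; \sum_{\mathrm{cat}} \Big[\, \chi^2\,\langle E \rangle \;+\;
  \mathrm{softPnn}\;\mathrm{clip}(\max E) \,\Big] \;+\;
  \langle E_{\mathrm{LJ}} \rangle ,
\]
with three ingredients:

* **clip** — identity up to $E = 10$, then $10 + \log(1 + E - 10)$. The
  plateau keeps one extreme outlier from dominating trade-offs: repairing a
  6σ deviate to 3σ is favorable even if it pushes a 20σ outlier to 20.4σ,
  although the raw squared deviates say otherwise.
* **softPnn** — the weight on the clipped worst energy is the probability
  that the worst deviate is not noise: the chance that the largest of $n$
  standard-normal magnitudes stays below $d$, $(2\Phi(d)-1)^n$. A 6σ worst
  among 100 terms weighs 1; a 1σ worst weighs 0; the median of the max-of-n
  null distribution weighs exactly 0.5.
* **χ²-weight** — the weight on the mean energy is the chi-square CDF with
  $n$ degrees of freedom at $\sum d_i^2$: 1 when the observed distribution
  is far broader than the library σ values predict, 0 when far better, and
  exactly 0.5 at the null median.

The mean normalized Lennard-Jones energy over all conformer-compatible
nonbond pairs, $E(r) = (r_0/r)^{12} - 2 (r_0/r)^6 \ge -1$, enters
unweighted and unclipped; it is the only negative term, so $wE \ge -1$,
and the floor is attained by an ideally packed model. Because clipped worst
energies saturate near the knee, wE runs at roughly ten units per category
carrying a severe outlier. Probability-based categories (rotamer,
Ramachandran), when supplied, are first converted to equivalent normal
deviates via the two-sided tail probability (`probToDeviate`); they are
inactive for bead fixtures.

Empty categories contribute zero rather than NA, because synthetic
fixtures deliberately activate a subset of the roster. Whether the "both
weights are 0.5" calibration applies per weight kind or per category is
ambiguous in the source material; both weight kinds are calibrated at
their respective null medians here, which satisfies either reading.

## Density model and misfit

Model density is a sum of occupancy-weighted isotropic Gaussians with
variance $(B + B_{\mathrm{base}})/8\pi^2$ per coordinate
($B_{\mathrm{base}} = 10\,\mathrm{\AA}^2$) and integral equal to the
element's electron count. The misfit against a target grid is the
normalized sum of squared voxel differences,
\[
E_{\mathrm{dens}} = s \cdot \frac{\sum_v (\rho_m - \rho_t)^2}
                             {\sum_v \rho_t^2},
\]
with analytic coordinate gradients (verified against central differences
to $10^{-4}$ relative). This real-space least-squares target stands in for
reciprocal-space refinement: the traps are a density-*shape* phenomenon,
so no structure factors, bulk solvent or R factors are needed to produce
them, and none are computed. Whether maneuver effectiveness changes under
a reciprocal-space target with a free set is untested here and a known
limitation.

The scale $s = 2 \times 10^6$ is the package's standing balance between
density and geometry, chosen once from the trap physics: it makes the
barrier of a single displaced atom dominate a ~25σ bond strain at the
default weight ($w_x = 1$), while the weight-snap low phase
($w_x \times 0.01$) lets that strain win. It is the real-space analog of a
refinement program's X-ray weight and is exposed as
`refineConfig(densityScale = )`.

Difference maps are reported in units of their own standard deviation.
The generator's map noise is band-limited (white noise smoothed with a
0.5 Å Gaussian, rescaled), as experimental maps are. On grids of $10^4$ to
$10^5$ effective independent noise samples the expected maximum noise
excursion is ≈4.2σ (max-order statistic), so genuine features are judged
against that ceiling: a single deleted atom leaves a ~70σ peak.

## The toy refiner

`localRefine` minimizes
$T = w_x E_{\mathrm{dens}} + \sum E_{\mathrm{geom}} + \sum E_{\mathrm{LJ}}$
over all coordinates with conformer assignments, occupancies and B factors
fixed, using Barzilai–Borwein gradient descent with Armijo backtracking.
The minimizer is a contract, not an algorithm choice: any scheme would do
provided it is strictly monotone over accepted steps (asserted per
iteration in the tests) and deterministic (identical inputs give
bit-identical coordinates). Convergence is declared when the energy
decrease falls below `tol` ($10^{-4}$ by default; properties that compare
refined states to $10^{-6}$ wE use a tighter `tol`). Optional harmonic
anchors ($k\,|p - p_0|^2$) implement positional restraints for the pincer
maneuver.

`weightSnap` runs three refinements with $w_x$ multiplied by 100, 0.01 and
1. The factors are not prescribed by the phenomenology ("very high, then
very low"); 100/0.01 exceed the strain scales of every fixture and are
exposed as configuration.

## The synthetic fixtures and what they do (not) show

A fixture is a bead-peptide chain: residues of a three-atom backbone
analog (N, CA, C) plus one side-chain bead (CB), with bond, angle and LJ
restraints only — enough chemistry for trap physics, none of the
side-chain combinatorics. The ground truth displaces each residue's atoms
perpendicular to the chain plane by a smooth two-lobe amplitude profile
(peak separation `splitAmplitude`, default 0.7 Å at 10 residues; the
within-1σ contract bounds the amplitude–length ratio, so shorter test
chains use 0.6 Å): conformer A at $+u_i$, B at $-u_i$, every atom split at
occupancy 0.5. Because the position *sets* are symmetric, the correlated
("windshield wiper") and anti-correlated ("jumping jacks", sign flipped
beyond the low-amplitude hinge) assignments generate identical densities
— the gauge degeneracy that makes tangling possible — while both remain
within 1σ of ideal geometry.

Tangled starting models apply planted letter swaps and are then refined;
a fixture is only emitted if it is a genuine trap (refined wE strictly
above the truth's), with bounded seed-advancing retries otherwise.

One geometric fact shapes the trap taxonomy: the CB bead points out of the
chain plane, parallel to the displacement, so a single-atom swap stretches
its bond *first-order* — every localized trap in this chemistry is
high-strain (the 6σ-and-beyond outliers of the hardest localized
real-world traps). A low-strain localized trap of the kind caused by a
clash with a neighboring water cannot be realized without waters; the
low-strain analog here is the *hinge block swap* — the jumping-jacks
assignment planted on a windshield-wiper truth — whose border strain is
sub-σ yet which no coordinate refinement or weight schedule can release.
This is exactly the long-range trap phenomenology: localized scans and
weight snaps fail; only flipping the whole block at once escapes.

Passing tests on these fixtures therefore demonstrate the trap mechanism,
the score's ability to rank tangled against untangled states, and the
maneuvers' escape behavior — not performance on real crystallographic
data, which adds solvent, resolution limits, model incompleteness and
far richer chemistry.

Map noise defaults to 0.2% of the peak density. Under a plain
least-squares real-space target every voxel is weighted equally, so
percent-level noise (as a maximum-likelihood reciprocal-space target
tolerates) would be over-fitted at the calibrated density weight and
distort the refined geometry; 0.2% keeps the refined ground truth within
a fraction of a σ of ideal while still exercising difference-map
statistics.

## The escape maneuvers

All four maneuvers accept a move only if wE strictly decreases —
`minImprove` ($10^{-5}$) guards against counting numerical reproducibility
jitter (measured at $\le 5\times10^{-6}$ between gauge-equivalent refined
states) as improvement; genuine signals start two orders of magnitude
higher. wE, not the refiner's total energy, is the judge, mirroring its
role as the cross-program arbiter; total-energy acceptance would couple
the verdict to the refiner's weight.

* **swap-and-rerefine scan** (`swapScan`): trial-swaps each candidate
  group (or pair, arity 2, under a move budget rather than full pair
  enumeration), re-refines, and accepts the best strictly improving move
  of each sweep. Candidates are evaluated in order of decreasing per-atom
  strain. Best-improvement selection (rather than first-improvement)
  matters: accepting the first improving move can walk a planted
  single-swap fixture into the complement assignment, a genuine arity-1
  fixed point above the optimum, whereas the best move is the planted
  group itself. With best-improvement, the iterated scan reaches the
  exhaustive-enumeration optimum on every ≤8-group fixture tested.
* **rectified simulated annealing** (`rectifiedSA`): per (temperature,
  seed), Gaussian coordinate kicks of scale
  $0.012\sqrt{T}\,\mathrm{\AA}$, a refinement, then restoration of every
  atom whose per-atom energy (full energies of all terms containing the
  atom, plus its LJ pairs — not apportioned) worsened by more than 4 (a
  2σ-equivalent); re-refine, and keep the sweep only if wE dropped. The
  one-way valve guarantees the output never scores worse than the input.
* **pincer** (`pincer`): both members of a group are collapsed to their
  midpoint — the top of the density hill — and anchored there while the
  rest relaxes; releasing the anchors lets geometry pull each member down
  the correct side. Accepted under the same wE guard.
* **block-swap search** (`blockSwapSearch`): trial-flips all split groups
  inside contiguous residue windows and unions of adjacent windows, the
  only maneuver that releases long-range traps.

`tangleReport` scores every doubly-split covalent bond four ways — the
cognate pairings AA and BB and the non-cognate AB and BA, as statistical
bond-length energies — and flags bonds whose best non-cognate energy beats
their worst cognate energy. The four scores per bond are the bond-length
reading of the per-bond geometry scores used interactively in ensemble
GUIs; flags are gauge-invariant, cluster at planted swaps, and their
contrast grows when the model is first refined with a high density weight.
`downstreamAtoms` supports propagating a suggested swap toward the C
terminus (main chain before side chain, side chains ordered by bond
distance from CA — a convention this package fixes, since "downstream" has
no canonical definition at branch points), never across disulfides, and
ring closures are visited once, so traversal terminates.

## Numerical choices and degenerate inputs

* Colinear angles/torsions: deviate flagged NA, excluded with a warning.
* Coincident nonbonded atoms: an error (the LJ energy diverges).
* Occupancies absent from an input model default to 1/(number of
  conformer letters); non-positive B factors are replaced by 10 Ų.
* Split-group occupancy sums above 1 + 10⁻⁶ warn but do not error.
* Nonbond pairs: 5 Å cutoff, 1-2/1-3/1-4 excluded, blank↔lettered pairs
  allowed, A↔B pairs excluded (the density-symmetric representation);
  pair lists are built once per refinement, not updated mid-minimization.
* Clashes: nonbond overlap beyond a 0.4 Å margin, scored as the excess
  overlap per 0.1 Å, kept separate from the LJ term.
* Disulfides: SG–SG below 2.5 Å; bond topology otherwise comes from the
  library's residue templates, so no external dictionaries are needed.

## Problem sizes

The test suite and the validation studies run on 6-residue fixtures
(48 sites, 24 split groups, 0.4 Å grids) with 20 seeds per recovery study,
the oracle-equivalence check on 2-residue fixtures (8 split groups, all
256 assignments enumerated and refined), and the long-range trap on an
8-residue chain. These are the package's chosen desk-scale study
conditions; the generator accepts larger chains and finer grids.

## Known limitations

* The 11-category roster is fixed by name, but only bond, angle, torsion
  and clash are populated from geometry; rotamer/Ramachandran scoring
  requires externally supplied probabilities.
* The amino-acid library is coarse (element-context bond ideals, one
  generic angle); it supports topology, IO and tangle reports on real
  residues, not publication-grade validation.
* Real-space least-squares misfit only; no reciprocal-space target, free
  set, bulk solvent, anisotropic B or occupancy refinement.
* Bead chemistry cannot reproduce clash-mediated localized low-strain
  traps; the low-strain phenomenology is carried by the hinge block swap.
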