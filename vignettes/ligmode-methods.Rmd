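---
title: "Binding-mode and rotamer geometry analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binding-mode and rotamer geometry analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligmode)
```

## Scope and model

`ligmode` analyses the geometry of ligand binding-mode switching in MD
trajectories of ligand–receptor complexes, in particular the coupling
between an alkyl-chain dihedral of a classical cannabinoid and the χ1
rotamer of the receptor side chain at Ballesteros–Weinstein position
6.51. The analysis reduces each trajectory to a small set of per-frame
series:

* the **chain dihedral** over a configured quartet of ligand atoms
  (1–2–3–4 of the alkyl chain);
* the **χ1 dihedral** N–CA–CB–Cγ of a configured receptor residue;
* the **ligand heavy-atom RMSD** after receptor-only superposition;
* the **gate distance** from the terminal chain carbon(s) to the
  centroid of a configured aromatic ring.

Discrete states are then read off these series, and the central claim —
that the extended chain pose and the gauche+ rotamer go together — is
quantified as association statistics on the joint state table.

## Conventions and numerical choices

**Torsions.** All angles are degrees on the half-open interval
(−180°, 180°], with +180° preferred over −180°. The sign follows the
IUPAC right-hand convention (positive = clockwise rotation of the far
bond viewed from atom 2 toward atom 3), implemented by the atan2
cross/dot formulation. Central-bond atoms closer than 10⁻⁵ Å or
collinear bond triples raise a structured degenerate-geometry error
naming the frame. The test suite checks the kernel against an
independently coded oracle on 1000 random quartets (10⁻⁹ ° tolerance)
and under 100 random proper rigid transforms.

**Superposition and RMSD.** Kabsch superposition is the closed-form SVD
solution restricted to proper rotations (determinant +1); reflected
optima are folded back by flipping the smallest singular direction.
Ligand RMSD is computed after superposing each frame onto a reference
frame using receptor atoms only (default: all alpha-carbons outside the
ligand residue), then scoring the ligand atoms with no further fitting.
The reference defaults to the first frame — the initial docked pose —
because the upstream fitting protocol of published trajectory figures is
generally unstated; this choice is a package convention, recorded here,
and configurable via `reference_frame`. No mass weighting and no
periodic-boundary corrections are applied: inputs are assumed whole and
centred, which is what multi-model PDB exports of binding-site regions
look like in practice.

**Ring centroids and distances.** Ring centroids are unweighted
arithmetic means of the member atoms, the standard construction for
aromatic rings. Wherever a distance involves a multi-atom selection
(a dimethyl pair, leucine's two δ-carbons), the per-frame value is the
minimum over all pairs — the closest contact — so one rule covers every
pairing.

**State definitions.** The chain-mode split is purely by sign: negative
dihedral → `MINUS_AC` (L-shape), positive → `PLUS_AC` (I-shape). Exactly
0° is assigned `PLUS_AC` so the rule is total; the boundary has measure
zero for any continuous emission. Rotamer windows are the standard
120°-wide staggered windows centred on the canonical rotamers:
`GPLUS` on [−120°, 0°), `GMINUS` on [0°, 120°), `T` on the remaining
third wrapping the ±180° seam. The g− window is included for
completeness even though aliphatic side chains at this position
essentially never visit it; a tiling test sweeps the circle at 0.1°
steps to confirm the windows partition it exactly. No dwell-time
debouncing is applied: transitions are raw adjacent-frame label changes,
since any smoothing constant would be an analysis choice the caller
should make explicitly.

**Circular statistics.** Per-state angle summaries use the
resultant-vector method: the circular mean is
atan2(mean sin, mean cos) and the resultant length R ∈ [0, 1] measures
concentration. Histograms use equal-width circular bins over
(−180°, 180°] (default 72 bins = 5° width, a conventional resolution for
rotamer work); counts are conserved exactly, including at the seam.

**Association statistics.** The joint chain×rotamer table retains zero
cells over the full state alphabet. Cramér's V and mutual information
(bits) are computed from the empirical joint distribution after dropping
never-visited states (zero marginals), which carry no information. The
odds ratio is reported when that reduced table is 2×2, with the
Haldane–Anscombe +0.5 correction applied to all cells whenever any cell
is zero — trajectories commonly never visit one joint state, and the
corrected OR stays finite and comparable. Frames are treated as
exchangeable: no autocorrelation correction is applied, so these are
effect sizes, not significance tests. Block-bootstrap p-values were
deliberately left out; naive counting p-values on autocorrelated MD
frames are misleading.

**Distance gating.** For each chain state the package reports the
fraction of frames with gate distance below a threshold (default 5 Å,
the contact criterion separating the two binding modes) plus per-state
mean/min/max. States never visited report `NA`, not 0 — absence of
evidence is kept distinct from evidence of absence.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
not the physics that produces it:

* the chain state evolves as a two-state first-order Markov chain
  (default: symmetric, per-frame stay probability 0.99, started from the
  stationary law — for the default chain that is (½, ½));
* the rotamer copies the chain state with probability `p_couple` per
  frame (L-shape ↔ t, I-shape ↔ g+) and otherwise resamples from its
  marginal. The default `p_couple = 0.9` models strong but imperfect
  coupling — tight enough that the association statistics are clearly
  positive, loose enough that off-diagonal cells are populated, which is
  what side-chain/ligand coupling looks like in practice. Per-frame
  copying was chosen over a joint Markov chain because it is the
  simplest mechanism spanning independence (p = 0, matched marginals) to
  lockstep (p = 1), and no kinetic detail exists to justify more;
* angles are emitted von Mises around the state centres (−90°/+90° for
  the chain, 180°/−60° for χ1) with concentration κ = 8 (≈ 20° circular
  standard deviation, a realistic single-well width). The sampler is a
  self-contained Best–Fisher (1979) rejection sampler;
* the gate distance is Gaussian with state-dependent mean
  (7.0 Å in the L-shape, 4.0 Å in the I-shape, sd 0.5 Å). The means are
  generator conventions chosen to straddle the 5 Å criterion so that the
  gate analysis is exercised; they are not measurements;
* the CB2-like variant locks the chain in `MINUS_AC` (absorbing
  transition row), emulating a receptor whose pocket blocks the switch.

Replica r uses seed `seed + r − 1`, so a dataset is fully determined by
its parameter object; regeneration is byte-identical.

Coordinates are realised frame by frame with standard aliphatic internal
coordinates (1.53 Å bonds, 111° angles) via NeRF placement: a 4-atom
ligand chain carrying the chain dihedral, an N–CA–CB–CG quartet carrying
χ1, a regular 1.39 Å-radius hexagon placed so the terminal-carbon-to-
centroid distance equals the emitted distance exactly, and four static
non-coplanar alpha-carbons as a superposition scaffold. Construction
round-trips are exact to ~10⁻⁴ ° and ~10⁻⁴ Å through PDB's fixed
3-decimal columns.

What the generator does **not** emulate: excluded volume, full ligand
topology, membrane, solvent, kinetic roughness within wells, or
autocorrelated emission noise. Passing tests on synthetic data therefore
demonstrate that the *analysis* is correct — classification, counting,
geometry, statistics — not that any physical claim about a real receptor
is reproduced. Real trajectories additionally need a correct selection
config, and their effective sample size is far below the frame count.

## Problem sizes used in the test suite

The packaged checks run at sizes chosen to make their statistical
assertions sharp while staying quick on a laptop: kernel-vs-oracle
comparisons at 1000 random quartets; superposition optimality against
1000 random rigid transforms on 50-point clouds; parameter recovery over
20 seeds × 10⁴ frames (occupancy within 3 Monte-Carlo standard errors,
circular means within 2°); end-to-end closure through PDB at
3 replicas × 1000 frames (≥ 99% label agreement). The acceptance script
uses 1000 CB2-like frames for the distance-floor check.

## Known limitations

* Ballesteros–Weinstein mapping is configuration, not computation; a
  wrong map silently analyses the wrong residue (selection errors catch
  missing atoms, not mislabelled ones).
* No binary trajectory formats (XTC/TRR); conversion to multi-model PDB
  or XYZ is an upstream step. This is a documented extension point.
* Association statistics ignore frame autocorrelation (see above).
* χ2 and higher side-chain torsions are out of scope; only χ1 states are
  classified.
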