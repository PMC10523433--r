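# ligmode

Trajectory-geometry analysis of ligand binding-mode switching in
G-protein-coupled receptors.

## The problem

Classical cannabinoids such as THC carry a flexible alkyl chain whose pose
inside the cannabinoid receptor binding pocket can switch between two
binding modes: a bent **L-shape**, with the chain tucked into the cavity
between transmembrane helices 3 and 5, and an extended **I-shape**, with the
chain reaching into an intracellular cavity between helices 3 and 6. The
switch is carried by a single chain dihedral (atoms 1–2–3–4 of the chain)
moving between the *−anticlinal* well near −90° (L-shape) and the
*+anticlinal* well near +90° (I-shape), and it is gated by the side chain at
Ballesteros–Weinstein position 6.51: leucine (CB1R) can move from its
*trans* rotamer (χ1 = 180°) to *gauche+* (χ1 = −60°) and open the
intracellular cavity, while the β-branched valine (CB2R) cannot. The
geometric fingerprint of the switch is the distance from the terminal
methyl carbon of the chain to the centroid of the Phe<sup>3.36</sup>
aromatic ring, which crosses a 5 Å contact criterion in the I-shape and
stays above it when the chain is locked in the L-shape.

`ligmode` turns this analysis into a tested, reusable pipeline for anyone
working with MD trajectories of ligand–receptor complexes:

* **Geometry kernels** — signed IUPAC torsions (range (−180°, 180°],
  verified against an independent oracle), aromatic-ring centroids,
  minimum group-to-target distances, Kabsch superposition, and ligand
  heavy-atom RMSD after receptor-only fitting.
* **State classification** — chain dihedrals → `MINUS_AC`/`PLUS_AC`
  binding modes (split at 0°); χ1 → `T`/`GPLUS`/`GMINUS` rotamers
  (120°-wide staggered windows); occupancies, dwell times, transition
  counts, circular means, circular histograms and replica×time heatmap
  matrices.
* **Coupling statistics** — contingency tables of chain mode × rotamer
  state with odds ratio (Haldane–Anscombe corrected), Cramér's V and
  mutual information, plus distance gating against the 5 Å criterion.
* **Synthetic trajectories** — a coupled Markov / von Mises generator that
  emits matched angle and distance series, realises them as 3-D
  coordinates, and writes multi-model PDB + ground-truth labels, so the
  whole pipeline runs and is testable with no external data.

Everything is tibble-first: series are tidy tables
(`replica_id`, `frame`, `label`, `value`), summaries have `tidy()` /
`glance()` methods, and every result type has an `autoplot()` method.

## Worked example

Generate a CB1R-like synthetic trajectory (switching enabled), classify
both state series, and quantify their coupling:

```r
library(ligmode)

params <- synthetic_params(n_frames = 1000, n_replicas = 3, seed = 42)
series <- simulate_series(params)
built  <- series_to_coordinates(series)

fr   <- built$frames[[1]]      # replica 1
spec <- built$selection

chain   <- classify_chain_mode(
  torsion_series(fr, resolve_selection(fr, spec, "ligand_quartet")))
rotamer <- classify_rotamer(
  torsion_series(fr, resolve_selection(fr, spec, "6.51")))

tidy(summarize_states(chain))
#> # A tibble: 2 × 6
#>   state    n_frames occupancy mean_dwell circular_mean circular_resultant
#>   <chr>       <int>     <dbl>      <dbl>         <dbl>              <dbl>
#> 1 MINUS_AC      662     0.662      132.          -90.6              0.934
#> 2 PLUS_AC       338     0.338       67.6          89.4              0.946

gate <- min_distance_series(
  fr, resolve_selection(fr, spec, "ligand_terminal_atoms"),
  ring_centroid(fr, resolve_selection(fr, spec, "ring_atoms")))

state_coupling(chain, rotamer, distances = gate, threshold = 5)
#> <coupling_summary> 1000 frames
#>            T GPLUS GMINUS
#> MINUS_AC 624    36      2
#> PLUS_AC   14   324      0
#> odds ratio NA | Cramer's V 0.891 | MI 0.657 bits
#> distance gate at 5 Angstrom:
#> # A tibble: 2 × 6
#>   state        n below_threshold_fraction  mean   min   max
#>   <chr>    <int>                    <dbl> <dbl> <dbl> <dbl>
#> 1 MINUS_AC   662                    0      6.99  5.43  8.51
#> 2 PLUS_AC    338                    0.973  4.02  2.63  5.30
```

Reading: the chain spends 66% of frames in the L-shape and 34% in the
I-shape; the rotamer tracks it tightly (Cramér's V 0.89, 0.66 bits of
mutual information; the odds ratio is undefined here because a handful of
frames leak into the never-modelled g− window, making the visited table
2×3). The distance gate separates cleanly: no L-shape frame dips below
5 Å, while 97% of I-shape frames do.

For real data, point `run_analysis()` at multi-model PDB trajectories
(one file per replica) and a YAML selection config mapping
Ballesteros–Weinstein positions and ligand atom names:

```r
run_analysis(list(
  replicas  = c("rep1.pdb", "rep2.pdb", "rep3.pdb"),
  selection = "selection.yaml",
  analyses  = c("rmsd", "chain_mode", "rotamer", "distances", "coupling"),
  threshold = 5, output_dir = "results/"
))
```

which writes per-replica series CSVs, pooled state summaries, heatmap and
histogram matrices, and the coupling JSON. A thin CLI wrapper lives at
`inst/scripts/ligmode-cli.R`.

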