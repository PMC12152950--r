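---
title: "Methods: active-learning-guided alchemical free energy workflows"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the workflow

`alfe` implements the computational core of a hit-optimization campaign that
couples alchemical **relative binding free energy (RBFE)** calculations with
**active learning (AL)**: analog libraries are filtered by substructure and
docking criteria, a thermodynamic-integration (TI) engine turns gradient time
series into RBFEs under on-the-fly convergence control, a perturbation map
anchors those RBFEs to absolute binding free energies (ABFEs), and an AutoML
surrogate model iteratively selects which molecules to simulate next.

The expensive physics engines are deliberately out of scope. Molecular
dynamics and docking enter only through their *outputs* — dU/dλ time series
and pose score tables — so every stage of the workflow is testable at desk
scale against synthetic inputs with known ground truth. The package therefore
ships a first-class synthetic-data module rather than example files.

# Library filtering

Libraries are plain data frames of molecule records (id, canonical isomeric
SMILES, net formal charge, Murcko scaffold, provenance tag). Chemistry is
delegated to OpenBabel via ChemmineR/ChemmineOB: canonicalization, SMARTS
matching, 3D structure generation and the native ECFP6 hashing. Net formal
charge is read from the InChI `/q` and `/p` layers, which treats zwitterions
as net-neutral — the intended semantics of a "remove charged molecules"
hygiene filter.

Two conventions worth noting:

* **Murcko scaffolds** are computed by iterative leaf pruning of the
  heavy-atom graph (which leaves exactly the rings plus inter-ring linkers),
  then re-attaching atoms joined by double bonds to the retained core — the
  usual Bemis–Murcko treatment of exocyclic carbonyls. Acyclic molecules have
  the empty scaffold.
* **Tanimoto distance** between two all-zero fingerprints is defined as 0
  (identical objects). Nearest-neighbor ties are broken by pool order, making
  searches reproducible.

Fingerprints come in five kinds. `ecfp6_2048` folds OpenBabel's 4096-bit
ECFP6 to 2048 bits by OR-ing the halves. `path7_2048` (linear paths up to 7
bonds), `ph4_2d_1024` / `ph4_3d_1024` (pharmacophore feature pairs binned by
topological or Euclidean distance) and `e3fp_default` (iterative 3D shells,
1024 bits) are implemented in-package on the molecular graph, because no
installed R package provides them at these lengths. Bit positions come from a
deterministic string hash; bit-identity with other toolkits is *not* promised,
only within-toolkit determinism — models and similarity searches only require
self-consistent features. The 3D kinds use OpenBabel's structure generation,
which is deterministic for a given input SMILES; molecules whose embedding
fails are skipped and reported rather than crashing the featurization.

# Docking-pose filter cascades

`best_pose_per_molecule` selects the pose minimizing the configured RMSD
(ties: better docking score, then lower pose id). The two cascade stages
retain molecules with `rmsd_indole <= 5` Å and score `<= -6` (template-free
stage), and `rmsd_murcko <= 4` Å, score `<= -6`, clash `<= 0.5` (template
stage). All thresholds are **inclusive**, reading the protocol's "≤"
literally, and are configuration values, not hard-coded chemistry: the
"indole-like" substructure that defines the first RMSD is supplied as a
SMARTS pattern.

RMSD values to a template or to a trajectory-average structure are computed
**without superposition**: docked poses and MD frames share one receptor
frame, so fitting would hide exactly the displacement being measured.
`representative_frame` discards a leading fraction of frames (default 0.1,
mirroring the discard of early production MD), averages ligand heavy atoms
and protein Cα atoms over the retained window, and returns the retained frame
closest to that average; ties go to the earliest frame. Indices are 1-based
throughout, as in R.

Atom mappings for alchemical topologies (`map_atoms`) are maximum common
substructures constrained so mapped heavy atoms lie within `dmax = 1.1` Å.
The search is an exact branch-and-bound over candidate atom pairs (element-
and bond-order-matched, connected growth, include/exclude branching with an
upper-bound prune and a 60 s timeout). The distance constraint keeps the
candidate set so small that exact search is practical at ligand size. An
empty mapping is a legitimate result signalling a fully decoupled
transformation.

# The TI engine

The λ-schedule is the n-point Gauss–Legendre rule mapped to [0, 1]
(default n = 9), so `integrate_leg` is a weighted sum whose weights add to 1
and which integrates polynomial mean-gradient curves of degree ≤ 17 exactly.
Leg standard errors propagate as `sqrt(sum(w_i^2 s_i^2))` and
`ddG = dG_complex − dG_solvent`.

Per window, the analysis chain is:

1. **Equilibration detection** (`detect_equilibration`): scan candidate
   truncation points t₀ on a 50-point grid (a denser grid is available via
   `n_grid`); for each, estimate the statistical inefficiency
   `g = 1 + 2 Σ (1 − t/N) ρ(t)` of the remaining samples, summing the
   autocorrelation until its first non-positive value; keep the t₀ maximizing
   the effective sample size `(N − t₀)/g`. The autocorrelation is computed by
   FFT, so the scan is cheap even for 10⁴-sample windows. Constant series are
   a defined degenerate case: `(t0 = 0, g = 1, n_eff = N)`.
2. **Decorrelation** (`subsample_decorrelated`): thin the equilibrated
   region with stride `ceiling(g)`.
3. **Convergence test** (`window_converged`): split the decorrelated samples
   into chronological halves and compare them by Jensen–Shannon distance on a
   shared equal-width binning; converged iff the distance is ≤ the criterion
   (default 0.1). Base-2 logarithms bound the distance by 1, making the
   criterion scale-free.
4. **Extension policy** (`extend_policy` / `run_window_protocol`): accept a
   converged window; otherwise request exactly one increment (defaults
   2.5 ns initial + 0.5 ns increments; the `fast` preset is 1.0/0.25) while
   the budget allows, else give up and carry the unconverged flag into the
   transformation result.
5. **Replicate pooling** (`combine_replicates`): each replicate is
   equilibrated and decorrelated independently, then all decorrelated values
   are pooled; the window mean is the pooled mean and its standard error is
   `sd/sqrt(n_pooled)`.

Two numerical choices deserve justification. First, the JS histogram bin
count: an empirical JS distance between two samples of the *same*
distribution is biased upward by roughly `sqrt(B / (4 n ln 2))` for `B` bins
and `n` independent points per half. Bin counts that grow like `sqrt(N)`
would hold the distance above 0.1 for any window short of ~10⁵ independent
samples, so no realistic window could ever converge. The test therefore (a)
runs on the *decorrelated* halves, since autocorrelation inflates the
effective bias the same way, and (b) uses a cube-root bin count
(minimum 4). At the default window lengths this leaves windows a realistic
path to acceptance (typically after 0–6 extensions at the synthetic noise
levels) while retaining power: a mean drift of one standard deviation between
halves produces distances well above 0.1. `js_distance` called directly (not
through the convergence test) defaults to Sturges bins.

Second, the maximum total length per window before giving up has no
protocol-blessed value; it is exposed as `max_total` in the configuration and
defaults to 10 ns.

# Perturbation-map thermodynamics

A perturbation map is a directed graph of `reference → target` edges
carrying ΔΔG with standard errors. `to_abfe` anchors each connected
component at reference ligands with known absolute ΔG (e.g. experimentally
measured hits) and converts by signed path sums — edges traversed against
their direction contribute `−ΔΔG` — with errors in quadrature. When a
component holds several anchors, the nearest (fewest edges) wins and
disagreements beyond 3σ raise a warning; the package reports discrepancies
rather than averaging, because campaign maps are trees and a least-squares
re-fit would be spurious sophistication. `cycle_closure` reports the signed
sum around each independent cycle (one per non-tree edge of a spanning
forest) — zero on thermodynamically consistent maps, empty on trees.

KD ↔ ΔG conversion uses `ΔG = RT ln(KD / 1 M)` with
`R = 1.987204e-3 kcal/(mol K)` at 298 K (a 25 °C assay temperature); the
18 µM → −6.5 and 230 µM → −5.0 kcal/mol endpoints confirm the temperature
choice within rounding.

# The AutoML active-learning loop

Each iteration trains surrogate models on all molecules with ABFE labels,
over a grid of (fingerprint representation × algorithm) cells. Algorithms:

* `linear_regression` — kernel ridge with a scaled linear kernel plus a
  constant term; the default near-zero ridge makes it the minimum-norm
  least-squares fit when features outnumber molecules, and `lambda = 1`
  provides the regularized grid point.
* `random_forest` — `randomForest`, grid over `ntree` {100, 500} and
  `nodesize` {1, 5} (depth control is expressed through `nodesize` in this
  implementation).
* `gp_tanimoto` — Gaussian-process regression with the Tanimoto kernel on
  binary fingerprints (plus the same constant kernel term, which absorbs the
  label mean so the zero-mean GP is well specified without ad hoc centering),
  noise grid {1e-4, 1e-2, 1e-1}.

Hyperparameters are tuned per cell by an inner 5-fold cross-validation grid
search; the tuned cell is then scored by **leave-one-out R²**, and the argmax
cell (ties: first in declared grid order) is refit on all data. For the
kernel models the LOOCV predictions use the exact closed form
`y_i − [K⁻¹y]_i / [K⁻¹]_ii`, which the test suite verifies against an
explicit refit loop; random forests are refit explicitly. A zero-variance
label set yields the `-Inf` sentinel so a degenerate cell can never win.

Acquisition is pure greedy exploitation — the batch with the most negative
predicted ΔG, ties broken lexicographically by id — matching a campaign that
harvests predicted binders rather than exploring uncertainty. The loop never
queries the oracle twice for one id; failed oracle calls (NA labels) are
recorded and not retried, mirroring failed MD runs. A scope mechanism
restricts training and screening to one analog series for the early
iterations and opens the full pool at a configured iteration, as when a
second hit series joins only the final round. Batch sizes per iteration are
configuration (the default is 7 × 20).

Final experimental candidates (`select_candidates`) combine `greedy_n`
most-negative picks with `diverse_n` diversity picks chosen by max–min
Tanimoto distance among molecules passing an eligibility predicate (default:
negative ΔG), seeded with the most negative eligible molecule — the
70 + 5 = 75 budget split is the default. `project_chemical_space` provides
the 2D t-SNE reporting view; it is an exact O(n²) implementation on Tanimoto
dissimilarities (no R t-SNE package is available in the supported
environment), deterministic under its seed, and used for reporting only.

# The synthetic data model

The generator defines the study conditions under which the workflow is
validated:

* **Affinity landscape**: additive group contributions. A molecule's true
  ΔG is a scaffold base value plus one term per substituent, plus Gaussian
  noise from a per-molecule seeded stream (default 0.5 kcal/mol, comparable
  to a TI standard error; the pipeline emulates TI noise at 0.4 kcal/mol).
  Additivity matches how medicinal-chemistry SAR is reasoned about and gives
  the surrogates learnable structure without trivializing the task — the
  fingerprints do not encode the substituent table directly.
* **Analog enumeration**: scaffolds with `{R1}`-style attachment
  placeholders and per-site fragment alphabets; products are validated and
  canonicalized, and sampling beyond `n_max` is seeded. The default campaign
  enumerates two hit-like series (an indole-2-carbonyl
  tetrahydroisoquinoline, 576 analogs, and a quinoline-2-carbonyl piperidine,
  432 analogs — about a thousand molecules in total, which keeps a full
  pipeline run in the minutes range on one CPU).
* **Mock docking**: three poses per molecule; the docking score is an affine
  function of true ΔG plus optional noise (so noiseless scores preserve the
  affinity ranking); a seeded fraction of molecules receives best-pose
  geometry inside the filter thresholds, the rest outside, with fields
  failing independently so the two cascade stages prune different subsets.
* **Gradient series**: per window, a polynomial mean-gradient curve whose
  Gauss–Legendre quadrature equals the requested leg free energy *by
  construction* (the constant coefficient absorbs the difference), plus
  stationary AR(1) noise (default sd 1.5 kcal/mol, correlation time 3
  samples at 1 ps per sample) and an optional exponentially decaying
  transient (amplitude in kcal/mol, e-folding time as a fraction of the
  series) to exercise equilibration detection.

What passing synthetic tests does and does not show: the suite demonstrates
that the estimator mathematics, convergence control, bookkeeping and
acquisition logic are correct under the stated statistical assumptions
(short-memory AR(1) gradients, additive SAR). It does not validate force
fields, docking accuracy, conformational sampling, or the realism of any
chemistry — real gradient series have fatter tails and slower modes, and real
SAR is only locally additive.

# Problem sizes and determinism

Default validation sizes are chosen to exercise the statistics meaningfully
on a single CPU: 200 synthetic transformations (two 9-window legs, 2500
samples per window) for TI recovery, 50 seeded series for the equilibration
oracle, and 10 seeded AL campaigns (1000-molecule pool, 50 pre-AL labels,
7 × 20 acquisitions) against random-selection baselines. Every stochastic
step draws from an explicit seed; reruns with one seed are bit-identical, and
the acceptance script threads its `--seed` argument through all of them.

# Known limitations

* Fingerprint bits are OpenBabel-/package-hashed; models trained here cannot
  be transplanted onto RDKit-featurized data bit-for-bit.
* The MCS search is exact but exponential in the worst case; it relies on
  the 1.1 Å distance constraint (and the timeout) to stay fast, and has no
  ring-matching heuristics beyond element/bond-order compatibility.
* `to_abfe` assumes anchors are trustworthy constants; anchor uncertainty is
  not propagated.
* The AL loop models no per-molecule cost: the budget is a count, not
  dollars.
* Convergence flags are conservative for short, strongly autocorrelated
  windows; the extension protocol, not the flag on a fixed-length series, is
  the intended acceptance path.
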