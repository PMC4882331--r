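---
title: "Comparative conformational dynamics: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative conformational dynamics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polconf)
```

## The problem

A-family DNA polymerases such as the *Bacillus stearothermophilus* large
fragment (a Klenow-fragment homolog) select the incoming nucleotide through a
large-scale motion of the fingers subdomain: an open state binds substrate, a
partially-closed ("ajar") state acts as a fidelity checkpoint, and a fully
closed state assembles the catalytic site. Crystal structures sample the
endpoints of this transition; molecular-dynamics trajectories sample the path
between them; and fidelity-modulating mutations (e.g. at the nucleotide-sensing
positions of the O/O1 helices) shift the equilibrium. `polconf` implements the
analyses used to compare such states quantitatively: interconformer PCA with
trajectory projection, distance-fluctuation (coordination propensity)
matrices, local flexibility profiles, the multidomain Energy Decomposition
Method (EDM), and FRET-proxy probe distances — plus synthetic generators with
planted ground truth so every stage is testable without multi-microsecond
trajectories.

## The statistics

**Interconformer PCA.** Conformers are reduced to Cα coordinates, masked to
alignment-shared residues, and iteratively superposed onto their mean. The
`3N × 3N` population covariance of the flattened coordinates,
`C_ij = <(r_i − <r_i>)(r_j − <r_j>)>`, is diagonalised; eigenvalues are the
variances (Å²) along each principal component and eigenvalue/trace is the
variance fraction. Trajectory frames are projected onto the *crystal-ensemble*
model (not a trajectory-fitted one), so simulation frames are placed in the
conformational space defined by the experimental structures.

**Coordination propensity.** The distance-fluctuation matrix
`A_ij = <(d_ij − <d_ij>)²>` is the time variance of the Cα *i–j* distance.
It needs no superposition — pairwise distances are rigid-motion invariant —
and low values mark residue pairs moving as one mechanical unit. Block
averages over a domain labelling (`block_coordination()`) summarise
within- versus between-domain rigidity.

**Local flexibility.** `p(i) = Σ_j A_ij f(<d_ij>)` with *j* restricted to the
sequence window `i ± 4` (truncated at the termini, no wraparound) reports
local deformability. The weight *f* is not fixed by the statistic's
definition; we default to `f ≡ 1` and expose `f(d) = 1/d²` as an alternative,
recording the choice in the output metadata.

**Energy Decomposition Method.** The `N × N` matrix *M* of average
inter-residue nonbonded energies (Coulomb + Lennard-Jones with
Lorentz–Berthelot combination, `k_e = 332.0636 kcal·Å/(mol·e²)`, intra-residue
pairs excluded, no cutoff by default) is eigen-decomposed. For a single
cooperative folding unit the most negative eigenpair dominates:
`m_ij ≈ λ₁ w_i1 w_j1`. For multidomain proteins a small *essential* set of
negative-eigenvalue eigenvectors is selected so that their significant
components — `|w_ik| > 1/√N`, the flat-vector reference at which every residue
would contribute equally — jointly cover the residues with minimal redundancy.
The low-rank reconstruction `Σ_k λ_k v_k v_kᵀ` over that set (the essential
folding matrix) is binarised ("symbolized") and its connected components are
the energetic domains. Column sums of *M* give the per-residue stabilization
profile; residues more negative than the profile mean are the stabilization
hotspots.

**Regulatory residues and probes.** Hotspots of two states are combined with
the flexibility difference `Δp = p_closed − p_open`: a residue is nominated
when it is a hotspot in either state *and* its Cα lies within a contact cutoff
of a residue whose `|Δp|` is in the top decile. Cα–Cα distances between two
labelled residues over time (`probe_distance_series()`) proxy the FRET
dye-pair readout of fingers opening/closing, classified by the sign of the
ordinary least-squares slope.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window` | 4 | residues | sequence half-width of `p(i)` |
| `weight_fn` | `"uniform"` | — | distance weight *f* in `p(i)` |
| `coverage_target` | 0.9 | fraction | stop when this share of residues is covered |
| `min_gain` | 5 | residues | smallest useful addition per eigenvector |
| `jaccard_max` | 0.25 | — | redundancy cap against already-covered residues |
| `symbolize_rule` | `"mean-negative"` | — | threshold at the mean of negative entries |
| `min_domain_size` | 5 | residues | components below this stay "unassigned" |
| `contact_cutoff` | 8 | Å | Cα–Cα contact for hotspot/flexibility overlap |
| `flex_quantile` | 0.9 | — | "significantly different flexibility" threshold |

The essential-selection rule (greedy maximum coverage under a Jaccard
redundancy cap) operationalises "smallest set, minimum redundancy"; its three
parameters are exposed and logged because reasonable variants exist. The
symbolization threshold uses ≤ (not <) the mean of the negative entries so
that a matrix with a single attractive entry symbolizes that entry. On real
polymerase-scale systems the defaults need not select exactly the same number
of essential eigenvectors as any particular published analysis.

## Numerical choices

- **Population (1/m) covariance and variance** throughout, for both `C` and
  `A`. The choice rescales eigenvalues, never variance fractions; it is fixed
  for reproducibility.
- **Sign conventions.** Every eigenvector's largest-magnitude entry is made
  positive, so projections and profiles are reproducible across linear-algebra
  backends.
- **Superposition** is Kabsch least-squares restricted to proper rotations
  (det +1): a mirror image cannot reach RMSD 0. All-collinear coordinate sets
  are rejected. The iterative mean converges when the mean moves < 1e−6 Å
  (max 50 iterations, warning on non-convergence), and the converged mean is
  put in a canonical pose (centroid at origin, principal axes along the
  coordinate axes) so results do not depend on the input's global pose.
- **Shared residues** come from pairwise global alignment with identity
  scoring (match +1, mismatch 0, gap −1) against the longest sequence,
  tie-broken lexicographically so the mask is input-order invariant. A
  pairwise alignment with zero identical columns means there is no alignable
  core and is an error: with identity scoring, unrelated equal-length
  sequences would otherwise "align" mismatch-to-mismatch.
- **Degenerate spectra.** Exactly equal-sized noise-free energy blocks have
  degenerate block eigenvalues whose eigenvectors mix across blocks; any
  noise, or unequal sizes, breaks the degeneracy. Numerically-zero
  eigenvalues are never candidates for the essential set.
- **Null behaviour of essential selection.** Eigenvectors of pure-noise
  matrices are delocalised (roughly a third of components exceed the `1/√N`
  reference), so depending on size and seed the greedy either stops early by
  `min_gain` — with a recorded warning — or accumulates several delocalised
  vectors to reach the coverage target. Either way no one-block structure
  exists to find, which is what the domain tests verify.
- **Connected components** (not spectral or hierarchical clustering) define
  domains: deterministic and parameter-light, at the documented price that a
  single spurious bridge merges two blocks.

## The synthetic generators

`synthetic_spec()` fixes the study conditions; the generators emulate three
data classes:

- `gen_basin_ensemble()` — multi-basin crystal-ensemble stand-ins: a coarse
  self-avoiding Cα chain (3.8 Å spacing, 4 Å excluded volume) whose second
  domain rotates about a hinge axis to angles drawn around each basin center
  (degrees), plus isotropic coordinate noise. Ground truth: basin memberships,
  angles, and the noiseless basin-center structures.
- `gen_hinge_trajectory()` — rigid two-unit hinge motion (closing, opening, or
  two-state switching); the rotation sense is chosen so that "closing" shrinks
  the inter-domain centroid distance, guaranteeing the labelled trend. Ground
  truth: domain labels, angle schedule, and a suggested probe pair.
- `gen_energy_matrix()` — block-structured attractive matrices: within-domain
  entries around −`energy_block_strength`, hotspot columns/rows shifted by
  −`hotspot_strength` (hotspot–hotspot pairs shifted once), symmetric Gaussian
  noise, zero diagonal. Ground truth: domain labels and hotspot indices.

Hinge amplitudes and basin centers are angles in degrees — a rigid rotation is
naturally parameterized by its angle, and displacement in Å follows as angle
times lever arm. Each generator draws from one RNG stream seeded by
`spec$seed` without touching the global state; identical spec and seed give
identical output, and `write_ground_truth()` emits the planted structure as a
sidecar so tests never re-derive it.

What the generators deliberately do **not** emulate: force-field energetics,
solvent, sequence realism, anharmonic multi-pathway transitions, or the
correlation structure of real thermal fluctuations. Passing the synthetic
recovery suite therefore shows the *estimators* are correct and robust at the
planted signal-to-noise, not that any particular biological system will show
such clean structure.

## Problem sizes

The test and acceptance runs use 20–100-residue systems, 10–50
frames/conformers, and 20-seed replications: large enough for the asymptotic
behaviour of the statistics (delocalisation, coverage, ARI) to be
representative, small enough that the full suite completes in well under a
minute of eigen-decompositions. The same code path handles real
polymerase-scale inputs (~580 residues) unchanged; only the inputs grow.

## Applying the pipeline to real ensembles

The analyses accept standard inputs: multi-model PDB files
(`read_conformers()`), the plain-text trajectory format
(`read_trajectory()`), and externally computed residue-pair energy matrices
as labelled TSV (`read_matrix_tsv()`), bypassing `pair_energy_matrix()` when
an MD package has already computed the averages. For a crystal-structure
homolog set (such as the ~90 experimental Klenow-fragment-family structures
retrievable from the PDB), the chain is
`read_conformers() |> align_shared() |> conformer_pca()`, after which
trajectory frames project onto the leading components with `project()`. On
such sets the first two components are expected to capture most of the
variance (the fingers-closure and fingers-on-DNA motions); reproducing that
requires downloading the structures and is not part of the offline test
suite.

## Known limitations

- Cα-only throughout: no side-chain flexibility, no all-atom RMSD fitting.
- No bonded/1-4 exclusion bookkeeping in `pair_energy_matrix()` beyond
  excluding intra-residue pairs; supply externally computed matrices when
  force-field-grade exclusions matter.
- Domain identification inherits the connectivity definition's
  bridge-merging behaviour.
- Probe distances are raw Cα–Cα proxies: no FRET efficiency model, R₀ or
  dye-linker geometry.
- Cross-species residue-numbering maps (e.g. Klenow versus Bst numbering of
  the FRET pair) are the user's responsibility; labels are treated as opaque.
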