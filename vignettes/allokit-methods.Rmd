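---
title: "Methods: quantifying serpin allosteric activation with allokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying serpin allosteric activation with allokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allokit)
```

Antithrombin circulates in a repressed native conformation (R) whose
reactive center loop and exosite are poorly available to coagulation
proteases; binding of the heparin pentasaccharide flips it to an activated
conformation (A/AH) with a ~10³-fold higher association rate toward factor
Xa. `allokit` packages the quantitative steps of dissecting that switch:
which residues move, how much a mutation activates, whether residues act
cooperatively, how stability and fluorescence shift, and how dynamics change
in simulation. This vignette documents the models, the parameters that
matter, and the design choices made where conventions genuinely diverge.

## Structure comparison and the distal-carbon convention

Two conformers are compared after an **iteratively trimmed Kabsch
superposition** of backbone atoms. We use N, CA, C as the backbone set
(carbonyl O optional, off by default): it is the minimal unambiguous
definition of "backbone atoms". Each cycle performs a closed-form SVD least
squares fit, then drops atom pairs deviating more than `trim_sigma` (default
2.0) standard deviations above the mean deviation; iteration stops when the
retained set is stable or after `max_cycles` (default 5). Repeated trimmed
alignment is the standard way of reaching the minimal RMSD for a pair of
conformers that differ by genuine local rearrangements; since the exact
trimming schedule used in any published overlay is rarely stated, both knobs
are exposed and the retained-pair set is reported in the result so an
overlay is reproducible from its metadata.

Per-residue conformational change is summarized by the displacement of the
**most distal side-chain carbon**: the side-chain carbon with maximal
bond-graph distance from CA. The table is fixed by residue chemistry (HIS →
CE1, TRP → CH2, MET → CE through the sulfur, LYS → CE because NZ is
nitrogen, ARG → CZ, PRO → CD with the side chain traversed CA→CB so the
backbone-nitrogen shortcut is excluded) and is verified in the test suite
against an independent breadth-first search over residue bond graphs.
Topological ties (LEU CD1/CD2, VAL CG1/CG2) are broken by the larger
Euclidean distance from CA in the conformer at hand, then lexicographically:
deterministic and conformer-aware. Glycine has no side-chain carbon and is
excluded from scans; if the top-ranked atom is missing from a model the next
table entry is used and the record is flagged. His CE1 versus CD2 is the one
place where published distance tables could have used a different
convention; the table is an explicit argument to every operation, so a
per-residue override is a one-line change.

Residue pairing across conformers is by residue number and insertion code —
both antithrombin entries use mature numbering — never by sequence
alignment. Multi-copy crystals are handled by explicit chain selection;
`chain = "auto"` picks the first chain containing residue 393 (the serpin
P1 position), since a chain choice must be made and the inhibitory monomer
always contains the reactive center.

## Inhibition kinetics

Progress curves are fit to the single-exponential decay with a **hard
zero-activity end point**, A(t) = A0·exp(−k_obs·t). The end point is fixed,
not fitted, because the assay design runs inhibition to completion; a
floating end point is available but off by default. The fit is unweighted
ordinary least squares (no weighting is implied by the assay), switchable to
relative (1/A²) weighting. Start values come from a log-linear regression on
the positive activities; refinement is Levenberg–Marquardt
(`minpack.lm::nlsLM`). Data that do not decay (no point below half the
initial activity, or non-negative log-slope) raise "no inhibition detected"
rather than returning a meaningless fit.

The second-order association rate constant is k2 = k_obs·SI/[AT]: the
stoichiometry of inhibition SI corrects the effective inhibitor
concentration for the substrate-pathway turnover that consumes SI moles of
serpin per mole of protease inhibited. SI itself is the abscissa intercept
(−intercept/slope) of the linear decline of residual activity with
inhibitor:protease ratio; titration points below 5% of the uninhibited
activity (default, configurable) lie past the linear regime and are excluded
before the regression.

Percent activation maps a variant's fold change onto the wild-type
native→activated window as 100·(fold−1)/(window−1). The alternative
convention 100·fold/window does not send the unactivated protein to 0%,
which is why we chose the anchored form; the convention is stamped into the
result object. The window itself (e.g. 360-fold) and the approximate pure
state rates (e.g. 10⁶/4×10³ ≈ 250) come from different measurements and are
deliberately **not** reconciled: both are plain inputs.

The two-state partition treats the observed native rate as the
population-weighted mean of the pure-state rates, f_A = (k_obs −
k_R)/(k_A − k_R). With the printed rates — 4×10³ observed, 0.5–1×10³ for the
locked R form (we use the midpoint 7.5×10²), 10⁶ activated — this puts
≈99.7% of native molecules in the R state, the quantitative statement of how
strongly the native conformation is silenced.

## Mutant-cycle coupling

Given a table of rate constants keyed by mutation sets, the coupling index
of mutations a and b over background bg is

CI = (k_bg+a · k_bg+b) / (k_bg · k_bg+a+b),  ΔG_int = R·T·ln CI.

CI is oriented so that a double mutant falling short of the multiplicative
prediction — the signature of two residues sharing a common silencing
function — gives CI > 1; the reciprocal orientation is available behind a
flag and the orientation used is recorded in the result. Temperature
defaults to 298.15 K (assays at 25 °C). When standard errors accompany the
rates, the CI error is propagated first-order in log space. Conditional
cycles over a third mutation decompose as ln CI(a,b|c) = ln CI(a,b) +
three-body term; the term is exactly zero for tables generated without
three-body energies, which is the package's round-trip verification route:
`make_rate_table()` builds tables from prescribed single and pairwise
energies, and `coupling_index()` must return each pairwise energy to
10⁻⁶ kcal/mol. Published per-mutant coupling magnitudes live in figure bar
plots rather than printed tables, so the synthetic round trip — not a
numeric reproduction — is the verification of this module.

## Thermal denaturation and fluorescence

Melting curves are fit to the six-parameter two-state van't Hoff model with
**linear** pre- and post-transition baselines (tryptophan emission drifts
with temperature; flat baselines are the degenerate case). The folded
fraction at the fitted Tm is 0.5 by construction. Initialization: Tm from
the steepest point of the curve, baselines from the first and last quarter
of the scan, ΔH_vH from 100 kcal/mol; bounds keep Tm inside the scanned
range (a boundary solution is flagged) and ΔH_vH in [1, 5000] kcal/mol.
Curves whose fluorescence range does not clear three times the local noise
floor, or that a straight line explains, are rejected as transition-free.
Points above a configurable post-transition cutoff can be masked, since
irreversible aggregation is outside the two-state model. Temperatures are
Kelvin internally, Celsius in all reports; R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹.

Baseline protein fluorescence is the OLS slope of corrected fluorescence on
protein concentration. The buffer/volume correction dialect is
F_corr = (F_raw − F_buffer)·(V_total/V_initial); published descriptions of
this adjustment are usually terse, so the arithmetic is documented here and
applied at parse time, upstream of the fit. The activation gain is
100·(F_sat − F_base)/F_base, with the saturated read conventionally taken at
five times the saturating pentasaccharide concentration; wild-type
antithrombin gains about 40%, and the synthetic wild-type preset encodes a
0.40 gain with 1% multiplicative noise.

## Trajectory dynamics

Frames are reduced to Cα atoms, aligned by Kabsch superposition onto the
initial frame of the **full** trajectory, and windowed to the trailing
`ceil(fraction·n)` frames (production convention: the final 15%; at the
production scale of 1000 ns saved every 20 ps that is 7,500 of 50,000
frames). PCA operates on mean-centered flattened 3N coordinates via SVD;
centering is over the analysis window (the windowed ensemble is the object
under study). Component signs follow a fixed convention — the
largest-magnitude element of each component is positive — so projections are
reproducible. The PC1–PC2 "how far did it drift" summary is the Euclidean
distance between the mean projections of the first and last 5% of frames
(both fractions configurable; published endpoint definitions vary and the
printed per-trajectory values depend on stochastic GPU-scale runs, so they
are not reproduction targets at desk scale).

The residue–residue correlation map defaults to the standard
displacement-vector DCCM, ρ_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩); a
coordinate-averaged per-axis Pearson variant exists behind a flag, and the
mode used is stamped on the matrix. A 3N-coordinate flattening would
natively give a 3N×3N matrix; the DCCM is the field's standard reduction to
residue level, which is why it is the default. Differential maps subtract
the reference matrix entrywise; entries under the magnitude threshold
(default 0.5) are zeroed only in the thresholded copy, and the most positive
and most negative upper-triangle pairs are ranked.

`align_and_window(..., align = FALSE)` bypasses the per-frame fit for input
already expressed in a common frame. Synthetic trajectories are generated
without global motion, and re-fitting them folds part of any collective
displacement into the rigid-body correction — a real effect (~1% on variance
ratios at the amplitudes used here) that would blur comparisons against
analytic truths; all rigid-motion-removal behaviour is tested separately
with genuinely moving frames.

## What the synthetic generators emulate — and what they do not

Each generator reproduces the statistical shape of one assay: exponential
decays with multiplicative noise (instrument read noise scales with signal),
linear titrations with additive noise, two-state melts on a 20–85 °C grid
with 2–5 °C steps, linear fluorescence series with a saturable gain step,
conformer pairs with prescribed distal-atom displacements under a random
rigid motion, trajectories as a sum of orthonormalized collective modes plus
isotropic Gaussian coordinate noise (with an optional block-confined shared
mode whose analytic cross-correlation s²/(s²+3σ²) is echoed as truth), and
rate tables built from explicit single/pairwise energies. Mode amplitudes
are centered and orthogonalized so the noise-free variance ratios are
analytic rather than asymptotic. All generators run under a locally scoped
seed: identical parameters give bit-identical output, and the caller's RNG
stream is untouched.

What they do **not** emulate: force-field physics, anharmonic or
multi-basin dynamics, slow-binding inhibition mechanisms, irreversible
aggregation above the melt transition, or crystallographic artifacts
(altloc disorder is exercised synthetically, lattice contacts are not).
Passing the synthetic suite therefore demonstrates estimator correctness —
that each fit recovers the parameters of its own generating model at
realistic noise — not that the models capture every behaviour of real data.

Problem sizes in the regression suite (hundreds to thousands of frames,
tens of residues, 100–200 seeded replicates per recovery statistic) were
chosen as the smallest ensembles at which the tested statistics stabilize
well inside their tolerances; production-scale inputs only change runtime,
not code paths.

## Numerical choices and degenerate inputs

* Kabsch uses SVD with the determinant guard, so reflections are never
  returned; all-pairs-trimmed and fewer-than-three-pairs cases are errors.
* Altloc resolution keeps the highest-occupancy location (first on ties),
  or file-order first under the `"first"` policy; it never changes atom
  counts for residues without altlocs.
* Zero-variance residues in a correlation map get NA rows/columns plus a
  warning rather than silent zeros.
* PCA on identical frames errors ("no variance"); trailing components below
  10⁻¹⁴ of the leading eigenvalue are dropped rather than normalized noise.
* `fit_stoichiometry` refuses non-declining titrations; `fit_progress_curve`
  refuses non-decaying curves; `equilibrium_partition` enforces
  k_R ≤ k_obs ≤ k_A.

## Known limitations

* mmCIF input, hydrogen handling and structure repair are out of scope;
  PDB I/O is delegated to `bio3d`.
* Sequence-alignment-based residue pairing is not implemented; conformers
  must share a numbering scheme.
* Compressed MD formats (XTC/DCD) are not read; multi-model PDB and plain
  coordinate matrices are the supported trajectory inputs.
* The real-structure acceptance checks need a one-time RCSB fetch; there is
  no bundled copy of the crystal structures.
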