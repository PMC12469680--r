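# allokit

Analysis toolkit for dissecting the allosteric activation of antithrombin
(AT), the plasma serpin that shuts down coagulation proteases once heparin
switches it from its repressed native conformation (R) to the activated one
(A / AH when pentasaccharide-bound). The package is written for structural
biochemists who combine crystal-structure comparison, inhibition kinetics,
mutant-cycle energetics, thermal stability and molecular-dynamics analysis to
map the residue network that keeps the native serpin silent.

## What it computes

**Conformer displacement scanning.** Two conformer structures are superposed
by iteratively trimmed Kabsch least squares on backbone atoms (N, CA, C;
pairs whose deviation exceeds `trim_sigma` standard deviations are discarded
each cycle). For every shared residue the displacement of the *most distal
side-chain carbon* — the side-chain carbon with maximal bond-graph distance
from CA (e.g. HIS → CE1, TRP → CH2, LYS → CE) — is measured and ranked,
nominating allosteric-communication-network (ACN) residues. Intra-structure
distal-carbon pair distances quantify contacts that form or break on
activation.

**Inhibition kinetics.** Residual protease activity A(t) under
pseudo-first-order conditions is fit to A(t) = A0·exp(−k_obs·t) with a fixed
zero-activity end point; the second-order association rate constant is
k2 = k_obs·SI/[AT], with the stoichiometry of inhibition SI taken from the
abscissa intercept of a linear inhibitor:protease titration. Fold activation
relative to the native wild type maps onto the native→activated window as
percent activation = 100·(fold−1)/(window−1). A two-state partition
f_A = (k_obs − k_R)/(k_A − k_R) converts rate constants into R/A state
populations.

**Mutant-cycle coupling.** For mutations a, b over a background bg,
CI = (k_bg+a · k_bg+b)/(k_bg · k_bg+a+b) and ΔG_int = R·T·ln CI
(R = 1.987×10⁻³ kcal mol⁻¹ K⁻¹). CI = 1 means energetically additive
effects; CI > 1 means cooperative linkage. Conditional cycles over a third
mutation expose three-body terms (linkage loss).

**Thermal stability and fluorescence.** Fluorescence melting curves are fit
to the two-state van't Hoff model with linear pre-/post-transition baselines,
F(T) = [F_n(T) + F_u(T)·K(T)]/[1 + K(T)], K(T) = exp[−(ΔH_vH/R)(1/T − 1/Tm)];
baseline protein fluorescence is the OLS slope of fluorescence on
concentration, and the pentasaccharide-induced gain is
100·(F_sat − F_base)/F_base.

**Trajectory dynamics.** Cα frames are aligned to the initial structure
(Kabsch), windowed to the trailing fraction, and decomposed by PCA
(flattened 3N coordinates, SVD); residue–residue Pearson correlation maps
(DCCM) and differential maps Δρ = ρ_target − ρ_reference with an |Δρ| ≥ 0.5
threshold rank the residue pairs whose dynamic coupling a mutation rewires.

**Synthetic generators.** Every stage has a seeded generator
(`make_conformer_pair`, `make_kinetics_dataset`, `make_melt_curve`,
`make_fluorescence_series`, `make_trajectory`, `make_rate_table`) that emits
fixtures with exact, echoed ground truth, so the whole pipeline is testable
without downloads.

## Worked example

```r
library(allokit)

## a synthetic conformer pair: residue 5's distal carbon moved (3,4,0) A,
## whole copy given a random rigid motion
p <- make_conformer_pair(10, displaced = list(`5` = c(3, 4, 0)), seed = 21)
sup <- iterative_superpose(p$b, p$a)
sup
#> superposition: rmsd 0.000 A over 29/30 backbone pairs (N,CA,C), 2 cycle(s)
head(as.data.frame(displacement_scan(p$b, p$a, sup)), 2)
#>   resno insert resid atom_a atom_b displacement fallback rank
#> 1     5          HIS    CE1    CE1 5.000000e+00    FALSE    1
#> 2    10          HIS    CE1    CE1 1.027421e-14    FALSE    2

## kinetics: native-scale AT + FXa rates
d <- make_kinetics_dataset(k2_true = 4e3, inhibitor_conc = 5e-7, noise_frac = 0)
fit <- fit_progress_curve(d$curve)
second_order_rate(fit, 5e-7, SI = 1)
#> k2 = 4000 1/(M s)  (k_obs 0.002 1/s, [I] 5e-07 M, SI 1)

## how activated is a 236-fold variant on a 360-fold window?
activation_metrics(236, 1, 360)
#> activation: 236-fold of a 360-fold window = 65.5% activation

## state populations behind the native rate
equilibrium_partition(4e3, 7.5e2, 1e6)
#> two-state partition: 99.67% R / 0.33% A  (k_obs 4e+03 between k_R 750 and k_A 1e+06)

## a 1 kcal/mol pairwise coupling energy, recovered from rates
tab <- make_rate_table(c(a = 1.5, b = 0.8), c(`a:b` = 1.0))
coupling_index(tab, "a", "b")
#> coupling a-b: CI = 5.409, dG_int = 1.000 kcal/mol (T 298.15 K)
```

The displacement scan recovers the planted 5 Å move (3–4–5 triangle) through
the rigid motion; the rate constant lands on the native AT×FXa scale; the
partition shows why a ~250-fold rate window between the pure R and A states
puts >99.5% of native molecules in the R state.

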