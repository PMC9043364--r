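---
title: "Models and methods: quantifying reader-domain binding and stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: quantifying reader-domain binding and stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readerbind)
```

readerbind analyses the four experimental readouts commonly combined to
characterize how a histone-tail reader domain (the motivating system is
the ASHH2 CW domain binding H3K4me1/2/3 peptides) recognizes its ligand:
isothermal titration calorimetry (ITC), fluorescence-monitored thermal
denaturation, NMR chemical-shift perturbation and heteronuclear NOE
dynamics, and the geometry of the tryptophan binding pocket in deposited
structures. This vignette is the package's own account of the models,
their assumptions, the tunable parameters, and the choices made where
the underlying methods literature leaves the design open.

## The single-site ITC model

An ITC experiment titrates ligand (syringe concentration $X_0$) into a
cell of volume $V_0$ containing macromolecule at $M_0$, in $N$
injections of volume $v_i$. For a single class of $n$ identical,
independent sites, the bound-site concentration $[MX]$ after injection
$i$ solves the 1:1 mass-action quadratic

$$[MX] = \tfrac{1}{2}\left(b - \sqrt{b^2 - 4\,nM_t X_t}\right),
\qquad b = nM_t + X_t + K_d .$$

`solve_bound_concentration()` evaluates the algebraically equivalent
form $2\,nM_tX_t/(b + \sqrt{b^2-4nM_tX_t})$, which is numerically stable
in the weak-binding limit where the textbook form suffers catastrophic
cancellation (at $K_d = 10^6$ M the bound concentration is
$\sim10^{-14}$ M, far below the rounding error of the naive
expression).

Because injected volume displaces cell content, the effective totals
after cumulative injection volume $d_i$ use the perfusion approximation
$M_{t,i} = M_0\,(1 - d_i/2V_0)/(1 + d_i/2V_0)$ and
$X_{t,i} = X_0\,(d_i/V_0)/(1 + d_i/2V_0)$. The cumulative heat is
$Q_i = \Delta H\, V_0\, [MX]_i$ and the measured heat of injection $i$
is $q_i = Q_i - Q_{i-1} + (v_i/V_0)(Q_i + Q_{i-1})/2$, the last term
accounting for complex carried out of the active volume during the
injection. We deliberately write $Q_i = \Delta H\,V_0\,[MX]_i$ with
$[MX]$ the *bound-site* concentration (which already contains the
factor $n$ through the site total $nM_t$): multiplying by $n$ a second
time would double-count stoichiometry and break the saturation identity
that the cumulative heat per mole of macromolecule approaches
$n\,\Delta H$ — an identity the test suite checks.

`itc_fit()` minimizes $\sum_i (q_i^{obs} - q_i^{pred})^2$ over
$(\log_{10} K_d, \Delta H, n)$ by Levenberg–Marquardt (minpack.lm),
with $n$ optionally fixed at 1. Fitting is done on raw per-injection
heats in μJ; the per-mole-of-injectant normalization familiar from
Wiseman plots is used for display only (`plot()` method), because
normalizing reweights the residuals of late, small injections.
Practical choices:

* **Bounds and starts.** $\log_{10} K_d \in [-12, 0]$,
  $|\Delta H| \le 500$ kJ/mol, $n \in [0.1, 10]$. $\Delta H$ starts
  from the mean of the first three normalized heats (early injections
  are near-stoichiometric for informative isotherms); a short
  multi-start over $\log_{10}K_d \in \{-7,\dots,-4\}$ plus a heuristic
  start guards against the flat weak-binding valley. One fit takes a
  few milliseconds.
* **Uncertainties** come from the fit covariance (residual variance
  times the inverse Gauss–Newton Hessian); the standard error of $K_d$
  is propagated from $\log_{10}K_d$ by the delta method.
* **The c-value** $c = nM_0/K_d$ measures isotherm curvature. Fits with
  $c < 1$ are flagged `weak_binding` ("parameters unreliable"), the
  regime in which the motivating study could not quantify two of its
  constructs. All-zero heats short-circuit to a non-converged fit.
* **First injection.** A `discard_first` flag implements the common
  practice of dropping an under-filled first injection; the default
  keeps it.
* **Temperature** defaults to 298.15 K everywhere (experiments at
  25 °C).

From the fitted $(K_d, \Delta H)$, `derive_state_functions()` computes
$\Delta G = RT\ln K_d$, $T\Delta S = \Delta H - \Delta G$ and
$\Delta S$ with $R = 8.314$ J/(mol K). Replicate parameter sets are
compared by a pooled two-sided Student's t-test
(`compare_groups_ttest()`, $n = 3$ replicates in the motivating study);
degenerate zero-variance inputs resolve to $p = 1$ (equal means) or
$p = 0$ deterministically rather than erroring.

```{r itc-example}
truth <- thermo_params(Kd = 1.3e-6, dH = -89, n = 1)
design <- itc_design(M0 = 1e-4, X0 = 8e-4)   # 185 uL cell, 22 x 2 uL
sim <- gen_isotherm(truth, design, noise_sigma = 0)
fit <- itc_fit(subtract_blank(sim$sample, sim$blank), free_n = TRUE)
fit
```

## Thermal denaturation

Intrinsic tryptophan fluorescence shifts red on unfolding, so the
ratio of emission intensities at 328 and 352 nm tracks the folded
fraction. `ratio_from_spectra()` reduces blank-subtracted spectra
(310–410 nm grid) to that ratio using the nearest grid wavelength —
with 1 nm grids, interpolation would change nothing material. The
melting curve is fitted by the four-parameter logistic

$$f(x) = y_0 + \frac{a}{1 + e^{-b(x - x_0)}},$$

whose inflection $x_0$ is the melting temperature $T_m$; the model
value at $x_0$ is exactly $y_0 + a/2$. We implement the formula
literally, with $y_0$ an offset and $a$ an amplitude, even though
method descriptions sometimes label these "slopes" of the pre- and
post-transition baselines; the algebra of the formula is what is
fitted. Initialization: $y_0$ from the first three ratios, $a$ from
last-minus-first, $x_0$ at the steepest finite-difference slope, $b$ as
4 divided by the temperature span of the central half of the amplitude.

Not every trace is a two-state transition, and reporting a $T_m$ from a
non-sigmoidal trace would be meaningless (the motivating study's I915A
mutant is exactly such a case). `assess_sigmoidality()` therefore gates
every fit and reports *why* a trace fails: optimizer failure; fitted
amplitude under 3× the residual RMS; inflection outside the sampled
range; or standard error of the inflection above 5 °C. When the
optimizer stops at its evaluation cap but has effectively converged,
the fit is kept and judged by those same quality checks. Group
comparisons of replicate $T_m$ values use one-way fixed-effects ANOVA
(`melt_anova()`), with identical degenerate groups resolving to
$F = 0$, $p = 1$.

The synthetic schedule defaults to 5–90 °C in 2.5 °C steps — fine
enough for stable four-parameter fits — with coarser 5–10 °C schedules
available to mimic instrument practice.

```{r melt-example}
cu <- gen_melt(list(y0 = 1.20, a = -0.45, b = 0.35, x0 = 67.3))
melt_fit(cu)
```

Replicates can be fitted per replicate and averaged (the default
reading of "triplicate" protocols) or pooled into one fit; both modes
exist because protocol descriptions are often ambiguous on this point.

## Chemical-shift perturbation and fingerprint comparison

Between two assigned ¹H–¹⁵N peak lists, the combined amide shift is

$$\Delta ppm = \sqrt{(\Delta\delta_{HN})^2 +
 (\alpha_N\,\Delta\delta_N)^2}, \qquad \alpha_N = 0.17,$$

the standard scaling that places nitrogen shifts on a proton-equivalent
ppm scale (`csp()`). Mutant fingerprints usually lack assignments, so
`match_unassigned()` pairs peaks by greedy mutual-nearest-neighbour
matching in the same scaled metric: candidate pairs in order of
increasing distance, ties broken by lowest reference id, each peak used
at most once. `fraction_shifted()` then reports the percentage of
matched pairs beyond a threshold (0.2 ppm by default, the customary
cutoff for a "substantial" shift); unmatched peaks are counted and
reported but excluded from the denominator, and both counts are exposed
because the natural denominator (all picked peaks vs assigned backbone
amides) is a reporting choice.

Greedy matching is deterministic and adequate at the ~60-peak density
of a small domain fingerprint; its error rate grows with peak density,
which is why the generator (`gen_fingerprint()`) enforces a minimum
peak separation of just over twice the designed displacement — under
that condition recovery of the designed shifted fraction is exact, and
the tests assert it. At 0.3 ppm displacement the amide window
(¹H 6.5–10.5, ¹⁵N 105–135 ppm) packs at most ~70 such peaks
(hexagonal bound); uniform placement is used where it works and a
randomly subsampled hexagonal lattice at densities where uniform
placement jams, with denser requests refused as infeasible.

## Backbone dynamics

The steady-state heteronuclear NOE is the ratio of crosspeak
intensities with and without proton saturation (`het_noe()`), with
uncertainty propagated from user-supplied per-spectrum noise floors.
Values around 0.8 indicate moderate picosecond motion; loops can drop
to 0.5–0.7 or below. `classify_mobility()` splits residues at a
configurable threshold, default 0.75 — the midpoint between those two
regimes, made explicit precisely because no universal cutoff exists;
the boundary is strict (a residue at exactly 0.75 is "ordered").
T1/T2 series on the standard delay grids (`t1_delays`, `t2_delays`)
are fitted by $I(t) = I_0 e^{-t/T}$ (`fit_monoexponential()`), using
the exact log-linear solution as the start for a Levenberg–Marquardt
refinement on the unlogged scale; non-decaying data are flagged rather
than fitted. No model-free (Lipari–Szabo) analysis is attempted.

## Binding-pocket geometry

The opening of the tryptophan π-cation pocket is summarized by the
angle between the planes of the two indole rings. `fit_plane()` fits a
total-least-squares plane through the nine ring atoms (CG, CD1, CD2,
NE1, CE2, CE3, CZ2, CZ3, CH2): the normal is the smallest-eigenvalue
eigenvector of the coordinate scatter matrix, which minimizes the
out-of-plane RMS over all planes. CB is excluded by default — it is
sp³ and off-plane, so "the side-chain atoms" is read as the planar
aromatic system — with an `include_cb` flag as a sensitivity check.

Two angles are reported, because printed angles above 90° imply a
normal-orientation convention that plane fitting alone cannot supply:

* `angle_unsigned` $= \arccos|n_1\!\cdot\!n_2| \in [0°, 90°]$,
  convention-free and the primary value;
* `angle_oriented` $\in [0°, 180°]$, using Newell-method normals over
  the canonical ring perimeter
  CG→CD1→NE1→CE2→CZ2→CH2→CZ3→CE3→CD2, making the orientation a
  deterministic function of atom identity.

`pocket_angle()` composes parsing (bio3d behind `read_pdb()`; altloc
filtered to blank/'A'; chain A by convention when several chains
exist), ring extraction with completeness checks, plane fits and the
angle. NMR ensembles are measured per model with model 1 as the
headline and the mean and range reported, since deposited ensembles do
not say which member produced any published single number. Generated
idealized ring pairs (`gen_ringpair()`, fused regular pentagon/hexagon
with 1.40 Å bonds) reproduce designed angles to better than $10^{-6}$
degrees and serialize to valid PDB text, so the geometric machinery is
fully testable without downloads; real deposited structures can be
fetched with `scripts/fetch_pdb.R` when a network is available.

```{r ring-example}
pocket_angle(list(gen_ringpair(65)), res_pair = c(1, 2))
```

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its arguments including the seed
(bit-identical reruns), and every output parses back through the
corresponding reader. Defaults are fixed study conditions, chosen once:

* `gen_isotherm()`: 185 μL cell (a typical low-volume calorimeter cell
  — working volume is rarely printed, and round trips generate and fit
  with the same $V_0$ so the choice cancels), 100 μM macromolecule,
  800 μM peptide — inside the 50–180 μM / 400–1,800 μM ranges of the
  motivating experiments, giving a final molar ratio ≈ 2.2 — with
  22 × 2 μL injections; additive Gaussian heat noise, default σ = 2 μJ,
  which reproduces replicate $K_d$ scatter of roughly a quarter of
  $K_d$ at the wild-type affinity, matching the printed replicate SDs;
  a constant −2 μJ dilution heat forms the matching blank.
* `gen_melt()`: exact logistic curves, or two log-normal basis emission
  bands (peaks near 330/355 nm) mixed per temperature so the 328/352
  ratio reproduces the target curve exactly; only that ratio is
  contractual, not the band shapes.
* `gen_relaxation()`: NOE pairs with $I_{ref} = 1$ and decay series on
  the standard delay grids, multiplicative noise.

The generators emulate idealized instrument output: integrated heats
(not raw thermograms), noiseless baselines, complete peak lists, exact
two-state melting, perfectly planar rings. Passing round-trip tests
therefore demonstrates correctness of the estimators under the stated
noise models — not robustness to baseline drift, peak overlap,
aggregation during melting, or partially disordered rings in real
data.

## Numerical choices and known limitations

* Stable quadratic root throughout; discriminants below $-10^{-12}$
  raise an internal error, smaller negatives are clamped to zero.
* All optimizations are Levenberg–Marquardt with tight
  (`1e-14`) tolerances; ITC fits multi-start over $\log_{10}K_d$.
  Problem sizes are those of the experiments themselves (22
  injections, ~35 temperatures, ≤ 60 peaks), so full simulation
  studies of 100 seeds complete in seconds.
* The t-test is pooled (Student's), not Welch, following the motivating
  analysis; ANOVA is fixed-effects one-way.
* Published p-values that cannot be reproduced from printed summary
  statistics (one mutant-vs-wild-type comparison) are treated as
  properties of the unpublished raw replicates, not as targets.
* PDB-format input only (no mmCIF); no peak picking, resonance
  assignment, multi-structure alignment, scan-rate corrections, or
  binding-constant extraction from CSP titrations.
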