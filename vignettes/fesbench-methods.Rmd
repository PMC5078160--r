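---
title: "Methods: free-energy estimation, overlap diagnostics and affinity benchmarking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: free-energy estimation, overlap diagnostics and affinity benchmarking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fesbench)
```

# Scope

fesbench implements the analysis half of a relative binding-affinity study
on congeneric ligand series: given per-window samples produced upstream by
molecular-dynamics engines, it estimates free-energy differences, judges
their convergence, composes relative affinities over a perturbation network
that includes auxiliary reference ligands, assembles composite QM/MM
binding scores from energy-component tables, and benchmarks predictions
against experiment. No sampling engine is included: perturbation energies,
reduced-potential matrices, dU/dlambda samples, energy components and
vibrational frequencies are all *inputs*.

All energies are kJ/mol, temperatures kelvin, and the gas constant is
R = 8.31446e-3 kJ/mol/K. The default temperature is 300 K and the default
coupling schedule is the 13-point one with 0.05 spacing at the endpoints
(`default_lambda_schedule()`).

# Free-energy estimators

Four estimators act on alchemical samples:

* **EA** (exponential averaging, `ea_estimate()`): the one-sided
  perturbation formula dG = -kT ln< exp(-dU/kT) >. All exponential averages
  in the package go through a max-shifted log-sum-exp, so inputs of any
  magnitude are safe.
* **BAR** (`bar_estimate()`): the acceptance-ratio estimate, found as the
  root of the self-consistent Bennett equation in its Fermi-function form
  including the ln(n_F/n_R) sample-size term. The residual is monotone in
  the trial dG, so we solve by bisection, bracketed by the two one-sided EA
  estimates (expanded geometrically if needed). Default tolerance 1e-6
  kJ/mol, cap 500 iterations; non-convergence is an error, never a silent
  result. The per-window standard error is Bennett's asymptotic variance
  evaluated from the Fermi weights at the solution and is flagged
  `"asymptotic"` in the result.
* **TI** (`ti_estimate()`): trapezoidal integration of the mean
  dU/dlambda over the schedule. The quadrature rule is deliberately the
  simplest defensible choice and is recorded in the result metadata; no
  spline is fitted. Optional per-point standard errors are propagated
  through the trapezoid weights, which also handles the fact that interior
  grid points serve two adjacent intervals.
* **MBAR** (`mbar_estimate()`): self-consistent multistate acceptance-ratio
  free energies for all states of a `reduced_potential_set`. The iteration
  is seeded by stagewise BAR along adjacent states and stops when the
  largest per-state change drops below the tolerance (default 1e-8 kJ/mol);
  the first state is pinned at zero. The same solution is the minimum of a
  convex objective, which the test suite exploits as an independent second
  route (direct BFGS minimisation) agreeing to 1e-6 kJ/mol.

Uncertainties of path-level quantities deserve care. Stagewise EA totals
use quadrature SEs, which is valid because each window's forward samples
come from a distinct state. For a telescoped BAR total this is *not* valid:
adjacent windows share each state's samples and their errors are positively
correlated, so `bar_path_estimate()` instead bootstraps snapshots within
each state (we measured the quadrature short-fall as a z-score spread of
about 1.5 on harmonic toys before switching). The MBAR endpoint SE is the
nonparametric bootstrap of `mbar_bootstrap_se()` (default 100 replicates,
resampling within states, failed replicates dropped and counted).

# Overlap diagnostics and lambda refinement

Six per-window measures (`overlap_report()`) flag poorly converged
perturbations; all thresholds live in `default_thresholds()`:

* **Omega**, the Bhattacharyya coefficient of the forward and
  negated-backward perturbation-energy distributions, computed on shared
  equal-width histogram bins (default 50 over the union range; under
  perfect phase-space overlap the two distributions coincide). Acceptable
  above 0.7. Binning is a design choice the source data do not dictate;
  a fixed default keeps results reproducible, and the bin count is an
  argument. With fewer than roughly 50 samples per direction the histogram
  goes sparse and Omega reads low; windows at the package's default
  cadence of 100 samples are fine.
* **K_AB** and **Pi**, overlap and bias measures in the spirit of Wu and
  Kofke. The original defining equations live in literature we treat as
  conceptual guidance; the closed forms used here are this package's own,
  chosen to reproduce the documented limiting behaviour and validated
  against those limits in the tests. K_AB = max(0, 2 C_A - C_B), where C_A
  is the forward histogram mass lying in bins occupied by the
  negated-backward distribution and C_B the converse: 0 for disjoint
  distributions, about 1 for coincident ones, approaching 2 when the first
  distribution nests inside the second. Pi compares available sample size
  with the dissipated work per direction, min over directions of
  sqrt(2 ln n) - sqrt(2 |d|) with d the direction's dissipation in kT
  (mean work minus the BAR estimate); it is large and positive when
  sampling comfortably covers the dissipation and negative when the
  required sample size exceeds n. Dissipation enters as a magnitude so
  that unphysically ordered inputs also count against the window. K_AB
  below 0.7 fails; Pi below 0.5 is alarming (a fail flag), and *negative*
  Pi alone forces refinement.
* **w_max**, the largest normalized weight in the exponential average
  (reported as the worse of the two directions); above 0.3 a single
  snapshot dominates.
* **ddG_EA**, the hysteresis |dG_EA,fwd + dG_EA,bwd| of the two one-sided
  estimates, and **ddG_TI**, the |BAR - TI| discrepancy of the window;
  both fail above 4 kJ/mol. Exact estimates make the hysteresis cancel;
  with finite samples it is strictly positive for any non-degenerate
  window, decaying with sample size.

`assess_window()` turns a report into advice: refine when at least two
measures fail, or whenever Pi is negative. The proposed new lambda is the
window midpoint - the simplest deterministic rule, given that only
"intermediate" placement is required. The decision is advisory; running
the extra simulations is out of scope.

# Perturbation networks

A `perturbation_network` holds ligands (including reference ligands, which
are auxiliary molecules without experimental affinities inserted to keep
each alchemical step small) and directed edges with the convention
value = dG_bind(to) - dG_bind(from). Edges may carry several conformer
candidates from independent perturbations; `select_conformer()` keeps the
candidate giving the most favourable binding of the non-reference ligand
(max value for X->ref, min for ref->X, first-listed on ties). For an edge
between two non-reference ligands no such rule exists, so multiple
candidates there are a configuration error unless a selection was recorded
upstream - the packaged benchmark tables carry exactly such recorded
selections.

`relative_affinity()` composes ddG(a,b) as the signed edge sum along the
fewest-edge path (the benchmark graphs are trees, so the path is unique
there), with SEs added in quadrature. Correlations between paths that share
edges are ignored - a documented simplification; a cycle-closure or
weighted least-squares treatment is deliberately out of scope.
`all_pairs_table()` enumerates three comparison schemes: a fixed reference
ligand, all pairs reachable within two edges, and all pairs. Non-binders
(ligands whose affinity exceeded the assay ceiling of 50 uM, corresponding
to a bound of about -24.7 kJ/mol at 300 K via `ic50_to_dg()`) are excluded
from comparisons by default and can be opted in.

# Composite QM/MM scores

`composite_binding_energy()` assembles the six-term score: big-QM
interaction energy in continuum solvent + basis-set correction + dispersion
+ thermal correction + ligand strain + ligand solvation correction
(COSMO-RS minus COSMO). Two sign conventions needed fixing against the
tabulated component values:

* the ligand-relaxation column is tabulated negative but enters the score
  as positive strain, so the stored value is negated on assembly - the only
  convention that reproduces the tabulated composite column and the
  positive 10-61 kJ/mol strain range;
* the `"as_submitted"` variant applies the ligand-solvation difference with
  the opposite (erroneous) sign, reproducing the originally submitted
  scores; `"corrected"` applies it properly. The two differ by exactly
  2 (dG_solv,RS - dG_solv,COSMO) per ligand.

The reduced score excluding the thermal term (`exclusions = "g_therm"`)
matches the tabulated dG' column; the table's own numbers satisfy
dG' = dG_bind - dG_therm even though its caption claims the relaxation term
is excluded too, so thermal-only exclusion is the default reading and both
exclusion sets are exposed.

`quasi_rrho_gibbs()` supplies the thermal correction from vibrational
wavenumbers: ZPE + vibrational energy - T S, with per-mode entropy
interpolated between harmonic-oscillator and free-rotor values by
w = 1/(1 + (omega0/omega)^4), omega0 = 100 cm^-1. The free rotor uses the
effective moment mu' = mu B_av / (mu + B_av) with B_av = 1e-44 kg m^2, the
standard average-moment cap of the interpolation model. Imaginary modes are
excluded with a warning and counted. Defaults are 298.15 K and 1 atm;
translational and rotational contributions of the whole molecule are not
included because the intended use is interaction energies of large
truncated systems where they cancel.

# Quality metrics and uncertainty

`metric_report()` covers MAD, MADtr (MAD after subtracting the mean signed
error - exactly zero for a constant offset, by construction), maximum
error, Pearson R and regression slope, and Kendall tau. Two Pearson modes
exist because relative (ddG) data depend on the arbitrary direction chosen
for each perturbation: the antisymmetrized mode augments every pair (x, y)
with (-x, -y) before the centred computation, making the result invariant
under direction flips. Both modes are exposed; the packaged set-2
benchmark reproduces its published cells with the antisymmetrized mode for
the no-water block and the plain mode for the with-water block. Kendall's
tau is tau-b (tie-corrected), because ties occur in the benchmark data.

`bootstrap_metrics()` is a parametric bootstrap (default 500 replicates):
independent Gaussian noise per point on both series - the calculated SEs
per point, and a typical experimental uncertainty of 1.7 kJ/mol where no
experimental SE is given - with each metric recomputed per replicate and
summarized by mean and SD. Replicates where a metric is undefined (e.g.
tau on a tied series) are dropped and counted. With all uncertainties zero
the bootstrap collapses exactly onto the point estimates. All resampling
is seeded and bit-reproducible.

IC50 conversion is dG = RT ln(IC50 / 1 M) at a caller-chosen temperature
(default 300 K; at 300 K a 50 uM ceiling gives -24.70 kJ/mol, at 298 K
-24.54).

# Synthetic data: what it emulates and what it does not

Three generators provide ground truth for every stage:

* `sample_harmonic_alchemy()`: one-dimensional harmonic states with the
  force constant interpolated linearly in lambda, independent Gaussian
  draws per state, exact endpoint dA = (kT/2) ln(k1/k0). Defaults mirror
  the study conditions: the 13-point schedule and 100 samples per state
  (the cadence of a 1 ns production window sampled every 10 ps). Linear
  interpolation rather than soft-core coupling is intentional - the point
  is an exact closed form, and soft-core functional forms belong to the
  sampling engine.
* `sample_gaussian_work()`: forward work N(mu_f, sigma^2) with the
  Crooks-consistent mirror for the backward direction, implied
  dG = mu_f - sigma^2/(2 kT). The generated pairs satisfy the Crooks
  ratio (the tests regress the histogram log-ratio and recover slope
  1/kT), and sigma controls overlap directly, which drives the refinement
  calibration tests.
* `generate_network()`: edge values from planted node free energies plus
  Gaussian noise, optional planted unfavourable conformer candidates.
  Noise-free networks compose exactly and path-independently; with noise,
  the all-pairs RMSE follows the quadrature path error.

What passing these tests does *not* show about real data: the generators
draw independent samples, so autocorrelation of molecular-dynamics time
series (and the attendant SE underestimation), conformational trapping,
binding-mode changes between ligands, and force-field error are all outside
what the synthetic suite can detect. The benchmark tables are fixture
inputs at 0.1 kJ/mol printed precision; every check against them uses
tolerances that reflect that rounding.

# Numerical choices and degenerate inputs

* Exponential averages, MBAR denominators and w_max all use max-shifted
  log-sum-exp.
* BAR bisection runs on a guaranteed bracket; the two one-sided EA
  estimates bound the root in well-behaved cases and the bracket expands
  geometrically otherwise.
* Histogram measures collapse to a single degenerate bin when all samples
  in both directions coincide (Omega = 1 by convention).
* Conformer ties keep the first-listed candidate; assessment flags are
  evaluated deterministically and order-independently.
* Every seeded routine saves and restores the caller's RNG state, and a
  pipeline run fans its master seed out to per-stage sub-seeds, so stages
  are independently reproducible and full reruns are byte-identical.
* Problem sizes in the test suite are the package's own calibration
  choices: 100 seeds for recovery rates, 25-40 bootstrap replicates inside
  multi-seed loops, 10^4 samples where a distributional limit (the
  Gaussian Bhattacharyya closed form) is checked to 0.03.

# Known limitations

* Path SEs ignore correlations between shared edges in the network stage.
* The K_AB/Pi closed forms are surrogates validated against limiting
  behaviour, not transcriptions of the original literature definitions.
* The histogram Omega degrades below ~50 samples per direction.
* No cycle-closure analysis, no enhanced-sampling advice beyond the
  midpoint refinement proposal, and no engine integration: the package
  trusts its inputs.
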