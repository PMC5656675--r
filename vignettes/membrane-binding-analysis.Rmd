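---
title: "Models and methods: membrane-binding kinetics, cross-link matching and native-MS deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proppinkit)
```

proppinkit implements three analyses that together characterize how a
peripheral membrane protein such as a PROPPIN-family β-propeller binds
lipid vesicles and oligomerizes on them. This vignette documents the
models, the parameters that matter, the numerical choices, and what the
synthetic-data generators do and do not emulate.

## The two-step binding scheme

Rapid mixing of dye-labelled protein with acceptor-labelled vesicles
yields fluorescence time courses governed, under pseudo-first-order
conditions, by the linear three-state system

$$\frac{dU}{dt} = -k_{on} L\,U + k_{off} B,\qquad
  \frac{dB}{dt} = k_{on} L\,U - (k_{off}+k_{oli})B + k_{dis} O,\qquad
  \frac{dO}{dt} = k_{oli} B - k_{dis} O,$$

with $U+B+O=1$, $U(0)=1$, and $L$ the *accessible* lipid concentration
(mM), held constant because lipid is in large excess over protein. $U$ is
unbound protein, $B$ membrane-bound monomer, $O$ membrane-bound oligomer.
The four rate constants are `k_on` (mM⁻¹s⁻¹), `k_off`, `k_oli`, `k_dis`
(all s⁻¹). Only the outer leaflet of a unilamellar vesicle faces the
protein, so `accessible_lipid()` multiplies the total lipid by an
accessible fraction whose default is 0.6.

`state_fractions()` solves the system in closed form by
eigendecomposition of the 3×3 rate matrix; a Padé matrix-exponential
fallback (via `Matrix::expm`) covers parameter combinations whose
eigenvector matrix is numerically singular. The test suite checks this
closed form against independent numerical integration with `deSolve` to
10⁻⁶ relative accuracy over random parameter draws, and checks
conservation $U+B+O=1$ to 10⁻⁹.

Observed traces are fit by `fit_multiexponential()` to

$$F(t) = F_0 + \sum_{i=1}^{n} A_{obs(i)}\,e^{-k_{obs(i)} t}, \qquad n \in \{1,2,3\},$$

with Levenberg–Marquardt least squares (`minpack.lm::nls.lm`, rates
bounded positive). Starting rates are log-spaced across
$[1/\mathrm{duration},\, n_{points}/\mathrm{duration}]$ — the window of
rates the sampling can resolve — with amplitudes split from the signal
range; if the optimizer fails, the rate guesses are rescaled through the
fixed multiplier schedule (1, 0.3, 3, 0.1, 10) before the fit is declared
unconverged. Unconverged fits carry `converged = FALSE` and are rejected
by downstream selection rather than silently propagated. Standard errors
come from the local curvature of the objective (inverse Hessian scaled by
the residual variance).

`select_kobs1()` keeps the fastest phase as $k_{obs1}$. The rationale:
the slower phases of a 2–3-exponential fit are dominated by
oligomerization and by slow vesicle aggregation, so they are discarded
for the binding analysis. A `largest_amplitude` rule is available as an
alternative. `fit_pseudo_first_order()` then fits

$$k_{obs1} = k_{on}\,[\text{accessible lipid}] + k_{off,app}$$

by weighted least squares with weights $1/se^2$; if any point has a zero
or missing standard error the whole fit uses equal unit weights (the
ordinary-least-squares fallback appropriate for noiseless fixtures). A
negative fitted intercept is reported as-is with a flag — never clamped —
because a negative `k_off,app` is diagnostic of a model violation the
user should see. Under the two-step scheme the intercept decomposes as
$k_{off,app} = k_{off} + k_{oli} + k_{dis}$ (`koff_app_from_rates()`).

The pseudo-first-order assumption itself is not enforced; a warning is
emitted when accessible lipid falls below 100× the protein concentration.

### Observable model

The FRET observable is modelled as
$F = F_{base} + c_U U + c_B B + c_O O$ plus optional slow drift phases
$a(1-e^{-rt})$. The raw data do not determine how the FRET signal weights
bound monomer against oligomer, so by design `coeff_bound ==
coeff_oligomer` by default — acceptor-labelled lipids sense any
membrane-bound protein — and both are configurable. The drift phases are
phenomenological stand-ins for vesicle aggregation, not a mechanistic
aggregation model. The donor-quench readout for site-mapping experiments
is defined as $\Delta F/F = (F_{with} - F_{without})/F_{without}$
(`donor_quench()`); the alternative normalization $F/F_{max}$ would only
rescale the ranking, which is what that assay consumes.

## Cross-link mass arithmetic

`digest()` implements tryptic cleavage (C-terminal to K/R, not before P)
with configurable missed cleavages and length window; zero-missed
peptides tile the protein exactly. Construct tags are handled by a
`numbering_offset` mapping sequence position 1 to an arbitrary protein
coordinate (offsets ≤ 0 give tag residues labels like "S-2" without
renumbering the native chain). Peptide masses are monoisotopic residue
sums plus water; carbamidomethyl-C (+57.021464 Da) and oxidation-M
(+15.994915 Da) are variable modifications.

An amine-reactive homobifunctional linker (BS3 by default, bridge mass
140.074 Da) connects peptides to the amine headgroup of DOPE (743.36 Da
in this accounting) or to a second peptide; each formed bond releases one
proton, so

$$\Delta_{lipid} = m_{lipid} + m_{linker} - 2\,m_{H^+} = 881.42\ \text{Da},
\qquad m_{dipep} = m_A + m_B + m_{linker} - 2\,m_{H^+}.$$

The DOPE value deliberately follows the 743.36 Da accounting rather than
the elemental monoisotopic mass of C41H78NO8P (≈743.55 Da); both are
reachable because the lipid mass is configuration, not code. Reactive
sites are K, S, T, Y and the protein N-terminus; a lysine at a peptide's
C-terminal cleavage site cannot carry a link (a cross-linked K is not
cleaved, so such a peptide would not exist) unless it is the protein
C-terminus, while S/T/Y links are assumed not to affect cleavage.

`match_precursors()` matches observed neutral masses at a ppm tolerance,
reporting *all* candidates within tolerance sorted by |ppm| then lower
candidate mass; the suite proves it equivalent to an exhaustive
O(n·m) scan. Matching is charge-agnostic: m/z inputs (two-column text or
MGF with PEPMASS/CHARGE) are converted to neutral masses on reading.
`classify_crosslink()` applies the homo-oligomer overlap rule: identical
or overlapping peptides can only be bridged between two protein copies
(intermolecular), disjoint peptides are ambiguous at the precursor level,
and peptides from different proteins are labelled heteromeric.
Spectrum-level scoring, FDR estimation and retention-time modelling are
out of scope; `fragment_masses()` provides b/y annotation (cross-linked
chains carry the partner as a fixed delta on the linked residue) to
support manual verification, not a search engine.

## Native-MS charge-series deconvolution

An n-mer of monomer mass $M$ at charge $z$ appears at
$m/z = (nM + z\,m_{H^+})/z$; only proton adducts are modelled. Profile
spectra are centroided by `pick_peaks()`: local maxima above 1% of the
base peak, refined to an intensity-weighted centroid over the
half-maximum region, with that region claimed so noise ripples on a flat
peak top cannot split one physical peak. `assign_peaks()` gives each peak
to the (n, z) pair minimizing ppm error within tolerance; the exact
degeneracy between an n-mer at z and a 2n-mer at 2z is resolved toward
the smaller order (parsimony) and flagged ambiguous. When the monomer
mass is only known to a window, a grid search maximizes total assigned
intensity. `oligomer_intensities()` sums assigned intensities per order
and reports them relative to the monomer (falling back, with a flag, to
the most abundant order when no monomer is present); per-order masses are
intensity-weighted means of the per-peak neutral masses with their SD
across charge states.

## Synthetic data and what it does (not) show

The generators define the study conditions used throughout the tests:

* `gen_trace_series()` — titrations of 0.25 µM protein over accessible
  lipid concentrations (the recovery tests use five concentrations
  spanning 0.1–0.6 mM, matching the working range of a vesicle
  titration), 10 s traces at 200 points, Gaussian noise of 0.01 a.u. —
  1% of the unit bound-state amplitude — and 5 replicates. Rate-recovery
  tests use the published Atg18 rate pairs (k_on/k_off,app of 0.85/0.66,
  1.55/1.03, 0.57/0.19 and 0.93/0.36) as generating truth and require
  the round trip to land within 2 recovered standard errors.
* `gen_xl_dataset()` — random 300-residue proteins (uniform residue
  frequencies; K and R at 5% each comfortably clear the 8% combined
  floor that guarantees tryptic peptides), true candidate masses
  perturbed by 3 ppm Gaussian error, decoys uniform over the candidate
  mass range. Decoys carry no intensity or retention realism; they exist
  to exercise the matcher, not to calibrate an FDR.
* `gen_native_spectrum()` — a 60 kDa monomer with orders 1–4 at
  100:50:20:10 relative abundance, charges 12–18 under a shared Gaussian
  envelope (centre 15, SD 1.5), 5 Th Gaussian peaks on a 1 Th grid, 2%
  multiplicative peak-height noise and a 0.1% additive baseline.

Every generator is deterministic under a fixed seed and returns a
`synthetic_truth` object that serializes to a YAML sidecar. What passing
tests show is that the estimators are unbiased and correctly implemented
under their own assumptions; they do not show robustness to instrument
baseline drift, photobleaching, isotope envelopes, salt adducts,
chromatographic artifacts or non-Gaussian noise, none of which the
generators emulate.

## Numerical choices and limitations

* Trace simulation is exact (closed form), so simulation accuracy never
  limits fitting tests; tolerance 10⁻⁶ against the ODE oracle.
* Multi-exponential fitting is a non-convex problem; the multi-start
  schedule makes the noiseless fixtures reproducible to 10⁻⁴–10⁻⁶
  relative, but strongly overlapping rates (within ~2×) remain hard to
  separate at realistic noise, as in any exponential analysis.
* The kinetic recovery tests run per-replicate regressions over five
  concentrations and compare means against 2 mean standard errors;
  problem sizes (5×5 traces of 200 points per rate pair) were chosen so
  the whole suite stays interactive.
* Matching ties are broken by |ppm| then lower candidate mass; isobaric
  candidates (same peptide, different link site; I/L) are all reported,
  since precursor mass cannot distinguish them.
* The native-MS mass-window search is a plain grid; its resolution is
  `mass_grid_points` over the window, and the assignment tolerance
  (default 200 ppm) must absorb the centroiding error of the m/z grid.
* Degenerate even-order/half-charge series are detectable only through
  odd-order peaks; spectra lacking them are reported with ambiguity
  flags rather than resolved.

## Interfaces

Traces travel as CSV with `#key=value` metadata headers
(`total_lipid_mM`, `accessible_fraction`, `protein_uM`, `label`, `seed`)
and 10-significant-digit numbers; proteins as FASTA (first header word =
id, optional `offset=N`); peak lists and mass lists as two-column text,
with MGF accepted for precursors; results as TSV. `read_run_config()`
merges a flat YAML configuration with overrides (flag > file > default),
rejects unknown keys by name, and `run_pipeline()` echoes the resolved
configuration next to its outputs, logs per-stage wall times to standard
error, and chains stages through files — see `inst/cli/proppinkit.R` for
the command-line entry point.
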