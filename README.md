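# cardiomapr

Automated action-potential analysis for optical mapping of 3D human cardiac
microtissues.

Cardiotoxicity screening platforms pace dye-loaded (di-4-ANEPPS)
hiPSC-cardiomyocyte microtissues and film them with a fast camera
(979 frames/s, 64 × 64 px, 18.7 µm/px — about four microtissues per view).
`cardiomapr` turns those movies into per-tissue, per-beat electrophysiology:

1. **Segmentation** — per-pixel FFT scores the spectral power in narrow
   bands at the pacing frequency and its first three harmonics; Otsu
   thresholding plus 8-connected labelling finds microtissue regions, and
   only regions **> 60 pixels** are analysed (a typical microtissue covers
   ~170 px). Pixels in a region are averaged and normalized to ΔF/F.
2. **Eight pro-arrhythmia metrics per beat** — excitability
   (100 · captured/delivered stimuli), stimulation delay (pulse → max
   dF/dt), 10–90% rise time, APD30/50/80 (upstroke → 30/50/80%
   repolarization, linearly interpolated), APD_MxR (upstroke → end of rapid
   repolarization at the maximum of d²F/dt²), triangulation
   APD_tri = APD_MxR − APD50, and an early-afterdepolarization (EAD) flag.
3. **Study-level statistics** — nested beat/tissue/mold/batch variance
   decomposition, KS normality, paired dose tests, power analysis,
   ECDFs and restitution curves, σ-shift and mean-difference signature maps,
   and the hERG-block indicator: a slope-equality Z-test,
   Z = (b_d − b_ctr)/√(SE_d² + SE_ctr²), on per-dose OLS fits of APD_tri
   against APD_MxR — I_Kr block delays phase-3 repolarization and steepens
   this slope.

Because no raw recordings are publicly deposited for this platform, the
package ships a ground-truthed synthetic generator: parametric AP waveforms
(with EADs) and a ≥10 kHz brute-force metric oracle, rendered movies with
known region labels, nested hierarchical APD datasets, and a minimal
ventricular ionic model (Bueno-Orovio–Cherry–Fenton, epicardial set, Rcpp)
with I_Kr/I_to/I_CaL conductance surrogates for direction-level validation.

All user-facing functions take a data frame first and return tibbles, so
stages compose with the pipe; result types have `autoplot()` methods and
`tidy()`/`glance()` for fitted objects.

## Worked example

Simulate a four-tissue recording (0.5 Hz pacing, 4 s, SNR 10), run the
pipeline, and summarize per tissue:

```r
library(cardiomapr)
library(dplyr)

wp <- waveform_params(amplitude = 0.1, t_activation = 30,
                      t_repol = 330, duration_ms = 900)
mk <- function(ctr) list(center = ctr, radius_px = 7.4, params = wp)
sc <- scene_spec(list(mk(c(16, 16)), mk(c(16, 48)),
                      mk(c(48, 16)), mk(c(48, 48))),
                 noise_sd = 10, n_frames = 3916)

res <- run_pipeline(scene = sc, protocol = sc$protocol)
res$per_tissue %>%
  select(tissue, excitability_pct, apd50_ms_mean, apd80_ms_mean,
         apd_mxr_ms_mean)
#> # A tibble: 4 × 5
#>   tissue excitability_pct apd50_ms_mean apd80_ms_mean apd_mxr_ms_mean
#>    <int>            <dbl>         <dbl>         <dbl>           <dbl>
#> 1      1              100          295.          317.            324.
#> 2      2              100          295.          319.            325.
#> 3      3              100          295.          317.            330.
#> 4      4              100          295.          318.            330.
```

Every stimulus captured, and the recovered APDs sit within a few ms of the
generator's analytic truth (APD50 296, APD80 318, APD_MxR 319 ms) despite
per-pixel SNR 10 — pixel averaging over ~170 px and sub-sample
interpolation buy back the precision.

The hERG-block indicator on a simulated I_Kr-block dose series:

```r
d <- simulate_dose_slope_data("gkr", dose_scales = c(1, 0.75, 0.55, 0.4),
                              n_tissues = 12, seed = 1)
tri_mxr_slopes(d, control = 0) %>% tidy()
#> # A tibble: 4 × 7
#>    dose  slope intercept     se     n z_vs_control   p_value
#>   <int>  <dbl>     <dbl>  <dbl> <int>        <dbl>     <dbl>
#> 1     0 0.0555      36.0 0.0140    12        NA    NA
#> 2     1 0.140       13.1 0.0170    12         3.82  1.34e- 4
#> 3     2 0.526     -134.  0.0336    12        12.9   4.45e-38
#> 4     3 3.55     -1571.  0.538     12         6.49  8.70e-11
```

The APD_tri-vs-APD_MxR slope rises monotonically and significantly with
graded I_Kr-surrogate block; the same experiment with `"gto"` (transient
outward block) or moderate `"gcal"` (L-type calcium augmentation) leaves
the slope statistically unchanged — the signature that separates
hERG-blocking compounds from benign APD prolongation.

A thin command-line front end wrapping these functions ships at
`inst/cli/cardiomap.R` (subcommands `simulate-movie`, `simulate-hierarchy`,
`simulate-ionic`, `segment`, `metrics`, `stats-variance`, `stats-power`,
`run`).

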