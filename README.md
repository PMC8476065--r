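# olfbold

Voxelwise analysis of olfactory block-design BOLD fMRI in R, built around
the nonparametric detector that olfactory studies use when responses
habituate: the two-sample Kolmogorov–Smirnov (KS) test.

Prolonged or repeated odor stimulation attenuates the BOLD response — the
second and third stimulation blocks of a paradigm can carry a fraction of
the first block's signal, and in the olfactory bulb the response within a
single 60 s block is bi-phasic with a suppressed second peak. A general
linear model with a fixed regressor models none of this; the KS test asks
only whether the intensity *distributions* of stimulus-on and stimulus-off
volumes differ. `olfbold` implements that analysis end to end, together
with a synthetic 4-D phantom that generates data with exactly this
phenomenology (plus drift, respiratory noise and susceptibility dropout)
and known ground truth, so every stage of the chain can be validated.

## What it computes

For each in-mask voxel with on/off sample index sets shifted by a
hemodynamic delay:

- **KS activation**: D = sup_x |F_on(x) − F_off(x)|, with p-values from the
  asymptotic two-sample Kolmogorov distribution whose effective sample size
  is calibrated per dataset from circular-shift surrogates (temporal
  filtering breaks the independent-samples assumption; the calibration
  restores valid p-values). Voxelwise FDR control by Benjamini–Hochberg,
  adjusted P < 0.01; significant voxels split into positive/negative by the
  sign of ΔS/S.
- **Relative signal change**: ΔS/S(block b) = 100 · (mean on-block b −
  B_b)/B_b, where B_b is the mean over the *second half* of the
  stimulus-off period preceding block b (the first half is contaminated by
  the post-stimulus transition).
- **tSNR and CNR**: temporal mean / temporal SD, and CNR = tSNR · ΔS/S
  (block 1, as a fraction). Conditions are compared on the union of
  positively activated voxels from either acquisition.
- **Group statistics**: within-subject one-way repeated-measures ANOVA
  across blocks, paired t-tests with BH adjustment, Cohen's d with pooled
  SD, relative differences.
- **Reproducibility**: per-region, per-sign Dice overlap of activation
  masks and ICC(2,1) of voxelwise ΔS/S between scan and re-scan.

## Worked example

```r
library(olfbold)

sched <- build_paradigm()   # 60 s off + 3 x (60 s pulsed-on + 120 s off), TR 2 s
print(sched)
#> Paradigm schedule: 300 volumes, TR 2 s (600 s total)
#>   60 s off + 3 x (60 s on / 120 s off); 20 odor pulses/block
#>   90 ON / 210 OFF volumes

sim <- simulate_bold(sched, sim_config(), seed = 7)

# detection path: smooth, detrend, regress the respiratory trace
det <- preprocess_bold(sim$bold, lp_cutoff_hz = 0,
                       traces = sim$truth$nuisance_traces)
amap <- ks_activation_map(det, sched)
print(amap)
#> Activation map (ks-calibrated, adjusted P < 0.01, delay 6 s)
#>   14664 tested voxels: 547 positive, 11 negative (n_eff 100.1)

# quantification path: full chain with paradigm-protected detrending
quant <- preprocess_bold(sim$bold, traces = sim$truth$nuisance_traces,
                         protect = protect_regressors(sched))
resp <- block_response(quant, sched)
roi_summarize(resp, amap, sim$truth$roi_labels, "positive",
              sim$truth$roi_names)[1:2, c("roi", "n_active", "delta_block1",
                                          "delta_block2", "delta_block3",
                                          "cnr")]
#>        roi n_active delta_block1 delta_block2 delta_block3  cnr
#> 1     bulb        7         1.79        0.714        0.388 1.94
#> 2 piriform      156         1.35        0.515        0.194 2.79
```

The bulb-like region shows the strongest first-block response with strong
habituation across blocks (the configured multipliers are 1/0.35/0.15 of
a calibrated amplitude; measured values include partial-volume dilution
and filter effects). The activated-voxel counts, the ~2 % bulb signal
change and the CNR scale match what 7 T olfactory studies report for the
human olfactory bulb. `run_pipeline(list(out_dir = "demo", seed = 1))`
runs the same chain for a scan/re-scan pair plus an EPI-like (high-dropout)
condition and writes NIfTI maps, per-region TSV tables, the scan/re-scan
Dice/ICC table and a `summary.json`.

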