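# loxquant

Quantification pipelines for Cre/LoxP recombination switching
experiments — and for the umbrella-sampling free-energy calculations
that accompany engineering of light-controlled recombinases.

Optogenetic Cre variants are characterised with four very different
measurements, each with its own quantification conventions:

1. **Free-energy profiles** (PMF) for helix unbinding, estimated from
   umbrella-sampling simulations by the weighted histogram analysis
   method (WHAM) with block-averaged error bars;
2. **Flow cytometry** of fluorescent reporter strains, where the
   fraction of switched ("ON") cells is read from density-gated events
   against a negative-control threshold;
3. **qPCR** of genomic DNA, where the excised fraction N_Lox/N_Total is
   inferred from standard curves built on known mixing ratios;
4. **Single-cell microscopy**, where per-cell fluorescence is the mean
   gray value of a segmented cell minus a background estimated from
   random cell-free regions.

`loxquant` implements all four as tested, seedable R functions, plus
synthetic-data generators that emulate every input (Brownian dynamics
on a known 1-D potential, log-normal cytometry mixtures, Ct tables,
labeled images), so the whole pipeline is verifiable without any
wet-lab or molecular-dynamics data.

## The statistics at the core

**PMF.** Umbrella windows restrain the reaction coordinate x with
harmonic biases b_w(x) = ½ k (x − c_w)². Each window's series is split
into blocks after an equilibration phase; WHAM is solved per block,

    p_i = (Σ_w n_wi) / (Σ_w N_w exp(−β(b_wi − f_w))),
    f_w = −kT ln Σ_i p_i exp(−β b_wi),

iterated until max |Δf_w| < 0.01 kcal/mol; block distributions are
averaged and each bin reports F_i = −kT ln(p̄_i) with
σ_Fi = kT σ_p̄i / p̄_i, where σ_p̄i is twice the standard error of the
mean over blocks. The profile is offset so its minimum is zero.
Defaults follow the canonical analysis: 13 bins on [3.75, 10.25] Å,
T = 310 K, 30 ns windows with 5 ns equilibration and 5 ns blocks.

**Cytometry.** A product-Gaussian kernel density over (FSC-H, SSC-H)
is evaluated exactly at every event (compiled O(n²) kernel); the gate
keeps the densest ⌈0.4 n⌉ events. The ON/OFF threshold is the 99.9th
percentile of the gated negative-control fluorescence; the readout is
the fraction of gated events strictly above it. Gate centroids are
screened across an experiment with a median/MAD rule.

**qPCR.** Ct = a + b·log10(q) is fitted by least squares on calibration
mixtures (0% points cannot amplify and are excluded); samples invert
through q = 10^((Ct−a)/b), and the excision fraction is the ratio of
the edited-assay and total-assay quantities. b = −3.3219 corresponds to
100% amplification efficiency.

**Imaging.** Per-cell mean gray values minus one per-image background,
pooled from 8 random cell-free disk regions of median-cell area. The
subtraction is computed on pooled pixel sums, so a constant offset on
the whole image cancels exactly.

## Worked example

```r
library(loxquant)

# ground truth: double well, minima at 5 and 9 Å, 3 kcal/mol barrier
pot  <- double_well_potential()
sims <- simulate_umbrella(pot, umbrella_ladder(),
                          langevin_spec(seed = 42), thermo())
estimate_pmf(sims)
#> Potential of mean force (wham), 13 bins, 5 block(s)
#>  bin_center_A F_kcal_mol sigma_F_kcal_mol defined
#>           4.0   3.419000           0.0743    TRUE
#>           4.5   0.706000           0.1060    TRUE
#>           5.0   0.000000           0.2110    TRUE
#>           ...
#>           7.0   2.618000           0.2860    TRUE
#>           ...
#>           9.0   0.008544           0.1730    TRUE
#>          10.0   3.740000           0.1490    TRUE
```

The estimate recovers the programmed landscape: minima at 5 and 9 Å
(F ≈ 0), a ~2.6 kcal/mol interior barrier at 7 Å (bin-averaging over
0.5 Å bins lowers the 3 kcal/mol point barrier), and error bars from
the five 5-ns blocks.

```r
neg  <- simulate_cytometry(cytometry_spec(n_events = 10000, seed = 8))
g    <- kde_gate(neg)                      # encloses exactly 4000 events
thr  <- negative_threshold(neg, g)         # 99.9th percentile -> 17.7
ev   <- simulate_cytometry(cytometry_spec(n_events = 10000,
                                          on_fraction = 0.25, seed = 7))
fraction_on(ev, kde_gate(ev), thr)
#> Switch result: 0.2477 ON (991 / 4000 gated, threshold 17.7)

sim   <- simulate_qpcr(qpcr_spec(true_fraction = 0.3, seed = 11))
curve <- fit_standard_curve(sim$calibration)
curve
#> Standard curve: Ct = 29.9422 -3.3139 * log10(q)  (r^2 = 0.9970, n = 24,
#>                 efficiency 100.3%)
excision_fraction(sim$sample$Ct, curve, curve$intercept, curve)
#> Excision fraction N_Lox/N_Total = 0.2888
```

A true ON fraction of 0.25 reads out as 0.248 (binomial error on 4000
gated cells), and a true excision fraction of 0.30 comes back as 0.289
under 0.2-cycle Ct noise.

End-to-end runs with CSV/TIFF/JSON outputs are driven by
`run_pipeline(default_config())` or the wrapper script
`inst/scripts/pipeline.R`; see `vignettes/quantification-methods.Rmd`
for the full model description.

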