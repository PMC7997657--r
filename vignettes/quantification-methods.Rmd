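---
title: "Models and methods behind loxquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind loxquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loxquant)
```

`loxquant` packages the four quantification computations used to
characterise engineered Cre/LoxP recombinases: a free-energy (PMF)
estimator for umbrella-sampling data, density-gated flow-cytometry
quantification of ON/OFF reporter fractions, qPCR standard-curve
estimation of DNA excision, and per-cell fluorescence quantification
from segmented images. This vignette explains each model, its
assumptions and tunable parameters, the synthetic generators used to
validate them, and the numerical choices made where conventions were
genuinely open.

## Free-energy estimation from umbrella windows

### Model

Umbrella sampling restrains a scalar reaction coordinate $x$ (here in
Å; in the motivating application, the distance between an α-helix and
its binding environment) with harmonic biases
$b_w(x) = \tfrac{1}{2} k (x - c_w)^2$ — note the one-half prefactor
convention for the spring constant $k$, in kcal mol$^{-1}$ Å$^{-2}$.
The default ladder has 13 windows at $c_w = 4, 4.5, \dots, 10$ Å with
$k = 20$.

Each window's series is processed as:

1. **Blocking** (`split_blocks`): discard 5 ns of equilibration, cut
   the remainder into consecutive 5 ns blocks, drop a trailing partial
   block. Equal-length blocks keep the block-to-block standard error
   unbiased; padding a short block would weight it incorrectly.
2. **Per-block WHAM** (`wham_solve`): the standard self-consistent
   equations over the bins $i$ of the analysis grid (13 bins on
   [3.75, 10.25] Å),
   $$p_i = \frac{\sum_w n_{wi}}{\sum_w N_w e^{-\beta (b_{wi} - f_w)}},
     \qquad f_w = -kT \ln \sum_i p_i e^{-\beta b_{wi}},$$
   iterated from $f_w = 0$ without damping until
   $\max_w |\Delta f_w| < 0.01$ kcal/mol (configurable; the cap is
   $10^5$ iterations, and non-convergence is an error reporting the
   last residual). Window free energies are reported relative to the
   first window. Samples outside the grid are dropped and counted; a
   window losing more than half its samples, or contributing none, is
   an error rather than a silent distortion.
3. **Block averaging** (`pmf_from_blocks`):
   $F_i = -kT\ln \bar p_i$ with $\bar p_i$ the mean block probability,
   and $\sigma_{F_i} = kT\,\sigma_{\bar p_i}/\bar p_i$ where
   $\sigma_{\bar p_i}$ is **twice** the standard error of the mean over
   blocks (sample standard deviation, $n-1$). The profile is shifted so
   its smallest defined value is zero. Bins with $\bar p_i = 0$ are
   reported as undefined (`NA`) — never a fabricated value — and are
   ignored by the offset; a single block leaves $\sigma_F$ undefined
   rather than zero.

Whether WHAM should be run once on pooled data or per block is a real
ambiguity in block-averaged PMF protocols; `estimate_pmf` solves WHAM
independently per block (block $b$ combines block $b$ of every window)
because the error formula above needs a distribution *per block*, and
each block's probabilities are normalised per block so that every
`BlockDistribution` sums to one.

### Numerical discretization: sub-binned iteration

The textbook discretization evaluates $b_w$ at bin centers. With the
default constants this is *not* adequate: the biased sampling width is
$\sqrt{kT/k} \approx 0.18$ Å, so a window's samples concentrate in a
small part of a 0.5 Å bin and the bias varies by about 1 kT across it.
Solving the fixed point on *expected* (infinite-sampling) histograms
shows the coarse-bin estimator mis-states the profile by more than
1 kcal/mol RMSE — a pure discretization artifact that no amount of
sampling removes. `wham_solve` therefore iterates on an internal
equal-width subdivision of each reporting bin (bias at sub-bin
centers) and sums the converged sub-bin probabilities back onto the
reporting grid. The automatic subdivision keeps the sub-bin width
below half the narrowest biased-sampling width
($\lceil \Delta / (0.5\sqrt{kT/k_{max}}) \rceil$, capped at 20; 6 for
the defaults), which brings the expected-histogram error below
0.01 kcal/mol. Setting `sub_bins = 1` recovers the textbook coarse-bin
fixed point exactly, which is what the solver-equivalence tests pin.

### Thermodynamic constants and units

`thermo()` defaults to $T = 310$ K and
$k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$, so
$kT \approx 0.616$ kcal/mol. Spring constants are read as
kcal mol$^{-1}$ Å$^{-2}$ — the only dimensionally consistent unit for a
harmonic constant, even though such constants are sometimes printed
per-Å in the literature.

### The synthetic generator and what it does (not) emulate

`simulate_umbrella` replaces the molecular-dynamics engine with
overdamped (Brownian) Langevin dynamics on a known 1-D potential:
$$x \leftarrow x - \beta D\, U'(x)\, \Delta t + \sqrt{2 D \Delta t}\,\xi,
  \qquad \xi \sim N(0,1),$$
an Euler–Maruyama scheme whose stationary law is the Boltzmann density
of $U$. The PMF estimator consumes only scalar series, so the
integrator choice affects no downstream code. Defaults — chosen once as
physically plausible for a tethered helix and used everywhere — are
$D = 0.5$ Å$^2$/ns and $\Delta t = 0.002$ ns, giving a stability/
accuracy factor $\beta D k_{tot} \Delta t \approx 0.04$ (the scheme
requires it below 1; variance distortion grows with it and is ~2% at
the default), 30 ns per window sampled every step, and the recovery
potential $U_0(x) = 0.1875\,(x-5)^2(x-9)^2$: a double well with minima
at 5 and 9 Å and a 3 kcal/mol midpoint barrier, scaled to exercise
multi-window overlap across the default ladder.

What the generator does *not* emulate: multidimensional slow degrees of
freedom orthogonal to the reaction coordinate, non-Markovian friction,
force-field error, or hysteresis between windows started from different
structures. Passing recovery tests therefore demonstrates correctness
of the estimator, not of any molecular simulation.

`analytic_pmf` provides the ground truth as bin-integrated Boltzmann
weights, $F_i = -kT \ln \int_{bin_i} e^{-\beta U_0}$, by adaptive
quadrature (`stats::integrate`, rel. tol. $10^{-10}$, energies shifted
by their grid minimum before exponentiating to avoid underflow).

## Flow-cytometry quantification

### Gating

The automatic gate reproduces "a perimeter containing 40% of events":
a product-Gaussian kernel density over (FSC-H, SSC-H) is evaluated
**exactly at every event** (a compiled O(n²) kernel; no raster
interpolation), and the gate keeps the $\lceil 0.4\,n \rceil$ densest
events — the density threshold is the corresponding per-event density
quantile, so the enclosed fraction is exact by construction, with ties
broken by input order. A raster contour polygon at that threshold can
be computed for display, and affects nothing downstream. Bandwidths
default to Silverman's rule of thumb per axis (`stats::bw.nrd0`); the
enclosed-fraction contract, not the kernel, is the normative part, and
the brute-force comparison tests only require the density *ranking* to
be stable. Zero variance on either scatter axis is an error.

### Outlier screening, threshold, readout

Experiments are screened for samples whose gate drifted (unexpected
cell size): per axis, gate centroids are summarised by median and MAD
(`stats::mad`, consistency constant 1.4826, so the cutoff — default
5 — is in robust-SD units), and a sample further than the cutoff on
either axis is flagged. A zero MAD flags nothing on that axis. This is
an automated replacement for by-eye screening, so the cutoff is
deliberately loose and configurable; at least 3 samples per experiment
are required.

The ON/OFF threshold is the 99.9th percentile of the gated
negative-control fluorescence, computed by linear interpolation between
the closest order statistics (`quantile` type 6). That convention is
chosen so that exactly 99.9% of the 4000 gated negative-control values
sit at or below the threshold — e.g. for gated values $1..4000$ it
lands between the 3996th and 3997th order statistics — which makes the
expected false-ON rate of a pure negative control exactly 0.1%.
`fraction_on` uses a strictly-greater comparison at the threshold, so
the negative control's own threshold region stays OFF.

Group summaries report mean ± s.e.m. ($sd/\sqrt{n}$, sample sd;
undefined for $n=1$), and `compare_conditions` wraps Welch's two-sided
t-test and the two-sided Wilcoxon rank-sum test (exact for combined
$n \le 20$ without ties, normal approximation with continuity
correction above). Two constant, equal groups give $p = 1$ by
convention.

### Synthetic mixtures

`simulate_cytometry` draws each event as debris (5% by default, broad
low-scatter log-normal — included so the gate has something to
exclude), otherwise ON with the requested probability. Scatter is
bivariate log-normal; fluorescence is log-normal with OFF median 5 and
ON median 500 (arbitrary cytometer units, a 100-fold separation typical
of a bright reporter over autofluorescence). These are stand-ins with
stated distributions, not estimates of any deposited dataset; real
instrument effects (spillover, saturation, time drift, doublets) are
out of scope, and the CSV event-table dialect is the canonical input.

## qPCR excision quantification

`fit_standard_curve` regresses Ct on $\log_{10}$(known quantity) for
calibration mixtures of edited and non-edited DNA (default ladder 0,
0.5, 1, 5, 10, 50, 70, 90, 100%). Zero-quantity mixtures cannot
amplify; they are excluded and counted, never imputed — the fitted
slope and intercept are identical whether or not the 0% rows are
present. The amplification efficiency is $10^{-1/slope} - 1$. A
non-negative slope attaches a warning rather than failing, so that
degenerate calibrations remain inspectable.

Samples invert through $q = 10^{(Ct - a)/b}$; replicate Ct values are
averaged *as cycles* before inversion (averaging quantities instead
would change estimates under noise; Ct averaging is the common
convention and is stated here because either choice is defensible).
`excision_fraction` divides the edited-assay quantity by the
total-template-assay quantity, each through its own curve; a ratio
above 1 — possible since both carry error — is flagged, not clipped.
A no-amplification edited assay gives fraction 0; a zero total is an
error.

The simulator draws $Ct = a + b\log_{10}(q) + N(0, \sigma)$ with
defaults $a = 30$ cycles, $b = -3.3219$ (100% efficiency),
$\sigma = 0.2$ cycles and 3 replicates — typical instrument
repeatability. It does not model efficiency differences between
mixtures, inhibitors, or the discreteness of very low copy numbers.

## Imaging quantification

Segmentation is an input (an integer label mask; 0 = background), not
a responsibility of the package. `cell_mean_fluorescence` reports the
mean gray value per labeled region. The background is estimated from
8 random disk regions (the count is configurable) placed entirely
outside all labels, each with area similar to a single cell (default:
the median cell area), non-overlapping, rejection-sampled with a retry
bound so placement is deterministic under a seed and fails loudly when
the image has too little free background. The estimate pools all
region pixels into one mean — identical to averaging the 8 region
means when areas are equal, and slightly better conditioned otherwise.

The corrected intensity is cell mean minus background, computed on
pooled pixel sums with a common denominator,
$(S_c n_b - S_b n_c)/(n_c n_b)$: on integer images this cancels a
constant offset *exactly* (bit-for-bit), which is the natural
invariance for a subtractive background model. Corrected values may be
negative under noise and are never clipped. One background per image
is used, matching a per-image (not per-cell) subtraction scheme;
time-lapse frames are processed independently.

The synthetic images are uniform backgrounds with non-overlapping
constant-intensity disks plus Gaussian noise clipped at zero — enough
to verify the estimator's arithmetic and invariances, but not an
emulation of real point-spread functions, uneven illumination, or
segmentation error.

## The runner

`default_config()` carries every analysis constant at its canonical
value (13 bins on [3.75, 10.25] Å, tolerance 0.01 kcal/mol, 5 ns/5 ns
blocking, 310 K, 40% gate, 99.9th percentile, 5-MAD screening,
8 background regions). `validate_config()` returns one finding per
violated field with its allowed domain; `run_pipeline()` executes the
requested stages in dependency order, derives every stage seed from
the single configuration seed, serialises floats with 9 significant
digits, and returns a record with per-stage timings and an MD5
manifest — identical configurations reproduce byte-identical CSVs.
FCS list-mode reading is not included; event tables travel as CSV.

## Test and validation scale

The validation suite was sized for a laptop-class single CPU: PMF
recovery uses the full 13-window, 30 ns default budget across 20 seeds
(about 15 s); cytometry checks gate 10,000-event samples exactly as the
defaults prescribe, with 2,500-event samples for the 50-replicate
negative-control calibration; qPCR bias checks use 100 seeded
simulations. The statistical tests compare replicate means against
their empirical standard errors rather than fixed magic numbers, so
they remain meaningful if defaults change.

## Known limitations

- No MBAR and no autocorrelation-aware decorrelation: error bars come
  from 5-ns blocking only, and are honest only when blocks are longer
  than the slowest relaxation along the coordinate.
- Periodic or multidimensional reaction coordinates are unsupported.
- The density gate assumes a unimodal main population; it encloses a
  fixed fraction and will happily bridge two modes of similar density.
- qPCR quantification assumes a shared, constant amplification
  efficiency across the calibration range.
- Background estimation needs enough cell-free area; crowded images
  fail loudly rather than degrading silently.
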