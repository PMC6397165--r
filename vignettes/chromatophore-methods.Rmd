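---
title: "Methods: quantitation, optics and color dynamics in the chromatophore package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitation, optics and color dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromatophore)
```

## Scope

Cephalopod chromatophores are neuromuscular pigment organs: radial muscles
expand a pigment-filled cell (the chromatocyte) into a colored disc, and the
membranous sheath cells that envelop it can act as a wavelength-selective
reflector. This package implements the quantitative analyses such a study
needs: label-free protein quantitation from spectral counts, the
identification/annotation acceptance rules applied to search-engine and
BLAST tables, a thin-film interference model of sheath-cell multilayers,
construction of pigment absorption spectra from excited-state line lists,
pH-titration analysis, and region-of-interest (ROI) color extraction from
movie frames. A synthetic-data generator provides inputs with the
statistical structure each stage assumes.

## Spectral-count quantitation

The quantitation substrate is a protein-by-sample table of spectral counts
$c_{p,s}$. Two normalizations are applied:

1. **Loading normalization.** Assuming the total protein content per sample
   is similar, the column totals $T_s=\sum_p c_{p,s}$ estimate relative
   loading. Loading factors are $f_s = T_s / T_{\mathrm{ref}}$ and counts
   are divided by them. The default reference is the sample with the
   smallest total, which yields factors $\ge 1$ (for yellow/red/brown
   chromatophore pools with totals in ratio 1 : 2.2 : 1.8 this fixes yellow
   at 1). The reference is configurable because the convention, not the
   arithmetic, is a choice.
2. **Peptide scaling.** Larger proteins produce more detectable tryptic
   peptides, so raw counts over-represent them. The abundance index divides
   by the protein's expected tryptic peptide count $k_p$ and rescales by
   the proteome mean $\bar k$:
   $$\mathrm{AI}_{p,s} = \frac{c_{p,s}/f_s}{k_p}\,\bar k.$$
   The published chromatophore proteome of 469 entries has $\bar k = 65.5$;
   the package recomputes $\bar k$ from whatever protein set it is given.
   Because reported "normalized peptide counts" are printed as integers,
   both the float index and a nearest-integer view (half away from zero)
   are returned.

Loading normalization is applied before peptide scaling, following the
order in which the two steps are described for this analysis; the reference
column is unaffected by the order either way. A `normalize_loading = FALSE`
mode exists for granule/pigment samples, where protein loading is
deliberately not normalized between samples.

$k_p$ comes from in-silico trypsin digestion: cleavage C-terminal to K or
R, suppressed before P (the proline rule, default on), terminal K/R
producing no empty peptide. Default digest parameters are 0 missed
cleavages and no length or mass filter — the expected-peptide definition
behind the scaling does not state digest settings, so the package exposes
all of them (`missed_cleavages`, `proline_rule`, `min_length`,
`mass_window`) and defaults to the plainest rule. With `missed_cleavages =
m`, every run of up to $m+1$ adjacent fully-cleaved fragments is emitted,
so with $F$ fragments the count is $\sum_{j=0}^{m}\max(F-j,0)$. Peptides
failing filters are dropped from the returned list but recoverable via
`keep_all = TRUE`. Unknown residues (X) are legal and contribute zero mass;
a notice is emitted when a mass window is active.

Contaminant filtering partitions records by case-insensitive description
rules (defaults: bacterial ribosomal proteins and the preparation enzymes
trypsin, collagenase, papain) plus an id blocklist; kept + removed always
equals the input, and each removed record carries the rule that fired.

### Identification and annotation thresholds

Acceptance rules follow the printed operators exactly, because such rules
are often misread: identifications keep entries with protein score
$\ge 22$ **and** discriminant score $\ge 0.0$ **and** peptide expectation
value $\le 0.01$ (all inclusive); annotation hits keep e-value
$\le 10^{-10}$; and a polypeptide is classified S-crystallin (vs its GST
homologs) only with **strictly** more than 90% query coverage and strictly
more than 60% identity. When no coverage column is present, coverage is
alignment length / query length × 100; a union-of-intervals option merges
overlapping alignments of the same query/subject pair, since multi-domain
hits otherwise double-count.

## Thin-film interference model

Sheath-cell membranes and cytoplasm form an alternating dielectric stack
around the chromatocyte. Two model levels are provided:

* the **two-beam condition** $m\lambda = 2\,(n_a d_a\cos\theta_a +
  n_b d_b\cos\theta_b)$, with internal angles from Snell's law, which gives
  the constructive wavelength in closed form; and
* the full **characteristic-matrix (transfer-matrix) recursion**, per layer
  and polarization, with unpolarized reflectance the mean of s and p. For
  lossless stacks $R+T=1$ holds to better than $10^{-9}$ (the suite
  observes $\sim 10^{-15}$), and an empty stack reduces to the Fresnel
  interface result.

Refractive indices are not part of the measured data, so defaults are the
standard values $n_a = 1.33$ (cytoplasm) and $n_b = 1.46$ (lipid
membrane), overridable everywhere; ambient and substrate default to the
cytoplasm index because the stack is embedded in tissue. Dispersion is
neglected (constant $n$ across the visible) and the default wavelength
grid is 380–750 nm at 1 nm. The number of participating layer pairs per
sheath-cell wrap is unknown and therefore a parameter (`n_pairs`,
default 8; the two-beam/full-wave agreement check uses 12).

Measured layer heights are emulated by truncated-normal draws: cytoplasm
116 ± 102 nm ($n = 292$) and membrane 71 ± 14 nm ($n = 237$). Since the
cytoplasm sd exceeds its mean, a lower truncation bound (default 10 nm)
is required; draws below it are resampled. Note the truncation shifts the
realized cytoplasm mean above 116 nm (the closed-form truncated mean is
$\sim$144 nm at these parameters) — the stated mean/sd are used as the
underlying normal's parameters, not re-fit to the truncated draw.

**Expansion.** A layer conserving volume while spreading $f$-fold in area
thins $f$-fold; `expand_layers()` implements this (optionally holding
membrane layers fixed, since a bilayer has a set thickness). The two-beam
wavelength is strictly decreasing in $f$ — the blue shift on actuation —
and strictly increasing in each of $d_a$, $d_b$, $n_a$, $n_b$. The
full-wave peak obeys the same monotonicity while the fundamental remains
inside the modeled band; at the paper-mean geometry the first-order peak
($\sim$516 nm at rest) exits the near-UV edge at roughly 2.5× areal
expansion, so sweeps track it only up to that point. Physically, this is
the statement that a maximally distended stack no longer reflects in the
visible.

**Rendering.** Perceived color is obtained by integrating spectrum ×
illuminant against the CIE 1931 2° color-matching functions, adapting the
illuminant white to the sRGB D65 white point, applying the linear
XYZ→sRGB matrix and gamma-encoding. The CMFs use the multi-lobe piecewise
Gaussian analytic fit (accurate to about a percent), which keeps the
package free of numeric tables; out-of-gamut colors are clipped with a
notice. The default illuminant is equal-energy.

## Pigment spectra and titration

Absorption spectra are built from excited-state line lists (wavelength +
oscillator strength, as produced by TD-DFT calculations at typically 200
states) by Lorentzian broadening with FWHM 30 nm:
$$A(\lambda)=\sum_i f_i\,\frac{(\gamma/2)^2}{(\lambda-\lambda_i)^2+(\gamma/2)^2},
\qquad \gamma = \mathrm{FWHM}.$$
Broadening is applied in the wavelength domain because the FWHM is stated
in nm; an energy-domain option (FWHM in eV) is provided and labeled, since
electronic-structure broadening is often done in eV. The envelope is
linear in the line list and scale-equivariant in the strengths. Spectrum
units are arbitrary; a max-normalization flag exists. Both the broadened
envelope's $\lambda_{\max}$ and (via the line list itself) the strongest
single excitation are accessible, since either convention is used for a
reported theoretical $\lambda_{\max}$.

pH series (absorbance at a fixed wavelength, e.g. 430 nm, versus pH) are
fit with a two-state Henderson–Hasselbalch model
$$A(\mathrm{pH}) = A_{\mathrm{acid}} +
\frac{A_{\mathrm{base}}-A_{\mathrm{acid}}}{1+10^{\,n(\mathrm{p}K-\mathrm{pH})}},$$
monotone between plateaus with midpoint at $\mathrm{pH}=\mathrm{p}K$.
Fitting is Levenberg–Marquardt least squares with a deterministic
initialization (p$K$ at the half-range pH, plateaus at the end values,
slope 1), so repeated fits are identical. Constant series are rejected as
degenerate. The synthetic titration default spans pH 1.9–8.9 (the
experimental titration range) with p$K = 5.65$, chosen as the midpoint of
a transition beginning near pH 3.6 and saturating near pH 7.7; plateau
absorbances 0.2 and 1.0 give an order-unity dynamic range.

## ROI color dynamics

A movie is a list of H×W×3 frames in [0, 255] at a fixed interval
(default 0.03 s/frame), and the measurement is the per-frame arithmetic
mean of each channel over a fixed window (default 20 × 20 px), computed in
floating point with no rounding, no background subtraction and no white
balance — raw stored units, because the camera's color space and gamma
are unknown. Channel order is fixed R, G, B regardless of file layout.
The per-frame dominant channel is the argmax with ties resolved by the
fixed priority R > G > B (logged).

## Synthetic-data generator

Each generator reproduces the statistical structure its consumer assumes,
is deterministic under a fixed seed (one global seed derives per-generator
substreams via `substream_seed()`), and stores its ground truth alongside
the data:

* `make_proteome()` — random sequences with configurable K/R and P
  frequencies, so expected peptide yields span a wide range
  ($\approx 1+(L-1)p_{KR}(1-p_P)$).
* `make_count_table()` — multinomial counts with sampling probability
  $\propto a_p k_p$: larger proteins yield more observable peptides, which
  is exactly the bias the peptide scaling inverts. This is the assumption
  implicit in scaling counts by expected peptides.
* `make_layer_measurements()` — truncated-normal thicknesses at the study
  sampling design (292 and 237 measurements).
* `make_titration_series()` — model curve plus Gaussian noise on a pH
  grid spanning 1.9–8.9.
* `make_movie()` — an expanding disc whose areal factor ramps linearly to
  15 (the maximal distension of a chromatocyte) and whose fill color per
  frame is the rendered transfer-matrix reflectance of the correspondingly
  thinned stack, normalized to peak reflectance so the disc is bright;
  optional additive Gaussian pixel noise.

What the generators do **not** emulate: real MS/MS identification noise
(shared peptides, FDR structure, saturation of spectral counting at high
abundance), correlated layer-thickness disorder, absorbing pigment layers
coupled into the optical stack, camera optics and compression artifacts,
or skin texture. Passing tests therefore demonstrate correctness of the
computations under their stated assumptions, not robustness to every
artifact of real data.

## Numerical choices and problem sizes

* Digest oracle checks run brute-force enumeration on 1000 random
  sequences (length ≤ 200, missed cleavages 0–2).
* Abundance recovery uses 50 proteins at sampling depth $10^4$ over 20
  replicate seeds; Spearman correlation between true abundance and the
  recovered index exceeds 0.9 in every replicate.
* The transfer matrix is validated against the closed-form quarter-wave
  admittance result and a reciprocity identity; two-beam vs full-wave
  agreement is checked at index contrast 0.13 with 12 pairs (≤ 5 nm).
* Titration recovery uses 30 points; noiseless round trips recover
  parameters to $10^{-6}$ and, at 2% noise over 100 seeds, the median
  |p$K$ error| stays below 0.1 pH units.
* Movies for round-trip tests are 80×80 px and ≤ 10 frames; the noiseless
  ROI trace matches the ground-truth colors to within 1/255 per channel.

These sizes make the whole suite run in well under a minute while leaving
every statistical margin (3 SE bounds, median errors) comfortably wide.

## Known limitations

* Reproducing published absolute values (e.g. specific normalized peptide
  counts per protein, or $\bar k = 65.5$) requires the study's deposited
  supplementary tables and sequences; the package implements the exact
  pipeline but ships no third-party data.
* Constant refractive indices and lossless layers: no dispersion, no
  absorption coupled into the stack, no 2D/3D photonic structure.
* The coverage definition for multi-domain BLAST hits is not standardized;
  both per-hit and union-of-intervals coverage are offered, and the choice
  can change S-crystallin classification near the 90% boundary.
* Spectral counting itself is semi-quantitative; low-abundance proteins
  have noisy indices, and the multinomial generator reproduces exactly
  that behavior.
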