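---
title: "Methods: absolute quantification and chromatin-binding kinetics of cohesin"
author: "cohesinCensus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: absolute quantification and chromatin-binding kinetics of cohesin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohesinCensus)
```

This vignette is the package's own account of the science it implements:
the models, their assumptions, the tunable parameters, what the synthetic
generators do and do not emulate, and the numerical choices made where the
design was genuinely open.

## 1. The measurement problem

Cohesin (core subunits SMC1, SMC3, SCC1 and STAG1 or STAG2) both holds
sister chromatids together and organises interphase chromatin into loops
and TADs, positioned by CTCF. Mechanistic models of loop extrusion and
cohesion depend on *absolute* numbers: how many complexes exist per
nucleus, how many are chromatin-bound, for how long, and how these compare
with the number of genomic enrichment sites. The package implements three
orthogonal quantification routes — FCS (per-cell concentrations),
iFRAP (binding kinetics and pool partition) and spike-in SRM
(population-average copies per cell) — plus the equilibrium model and the
genomic arithmetic that tie them together.

## 2. FCS: two-component diffusion model

An FCS measurement records photon counts in a femtolitre-scale confocal
volume; concentration fluctuations of diffusing fluorescent molecules make
the autocorrelation function (ACF) informative. The package fits

$$G(\tau) = o + \frac{1}{N}\sum_{i=1,2} f_i
  \left(1+\frac{\tau}{\tau_i}\right)^{-1}
  \left(1+\frac{\tau}{\kappa^2\tau_i}\right)^{-1/2},$$

a two-component free-diffusion model in a 3D Gaussian focal volume.
The two diffusion times accommodate a fast (free) and a slow
(chromatin-interacting) population; $1/N$ is the amplitude at
$\tau \to 0$. Assumptions: Gaussian detection profile, no triplet-state
blinking (an optional `triplet = TRUE` correction factor
$1 + \tfrac{T}{1-T}e^{-\tau/\tau_T}$ exists but is off by default, since
the curves this package targets are fit without one), and a structure
parameter $\kappa$ fixed from the dye calibration rather than fit
(defaults to 5 when no calibration is supplied — freeing $\kappa$ trades
a poorly identified axial ratio against $N$).

Key parameters:

| parameter | units | default | role |
|---|---|---|---|
| `kappa` | — | 5 | axial/lateral focal ratio; fix from calibration |
| `r2Min` | — | 0.92 | QC: minimum fit $R^2$ |
| `chisqMax` | — | 1.2 | QC: maximum $\chi^2/N_{\mathrm{pts}}$ |
| `tukeyK` | — | 3 | QC: CPM outlier fence multiplier |
| `cpmCap` | — | 10 | QC: CPM cap vs free mEGFP |
| dye concentration | nM | 50 | volume calibration standard |
| $V_r$ | — | 3.04 / 5.72 | cell/nucleus volume ratio (interphase / prometaphase) |

**$\chi^2/N$ definition.** The per-point noise variance is not recorded by
the instrument, so it is estimated from the fit residuals in the *last
decade of lags*, where the ACF is flat and residuals are pure noise. FCS
noise is strongly lag-dependent (shot noise scales with the correlation
amplitude), so the tail estimate anchors the noise *scale* while the
photon-statistics profile $\sigma(\tau) \propto G(\tau) + 1/N$ sets the
per-lag *shape*. A tail-only (flat) variance would systematically inflate
$\chi^2$ for perfectly good fits by under-weighting short lags.

**CPM cap direction.** The cap removes fits whose counts-per-molecule is at
or above `cpmCap` times the mean free-mEGFP CPM, i.e. *keeps* CPM below the
cap: bright outliers are aggregates or misfits, while the monomer check is
done separately by `cpmStoichiometry()` (ratio ≈ 1 monomer, ≈ 2 dimer).
The per-rule rejection counts in the QC report make the rule auditable.

**Fitting.** Bounded Levenberg–Marquardt (`minpack.lm`), `frac1` in
$[0,1]$, diffusion times relabelled post-fit so $\tau_1 \le \tau_2$ (the
model is symmetric under component exchange). Non-convergence triggers one
single-component fallback; a fit that still fails is *flagged*, never
returned as numbers, and the QC cascade drops it.

## 3. iFRAP: exponential dissociation kinetics

Inverse FRAP bleaches half the nucleus and follows the *difference* between
unbleached and bleached regions; its decay reflects chromatin dissociation,
not diffusion (exchange across the nucleus is fast relative to the 1-min
frame interval — the package's normalisation assumes this). Curves are
normalised to the pre-bleach mean and anchored to 1 at the first
post-bleach frame.

Two nested models are fit: $e^{-k_{\mathrm{off}1}t}$ and
$a e^{-k_{\mathrm{off}1}t} + (1-a) e^{-k_{\mathrm{off}2}t}$, with hard box
bounds $1/k_{\mathrm{off}2} \in [1.5, 15]$ h on the slow residence time —
outside that window a 40–60 min experiment carries no information about the
slow rate, so boundary-pinned estimates are flagged as censored rather than
reported as free optima. Model choice uses AICc (ties to the single model
by parsimony): a criterion was preferred over visual assessment because the
G1/G2 distinction should be reproducible, and both fits and both scores are
always retained. The fits run on `minpack.lm::nls.lm` directly so that a
degenerate second component ($a \to 1$) returns its parameter vector
instead of failing on the singular gradient.

The soluble fraction comes from the unbleached-region signal drop during
the bleach: $s_{\mathrm{sol}} = ((\mathrm{pre}-\mathrm{post})/\mathrm{pre})
/ f_{\mathrm{bleached}}$ with the bleached volume fraction defaulting to
0.5 (half-nucleus bleach; configurable because bleach geometry varies).
The nuclear pool then partitions as soluble / dynamic
($(1-s_{\mathrm{sol}})a$) / stable ($(1-s_{\mathrm{sol}})(1-a)$), summing
to one by construction, and multiplies against the FCS nuclear median to
give per-population copy numbers whose total is preserved exactly.

## 4. SRM: spike-in absolute quantification

Endogenous (light) peptides are quantified against spiked heavy-labelled
reference peptides — soluble extracts at 2.5/5 fmol, chromatin extracts at
10/15 fmol — from the height of the elution apex of each of three
transitions per peptide. The cascade is
transition → peptide (mean of retained transitions) → copies per cell
(fmol · $N_A$ / cells, with 62,500 cells per chromatin aliquot) → protein
(unweighted mean across peptides; the printed tables do not state the
combiner, so the mean is used and the peptide count is flagged so a median
variant can be compared). The SD is taken across all peptide × replicate
values. A peptide whose transitions are all retracted is *missing*, never
zero. The measured 17% acetone-precipitation loss is exposed as an
optional multiplicative correction (`lossCorrection = 1/(1-0.17)`), off by
default because it is not stated whether the published values include it.
Stoichiometry ratios against SCC1 use per-replicate ratios and a 95%
t-interval; STAG1 and STAG2 can be summed per replicate before ratioing.

## 5. The equilibrium binding model

With $C_T = U + D + S$ (unbound, dynamic, stable) and detailed balance
$k_{on}U = k_{off}D$, the bound fraction is affine in the stable fraction:

$$b_T = \frac{k_{on}}{k_{on}+k_{off}} + \frac{k_{off}}{k_{on}+k_{off}}\,s,
\qquad \text{intercept} + \text{slope} = 1 .$$

G1 cells have no stable pool ($s=0$), so their bound fraction fixes the
intercept; the model then predicts G2 from the measured stable fraction
alone, *assuming the kinetic rate constants are unchanged between G1 and
G2* — the model asserts this assumption, it does not test it. Only the
rate *ratio* is identified from fractions; supplying $k_{off}$ (e.g.
1/residence time from iFRAP) anchors absolute rates. Fractions are carried
at full precision; three-decimal rounding happens only in the report layer.

```{r equilibrium}
params <- calibrateFromG1(0.635)
boundFraction(0.367, params)
partitionEquilibrium(250755, 0, params)
```

## 6. Genomic occupancy arithmetic

Peak sets are BED-convention intervals (0-based half-open, strand
ignored), sorted and merged on load. Design choices:

* **Genome sizes in Gb.** The mappable human genome is taken as 2.7 Gb and
  the (polyploid) HeLa genome as 7.9 Gb; site counts scale linearly
  between them.
* **Distance anchor.** Inter-peak distances are midpoint-to-midpoint
  between *consecutive* peaks on the same chromosome (never across
  chromosomes); an edge-to-edge variant is available via
  `anchor = "edge"`. Consecutive (not all-pairs) distances are the
  declared reading of "pairwise genomic distances".
* **Connected sites.** Overlap across datasets is counted on connected
  components of mutually overlapping intervals: one entry per component,
  labelled by contributing sets, so per-set totals never exceed raw peak
  counts. Abutting half-open intervals share no base and are *not*
  connected (`min.gapwidth = 0`).
* **Report-layer rounding** (nearest thousand / hundred / integer) is a
  separate function; raw values are never lost.

## 7. What the synthetic generators emulate — and what they do not

The generators provide every stage with inputs of known ground truth:

* **FCS**: the exact two-component ACF plus additive Gaussian noise with
  SD proportional to $G(\tau)+1/N$ — a simple stand-in for photon
  statistics on a quasi-logarithmic (multiple-tau) lag ladder. Not
  emulated: photon arrival times, detector afterpulsing, bleaching during
  acquisition, triplet blinking. The noise structure of the real
  instrument is not documented, so the Gaussian model is a stated choice.
* **iFRAP**: 1- or 2-exponential difference decays with a soluble pool
  encoded in the pre/post unbleached intensity pair, plus white noise on
  the normalized signal. Not emulated: diffusion-limited recovery,
  photobleaching during imaging beyond the stated normalisation.
* **SRM**: three transitions per peptide with fixed per-transition
  response factors and mean-one log-normal ratio noise (heights are
  positive; the `cv` is the SD of the log-ratio). Not emulated:
  chromatograms, interference, retention-time scheduling.
* **Peak sets**: non-overlapping fixed-width peaks with configurable
  midpoint-spacing distributions (exponential, constant, log-normal);
  spacings below the peak width are redrawn, a negligible truncation when
  the width is far below the mean spacing.

Each generated entity draws from its own seeded substream, so enlarging an
experiment never perturbs existing cells' noise, and identical seeds give
byte-identical outputs. Passing parameter-recovery tests on these inputs
demonstrates that the estimators are unbiased and correctly scaled *under
the stated noise models*; it does not certify performance under real
instrument artefacts (afterpulsing, drift, chromatographic interference).

## 8. Numerical choices and degenerate inputs

* Percentiles (median, central 68% interval) use linear interpolation
  between order statistics (quantile type 7).
* The bootstrap method comparison resamples each method's full sample with
  replacement per iteration, computes a summary statistic (median by
  default, matching how the copy-number distributions are summarised) for
  each, and takes the ratio; the median and 16th–84th percentile of the
  ratio distribution are reported. This resampled-statistic reading was
  chosen over single-measurement pairing because only it yields a 68%
  interval with ~68% coverage of a true ratio, which the test suite
  verifies. Zero-denominator draws are redrawn and counted.
* A constant iFRAP signal pins the dissociation rate at its lower bound
  (1e-6/min) with a warning; a soluble-fraction estimate outside $[0,1]$
  is clipped with a warning; a negative signal drop returns 0.
* Zero copies, empty QC input, and single-value summaries are all legal
  and return the obvious limits; empty peptide sets and zero reference
  medians are errors.

## 9. Experiment sizes used in the tests

The test suite runs the recovery experiments at the scale of the study
design: 200 ACF curves with cell-to-cell concentration spread (log-SD
0.25, median 330 nM), 19 iFRAP cells per condition at 1-min sampling
(41 frames for G1-like, 61 for G2-like experiments — an hour of imaging
is the natural window for resolving an 8.6 h slow component against the
[1.5, 15] h constraint box), SRM tables with 2 biological × 2 technical
replicates at 10% CV, 500-repeat bootstrap calibration and 100 random
interval-graph instances for the overlap oracle.

## 10. Known limitations

* The FCS fitter assumes pure diffusion; binding-dominated correlation
  decays would bias $\tau_2$ and, through the QC cascade, the retained
  set.
* The iFRAP model ignores diffusion during recovery; with a 1-min frame
  interval this is safe for residence times of minutes to hours, not for
  sub-minute exchange.
* The equilibrium model is deterministic and spatially homogeneous; no
  stochastic or spatial extension is attempted.
* SRM aggregation assumes equimolar peptide response after the spike-in
  normalisation; systematic per-peptide recovery differences propagate
  directly into the protein mean (the per-peptide flags expose how thin
  the support is).
* Genome-occupancy arithmetic treats site density as uniform between the
  mappable and full genome and ignores CTCF site orientation entirely.
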