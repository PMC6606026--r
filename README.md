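# cohesinCensus

Absolute copy numbers and chromatin-binding dynamics of cohesin, CTCF and
their regulators in human (HeLa) cells: an R package implementing the full
quantitative machinery that turns raw fluorescence-correlation spectroscopy
(FCS) curves, inverse-FRAP time series, selected-reaction-monitoring (SRM)
transition tables and ChIP-seq peak coordinates into absolute protein copy
numbers, chromatin residence times, soluble/dynamic/stable pool sizes and
genome-occupancy estimates.

## Who it is for

Quantitative cell biologists and proteomics/imaging analysts who need to

* convert FCS autocorrelation curves into absolute nuclear and cytoplasmic
  protein concentrations and copy numbers,
* partition a nuclear pool into soluble, dynamically chromatin-bound and
  stably chromatin-bound populations from iFRAP recovery curves,
* derive copies-per-cell from spike-in SRM measurements with replicate
  statistics and subunit stoichiometries,
* relate bound copy numbers to genomic binding-site counts.

All stages are fed by seeded synthetic-data generators with known ground
truth, so the whole pipeline is testable end-to-end without any external
download.

## The models at the core

**FCS.** The autocorrelation of the fluorescence signal is fit to a
two-component 3D diffusion model

G(&tau;) = o + (1/N) &Sigma;<sub>i=1,2</sub> f<sub>i</sub>
(1+&tau;/&tau;<sub>i</sub>)<sup>-1</sup>
(1+&tau;/(&kappa;&sup2;&tau;<sub>i</sub>))<sup>-1/2</sup>

whose amplitude gives the particle number N in the confocal volume. A dye
standard of known concentration (50 nM) calibrates the effective volume
V<sub>eff</sub> = N/(C&middot;N<sub>A</sub>); copy numbers follow from
C&middot;V&middot;N<sub>A</sub> with compartment volumes (V<sub>cyt</sub> =
V<sub>nuc</sub>(V<sub>r</sub> − 1)). Quality control keeps fits with
R&sup2; > 0.92 and &chi;&sup2;/N < 1.2, then removes counts-per-molecule
(CPM) outliers by Tukey's fences (3&times;IQR) and any fit at &ge; 10&times;
the free-mEGFP CPM.

**iFRAP.** The normalized bleached/unbleached difference signal is fit with
f(t) = exp(−k<sub>off1</sub>t) or
f(t) = a&middot;exp(−k<sub>off1</sub>t) + (1−a)&middot;exp(−k<sub>off2</sub>t),
the slow residence time 1/k<sub>off2</sub> box-constrained to [1.5, 15] h,
model choice by AICc. The unbleached-signal drop estimates the soluble
fraction; bound = 1 − soluble splits into dynamic (a) and stable (1−a).

**Equilibrium model.** With on/off rates balanced
(k<sub>on</sub>U = k<sub>off</sub>D), the chromatin-bound fraction is affine
in the stable fraction s:
b<sub>T</sub> = k<sub>on</sub>/(k<sub>on</sub>+k<sub>off</sub>) +
k<sub>off</sub>/(k<sub>on</sub>+k<sub>off</sub>)&middot;s, with intercept +
slope = 1. Calibrated at s = 0 (G1), it predicts the G2 bound fraction.

**SRM.** fmol<sub>light</sub> = (light/heavy apex height)&middot;spiked
fmol, averaged over retained transitions and peptides, converted by
N<sub>A</sub>/cells to copies per cell; stoichiometry ratios against SCC1
carry 95% t-intervals.

**Genome occupancy.** Site counts in the mappable genome (2.7 Gb) scale to
the full HeLa genome (7.9 Gb); inter-peak spacings are midpoint distances of
consecutive peaks per chromosome; overlapping peaks across datasets are
counted as connected genomic sites (one entry per connected component).

## Worked example

```r
library(cohesinCensus)

## calibrate the confocal volume from a 50 nM dye standard
dye <- fitAcf(simulateFcsMeasurement(
  fcsTruth(nParticles = 12, tau1 = 0.03, tau2 = 0.03, frac1 = 1),
  cellId = "dye"))
cal <- calibrateConfocalVolume(dye, 50)
effectiveVolume(cal)
#> [1] 3.985294e-16          # litres, ~0.4 fl

## a synthetic nuclear FCS measurement at cohesin-like concentration
targetN <- 330e-9 * effectiveVolume(cal) * 6.02214076e23
fit <- fitAcf(simulateFcsMeasurement(
  fcsTruth(nParticles = targetN, tau1 = 0.5, tau2 = 30, frac1 = 0.4,
           cpm = 10, noiseSdScale = 0.02, seed = 42)))
fit
#> AcfFit: N = 78.58, tau1 = 0.4157 ms, tau2 = 27.72 ms, frac1 = 0.376
#>   kappa = 5, offset = -4.16e-05, R2 = 0.9910, chi2/N = 1.035, CPM = 10.1 kHz
concentrationFromFit(fit, cal)
#> [1] 327.432               # nM, truth was 330
copiesFromConcentration(327.432, 1247)   # a 1247 um^3 nucleus
#> [1] 245888.6              # ~250,000 nuclear copies

## equilibrium model: calibrate on G1, predict G2
params <- calibrateFromG1(0.635)
params
#> EquilibriumParams: bT(s) = 0.635 + 0.365 s
boundFraction(0.367, params)
#> [1] 0.768955              # vs 0.728 observed in G2
partitionEquilibrium(250755, 0, params)
#> EquilibriumState: cT = 250755; U = 91525.6 (0.365), D = 159229 (0.635),
#>   S = 0 (0.000); bT = 0.635

## genome occupancy arithmetic
scaleToGenome(40000, 2.7e9, 7.9e9)$rounded
#> [1] 117000                # cohesin enrichment sites per HeLa genome
extrusionRate(185, 13.7)$raw
#> [1] 13.50365              # kb/min to extrude a median TAD in one residence
```

The fitted N is the particle count in the focal volume; dividing by the
calibrated volume and Avogadro's constant gives the concentration, and the
nuclear volume converts that to copies. The equilibrium prediction of the
G2 bound fraction (0.769) sits within 0.041 of the measured 0.728,
consistent with unchanged binding kinetics plus a stabilised subpopulation.

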