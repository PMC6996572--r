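---
title: "Methods: quantitative SILAC complexome profiling"
author: "complexomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative SILAC complexome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(complexomics)
```

# The experiment and its data model

A complexome profiling experiment separates intact protein complexes on a
blue-native gel, cuts the lane into `n_slices` consecutive slices (64 by
default; slice 1 is the top of the gel, where the largest native species
run) and quantifies peptide intensities per slice by mass spectrometry.
With SILAC labeling, two biological conditions are mixed 1:1 into the same
lane and read out as the heavy (H) and light (L) channel of one run; a
second experiment with swapped labels (*reciprocal labeling*) controls for
label-specific artifacts.

The package's sole quantitative input is the long-form
`PeptideSliceTable`: one row per (experiment, channel, protein, peptide,
slice) with a non-negative intensity in arbitrary units. Two conventions
are load-bearing:

* **Zero means unobserved.** A zero intensity and an absent row are
  equivalent; no imputation is ever performed and writers omit zero rows.
* **Keys are unique.** A duplicated (experiment, channel, protein,
  peptide, slice) key is an upstream processing error and is rejected, not
  silently summed.

# Native-mass calibration

Complexes of known mass define a calibration between slice position and
native mass. We fit, by ordinary least squares,

$$\log_{10}(\mathrm{mass\ [kDa]}) = a + b \cdot \mathrm{slice}, \qquad b < 0,$$

the standard Ferguson-style log-linear law for blue-native gels. The
experimental literature typically states only that complexes and
supercomplexes were used "as the standards to generate a calibration
curve"; the single log-linear fit (rather than a piecewise or spline
curve) is this package's documented choice, and the residual standard
deviation of the fit is reported so users can judge its adequacy. A fitted
slope that is not negative means the slice axis is inverted relative to
the expected gel orientation and is treated as an error, not corrected
silently. Standards are trusted point estimates; no errors-in-variables
model is attempted, since positional jitter of well-chosen standards is
small relative to their spread along the lane.

Mass windows (`massWindowToSlices()`) translate a relative window
$[m(1-t),\, m(1+t)]$ (default $t = 0.10$) into fractional slice bounds.
Because the window width in slices is $\log_{10}\frac{1+t}{1-t}/|b|$,
a ±10% window spans about 0.9 slices at $|b| = 0.1$ and about 2.4 slices
at the reference scenario's $|b| = 0.036$. Windows narrower than half a
slice are below the sampling resolution of the gel and are widened to one
slice with a warning; wider-than-half-slice windows are used as computed,
with linear interpolation of the trace at the fractional endpoints.

# From peptide tables to migration profiles

1. **Aggregation.** A protein's per-slice trace in one sample is the sum
   of its peptide intensities (`method = "sum"`). Heatmaps instead use the
   single most frequently observed peptide of that sample (`"top_peptide"`;
   the peptide with non-zero intensity in the most slices, ties broken by
   larger total intensity, then lexicographically smaller peptide id) —
   mirroring the two presentation styles used in the field. Sums are less
   noisy and are the default for traces.
2. **Orientation.** The labeling design maps each experiment's H and L
   channels to conditions; all downstream code sees conditions only.
3. **Joint normalization.** Within one mixed lane, the two condition
   traces of a protein are divided by the single maximum over both, so the
   maximum becomes 1.0 *and the relative scale between conditions is
   preserved* — the between-condition comparison comes entirely from the
   two channels of the same lane, with no external normalization. Whether
   the original analyses normalized jointly or per cell line is not
   documented; joint normalization within the mixed lane is this package's
   choice because it keeps every intra- and inter-condition intensity
   ratio invariant (a property the tests assert).
4. **Merging.** The per-experiment traces are averaged into mean ± SEM
   profiles. With the canonical two reciprocal experiments the SEM is the
   exact two-point formula $|x_1 - x_2|/2$; no inferential power is
   pretended at $n = 2$. A single-experiment profile carries an all-zero
   SEM and $n = 1$.
5. **Condition ratios.** The per-protein abundance ratio between
   conditions is the median, over all peptide-slice cells quantified in
   *both* channels, of the oriented intensity ratio, reported as log2 and
   averaged over experiments. Proteins with no shared cells (e.g. found in
   only one cell line, or migrating at disjoint positions) have an
   undefined ratio and are reported per-sample only.
6. **Module averaging.** Assembly modules (e.g. the complex I N/Q/ND
   modules) are predefined subunit groups; the module trace is the
   unweighted per-slice mean of the members' normalized mean traces, with
   the SEM taken across members (the profile's `n` then records the member
   count). Members without a quantifiable profile are skipped with a
   message. Module membership beyond the subunit–module assignments
   planted in the reference scenario is user-supplied annotation.

# Peak detection and quantification

Areas under profiles are trapezoid integrals on the integer slice axis
(unit spacing, x = slice number), never resampled to the mass axis —
resampling to the strongly nonlinear mass axis would distort relative
areas. Peaks are local maxima of the 3-point moving-average-smoothed trace
with height at least `minProminence` (default 0.1) times the profile
maximum and centers at least `minSeparation` (default 2) slices apart
(taller peaks win); centers are refined by parabolic interpolation on the
raw trace (error below 0.25 slices for a band of one-slice width, which
the tests verify by grid evaluation), and integration bounds sit at the
flanking minima. Both prominence and separation are exposed as arguments.
Windowed areas (the default for targeted quantification, e.g. "how much
N-module signal sits at the holo-complex mass") use the calibrated mass
window rather than flanking minima; both are available because the
literature does not define peak boundaries for such figures.

Cross-condition window ratios are percentages of jointly normalized
areas. Group comparisons of replicate AUCs delegate to a standard
two-factor (subject × condition) ANOVA with Sidak-adjusted per-subject
contrasts (emmeans); the package deliberately re-derives nothing here.

# Immunopurification scoring

Reciprocal co-IP SILAC experiments are summarized per protein as an
oriented log2 ratio pair $(x, y)$ — one ratio per experiment, both
oriented to mutant/control, so genuine effects fall on the scatter
diagonal. Protein-level ratios sum the channel intensities (the synthetic
IP model is protein-level; a peptide-median mode is provided). A pair is
*consistent* when the ratios share a sign or both lie inside the unchanged
band; classification at threshold 1.0 log2 (a two-fold change — a
decision, since the literature reports magnitudes rather than a cutoff)
labels points depleted / enriched / unchanged, with sign-discordant pairs
beyond the band flagged *inconsistent* and treated as discards rather than
change calls.

# The synthetic-data generator

The generator exists so that every stage above can be tested by parameter
recovery. `defaultScenario()` encodes a two-condition reference model — a
control line versus a mutant devoid of complex III — whose species
structure mirrors the biology of complex-III-dependent maturation:

* In the control (digitonin), complex I N-module subunits migrate only
  within respirasome supercomplexes (2,110 kDa); under DDM, supercomplexes
  dissociate and the holo complex I runs at 1,002 kDa.
* The mutant lacks every complex-III-containing species and accumulates a
  pre-complex-I intermediate lacking the N-module (991 kDa in digitonin,
  812 kDa in DDM, carrying the assembly factor NDUFAF2), a residual
  N-module signal at the free holo-complex mass (1,172 / 1,002 kDa)
  planted at 6.1% of the control's respirasome abundance, low-mass
  NDUFV1/NDUFV2 species (37 kDa), and CYC1/UQCR10-containing intermediates
  (750 and 150 kDa).
* Complex II (156 kDa) is halved in the mutant; ATP synthase (700 kDa)
  and the internal-control proteins (citrate synthase dimer, TOM20/TOM22)
  have equal abundance in both conditions.

Expected intensities follow
$\mathrm{abundance}_{s}(c)\times \mathrm{copies}_{p,s}\times
\mathrm{response}_{j}\times \varphi(k;\mu_s,\sigma)$, where $\varphi$ is a
discretized Gaussian band at the slice position $\mu_s$ implied by the
species mass under the generating law $\log_{10}(\mathrm{kDa}) = 3.7 -
0.036\,\mathrm{slice}$ (chosen once so that all planted masses, 37–2,110
kDa, fall inside slices 1–64). Observed intensities multiply the
expectation by lognormal noise $e^{\varepsilon}$,
$\varepsilon \sim N(0, \sigma_{\ln}^2)$ with $\sigma_{\ln} = 0.2$
(typical MS intensity variability), and are censored below a detection
limit of 100 arbitrary units against species abundances of
$6\times10^4$–$10^6$, which reproduces the absent-peptide pattern of real
data without an additive baseline. The band spread is a single
species-independent $\sigma = 1$ slice — real bands broaden somewhat with
mass, but no band-width model is available to emulate, so one knob is
preferred. Proteins are reported by 3–6 abstract peptides with fixed
response factors; chromatography, isotope envelopes and missed cleavages
are intentionally not modelled.

All randomness flows through R's Mersenne–Twister generator with inversion
normals from one seed per lane, so fixtures are byte-stable. Noise is
independent across slices, peptides, channels and experiments; the true
inter-slice noise correlation of real data is unknown, and this
independence assumption is the main caveat when transferring the recovery
results below to real data. Equally, passing recovery tests show that the
*analysis* is correct and well-calibrated under this generative model —
they cannot certify upstream steps the package does not model (protein
inference, ionization competition, co-migration of unrelated species).

A deliberately omitted feature: a second N-module-containing species
around 1,386 kDa is seen in such systems, but under the generating law it
would sit about two slices from the 1,172 kDa holo-complex — within one
band width. Resolving it would require mixture deconvolution of
overlapping species, which is out of scope, so the reference scenario does
not plant it.

# Numerical choices and degenerate inputs

* Trapezoid integration over fractional windows interpolates the trace
  linearly at the endpoints; windowed areas over a partition of the lane
  sum to the total area to $10^{-9}$.
* An all-zero condition pair is flagged unquantifiable and returned as
  zeros rather than producing NaN; an all-zero or flat profile yields an
  empty peak list.
* Peak centers from parabolic refinement are clamped to ±0.5 slices of
  the integer maximum; at plateau or boundary maxima the integer position
  is kept.
* Writers format floats with 6 significant digits via C-locale
  `sprintf`, sort rows by declared keys and use LF line endings, making
  outputs byte-reproducible across platforms and locales.
* Under-determined calibrations (< 3 standards) and inverted gel
  orientations are errors; non-monotone standards are a warning only,
  since the least-squares fit tolerates positional jitter.

# Validation problem sizes

The shipped test-suite exercises: calibration against a normal-equations
oracle (25 random standard sets) and 2-SE recovery under 0.3-slice jitter
(100 replicates); species-mass recovery on the reference scenario in both
detergents (10 reciprocal pairs each, ~39 proteins, 64 slices) with a 5%
apparent-mass criterion and spurious-peak accounting; ratio recovery for
planted log2 ratios in {−3, −1, 0, 1} (10 pairs) and orientation sign
consistency (100 pairs); windowed-fraction recovery of a 6% planted
in-window fraction (20 pairs) and of the mutant:control window ratio (20
pairs, ±15% relative); co-IP classification with 8-fold planted effects
against 200 null proteins. These sizes keep the full suite under a minute
on one core while leaving each statistical criterion comfortable margin.
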