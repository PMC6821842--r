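---
title: "Comparing neural and network face-space geometries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing neural and network face-space geometries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(facespace)
```

## The scientific question

Face-selective sites in human ventral visual cortex respond with different
amplitudes to different face exemplars. One way to characterize what such a
population encodes is its *face-space geometry*: the set of pairwise
distances between the activation patterns evoked by different faces. This
package implements a pipeline that (i) extracts exemplar-level responses
from continuous intracranial recordings, (ii) quantifies face selectivity
and single-trial decodability, and (iii) compares the neural geometry,
layer by layer, with the activation geometry of a deep convolutional
network of the VGG family, using representational similarity analysis (RSA)
with permutation and FDR inference. Because real patient recordings and
pretrained network weights cannot be redistributed, the package ships a
synthetic-data generator that emulates the full experiment with planted
ground truth, so every stage is testable end to end.

## Signal model and HFA estimation

Recordings are channels-by-samples matrices at 500 Hz (512 Hz input is
resampled). After common average referencing over intact channels, the
high-frequency amplitude (HFA, 48-154 Hz) is estimated per channel by:

1. band-passing the signal in nine 10 Hz sub-bands that avoid the 59-61 and
   117-121 Hz line-noise ranges (edges `hfa_bands()`, configurable);
2. taking the Hilbert envelope of each band (analytic signal via FFT);
3. dividing each band's envelope by its own temporal mean — without this,
   the 1/f spectrum makes the lowest bands dominate the average;
4. averaging the nine normalized envelopes.

The resulting trace is dimensionless with temporal mean 1. Filters are
zero-phase Hamming-window FIRs with order set by the 3.3/transition-width
rule (2 Hz transitions by default); they are applied by FFT convolution
with exact group-delay compensation, which is mathematically the same
zero-phase linear filter at much lower cost on minutes-long recordings.

Epochs cover `[-200, 500)` ms around stimulus onset (half-open windows; the
sample at t = 0 belongs to the response side). Responses are expressed as
percent signal change relative to a *global* per-channel baseline B, the
mean over all retained trials' `[-200, 0)` ms samples. Repeat trials (the
1-back targets) are excluded, as is anything flagged in an `excluded`
column. ERP and 8-13 Hz band-limited-power controls use the same epoching
on the referenced raw signal, with a `[125, 250)` ms analysis window kept
in metadata and no percent-change normalization (they are in microvolts).

## Contact screening and the grand matrix

A contact is *visually responsive* when a paired t-test of per-exemplar
mean responses (`[50, 500)` ms) against per-exemplar baselines survives
Benjamini-Hochberg FDR at 0.05 across all contacts **and** Glass' delta
exceeds 1. We take the SD of the exemplar-mean baselines as the Glass
denominator — it is the control-condition spread of exactly the quantities
the paired test compares. A visually responsive contact is a *face
contact* when one-sided Wilcoxon rank-sum tests show larger exemplar-mean
responses to faces than to places and to patterns (both p < 0.05,
uncorrected), and anatomical constraints hold (not V1/V2/frontal, not
deeper than 10 mm; labels arrive as metadata).

Exemplar selectivity of a contact is the d-prime between its most- and
least-preferred faces,
\[
  d' = \frac{\mu_{best} - \mu_{worst}}
            {\sqrt{\tfrac12(\sigma^2_{best} + \sigma^2_{worst})}},
\]
with means and variances taken over repetitions of the window-mean
response; its p-value comes from 1000 shuffles of single-trial exemplar
labels, re-selecting the extremes per shuffle.

Face-contact responses are assembled into the grand matrix **G**
(exemplars x contacts x repetitions x time, `[50, 500)` ms = 225 samples
at 500 Hz). A 50 ms running average is applied for decoding input and off
for RSA input — the smoothing is part of the decoding scheme's definition,
while the distance analyses use the unsmoothed series; both are
configurable (`smoothing_ms`).

## Template-matching decoding

Each decoding iteration picks one random trial per (exemplar, contact)
cell into a test matrix T (rows: exemplars, features: concatenated contact
time series) and averages the remaining trials into a reference matrix R.
Labels are assigned greedily: the globally smallest Euclidean row-to-row
distance is found, that test row takes that reference row's label, both
are removed, and the step repeats, so each reference row is used once.
Ties break lexicographically. Accuracy is the fraction of exemplars
assigned their own template, averaged over 1000 iterations. The
permutation test reassigns single trials across exemplars *within* each
contact (missing repetitions stay in place) — relabeling whole cells would
leave the scheme's accuracy unchanged, since test and reference rows would
move together.

## RSA across network layers

The neural representation is the trial-averaged G flattened to exemplars x
(contacts x time); pairwise Euclidean distances over the N = 10 exemplars
give 45 values. Each of the 22 evaluation layers of the network (13
rectified convolutions, 5 poolings, 3 fully connected layers, and the
class-score output — the last entry is our resolution of an ambiguous
layer count, and the enumeration is configurable) contributes its own
distance vector, and the profile is the Spearman correlation per layer.
Inference shuffles exemplar labels of the neural representation 1000
times, recomputing its distance vector while layer vectors stay fixed; p
is the proportion of null correlations exceeding the observed one, and
Benjamini-Hochberg FDR runs across the 22 layers. Variants: sliding
200 ms windows with 50 ms stride; temporal-mean collapse; per-patient
profiles (patients with at least five face contacts, unweighted average);
two-cluster ROI profiles with a contact-label permutation test on the
per-layer correlation difference; partial profiles that residualize ranks
on pairwise absolute differences in luminance, RMS contrast, gradient and
saturation (our definition of a covariate "pair distance" for a scalar
image parameter; the rank-based residualization keeps the estimate
Spearman-consistent). Cross-set pooling Fisher-z transforms the per-layer
coefficients, averages with face-contact-count weights, computes the
weighted standard error, and transforms back; correlations at |rho| = 1
are clipped to 1 - 1e-7 first. Pair-bootstrap standard errors resample the
45 pairs with replacement.

## Image parameters and manipulations

Low-level image statistics are measured on the 0-255 scale: luminance =
mean grayscale pixel, RMS contrast = SD of grayscale pixels, gradient =
summed central-difference gradient magnitude, saturation = mean of
(max - min)/max over RGB pixels; grayscale conversion is
0.299R + 0.587G + 0.114B, and for native grayscale images the parameters
are computed on raw pixels with saturation not applicable. Luminance
matching shifts every image to the set mean on the HSV value plane
(value = max(R,G,B)); because a value shift changes grayscale-mean luminance
by roughly the luminance-to-value ratio, the shift is solved iteratively
(three fixed-point steps), hue and hexcone saturation are preserved
exactly by per-pixel scaling, and pixels are clipped to [0, 255] with the
clipped fraction logged. Background-removed, altered-appearance and
rotated-view images are accepted as supplied inputs — they were manual
edits in the original workflow and are out of scope to compute.

The impact of a manipulation on a layer's match is
delta = rho(original) - rho(manipulated), tested by the same
exemplar-label permutation (p = fraction of null deltas at or above the
observed one, so a no-op manipulation reads p = 1) and by a 95% pair
bootstrap interval around the original correlation. Identity decoding
across conditions holds out one random image per identity and classifies
it by its Euclidean nearest neighbor; the viewpoint matrix scores
cross-view identity preservation as the fraction of identities whose
same-identity entry is their row minimum.

## Model units and receptive fields

The leave-one-out unit search asks whether a single network unit predicts
a single contact: per fold, the unit best Pearson-correlated with the
N - 1 retained exemplar responses is recorded (ties to the lowest index,
near-constant units skipped); only if one unit wins *every* fold is a
per-fold least-squares line used to predict each held-out response, with
one-sided permutation significance on the prediction-observation
correlation. Because the winning unit is selected on overlapping folds,
per-contact detections are not family-wise safe on their own; the cluster
correction re-runs the whole search under exemplar-label shuffles and
declares a layer's count significant only if it strictly exceeds the
null's 95th percentile.

Receptive fields are visualized on a small convolutional network whose
weights are reproducible from a seed (Xavier-normal or fixed): the
*deconvolution* pass zeroes all units in the target layer except the
chosen one and propagates its activation back through transposed
convolutions, switch-recorded unpooling, and masking by the forward ReLU
pattern — for a purely linear network this is exactly the adjoint
operator, which the tests verify against brute-force forward passes on the
pixel basis. *Activation maximization* iterates deconvolution, adding the
reconstruction times a learning rate to the image (defaults 300
iterations, rate 200 as in the original procedure; the toy-network tests
use smaller values scaled to their weight magnitudes). The image is not
re-clipped during the ascent — the delta visualization needs unbounded
values — and contrast stretching is applied only at PNG export.

## The synthetic-data generator

`generate_protocol()` reproduces the three 1-back task versions exactly:
360 trials / 24 repeats / 60 stimuli x 6 (set 1, 250 ms, 750-1050 ms
jitter), 205 trials / 25 repeats / 37 stimuli x 4 + 19 x 3 (set 2, the
unique split reaching 205 with 56 stimuli at 3-4 each, fixed 1 Hz pace),
and 260 trials in 26 single-category ten-trial blocks with 18 repeats
(set 3, 500 ms, 750-1500 ms jitter, 4 or 8 s block gaps). Block
categories are scheduled 6+5+5+5+5 with no two alike in a row; within a
repeat block the most-presented exemplar sits out and the least-presented
repeats, which keeps presentation counts as even as the printed totals
allow. Repeats count toward presentation quotas (the set-1 arithmetic
forces this). Protocols start 2 s into the session so baselines fit.

`simulate_recording()` is the forward model: Brownian (1/f^2) background
plus broadband noise, a shared common-mode component, a 60 Hz line
sinusoid, and stimulus-locked bursts of a 70-150 Hz band-limited carrier
under a gamma-shaped envelope rising 50 ms after onset and peaking at
200 ms. On face trials the burst amplitude is the channel's face gain
times a softplus of the tuning-weight dot embedding — softplus keeps
amplitudes positive while preserving tuning order; other trials get the
channel's general visual gain. The generator emulates category- and
exemplar-selective HFA on realistic background; it does *not* emulate
cortical geometry, volume conduction, epileptiform artifacts, or
behavioral errors, so passing tests demonstrate correct recovery of
planted structure, not performance on clinical data.

`latent_face_space()` fixes the ground-truth geometry;
`simulate_layer_stack()` embeds `alpha * z + (1 - alpha) * noise` through
per-layer random isometries, so `alpha` dials each layer's geometry match
from pure noise (0) to exact (1); `simulate_response_patterns()` produces
trial-averaged exemplar-by-contact matrices the same way for analyses
where continuous signals are unnecessary. Procedurally generated face
images hit requested luminance/contrast/saturation targets exactly by an
affine grayscale mapping plus hue-preserving colorization, with a bounded
base pattern so 8-bit targets are reachable; infeasible targets raise an
error rather than clip.

## Numerical choices, scales, and known limitations

- Every stochastic function takes an integer seed; multi-stage runs derive
  per-stage seeds by a fixed counter scheme, so a configuration determines
  its outputs bit for bit.
- Permutation p-values follow the "proportion exceeding" convention
  (p = 0 is possible and is printed as "< 1/n_perm"); the manipulation
  delta test uses "at or above" so the degenerate zero-delta case reads
  p = 1.
- Greedy assignment ties break lexicographically; unit-search argmax ties
  break to the lowest index; the cluster threshold uses a discrete
  (type 1) quantile with strict exceedance.
- The test suite and the demonstration pipeline run at reduced problem
  sizes chosen to exercise every code path on a single CPU: 20-seed
  recovery loops at 10 exemplars / 40 contacts with 500-1000
  permutations, one full recording session at 8 channels, and toy
  networks of 2-3 layers on 8-16 pixel inputs. These sizes are stated
  here as the package's own reproducibility conditions.
- Under the global null, BH-FDR across 22 layers spends its full 5%
  family-wise budget, so about one in twenty null stacks will flag some
  layer; calibration checks treat 95% as the expected clean rate, not a
  floor.
- With only a handful of simulated channels, strong shared stimulus-locked
  bursts leak into the common average, and subtracting the reference adds
  burst-locked *amplitude* to otherwise silent channels (envelopes are
  magnitudes, so sign does not cancel). Demonstration sessions therefore
  keep at most half the montage strongly face-driven; real montages with
  thousands of contacts dilute the reference and do not face this at the
  same scale.
- The statistical behavior of the leave-one-out unit search depends on
  layer width: fold agreement under the null becomes rarer as units are
  added, while the selected unit's spurious correlation grows. Only the
  cluster correction is family-wise safe, and analyses should report it.
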