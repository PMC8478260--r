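---
title: "gazeSPRT: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gazeSPRT: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The task and the model in brief

In a flicker change-blindness trial an observer watches an alternating
sequence A, blank, A', blank (each epoch 250 ms here) and must find the one
localised difference between A and A' within 60 s. gazeSPRT simulates an
observer for this task as a neurally-constrained sequential probability
ratio test (SPRT): each grid region of the display is encoded by an
independent Poisson population whose rate is a bounded linear function of
local visual saliency computed on a foveally magnified view; the observer
accumulates, per region, the log posterior odds that the region changed;
crossing a positive bound signals the change, crossing a negative bound
ends the fixation and a temperature-controlled softmax over the evidence
map (optionally re-weighted by human saccade amplitude/turn-angle biases)
selects the next fixation.

The package also implements the matched control models, parameter sweeps,
an inhibition-of-return saliency baseline, the eye-movement analytics that
accompany such experiments (feature selection scores, density-filtered
fixation clustering with BIC model selection, scanpath strings and edit
distances, saccade probability matrices, fixation maps, change-proximity
profiles), and synthetic generators for all inputs, so that every part is
testable without external data.

# Encoding pipeline

**Grid.** The display is partitioned into non-overlapping 12 px patches;
the reference 864 x 648 frame gives 72 x 54 = 3888 regions, the reduced
432 x 324 frame used for desk-scale simulation gives 36 x 27 = 972.
Portrait frames swap the two grid resolutions automatically. Regions are
indexed row-major; pixel coordinates are 1-based, origin top-left.

**Foveation (CVR transform).** A signed pixel offset d from the fixation
centre maps to sign(d) ln(beta |d| + 1) S_f per axis. The transform is
applied to |d| with the sign restored (the logarithm is otherwise undefined
for negative offsets), and the output is resampled onto the original
lattice by inverse mapping with bilinear interpolation, clipping source
coordinates to the frame (edge replication). Multiplication by S_f (rather
than division) is adopted: with beta = 0.05 and S_f = 200 it gives the
intended ~10x central magnification, whereas division would collapse the
image below a pixel. S_f = 200 is tied to the 864-px frame; the simulator
scales it with the frame (S_fx = 200 w/864, S_fy = 200 h/648) so reduced
frames keep the same visible-field geometry. A consequence worth knowing:
content beyond roughly (e^{(w/2)/S_fx} - 1)/beta pixels from fixation maps
outside the frame and is represented only by clipped border values — the
model has a genuinely finite visual field whose radius shrinks as the
foveal magnification factor grows. This is the mechanism behind the
saccade-amplitude effects of the FMF parameter.

**Saliency.** Frequency-tuned saliency: per pixel, the Euclidean distance
in CIELab space between the image's global mean Lab vector and the
Gaussian-blurred Lab image, min-max normalised to [0, 1]. The blur standard
deviation defaults to 1.6 px (the reference method uses a small
binomial/Gaussian kernel; the exact width is not critical and is exposed as
`blur_sigma`). Saliency is computed on the foveated image, not the
original, mirroring the order of these operations in the visual pathway.
For speed the simulator converts each image to Lab once and foveates the
Lab planes; foveating in Lab rather than RGB changes values only through
the interpolation nonlinearity and is part of the package's definition of
the pipeline.

**Rates.** lambda_i = lambda_min + (lambda_max - lambda_min) <S>_i with the
region-mean saliency <S>_i, bounded in [5, 120] spikes per 25-ms bin.
Per-fixation maps are memoised per fixation centre (the standard
precomputation short-cut); catch pairs, being identical, are encoded once.

# Likelihood of change versus no change

Within a fixation, spikes are counted over the epochs of each A → blank →
A' cycle: X_i over the m observed bins of the first image, Y_i over the q
bins of the second; blanks contribute nothing. The observer sees only the
difference z = Y_i - X_i and the running rate estimate lambda_hat =
(X_i + Y_i)/(m + q), updated every bin. Under no change, z follows the
Skellam law with means m lambda and q lambda. Under change, the observer
expects a firing-rate difference of +/- mu_f (a singleton prior, both signs
equally likely), so the change likelihood is the half/half mixture of two
Skellam laws with means m(lambda +/- mu_f) and q(lambda -/+ mu_f). The
log-likelihood ratio is evaluated through exponentially scaled modified
Bessel functions of the first kind, entirely in log space. Where direct
evaluation under- or overflows the implementation switches to closed
asymptotic forms: the large-argument expansion (carried to 15 terms, used
as the primary path for x >= 400 with nu^2 <= x, where it is accurate to
machine precision and much faster than the direct evaluation), the
large-order form (x/2)^nu / Gamma(nu+1) when x^2 < 2(nu+1), and the
uniform (Debye) large-order form bridging the remaining failures. The
change-hypothesis rate lambda - mu_f is clamped at 1e-6 when mu_f >=
lambda, a case the formulation leaves open.

Cycle bookkeeping is non-rolling: when a cycle completes (second epoch
ends), the counters reset and the next image epoch starts a fresh cycle, so
likelihoods are evaluated during every second image epoch of a fixation. A
fixation that begins mid-epoch counts the remaining bins of that epoch as
its first-image phase.

# Evidence accumulation and the decision rules

Each evaluated bin updates every region:

E_i(t) = (1 - gamma_i) E_i(t-1) + log L_i(t) + [i = fixated] log P + W_i(t)

with W_i ~ U(-w, w) and the Gaussian decay field gamma_i = gamma
exp(-d^2 / (2 beta_decay^2)) centred on the fixated region (d in grid
units). Larger gamma means leakier accumulation. Likelihoods are computed
in the foveated (CVR) frame and projected back to original image space by
the region-centre mapping of the inverse transform before accumulation.
During blanks and first-image bins no new evidence is available and the map
only decays.

Three accumulation details are deliberate design choices of this package,
exposed as configuration switches and worth stating plainly:

* **Scope of the prior (`prior_scope = "fixated"`).** Applying log P at
  every region each evaluated bin — the literal reading of the update rule
  with a spatially constant prior — makes every region drift by log(0.1) =
  -2.3 per evaluated bin, about -1400 over a trial. Every newly fixated
  region would then already sit far below the no-change bound and every
  fixation would terminate on arrival; the model degenerates into a
  one-bin random walker that can never detect anything. Restricting the
  prior term to the currently fixated region — the location whose
  posterior odds the observer is actually testing — preserves every
  behaviour the model is meant to produce: fixation durations of order one
  second set by P and F_n, their modulation by P and zeta, the collapse of
  detection for gamma above ~0.1-0.2 (the within-fixation drift
  equilibrium -log(P)/gamma no longer reaches F_n), and negligible false
  alarms.

* **Fresh test per fixation (`reset_on_fixation = TRUE`).** The fixated
  region's evidence restarts at zero at fixation onset: each fixation is a
  fresh sequential test at that location, as in the SPRT it implements.
  The region's value at fixation end (near F_n after an unsuccessful test)
  stays in the map and relaxes through the local decay field, which is
  exactly what produces the emergent inhibition of return: recently
  rejected locations carry negative evidence and are avoided by the
  softmax until the decay field has washed it out.

* **Noise per neural population.** The accumulation noise W is drawn per
  CVR-space region and projected alongside the likelihood. Regions the
  current fixation cannot resolve (everything beyond the visible-field
  radius maps onto border cells) therefore share one noisy evidence
  stream rather than each performing an independent random walk. With
  fully independent per-region noise the evidence map outside the fovea
  becomes ~10^3 unrelated random walks whose extremes dominate the softmax
  and erase every spatial signature of foveation.

Updates carrying noise and prior happen only on evaluated bins; on other
bins the map decays. (Adding noise on every bin merely quadruples a random
walk that the thresholds were not scaled for.)

The decision bounds are checked at the fixated region each bin: E >= F_c
= 100 signals the change (a hit if the region intersects the ground-truth
mask, a false alarm otherwise); E <= F_n(t) = -20 e^{-zeta t} ends the
fixation. `check_all_regions` exposes the alternative reading in which any
region may cross F_c; the default is the fixated region only. F_c does not
decay (decaying it would produce false alarms).

# Saccade policy

Weights are the clipped third-order Taylor expansion of exp(E/T): w =
max(1 + x + x^2/2 + x^3/6, 0) with x = E/T — a softer saturation than the
exact exponential. If every weight clips to zero the policy falls back to
uniform rather than failing. The human bias distribution multiplies these
weights (not the signed evidence, which would flip signs) as a function of
candidate amplitude (grid units) and turn angle relative to the previous
saccade, in (-180, 180]; before the first saccade only the amplitude
marginal applies. The packaged parametric bias has an exponentially
decaying amplitude marginal and a 1 + w cos^2(theta) angle marginal
(bimodal at 0 and 180 degrees, a trough near +/-90), normalised to unit
mass on its polar grid; user-supplied tables are accepted via the same
container.

The IOR saliency baseline implements the comparison sampler: an IOR map
accumulates a Gaussian patch (sd 20 px) at each fixation, scaled by
tanh(0.05 t) and discounted by 0.25 per step, clipped to [0, 1]; saccade
weights are (1 - IOR) times the saliency map through the same softmax. It
takes any saliency map, so a learned map can be plugged in where the
frequency-tuned one is used by default.

# Controls and calibration

Control 1 forces gamma = 1 and signals change when the instantaneous log
posterior odds at the fixated region cross a calibrated threshold; control
2 uses the one-bin first difference of that quantity (the differencing
window is one bin; nothing in the formulation fixes it); control 3 is the
full model with T = 10^4, a random searcher. All controls follow the
fixation-duration schedule of a paired main-model run with the same seed,
so fixation timing is identically matched. Thresholds for controls 1-2 are
calibrated on synthetic catch pairs: the per-trial maxima of the control
statistic form the candidate grid, and the smallest threshold whose
empirical false-alarm rate respects the bound is returned (the rate is
non-increasing in the threshold, so the grid search is exact).

# Synthetic data

**Image pairs.** Band-limited noise backgrounds (blurred white noise) with
scattered saturated geometric objects, one object at the change location,
and A' modified only inside the change region according to the change kind
(appearance fade, colour rotation, or size growth), scaled by a contrast
parameter in [0, 1]; contrast 0 yields a bitwise-identical catch pair. The
mask marks exactly the altered pixels. Background objects are deliberately
as saturated as the change object so that the global min-max normalisation
of the saliency map is anchored by unchanged content; otherwise the
normalisation shift makes every region's rate differ between A and A' and
the simulator (correctly) reports spurious evidence everywhere.

**Gaze logs.** Two groups whose distributions differ only in mean fixation
duration (log-normal, parameterised by mean and sd so the sd can be held
equal across groups) and saccade-amplitude variance (gamma with equal
means). Saccade duration and peak speed follow main-sequence-style
monotone maps of amplitude (affine, and a power law) with the substantial
scatter real main sequences show, so they carry only a diluted version of
the information inherited through amplitude. Defaults: 280 vs 220 ms mean fixation duration, common
70 ms sd; amplitude mean 5 degrees with variance 4 vs 9 deg^2 — group
differences of the size such experiments report, large enough to be
detectable from a trial's ~30 fixations but far from trivially separable.

# Gaze analytics

Quartiles everywhere (outlier fences, duration domains) use linear
interpolation (R type 7). The boxplot rule drops values outside
q1 - 1.5 IQR, q3 + 1.5 IQR. Feature extraction strips the trailing
fixations inside the change region on hit trials (the detection dwell)
before computing the eight per-trial summaries. Fisher score and
information gain follow their standard two-class forms (information gain
in bits, split points at midpoints of adjacent sorted distinct values,
best split taken). The AUC-change score uses the rank (Mann-Whitney) AUC
under seeded cross-validation and a pluggable classifier contract
(function(train_x, train_y, test_x) -> scores); the shipped default is a
ridge-regularised linear discriminant, deliberately minimal — any
stronger learner honouring the contract can be substituted.

Fixation density divides the inverse mean within-radius (40 px)
neighbour distance at a fixation by the same quantity at the nearest
point of a deterministic uniform lattice of equal cardinality (a lattice
rather than a random uniform draw, for reproducibility); points below
density 1 form the sparse cluster. Clustering is k-means with kmeans++
seeding, several restarts per candidate k (best kept), scored by the
x-means spherical-Gaussian BIC; the profile is smoothed by a
bi-exponential (difference of exponentials) fit when at least 8 candidate
k values are available — with fewer candidates, or if the fit fails, the
raw (or spline-smoothed) argmax is used. Scanpath strings use one
character per cluster ("." for the sparse cluster); the edit distance is
unit-cost Levenshtein by dynamic programming, normalised by the longer
string. Saccade matrices are column-stochastic (destination given origin);
domains are quartile groups of per-cluster cumulative fixation duration,
ties resolved by cluster index; saccades touching the sparse cluster (or,
for the top-k matrix, any cluster outside the top k) are excluded.
Fixation maps use 13 x 18 tiles; change-proximity profiles use 50-px
annuli.

# Problem sizes and study conditions used by the test suite

The simulation test blocks run on the reduced 432 x 324 frame (36 x 27
grid) with 30-s (1200-bin) trials and 20 seeded trials per sweep point —
sizes chosen so the whole battery is a desk-scale experiment; the
catch-trial false-alarm check runs full 60-s trials at default parameters.
Two image batteries are used, matching what each sweep probes:

* a detection battery of four pairs spanning contrasts 0.3-0.75 (change
  radius 14 px), used for the gamma, blank-fraction, prior-odds and zeta
  sweeps — mixed difficulty, so floor and ceiling effects do not mask the
  parameter;
* a policy battery of two pairs at contrast 0.45, used for the
  temperature and FMF sweeps, whose read-outs are saccade statistics and
  need trials long enough to contain many evidence-driven saccades.

The FMF sweep covers the two-fold range 0.025-0.05 (up to the default).
Above the default the shrinking visible field begins to cost exploration
on this small frame, and detection success no longer improves — a
desk-scale limitation worth knowing when extrapolating. Fixation-duration
read-outs for the prior-odds and zeta insets are taken on a catch pair,
where every fixation terminates at the no-change bound and durations are
not truncated by detections. The saccade bias distribution is imposed in
all sweep runs, as in the model's quantitative comparisons.

Trial seeds are paired across the values of a sweep (trial k shares its
seed at every parameter value), which removes between-seed variance from
the trend comparisons.

# What the synthetic conditions do and do not show

The generators emulate the structure of the task (a single localised
change on a cluttered background; two-group gaze statistics with planted
effects), not the content of natural scenes: there are no semantic
objects, no photographic statistics, and change difficulty is controlled
by a single contrast knob. Passing trend tests therefore demonstrates that
the mechanisms behave as described under controlled conditions — not that
the model reproduces human numbers on natural images, which would require
the original stimuli and eye-tracking data. The blank-fraction trend is
asserted on the blank-heavy side of the 50-bin image+blank budget: with
image shares well above the default, the fixed prior drift can terminate a
fixation before the late (informative) bins of a long image epoch are
reached, and the benefit of additional image time is not realised under
the fresh-test-per-fixation rule. Known limitations, all documented at
their definition sites: the singleton mu_f prior (no density), no decay of
the change bound, non-overlapping receptive fields, and the finite visible
field of the scaled CVR transform.
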