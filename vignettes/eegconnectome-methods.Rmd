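---
title: "Methods: from resting-state EEG to fluency regressions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from resting-state EEG to fluency regressions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegconnectome)
```

## The pipeline in one paragraph

`eegconnectome` turns cleaned, continuous multichannel EEG into
per-subject, per-band functional-connectome summaries and relates them
to verbal-fluency scores. The stages are: a 30 Hz zero-phase low-pass;
segmentation into 12 s epochs with 50% overlap; Hanning-tapered
per-epoch Fourier coefficients (frequency resolution 1/12 Hz); an
individual alpha peak frequency (IAPF) estimate that anchors
subject-specific delta/theta/alpha/beta band edges; the debiased
weighted phase lag index (dwPLI) between all channel pairs, averaged
over each band's bins; thresholding by orthogonalized minimum spanning
trees (OMST) maximising global cost efficiency; weighted graph indices
of segregation (Onnela clustering coefficient, modularity) and
integration (characteristic path length), plus a small-world index
against degree-preserving nulls; and finally OLS regressions of fluency
scores on z-scaled metrics with treatment-coded age and sex, a
metric-by-age interaction, and a one-pass leverage filter.

A synthetic-cohort generator sits beside the pipeline so that every
stage can be validated against known ground truth without access to any
real recordings.

## Spectral stage

**Low-pass filter.** A Butterworth low-pass applied forward and
backward (`signal::filtfilt`), so the filter is zero-phase — phase
relations between channels are what the connectivity stage measures, so
group delay is not acceptable. The default order is 6 per pass: the
two-pass magnitude is $|H(f)|^2 = (1 + (f/f_c)^{12})^{-2}$, which is
down more than 20 dB at $1.25 f_c$ while the pass band stays flat to
well under 1%. A lower order would not reach 20 dB that close to the
cutoff; the order is an argument for users who want the classical
4th-order design.

**Epoching.** Epoch count is
$\lfloor (T - L) / (L(1-o)) \rfloor + 1$ for duration $T$, epoch length
$L = 12$ s and overlap $o = 0.5$; trailing samples that do not fill an
epoch are discarded. An optional `keep` index vector lets users apply
an external epoch-quality screen; the package itself does no artifact
rejection (inputs are assumed clean).

**Cross-spectra.** One Hanning taper per epoch (the single-taper
special case of the multitaper estimator). Coefficients are scaled by
$1/\sqrt{\sum_t w_t^2}$ so the epoch-mean auto-spectrum of
unit-variance white noise is 1 per bin — a convention chosen because it
makes the Parseval check in the tests a direct identity. Cross-spectra
are formed on demand from the per-epoch coefficients rather than
materialised as a dense epochs × channels × channels × frequencies
array; at 61 channels and hundreds of bins the dense array costs
gigabytes while the coefficients cost megabytes.

**IAPF.** Per-channel epoch-averaged spectra are smoothed with a
Savitzky–Golay filter (window 11 bins ≈ 0.9 Hz, polynomial order 5) and
searched for local maxima strictly inside the window [7, 13] Hz. A
candidate peak qualifies only if its smoothed height reaches at least
twice the median smoothed power inside the window: bare local-maximum
detection marks smoothing ripple on a peakless spectrum as a "peak",
and the height criterion is what separates a genuine alpha bump from
that ripple. The subject-level IAPF is the prominence-weighted mean of
qualifying channel peaks; with no qualifying channel the estimate is
flagged `no_peak` (a value, not an error — band derivation then either
errors or, with `fallback = TRUE`, anchors canonical bands at 10 Hz).

**Bands.** delta $[\mathrm{IAPF}-8, \mathrm{IAPF}-6)$, theta
$[\mathrm{IAPF}-6, \mathrm{IAPF}-4)$, alpha
$[\mathrm{IAPF}-4, \mathrm{IAPF}+2)$, beta $[\mathrm{IAPF}+2, 30]$ —
half-open except beta, which includes 30 Hz. A frequency bin belongs to
a band iff its centre lies in the interval. The four bands tile
$[\mathrm{IAPF}-8, 30]$ exactly for any IAPF, which is enforced by a
property test.

## Connectivity: dwPLI

With $I_k = \mathrm{Im}\, S_{xy}^{(k)}$ the imaginary cross-spectrum at
epoch $k$, the per-bin debiased WPLI estimate is

$$\frac{(\sum_k I_k)^2 - \sum_k I_k^2}{(\sum_k |I_k|)^2 - \sum_k I_k^2}.$$

Zero-lag (instantaneous) mixing — volume conduction at the sensors —
contributes only to the real part of the cross-spectrum and cannot move
this estimator, which is the reason for using it in sensor space. When
every $I_k$ is exactly zero the denominator vanishes; the estimate is
then defined as 0 and flagged degenerate, because zero imaginary parts
mean there is no measurable lagged coupling (not an undefined one).

Band aggregation averages the *signed* per-bin estimates over the
band's bins and then takes the absolute value. The alternative order
(absolute value per bin, then average) is available behind
`abs_per_bin = TRUE` but inflates the null: per-bin noise that averages
out under the signed convention accumulates under the absolute one.
The diagonal is set to 0 (self-connectivity carries no information for
the graph stage) and the per-subject, per-band scalar used downstream
is the mean of the off-diagonal upper triangle.

## OMST thresholding

Edges carry coherence-like weights; the distance convention throughout
is $d = 1/w$ (chosen over $-\log w$, which misbehaves when normalised
weights reach 1). Round $r$ computes a maximum-weight spanning tree —
Kruskal on $1/w$, with equal-weight ties broken lexicographically by
label pair for cross-platform reproducibility — on the graph with the
previous rounds' edges removed, so rounds are pairwise edge-disjoint.
After each cumulative union the global cost efficiency is evaluated:

$$J(m) = \frac{\mathrm{GE}(\text{union}_m)}{\mathrm{GE}(\text{full})} -
  \frac{\sum_{\text{union}_m} w}{\sum_{\text{all}} w},$$

where GE is the mean over ordered node pairs of $1/d_{ij}$ on the
weighted graph (unreachable pairs contribute 0). The efficiency is
reported *relative to the full graph*: with raw efficiencies, realistic
dwPLI weight scales (medians of a few hundredths) make GE a few
hundredths while the first tree's cost is already ~0.5, so $J$ is
negative and strictly decreasing and the selection always degenerates
to a single MST. The relative form — selecting every edge gives
$\mathrm{ge} = 1$ at $\mathrm{cost} = 1$, $J = 0$ — restores the
interior maximum the method is built around, and leaves closed-form
cases (e.g. a unit triangle) unchanged.

The selection is the cumulative union at the maximum $J$, ties broken
toward fewer rounds. By default rounds are capped at
$\lfloor (n-1)/2 \rfloor$ and the scan stops after three consecutive
decreases of $J$ (a cheap convexity heuristic); `exhaustive = TRUE`
evaluates every feasible round, and the acceptance tests use that mode
when comparing against an exhaustive-search oracle. A thresholded graph
is by construction spanning-connected (it contains round 1's tree).
Graphs that are *too sparse* for some downstream index are not an error
here — missingness is the metric stage's contract.

Only OMST and a pass-through `full` mode exist; arbitrary proportional
or absolute thresholds are deliberately not offered, since the point of
a data-driven threshold is to remove that researcher degree of freedom.

## Graph metrics and missingness

All indices are computed on weights rescaled by the maximum
(`w' = w / max(w)`), which makes every index invariant to positive
rescaling of the raw connectivity — enforced as a property test.

* **Clustering (Onnela):**
  $C_i = \frac{1}{k_i(k_i-1)} \sum_{j,h} (w'_{ij} w'_{ih} w'_{jh})^{1/3}$
  with binary degree $k_i$. Nodes with $k_i < 2$ cannot close a
  triangle and are *excluded* (undefined), not counted as 0; the mean
  is missing only when no node has degree ≥ 2. On a tree every defined
  node has $C_i = 0$, so the mean is 0 — which is how sparse OMST
  graphs produce missing small-world values downstream while clustering
  itself stays defined.
* **Modularity:** weighted Newman
  $Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} - \frac{s_i s_j}{2m}\right]\delta(c_i,c_j)$.
  For graphs of at most 8 nodes the optimum is found exactly by
  enumerating all set partitions (Bell(8) = 4140, instant); larger
  graphs use Louvain with 20 seeded restarts over permuted vertex
  orders, keeping the best $Q$. Exact search below the cutoff means
  small-graph results are reproducible facts rather than heuristic
  outcomes, and gives the test suite a meaningful brute-force
  comparison; Louvain at 61 nodes is the standard practical choice.
* **Characteristic path length:** mean over ordered pairs of weighted
  shortest-path distances on $1/w'$. Disconnected graph → missing, by
  design: substituting a harmonic-mean efficiency would silently change
  the estimand. OMST graphs are always connected, so this missingness
  can only arise for user-supplied graphs.
* **Small-world index:** $\sigma = (C/\bar C_{null})/(L/\bar L_{null})$
  over `n_null` surrogates (default 50) built by degree-preserving
  Maslov–Sneppen rewiring of the binary topology with the original
  weights shuffled among the edges. Missing whenever the graph's own
  $C$ or $L$ is missing or zero (trees) or any surrogate statistic is.
  The per-surrogate ratio SD is reported so σ ≈ 1 can be judged against
  the null spread.

Nothing is ever imputed; the long-format metrics table carries an
explicit `missing_flag`.

## Statistical stage

Group differences in fluency use a Wilcoxon rank-sum test with
midranks, tie-corrected variance and continuity correction, reporting
$r = |Z|/\sqrt{n}$ as the effect size; an exact-enumeration mode exists
for small groups and doubles as the test oracle. Score outliers are
defined as $|x - \bar x| > k\,\mathrm{SD}$ with $k = 3$. Note a
finite-sample fact the tests respect: with $n$ observations the largest
attainable $|z|$ is $(n-1)/\sqrt{n}$, so at very small $n$ the rule
cannot fire at $k = 3$.

Four model families are fit per band and outcome (semantic, letter):

* connectivity strength: `outcome ~ dwpli * age + sex`
* segregation: `outcome ~ clustering * age + modularity * age + sex`
* small-world: `outcome ~ small_world * age + sex`
* integration: `outcome ~ path_length * age + sex`

Numeric predictors are z-scaled on the listwise-complete analysis rows;
age and sex are treatment-coded (references: younger, female), so the
interaction term is the scaled metric × older dummy. Scaling happens
*before* leverage filtering and is not redone on the refit — the
alternative (rescale after removal) changes the coefficient metric
between the two fits and makes them incomparable. Rows with hat values
above $2(p+1)/n$ (design including intercept; $p$ = non-intercept
predictors) are removed in a single pass and the model refit; only the
refit is reported. The full grid is 4 families × 4 bands × 2 outcomes =
32 summaries, with no multiple-testing correction; a band or family
that cannot be fit (absent, constant or collinear metrics) is skipped
with a logged warning rather than aborting the grid.

## The synthetic generator

Each channel carries a unit-variance stochastic alpha oscillator —
narrowband-filtered white noise with a sharp ±1 Hz component at the
subject's true alpha peak riding on a full-alpha-band plateau — plus
1/f background noise (exponent 1 by default). A coupling replaces a
fraction `strength` of the target's band oscillator with a copy of the
source's delayed by `phase_lag` (converted to samples at the band's
centre frequency; default π/2, the lag that maximises the imaginary
cross-spectrum). `zero_lag_mix` blends one shared broadband source into
all channels instantaneously — a volume-conduction surrogate that, by
construction, the dwPLI must ignore.

Cohorts draw balanced younger/older groups with alpha peaks from
N(10.1, 0.9²) and N(9.4, 0.9²) Hz respectively, 61 channels in the
10–10 layout, 250 Hz sampling, 120 s per subject. Planted structure is
four contiguous channel modules with within-module chains at strength
0.4, second-neighbour chords at 0.2 and a weak inter-module ring at
0.15: the chords create genuine within-module triangles and the graded
strengths produce dwPLI matrices whose OMST unions keep several trees —
single-strength chains turn out to concentrate all planted weight in
one spanning tree, collapsing clustering to exactly 0 for every
subject, which no real cohort shows. Behavioural scores follow a
linear model on one z-scaled metric with age, sex and metric × age
terms plus Gaussian noise, rounded and clipped at zero because fluency
scores are word counts (defaults sit at typical group means: 25 vs
22 semantic, 15 vs 13 letter words). Missing metrics give missing
scores.

What the generator does *not* emulate: artifacts (blinks, line noise,
channel dropout), non-stationarity across the recording, realistic
scalp topography or lead-field mixing beyond the single shared source,
and task data. Passing tests therefore show the estimators and the
pipeline plumbing are correct — not that any scientific conclusion
transfers to real recordings.

## Numerical choices and problem sizes

Determinism is a contract: every stochastic step (cohort draws,
signals, Louvain restarts, surrogate rewiring) runs under an explicit
seed, per-subject seeds are derived reproducibly from the cohort seed,
and the end-to-end test asserts byte-identical output tables across
repeated runs. Kruskal tie-breaks are lexicographic; modularity ties
resolve to the first enumerated optimum; equal-$J$ OMST rounds resolve
to fewer rounds.

The test suite runs cohorts of 4–8 subjects at 90–120 s, dwPLI
estimator checks at up to 200 epochs (≈ 20 simulated minutes),
brute-force metric comparisons on 1000 random graphs of ≤ 6 nodes at
1e-10, OMST oracle comparisons on 100 random 8-node graphs, small-world
checks on 30-node lattices with 20 surrogates, and regression
calibration with 100 recovery fits at n = 400 plus 1000 null fits at
n = 100. The acceptance script processes a 60-subject cohort (30 per
group) with 20 surrogates and 10 Louvain restarts per graph. These
sizes were chosen so the whole suite completes in a few minutes while
every Monte-Carlo tolerance still has comfortable margin.

## Known limitations

* Sensor-space only: no source localisation, and no claim that effects
  localise to regions.
* The dwPLI needs multiple epochs; two-epoch estimates are legal but
  extremely noisy, and the generator's 120 s default (19 epochs) is a
  compromise, not a recommendation for real studies.
* The small-world null model rewires topology and shuffles weights; it
  does not preserve weighted node strength, which is one of several
  defensible null choices.
* `read_eeg` supports the plain matrix + JSON sidecar format;
  BrainVision/EDF ingestion is out of scope for this package and can be
  done upstream with dedicated readers.
* Verbal-fluency scores enter as given; their administration and
  scoring are outside the pipeline.
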