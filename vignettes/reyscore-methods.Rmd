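---
title: "Scoring tablet-recorded Rey figure copies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring tablet-recorded Rey figure copies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reyscore)
```

This vignette is the package's account of the science it implements: the
measurement model behind the 12 drawing indices, the statistical pipeline
that reduces them to composite scores, what the simulator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The measurement model

A tablet recording is a time-stamped pen trajectory `(t, x, y, contact)` in
seconds and millimetres (y up, origin at the sheet's lower-left; a y-down
source declares itself in the file header and is flipped on read; any
pressure > 0 counts as contact, because tablet exports vary). A raw stroke
is a maximal pen-down run. Because a single pen trace sometimes implements
several figure parts, strokes may be split into substrokes; the boundary
sample belongs to the earlier part, a deterministic tie-break. Each
substroke is labeled with one of the 48 basic elements of the reference
figure, or flagged incomplete, repeated, or unclassified. Labeling is
assisted (`auto_match()`) but deliberately advisory: distorted drawings
need human review, and every downstream computation consumes the reviewed
label table.

Three eligibility sets drive the three index families:

* **spatial** — linear elements (the 44 segments) drawn recognisably,
  completely, and not repeated. A repeated element is excluded entirely,
  the conservative reading of "not repeated": scoring either trace would
  require choosing one arbitrarily.
* **procedural** — every classified substroke (incomplete and repeated
  included; only unrecognisable material is excluded).
* **kinematic** — the entire drawing.

### Spatial indices and the global transform

Whole-figure placement, size, and tilt are not errors of *relative*
arrangement, so before measuring the spatial indices the drawing is
corrected by the least-squares transform

$$ p \mapsto \mathrm{diag}(s_x, s_y)\, R(\theta)\, p + t, $$

fit over the drawn endpoints of the spatially eligible elements against the
template endpoints (endpoints rather than midpoints: two constraints per
element stabilise the rotation; the pairing of drawn to template endpoints
is resolved per element by keeping the cheaper of the two orders, since
drawn direction is arbitrary). Given the rotation, the optimal scales and
translations are closed-form per axis, so the optimisation is a
one-dimensional search in θ (interval ±60°, tolerance near machine
precision), alternated with the endpoint re-pairing until stable. The
fitted transform and its residual are reported in every score report for
audit.

One property worth being explicit about: the shear-free family above is not
closed under composition with *anisotropic* distortions, so index
invariance under arbitrary `diag(s_x, s_y)` distortion of an imperfect
drawing is approximate, not exact (the residual mismatch grows with the
drawing's own fitted rotation). Under similarity distortions — rotation,
a single scale factor, translation — the composition stays in the family
and the spatial and procedural indices are invariant to numerical
precision. The simulator therefore applies distortions as scale-then-
rotate-then-translate (`R(θ) diag(s) p + t`), the inverse ordering of the
correction, which the correction family can undo exactly.

Each eligible element is observed as a chord: the pair of substroke
extremities with maximal mutual separation (an element drawn in two pieces
still yields its full extent). The deviations — midpoint x, midpoint y,
length, inclination — are taken observed-minus-template, and each spatial
index is the *population* standard deviation of its deviations about their
own mean. The SD-about-the-mean reading (rather than RMS about zero)
follows the word "standard deviation"; after normalisation the mean
deviation is near zero, so the distinction is minor. Inclination deviations
are wrapped to (−90°, 90°] before the SD: lines are undirected, so 179°
versus 1° is a 2° error, not 178°.

### Procedural indices

Progress is measured on a 0–100 scale of cumulative *pen-down* time (first
pen contact = 0, last = 100; pen-up intervals contribute nothing). pBR and
pID are the mean progress over the samples spent on the base rectangle and
the inner details; the mean is time-weighted through uniform sampling. A
structure never drawn reports a missing value, never a fabricated zero.
Whether progress should instead be measured along drawn path length is
ambiguous in principle; pen-down time is the default here, and the
graphical procedure output (which is keyed to drawn length) computes its
own length-based scale independently.

pOR counts transitions from a primary-relevance visit (base rectangle, main
substructure) to a secondary-relevance visit that occur while at least one
primary element *seen somewhere in the sequence* is still unvisited. Two
deliberate choices: a drawer who finishes all primary work before any
secondary element must score 0 (returning to finished primaries creates no
pending work), and the pending-set universe is the elements actually drawn
— measuring order, not omissions, which the spatial indices already
penalise.

pFR counts, over the unit sequence of the visits (consecutive same-unit
visits merged), the number of maximal runs of each unit beyond the first.
The unit-level reading is implemented as the default; an element-level
variant is exposed (`fragmentation(..., by = "element")`) since
fragmentation can also be read per basic element.

### Kinematic indices

The tangential speed (central differences of position after per-run linear
resampling to a uniform 100 Hz grid — comfortably above the filter band;
no interpolation across pen lifts) is smoothed per pen-down run with a
zero-phase 4th-order Butterworth low-pass at 7 Hz, applied
forward-backward with reflective padding. At 100 Hz this passes a 2 Hz
oscillation essentially unattenuated and removes > 95% of a 20 Hz one.
Runs shorter than 15 samples are skipped with a warning rather than
filtered unreliably.

Strokes are parsed at near-zero crossings of the smoothed speed
(< 5 mm/s): each *interior* low-speed region splits its run at the region's
speed minimum, while low-speed tails at the run ends stay inside the
first/last stroke — they abut a pen event, and trimming them would bias
per-stroke means upward. Strokes with drawn path ≤ 10 mm are discarded.
kVL is the mean smoothed speed per stroke averaged across strokes; kAC and
kDC average |dv/dt| over the positive and negative phases of the *scalar*
speed derivative (the indices are defined on the velocity profile, not the
velocity vector); kPK counts local maxima of the speed series — strict
derivative sign changes, with no prominence threshold by default (the 7 Hz
filter is the noise control; a configurable prominence is exposed). A
monotone within-stroke profile counts its boundary maximum, so any stroke
has at least one peak. With no qualifying stroke the kinematic indices are
missing, never zero.

## The cohort pipeline

Index matrices (participants × 12 indices) are reduced as follows.
Participants with any index more than 4 SD from its column mean are
excluded in a single pass (means and SDs from the full sample; no
re-estimation). Factorability is screened by per-variable KMO/MSA computed
from marginal and anti-image partial correlations; variables below 0.5 are
dropped iteratively, worst first — the data-driven path by which an index
uncorrelated with the rest (typically the inner-details priority in healthy
samples) leaves the analysis, rather than hard-coding its removal.
Bartlett's sphericity χ² uses `−(n − 1 − (2p+5)/6)·log det R` with
p(p−1)/2 degrees of freedom.

The PCA operates on the correlation matrix; the first k loadings
(eigenvector × √eigenvalue) are rotated with Kaiser-normalised varimax
(`stats::varimax`), ordered by rotated variance, and sign-fixed so each
component's largest loading is positive. Communality h2 is the row sum of
squared loadings, u2 = 1 − h2 (an identity under orthogonal rotation, held
to 1e-10), and Hoffman's complexity is (Σλ²)²/Σλ⁴. Retention is informed
by both the Kaiser criterion (eigenvalues > 1) and Horn parallel analysis:
the mean eigenvalues of 1000 standard-normal datasets of identical shape
(the central-tendency reference; a quantile variant, e.g. 0.95, is a
configuration option), retaining while observed exceeds reference from the
first component.

Indices are assigned to their largest-|loading| component when that loading
reaches 0.50; indices loading ≥ 0.30 on two or more components are
cross-loading and dropped (the fit is then re-estimated without them);
communalities below 0.5 are flagged. Composites are means of the assigned
standardised indices with negative-loading indices reverse-scored, and the
spatial and procedural composites are then reversed so that higher always
means better. Components are named SPA/PRO/KIN by the dimension prefix of
the majority of their indices. Reliability is Cronbach's alpha on the
oriented items; robustness is checked by a seeded random half-split with
varimax PCA per half and Tucker congruence between greedily matched
components. Partial correlations remove covariates by linear regression
from both variables and use df = n − #covariates − 2, two-tailed unless a
direction is declared.

## The simulator

`simulate_drawing()` exists so that every stage has a ground truth. Per
segment it perturbs the observed quantities directly — midpoint x and y,
length, inclination — with the configured SDs, then rebuilds endpoints, so
the *realized* per-drawing population SDs (returned in the truth record)
are exactly what an ideal scorer should report; recovery tests compare
against realized truth, not the nominal σ, removing finite-sample noise
from the comparison. The drawing order is either organised (base rectangle
→ main substructure → outer configurations → inner details, units
contiguous) or fragmented (elements split with a given probability and the
task order shuffled by rank noise). Strokes are traced with a half-sine
speed profile — the idealised single-peak fluent stroke — whose duration
is set by the path length and peak speed (default 60 mm/s, a comfortable
adult drawing speed); extra submovements are multiplicative hesitation
dips that extend the duration, each turning one velocity peak into two and
lowering mean velocity, which is how the kPK/kVL trade-off shows up in
real pen data. Pauses of 0.3 s separate strokes, with an explicit pen-up
sample at the lift position. Dots are drawn as sub-millimetre ticks long
enough to sample but far below the 10 mm kinematic floor. Global
distortion, when configured, is applied last, in the ordering the
correction family inverts exactly (see above). All randomness flows from
one seed recorded in the config.

What the simulator does **not** emulate: curvature of real hand-drawn
"straight" lines, pressure and tilt, pen drift during pauses, corrections
and overtracing, biomechanical speed–curvature coupling, or clinical error
patterns (omissions, perseverations, closing-in). Passing recovery tests
therefore shows the *scoring* chain is correct and unbiased under the
stated noise model; it does not validate the indices as clinical
measurements on real populations.

`simulate_cohort()` draws index matrices from the orthogonal factor model
`Z = FΛᵀ + E·diag(√u)`; the default Λ assigns each index family to its own
factor at 0.8 (kPK negative), the simple structure this family of indices
exhibits empirically, with uniquenesses completing unit variances.

## Numerical choices and degenerate inputs

* Default resampling rate 100 Hz (typical digitiser rates; well above the
  7 Hz cut-off); resampling below 14 Hz is refused.
* The transform fit requires ≥ 3 non-collinear eligible elements; spatial
  SDs require ≥ 2. Below these, the spatial indices are missing and the
  report says why.
* Scales are constrained positive; a degenerate axis falls back to scale 1
  before refitting the translation.
* The canonical template is the package's own geometry (the published
  figure fixes the element/unit/structure taxonomy but no coordinates):
  base rectangle 80 × 56 mm centred at the origin, sub-figures placed at
  conventional proportions, points and the circle at ids 25–28 so the
  linear ids are exactly {1–24, 29–48}. The shipped CSV carries every
  coordinate so users may substitute their own figure; a checksum of the
  geometry is recorded in each score report. The connectivity audit checks
  the figure forms one connected component at 1 mm tolerance (the circle
  treated as a disk so its interior dots count as attached); a per-unit
  mutual-contact audit is not meaningful for this figure, whose hatching
  units are sets of parallel, non-touching lines.
* Problem sizes used by the test and acceptance suites — 200 drawings for
  jitter recovery, 50 distortions for invariance, 100 cohorts for
  structure recovery, 10,000 sequences for the procedural oracles — were
  chosen to pin the Monte-Carlo error comfortably below the tolerances
  being asserted.

## Known limitations

The classification assist is a heuristic (bounding-box alignment, then a
transform-refined nearest-element assignment with a 10 mm rejection
threshold, roughly half the smallest inter-element spacing); on heavily
distorted drawings it is advisory only. The kinematic indices inherit the
7 Hz smoothing: genuine motor events faster than the filter band are
invisible by design. The composite-score stage presumes the cohort shows
an interpretable simple structure; with ambiguous retention evidence the
pipeline reports both the Kaiser and parallel-analysis counts and lets the
analyst set `k` explicitly.
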