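---
title: "Ocularity-contrast saliency: models, stimuli, and analysis choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ocularity-contrast saliency: models, stimuli, and analysis choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocusearch)
```

## The ocularity model

Each search item delivers input contrasts $C_L, C_R \in [0,1]$ to the two
eyes.  The eye weights are $s_L = C_L/(C_L+C_R)$ and $s_R = 1 - s_L$, and
the ocularity value is $O = s_L - s_R \in [-1, 1]$: $\pm 1$ for monocular
items, $0$ for ocularly balanced ones.  The binocular contrast sum
$C_{\text{sum}} = C_L + C_R$ and $O$ parameterise an item completely, and
`contrasts_from_ocularity()` inverts the definition exactly:
$C_L = C_{\text{sum}}(1+O)/2$.  All round trips hold to $10^{-12}$.

Three display mappings translate eye weights into screen luminance:

* **Bright bars on black** — each eye receives $s \cdot L_{\text{sum}}$,
  where $L_{\text{sum}}$ is the binocular luminance sum fixed by an
  ocularly balanced reference bar of 24 cd/m² per eye.  A 9:1
  eye-dominance bar ($s = 0.9/0.1$, $|O| = 0.8$) therefore delivers
  43.2 and 4.8 cd/m².
* **Decrement (dark-on-white)** — item luminance $110(1-s)$ cd/m² per
  eye: the dominant eye sees the darker image.
* **Increment letters on grey** — non-target strokes at
  $L_o + L_1(0.5+x)$ in both eyes and target strokes at
  $L_o + L_1 s (1+x)$ per eye, with $L_o = 43$, $L_1 = 67$ cd/m².  The
  target's per-eye increments always sum to $L_1(1+x)$, so its contrast
  sum is invariant to its ocularity.

Luminance fluctuations $x$ are drawn from *open* intervals —
$(-0.3, 0.3)$ for non-targets, $(-0.2, 0.2)$ for the target — enforced by
rejection sampling, because the stated ranges exclude their endpoints.
All luminances are screen-side values; the optical attenuation of goggles
or mirrors (e.g. seven eighths lost through shutter goggles) is carried as
metadata and never applied.

### Transient ocularity

A singleton's ocularity can be `static`, vanish abruptly at $\Delta T$
(e.g. a monocular item becoming binocular after 0.15 s), or decay
*smoothly* to zero over $[\Delta T, \Delta T + 0.1]$ s.  Only "smoothly"
is specified by the design, so the package had to choose a ramp: the
default is a raised cosine
$O(t) = O_0 \left(1 + \cos(\pi (t-\Delta T)/0.1)\right)/2$, which is
$C^1$ at both ends of the window — the motivation for a smooth decay is
precisely to avoid perceptible transients, and a ramp with discontinuous
slope would reintroduce them.  A linear ramp is available via
`ramp = "linear"`; both pass through $O_0/2$ at the window midpoint, and
both leave $C_L + C_R$ unchanged at every instant.

## Stimulus generation

Grids are regular lattices whose *centres* span the stated extent
(spacing = extent/(n−1)); the stated array extents are ambiguous between
centre-span and outer-edge span, and centre-span is recorded in the
configuration.  Coordinates are degrees of visual angle, origin at the
array centre, x rightward, y upward; grid indices are 1-based from the
top-left, which keeps the row-band placement constraints literal.

Target placement enumerates the feasible cell set and samples uniformly.
For the circle-based constraints ("closest on a circle of radius r grid
units") the default keeps the cells minimising $|d - r|$.  On the
23 × 23 grid, cells at exactly radius 10 exist (offsets (±10, 0),
(±8, ±6), (±6, ±8)), so the rule is well-populated.  On the 17 × 17 grid
the literal rule leaves only the two cells at offsets (0, ±7) — a
degenerate set.  The package keeps the literal rule as the default and
exposes `radius_tol` to admit every cell within a tolerance band of the
circle (e.g. 0.5 grid units), which we consider the more plausible
reading of "closest on a circle" for that design; the choice does not
affect any reported quantity.

Disparity uses the convention $d = x_R - x_L$ ($d < 0$ crossed, nearer
than fixation), realised as equal-and-opposite half shifts of the two
monocular images, so the mean of the per-eye positions is the perceived
position.  Items in the first and last grid columns always have $d = 0$.
The incongruent singleton is placed by mirroring the target across the
vertical midline — guaranteeing the opposite perceived half at matched
eccentricity — with uniform sampling from the opposite half available as
an alternative policy (the original placement rule, "far from the
target", is under-specified).

The heterogeneous-contrast letter design draws all luminance
fluctuations per trial and resamples the whole trial until the target's
contrast sum is strictly between the minimum and maximum of all items'
(cap $10^4$; in practice one draw almost always suffices because the
target's range is nested inside the non-targets').  The target's $x$ is
redrawn together with the non-targets' on every resampling pass — the
alternative (freezing the target's draw) changes nothing detectable, and
redrawing keeps the accepted trial exchangeable.  In units of $L_1$ the
expected contrast sum is 1 for target and non-targets alike.

Session schedules replicate each condition cell (9 cells × 50 trials for
the bar search; 8 × 50 for the first letter search; 1 baseline + 9 DC
cells × 45 for the heterogeneous-contrast letter search) and shuffle
uniformly under the session seed.  The ocularity magnitudes of the
heterogeneous-contrast design's DC cells are $\{1/5, 1/3, 3/5\}$: the
design states three levels and names the outer two (lustre imperceptible
at $1/5$, perceptible at $3/5$); $1/3$ is adopted for the middle level for
consistency with the bar-search design.  Everything downstream of a
configuration and a seed is deterministic, and per-trial seeds let any
scheduled trial be regenerated bit-identically.

## The synthetic observer

The observer is deliberately phenomenological — a cortical-circuit
account of the saliency computation is out of scope here —
and exists to give the analysis pipeline data with the right condition
structure.  Item priorities are

$$p_i = w_{\text{ori}} [\text{odd identity}] +
        w_{\text{oc}} \max(0, \Delta O_i - \theta) +
        w_{\text{lum}} \frac{C_i - \bar C}{\bar C} +
        w_{\text{near}} \, \text{rank}_i -
        a [\text{unbalanced among balanced, persistent}]$$

with $\Delta O_i$ the item's ocularity difference from the median of the
other items at onset, $\theta$ (`oc_threshold`) the minimum contrast that
produces attraction, and $a$ (`aversion`) active only when the imbalance
persists beyond `tau_percept` (0.2 s): percept formation (lustre) is
slower than saliency, so an imbalance removed within ~0.15 s escapes the
aversion while still attracting.  The first saccade is a softmax draw
over priorities at `capture_temperature` (default 0.25) — soft rather
than hard so first-saccade error rates sit well below 50%, as observed.
A missed first saccade is followed by one corrective saccade to the
target at cost `t_move` (0.15 s); the button press adds `t_decide` and
multiplicative lognormal noise (`rt_noise_sd = 0.18`); `lapse` flips the
button side (injecting incorrect trials) and a small heavy-tail mixture
(`heavy_tail_prob = 0.01`, multiplier 3–6) injects RT outliers so the
exclusion rule has work to do.

Two simulation routes share this model.  The vectorised *fast* route
collapses the softmax into target / singleton / background classes; it is
exact whenever all background items share one priority (constant contrast
sum and $w_{\text{lum}} = w_{\text{near}} = 0$), which holds for every
bar-search preset, and the tests assert its equality with the per-item
route.  The heterogeneous-contrast letter design always uses the
per-item route.

Preset calibration: `paper_like_*` presets use $w_{\text{oc}} = 2.5$ and
$\theta = 0.5$, chosen so that attraction is absent at singleton-
background contrast $2|O| = 0.4$, marginal at $2/3$, and strong at
$6/5$ — the contrast dependence the bar-search results show.  The
aversion presets set $a = w_{\text{oc}}(\Delta O - \theta)$ exactly, so a
*persistent* monocular singleton among binocular items is behaviourally
neutral (no congruent speed-up, no incongruent slow-down), which is how
the masking manifested; the transient sessions (imbalance removed at
0.15 s < `tau_percept`) recover the full attraction.  The observer's RT
*scale* is compressed relative to the hardest human conditions (it
performs at most one corrective saccade, so baselines sit near 0.4–0.6 s
rather than 1–2 s); only the condition *structure* — orderings,
contrast-dependence, masking — is calibrated, and only that structure is
asserted anywhere.

What the generator does **not** emulate: serial search with multiple
fixations, oculomotor dynamics (velocity profiles, undershoot),
fixational eye movements, perceptual learning or condition-frequency
strategies, and between-observer parameter heterogeneity (cohorts are
i.i.d. draws of one parameter set).  Passing tests therefore show that
the pipeline detects the modelled effect structure at realistic trial
counts and noise levels — not that human data would show it.

## Analysis choices

* **Exclusion** is per observer × condition, single pass: incorrect
  trials out first; then, with mean and SD computed over the correct
  trials *before* any removal, trials with RT < 0.2 s or
  RT > mean + 3 SD (strict inequalities) are excluded.  No re-iteration.
  With zero variance the threshold equals the mean and nothing is
  excluded.
* **Gaze-RT pools** reuse the button-RT pool and additionally drop trials
  whose gaze never reached the target (reach radius 1.5° by default —
  half the inter-item spacing of the densest design would be ~0.4° and
  unrealistically strict against fixation scatter).
* **Normalisation** divides each observer's condition RT by their
  matching baseline (within the same $|O|$ family, or the single session
  baseline for the heterogeneous-contrast design); the baseline's own
  normalised RT is exactly 1.  The pipeline's `auto` policy normalises
  when the between-observer coefficient of variation of baseline RT
  exceeds 0.25, since normalisation is meant for cohorts whose raw RTs
  vary too much.
* **First-saccade scoring** compares the sign of the first saccade's
  horizontal displacement with the target's side; displacements below
  0.1° are unclassified, to avoid scoring micro-displacements.
* **Median splits**: far iff the target's disparity-depth is farther than
  the trial's median item depth; strong iff its contrast sum exceeds the
  trial median.  Exact-median ties go to near and weak respectively
  (configurable); arrays with no disparity at all are unlabelled.
* **Matched-sample t-tests**, two-sided, df = n − 1, significance at
  p < 0.05 with no multiple-testing correction (the stated criterion).
  All-zero differences give t = 0, p = 1; nonzero differences with zero
  variance are degenerate and reported with p = 0 and a flag.

## Problem sizes used in the checks

The validation suite runs, per check: $10^4$ random small pools for the
exclusion-rule oracle, $10^4$ random trials for each median-split oracle,
2000 random paired samples against the closed-form t-test; 20 replicate
6-observer cohorts of the full 450-trial bar-search session for effect
recovery, 400 such cohorts under the ocularity-blind observer for null
calibration (rejection rate 5% ± 3%); and scans of 60 generated trials
per bar/letter design for the structural invariants (constant contrast
sum, border-column zero disparity, unique-sign counts).  These sizes give
Monte-Carlo standard errors comfortably below the asserted margins.

## Known limitations

The renderer draws letters from axis-aligned strokes (a stroke-glyph
approximation of the original sans-serif letterforms) and rasterises
without anti-aliasing or gamma correction; monitor calibration and
perceived-contrast nonlinearities across eyes are out of scope.  The
literal reading of the letter-search placement circle is degenerate (two
cells) unless `radius_tol` is widened.  The observer's single-corrective-
saccade policy compresses RT scale, as noted above, and its parameters
are not fitted to any human dataset.
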