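---
title: "Quantifying coronary remodeling against inferred normal dimensions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying coronary remodeling against inferred normal dimensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(fvri)
library(dplyr)
```

## The problem

Atherosclerotic coronary arteries remodel: as plaque accumulates between the
lumen and the external elastic membrane (EEM), the vessel may enlarge enough
to accommodate it (the Glagov phenomenon), enlarge insufficiently, stay put,
or even shrink. Classical IVUS practice scores remodeling by comparing the
most diseased cross-section against nearby "reference" segments with little
plaque — but references sit at a different point of a tapering vessel and are
rarely disease-free, so the comparison conflates remodeling with anatomy.

The approach implemented here replaces the reference segment with an
*inferred normal dimension*: a per-frame estimate of the EEM area the vessel
would have at that exact location had plaque never formed. Every IVUS frame
(and every lesion) can then be scored against its own counterfactual.

## The normal dimension model

On IVUS, lumen and EEM coincide where plaque is absent, and early plaque
does not encroach on the lumen. Frames with plaque burden below 20% are
therefore treated as carrying their normal lumen calibre, and a linear model
is fitted to those frames:

$$\widehat{\mathrm{EEM}}_{\mathrm{pred}} = \beta_0 + \beta_1\,\mathrm{dominance}
 + \beta_2\,\mathrm{vessel} + \beta_3\,\log d + \beta_4\,\mathrm{BSA}$$

with `dominance` a binary indicator (right-dominant reference level),
`vessel` a single ordinal code (LM 0, LAD 1, LCx 2, RCA 3), $d$ the distance
from the coronary ostium in mm (natural log, clamped at 1 mm so the ostium
maps to zero), and BSA the body surface area in m² (Mosteller by default,
Du Bois selectable). Training is further restricted to lumen areas in
[3.1, 19.6] mm² — vessels of 2–5 mm average diameter, the clinically
relevant calibre window. The fit is stabilised by a bootstrap (5,000
replicates by default), resampling *patients* so that the strong
within-patient clustering of frames is respected; the final equation uses
the bootstrap coefficient means, with 2.5/97.5-percentile intervals.
Frame-level resampling is available (`resample = "frame"`) but treats
clustered frames as independent.

A ready-made model with published coefficients from a 67-patient
three-vessel IVUS cohort ships as `packaged_normal_model()`, so scoring
works without refitting:

```{r}
tidy(packaged_normal_model())
```

The covariate encodings behind those published coefficients (vessel order,
dominance levels, log base) are not recoverable from the publication; the
conventions above are this package's own, so per-frame numeric agreement
with the original authors' predictions cannot be asserted — only the
printed constants themselves (e.g. an intercept of 12.20 mm² at the
reference covariates) are reproduced exactly.

### A caveat on the training rule

Selecting training frames by their *observed* lumen area truncates the
response variable. When residual spread is large — and it is: the packaged
fit explains less than half the variance — this selection attenuates every
slope towards zero, because unusually large observed lumens are cut at the
top of the window and unusually small ones at the bottom, differentially
across the covariate range. On simulated cohorts where the generating
coefficients are known, refitting with the full training rule shrinks the
vessel and log-distance slopes by 10–20%, several bootstrap standard errors,
while dropping the calibre filter restores near-unbiased estimates. Users
refitting the model on their own data should read its coefficients as
estimates of the *selected* population's regression, not of the underlying
anatomical relation. This is an intrinsic property of the published training
rule, which the package reproduces faithfully.

## The fractional vessel remodeling index

With the predicted normal area in hand, each frame with plaque is scored by

$$\mathrm{FVRI} = \frac{\mathrm{EEM}_{\mathrm{actual}}}
{\mathrm{EEM}_{\mathrm{pred}} + \mathrm{plaque\ area}}$$

the ratio of the vessel's measured area to the area it would need for
complete compensatory enlargement. FVRI is exactly 1 when enlargement
matches plaque load. The index's published algebra is not printed as a
formula; this form is the one consistent with every published constraint
(index of 1 at complete compensation, a strictly positive frame-level
distribution, and the nesting of absolute shrinkage inside the sub-band
region). A second variant satisfying the same constraints,
$(\mathrm{EEM}_{\mathrm{actual}} - \mathrm{plaque})/\mathrm{EEM}_{\mathrm{pred}}$
(the preserved-lumen ratio), is selectable via
`fvri_config(formula_variant = "lumen_ratio")`; the two agree exactly at 1
and always agree on the sign of $\mathrm{FVRI} - 1$.

Classification uses the band (0.83, 1.17) — one standard deviation of the
lesion-level index around 1, recomputable as `derive_band_from_sd(0.17)`:

* plaque burden < 20%: `trivial_plaque` (no remodeling call);
* FVRI > 1.17: `ectatic` — enlargement out of proportion to plaque;
* 0.83 ≤ FVRI ≤ 1.17 (inclusive): `complete_compensatory`;
* FVRI < 0.83 with EEM below its predicted normal: `negative`
  (absolute shrinkage);
* FVRI < 0.83 otherwise: `incomplete_compensatory`.

One boundary subtlety is worth recording: for burden barely above 20% and a
vessel within ~0.4% of its predicted size, the index can reach up to
$1/(1+b)\approx 0.833$ while the EEM is still (marginally) below its
predicted normal. In that measure-zero sliver the band rule takes
precedence and the frame is called complete-compensatory; from ~20.5%
burden onwards, shrinkage always implies an index below 0.83.

## Lesions, the classical index, and agreement

A lesion is any maximal run of at least three consecutive frames with
plaque burden above 40%; runs never overlap, and lesion length is the
distance span of the run. The minimal-lumen-area (MLA) frame — ties broken
proximally — represents the lesion: the lesion's FVRI and class are that
frame's. The classical index divides the MLA frame's EEM area by the mean
EEM area of the two frames immediately adjacent to the run (which, by
maximality, have burden ≤ 40%); lesions touching a pullback boundary lack a
reference and are excluded from classical-index analysis (kept in the
output with NA). Classical classes: negative < 0.88, intermediate
0.88–1.00 inclusive, positive > 1.00.

`agreement_table()` cross-tabulates the two schemes. Concordant pairs are
negative/negative, incomplete/intermediate and complete/positive — reported
as `concordance_named_pct` — while `overall_agreement_pct` additionally
counts ectatic/positive, since both denote expansion; the published
rounding of the worked example cannot distinguish which convention its
headline figure used, so both are always reported. Cohen's kappa, an added
diagnostic absent from the original scheme, is computed on the 3×3 collapse
with ectatic merged into complete.

```{r}
glance(agreement_from_counts(as.matrix(read.csv(
  system.file("extdata", "example_lesion_counts.csv", package = "fvri"),
  header = FALSE
))))
```

Composition contrasts (`composition_by_class()`) run a classic one-way
ANOVA per virtual-histology tissue percentage (fibrous, fibrolipidic,
necrotic core, dense calcium, as percentages of the four-component sum — the
confluent-plaque convention) across the classes of either scheme.

## The synthetic cohort generator

No public IVUS pullback dataset accompanies this method, so the package
carries a first-class simulator whose defaults encode the study conditions:
67 patients (weight 72.0 ± 11.6 kg, height 161.6 ± 7.9 cm, 15% left or
balanced dominance), four arteries each — LAD/LCx/RCA pullbacks of
40–80 mm, a short 5–15 mm left main — at 0.3 mm frame spacing. Per frame:

1. the normal lumen is $N = X\beta + \varepsilon$ with the packaged
   coefficients as generating truth; $\varepsilon$ is Gaussian with sd
   2.95 mm², autocorrelated along the artery (5 mm correlation length —
   vessel calibre varies smoothly, not frame by frame), and fixed once by
   bisection (`calibrate_noise()`) so that refitting the model on the
   simulator's own training frames returns an adjusted R² of about 0.46.
   Correlated deviations shrink the effective number of independent
   training observations, so the refitted R² scatters more between
   cohorts than an equally sized independent sample would; a longer
   correlation length would be anatomically even smoother but makes
   single-cohort fit statistics unstable. Draws below a 3 mm² anatomical
   calibre floor (a 2 mm-diameter vessel, about the smallest the modelled
   proximal segments plausibly reach) are redrawn;
2. plaque bumps are raised-cosine-tapered plateaus (Tukey windows; taper
   fraction 0.10, widths 20–45 mm, peak burdens 45–75%) packed along the
   artery with 2 mm healthy gaps at a Poisson rate of 6 attempts per
   artery. A pure raised cosine (taper 1) spends ~40% of its width
   traversing the 0–20% burden band, which would leave far too many
   near-normal frames; the flattened profile reproduces the intended ~11%
   share of trivial-burden frames. Peak burden is capped at 50% for
   ectatic bumps, where burden beyond $1/\theta$ is geometrically
   unattainable;
3. each bump draws a remodeling response $\theta$ from a four-component
   mixture (weights 0.22/0.41/0.35/0.02 echoing the observed lesion-class
   mix) with ranges U(−0.9,−0.4), U(0.2,0.45), U(0.9,1.1), U(1.45,1.7)
   chosen so the implied true FVRI stays clear of the band edges at typical
   lesion burden — classes are generated as distinct phenotypes, not
   boundary cases. The *effective* response ramps from 1 below 20% burden
   to the lesion's $\theta$ by 35%: compensation is complete while plaque
   is trivial (the premise that makes low-burden frames valid training
   data, and the reason the simulated burden-binned FVRI starts near 1 and
   declines) and fully expressed in established plaque. Plaque area then
   follows from the target burden as $P = bN/(1-b\theta)$, the true EEM is
   $N + \theta P$, and the true index $(N+\theta P)/(N+P)$;
4. measured EEM adds tracing noise that is *autocorrelated* along the
   pullback (Gaussian kernel, 5 mm correlation length — semi-automatic
   contours propagate between neighbouring frames) and scales with the
   contour perimeter, i.e. with $\sqrt{\mathrm{area}}$: the default
   0.8 mm² sd at the cohort-mean 14.2 mm² EEM corresponds to ~60 µm radial
   jitter. Independent constant-variance noise would be both physically
   wrong and statistically misleading: the MLA frame is a minimum over
   many near-tied frames, and white noise turns that selection into an
   extreme-value statistic that biases every lesion index downward;
5. virtual-histology composition is drawn on the log scale around typical
   percentages (55/20/15/10), with a $\theta$-linked shift — constrictive
   lesions gain dense calcium and necrotic core, expansive ones
   fibrolipidic tissue — plus per-lesion and per-frame noise. Softmax
   closure guarantees percentages sum to 100.

Ground truth (per-frame normal area, plaque, $\theta$, true FVRI and class;
per-bump summaries in `lesion_truth`) is emitted alongside, and identical
seeds give byte-identical outputs.

What the simulator does *not* emulate: deterministic anatomical tapering
beyond the log-distance trend (calibre deviations are smooth but random),
bifurcation-related calibre steps, eccentric or ruptured plaque morphologies, catheter-induced
artefacts, and any longitudinal progression. Tests that pass on this
generator therefore validate the *algorithms* — selection rules, index
algebra, classification logic, lesion bookkeeping, statistical machinery —
under realistic noise, not the clinical accuracy of the method on real
pullbacks.

## Numerical conventions and test scales

Distances at or below 1 mm enter the log term as 0. Predictions outside
[3.1, 19.6] mm² are flagged with a warning but never clamped. MLA ties go
to the most proximal frame. Band endpoints are inclusive for complete
compensation; the burden cutoffs are strict (`< 20`, `> 40`). Bootstrap
replicates with rank-deficient designs are redrawn (more than 10% redraws
aborts). Serialised tables round numerics to 6 decimals, and the read/write
round trip is exact from the first rewrite onwards.

The test suite exercises the pipeline at deliberately modest scales chosen
to keep a full run in minutes on one CPU: oracle comparisons on hundreds of
random designs and a thousand random burden sequences; classification
fidelity on 20–40-patient cohorts (a few hundred lesions); parameter
recovery on one hundred 67-patient cohorts with 500-replicate bootstraps;
composition power on one hundred 10-patient cohorts. The study-scale
properties asserted there — the ~11% trivial-burden share, adjusted R²
near 0.46, monotone FVRI decline with burden, ≥90% class recovery at
default noise against the known normal areas — are all recomputed from
scratch on simulated cohorts at those sizes.

## Known limitations

* The packaged model's covariate conventions are reconstructions; apply it
  to real pullbacks only as a demonstration, or refit on your own cohort.
* The training rule's response truncation (above) biases refitted
  coefficients; the package reproduces the rule rather than correcting it.
* Remodeling calls inherit the full uncertainty of the normal-dimension
  model; no per-frame uncertainty is propagated from the coefficient
  intervals into the index.
* Lesions separated by a single sub-threshold frame are not merged; the
  run definition is applied literally.
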