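---
title: "Measuring pyrodiversity and modelling its drivers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring pyrodiversity and modelling its drivers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pyrodiv)
```

## The measurement problem

Pyrodiversity is the variation in spatio-temporal fire patterns across a
landscape. Fire regimes differ along at least four axes — how often an area
burns, how severely, in what season, and in what spatial pattern — and a
landscape's ecological heterogeneity depends on the joint variation of all
four, including the legacy of earlier fires (the "invisible mosaic") that the
most recent burn scar does not show. `pyrodiv` quantifies pyrodiversity with
a functional-diversity construction: every grid cell is an individual, every
unique combination of discretized fire-regime traits (a *fire history*) is a
species, the number of cells carrying a history is its abundance, and a
landscape unit (for example a watershed) is the community. Pyrodiversity is
then the community's functional dispersion (FDis): the abundance-weighted
mean distance of histories from the community's abundance-weighted centroid
in trait space. FDis is unitless, zero exactly when all cells share one
history, independent of how many histories there are, and insensitive to
raster resolution (abundances enter only as relative frequencies).

## Trait surfaces

Four per-pixel trait grids are built from a record of fire perimeters and
composite burn index (CBI, 0–3) severity surfaces:

* **Fire return interval (years).** The intervals between successive burn
  years at a pixel, plus the two open intervals to the record's first and
  final year. A never-burned pixel carries the full record length — a
  minimum-frequency estimate, so frequency comparisons are relative, not
  absolute.
* **Burn severity (CBI).** Per-event CBI at the pixel; unburned pixels are 0
  (no vegetation change).
* **Burn season (cosine of date).** Each ignition day-of-year is mapped to
  `cos(2*pi*(doy - 1)/365)` so the calendar wraps: 1 January and 31 December
  are adjacent, and a leap day folds onto its neighbour within rounding
  precision. Unburned pixels have no season (missing).
* **Patch size (log hectares).** Each event's severity surface is classified
  into unchanged/low/moderate/high CBI classes (breaks 0.1, 1.25, 2.25),
  connected components are delineated with 8-connectivity, and the pixel
  takes the natural log of the hectare area of its component. Unburned
  pixels have no patch (missing).

### Recency weighting

Averaging a pixel's history treats neither extreme — "most recent event
only" and "all events equally" — as privileged. Instead the k-th most recent
event receives raw weight $(1-d)^{k-1}$, normalized to sum to one, with a
single decay parameter $d \in [0,1]$. $d=0$ is the plain mean, $d=1$ keeps
only the most recent event, and the default $d=0.5$ halves the weight of
each prior event. This is the unique one-parameter geometric family matching
those three behaviours. Weighting is by fire *order*, not elapsed time:
time-based decay would confound the weighting with the frequency trait
itself. For the return-interval trait the open interval back to the record
end is treated as the most recent "event", so the current state of the
regime dominates under recency weighting; the interval sequence for burns
$y_1 < \dots < y_n$ in window $[s, e]$ is
$(e - y_n), (y_n - y_{n-1}), \dots, (y_1 - s)$, most recent first.

### Discretization

Traits are rounded *after* weighting (not per event) to bound the size of
the history table: whole years for frequency, 0.5 CBI for severity, 0.1
cosine units for season, and 0.1 log-hectares for patch size (configurable;
0.1 log-ha gives roughly ninety bins over realistic patch sizes). Rounding
is round-half-even at each precision, so ties do not drift systematically.
Whether the record length for unburned pixels counts the window inclusively
(34 years for 1985–2018) or as the difference (33) is convention; the
default is the difference, `record_end - record_start`, and it is
configurable (`unburned_fri`).

## From traits to FDis

`tabulate_histories()` counts every cell whose centre falls inside the unit
polygon (cell-centre membership is the unambiguous standard for 30 m burn
products), optionally intersected with a flammable-area mask, and collapses
identical trait tuples into abundances.

Dissimilarity between histories is the Gower distance: per trait, the
absolute difference divided by the trait's **fixed global range** (frequency:
0 to record length; severity: 0–3; season: −1 to 1; patch: log of one cell
to log of the whole grid), averaged over traits with equal weights by
default. Fixed ranges — rather than per-unit observed ranges — keep FDis
comparable across landscape units, which a regional analysis requires.
Missing-trait comparisons (season/patch of unburned pixels) are excluded
and the remaining weights renormalized, so unburned ground still registers
as distinct from burned ground through frequency and severity without
inventing season or patch values.

FDis embeds the dissimilarity matrix by principal coordinates
(eigendecomposition of the Gower-centred matrix), keeping positive *and*
negative eigenvalue axes: Gower distances on these traits are Manhattan-like
and not exactly Euclidean-embeddable. The squared distance of history $j$
from the abundance-weighted centroid $c$ is the positive-axis part minus the
negative-axis part, floored at zero before the square root (the standard
signed correction), and

$$\mathrm{FDis} = \frac{\sum_j a_j z_j}{\sum_j a_j}.$$

Two internal identities pin the numerics down and are enforced in the test
suite at 1e−8: the signed-correction distances satisfy the generalized
Huygens theorem
$z_j^2 = \sum_k w_k d_{jk}^2 - \tfrac12 \sum_{k,l} w_k w_l d_{kl}^2$
(with $w = a/\sum a$) computed directly from the dissimilarity matrix with
no eigendecomposition, and on complete-case tables the ordination path
applied to a genuinely Euclidean distance matrix reproduces the direct
trait-space computation. Eigenvalues within `1e-9` of the largest magnitude
are treated as null axes. Functional richness (convex-hull volume) is not
computed — it is sensitive to outliers and sample size, and the history
count `n_histories` is reported as the simple richness diagnostic instead.

`local_pyrodiversity()` applies the same machinery to the cells within a
radius of a point, the form used around field survey locations.

## Trait covariance across units

`trait_dispersions()` computes, per unit, the univariate analogue of FDis
for each trait — the abundance-weighted mean absolute deviation about the
abundance-weighted mean — together with the number of fires intersecting
the unit. `correlation_sweep()` then correlates trait dispersions across
units while progressively excluding units with fewer recorded fires
(thresholds 1–15 by default). Pearson correlation is the default ("rank"
behaviour is available via `method = "spearman"`); correlations on fewer
than three units or on a zero-variance column are flagged undefined rather
than propagated as NaN. On synthetic unit tables in which all four
dispersions are coupled only through a saturating function of fire count,
the sweep reproduces the qualitative signature expected of
data-availability coupling: strong correlations among rarely burned units
that decline steadily as the minimum-fire threshold rises.

## Drivers of pyrodiversity

Unit-level pyrodiversity $y_{i,j} \in (0,1)$ for unit $i$ in parent group
$j$ is modelled with a mean-precision Beta likelihood and logit link:

$$y_{i,j} \sim \mathrm{Beta}(\bar P_{i,j}\,\theta,\ (1-\bar P_{i,j})\,\theta)$$
$$\mathrm{logit}(\bar P_{i,j}) = \alpha_0 + \alpha_j
  + \beta_{\mathrm{AET}} X_1 + \beta_{\mathrm{CWD}} X_2
  + \beta_{\mathrm{AET*CWD}} X_1 X_2
  + \beta_{\mathrm{elev}} X_3 + \beta_{\mathrm{rough}} X_4
  + \beta_{\mathrm{elev*rough}} X_3 X_4
  + \beta_{\mathrm{pop.den}} X_5 + \beta_{\mathrm{wild}} X_6
  + \beta_{\mathrm{prop.burn}} X_7 + \beta_{\mathrm{prop.burn2}} X_8$$
$$\alpha_j \sim \mathrm{Normal}(0, \sigma_{\mathrm{group}})$$

with all predictors standardized (mean 0, sd 1), $X_7$ the standardized
cumulative proportion of flammable area burned (it may exceed one where
areas reburn), and $X_8 = X_7^2$. Burn activity itself is modelled by a
hurdle submodel on the same climate/topography/human covariates: a logit
model of whether any area burned times a Gamma log-link model of the
positive proportion, each with its own varying intercepts. The hurdle form
is a deliberate choice for a zero-inflated, positively skewed quantity that
is not bounded by one; the family is pluggable.

Fitting uses `glmmTMB` (maximum likelihood with Laplace-approximated
varying intercepts). The "posterior" contract is satisfied by
multivariate-normal draws around the estimates using the estimated
covariance; a full MCMC backend would slot in behind the same `model_fit`
interface. Propagation of burn-model uncertainty into the pyrodiversity
model follows a multiple-imputation scheme: parameter draws from the burn
posterior generate realizations of the expected proportion burned, the
pyrodiversity model is refitted to each realization (8 by default), and
draws are pooled — which demonstrably widens the intervals of the
burn-activity coefficients relative to plugging in observed values. A
cheaper plug-in-mean mode exists for quick checks. Zero responses are
incompatible with a Beta likelihood; the default treats values below 1e−12
as zeros and nudges them to half the smallest positive observed value, with
a loud message (a zero-inflated Beta is the natural extension if zeros
carry signal).

`derived_quantities()` converts the quadratic burn-activity effect into
interpretable numbers per draw: the vertex $-\beta_{\mathrm{prop.burn}} /
(2\beta_{\mathrm{prop.burn2}})$ on the standardized scale, back-transformed
to a raw proportion with the stored scaling, and the fire rotation —
record length divided by the peak proportion, the time needed to burn an
area equal to the landscape. Draws with a non-negative quadratic term admit
no peak and are dropped; if they are the majority the peak is flagged
undefined. Summaries are means with central 90% intervals, the reporting
convention used for these effects.

## The synthetic generator

`simulate_fire_records()` emulates an MTBS-style record: Poisson annual
ignition counts, log-normal fire sizes, wrapped-normal ignition dates, and
severity surfaces drawn from a spatially correlated Gaussian field scaled
to a target mean/sd and clipped to CBI's 0–3 range. Perimeters are
star-shaped blobs — smooth random radial harmonics scaled so the polygon
area equals the sampled area exactly — which gives connected, irregular,
cheaply generated shapes; they are star-convex, unlike the occasionally
multi-lobed or holed perimeters of real fires, and fires are placed
independently rather than responding to fuels or topography. Passing tests
on these mosaics therefore demonstrate the correctness of the metric's
mechanics, not realism of fire spread.

`two_regime_fixture()` builds a landscape whose west half burns often at
low severity in small patches and whose east half burns rarely at high
severity in large patches, with both halves substantially burned; its
contract is that the union's FDis exceeds either half's, because mixing two
internally homogeneous regimes adds between-regime dispersion.

`simulate_driver_table()` draws standardized covariates, simulates burn
activity and pyrodiversity from a `model_spec`, and stores the generating
spec for recovery tests. The default regime (`default_model_spec()`)
mirrors a western-US-like system: the quadratic burn-activity effect
(2.5, −0.78 standardized) dominates, precision $\theta = 30$ concentrates
responses near small values, and the burn regime yields ~30% unburned
units, a median proportion burned of a few percent and a maximum around
1.5–2.5. The burn regime is deliberately light-tailed: pushing the
standardized burn predictor many sd past the quadratic vertex drives the
Beta mean below double-precision resolution, where simulated draws
underflow and no likelihood method can recover the truth — a numerical
boundary of the simulation design, not of the estimator.

## Problem sizes and numerical choices

The test suite runs on grids of 40×40 to 60×120 cells of 30–100 m,
records of a few dozen fires over 1985–2018, driver tables of 300–3000
units in 3–6 groups, and 20-replicate recovery studies at n = 500 — sizes
chosen so the full suite completes in about a minute while leaving
parameter-recovery checks well powered. Other fixed numerical choices:
round-half-even at every trait precision; the 1e−9 relative eigenvalue
cutoff in the ordination; squared centroid distances floored at zero before
the square root; the 404 ha large-fire threshold applied as a strict
inequality and the 50% forest-cover filter as a strict "less than", both
matching the conventions of the source record; severity values outside
0–3 clipped (with a warning) rather than rejected, since remotely sensed
CBI models can overshoot slightly.

## Known limitations

* No coordinate reprojection is bundled: all inputs must already be in a
  common projected metric CRS, and longitude/latitude-looking coordinates
  are rejected outright.
* Raster interchange uses plain-text ESRI ASCII grids and vector
  interchange uses GeoJSON; there is no GeoTIFF/Shapefile reader.
* Inference is maximum likelihood with a Gaussian approximation to the
  posterior; with very few parent groups the group-intercept sd (and hence
  the intercept's interval) is weakly identified, which MCMC would also
  struggle with but would at least propagate honestly.
* Whether unburned-but-flammable area belongs in the community table is a
  scientific choice; both options are supported via `flammable_mask`, and
  the default includes all cells of the unit.
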