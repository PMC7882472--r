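---
title: "Methods: quantitative plant-leafhopper webs, connectivity and multimodel inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative plant-leafhopper webs, connectivity and multimodel inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragweb)
```

This vignette is the package's own account of its methods: the models and
the assumptions behind them, the parameters that matter, what the synthetic
generator does and does not emulate, and the numerical and design choices
made where the field's conventions leave room.

## From surveys to communities

A fragment is surveyed on six transects; each transect has one botanical
plot (percent cover per vascular plant species, plus bare ground and litter)
and three sweep-net samples of leafhoppers across the season. Leafhopper
counts are pooled per fragment by summing over transects and occasions —
pooling is order-independent, and a sampling occasion absent from the counts
is treated as zeros with a warning rather than an error, because a long
count table normally records only positive catches.

Relative cover of species $s$ on a transect is
$c_s / (\sum_t c_t + c_{bare} + c_{litter})$, so the plant shares plus the
bare-ground and litter shares sum to one. The fragment-level quantity is the
**mean of per-transect ratios**, not the ratio of summed covers. The
defining sentence of the procedure computes a relative cover per transect
first and a fragment mean second, and the two orders differ whenever total
cover varies among transects; the mean-of-ratios choice weights transects
equally, which matches a fixed-plot design. This is pinned by a test, and
sensitivity to the alternative would show up only through the allocation
weights, which are renormalised anyway (below).

A leafhopper is a **habitat specialist** if it either has habitat
requirements confined to calcareous grassland or feeds exclusively on plants
of such grasslands; either condition alone suffices. The classification is
total: every species in the diet database receives exactly one label.

## Web assembly

Three exclusion rules produce the retained community:

1. taxa not identified to species level (global),
2. taxa whose food plants are unknown at species or genus rank (global),
3. taxa none of whose food plants were recorded in the given fragment
   (fragment-specific).

A taxon counted in the field but absent from the diet database is a hard
error, not a silent exclusion — the database must state explicitly that a
diet is unknown. Every exclusion is logged with its specimen count, and the
pipeline enforces the conservation identity
$\text{pooled} = B + \text{excluded}$ exactly.

Genus-rank diet entries match **all** recorded congeners. Diets recorded
only to genus were treated as usable knowledge (only diets unknown at both
ranks trigger rule 2), which makes congener matching the consistent reading;
the alternative (dropping genus-rank entries) would reclassify those taxa
into rule 2 and discard information.

Allocation: a species with a single available food plant (monophagy, or one
plant present) puts its whole abundance there; with several, abundance is
split proportionally to the plants' mean relative covers **renormalised over
the matched plants only**. Renormalisation makes allocations invariant to
rescaling all covers and keeps column sums equal to retained abundances to
machine precision (a residual of order 1e-15 is folded into the largest
cell so conservation is exact). Allocations are continuous; no integer
rounding.

## Network indices

With $p_{ij} = b_{ij}/B$: interaction diversity $H = -\sum p_{ij}\ln
p_{ij}$; weighted generality $G = \sum_j (b_{\cdot j}/B)\, e^{H_j}$ with
$H_j$ the entropy of column $j$'s proportions; vulnerability $V$ is the
row-wise mirror; linkage density $LD = (G+V)/2$. All entropies are natural;
effective numbers are base-invariant, so base 2 with $2^H$ would give
identical $G$, $V$, $LD$ — the base only changes the units of $H$ (nats
here). Empty cells contribute $0$ ($0\ln 0 := 0$). Useful identities used as
tests: $H \le \ln(\text{links})$, $1 \le G \le \#\text{plants}$,
$LD \equiv (G+V)/2$, $V(b) = G(b^\top)$, invariance under rescaling $b$, and
merging two identical independent sub-webs adds $\ln 2$ to $H$ while leaving
$G$, $V$, $LD$ unchanged.

## Connectivity

The incidence-function index of focal patch $i$ is
$S_i = \sum_{j \ne i,\ d_{ij} \le r} e^{-\alpha d_{ij}} (a A_j)^\beta$ with
centroid distances in metres. Defaults: $\alpha = 0.001$ m$^{-1}$ (a 1 km
e-folding of dispersal), $\beta = 0.5$ (boundary-length scaling of emigrant
numbers), $r = 2000$ m. The literature rarely states the **area unit**
entering $A_j^\beta$, yet the index magnitude depends on it. `connectivity()`
therefore applies the formula to areas exactly as supplied
(`area_scale = 1`, hectares), while the synthetic generator sets
`area_scale = 1e4` (square metres): published index ranges of order 20–849
over a 2 km radius are attainable with realistic patch geometry only on the
m² convention — on hectares they would require thousands of hectares of
neighbouring grassland inside the radius. Both conventions are exposed as an
explicit parameter rather than hidden in the data.

## Statistical protocol

Continuous predictors (arable %, log10 connectivity, richness covariate) are
standardized to $[0,1]$ (min to 0, max to 1) so effects are comparable;
size class is coded small = 0, large = 1. Connectivity enters as log10
because its effect saturates over an order-of-magnitude range.

The global model per response is {L, S, C, L:C, S:C, L:S, R}. All subsets
respecting marginality (an interaction only with both parents) are fitted —
18 models over the three mains and their interactions, 36 with the free
covariate R — including the null model. Gaussian responses use OLS with the
ML residual variance in the log-likelihood and $k$ counting intercept,
slopes **and** variance, so AICc values match implementations that count the
variance parameter; the binomial response (specialist species out of all web
species) uses a logit GLM via IRLS (tolerance 1e-8), with separation or
non-convergence flagged and the fit excluded from averaging with a warning.
$n$ is the number of fragments for both families.

$AICc = -2\ell + 2k + 2k(k+1)/(n-k-1)$. The candidate set keeps models with
$\Delta AICc < 6$ (strict), with Akaike weights renormalised over the kept
set; AICc ties break by fewer terms, then lexicographic term order, so the
candidate ordering is deterministic. Coefficients are averaged
**conditionally**: per term, weights are renormalised over the candidate
models containing it, $\bar\beta = \sum \tilde w_m \beta_m$, and the
unconditional standard error
$SE = \sum_m \tilde w_m \sqrt{se_m^2 + (\beta_m - \bar\beta)^2}$ combines
within-model variance and between-model spread; the 95% CI is $1.96\,SE$.
Conditional averaging avoids the shrinkage towards zero that full averaging
imposes on terms absent from many models. **Importance** is reported as the
integer count of candidate models containing the term (not a weight sum),
matching the journal-table convention this layout mirrors.

Fit quality of the full model is the multiple $R^2$ for Gaussian responses;
for the binomial response no single pseudo-$R^2$ is canonical, and the
squared correlation between observed and fitted proportions is reported as
the analogue (labelled as such in `model_table()`). VIFs are computed over
the independent variables (L, S, C, R) only — product interaction columns
are correlated with their parents by construction, and a variance-inflation
screen is about the design, not the parameterisation.

## The synthetic generator

`generate_study()` emulates the study conditions: 14 small (0.06–0.60 ha)
and 14 large (1.24–8.76 ha) fragments; connectivity spanning 20–849 (the
two endpoints are realised exactly, the rest log-uniform, and background
patch areas are scaled so the geometry reproduces each target index);
arable 27–77%; pairwise $|\rho| < 0.3$ among the design variables by
rejection sampling (echoing an orthogonal design); a 167-species flora with
log-normal commonness; 67 retainable leafhopper species (29 specialists)
plus one unidentifiable taxon, four with unknown diets and four whose hosts
never occur on transects, calibrated to an excluded-specimen share near 5%;
monophagy probabilities 0.66 (specialists) and 0.24 (generalists).

The ground truth is a logit model on the probability that a fragment
occupant is a specialist species:
$\text{logit}(p) = \theta_0 + \theta_L L + \theta_S S + \theta_C C +
\theta_{LC} LC + \theta_{SC} SC + \theta_{LS} LS$, with defaults dominated
by a positive size × connectivity interaction ($\theta_{SC} = 1.13$,
$\theta_S = -1.02$, the remaining terms near zero) — the effect structure
the pipeline exists to detect. Counts are overdispersed (negative binomial,
size 1.5, shifted by 1 so every occupant is observed at least once) because
pure Poisson counts are unrealistically clean; specialists get a higher
per-species abundance mean (14 vs 7) so specimen totals lean specialist.
Consumers settle only in fragments containing at least one of their food
plants — without this, host-absence exclusions would inflate the excluded
share several-fold beyond anything a field study reports. Plant covers are
log-normal, thinned by fragment (occupancy increasing with commonness) and
by transect (75% retention), and scaled to a 55–95% total cover.

What the generator does **not** emulate: spatial autocorrelation among
fragments, phenology across the three occasions (independent multinomial
splits), observation error in cover estimation, and any direct dependence of
web structure on the design beyond the specialist-share channel and richness.
Passing tests therefore certify the pipeline's arithmetic and its power
against this data-generating model, not the ecological conclusions one would
draw from field data.

A single seed drives stage-specific derived sub-seeds (flora, landscape,
diet, community), so stages can be regenerated independently and the whole
study is bit-reproducible. A deterministic 3-fragment fixture
(`toy_study()`) exercises every assembly path — monophagy, genus matching,
proportional allocation, all three exclusion rules — without randomness.

## Numerical choices and degenerate inputs

Zero-denominator transects error individually and are dropped at fragment
level with a warning (error only if all six are degenerate). An empty
candidate set cannot occur (the null model always fits); an empty web (no
consumer survives exclusion) is an error naming the fragment. AICc is
undefined when $n \le k + 1$; tiny analytic fixtures carry `NA` there and
only model comparison refuses to proceed. Rank-deficient designs error
naming the aliased columns. Perfect collinearity reports `VIF = Inf`.

## Problem sizes used by the test suite

Oracle equivalence of $H$, $G$, $V$, $LD$ is checked on 1000 random webs of
up to 8 × 8 species against plain-loop entropy implementations (agreement
within 1e-10; the identity $LD = (G+V)/2$ to 1e-12). Parameter recovery
runs 100 replicates of 200 fragments with a planted standardized
size × connectivity coefficient of 2: the conditional-average estimate
covers the truth in at least 90% of replicates and recovers the sign in at
least 95%. The end-to-end pipeline tests use the default 28-fragment study
and smaller 6–10-fragment configurations. These sizes were chosen to give
the properties enough resolution while keeping a full test run around a
minute.

## Known limitations

Diet-based allocation assumes feeding follows availability among known
hosts; it cannot detect preference beyond the literature's host lists.
Conditional averaging reports terms that appear in any candidate model, so
weakly supported terms carry wide CIs rather than being absent. The
binomial pseudo-$R^2$ is a descriptive analogue, not a likelihood-ratio
measure. The connectivity index depends on an area-unit convention that
published ranges rarely state; comparisons across studies should fix
`area_scale` explicitly.
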