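---
title: "Methods: neighborhood sentiment, spatial dependence, and dialect confounding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: neighborhood sentiment, spatial dependence, and dialect confounding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sentitract)
```

# The measurement model

`sentitract` operationalizes a two-part question: does the aggregate
sentiment of geolocated short texts predict small-area health outcomes,
and how much of any such association is an artifact of *who* writes in a
neighborhood rather than *how they feel*?

## Hedonometer scoring

The sentiment instrument is a lexicon of words with human-annotated
happiness ratings on a 1–9 scale. A text $T$ with word frequencies
$f(w_i)$ scores

$$h_{avg}(T) = \frac{\sum_i h(w_i)\, f(w_i)}{\sum_i f(w_i)},$$

a frequency-weighted mean over lexicon-matched tokens only. Two
robustness conventions are applied before scoring:

* **Neutral window.** Words rated within $\pm 1$ of the midpoint 5 are
  removed (`apply_neutral_filter()`). We treat the window as the *closed*
  interval $[4, 6]$: ratings of exactly 4.0 or 6.0 are excluded. The
  boundary convention matters for a handful of words only; it is recorded
  here because the alternative (open interval) is equally defensible, and
  the choice is exposed through `neutral_center`/`neutral_halfwidth`
  rather than hard-coded.
* **Unit-level pooling.** A unit's score pools token counts across all
  its messages and applies the same weighted mean — it is *not* the
  average of per-message scores. Pooling is the standard hedonometer
  reading and makes the unit score the score of the unit's concatenated
  corpus; the two conventions diverge when message lengths correlate with
  message sentiment.

Tokenization is deliberately minimal: lowercase, split on whitespace,
strip leading/trailing punctuation, preserve internal apostrophes. No
stemming, no spelling normalization. This is a substantive choice, not a
simplification: dialect forms (*don't*/*dont*, *gone* as a future-tense
marker) must remain distinct tokens because differential usage of exactly
such forms is the confounding mechanism under study. Leading `#` and `@`
are stripped so hashtag and mention residuals can match the lexicon;
the assumption is configurable at the tokenizer boundary.

## Corpus filtering

Messages pass three filters before scoring, mirroring standard practice
for platform data:

1. a **source whitelist** of interactive clients
   (`default_source_whitelist()`), matched exactly and case-sensitively,
   which drops bots, feeds, and cross-posts;
2. **deduplication** on the `(user_id, text)` pair, keeping first
   occurrences. Scoping duplicates to the same user avoids deleting
   genuine reposts of the same text by different users; `by_user = FALSE`
   gives the stricter text-only rule;
3. **point-in-polygon assignment** to areal units, planar in lon/lat
   (curvature is negligible at tract scale). A point on a shared boundary
   is assigned to the lowest-sorted containing `unit_id` — an arbitrary
   but deterministic tie-break, so assignment never depends on record or
   polygon order.

Units with fewer than `min_messages` messages (default 1,000, the
standard inclusion threshold for tract-level studies of this kind) are
excluded and reported rather than silently scored from thin corpora.

## Word-shift decomposition

For a comparison corpus and a reference corpus (by default the pooled
all-units corpus), the contribution of word $i$ to the happiness
difference is

$$\delta h_{avg,i} = \frac{100}{|h_{avg}(comp) - h_{avg}(ref)|}
  \left[h(w_i) - h_{avg}(ref)\right]\left[p_i(comp) - p_i(ref)\right].$$

Relative frequencies $p_i$ are normalized over lexicon-matched tokens
only; with that convention the contributions sum to exactly $\pm 100$
(sign of $h_{comp} - h_{ref}$), which the test suite verifies to
$10^{-9}$ across random corpus pairs. Reports are ranked by $|\delta|$
with an alphabetical tie-break, and carry frequency (up/down) and
sentiment (plus/minus) direction markers. When the two corpora have equal
scores the normalizer vanishes and `word_shift()` refuses to divide by
zero rather than returning infinities.

# Spatial analysis

## Weights

Contiguity weights are built from shared polygon vertices after snap
rounding (`snap = 1e-8` in coordinate units): queen contiguity requires
at least one shared vertex, rook at least two. This is exact on lattices
and on any polygon layer whose shared borders are identically noded — the
situation for census products — but it will miss neighbors across
borders digitized with different vertex sets; that is the main known
limitation of the weights builder. Queen is the default rule, the common
choice for tract analyses. Islands (units with no neighbors) are
reported, left as zero rows under row standardization, and escalated to a
hard error in pipeline runs, where a disconnected unit would silently
break the spatial-lag model.

## Moran's I and LISA

Global autocorrelation uses the standard cross-product statistic with
expectation $-1/(n-1)$ under the randomization null; inference is by
random permutation of the value vector (999 permutations by default,
pseudo $p = (\#\{\text{as extreme}\} + 1)/(B + 1)$, so the smallest
attainable $p$ is $1/(B+1)$). Local statistics use
$I_i = z_i \sum_j w_{ij} z_j / m_2$ with $m_2 = \sum z^2 / n$, whose mean
equals the global $I$ under row-standardized weights — an identity the
tests assert to $10^{-9}$. LISA significance uses *conditional*
permutation (unit $i$ held fixed, the remaining values reassigned among
its neighbors). No multiple-testing correction is applied by default,
matching how LISA cluster maps are conventionally read; a
Benjamini–Hochberg option exists for users who want calibrated
cluster counts. All permutation streams are isolated from the caller's
RNG state and reproducible from an explicit seed.

## Regression ladder

The pipeline fits, per outcome: (1) OLS of the outcome on the
standardized sentiment score; (2) a SARAR model on the same design;
(3) a SARAR model adding the covariate set. Predictors are z-scored, so
the OLS intercept equals the outcome mean — a useful cross-check that
standardization happened (asserted to $10^{-8}$ in the tests).

The SARAR model
$$y = X\beta + \lambda W y + u, \qquad u = \rho M u + \varepsilon$$
is estimated by generalized spatial two-stage least squares: 2SLS for
$(\beta', \lambda)'$ with instruments $[X, WX, W^2X]$ (constant and
collinear columns pruned by pivoted QR; the lag order is configurable),
generalized-moments estimation of $\rho$ from the stage-one residuals
(the three-moment system is solved by profiling the innovation variance
out linearly and line-searching $\rho$ on $(-0.995, 0.995)$), then
spatial Cochrane–Orcutt filtering by $(I - \hat\rho M)$ and a final 2SLS
pass. We chose the GS2SLS/GM estimator over maximum likelihood because it
is the estimator the applied literature this package serves actually
cites, it needs no Jacobian determinant, and it remains well defined with
$W = M$ (the default). Consequences to be aware of: the GM step provides
no standard error for $\rho$ (reported as `NA`), and $\hat\rho$ carries a
modest downward bias at a few hundred units — visible in the acceptance
replication, which requires the mean of $\hat\rho$ within 0.07 of the
truth at $n = 400$ rather than the 0.05 demanded of $\hat\lambda$.
Degenerate weights (no links) reduce the fit to OLS with
$\lambda = \rho = 0$ exactly; a lag estimate on or beyond the unit circle
is flagged rather than silently reported.

Model selection diagnostics are the standard LM battery computed from
OLS residuals — LM-lag, LM-error, and the robust variants — each
$\chi^2_1$ under the null. The pipeline's decision rule reads the robust
pair at $\alpha$: both significant suggests SARAR, one suggests that
single-process model, neither keeps OLS. The robust statistics are
robust to *local* misspecification only: under a strong pure-lag process
(e.g. $\lambda = 0.7$) the robust error test also rejects and the rule
reads "sarar". That is a property of the statistics, not a bug, and the
power test in the suite therefore checks the rule where it is
informative (at $\lambda = 0.4$ the "lag" verdict is the clear
majority).

Coefficient changes across models use the Clogg–Petkova–Haritou $z$
statistic. Both variance rules are implemented: the conservative
`"sum"` form $z = (b_a - b_b)/\sqrt{se_a^2 + se_b^2}$, always defined and
used by the pipeline, and the nested `"difference"` form with
$se_a^2 - se_b^2$ in the denominator, which requires the first model to
be noisier and errors otherwise.

## Composite index

`pca_composite()` z-scores the indicators, extracts the first principal
component of their correlation matrix, reports loadings on the
correlation scale (eigenvector $\times \sqrt{\lambda_1}$) and the percent
of variance as the first eigenvalue's share of total standardized
variance. "Common variance" is thus read as total standardized variance
captured by component 1 — not communality-reduced variance, which would
require a factor model the method does not fit. Scores use the
regression method, which for a principal component reduces to the
standardized component scores $Z v_1 / \sqrt{\lambda_1}$ (mean 0,
variance 1). The component sign is arbitrary; we orient it so a
designated positive-pole indicator (income-like) loads positively.

# The synthetic world

The generator exists so every pipeline stage can be exercised, and the
confounding mechanism demonstrated, without restricted platform or survey
data. Its components:

* **Geography**: a `rows × cols` lattice of unit squares. Unit squares
  keep point-in-polygon exact and contiguity unambiguous; an
  irregular-polygon fixture in the tests covers the boundary tie-break.
* **Covariates**: `x_smooth`, a standardized spatially autocorrelated
  field $(I - \kappa W)^{-1}\xi$ (default $\kappa = 0.7$) emulating
  clustered socio-economic disadvantage, and iid `x_noise`.
* **Outcomes**: the exact SARAR reduced form
  $y = (I-\lambda W)^{-1}(\alpha + X\beta + (I-\rho M)^{-1}\varepsilon)$,
  solved sparsely — no approximation, as confirmed against fixed-point
  iteration in the tests. Defaults $\lambda = 0.4$, $\rho = 0.3$,
  $\sigma = 1$: moderate dependence of the size reported in tract-scale
  health studies.
* **Corpus**: per unit, messages of Poisson length (mean 8 tokens,
  tweet-scale) drawn from three word pools — standard-positive,
  standard-negative, and dialect-marked words that raters score low. The
  dialect-pool weight follows
  $\mathrm{logit}^{-1}(\mathrm{logit}(0.15) + \gamma\, g_u)$ where $g_u$
  is the unit's standardized `x_smooth` and $\gamma$ is
  `dialect_gradient`; the positive/negative split of the remaining mass
  (`mood`, default 0.6) is constant across units. Confounding is thus
  implemented **at the word-frequency level, never by altering ratings**:
  the lexicon stays fixed and "correct" for the standard dialect, and
  measured happiness drifts only because usage differs — the actual
  mechanism by which standard-dialect-calibrated lexicons mismeasure
  other dialects. The default is 1,200 messages per unit (just above the
  1,000-message inclusion threshold) and `dialect_gradient = 0`; the
  confounding experiments switch the gradient on explicitly.
* **Plumbing realism**: a fraction of messages gets off-list sources
  (default 10%) and a small fraction is duplicated verbatim (2%), so the
  whitelist and deduplication stages are exercised end to end, and
  writers emit the exact file formats the readers consume (CSV/ND-JSON
  messages, GeoJSON geography, TSV lexicon).

All streams derive from one master seed through named sub-streams, so
regenerating the corpus never perturbs the outcomes and vice versa, and
every run is bit-reproducible.

**What passing tests on this generator do and do not show.** They show
the pipeline's arithmetic, estimators and decision rules behave correctly
on data whose generating process is fully known — including recovering
true SARAR parameters and reproducing the confound qualitatively
(sentiment spuriously significant until the latent factor is
controlled). They do not show anything about real text: the generator
produces bags of lexicon words, with no syntax, polysemy, emoji,
code-switching, sarcasm, or temporal structure, and its "dialect" is a
frequency shift over a designated pool rather than real dialect
variation. Results on real corpora inherit every limitation of lexicon
sentiment that the confounding experiment dramatizes.

# Problem sizes and numerics

The validation suite runs at sizes chosen to make Monte Carlo error
small relative to the tolerances while staying desk-scale: parameter
recovery uses 200 replicates on the 20×20 lattice (plus 60-replicate
RMSE comparisons at 10×10 vs 30×30), LM test sizes use 1,000 null
replicates at $n = 225$, and the confounding experiment uses 50 seeded
worlds of 100 tracts × 150 messages. Closed-form identities (shift
conservation, local/global Moran consistency, the intercept identity) are
asserted at $10^{-8}$–$10^{-12}$; stochastic recoveries at the tolerances
stated above. Degenerate inputs error early and descriptively: constant
vectors in Moran/LISA, equal-score corpora in word shifts, rank-deficient
designs, constant indicators in the PCA, self-intersecting polygons, and
islands in pipeline mode.

# Known limitations

* Vertex-based contiguity requires identically noded shared borders.
* GPS-point geolocation only; place-polygon messages are out of scope.
* Single-language, unigram lexicons; no negation handling or n-grams.
* The GM estimator reports no standard error for $\rho$; users needing
  one should bootstrap.
* Per-text external scorers (e.g. rule-based valence systems) can be
  substituted upstream of the areal aggregation, but their rule sets are
  not reproduced here.
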