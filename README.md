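# sentitract

Neighborhood sentiment scoring and spatial regression of areal health
outcomes.

`sentitract` is an R package for researchers who want to test whether the
"mood" of a neighborhood, as measured from geolocated short texts (tweets
and similar), predicts small-area health outcomes — and, just as
importantly, for researchers who want to probe how easily that measurement
is confounded by dialect and demographics. It implements the full analysis
chain at tract scale:

1. **Hedonometer scoring.** The happiness of a text *T* is the
   frequency-weighted mean of human-annotated word ratings on a 1–9 scale,

   *h*<sub>avg</sub>(*T*) = Σ<sub>i</sub> *h*(*w*<sub>i</sub>) *f*(*w*<sub>i</sub>) / Σ<sub>i</sub> *f*(*w*<sub>i</sub>),

   after removing "neutral" words rated within ±1 of the scale midpoint 5.
   Messages are filtered by a whitelist of interactive client source
   strings, deduplicated per user, assigned to areal units by
   point-in-polygon, pooled per unit, and units with too few messages
   (default threshold 1,000) are excluded.

2. **Word-shift decomposition.** The difference in happiness between a
   comparison corpus and a reference corpus is attributed word by word:

   δ*h*<sub>avg,i</sub> = 100 / |*h*<sub>avg</sub>(comp) − *h*<sub>avg</sub>(ref)| · [*h*(*w*<sub>i</sub>) − *h*<sub>avg</sub>(ref)] · [*p*<sub>i</sub>(comp) − *p*<sub>i</sub>(ref)],

   which sums to ±100 across the lexicon and so ranks the words driving a
   neighborhood's apparent mood.

3. **Exploratory spatial data analysis.** Queen/rook contiguity weights,
   global Moran's I with conditional-permutation inference, and LISA local
   cluster classification (High-High, Low-Low, High-Low, Low-High).

4. **Spatial regression.** OLS with standardized predictors, the Lagrange
   multiplier battery (LM-lag, LM-error, and robust variants) for model
   selection, and the SARAR model

   *y* = *X*β + λ*W y* + *u*,  *u* = ρ*M u* + ε,

   estimated by generalized spatial two-stage least squares (GS2SLS) with
   generalized-moments estimation of ρ, plus Clogg–Petkova–Haritou
   comparison of coefficients across models and a PCA composite index
   (regression-method scores) for socio-economic covariates.

5. **Synthetic worlds.** A fully seeded generator of lattice geographies,
   spatially autocorrelated covariates, SARAR outcomes, and message
   corpora in which dialect-marked word use can be made to track a latent
   demographic factor — so the well-known failure mode of lexicon
   sentiment (ratings calibrated to the standard dialect while usage
   varies) can be reproduced and studied quantitatively.

## Worked example

Score a text against a two-word lexicon (ratings 6.80 and 2.76):

```r
library(sentitract)
lex <- lexicon(c(animals = 6.80, lost = 2.76))
score_text(tokenize("Animals lost... ANIMALS!"), lex)
#> <sentiment_score: h_avg = 5.4533 (3 matched tokens, coverage 100.0%)>
```

The value is the weighted mean (2·6.80 + 2.76)/3 = 5.4533. Decompose a
happiness difference between two corpora:

```r
word_shift(unit_corpus("tractA", c(animals = 3)),
           unit_corpus("ref", c(animals = 1, lost = 1)), lex)
#> <shift_report: h_comp = 6.8000, h_ref = 4.7800 (total shift +100)>
#>      word delta freq_direction sent_direction p_comp p_ref
#> 1 animals    50             up           plus      1   0.5
#> 2    lost    50           down          minus      0   0.5
```

Each word contributes +50: "animals" (positive, more frequent than the
reference) and "lost" (negative, less frequent) each push tractA up by
half of the total +100.

Now a full confounded study on synthetic data: an 8×8 lattice of tracts
where the outcome is driven by a spatially smooth disadvantage factor
(`x_smooth`, coefficient 1.5) and **not** by mood — but dialect-marked,
low-rated words are used more where `x_smooth` is high:

```r
sw <- synthetic_world(synthetic_config(
  rows = 8, cols = 8, messages_per_unit = 150,
  lambda_lag = 0.3, rho_err = 0.2, dialect_gradient = 1,
  beta = c(x_smooth = 1.5, x_noise = 0), seed = 42))

dir <- tempfile(); dir.create(dir)
write_lexicon(sw$lexicon, file.path(dir, "lexicon.tsv"))
write_messages(sw$corpus, file.path(dir, "messages.csv"))
write_geography(sw$geography, file.path(dir, "geography.geojson"))

cfg <- run_config(lexicon = file.path(dir, "lexicon.tsv"),
                  corpus = file.path(dir, "messages.csv"),
                  geography = file.path(dir, "geography.geojson"),
                  outcomes = "y", covariates = "x_smooth",
                  min_messages = 100, permutations = 199, seed = 7)
res <- run_pipeline(cfg, file.path(dir, "out"))

read.csv(file.path(dir, "out", "moran.csv"))
#>   outcome         I    expected p_perm permutations
#> 1       y 0.5116979 -0.01587302  0.005          199
```

The outcome is strongly spatially autocorrelated (I = 0.512, pseudo
p = 0.005). The three-model ladder for the sentiment coefficient:

```r
m <- read.csv(file.path(dir, "out", "models_y.csv"))
subset(m, term %in% c("h_avg", "lambda_lag", "rho_err"))
#>         model       term    estimate        se      z         p stars
#>      ols_base      h_avg -1.76452878 0.1590055 -11.10  1.29e-28   ***
#>    sarar_base      h_avg -1.28128916 0.1842812  -6.95  3.58e-12   ***
#>    sarar_base lambda_lag  0.52033025 0.1290197
#>    sarar_base    rho_err -0.10317123
#>    sarar_full      h_avg  0.02652787 0.3223304   0.08  9.34e-01
#>    sarar_full lambda_lag  0.33388611 0.1240849
#>    sarar_full    rho_err  0.21773054
```

Tract happiness looks like a strong "protective" predictor in the base OLS
(−1.76, p < 0.001), remains significant but attenuated once spatial
dependence is modelled (−1.28), and vanishes entirely (0.03, p = 0.93)
once the latent disadvantage factor enters the model — even though the
generating process gave mood no effect at all. The Clogg-style comparison
of the sentiment coefficient between the OLS and SARAR fits is written to
`comparisons.csv` (here z = −1.99, p = 0.047).

The same sequence is available from a shell via the thin wrapper
`inst/cli/sentitract.R` with subcommands `simulate`, `score`, `esda`,
`regress`, and `run`.

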