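---
title: "Methods: constructing and validating a composite anxiety-depression index from search trends"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constructing and validating a composite anxiety-depression index from search trends}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadindex)
```

## The problem

Survey-based measurement of population anxiety and depression is slow,
expensive, and sparse in time and space. Search engines log, daily and per
region, how intensely people look up emotion-laden words. The Composite
Anxiety and Depression Index (CADI) turns those logs into a region-by-year
surveillance index: it selects words empirically associated with the
targets "anxiety" and "depression", weights each word by how relevant and
how searched-for it is, normalizes each word's regional search intensity
against the cross-region range, and aggregates to a single number per
region and year on a fixed [100 − τ, 100] scale. Higher means worse
negative public mental health.

The package implements the full chain — dictionary construction, index
synthesis, survey validation, regression analysis — plus a synthetic-data
generator with a planted latent severity signal, so that every stage's
recovery behaviour is a testable property.

## Dictionary construction

`build_pod()` runs four stages, each exposed on its own:

1. **Corpus filter** (`filter_corpus`): documents with fewer than
   `min_chars = 15` characters are dropped (a document of exactly 15 is
   kept); an optional user predicate removes off-topic material (default:
   keep everything — there is no universal relevance rule, so it is a
   hook, not a policy).
2. **Vocabulary selection** (`select_vocabulary`): keep words occurring at
   least once as a noun or adjective, with surface length ≥
   `min_char_len = 2`, not in the stopword list, with total corpus
   frequency ≥ `min_frequency = 5`. The frequency cutoff operationalizes
   "retain high-frequency words"; 5 is a conventional floor below which
   embedding vectors are dominated by initialization noise.
3. **Embeddings** (`train_embeddings`): CBOW with negative sampling,
   implemented in compiled code with a dedicated xorshift RNG so training
   is bit-reproducible single-threaded. Defaults: `dim = 100`,
   `window = 5`, `epochs = 20`, `min_count = 2`, 5 negative samples,
   initial learning rate 0.025 with linear decay — the standard small-corpus
   word2vec regime; 20 epochs compensates for corpora of only a few
   thousand documents.
4. **Relevance scoring** (`compute_relevance`): the word's score is

   α(i) = clip₀¹( mean over targets t of cos(v_in(i), v_out(t)) ).

Tokenization is pluggable: the default tokenizer consumes
whitespace-delimited `surface/pos` tagged tokens (what the synthetic
corpus emits), and an adapter to any external segmenter/tagger producing
the same token schema (e.g. a Chinese segmenter for real text) can be
passed as `tokenizer =`.

### Why input–output similarity

A word-embedding model holds two matrices: input (word) vectors and output
(context) vectors. Cosine between two *input* vectors measures
second-order similarity — "these words occur in similar contexts" — and is
the right notion for synonym retrieval. Relevance to a target is a
different, first-order question: "does this word occur *with* the
target?". In negative-sampling training the input–output dot product
converges toward the pointwise mutual information of the pair, so
cos(v_in(word), v_out(target)) ranks words by direct association with the
target. On planted corpora the two notions disagree dramatically:
input–input cosine ranks background words *above* the planted co-occurring
words (they share the generic context distribution with everything else),
while input–output cosine separates planted from background cleanly — the
property the dictionary needs and the test suite asserts. The clip to
[0, 1] guarantees nonnegative downstream weights; how the two targets are
combined (arithmetic mean) is a genuine open choice, and the mean is used
because it treats anxiety- and depression-associated words symmetrically.

## Index synthesis

For word *i*, region *r*, year *y*:

- β(i, y): yearly mean of the national daily trend; γ(r, i, y): yearly
  mean of the regional daily trend (`yearly_average`,
  `aggregate_*_trends`). Missing days are simply absent from the mean.
- Weights: φ(i, y) = α(i)·β(i, y), w(i, y) = φ(i, y)/Σᵢφ(i, y), computed
  within each year (`compute_weights`). Weights are shares: nonnegative,
  summing to 1 per year. A year in which every word has φ = 0 is an error,
  not a silent renormalization.
- Population adjustment: γ̄ = γ/δ with δ(r, y) the region's population in
  persons (`population_adjust`) — per-person search intensity.
- Efficacy-coefficient scoring (`efficacy_score`, `compute_cadi`): within
  each (word, year), the cross-region envelope [min_r γ̄, max_r γ̄]
  (including the region being scored) maps linearly onto
  [100 − τ, 100]; the index is the w-weighted sum over words. As a convex
  combination of per-word scores it is confined to [100 − τ, 100], it is
  invariant to any per-(word, year) positive affine rescaling of γ̄ (units
  of the trend provider cancel), and it is monotone: raising one region's
  γ̄ within the envelope never lowers its index.
- Penetration adjustment (`penetration_adjust`):
  CADI~ = CADI · π(y)/π(y−1) with π the national Internet-penetration
  rate. The displayed recurrence uses only the adjacent-year ratio — it is
  applied exactly so, not compounded from a base year; the first year of
  the span has no predecessor and uses ratio 1. Consequently CADI~ may
  exceed 100 when penetration grows; only the raw CADI is bounded.

**τ** (default 40, must lie in (0, 100]) fixes the index floor at
100 − τ = 60: τ controls how much of the scale is allowed to respond to
regional variation.

### Numerical and degenerate-case choices

- **Degenerate words** (max = min across regions in a year): the
  normalized fraction is set to ½, scoring 100 − τ/2. The word stays in
  the weighted sum, conveying no regional information, rather than being
  dropped — dropping would silently renormalize the remaining weights and
  change the index of every region.
- Envelope membership is validated with a relative 1e-9 guard; values
  outside [lo, hi] are an error, not clipped silently.
- POD ordering ties break by frequency (descending) then word
  (lexicographic), making `build_pod` output total-order deterministic.
- Balanced-panel validation: a (word, year) cell missing for some region
  is an error ("unbalanced panel"), because min/max over an incomplete
  region set would silently change the envelope.

## Validation layer

`weighted_prevalence` computes Σ weight·disorder / Σ weight per region
(records with missing disorder status dropped listwise; prevalence is
invariant to rescaling a region's weights). `correlation_suite` reports
Pearson, Kendall τ-b (tie-corrected — ties are expected in prevalence
data), and Spearman coefficients. P-values are exact permutation
probabilities (all n! orderings enumerated) when n ≤ 9 — validation
typically pairs few regions, where asymptotics are untrustworthy — and the
usual asymptotic approximations otherwise. Zero-variance inputs make a
correlation undefined: it is reported as NA with a warning, never as 0.

## Association layer

`build_design` assembles intercept + the eight covariates (DI, CPI, CGR,
IE, ACP, RHE, RD, RU, on their supplied scales — no standardization, so
coefficients are raw-scale) + one indicator per calendar year except the
earliest (reference coding; a six-year panel yields five dummies; a
single-year panel is allowed and yields none). Rank-deficient designs are
rejected with the dependent columns named.

- `fit_lrm`: OLS via base `lm.fit`, conventional standard errors,
  two-sided t p-values, centered R².
- `fit_qrm`: minimizes the check loss Σ ρ_q(y − Xb) by iteratively
  reweighted least squares (weights (q·1[r>0] + (1−q)·1[r≤0])/max(|r|, ε),
  ε = 1e-9·scale), started at OLS, followed by an interpolation polish —
  the exact minimizer passes through p observations, so the p
  smallest-residual rows are refit exactly and kept if the loss does not
  worsen. Convergence is *verified*, not assumed: at exit, no ±1e-6
  coordinate perturbation may reduce the loss; otherwise the fit errors
  with diagnostics. With an intercept-only design the estimate is the
  sample q-quantile directly (q = 0.5, even n: midpoint of the central
  pair — the whole central interval minimizes the loss, and the midpoint
  is the symmetric representative). Standard errors: nonparametric
  bootstrap over rows (default 500 resamples, fixed seed) with
  normal-approximation p-values — the bootstrap is the one QRM
  standard-error method that needs no density estimation at the quantile.
- `split_by_gdp`: threshold = mean per-capita GDP over all region-year
  rows; each region assigned wholly by its own multi-year mean; ties (and
  exact equality) go to the high-GDP subgroup so the rule is a total
  function.
- `run_full_analysis` fits LRM and QRM on the overall panel and both
  subgroups and formats the six-column grid with stars (* p<0.05,
  ** p<0.01, *** p<0.001).

## The synthetic-data generator

`scenario_config()` fixes the study conditions; the defaults mirror the
method's intended scale: **31 regions, years 2016–2021** (186 region-year
rows), 10 dictionary words, 2000 corpus documents, noise standard
deviation 0.1, planted covariate effects IE = −1 (import–export index
lowers severity) and ACP = +1 (patient cost raises it), 200 survey
respondents per region, Internet penetration starting at 0.50 and growing
5% per year, and populations log-normal around 45 million persons — the
scale of Chinese provinces.

The generator plants one latent quantity, severity
s(r, y) = Σₖ effectₖ·xₖ(r, y) + N(0, noise_sd), and threads it through all
streams:

- **Corpus**: tagged pseudo-tokens (`surface/pos`), not natural language.
  Around half the documents contain a target word; context slots within
  two tokens of the target hold a planted word with probability
  `cooccur_excess = 0.8`, otherwise a uniform draw from the whole
  candidate pool — so at excess 0 planted and background words are
  exchangeable, and the excess alone creates the association the
  dictionary must find. Filler tokens (verbs, a one-character word,
  stopwords, a frequency-1 word) exist to exercise every filter; document
  lengths straddle the 15-character cutoff.
- **Trends**: per-capita intensity base(i) + λ·s(r, y)·relevance(i) +
  N(0, noise_sd), truncated at 0. The *emitted* regional trend scales this
  intensity by the region's relative population (search volume grows with
  the searching population); dividing by population downstream recovers
  the per-capita signal, which keeps the full pipeline monotone in s. The
  unscaled variant (`volume_scaling = "none"`) emits the intensity
  directly — with λ = 0 and no noise every region then shares an identical
  series. The national series is the population-weighted mean of the
  regional ones, keeping the two streams internally consistent. Trends are
  daily by default; `resolution = "yearly"` emits the yearly mean directly
  with noise scaled by 1/√days — statistically equivalent after yearly
  averaging, used where a simulation study needs hundreds of replicate
  panels.
- **Survey**: binary disorder indicator with probability
  logistic(−2 + 1.5·standardized s) in the year nearest 2020, log-normal
  positive weights.

What the generator does *not* emulate: natural-language text (so passing
dictionary tests show filter/embedding correctness, not segmenter
quality), real search-engine query dynamics (trends here are Gaussian
around a linear signal; real trends have seasonality, spikes, and platform
rescaling), epidemic-era shocks, and survey design features beyond one
weight column. Passing tests demonstrate that the machinery recovers a
signal constructed to be recoverable — they say nothing about how much
signal real search trends carry.

## Simulation sizes used by the checks

The test suite asserts, among others: exact index anchors (60/100 at
τ = 40 for all-minimum/all-maximum regions), weight normalization over
1000 randomized cases, equality with a naive triple-loop recomputation on
50 random balanced panels (≤ 1e-10), per-(word, year) affine invariance
(≤ 1e-9), within-year Spearman 1 between severity and index on the
noise-free default scenario and seed-averaged Spearman > 0.9 over 20 noisy
seeds at daily resolution, LRM recovery of both planted signs (p < 0.05)
in ≥ 95 of 100 panels with null rejection calibrated within [0.02, 0.09]
over 200 zero-effect panels (both at yearly trend resolution), and the
estimator identities. These sizes keep the default test run within a few
minutes while leaving the statistical assertions well-powered.

## Known limitations

- The CBOW trainer is single-threaded by design (reproducibility over
  speed); corpora beyond a few hundred thousand tokens will be slow.
- Relevance scores on small corpora are small in magnitude (cosines a few
  hundredths); they are meaningful as a ranking and as nonnegative weight
  inputs, not as calibrated probabilities.
- The index is only as comparable across years as the penetration series
  is accurate, and the adjacent-year ratio adjustment propagates any error
  in π multiplicatively.
- Exact permutation p-values are enumerated only up to n = 9 (9! ≈ 3.6e5
  orderings); between 10 and ~15 regions the asymptotic approximations are
  used and should be read with care.
- The regression layer is deliberately plain pooled OLS/QRM with year
  dummies — no fixed effects, spatial correlation, or causal claims.
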