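---
title: "Modeling lexical categorization in ventral occipito-temporal cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling lexical categorization in ventral occipito-temporal cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexcat)
```

## The model

Readers recognize written words with the help of a region in left
ventral occipito-temporal cortex (lvOT, containing the visual word form
area). Its activation profile is non-linear in the "word-likeness" of a
letter string: orthographically illegal strings and highly familiar
words both elicit little activation, while rare words and word-like
pseudowords elicit a lot. The lexical categorization model (LCM)
implemented here explains this profile as the *difficulty of deciding
whether a string is a word*, given only its word-likeness.

Word-likeness is operationalized by OLD20: the mean Levenshtein distance
from a string to its 20 nearest words in a reference lexicon (lower =
more word-like). From a set of labeled strings (words W, pseudowords PW,
consonant strings CS) the package estimates the conditional probability
$p(W \mid \mathrm{OLD20})$, and the per-item simulated activation is the
binary entropy of that probability:

$$E_i = -p_i\,\log_2 p_i \;-\; (1 - p_i)\,\log_2(1 - p_i),
\qquad p_i = p(W \mid \mathrm{OLD20}_i),$$

with $0 \log_2 0 := 0$. Entropy is 1 bit where word and non-word are
equally likely (maximal categorization difficulty) and 0 where the
word-likeness alone settles the decision. Scrambled-letter controls
(SL), which carry no orthographic content, are assigned activation 0 in
every model. Raw entropy in $[0, 1]$ bits is the canonical output;
rescaling for plots is cosmetic and never enters statistics.

```{r pipeline}
lex <- synth_lexicon(400, length = 5, seed = 1)
run <- lcm_pipeline(lex, seed = 1)
tapply(run$sim$activation, run$sim$category, median)
```

## Estimating the categorization curve

Two estimators are provided, and which one the smooth published curves
came from is not decidable from their description, so the transparent
one is the default:

* **`exact-bin`** (default): strings are grouped by OLD20 rounded to a
  bin width of 1/20 — the natural granularity of a 20-neighbor mean of
  integer distances — and $p(W \mid \text{bin})$ is word count over
  total count. This reproduces counting arithmetic exactly: a bin with
  137 strings of which 116 are words gives $p = .85$ (two decimals,
  rounded half away from zero, the convention used for all printed
  probabilities).
* **`kde`**: separate Gaussian kernel densities (Silverman's rule per
  class) for the word and non-word OLD20 samples, combined with
  empirical class priors, $p(W \mid x) = n_W f_W(x) / (n_W f_W(x) +
  n_{NW} f_{NW}(x))$. With the canonical balanced design this is a 1:2
  word:non-word prior, matching the counting logic.

Numerical conventions, chosen once and asserted in tests:

* Queries in empty OLD20 regions are linearly interpolated between the
  flanking occupied bins; queries beyond the support take the nearest
  occupied bin's value. (The empirical materials never query outside
  their range; new strings need a defined rule.)
* Ties at the 20th neighbor rank need no tie-break: any subset of
  equally distant words yields the same mean.
* Because OLD20 lives on a 1/20 grid, busy bins are probability *atoms*
  that a kernel necessarily spreads. On the canonical synthetic set the
  two estimators agree to about 0.05 on average in bins holding at
  least 50 strings, with pointwise differences up to about 0.08 at
  steep transitions, and they cross $p = 0.5$ at nearly the same
  word-likeness. The exact-bin estimator is authoritative for counts;
  the kde estimator is for smooth curves.
* A curve fitted on a single category is an error, not a degenerate
  curve; zero-variance simulations propagate `NA` correlations with a
  warning, never silent zeros.

## The synthetic lexicon

All development and testing runs on a synthetic Zipf-distributed lexicon
so that no proprietary frequency corpus is required. The generator
emulates the features of a natural five-letter noun inventory that the
model's behavior depends on:

* **Zipf frequencies**: rank-$r$ frequency $\propto r^{-a}$ (default
  $a = 1$), on a counts-per-million scale.
* **Consonant-vowel structure**: alternating CV template, uppercase
  initial, at least one vowel (so the pseudoword generator always has a
  substitution site). German vowel inventory AEIOUÄÖÜ by default.
* **Skewed letter use** (default `letter_model = "zipf-cv"`): within
  each letter class, letters are drawn with Zipf weights (exponent 2).
  This is the load-bearing choice. Letter frequencies in
  European-language corpora are strongly skewed, and that skew is what
  gives real lexica their dense orthographic neighborhoods: words
  concentrate on common letters and are therefore close to many other
  words, while a vowel-substituted pseudoword lands, on average, on a
  rarer vowel and moves away from the lexicon mass. With *uniform*
  letter draws (available as `"uniform-cv"`), words and their
  vowel-substituted pseudowords are statistically exchangeable and no
  word-likeness gradient can arise — useful as a null model, useless as
  an emulation. With the default skew, a 2,000-word lexicon yields
  OLD20 distributions with medians near 1.5 (W), 1.9 (PW) and 2.7 (CS),
  mirroring the shape of the empirical distributions (words focused
  between 1 and 2, consonant strings peaking near 3).

What the generator does **not** emulate: morphological families,
phonotactics beyond the CV template, real bigram statistics, and any
coupling between a word's frequency and its neighborhood density.
Passing tests on synthetic data therefore demonstrate that the
machinery reproduces the *qualitative* activation patterns under
realistic distributional shape, not the published effect sizes; those
require the original corpus.

Median simulated activation on the canonical synthetic set orders
PW > W > CS. A caveat worth knowing: entropy saturates near 1 over the
word/pseudoword overlap region, so with the binned estimator the W and
PW *medians* can tie exactly at some seeds (both medians land on the
same OLD20 atom) even though the means and the fitted contrasts
separate cleanly. The canonical test conditions are 2,000 words at seed
1.

## Stimulus construction

Pseudowords replace one or more vowels with other vowels so that the
result is not in the lexicon; consonant strings replace every vowel
with a consonant, preserving the consonant skeleton. For words with up
to four vowel positions the full substitution space is enumerated and an
admissible candidate drawn uniformly, so generation fails only when no
admissible pseudoword exists.

The hand-curated stimulus lists behind the published benchmarks were
manually screened for illegal letter combinations. The automated
stand-in is bigram attestation: every bigram of a pseudoword must occur
somewhere in the lexicon. Three modes are provided: strict
(`"bigram-attested"`, errors when unsatisfiable), best-effort
(`"bigram-preferred"`, falls back to any non-member substitution when no
candidate passes — the stimulus-set default, because category balance
requires one pseudoword per base word and small lexica attest few
bigrams), and `"none"`. Pseudohomophones cannot be generated without a
phonology and are accepted as an input list (category PH); scrambled
letters are category-only items with no string content.

## Competitor models

Four alternative accounts of lvOT activation are implemented from their
functional descriptions, each mapped to $[0, 1]$:

* **Serial lexicon search**: activation = frequency rank / lexicon
  size; non-words require exhaustive search (activation 1).
* **Combination detector (CD)**: linear in word-similarity, the negated
  min-max-normalized OLD20.
* **Engagement and effort (E&E)**: decreasing logistic gate in OLD20
  (engagement) times one minus normalized $\log_2(1 + \text{frequency})$
  (effort; non-words have effort 1).
* **Interactive account (IA)**: formally the gate-times-surprise
  product of the same two ingredients, interpreted as prediction
  eligibility times prediction error. Under this single-knob
  parameterization E&E and IA share their functional form; they are
  kept as separately named models with independent parameter blocks so
  that more detailed forms can be dropped in later.

The logistic midpoint defaults to the word/non-word crossover of the
fitted categorization curve ([curve_crossover()]) and the slope to 4
per OLD20 unit, which saturates the gate within roughly one distance
unit. These are transparent defaults chosen to produce each model's
qualitative signature — the published comparisons score effect
*directions*, not magnitudes, and the original parameter choices for
the competitor implementations are not available. With slope 0 the IA
gate is constant and the model degenerates to the lexicon model's
frequency ordering over words (a tested limit).

## Benchmarks, scoring, and model comparison

`contrast_registry()` encodes the nine published lvOT contrasts:
PW > W; W > CS; their conjunction (scored as the conjunction of the two
pairwise results but counted once); PH > W; PH = PW (a null effect);
matched PW > matched W; the word-similarity gradient
(lWS < iWS < hWS = W); a negative log-frequency slope over W and PW
(PW frequency fixed at 0; logs are $\log_2(1 + x)$, with the frequency
column read as counts per million); and a positive log-bigram-frequency
slope with a quadratic refit reported for the documented non-linearity.
Categorical contrasts are two-group linear models on items (items are
treated as independent observations; no item random effects), slopes are
ordinary least squares, and p-values are Bonferroni-corrected over the
family of nine. Equality contrasts count as correct when the adjusted p
is at least .05 — the pragmatic non-significance criterion used for the
published null effects; an equivalence-test alternative was considered
and rejected as a default because the reference analyses used
non-significance. Missing conditions produce `skipped` verdicts with
warnings, never silent passes.

Matched and similarity conditions are built by greedy nearest-neighbor
matching without replacement on standardized covariates (Coltheart's N
and bigram frequencies for the matched word/pseudoword contrast, 108
pairs by default; quadrigram frequency for high-similarity non-words,
bigram frequency for intermediate, leftover consonant strings as low).
Greedy matching is order-dependent and not globally optimal, which is
acceptable here because the contrasts compare group means, not pairs.

`compare_to_observed()` implements the quantitative comparison with
region-of-interest data: simulations are z-scored across items, observed
percent-signal-change tables across all participant-by-condition cells
(pooled; per-participant scaling is a flag, pooled is the default
reading of "within each dataset"), and each contrast's deviation is
$|\Delta_{\text{sim}} - \Delta_{\text{obs}}| / SD_{\text{obs}}$ where
$SD_{\text{obs}}$ is the standard deviation of the participant-level
observed difference scores — the participant distribution, not the
pooled cell SD, because the reference visualization draws its ±1 SD
band from the observed differences. The z-transforms make the metric
invariant to affine rescaling of raw simulations (tested).

## Robustness analyses

* `subset_stability()`: stratified random subsets (category proportions
  preserved), curve refitted per subset, subset-based entropy
  correlated with the full-set entropy over all items; 20 draws per
  proportion by default, one top-level seed, draw counts reported. The
  full-set proportion returns r = 1 bit-exactly.
* `lexicon_size_sweep()`: the reference lexicon truncated to its most
  frequent 100, 1,000, 10,000, ... entries; OLD20, curve, and simulation
  recomputed per size; sizes below 21 words cannot support a 20-neighbor
  distance and are skipped with a warning. On synthetic data the
  category medians are indistinguishable for tiny lexica and the
  canonical ordering emerges with size, mirroring the published
  vocabulary-growth pattern.

## Problem sizes

The test suite and examples run entirely on synthetic lexica: 2,000
words (seed 1) for the canonical qualitative pattern and subset
stability, 800 words (seed 5) for the benchmark and model-comparison
machinery, smaller lexica for unit cases. These sizes were chosen as the
smallest at which the distributional shapes and contrast significances
are stable across refits; the full published analysis used 3,110
five-letter uppercase words drawn from a 193,236-word corpus, which the
package will reproduce when pointed at such a corpus export with
`load_lexicon()`.

## Limitations

The package models per-item scalar activations: no trial dynamics, no
hemodynamic convolution, no decision or response-time model, and no
whole-brain analysis — observed ROI tables are consumed, never estimated
from images. OLD20 values are reproducible against a given corpus, but
published OLD20 anchors depend on the exact reference set and distance
variant (plain Levenshtein is the default here, matching the reference
implementation the original analysis used; the
adjacent-transposition variant is a flag and is documented as
non-metric). Pseudohomophone generation and grapheme-to-phoneme
modeling are out of scope.
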