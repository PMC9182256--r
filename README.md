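# lexcat

Computational modeling of left ventral occipito-temporal cortex (lvOT)
activation during visual word recognition.

A region of lvOT — in and around the visual word form area — responds
non-linearly to letter strings: rare words and word-like pseudowords
drive it hard, while familiar words and orthographically illegal
consonant strings leave it comparatively quiet. `lexcat` implements the
**lexical categorization model (LCM)** of this profile: lvOT is taken to
decide *word or not a word* from the string's orthographic
word-likeness, and its activation reflects how difficult that decision
is.

Word-likeness is measured by **OLD20** — the mean Levenshtein distance
from a string to its 20 nearest words in a reference lexicon. From
labeled strings (words **W**, pseudowords **PW**, consonant strings
**CS**) the package estimates `p(W | OLD20)` and simulates per-item
activation as the binary entropy

```
E_i = −p_i · log2(p_i) − (1 − p_i) · log2(1 − p_i),   p_i = p(W | OLD20_i)
```

1 bit where word and non-word are equally likely, 0 where word-likeness
alone settles the categorization.

The package covers the full modeling workflow:

- **Lexicon handling** — read SUBTLEX-style tab-separated frequency
  lists, filter by length/initial case, truncate by frequency, or
  generate a seeded synthetic Zipf lexicon so nothing requires a corpus
  download (`load_lexicon`, `filter_lexicon`, `truncate_by_frequency`,
  `synth_lexicon`).
- **Word-likeness metrics** — OLD20, Coltheart's N, positional n-gram
  frequencies (`old20`, `coltheart_n`, `ngram_score`, `build_table`).
- **Stimulus generation** — pseudowords by vowel substitution, consonant
  strings, balanced W/PW/CS sets, covariate matching
  (`make_pseudoword`, `make_consonant_string`, `build_stimulus_set`,
  `match_groups`).
- **The LCM proper** — categorization curve (exact counting bins or
  kernel densities), entropy, per-item simulation (`fit_curve`,
  `binary_entropy`, `simulate_lcm`).
- **Competitor models** — serial lexicon search, combination detector,
  engagement-and-effort, interactive account (`simulate_*_model`).
- **Evaluation** — the nine-contrast benchmark registry with qualitative
  scoring, simulated-vs-observed ROI comparison in observed-SD units,
  model correlation matrices, subset stability, lexicon-size sweeps
  (`run_benchmark_contrasts`, `score_models`, `compare_to_observed`,
  `subset_stability`, `lexicon_size_sweep`).

## Worked example

```r
library(lexcat)

lex <- synth_lexicon(2000, length = 5, seed = 1)   # Zipf lexicon, CV words
run <- lcm_pipeline(lex, seed = 1, n_sl = 10)      # stimuli, OLD20, curve, sim

round(tapply(run$sim$activation, run$sim$category, median), 3)
#>    CS    PW    SL     W
#> 0.125 0.831 0.000 0.780
```

Median simulated activation orders pseudowords above words above
consonant strings — the canonical published lvOT pattern — and the
scrambled-letter controls (SL) sit at exactly 0. The benchmark contrasts
confirm it inferentially (Bonferroni-adjusted p over the family of
nine):

```r
res <- run_benchmark_contrasts(run$sim, run$table)
res[res$id %in% c("pw_gt_w", "w_gt_cs", "freq_slope"),
    c("id", "estimate", "p_adj", "verdict")]
#>           id    estimate        p_adj verdict
#> 1    pw_gt_w  0.05872465 6.963542e-08 correct
#> 2    w_gt_cs  0.48550311 0.000000e+00 correct
#> 8 freq_slope -0.01342052 3.146782e-23 correct
```

`pw_gt_w`: pseudowords elicit significantly more simulated activation
than words; `w_gt_cs`: words more than consonant strings; `freq_slope`:
activation falls with log2 word frequency over words and pseudowords
(pseudoword frequency fixed at 0). Querying the fitted curve directly:

```r
p <- word_probability(run$curve, 1.5)   # p(word | OLD20 = 1.5)
binary_entropy(p)                       # categorization difficulty, bits
```

A command-line wrapper mirrors this flow
(`exec/lexcat lexicon synth | stimuli | metrics | simulate`).

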