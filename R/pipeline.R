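#' Run the full lexical-categorization pipeline on a lexicon
#'
#' Convenience wrapper chaining the canonical stages: build the balanced
#' word/pseudoword/consonant-string stimulus set, compute word-likeness
#' against the lexicon, fit the categorization curve, and simulate
#' per-item activation under the lexical categorization model.
#'
#' @param lex A [lexicon()] of base words.
#' @param seed Seed for stimulus construction.
#' @param measures Word-likeness measures for the table (the benchmark
#'   contrasts additionally need bigram and quadrigram columns).
#' @param estimator,bin_width Curve settings, see [fit_curve()].
#' @param n_sl Scrambled-letters control items to append.
#' @return List with `items`, `table`, `curve`, and `sim`.
#' @examples
#' run <- lcm_pipeline(synth_lexicon(60, 5, seed = 3), seed = 3)
#' tapply(run$sim$activation, run$sim$category, median)
#' @export
lcm_pipeline <- function(lex, seed = 1L,
                         measures = c("old20", "coltheart_n", "bigram"),
                         estimator = "exact-bin", bin_width = 0.05,
                         n_sl = 0L) {
  items <- build_stimulus_set(lex, seed = seed, n_sl = n_sl)
  table <- build_table(items, lex, measures = measures)
  curve <- fit_curve(table, estimator = estimator, bin_width = bin_width)
  sim <- simulate_lcm(curve, items, table)
  list(items = items, table = table, curve = curve, sim = sim)
}
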