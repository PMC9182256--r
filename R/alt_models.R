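#' Parameters for the sigmoid competitor models
#'
#' The engagement-and-effort and interactive-account models share a
#' single-knob parameterization: a decreasing logistic in word-likeness
#' (distance units) gates how strongly a string engages the word
#' recognition system (or how eligible it is for top-down prediction),
#' and a normalized log2 frequency term captures processing effort (or
#' surprise). Midpoints default to the word/non-word crossover of a
#' fitted categorization curve; the slope default of 4 per OLD20 unit
#' makes the gate saturate within roughly one distance unit.
#'
#' @param midpoint Word-likeness at which the logistic gate is 0.5.
#' @param slope Positive logistic slope (per word-likeness unit).
#' @param log_base Base of the frequency log-transform (default 2).
#' @return A list of class `alt_model_params`.
#' @export
alt_model_params <- function(midpoint, slope = 4, log_base = 2) {
  stopifnot(is.numeric(midpoint), length(midpoint) == 1,
            is.numeric(slope), slope >= 0, log_base > 1)
  structure(list(midpoint = midpoint, slope = slope, log_base = log_base),
            class = "alt_model_params")
}

# Decreasing logistic gate in word-likeness.
.gate <- function(wl, params) {
  1 / (1 + exp(params$slope * (wl - params$midpoint)))
}

# 1 - min-max normalized log frequency: 0 for the most frequent string in
# the set, 1 for anything at frequency zero (all non-words).
.effort <- function(freq, log_base = 2) {
  lf <- log(1 + freq, base = log_base)
  if (max(lf) == 0) return(rep(1, length(lf)))
  1 - lf / max(lf)
}

# Frequencies aligned to items: lexicon frequency for member words, zero
# otherwise (non-words never carry frequency).
.item_frequency <- function(items, lexicon) {
  idx <- match(items$string, lexicon$word)
  f <- ifelse(is.na(idx), 0, lexicon$frequency[idx])
  f[items$category != "W"] <- 0
  f
}

#' Simulate the serial lexicon-search model
#'
#' A word-frequency-ordered serial search through the whole-word lexicon:
#' frequent words are found early (low activation), rare words late, and
#' non-words require an exhaustive search, giving the maximal activation
#' of 1. Activation for words is the frequency rank normalized by the
#' lexicon-search depth, so it decreases strictly with frequency over
#' untied words. Scrambled-letters controls are 0.
#'
#' @param items A [stimulus_set()].
#' @param lexicon The [lexicon()] searched.
#' @return A `lexcat_sim` with model label `"lexicon"`.
#' @export
simulate_lexicon_model <- function(items, lexicon) {
  n <- nrow(lexicon)
  depth <- rank(-lexicon$frequency, ties.method = "first")  # 1 = most frequent
  idx <- match(items$string, lexicon$word)
  act <- ifelse(is.na(idx), 1, depth[idx] / n)
  act[items$category != "W"] <- 1
  act[items$category == "SL"] <- 0
  new_simulation(items, wordlikeness = rep(NA_real_, nrow(items)),
                 activation = act, model = "lexicon",
                 provenance = list(lexicon = attr(lexicon, "name")))
}

#' Simulate the combination-detector model
#'
#' A linear overlap account: activation increases with a string's
#' similarity to stored orthographic representations. Similarity defaults
#' to negated, min-max-normalized word-likeness distance, so the most
#' word-like item in the set gets activation 1 and the least word-like 0.
#' Scrambled-letters controls are 0.
#'
#' @param items A [stimulus_set()].
#' @param table Word-likeness table covering every non-SL item.
#' @param measure Word-likeness (distance) column name.
#' @return A `lexcat_sim` with model label `"CD"`.
#' @export
simulate_cd_model <- function(items, table, measure = "old20") {
  wl <- .item_wordlikeness(items, table, measure)
  live <- items$category != "SL"
  if (length(unique(wl[live])) < 2) {
    stop("word-likeness column is constant: the combination-detector model has no contrast",
         call. = FALSE)
  }
  act <- numeric(nrow(items))
  act[live] <- 1 - min_max(wl[live])
  new_simulation(items, wl, act, model = "CD",
                 provenance = list(measure = measure))
}

#' Simulate the engagement-and-effort model
#'
#' Activation is the product of engagement — a decreasing logistic in
#' word-likeness distance, reflecting that orthographically illegal
#' strings barely engage the word recognition system — and effort, one
#' minus normalized log frequency, reflecting that rarely encountered
#' strings are costly to process (non-words have maximal effort 1).
#'
#' @inheritParams simulate_cd_model
#' @param lexicon Lexicon supplying word frequencies.
#' @param params An [alt_model_params()]; `NULL` uses the crossover of
#'   `curve` (required in that case) with slope 4.
#' @param curve Optional fitted `lcm_curve` used only to derive the
#'   default midpoint.
#' @return A `lexcat_sim` with model label `"EE"`.
#' @export
simulate_ee_model <- function(items, table, lexicon, params = NULL,
                              curve = NULL, measure = "old20") {
  .simulate_gate_model(items, table, lexicon, params, curve, measure, "EE")
}

#' Simulate the interactive-account model
#'
#' A predictive-coding account: activation is prediction error. The
#' eligibility gate (decreasing logistic in word-likeness distance)
#' captures that few top-down predictions form for consonant strings, so
#' their error is low; surprise (one minus normalized log frequency)
#' captures that frequent words are well predicted while rare words and
#' pseudowords violate predictions. Under this parameterization the
#' interactive account shares its functional form with the
#' engagement-and-effort model and differs in interpretation; it is kept
#' as a separately named model with its own parameter block.
#'
#' @inheritParams simulate_ee_model
#' @return A `lexcat_sim` with model label `"IA"`.
#' @export
simulate_ia_model <- function(items, table, lexicon, params = NULL,
                              curve = NULL, measure = "old20") {
  .simulate_gate_model(items, table, lexicon, params, curve, measure, "IA")
}

.simulate_gate_model <- function(items, table, lexicon, params, curve,
                                 measure, model) {
  if (is.null(params)) {
    if (is.null(curve)) {
      stop("provide either `params` or a fitted `curve` for the default midpoint",
           call. = FALSE)
    }
    params <- alt_model_params(midpoint = curve_crossover(curve))
  }
  stopifnot(inherits(params, "alt_model_params"))
  wl <- .item_wordlikeness(items, table, measure)
  freq <- .item_frequency(items, lexicon)
  live <- items$category != "SL"
  act <- numeric(nrow(items))
  act[live] <- .gate(wl[live], params) * .effort(freq[live], params$log_base)
  new_simulation(items, wl, act, model = model,
                 provenance = list(midpoint = params$midpoint,
                                   slope = params$slope, measure = measure))
}
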