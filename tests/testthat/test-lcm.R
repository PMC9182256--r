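# Helper: a minimal table with specified word-likeness values per category.
manual_table <- function(wl, category) {
  out <- data.frame(string = sprintf("s%03d", seq_along(wl)),
                    category = category, frequency = 0, old20 = wl,
                    stringsAsFactors = FALSE)
  class(out) <- c("lexcat_table", "data.frame")
  out
}

test_that("binary entropy matches its closed form and conventions", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.85), 0.609840, tolerance = 1e-6)
  expect_equal(binary_entropy(0.85), oracle_entropy(0.85), tolerance = 1e-12)
  expect_error(binary_entropy(1.01), "\\[0, 1\\]")
  expect_error(binary_entropy(-0.1), "\\[0, 1\\]")
  # symmetry on a fine grid
  p <- seq(0, 1, length.out = 1001)
  expect_equal(binary_entropy(p), binary_entropy(1 - p), tolerance = 1e-12)
  # strictly increasing up to 1/2, strictly decreasing after
  lo <- binary_entropy(seq(0, 0.5, length.out = 501))
  hi <- binary_entropy(seq(0.5, 1, length.out = 501))
  expect_true(all(diff(lo) > 0))
  expect_true(all(diff(hi) < 0))
})

test_that("exact-bin fit reproduces the worked counting example", {
  # one bin with 137 strings, 116 of them words
  tab <- manual_table(rep(1.5, 137), c(rep("W", 116), rep("PW", 21)))
  curve <- fit_curve(tab, estimator = "exact-bin")
  p <- word_probability(curve, 1.5)
  expect_equal(round(p, 2), 0.85)
  expect_equal(round(1 - p, 2), 0.15)
  expect_equal(p, 116 / 137, tolerance = 1e-12)
  # the hand count is stored alongside
  expect_equal(curve$counts$n_word, 116)
  expect_equal(curve$counts$n_total, 137)
})

test_that("fit_curve enforces two categories and handles degenerate input", {
  all_w <- manual_table(c(1, 1.5, 2), rep("W", 3))
  expect_error(fit_curve(all_w), "both word and non-word")
  # adding a single non-word row: pure-word bins give entropy 0
  tab <- manual_table(c(1, 1, 2), c("W", "W", "PW"))
  curve <- fit_curve(tab)
  expect_equal(word_probability(curve, 1), 1)
  expect_equal(binary_entropy(word_probability(curve, 1)), 0)
})

test_that("curve invariants hold on fitted synthetic data", {
  run <- canonical_run()
  for (est in c("exact-bin", "kde")) {
    curve <- fit_curve(run$table, estimator = est)
    expect_true(all(abs(curve$p_word + curve$p_nonword - 1) < 1e-12))
    expect_true(all(curve$entropy >= 0 & curve$entropy <= 1))
    pure <- curve$p_word %in% c(0, 1)
    expect_true(all(curve$entropy[pure] == 0))
  }
})

test_that("exact-bin and kde agree in well-populated bins", {
  run <- canonical_run()
  bin <- fit_curve(run$table, estimator = "exact-bin")
  kde <- fit_curve(run$table, estimator = "kde")
  busy <- bin$counts$n_total >= 50
  expect_gt(sum(busy), 3)  # the synthetic set populates several busy bins
  p_bin <- bin$p_word[busy]
  p_kde <- word_probability(kde, bin$support[busy])
  # OLD20 values sit on a 1/20 grid, so busy bins are atoms that the
  # kernel spreads; pointwise disagreement can reach ~0.08 at steep
  # transitions while the curves tell the same story on average
  expect_lt(mean(abs(p_bin - p_kde)), 0.05)
  expect_lt(max(abs(p_bin - p_kde)), 0.10)
  # the two estimators cross p = 0.5 at nearly the same word-likeness
  expect_lt(abs(curve_crossover(bin) - curve_crossover(kde)), 0.1)
})

test_that("kde posterior is one half where class densities coincide", {
  # identical samples shifted to coincide: equal densities force p = 0.5
  x <- rep(seq(1, 2, by = 0.1), times = 3)
  tab <- manual_table(c(x, x), c(rep("W", length(x)), rep("PW", length(x))))
  curve <- fit_curve(tab, estimator = "kde", bandwidth = 0.2)
  expect_equal(word_probability(curve, c(1.2, 1.5, 1.9)), rep(0.5, 3),
               tolerance = 1e-9)
})

test_that("word_probability interpolates empty regions and clamps extremes", {
  tab <- manual_table(c(rep(1, 4), rep(2, 4)),
                      c(rep("W", 4), rep("PW", 4)))
  curve <- fit_curve(tab)  # occupied bins at 1.0 (p=1) and 2.0 (p=0)
  expect_equal(word_probability(curve, 1.5), 0.5)
  expect_equal(word_probability(curve, 1.25), 0.75)
  # beyond the support: nearest occupied bin
  expect_equal(word_probability(curve, 0.2), 1)
  expect_equal(word_probability(curve, 3.7), 0)
  expect_error(word_probability(list(), 1), "fitted")
})

test_that("simulate_lcm composes probability and entropy, fixing SL at zero", {
  tab <- manual_table(rep(1.5, 137), c(rep("W", 116), rep("PW", 21)))
  curve <- fit_curve(tab)
  items <- stimulus_set(c(tab$string[1], tab$string[120], NA),
                        c("W", "PW", "SL"))
  sim <- simulate_lcm(curve, items, tab)
  # composition of the two oracles: entropy of the exact bin probability
  expect_equal(sim$activation[1], oracle_entropy(116 / 137), tolerance = 1e-12)
  # at the printed two-decimal probability the entropy is 0.609840
  expect_equal(binary_entropy(0.85), 0.609840, tolerance = 1e-6)
  expect_identical(sim$activation[3], 0)
  # a missing table row is a named error
  orphan <- stimulus_set("Zzzzz", "W")
  expect_error(simulate_lcm(curve, orphan, tab), "Zzzzz")
})

test_that("curve JSON round-trip preserves predictions", {
  run <- canonical_run()
  f <- withr::local_tempfile(fileext = ".json")
  for (est in c("exact-bin", "kde")) {
    curve <- fit_curve(run$table, estimator = est)
    curve_to_json(curve, f)
    back <- curve_from_json(f)
    x <- seq(0.8, 4, by = 0.1)
    expect_equal(word_probability(back, x), word_probability(curve, x),
                 tolerance = 1e-9)
    expect_equal(back$estimator, curve$estimator)
  }
})

test_that("the canonical synthetic set shows the empirical activation pattern", {
  run <- canonical_run()
  med <- tapply(run$sim$activation, run$sim$category, median)
  expect_gt(med[["PW"]], med[["W"]])
  expect_gt(med[["W"]], med[["CS"]])
  expect_true(all(run$sim$activation[run$sim$category == "SL"] == 0))
  # word-frequency slope over words and pseudowords is negative
  rows <- run$table$category %in% c("W", "PW")
  fit <- stats::lm(run$sim$activation[rows] ~ log2(1 + run$table$frequency[rows]))
  expect_lt(coef(fit)[2], 0)
})
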