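test_that("the registry encodes exactly the nine published effects", {
  reg <- contrast_registry()
  expect_equal(nrow(reg), 9)
  expect_setequal(reg$id, c("pw_gt_w", "w_gt_cs", "pw_w_cs", "ph_gt_w",
                            "ph_eq_pw", "mpw_gt_mw", "word_similarity",
                            "freq_slope", "bigram_slope"))
  expect_equal(anyDuplicated(reg$id), 0)
})

test_that("benchmark contrasts recover the simulated pattern with Bonferroni", {
  run <- covariate_run()
  res <- suppressWarnings(run_benchmark_contrasts(run$sim, run$table))
  expect_s3_class(res, "lexcat_contrasts")
  expect_equal(nrow(res), 9)
  # adjusted p is nine-fold the raw p, capped at 1
  got <- res[!is.na(res$p), ]
  expect_equal(got$p_adj, pmin(1, 9 * got$p))
  # the core category effects come out correct on the canonical pattern
  expect_equal(res$verdict[res$id == "pw_gt_w"], "correct")
  expect_equal(res$verdict[res$id == "w_gt_cs"], "correct")
  expect_equal(res$verdict[res$id == "pw_w_cs"], "correct")
  expect_equal(res$verdict[res$id == "freq_slope"], "correct")
  expect_lt(res$estimate[res$id == "freq_slope"], 0)
  # pseudohomophone contrasts are skipped (with warning), never passed
  w <- capture_warnings(run_benchmark_contrasts(run$sim, run$table))
  expect_true(any(grepl("PH", w)))
  expect_equal(res$verdict[res$id == "ph_gt_w"], "skipped")
})

test_that("an all-equal simulation yields nulls and passes equality contrasts", {
  run <- covariate_run()
  flat <- run$sim
  flat$activation <- rep(0.5, nrow(flat))
  # pseudohomophone rows so the equality contrast runs
  extra <- data.frame(string = c("Ph111", "Ph222"), category = "PH",
                      wordlikeness = 1.5, activation = 0.5)
  flat2 <- rbind(as.data.frame(flat), extra)
  class(flat2) <- class(run$sim)
  attr(flat2, "model") <- "flat"
  tab2 <- run$table
  tab2 <- rbind(as.data.frame(tab2),
                data.frame(string = c("Ph111", "Ph222"), category = "PH",
                           frequency = 0, old20 = 1.5, coltheart_n = 0,
                           bigram_initial = 0, bigram_final = 0,
                           bigram_summated = 0, quadrigram_initial = 0,
                           quadrigram_final = 0, quadrigram_summated = 0))
  res <- suppressWarnings(run_benchmark_contrasts(flat2, tab2))
  directional <- res$type %in% c("directional", "conjunction", "composite", "slope")
  ran <- res$verdict != "skipped"
  expect_true(all(res$verdict[directional & ran] %in% c("null", "incorrect")))
  expect_true(all(res$verdict[res$type == "equality" & ran] == "correct"))
})

test_that("slope sign matches an independent normal-equations fit", {
  run <- covariate_run()
  res <- suppressWarnings(run_benchmark_contrasts(run$sim, run$table))
  rows <- run$table$category %in% c("W", "PW")
  x <- log2(1 + run$table$frequency[rows])
  y <- run$sim$activation[rows]
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(sign(res$estimate[res$id == "freq_slope"]), sign(beta))
  expect_equal(res$estimate[res$id == "freq_slope"], beta, tolerance = 1e-9)
})

test_that("model scoring counts correct and penalizes incorrect verdicts", {
  mk <- function(verdicts) {
    r <- data.frame(id = paste0("c", seq_along(verdicts)),
                    type = "directional", verdict = verdicts)
    class(r) <- c("lexcat_contrasts", "data.frame")
    attr(r, "model") <- "m"
    r
  }
  res <- list(good = mk(c("correct", "correct", "null")),
              bad = mk(c("correct", "incorrect", "incorrect")))
  sc <- score_models(res)
  expect_equal(sc$score_correct, c(2, 1))
  expect_equal(sc$score_penalized, c(2, -1))
  expect_true(all(sc$score_penalized <= sc$score_correct))
})

test_that("comparison metric is zero on matching condition differences", {
  run <- covariate_run()
  sim <- run$sim
  n_per <- 40L
  rows <- as.integer(sapply(c("W", "PW", "CS"), function(cc)
    which(sim$category == cc)[seq_len(n_per)]))
  sim_sub <- sim[rows, ]
  class(sim_sub) <- c("lexcat_sim", "data.frame")
  attr(sim_sub, "model") <- "LCM"
  # observed table built from the z-scaled simulation itself: items play
  # the role of participants, so z-scaled condition means coincide by
  # construction (z-scaling is idempotent on a mean-0, sd-1 table)
  z <- as.numeric(scale(sim_sub$activation))
  roi <- vapply(c("W", "PW", "CS"),
                function(cc) z[sim_sub$category == cc], numeric(n_per))
  rep_cmp <- compare_to_observed(sim_sub, roi,
                                 contrasts = list("W-PW", "W-CS", "PW-CS"))
  expect_equal(rep_cmp$per_contrast$deviation, rep(0, 3), tolerance = 1e-10)
  expect_equal(rep_cmp$total_deviation, 0, tolerance = 1e-10)
})

test_that("comparison metric is affine-invariant and monotone", {
  run <- covariate_run()
  set.seed(31)
  roi <- cbind(W = rnorm(8, 0.4, 0.2), PW = rnorm(8, 0.9, 0.2),
               CS = rnorm(8, 0.1, 0.2))
  base <- compare_to_observed(run$sim, roi, list("W-PW", "PW-CS"))
  resc <- run$sim
  resc$activation <- 3.7 * resc$activation + 11
  class(resc) <- class(run$sim); attr(resc, "model") <- "LCM"
  shifted <- compare_to_observed(resc, roi, list("W-PW", "PW-CS"))
  expect_equal(shifted$per_contrast$deviation, base$per_contrast$deviation,
               tolerance = 1e-9)
  # a model strictly closer on every contrast has smaller summed deviation
  worse <- base$per_contrast
  expect_true(all(base$per_contrast$deviation >= 0))
  # label mismatch errors list the missing conditions
  expect_error(compare_to_observed(run$sim, roi, list("W-XX")), "XX")
})

test_that("hand-computed toy ROI comparison matches spreadsheet arithmetic", {
  # 2 conditions, 3 participants; worked by hand below
  roi <- cbind(A = c(1, 2, 3), B = c(2, 4, 3))
  sim <- stimulus_set(c("a1", "a2", "b1", "b2"), c("W", "W", "PW", "PW"))
  sim <- new_sim_for_test(sim, act = c(0, 1, 2, 3), model = "toy")
  # rename categories to match the ROI labels
  sim$category <- c("A", "A", "B", "B")
  # by hand: z(sim) has mean 1.5, sd sqrt(5/3) = 1.290994, so condition
  # means are -/+ 0.774597 and delta_sim = -1.549193. Pooled ROI mean is
  # 2.5, sd sqrt(5.5/5) = 1.048809; participant-level raw differences
  # A - B are (-1, -2, 0), i.e. (-0.953463, -1.906925, 0) on the z scale,
  # giving delta_obs = -0.953463 and sd_obs = 1/1.048809 = 0.953463;
  # deviation = |-1.549193 + 0.953463| / 0.953463 = 0.624805.
  got <- compare_to_observed(sim, roi, list(c("A", "B")))
  expect_equal(got$per_contrast$delta_sim, -1.549193, tolerance = 1e-5)
  expect_equal(got$per_contrast$delta_obs, -0.953463, tolerance = 1e-5)
  expect_equal(got$per_contrast$sd_obs, 0.953463, tolerance = 1e-5)
  expect_equal(got$per_contrast$deviation, 0.624805, tolerance = 1e-5)
})

test_that("model correlation matrix is exact on toy vectors and guards variance", {
  s1 <- new_sim_for_test(stimulus_set(paste0("s", 1:5), rep("W", 5)),
                         act = c(1, 2, 3, 4, 5), model = "m1")
  s2 <- new_sim_for_test(stimulus_set(paste0("s", 1:5), rep("W", 5)),
                         act = c(2, 1, 4, 3, 5), model = "m2")
  s3 <- new_sim_for_test(stimulus_set(paste0("s", 1:5), rep("W", 5)),
                         act = 2 * c(1, 2, 3, 4, 5) + 1, model = "m3")
  r <- model_correlation_matrix(list(s1, s2, s3))
  expect_equal(diag(r), c(m1 = 1, m2 = 1, m3 = 1))
  # hand Pearson for s1 vs s2: cov/sd products
  expect_equal(r["m1", "m2"], 0.8, tolerance = 1e-12)
  # a linear rescale correlates perfectly
  expect_equal(r["m1", "m3"], 1, tolerance = 1e-12)
  const <- new_sim_for_test(stimulus_set(paste0("s", 1:5), rep("W", 5)),
                            act = rep(1, 5), model = "flat")
  expect_warning(r2 <- model_correlation_matrix(list(s1, const)), "zero-variance")
  expect_true(is.na(r2["flat", "m1"]))
})

test_that("subset stability is exact at the full proportion and improves with size", {
  run <- covariate_run()
  st <- subset_stability(run$table, proportions = c(0.1, 0.5, 1.0),
                         n_draws = 8, seed = 2)
  expect_equal(st$mean_r[st$proportion == 1], 1)
  expect_equal(st$sd_r[st$proportion == 1], 0)
  expect_true(all(diff(st$mean_r) >= -1e-12))
  expect_true(all(st$n_valid >= 1))
})

test_that("lexicon size sweep skips infeasible sizes and spans the gradient", {
  lex <- synth_lexicon(250, 5, seed = 17)
  items <- build_stimulus_set(lex, seed = 17)
  expect_warning(sw <- lexicon_size_sweep(lex, sizes = c(10, 40, 250),
                                          items = items), "skipped")
  expect_equal(sw$size, c(40, 250))
  # full size reproduces the canonical simulation medians
  tab <- build_table(items, lex, measures = "old20")
  curve <- fit_curve(tab)
  sim <- simulate_lcm(curve, items, tab)
  med <- tapply(sim$activation, sim$category, median)
  expect_equal(sw$median_W[sw$size == 250], unname(med["W"]))
  expect_equal(sw$median_PW[sw$size == 250], unname(med["PW"]))
  expect_error(lexicon_size_sweep(lex, sizes = 500), "sizes")
})
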