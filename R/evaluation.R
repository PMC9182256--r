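#' The registry of nine benchmark activation contrasts
#'
#' Encodes the nine published occipito-temporal activation effects that a
#' candidate model simulation must reproduce, together with the direction
#' expected from the literature: pseudowords > words; words > consonant
#' strings; their conjunction; pseudohomophones > words;
#' pseudohomophones = pseudowords; matched pseudowords > matched words;
#' the word-similarity gradient (low < intermediate < high = words); a
#' negative log-frequency slope over words plus pseudowords; and a
#' positive log-bigram-frequency slope (with a documented quadratic
#' refit). The combined three-way contrast is scored as the conjunction
#' of its two pairwise components but still counts as one of the nine.
#'
#' @return Data frame with columns `id`, `type`, and `description`.
#' @export
contrast_registry <- function() {
  data.frame(
    id = c("pw_gt_w", "w_gt_cs", "pw_w_cs", "ph_gt_w", "ph_eq_pw",
           "mpw_gt_mw", "word_similarity", "freq_slope", "bigram_slope"),
    type = c("directional", "directional", "conjunction", "directional",
             "equality", "directional", "composite", "slope", "slope"),
    description = c(
      "pseudowords > words",
      "words > consonant strings",
      "pseudowords > words > consonant strings (conjunction)",
      "pseudohomophones > words",
      "pseudohomophones = pseudowords (null)",
      "matched pseudowords > matched words",
      "word similarity: lWS < iWS < hWS = words",
      "negative log2 word-frequency slope over words and pseudowords",
      "positive log2 bigram-frequency slope (quadratic refit reported)"),
    stringsAsFactors = FALSE)
}

#' Construct derived benchmark conditions from a word-likeness table
#'
#' Builds the matched and word-similarity conditions needed by the
#' benchmark registry. Matched words/pseudowords (`mW`/`mPW`) pair the
#' two categories by greedy nearest-neighbor matching on the lexical
#' covariates present in the table (Coltheart's N and bigram frequencies
#' by default). The word-similarity gradient matches non-words to words
#' on quadrigram frequency (high similarity, `hWS`) and bigram frequency
#' (intermediate, `iWS`), with the leftover consonant strings as the
#' low-similarity condition (`lWS`) and the words as comparison words
#' (`cmW`).
#'
#' Pool sizes are capped (the greedy matcher scans a full distance
#' matrix) — caps are configurable and only affect condition sizes, not
#' their construction rule.
#'
#' @param table A [build_table()] table with categories W/PW/CS and the
#'   covariate columns; quadrigram and bigram summated frequencies are
#'   required for the similarity conditions.
#' @param n_matched_pairs Pairs for the matched word/pseudoword contrast
#'   (default 108, the benchmark's published size, capped by group size).
#' @param n_hws,n_iws Caps for the high/intermediate-similarity matches.
#' @return Named list of integer row-index vectors into `table` for
#'   conditions `mW`, `mPW`, `hWS`, `iWS`, `lWS`, `cmW` (entries missing
#'   when the table lacks the needed columns).
#' @export
benchmark_conditions <- function(table, n_matched_pairs = 108L,
                                 n_hws = 150L, n_iws = 300L) {
  rows_w <- which(table$category == "W")
  rows_pw <- which(table$category == "PW")
  rows_cs <- which(table$category == "CS")
  out <- list()

  match_feats <- intersect(c("coltheart_n", "bigram_initial", "bigram_final",
                             "bigram_summated"), names(table))
  if (length(match_feats) && length(rows_w) && length(rows_pw)) {
    np <- min(n_matched_pairs, length(rows_w), length(rows_pw))
    m <- match_groups(table[rows_w, , drop = FALSE],
                      table[rows_pw, , drop = FALSE],
                      features = match_feats, n_pairs = np)
    out$mW <- rows_w[m$pairs$a_row]
    out$mPW <- rows_pw[m$pairs$b_row]
  }

  pool <- c(rows_pw, rows_cs)
  if ("quadrigram_summated" %in% names(table) &&
      "bigram_summated" %in% names(table) &&
      length(rows_w) && length(pool) > 2) {
    nh <- min(n_hws, length(rows_w), length(pool) %/% 3)
    mh <- match_groups(table[pool, , drop = FALSE],
                       table[rows_w, , drop = FALSE],
                       features = "quadrigram_summated", n_pairs = nh)
    out$hWS <- pool[mh$pairs$a_row]
    remaining <- setdiff(pool, out$hWS)
    ni <- min(n_iws, length(rows_w), length(remaining))
    mi <- match_groups(table[remaining, , drop = FALSE],
                       table[rows_w, , drop = FALSE],
                       features = "bigram_summated", n_pairs = ni)
    out$iWS <- remaining[mi$pairs$a_row]
    out$lWS <- setdiff(rows_cs, c(out$hWS, out$iWS))
    out$cmW <- rows_w
  }
  out
}

# Two-group linear model (equivalent to a pooled-variance t test), robust
# to the degenerate zero-variance case, where no evidence means p = 1.
.two_group_test <- function(act_a, act_b) {
  delta <- mean(act_a) - mean(act_b)
  df_res <- length(act_a) + length(act_b) - 2L
  if (df_res < 1 || (stats::var(act_a) == 0 && stats::var(act_b) == 0)) {
    return(list(delta = delta, statistic = 0, p = if (delta == 0) 1 else 0))
  }
  fit <- stats::lm(act ~ grp,
                   data = data.frame(act = c(act_a, act_b),
                                     grp = rep(c("a", "b"),
                                               c(length(act_a), length(act_b)))))
  sm <- summary(fit)$coefficients
  t_val <- sm[2, "t value"]
  p <- sm[2, "Pr(>|t|)"]
  if (!is.finite(p)) { t_val <- 0; p <- if (delta == 0) 1 else 0 }
  list(delta = delta, statistic = -t_val, p = p)  # sign so + means a > b
}

.slope_test <- function(act, x, quadratic = FALSE) {
  if (stats::var(act) == 0 || stats::var(x) == 0) {
    return(list(slope = 0, statistic = 0, p = 1, quad = NA_real_))
  }
  fit <- stats::lm(act ~ x)
  sm <- summary(fit)$coefficients
  quad <- NA_real_
  if (quadratic) {
    qfit <- stats::lm(act ~ x + I(x^2))
    quad <- stats::coef(qfit)[["I(x^2)"]]
  }
  p <- sm[2, "Pr(>|t|)"]
  if (!is.finite(p)) p <- 1
  list(slope = sm[2, "Estimate"], statistic = sm[2, "t value"], p = p,
       quad = quad)
}

.verdict <- function(type, direction_ok, p_adj, alpha = 0.05) {
  if (type == "equality") {
    if (p_adj >= alpha) "correct" else "incorrect"
  } else {
    if (p_adj < alpha) {
      if (direction_ok) "correct" else "incorrect"
    } else "null"
  }
}

#' Run the nine benchmark contrasts on a model simulation
#'
#' Fits each registry contrast on the per-item simulated activations:
#' categorical contrasts as two-group linear models, slope contrasts as
#' ordinary least-squares regressions of activation on the
#' log2-transformed predictor (frequency over words and pseudowords with
#' pseudoword frequency fixed at zero; summated bigram frequency over all
#' three base categories, with an additional quadratic refit whose
#' curvature coefficient is reported). p-values are Bonferroni-corrected
#' over the family of nine. A contrast whose conditions are absent from
#' the simulation is skipped with a warning, never silently passed.
#'
#' Verdicts: a directional contrast is `correct` when its adjusted p is
#' below `alpha` and the estimated direction matches the literature,
#' `incorrect` when significant in the opposite direction, `null`
#' otherwise. Equality contrasts are `correct` when the adjusted p is at
#' least `alpha`. The three-way conjunction and the word-similarity
#' composite are correct only when all components are.
#'
#' @param sim A `lexcat_sim`.
#' @param table The word-likeness table the simulation was computed from
#'   (supplies frequency and bigram predictors; rows matched by string).
#' @param conditions Optional list from [benchmark_conditions()]; derived
#'   automatically when `NULL`.
#' @param alpha Family-wise significance level (default .05).
#' @param registry The contrast registry (for inspection/extension).
#' @return Data frame of class `lexcat_contrasts`: one row per registry
#'   contrast with estimate, statistic, raw and Bonferroni-adjusted p,
#'   and verdict in `c("correct", "incorrect", "null", "skipped")`.
#' @export
run_benchmark_contrasts <- function(sim, table, conditions = NULL,
                                    alpha = 0.05,
                                    registry = contrast_registry()) {
  stopifnot(inherits(sim, "lexcat_sim"))
  if (is.null(conditions)) conditions <- benchmark_conditions(table)
  n_family <- nrow(registry)
  aligned <- identical(sim$string, table$string)
  act_of <- function(rows) {
    if (aligned) sim$activation[rows]
    else sim$activation[match(table$string[rows], sim$string)]
  }
  cat_rows <- function(cat) which(table$category == cat)

  res <- data.frame(id = registry$id, type = registry$type,
                    expected = registry$description,
                    estimate = NA_real_, statistic = NA_real_,
                    p = NA_real_, p_adj = NA_real_,
                    verdict = "skipped", stringsAsFactors = FALSE)
  extras <- list()

  pair_contrast <- function(rows_a, rows_b) {
    t <- .two_group_test(act_of(rows_a), act_of(rows_b))
    t$p_adj <- min(1, n_family * t$p)
    t
  }
  have <- function(rows) length(rows) >= 2
  store <- function(i, t, direction_ok) {
    res$estimate[i] <<- t$delta %||% t$slope
    res$statistic[i] <<- t$statistic
    res$p[i] <<- t$p
    res$p_adj[i] <<- t$p_adj
    res$verdict[i] <<- .verdict(res$type[i], direction_ok, t$p_adj, alpha)
  }
  skip <- function(i, what) {
    warning(sprintf("contrast '%s' skipped: %s", res$id[i], what), call. = FALSE)
  }

  components <- list()
  # 1, 2: simple category contrasts (higher category first)
  for (spec in list(list(i = 1L, a = "PW", b = "W"),
                    list(i = 2L, a = "W", b = "CS"),
                    list(i = 4L, a = "PH", b = "W"))) {
    ra <- cat_rows(spec$a); rb <- cat_rows(spec$b)
    if (have(ra) && have(rb)) {
      t <- pair_contrast(ra, rb)
      store(spec$i, t, direction_ok = t$delta > 0)
      components[[res$id[spec$i]]] <- res$verdict[spec$i]
    } else skip(spec$i, sprintf("needs categories %s and %s", spec$a, spec$b))
  }
  # 3: conjunction of 1 and 2
  v1 <- components[["pw_gt_w"]]; v2 <- components[["w_gt_cs"]]
  if (!is.null(v1) && !is.null(v2)) {
    res$verdict[3L] <- if (v1 == "correct" && v2 == "correct") "correct"
                       else if (v1 == "incorrect" || v2 == "incorrect") "incorrect"
                       else "null"
    res$p_adj[3L] <- max(res$p_adj[c(1L, 2L)])
  } else skip(3L, "component contrasts unavailable")
  # 5: pseudohomophones = pseudowords (null contrast)
  rph <- cat_rows("PH"); rpw <- cat_rows("PW")
  if (have(rph) && have(rpw)) {
    t <- pair_contrast(rph, rpw)
    store(5L, t, direction_ok = NA)
  } else skip(5L, "needs categories PH and PW")
  # 6: matched pseudowords > matched words
  if (!is.null(conditions$mPW) && !is.null(conditions$mW)) {
    t <- pair_contrast(conditions$mPW, conditions$mW)
    store(6L, t, direction_ok = t$delta > 0)
  } else skip(6L, "matched conditions unavailable")
  # 7: word-similarity gradient lWS < iWS < hWS = cmW
  need <- c("lWS", "iWS", "hWS", "cmW")
  if (all(need %in% names(conditions)) &&
      all(vapply(conditions[need], length, 1L) >= 2)) {
    t1 <- pair_contrast(conditions$iWS, conditions$lWS)
    t2 <- pair_contrast(conditions$hWS, conditions$iWS)
    t3 <- pair_contrast(conditions$hWS, conditions$cmW)
    v <- c(.verdict("directional", t1$delta > 0, t1$p_adj, alpha),
           .verdict("directional", t2$delta > 0, t2$p_adj, alpha),
           .verdict("equality", NA, t3$p_adj, alpha))
    res$verdict[7L] <- if (all(v == "correct")) "correct"
                       else if (any(v == "incorrect")) "incorrect" else "null"
    res$p_adj[7L] <- max(t1$p_adj, t2$p_adj)
    extras$word_similarity <- data.frame(
      component = c("iWS>lWS", "hWS>iWS", "hWS=cmW"),
      delta = c(t1$delta, t2$delta, t3$delta),
      p_adj = c(t1$p_adj, t2$p_adj, t3$p_adj), verdict = v)
  } else skip(7L, "similarity conditions unavailable")
  # 8: word-frequency slope over W and PW (PW frequency = 0)
  rows_wpw <- which(table$category %in% c("W", "PW"))
  if (length(rows_wpw) >= 3 && "frequency" %in% names(table)) {
    x <- log2(1 + table$frequency[rows_wpw])
    t <- .slope_test(act_of(rows_wpw), x)
    t$p_adj <- min(1, n_family * t$p)
    store(8L, t, direction_ok = t$slope < 0)
  } else skip(8L, "needs W and PW rows with frequency")
  # 9: bigram-frequency slope over W, PW, CS (+ quadratic refit)
  rows_all <- which(table$category %in% c("W", "PW", "CS"))
  if (length(rows_all) >= 3 && "bigram_summated" %in% names(table)) {
    x <- log2(1 + table$bigram_summated[rows_all])
    t <- .slope_test(act_of(rows_all), x, quadratic = TRUE)
    t$p_adj <- min(1, n_family * t$p)
    store(9L, t, direction_ok = t$slope > 0)
    extras$bigram_quadratic_coef <- t$quad
  } else skip(9L, "needs bigram_summated column")

  class(res) <- c("lexcat_contrasts", "data.frame")
  attr(res, "model") <- attr(sim, "model")
  attr(res, "alpha") <- alpha
  attr(res, "extras") <- extras
  res
}

#' Qualitative model scores over the benchmark registry
#'
#' `score_correct` counts contrasts a model simulated correctly;
#' `score_penalized` subtracts the incorrectly simulated effects (null
#' results on directional contrasts are excluded from the penalty).
#'
#' @param results Named list of `lexcat_contrasts` (one per model, all
#'   run on the same registry).
#' @return Data frame: model, score_correct, score_incorrect,
#'   score_penalized, n_scored.
#' @export
score_models <- function(results) {
  stopifnot(is.list(results), length(results) >= 1)
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    model <- names(results)[i] %||% attr(r, "model")
    if (is.null(model) || !nzchar(model)) model <- attr(r, "model")
    data.frame(model = model,
               score_correct = sum(r$verdict == "correct"),
               score_incorrect = sum(r$verdict == "incorrect"),
               score_penalized = sum(r$verdict == "correct") -
                 sum(r$verdict == "incorrect"),
               n_scored = sum(r$verdict != "skipped"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read an observed ROI table from CSV
#'
#' Expected layout: first column a participant identifier, remaining
#' columns one per condition, cells holding percent signal change.
#'
#' @param path CSV file path.
#' @return Numeric matrix (participants x conditions) with condition
#'   column names and participant row names.
#' @export
read_observed_roi <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3) stop("ROI table needs a participant column and >= 2 conditions",
                         call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  if (anyDuplicated(colnames(m))) stop("condition labels must be unique", call. = FALSE)
  if (nrow(m) < 2) stop("ROI table needs at least two participants", call. = FALSE)
  m
}

#' Compare simulated condition differences to observed ROI data
#'
#' Quantitative model comparison on a common scale: simulated activations
#' are z-transformed across items, observed percent-signal-change values
#' across all participant-by-condition cells (pooled; per-participant
#' scaling available via `scale_within_participant`). For each contrast
#' (pair of condition labels) the deviation is
#' `|delta_sim - delta_obs| / SD_obs`, where the deltas are condition-mean
#' differences on the z scale and `SD_obs` is the standard deviation of
#' the participant-level observed difference scores. Because both sides
#' are z-scaled first, the metric is invariant to affine rescaling of the
#' raw simulation.
#'
#' @param sim A `lexcat_sim` whose categories include the ROI condition
#'   labels.
#' @param roi Matrix from [read_observed_roi()] (participants x
#'   conditions) or any numeric matrix with condition column names.
#' @param contrasts List of length-2 character vectors, or strings like
#'   `"W-PW"`.
#' @param scale_within_participant Z-scale each participant's row
#'   separately instead of pooling (default `FALSE`).
#' @return List of class `lexcat_comparison`: `per_contrast` data frame
#'   (contrast, delta_sim, delta_obs, sd_obs, deviation) and
#'   `total_deviation`.
#' @export
compare_to_observed <- function(sim, roi, contrasts,
                                scale_within_participant = FALSE) {
  stopifnot(inherits(sim, "lexcat_sim"), is.matrix(roi))
  contrasts <- lapply(contrasts, function(ct) {
    if (is.character(ct) && length(ct) == 1) strsplit(ct, "-", fixed = TRUE)[[1]] else ct
  })
  wanted <- unique(unlist(contrasts))
  missing_roi <- setdiff(wanted, colnames(roi))
  missing_sim <- setdiff(wanted, unique(sim$category))
  if (length(missing_roi) || length(missing_sim)) {
    stop(sprintf("condition labels not found%s%s",
                 if (length(missing_roi)) paste0(" in ROI data: ",
                                                 paste(missing_roi, collapse = ", ")) else "",
                 if (length(missing_sim)) paste0(" in simulation: ",
                                                 paste(missing_sim, collapse = ", ")) else ""),
         call. = FALSE)
  }
  z_sim <- as.numeric(scale(sim$activation))
  z_roi <- if (scale_within_participant) {
    t(apply(roi, 1, function(r) (r - mean(r)) / stats::sd(r)))
  } else {
    (roi - mean(roi)) / stats::sd(as.numeric(roi))
  }
  rows <- lapply(contrasts, function(ct) {
    a <- ct[1]; b <- ct[2]
    d_sim <- mean(z_sim[sim$category == a]) - mean(z_sim[sim$category == b])
    diffs <- z_roi[, a] - z_roi[, b]
    d_obs <- mean(diffs)
    sd_obs <- stats::sd(diffs)
    data.frame(contrast = paste(a, b, sep = "-"),
               delta_sim = d_sim, delta_obs = d_obs, sd_obs = sd_obs,
               deviation = abs(d_sim - d_obs) / sd_obs,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, rows)
  structure(list(model = attr(sim, "model"), per_contrast = per,
                 total_deviation = sum(per$deviation)),
            class = "lexcat_comparison")
}

#' @export
print.lexcat_comparison <- function(x, ...) {
  cat(sprintf("<lexcat_comparison> model %s: summed deviation %.3f SD over %d contrast(s)\n",
              x$model, x$total_deviation, nrow(x$per_contrast)))
  print(x$per_contrast)
  invisible(x)
}

#' Pairwise correlation matrix of model simulations
#'
#' Pearson correlations of per-item simulated activations across models.
#' All simulations must cover the same items in the same order. A model
#' with zero variance gets `NA` in its row and column (with a warning)
#' rather than a silent zero.
#'
#' @param sims Named list of `lexcat_sim` objects.
#' @return Symmetric correlation matrix with model names.
#' @export
model_correlation_matrix <- function(sims) {
  stopifnot(is.list(sims), length(sims) >= 2)
  strings <- sims[[1]]$string
  for (s in sims[-1]) {
    if (!identical(s$string, strings)) {
      stop("all simulations must cover the same item list", call. = FALSE)
    }
  }
  names(sims) <- vapply(seq_along(sims), function(i) {
    names(sims)[i] %||% attr(sims[[i]], "model") %||% paste0("model", i)
  }, "")
  m <- vapply(sims, function(s) s$activation, numeric(nrow(sims[[1]])))
  const <- apply(m, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(m))
  if (any(const)) {
    warning(sprintf("zero-variance simulation(s): %s; correlations set to NA",
                    paste(colnames(m)[const], collapse = ", ")), call. = FALSE)
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
    diag(r)[!const] <- 1
  }
  r
}

#' Stability of the categorization curve under stimulus subsetting
#'
#' Repeatedly refits the categorization curve on stratified random
#' subsets of the word-likeness table (category proportions preserved)
#' and correlates the subset-based per-item entropy with the full-set
#' entropy over all items. With the full-set proportion the subset is the
#' whole table and r is exactly 1.
#'
#' @param table A [build_table()] table.
#' @param proportions Proportions in `(0, 1]`.
#' @param n_draws Random subsets per proportion (default 20).
#' @param seed Top-level seed; each draw is reproducible.
#' @param estimator,bin_width Curve settings, see [fit_curve()].
#' @param measure Word-likeness column.
#' @return Data frame: proportion, mean_r, sd_r, n_valid (draws whose
#'   subset supported a curve fit).
#' @export
subset_stability <- function(table, proportions = c(0.05, 0.1, 0.25, 0.5, 1.0),
                             n_draws = 20L, seed = 1L,
                             estimator = "exact-bin", bin_width = 0.05,
                             measure = "old20") {
  stopifnot(all(proportions > 0), all(proportions <= 1))
  live <- which(!is.na(table[[measure]]))
  full_curve <- fit_curve(table, estimator = estimator, bin_width = bin_width,
                          measure = measure)
  full_entropy <- binary_entropy(word_probability(full_curve, table[[measure]][live]))
  cats <- split(live, table$category[live])
  with_seed(seed, {
    rows <- lapply(proportions, function(p) {
      rs <- numeric(0)
      for (d in seq_len(n_draws)) {
        sub <- unlist(lapply(cats, function(rws) {
          k <- max(1L, ceiling(p * length(rws)))
          if (k >= length(rws)) rws else sample(rws, k)
        }), use.names = FALSE)
        curve_d <- tryCatch(
          fit_curve(table[sub, , drop = FALSE], estimator = estimator,
                    bin_width = bin_width, measure = measure),
          error = function(e) NULL)
        if (is.null(curve_d)) {
          warning(sprintf("draw skipped at proportion %.2f: subset too small to fit a curve", p),
                  call. = FALSE)
          next
        }
        ent <- binary_entropy(word_probability(curve_d, table[[measure]][live]))
        rs <- c(rs, if (stats::sd(ent) == 0 || stats::sd(full_entropy) == 0) NA
                else stats::cor(full_entropy, ent))
      }
      rs <- rs[!is.na(rs)]
      data.frame(proportion = p, mean_r = mean(rs), sd_r = stats::sd(rs),
                 n_valid = length(rs))
    })
    do.call(rbind, rows)
  })
}

#' Effect of lexicon size on word-likeness and model simulations
#'
#' Emulates vocabulary growth: for each size, the reference lexicon is
#' truncated to its most frequent entries, the stimulus items'
#' word-likeness is recomputed against the truncated reference, the
#' categorization curve is refitted, and activation is simulated. Very
#' small lexica cannot support a 20-neighbor distance and are skipped
#' with a warning.
#'
#' @param full_lexicon The full [lexicon()].
#' @param sizes Integer vector of truncation sizes.
#' @param items Optional [stimulus_set()]; built from `full_lexicon` with
#'   `seed` when `NULL`.
#' @param seed Seed for stimulus construction.
#' @param estimator,bin_width Curve settings.
#' @return Data frame of class `lexcat_sweep`: one row per retained size
#'   with median activation per category and whether the canonical
#'   ordering (pseudowords and pseudohomophones above words above
#'   consonant strings) holds.
#' @export
lexicon_size_sweep <- function(full_lexicon, sizes, items = NULL, seed = 1L,
                               estimator = "exact-bin", bin_width = 0.05) {
  stopifnot(inherits(full_lexicon, "lexcat_lexicon"),
            all(sizes <= nrow(full_lexicon)))
  if (is.null(items)) items <- build_stimulus_set(full_lexicon, seed = seed)
  min_size <- 21L  # a 20-neighbor mean needs 21 entries once the query itself is excluded
  rows <- list()
  for (sz in sizes) {
    if (sz < min_size) {
      warning(sprintf("size %d skipped: a 20-nearest-neighbor distance needs >= %d words",
                      sz, min_size), call. = FALSE)
      next
    }
    ref <- truncate_by_frequency(full_lexicon, sz)
    tab <- build_table(items, ref, measures = "old20")
    curve <- fit_curve(tab, estimator = estimator, bin_width = bin_width)
    sim <- simulate_lcm(curve, items, tab)
    med <- tapply(sim$activation, sim$category, stats::median)
    get <- function(cat) if (cat %in% names(med)) med[[cat]] else NA_real_
    ord <- isTRUE(get("PW") > get("W") && get("W") > get("CS")) &&
      (is.na(get("PH")) || isTRUE(get("PH") > get("W")))
    rows[[length(rows) + 1L]] <-
      data.frame(size = sz, median_W = get("W"), median_PW = get("PW"),
                 median_CS = get("CS"), median_PH = get("PH"),
                 ordering_holds = ord)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("lexcat_sweep", "data.frame")
  out
}
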