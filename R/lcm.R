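#' Binary entropy of a categorization probability
#'
#' `-p*log2(p) - (1-p)*log2(1-p)` with the convention `0*log2(0) = 0`.
#' This is the lexical categorization difficulty at the heart of the
#' model: 1 bit at maximal word/non-word uncertainty (`p = 0.5`), 0 bits
#' at certainty (`p` of 0 or 1).
#'
#' @param p Probability (vectorized), each value in `[0, 1]`.
#' @return Real values in `[0, 1]`.
#' @examples
#' binary_entropy(c(0, 0.5, 0.85, 1))
#' @export
binary_entropy <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  q <- 1 - p
  term <- function(z) ifelse(z == 0, 0, -z * log2(z))
  term(p) + term(q)
}

# Robust log kernel density: log(mean(dnorm(x, xi, h))) via log-sum-exp.
.log_kde <- function(x, xi, h) {
  vapply(x, function(v) {
    lk <- stats::dnorm(v, mean = xi, sd = h, log = TRUE)
    m <- max(lk)
    if (!is.finite(m)) return(-Inf)
    m + log(mean(exp(lk - m)))
  }, numeric(1))
}

#' Fit the lexical categorization curve
#'
#' Estimates `p(word | word-likeness)` from a word-likeness table holding
#' both word and non-word rows, plus its complement and the resulting
#' binary-entropy categorization difficulty over the word-likeness axis.
#'
#' Two estimators are available:
#' \describe{
#'   \item{`"exact-bin"` (default)}{Strings are grouped by word-likeness
#'     rounded to `bin_width` (default 1/20, the natural granularity of a
#'     20-neighbor mean of integer distances) and
#'     `p(word | bin) = word count / total count` — the transparent
#'     counting estimator: take all strings at a given word-likeness,
#'     identify the words, count, divide. Empty bins are absent from the
#'     support.}
#'   \item{`"kde"`}{Separate Gaussian kernel densities (Silverman's rule
#'     by default) are fitted to the word and non-word word-likeness
#'     samples and combined with empirical class priors:
#'     `p(word | x) = nW * fW(x) / (nW * fW(x) + nNW * fNW(x))`. This
#'     yields the smooth curves usually plotted.}
#' }
#'
#' @param table A `lexcat_table` from [build_table()] with an `old20`
#'   column (or another word-likeness column named by `measure`).
#' @param estimator `"exact-bin"` or `"kde"`.
#' @param bin_width Bin width for the exact-bin estimator (default 0.05).
#' @param bandwidth Kernel bandwidth: `"silverman"` or a positive number
#'   applied to both classes.
#' @param measure Name of the word-likeness column (default `"old20"`).
#' @param word_categories Categories counted as words (default `"W"`).
#' @param nonword_categories Categories counted as non-words (default
#'   pseudowords and consonant strings; pseudohomophones are scored by
#'   the fitted curve but, like the empirical materials, do not enter its
#'   construction).
#' @param n_grid Grid size of the kde support (default 512).
#' @return An object of class `lcm_curve`: support, `p_word`,
#'   `p_nonword`, `entropy`, per-bin counts (exact-bin) or class samples
#'   and bandwidths (kde), and estimator metadata.
#' @export
fit_curve <- function(table, estimator = c("exact-bin", "kde"),
                      bin_width = 0.05, bandwidth = "silverman",
                      measure = "old20",
                      word_categories = "W",
                      nonword_categories = c("PW", "CS"),
                      n_grid = 512L) {
  estimator <- match.arg(estimator)
  stopifnot(measure %in% names(table))
  x <- table[[measure]]
  keep <- !is.na(x) & table$category %in% c(word_categories, nonword_categories)
  x <- x[keep]
  is_word <- table$category[keep] %in% word_categories
  if (!any(is_word) || !any(!is_word)) {
    stop("fitting the categorization curve needs both word and non-word rows",
         call. = FALSE)
  }
  curve <- if (estimator == "exact-bin") {
    stopifnot(is.numeric(bin_width), bin_width > 0)
    bins <- round(x / bin_width) * bin_width
    support <- sort(unique(bins))
    n_total <- vapply(support, function(b) sum(bins == b), numeric(1))
    n_word <- vapply(support, function(b) sum(bins == b & is_word), numeric(1))
    p_word <- n_word / n_total
    list(support = support, p_word = p_word, p_nonword = 1 - p_word,
         entropy = binary_entropy(p_word),
         estimator = "exact-bin", bin_width = bin_width,
         counts = data.frame(bin = support, n_word = n_word, n_total = n_total),
         n_word = sum(is_word), n_nonword = sum(!is_word))
  } else {
    xw <- x[is_word]; xn <- x[!is_word]
    h <- if (identical(bandwidth, "silverman")) {
      c(w = stats::bw.nrd0(xw), nw = stats::bw.nrd0(xn))
    } else {
      stopifnot(is.numeric(bandwidth), bandwidth > 0)
      c(w = bandwidth, nw = bandwidth)
    }
    support <- seq(min(x) - 3 * max(h), max(x) + 3 * max(h), length.out = n_grid)
    p_word <- .kde_p_word(support, xw, xn, h)
    list(support = support, p_word = p_word, p_nonword = 1 - p_word,
         entropy = binary_entropy(p_word),
         estimator = "kde", bandwidth = h,
         samples = list(word = xw, nonword = xn),
         n_word = length(xw), n_nonword = length(xn))
  }
  curve$measure <- measure
  class(curve) <- "lcm_curve"
  curve
}

.kde_p_word <- function(x, xw, xn, h) {
  lw <- .log_kde(x, xw, h[["w"]]) + log(length(xw))
  ln <- .log_kde(x, xn, h[["nw"]]) + log(length(xn))
  p <- 1 / (1 + exp(ln - lw))
  # Far outside both samples the nearer class dominates; resolve exact
  # -Inf/-Inf ties to the closer sample mean.
  und <- !is.finite(lw) & !is.finite(ln)
  if (any(und)) {
    p[und] <- ifelse(abs(x[und] - mean(xw)) <= abs(x[und] - mean(xn)), 1, 0)
  }
  p
}

#' @export
print.lcm_curve <- function(x, ...) {
  cat(sprintf("<lcm_curve> %s estimator over '%s': %d support points, %d words vs %d non-words\n",
              x$estimator, x$measure, length(x$support), x$n_word, x$n_nonword))
  invisible(x)
}

#' Probability of being a word at a given word-likeness
#'
#' Evaluates a fitted categorization curve. For the exact-bin estimator,
#' `x` inside an occupied bin returns that bin's probability; `x` in an
#' empty region is linearly interpolated between the two flanking
#' occupied bins, and queries beyond the support take the nearest
#' occupied bin's value. For the kde estimator the posterior is evaluated
#' in closed form from the stored class samples.
#'
#' @param curve An `lcm_curve` from [fit_curve()].
#' @param x Word-likeness values (vectorized).
#' @return Probabilities in `[0, 1]`.
#' @export
word_probability <- function(curve, x) {
  if (!inherits(curve, "lcm_curve")) {
    stop("`curve` must be a fitted lcm_curve", call. = FALSE)
  }
  stopifnot(is.numeric(x))
  if (curve$estimator == "exact-bin") {
    snapped <- round(x / curve$bin_width) * curve$bin_width
    hit <- match(round(snapped, 9), round(curve$support, 9))
    out <- numeric(length(x))
    ok <- !is.na(hit)
    out[ok] <- curve$p_word[hit[ok]]
    if (any(!ok)) {
      if (length(curve$support) == 1L) {
        out[!ok] <- curve$p_word[1L]
      } else {
        out[!ok] <- stats::approx(curve$support, curve$p_word,
                                  xout = x[!ok], rule = 2)$y
      }
    }
    out
  } else {
    .kde_p_word(x, curve$samples$word, curve$samples$nonword, curve$bandwidth)
  }
}

#' Word/non-word crossover point of a fitted curve
#'
#' The word-likeness at which the fitted curve crosses
#' `p(word) = 0.5` (linear interpolation between the bracketing support
#' points). Used as the default engagement/eligibility midpoint of the
#' sigmoid competitor models; falls back to the support median when the
#' curve never crosses.
#'
#' @param curve An `lcm_curve`.
#' @return A single word-likeness value.
#' @export
curve_crossover <- function(curve) {
  p <- curve$p_word
  s <- curve$support
  below <- which(p < 0.5)
  above <- which(p >= 0.5)
  if (length(below) == 0 || length(above) == 0) return(stats::median(s))
  i <- which(diff(p >= 0.5) != 0)
  if (length(i) == 0) return(stats::median(s))
  i <- i[1]
  p1 <- p[i]; p2 <- p[i + 1]
  if (p2 == p1) return(mean(s[i:(i + 1)]))
  s[i] + (0.5 - p1) * (s[i + 1] - s[i]) / (p2 - p1)
}

# Shared constructor for per-item model simulations.
new_simulation <- function(items, wordlikeness, activation, model,
                           provenance = list()) {
  out <- data.frame(string = items$string, category = items$category,
                    wordlikeness = wordlikeness, activation = activation,
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$activation))) {
    stop("simulated activation must be finite for every item", call. = FALSE)
  }
  class(out) <- c("lexcat_sim", "data.frame")
  attr(out, "model") <- model
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.lexcat_sim <- function(x, ...) {
  cat(sprintf("<lexcat_sim> model %s: %d items, activation range [%.3f, %.3f]\n",
              attr(x, "model"), nrow(x), min(x$activation), max(x$activation)))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

# Look up each non-SL item's word-likeness in the table, with a clear
# error naming any missing string.
.item_wordlikeness <- function(items, table, measure = "old20") {
  wl <- rep(NA_real_, nrow(items))
  live <- items$category != "SL"
  idx <- match(items$string[live], table$string)
  if (anyNA(idx)) {
    missing <- items$string[live][is.na(idx)]
    stop(sprintf("no word-likeness table row for: %s",
                 paste(utils::head(missing, 5L), collapse = ", ")), call. = FALSE)
  }
  wl[live] <- table[[measure]][idx]
  if (anyNA(wl[live])) {
    bad <- items$string[live][is.na(wl[live])]
    stop(sprintf("word-likeness is NA for: %s",
                 paste(utils::head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  wl
}

#' Simulate lvOT activation under the lexical categorization model
#'
#' The model's central claim: word-sensitive occipito-temporal activation
#' reflects the difficulty of categorizing a letter string as word versus
#' non-word given only its word-likeness. Each item's activation is the
#' binary entropy of the fitted `p(word | word-likeness)` at the item's
#' word-likeness. Scrambled-letters controls, which carry no orthographic
#' content, are fixed at activation 0. Raw entropy in `[0, 1]` bits is the
#' canonical output; any rescaling for plotting is cosmetic.
#'
#' @param curve A fitted `lcm_curve`.
#' @param items A [stimulus_set()].
#' @param table The [build_table()] word-likeness table covering every
#'   non-SL item.
#' @param measure Word-likeness column name (default `"old20"`).
#' @return A `lexcat_sim` data frame (string, category, wordlikeness,
#'   activation) with model label `"LCM"`.
#' @export
simulate_lcm <- function(curve, items, table, measure = "old20") {
  wl <- .item_wordlikeness(items, table, measure)
  act <- numeric(nrow(items))
  live <- items$category != "SL"
  act[live] <- binary_entropy(word_probability(curve, wl[live]))
  new_simulation(items, wl, act, model = "LCM",
                 provenance = list(estimator = curve$estimator,
                                   measure = measure))
}

#' Export a categorization curve to JSON
#'
#' Serializes support, probabilities, entropy, and estimator metadata
#' (including class samples for the kde estimator) so a fitted curve can
#' be reused across sessions.
#'
#' @param curve An `lcm_curve`.
#' @param path Output file path.
#' @export
curve_to_json <- function(curve, path) {
  payload <- unclass(curve)
  payload$counts <- if (!is.null(payload$counts)) as.list(payload$counts)
  # named atomic vectors serialize as bare arrays; keep the names
  if (!is.null(payload$bandwidth)) payload$bandwidth <- as.list(payload$bandwidth)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Import a categorization curve from JSON
#'
#' @param path File written by [curve_to_json()].
#' @return An `lcm_curve`.
#' @export
curve_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(payload$counts)) payload$counts <- as.data.frame(payload$counts)
  if (!is.null(payload$bandwidth)) {
    payload$bandwidth <- unlist(payload$bandwidth)
  }
  if (!is.null(payload$samples)) {
    payload$samples <- lapply(payload$samples, as.numeric)
  }
  class(payload) <- "lcm_curve"
  payload
}

#' Plot a categorization curve
#'
#' Draws `p(word | word-likeness)`, its complement, and the entropy
#' (categorization difficulty) over the word-likeness axis.
#'
#' @param x An `lcm_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lcm_curve <- function(x, ...) {
  graphics::plot(x$support, x$p_word, type = "l", col = "grey40", lwd = 2,
                 xlab = x$measure, ylab = "probability / entropy (bits)",
                 ylim = c(0, 1), ...)
  graphics::lines(x$support, x$p_nonword, col = "steelblue", lwd = 2)
  graphics::lines(x$support, x$entropy, col = "black", lwd = 2, lty = 2)
  graphics::legend("right", legend = c("p(word)", "p(non-word)", "entropy"),
                   col = c("grey40", "steelblue", "black"),
                   lty = c(1, 1, 2), lwd = 2, bty = "n")
  invisible(x)
}
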