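#' Orthographic Levenshtein distance over the 20 nearest words (OLD20)
#'
#' Mean edit distance from `s` to its `n_nearest` closest words in a
#' reference lexicon. Lower values mean more word-like strings. With the
#' default 20 neighbors and integer distances the result is always a
#' multiple of 1/20.
#'
#' The search prunes by a length-window bound: candidates are visited in
#' order of `|nchar(candidate) - nchar(s)|`, which lower-bounds the edit
#' distance, and scanning stops once that bound exceeds the current
#' 20th-best distance. Results are identical to a full scan; ties at the
#' 20th rank are immaterial because any subset of equally distant words
#' yields the same mean.
#'
#' @param s Query string (need not be a word).
#' @param reference A [lexicon()].
#' @param exclude_self Drop exact matches of `s` from the reference before
#'   ranking (default `TRUE`): a word's distance-0 match to itself would
#'   deflate its own neighborhood distance.
#' @param variant Edit-distance variant, see [edit_distance()].
#' @param n_nearest Number of nearest neighbors averaged (default 20).
#' @return Non-negative real.
#' @examples
#' lex <- synth_lexicon(100, 5, seed = 1)
#' old20(lex$word[1], lex)
#' @export
old20 <- function(s, reference, exclude_self = TRUE,
                  variant = c("levenshtein", "osa-transposition"),
                  n_nearest = 20L) {
  variant <- match.arg(variant)
  stopifnot(is.character(s), length(s) == 1, nzchar(s),
            inherits(reference, "lexcat_lexicon"))
  words <- reference$word
  if (exclude_self) words <- words[words != s]
  k <- as.integer(n_nearest)
  if (length(words) < k) {
    stop(sprintf("reference too small for OLD%d: %d eligible words, need >= %d%s",
                 k, length(words), k,
                 if (exclude_self) " (after excluding the query itself)" else ""),
         call. = FALSE)
  }
  lb <- abs(nchar(words) - nchar(s))
  best <- numeric(0)
  kth <- Inf
  for (d0 in sort(unique(lb))) {
    if (length(best) >= k && d0 > kth) break
    cand <- words[lb == d0]
    best <- c(best, string_distances(s, cand, variant = variant))
    if (length(best) >= k) {
      best <- sort(best, partial = k)[seq_len(k)] + 0  # keep only the top k
      kth <- best[k]
    }
  }
  mean(sort(best)[seq_len(k)])
}

#' Coltheart's orthographic neighborhood size
#'
#' Number of same-length reference words that differ from `s` in exactly
#' one letter position (substitution only). The string's own lexicon entry
#' is never counted.
#'
#' @inheritParams old20
#' @return Non-negative integer count.
#' @export
coltheart_n <- function(s, reference) {
  stopifnot(is.character(s), length(s) == 1, nzchar(s),
            inherits(reference, "lexcat_lexicon"))
  words <- reference$word
  cand <- words[nchar(words) == nchar(s) & words != s]
  if (length(cand) == 0) return(0L)
  sm <- str_chars(s)[[1]]
  cm <- matrix(unlist(str_chars(cand)), ncol = nchar(s), byrow = TRUE)
  mismatches <- rowSums(cm != matrix(sm, nrow = length(cand),
                                     ncol = nchar(s), byrow = TRUE))
  sum(mismatches == 1L)
}

# Batch OLD20 for the plain-Levenshtein variant: one C-level distance
# matrix per chunk of query strings, then row-wise partial sorts. Equal
# by construction to per-query old20() (both compute the exact distance
# lattice; ties among equal distances share the same mean).
.old20_batch <- function(strings, reference, exclude_self = TRUE,
                         n_nearest = 20L, chunk = 500L) {
  k <- as.integer(n_nearest)
  words <- reference$word
  if (length(words) - 1L < k) {
    stop(sprintf("reference too small for OLD%d: need >= %d eligible words",
                 k, k + 1L), call. = FALSE)
  }
  out <- numeric(length(strings))
  for (start in seq(1L, length(strings), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(strings))
    d <- utils::adist(strings[idx], words)
    for (j in seq_along(idx)) {
      di <- d[j, ]
      if (exclude_self) di <- di[words != strings[idx[j]]]
      out[idx[j]] <- mean(sort(di, partial = k)[seq_len(k)])
    }
  }
  out
}

# Frequency table of all n-grams occurring in the reference, counting
# every within-word position. Token weighting multiplies each occurrence
# by the word's per-million frequency; type weighting counts words once
# per occurrence.
ngram_freq_table <- function(reference, n, weighting = c("token", "type")) {
  weighting <- match.arg(weighting)
  words <- reference$word
  len <- nchar(words)
  keep <- len >= n
  words <- words[keep]
  w <- if (weighting == "token") reference$frequency[keep] else rep(1, sum(keep))
  grams <- character(0)
  weights <- numeric(0)
  npos <- nchar(words) - n + 1L
  for (p in seq_len(max(npos, 0L))) {
    sel <- npos >= p
    grams <- c(grams, substr(words[sel], p, p + n - 1L))
    weights <- c(weights, w[sel])
  }
  if (length(grams) == 0) return(stats::setNames(numeric(0), character(0)))
  tab <- rowsum(weights, group = grams)
  stats::setNames(as.numeric(tab[, 1]), rownames(tab))
}

#' Positional n-gram frequency score
#'
#' Frequency of the query's n-grams in the reference lexicon. An n-gram's
#' frequency is the (token- or type-weighted) count of its occurrences at
#' any position in any reference word. `"initial"`/`"final"` return the
#' frequency of the query's first/last n-gram, `"summated"` sums the
#' frequencies of all its n-grams, `"mean"` divides that sum by the number
#' of n-gram positions, `nchar(s) - n + 1`.
#'
#' @inheritParams old20
#' @param n n-gram order: 2 (bigram), 3 (trigram), or 4 (quadrigram).
#' @param position One of `"initial"`, `"final"`, `"summated"`, `"mean"`.
#' @param weighting `"token"` (frequency-weighted, default) or `"type"`.
#' @param freq_table Optional precomputed table from the same reference,
#'   `n`, and weighting; used internally to avoid recomputation.
#' @return Non-negative real.
#' @export
ngram_score <- function(s, reference, n = 2L,
                        position = c("initial", "final", "summated", "mean"),
                        weighting = c("token", "type"),
                        freq_table = NULL) {
  position <- match.arg(position)
  weighting <- match.arg(weighting)
  stopifnot(is.character(s), length(s) == 1, nzchar(s), n %in% 2:4)
  if (nchar(s) < n) {
    stop(sprintf("cannot score %d-grams of '%s': string has only %d letters",
                 n, s, nchar(s)), call. = FALSE)
  }
  tab <- freq_table %||% ngram_freq_table(reference, n, weighting)
  look <- function(g) {
    v <- tab[g]
    ifelse(is.na(v), 0, v)
  }
  starts <- seq_len(nchar(s) - n + 1L)
  grams <- substring(s, starts, starts + n - 1L)
  switch(position,
         initial  = unname(look(grams[1L])),
         final    = unname(look(grams[length(grams)])),
         summated = sum(look(grams)),
         mean     = sum(look(grams)) / length(grams))
}

#' Build a word-likeness table for a stimulus set
#'
#' Computes the requested word-likeness measures for every item against a
#' reference lexicon. Items whose string is present in the reference carry
#' the reference frequency; all other items (pseudowords, consonant
#' strings, pseudohomophones) get frequency 0. Scrambled-letter items
#' (category `"SL"`, no string content) receive `NA` measures and are
#' assigned zero activation downstream by every model.
#'
#' @param items A [stimulus_set()], or a character vector of strings
#'   (treated as unlabeled items, category `NA`).
#' @param reference A [lexicon()].
#' @param measures Character vector from `"old20"`, `"coltheart_n"`,
#'   `"bigram"`, `"trigram"`, `"quadrigram"`. n-gram measures add
#'   `_initial`, `_final`, and `_summated` columns.
#' @param exclude_self,variant Passed to [old20()].
#' @param weighting n-gram weighting, see [ngram_score()].
#' @return Data frame of class `lexcat_table`: one row per item with
#'   columns `string`, `category`, `frequency`, and one column per
#'   measure. Deterministic given its inputs.
#' @export
build_table <- function(items, reference,
                        measures = c("old20", "coltheart_n", "bigram"),
                        exclude_self = TRUE,
                        variant = c("levenshtein", "osa-transposition"),
                        weighting = c("token", "type")) {
  variant <- match.arg(variant)
  weighting <- match.arg(weighting)
  stopifnot(inherits(reference, "lexcat_lexicon"))
  known <- c("old20", "coltheart_n", "bigram", "trigram", "quadrigram")
  bad <- setdiff(measures, known)
  if (length(bad)) stop("unknown measure(s): ", paste(bad, collapse = ", "), call. = FALSE)

  if (is.character(items)) {
    items <- data.frame(string = items, category = NA_character_,
                        base_word = NA_character_,
                        frequency = NA_real_, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("string", "category") %in% names(items)))
  out <- data.frame(string = items$string, category = items$category,
                    stringsAsFactors = FALSE)
  # Frequency: copied from the reference for member words, zero otherwise.
  fidx <- match(out$string, reference$word)
  out$frequency <- ifelse(is.na(fidx), 0, reference$frequency[fidx])

  live <- !is.na(out$string)  # SL items have no string content
  strings <- out$string[live]

  guard <- function(expr, s) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("measure failed for string '%s': %s", s, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if ("old20" %in% measures) {
    out$old20 <- NA_real_
    out$old20[live] <- if (variant == "levenshtein") {
      .old20_batch(strings, reference, exclude_self)
    } else {
      vapply(strings, function(s) {
        guard(old20(s, reference, exclude_self = exclude_self, variant = variant), s)
      }, numeric(1), USE.NAMES = FALSE)
    }
  }
  if ("coltheart_n" %in% measures) {
    out$coltheart_n <- NA_integer_
    out$coltheart_n[live] <- vapply(strings, function(s) {
      guard(as.integer(coltheart_n(s, reference)), s)
    }, integer(1), USE.NAMES = FALSE)
  }
  for (m in intersect(measures, c("bigram", "trigram", "quadrigram"))) {
    n <- c(bigram = 2L, trigram = 3L, quadrigram = 4L)[[m]]
    tab <- ngram_freq_table(reference, n, weighting)
    for (pos in c("initial", "final", "summated")) {
      col <- paste0(m, "_", pos)
      out[[col]] <- NA_real_
      out[[col]][live] <- vapply(strings, function(s) {
        guard(ngram_score(s, reference, n = n, position = pos,
                          weighting = weighting, freq_table = tab), s)
      }, numeric(1), USE.NAMES = FALSE)
    }
  }
  class(out) <- c("lexcat_table", "data.frame")
  attr(out, "reference") <- attr(reference, "name")
  out
}
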