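#' Derive a pseudoword by vowel substitution
#'
#' Replaces one or more vowels of `word` with other vowels so that the
#' result is no longer a member of the lexicon. Pseudowords keep the base
#' word's length and consonant skeleton, so they remain orthographically
#' word-like while being meaningless.
#'
#' Legality rules stand in for the manual screening of illegal letter
#' combinations applied to hand-curated stimulus lists:
#' \describe{
#'   \item{`"bigram-attested"`}{Every bigram of the output must occur
#'     somewhere in the lexicon; if no vowel substitution satisfies this,
#'     the call errors.}
#'   \item{`"bigram-preferred"`}{As above, but when no substitution passes
#'     the bigram filter, the best-effort fallback accepts any non-member
#'     substitution — mirroring that a human reviser keeps the most
#'     acceptable candidate rather than discarding the base word. This is
#'     the stimulus-set default, where category balance requires one
#'     pseudoword per word.}
#'   \item{`"none"`}{Membership check only.}
#' }
#'
#' For words with up to four vowel positions the full substitution space
#' is enumerated and one admissible candidate is drawn uniformly at
#' random, so the call fails only when no admissible pseudoword exists at
#' all; longer vowel patterns fall back to rejection sampling with
#' `max_attempts` draws.
#'
#' @param word Base word containing at least one vowel.
#' @param lex A [lexicon()] used for the membership and legality checks.
#' @param legality `"bigram-attested"`, `"bigram-preferred"`, or `"none"`.
#' @param max_attempts Seeded draws before giving up (rejection-sampling
#'   path only).
#' @param vowels Vowel inventory (German default, includes umlauts).
#' @return A single string: same length as `word`, differing only at
#'   vowel positions, not a lexicon member.
#' @examples
#' # tiny lexicon: few bigrams are attested, so use the best-effort rule
#' lex <- lexicon(c("Augen", "Laden", "Lagen", "Lugen"), c(10, 5, 3, 1))
#' set.seed(42)
#' make_pseudoword("Augen", lex, legality = "bigram-preferred")
#' @export
make_pseudoword <- function(word, lex,
                            legality = c("bigram-attested", "bigram-preferred",
                                         "none"),
                            max_attempts = 200L,
                            vowels = lexcat_vowels("both")) {
  legality <- match.arg(legality)
  stopifnot(inherits(lex, "lexcat_lexicon"))
  attested <- if (legality != "none") {
    names(ngram_freq_table(lex, 2L, weighting = "type"))
  } else NULL
  words_env <- .word_env(lex)
  .make_pseudoword_impl(word, words_env, attested, legality, max_attempts,
                        vowels)
}

.word_env <- function(lex) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (w in lex$word) assign(w, TRUE, envir = env)
  env
}

.bigrams_ok <- function(s, attested) {
  starts <- seq_len(nchar(s) - 1L)
  all(substring(s, starts, starts + 1L) %in% attested)
}

.make_pseudoword_impl <- function(word, words_env, attested, legality,
                                  max_attempts, vowels) {
  stopifnot(is.character(word), length(word) == 1, nzchar(word))
  chars <- str_chars(word)[[1]]
  vpos <- which(chars %in% vowels)
  if (length(vpos) == 0) {
    stop(sprintf("cannot build a pseudoword from '%s': it contains no vowel", word),
         call. = FALSE)
  }
  lower_v <- tolower(vowels)
  pool_at <- function(p) {
    if (chars[p] %in% lower_v) lower_v else toupper(lower_v)
  }
  is_member <- function(s) exists(s, envir = words_env, inherits = FALSE)

  if (length(vpos) <= 4L) {
    # enumerate the full substitution space (original vowel included so
    # partial substitutions are covered; the unchanged word is dropped)
    grids <- lapply(vpos, pool_at)
    combos <- expand.grid(grids, stringsAsFactors = FALSE)
    cand <- vapply(seq_len(nrow(combos)), function(i) {
      cc <- chars
      cc[vpos] <- as.character(combos[i, ])
      paste(cc, collapse = "")
    }, character(1))
    cand <- unique(cand[cand != word])
    cand <- cand[!vapply(cand, is_member, logical(1))]
    if (length(cand) == 0) {
      stop(sprintf("no admissible pseudoword exists for base word '%s'", word),
           call. = FALSE)
    }
    if (!is.null(attested)) {
      legal <- cand[vapply(cand, .bigrams_ok, logical(1), attested)]
      if (length(legal)) {
        cand <- legal
      } else if (legality == "bigram-attested") {
        stop(sprintf("no vowel substitution of '%s' passes the bigram-attestation filter",
                     word), call. = FALSE)
      }  # bigram-preferred: fall back to the non-member candidates
    }
    return(cand[sample.int(length(cand), 1L)])
  }

  # many vowel positions: rejection sampling
  for (attempt in seq_len(max_attempts)) {
    k <- sample.int(length(vpos), 1L)
    change <- if (length(vpos) == 1L) vpos else sample(vpos, k)
    cc <- chars
    for (p in change) cc[p] <- sample(setdiff(pool_at(p), chars[p]), 1L)
    s <- paste(cc, collapse = "")
    if (s == word || is_member(s)) next
    if (!is.null(attested) && legality == "bigram-attested" &&
        !.bigrams_ok(s, attested)) next
    return(s)
  }
  stop(sprintf("pseudoword attempt budget (%d) exhausted for base word '%s'",
               max_attempts, word), call. = FALSE)
}

#' Derive a consonant string by replacing all vowels with consonants
#'
#' Every vowel of `word` is replaced by a randomly selected consonant;
#' consonant positions are untouched, so length and consonant skeleton are
#' preserved while the result is orthographically illegal (it contains no
#' vowel).
#'
#' @inheritParams make_pseudoword
#' @param mode `"uniform"` draws consonants uniformly;
#'   `"letter-frequency-matched"` draws them proportionally to their
#'   token-weighted letter frequency in `lex` (which is then required).
#' @param lex Lexicon; only needed for the frequency-matched mode.
#' @return A vowel-free string of the same length as `word`.
#' @export
make_consonant_string <- function(word, mode = c("uniform", "letter-frequency-matched"),
                                  lex = NULL,
                                  vowels = lexcat_vowels("both")) {
  mode <- match.arg(mode)
  stopifnot(is.character(word), length(word) == 1, nzchar(word))
  chars <- str_chars(word)[[1]]
  vpos <- which(chars %in% vowels)
  cons_lower <- lexcat_consonants("lower")
  prob <- NULL
  if (mode == "letter-frequency-matched") {
    if (is.null(lex)) {
      stop("letter-frequency-matched mode requires a lexicon", call. = FALSE)
    }
    letters_all <- tolower(unlist(str_chars(lex$word)))
    w <- rep(lex$frequency, nchar(lex$word))
    counts <- rowsum(w, group = letters_all)
    prob <- counts[match(cons_lower, rownames(counts)), 1]
    prob[is.na(prob)] <- 0
    if (sum(prob) == 0) prob <- NULL else prob <- prob / sum(prob)
  }
  for (p in vpos) {
    was_upper <- chars[p] != tolower(chars[p])
    draw <- sample(cons_lower, 1L, prob = prob)
    chars[p] <- if (was_upper) toupper(draw) else draw
  }
  paste(chars, collapse = "")
}

#' Construct a stimulus set
#'
#' Bundles labeled letter strings into the ordered collection used by all
#' simulation and evaluation functions. Categories follow the
#' word-recognition literature: `W` word, `PW` pseudoword, `CS` consonant
#' string, `PH` pseudohomophone, `SL` scrambled-letters control (no string
#' content; its simulated activation is fixed at zero by every model).
#'
#' @param string Character vector (`NA` allowed only for `SL` items).
#' @param category Character vector of labels in
#'   `c("W", "PW", "CS", "PH", "SL")`.
#' @param base_word Optional originating word for derived items.
#' @param frequency Per-million frequency; 0 for non-words.
#' @param provenance Named list of metadata (lexicon name, seed, config).
#' @return Data frame of class `lexcat_stimuli`.
#' @export
stimulus_set <- function(string, category, base_word = NA_character_,
                         frequency = 0, provenance = list()) {
  stopifnot(length(string) == length(category))
  ok <- category %in% c("W", "PW", "CS", "PH", "SL")
  if (!all(ok)) stop("unknown stimulus category: ", paste(unique(category[!ok]), collapse = ", "),
                     call. = FALSE)
  if (any(is.na(string) & category != "SL")) {
    stop("only SL items may lack string content", call. = FALSE)
  }
  out <- data.frame(string = as.character(string),
                    category = as.character(category),
                    base_word = rep_len(as.character(base_word), length(string)),
                    frequency = rep_len(as.numeric(frequency), length(string)),
                    stringsAsFactors = FALSE)
  class(out) <- c("lexcat_stimuli", "data.frame")
  attr(out, "provenance") <- provenance
  out
}

#' @export
print.lexcat_stimuli <- function(x, ...) {
  cat(sprintf("<lexcat_stimuli> %d items: %s\n", nrow(x),
              paste(sprintf("%s=%d", names(table(x$category)), table(x$category)),
                    collapse = ", ")))
  print(utils::head(as.data.frame(x), 6L))
  invisible(x)
}

#' Build the canonical three-category stimulus set from a lexicon
#'
#' For every lexicon word (the `W` items), derives one pseudoword (`PW`,
#' vowel substitution) and one consonant string (`CS`, vowels replaced by
#' consonants), giving equal category counts. Words without a vowel are
#' skipped with a warning. The construction is deterministic given `seed`.
#'
#' @param word_lexicon A [lexicon()] providing the base words.
#' @param seed Integer seed for the generators.
#' @param legality Pseudoword legality rule, see [make_pseudoword()]. The
#'   default best-effort rule keeps category balance: every base word
#'   yields a pseudoword even when none of its substitutions has all
#'   bigrams attested (small lexica attest few bigrams).
#' @param cs_mode Consonant-string sampling mode, see
#'   [make_consonant_string()].
#' @param n_sl Number of scrambled-letters control items to append
#'   (default 0).
#' @param vowels Vowel inventory.
#' @param max_attempts Per-word pseudoword attempt budget.
#' @return A [stimulus_set()] with equal `W`/`PW`/`CS` counts over the
#'   non-skipped base words.
#' @export
build_stimulus_set <- function(word_lexicon, seed = 1L,
                               legality = c("bigram-preferred",
                                            "bigram-attested", "none"),
                               cs_mode = c("uniform", "letter-frequency-matched"),
                               n_sl = 0L,
                               vowels = lexcat_vowels("both"),
                               max_attempts = 200L) {
  legality <- match.arg(legality)
  cs_mode <- match.arg(cs_mode)
  stopifnot(inherits(word_lexicon, "lexcat_lexicon"))
  has_vowel <- vapply(str_chars(word_lexicon$word),
                      function(ch) any(ch %in% vowels), logical(1))
  if (!all(has_vowel)) {
    warning(sprintf("skipped %d vowel-free base word(s): %s",
                    sum(!has_vowel),
                    paste(utils::head(word_lexicon$word[!has_vowel], 5L), collapse = ", ")),
            call. = FALSE)
  }
  base <- word_lexicon[has_vowel, , drop = FALSE]
  attested <- if (legality != "none") {
    names(ngram_freq_table(word_lexicon, 2L, weighting = "type"))
  } else NULL
  words_env <- .word_env(word_lexicon)
  with_seed(seed, {
    pw <- vapply(base$word, function(w) {
      tryCatch(.make_pseudoword_impl(w, words_env, attested, legality,
                                     max_attempts, vowels),
               error = function(e) stop(sprintf("base word '%s': %s", w,
                                                conditionMessage(e)), call. = FALSE))
    }, character(1), USE.NAMES = FALSE)
    cs <- vapply(base$word, function(w) {
      make_consonant_string(w, mode = cs_mode, lex = word_lexicon, vowels = vowels)
    }, character(1), USE.NAMES = FALSE)
    out <- stimulus_set(
      string = c(base$word, pw, cs, rep(NA_character_, n_sl)),
      category = c(rep("W", nrow(base)), rep("PW", nrow(base)),
                   rep("CS", nrow(base)), rep("SL", n_sl)),
      base_word = c(rep(NA_character_, nrow(base)), base$word, base$word,
                    rep(NA_character_, n_sl)),
      frequency = c(base$frequency, numeric(2 * nrow(base) + n_sl)),
      provenance = list(lexicon = attr(word_lexicon, "name"), seed = seed,
                        legality = legality, cs_mode = cs_mode))
    out
  })
}

#' Greedy covariate matching between two item groups
#'
#' Pairs items of `a` with items of `b` by greedy nearest-neighbor search
#' on standardized feature vectors, without replacement: the globally
#' closest pair is taken first, then the closest among the remainder, and
#' so on until `n_pairs` pairs are formed. Used to build matched
#' word/pseudoword benchmark conditions.
#'
#' @param a,b Data frames carrying all columns named in `features`.
#' @param features Character vector of feature column names.
#' @param n_pairs Number of pairs to return; must not exceed the smaller
#'   group size.
#' @return List with `pairs` (data frame of row indices `a_row`, `b_row`
#'   and the pair distance) and `balance` (per-feature standardized mean
#'   difference of the matched groups).
#' @export
match_groups <- function(a, b, features, n_pairs = min(nrow(a), nrow(b))) {
  stopifnot(all(features %in% names(a)), all(features %in% names(b)))
  if (n_pairs > min(nrow(a), nrow(b))) {
    stop(sprintf("n_pairs = %d exceeds the smaller group size (%d)",
                 n_pairs, min(nrow(a), nrow(b))), call. = FALSE)
  }
  fa <- as.matrix(a[, features, drop = FALSE])
  fb <- as.matrix(b[, features, drop = FALSE])
  pooled <- rbind(fa, fb)
  mu <- colMeans(pooled)
  sdv <- apply(pooled, 2, stats::sd)
  sdv[sdv == 0] <- 1  # constant feature carries no matching information
  za <- sweep(sweep(fa, 2, mu), 2, sdv, "/")
  zb <- sweep(sweep(fb, 2, mu), 2, sdv, "/")
  d <- as.matrix(stats::dist(rbind(za, zb)))[seq_len(nrow(za)),
                                             nrow(za) + seq_len(nrow(zb)),
                                             drop = FALSE]
  a_rows <- integer(n_pairs); b_rows <- integer(n_pairs); dist_k <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    idx <- arrayInd(which.min(d), dim(d))
    a_rows[k] <- idx[1]; b_rows[k] <- idx[2]; dist_k[k] <- d[idx]
    d[idx[1], ] <- Inf
    d[, idx[2]] <- Inf
  }
  ma <- fa[a_rows, , drop = FALSE]
  mb <- fb[b_rows, , drop = FALSE]
  smd <- (colMeans(ma) - colMeans(mb)) / sdv
  list(pairs = data.frame(a_row = a_rows, b_row = b_rows, distance = dist_k),
       balance = smd)
}
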