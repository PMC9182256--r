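test_that("make_pseudoword substitutes vowels and avoids the lexicon", {
  lex <- toy_lexicon()
  vowels <- lexcat_vowels()
  set.seed(1)
  for (i in 1:200) {
    w <- sample(c("Augen", "Leben", "Rosen"), 1)
    pw <- make_pseudoword(w, lex, legality = "none")
    expect_equal(nchar(pw), nchar(w))
    expect_false(pw %in% lex$word)
    wc <- strsplit(w, "")[[1]]; pc <- strsplit(pw, "")[[1]]
    changed <- which(wc != pc)
    expect_gte(length(changed), 1)
    # only vowel positions change, and vowels stay vowels
    expect_true(all(wc[changed] %in% vowels))
    expect_true(all(pc[changed] %in% vowels))
  }
})

test_that("bigram-attested legality admits only attested bigrams", {
  lex <- toy_lexicon()
  attested <- character(0)
  for (w in lex$word) {
    st <- seq_len(nchar(w) - 1)
    attested <- union(attested, substring(w, st, st + 1))
  }
  set.seed(2)
  for (i in 1:50) {
    pw <- make_pseudoword("Lagen", lex, legality = "bigram-attested")
    st <- seq_len(nchar(pw) - 1)
    expect_true(all(substring(pw, st, st + 1) %in% attested))
  }
})

test_that("make_pseudoword rejects vowel-free words and exhausted spaces", {
  lex <- toy_lexicon()
  expect_error(make_pseudoword("BCDFG", lex), "no vowel")
  # a one-vowel word whose every substitution is itself a lexicon word
  tight <- lexicon(c("Bat", "Bet", "Bit", "Bot", "But", "Bät", "Böt", "Büt"),
                   rep(1, 8))
  set.seed(3)
  expect_error(make_pseudoword("Bat", tight, legality = "none"), "admissible")
  # strict attestation errors when no substitution is bigram-legal;
  # best-effort falls back to a non-member candidate
  iso <- lexicon(c("Bat", "Xyz", "Qrs"), c(1, 1, 1))
  set.seed(3)
  expect_error(make_pseudoword("Bat", iso, legality = "bigram-attested"),
               "bigram")
  pw <- make_pseudoword("Bat", iso, legality = "bigram-preferred")
  expect_false(pw %in% iso$word)
})

test_that("make_consonant_string removes every vowel and keeps the skeleton", {
  set.seed(4)
  vowels <- lexcat_vowels()
  for (i in 1:100) {
    cs <- make_consonant_string("Augen")
    expect_equal(nchar(cs), 5)
    expect_false(any(strsplit(cs, "")[[1]] %in% vowels))
    # non-vowel positions are untouched: "??g?n" pattern
    expect_equal(substr(cs, 3, 3), "g")
    expect_equal(substr(cs, 5, 5), "n")
  }
  expect_error(make_consonant_string("Augen", mode = "letter-frequency-matched"),
               "requires a lexicon")
  set.seed(5)
  cs <- make_consonant_string("Augen", mode = "letter-frequency-matched",
                              lex = toy_lexicon())
  expect_false(any(strsplit(cs, "")[[1]] %in% vowels))
})

test_that("build_stimulus_set balances categories and is seed-deterministic", {
  lex <- synth_lexicon(10, 5, seed = 12)
  set_a <- build_stimulus_set(lex, seed = 7)
  expect_equal(unname(table(set_a$category)[c("W", "PW", "CS")]),
               rep(10L, 3), ignore_attr = TRUE)
  set_b <- build_stimulus_set(lex, seed = 7)
  expect_identical(as.data.frame(set_a), as.data.frame(set_b))
  # vowel-free base words are skipped with a warning, balance preserved
  mixed <- lexicon(c(lex$word, "Bcdfg"), c(lex$frequency, 1))
  expect_warning(set_c <- build_stimulus_set(mixed, seed = 7), "vowel-free")
  expect_equal(sum(set_c$category == "W"), sum(set_c$category == "PW"))
  expect_equal(sum(set_c$category == "W"), sum(set_c$category == "CS"))
  # derived items carry their base word and zero frequency
  pw_rows <- set_a[set_a$category == "PW", ]
  expect_true(all(pw_rows$base_word %in% lex$word))
  expect_true(all(pw_rows$frequency == 0))
})

test_that("generated stimulus items satisfy the category invariants over seeds", {
  lex <- synth_lexicon(30, 5, seed = 13)
  vowels <- lexcat_vowels()
  for (s in 1:5) {
    st <- build_stimulus_set(lex, seed = s)
    pw <- st[st$category == "PW", ]
    cs <- st[st$category == "CS", ]
    expect_false(any(pw$string %in% lex$word))
    expect_false(any(cs$string %in% lex$word))
    expect_true(all(!vapply(strsplit(cs$string, ""),
                            function(ch) any(ch %in% vowels), logical(1))))
    # pseudowords differ from their base only at vowel positions
    for (j in seq_len(nrow(pw))) {
      wc <- strsplit(pw$base_word[j], "")[[1]]
      pc <- strsplit(pw$string[j], "")[[1]]
      ch <- which(wc != pc)
      expect_true(all(wc[ch] %in% vowels) && all(pc[ch] %in% vowels))
    }
  }
})

test_that("match_groups pairs identical groups perfectly", {
  a <- data.frame(f1 = c(1, 5, 9, 2), f2 = c(0, 1, 0, 1))
  m <- match_groups(a, a, features = c("f1", "f2"))
  expect_equal(sort(m$pairs$a_row), 1:4)
  expect_equal(m$pairs$a_row, m$pairs$b_row)
  expect_equal(unname(m$balance), c(0, 0))
  expect_equal(m$pairs$distance, rep(0, 4))
})

test_that("greedy matching on a line recovers the sorted-order pairing", {
  # frozen instance checked by exhaustive enumeration of all 3! pairings:
  # sorted-order pairing (1-2, 5-6, 9-10) minimizes total distance and is
  # what the greedy matcher returns here
  a <- data.frame(x = c(9, 1, 5))
  b <- data.frame(x = c(6, 10, 2))
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  total <- vapply(perms, function(p) sum(abs(a$x - b$x[p])), numeric(1))
  best <- perms[[which.min(total)]]
  m <- match_groups(a, b, features = "x")
  got <- m$pairs$b_row[order(m$pairs$a_row)]
  expect_equal(got, best)
  expect_error(match_groups(a, b, "x", n_pairs = 4), "exceeds")
})
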