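# Internal helpers shared across modules.

# German orthography defaults; configurable via function arguments where
# other alphabets matter.
.VOWELS_UPPER <- c("A", "E", "I", "O", "U", "Ä", "Ö", "Ü")
.CONSONANTS_UPPER <- setdiff(LETTERS, c("A", "E", "I", "O", "U"))

#' Vowel and consonant inventories
#'
#' The default German inventories used by the stimulus generators: vowels
#' AEIOU plus umlauts (and lowercase counterparts); consonants are the
#' remaining base letters. Pass other inventories to the generator
#' functions for other orthographies.
#'
#' @param case `"both"`, `"upper"`, or `"lower"`.
#' @return Character vector of single letters.
#' @export
lexcat_vowels <- function(case = c("both", "upper", "lower")) {
  case <- match.arg(case)
  up <- .VOWELS_UPPER
  lo <- tolower(up)
  switch(case, both = c(up, lo), upper = up, lower = lo)
}

#' @rdname lexcat_vowels
#' @export
lexcat_consonants <- function(case = c("both", "upper", "lower")) {
  case <- match.arg(case)
  up <- .CONSONANTS_UPPER
  lo <- tolower(up)
  switch(case, both = c(up, lo), upper = up, lower = lo)
}

is_vowel_char <- function(chars) chars %in% lexcat_vowels("both")

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so library code never disturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Round half away from zero (printed probabilities in the source
# literature use this convention, unlike base R's round-half-even).
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Split strings into per-character matrices padded with NA.
str_chars <- function(s) strsplit(s, "", fixed = TRUE)

min_max <- function(x) {
  r <- range(x, finite = TRUE)
  if (!all(is.finite(r)) || r[1] == r[2]) {
    stop("cannot min-max normalize a constant or non-finite vector",
         call. = FALSE)
  }
  (x - r[1]) / (r[2] - r[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
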