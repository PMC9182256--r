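#' Edit distance between two letter strings
#'
#' Minimal number of single-character insertions, deletions, and
#' substitutions (plus adjacent transpositions under
#' `variant = "osa-transposition"`) converting `a` into `b`. The plain
#' Levenshtein variant is a true metric; the optimal-string-alignment
#' transposition variant is not (it can violate the triangle inequality)
#' and is provided because descriptions of orthographic distance in the
#' word-recognition literature sometimes include adjacent-letter
#' transpositions.
#'
#' @param a,b Non-empty strings.
#' @param variant `"levenshtein"` (default) or `"osa-transposition"`.
#' @return Non-negative integer distance.
#' @examples
#' edit_distance("Augen", "Augon")            # 1
#' edit_distance("AB", "BA")                  # 2
#' edit_distance("AB", "BA", "osa-transposition")  # 1
#' @export
edit_distance <- function(a, b, variant = c("levenshtein", "osa-transposition")) {
  variant <- match.arg(variant)
  stopifnot(is.character(a), is.character(b), length(a) == 1, length(b) == 1,
            nzchar(a), nzchar(b))
  .edit_distance1(utf8ToInt(a), utf8ToInt(b), osa = variant == "osa-transposition")
}

# Dynamic program over integer code points; rolling two (three for OSA)
# row storage.
.edit_distance1 <- function(x, y, osa = FALSE) {
  n <- length(x); m <- length(y)
  prev2 <- NULL
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cost <- if (x[i] == y[j]) 0L else 1L
      d <- min(prev[j + 1L] + 1L,   # deletion
               cur[j] + 1L,         # insertion
               prev[j] + cost)      # substitution / match
      if (osa && i > 1L && j > 1L &&
          x[i] == y[j - 1L] && x[i - 1L] == y[j]) {
        d <- min(d, prev2[j - 1L] + 1L)  # adjacent transposition
      }
      cur[j + 1L] <- d
    }
    prev2 <- prev
    prev <- cur
  }
  prev[m + 1L]
}

# Distances from one query string to a character vector of candidates.
# The Levenshtein variant dispatches to utils::adist (C implementation of
# the same insert/delete/substitute lattice); the transposition variant
# runs the R dynamic program per candidate.
string_distances <- function(s, candidates,
                             variant = c("levenshtein", "osa-transposition")) {
  variant <- match.arg(variant)
  if (length(candidates) == 0) return(integer(0))
  if (variant == "levenshtein") {
    as.integer(utils::adist(s, candidates)[1L, ])
  } else {
    sx <- utf8ToInt(s)
    vapply(candidates, function(w) .edit_distance1(sx, utf8ToInt(w), osa = TRUE),
           integer(1), USE.NAMES = FALSE)
  }
}
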