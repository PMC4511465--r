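#' Porter stem of a word
#'
#' Deterministic English suffix-stripping (the classic Porter algorithm).
#' Input is lowercased first; the all-caps protein placeholder `"PROT"` is
#' returned unchanged so masked tokens keep their distinguished surface.
#'
#' @param words character vector.
#' @return character vector of stems, same length.
#' @examples
#' porter_stem(c("regulation", "requires", "expression"))
#' @export
porter_stem <- function(words) {
  vapply(words, function(w) {
    if (identical(w, "PROT")) return("PROT")
    stem1(tolower(w))
  }, "", USE.NAMES = FALSE)
}

# --- Porter (1980) implementation -----------------------------------------
# Regions are measured with the usual m = number of VC sequences; 'y' is a
# consonant at word start or after a vowel.

.is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.is_cons(chars, i - 1L))
  }
  TRUE
}

.measure <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  n <- length(chars)
  if (n == 0L) return(0L)
  cons <- vapply(seq_len(n), function(i) .is_cons(chars, i), TRUE)
  # collapse runs, count VC transitions
  runs <- rle(cons)$values
  sum(runs[-length(runs)] == FALSE & runs[-1] == TRUE)
}

.has_vowel <- function(stem) {
  chars <- strsplit(stem, "")[[1]]
  any(!vapply(seq_along(chars), function(i) .is_cons(chars, i), TRUE))
}

.double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L); b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  chars <- strsplit(stem, "")[[1]]
  .is_cons(chars, n)
}

# *o condition: stem ends cvc where final c is not w, x or y
.cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  chars <- strsplit(stem, "")[[1]]
  if (!.is_cons(chars, n) || .is_cons(chars, n - 1L) || !.is_cons(chars, n - 2L))
    return(FALSE)
  !(chars[n] %in% c("w", "x", "y"))
}

.ends <- function(w, s) {
  nchar(w) >= nchar(s) &&
    substr(w, nchar(w) - nchar(s) + 1L, nchar(w)) == s
}

.chop <- function(w, s) substr(w, 1L, nchar(w) - nchar(s))

stem1 <- function(w) {
  if (nchar(w) <= 2L) return(w)

  # step 1a
  if (.ends(w, "sses")) w <- .chop(w, "es")
  else if (.ends(w, "ies")) w <- paste0(.chop(w, "ies"), "i")
  else if (!.ends(w, "ss") && .ends(w, "s")) w <- .chop(w, "s")

  # step 1b
  if (.ends(w, "eed")) {
    if (.measure(.chop(w, "eed")) > 0L) w <- .chop(w, "d")
  } else {
    done <- FALSE
    if (.ends(w, "ed") && .has_vowel(.chop(w, "ed"))) {
      w <- .chop(w, "ed"); done <- TRUE
    } else if (.ends(w, "ing") && .has_vowel(.chop(w, "ing"))) {
      w <- .chop(w, "ing"); done <- TRUE
    }
    if (done) {
      if (.ends(w, "at") || .ends(w, "bl") || .ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.double_cons(w) &&
                 !(.ends(w, "l") || .ends(w, "s") || .ends(w, "z"))) {
        w <- substr(w, 1L, nchar(w) - 1L)
      } else if (.measure(w) == 1L && .cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }

  # step 1c
  if (.ends(w, "y") && .has_vowel(.chop(w, "y")))
    w <- paste0(.chop(w, "y"), "i")

  # step 2
  s2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
          izer = "ize", abli = "able", alli = "al", entli = "ent",
          eli = "e", ousli = "ous", ization = "ize", ation = "ate",
          ator = "ate", alism = "al", iveness = "ive", fulness = "ful",
          ousness = "ous", aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(s2)) {
    if (.ends(w, suf)) {
      base <- .chop(w, suf)
      if (.measure(base) > 0L) w <- paste0(base, s2[[suf]])
      break
    }
  }

  # step 3
  s3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic",
          ical = "ic", ful = "", ness = "")
  for (suf in names(s3)) {
    if (.ends(w, suf)) {
      base <- .chop(w, suf)
      if (.measure(base) > 0L) w <- paste0(base, s3[[suf]])
      break
    }
  }

  # step 4
  s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
          "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive",
          "ize")
  for (suf in s4) {
    if (.ends(w, suf)) {
      base <- .chop(w, suf)
      if (suf == "ion" &&
          !(.ends(base, "s") || .ends(base, "t"))) next
      if (.measure(base) > 1L) w <- base
      break
    }
  }

  # step 5a
  if (.ends(w, "e")) {
    base <- .chop(w, "e")
    m <- .measure(base)
    if (m > 1L || (m == 1L && !.cvc(base))) w <- base
  }
  # step 5b
  if (.double_cons(w) && .ends(w, "l") && .measure(w) > 1L)
    w <- substr(w, 1L, nchar(w) - 1L)

  w
}
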