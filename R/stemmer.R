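#' Porter stemmer
#'
#' Reduces English words to stems with the classic Porter (1980) suffix
#' stripping algorithm. Used both for the `STEM` tokenization mode and for
#' the order-insensitive, derivation-tolerant matching of lexicon terms
#' against text, where two surface forms are conflated when their stem
#' multisets agree.
#'
#' @param words character vector of lowercase words.
#' @return character vector of stems, same length as `words`.
#' @examples
#' porter_stem(c("injuries", "replacement", "tenderness"))
#' @export
porter_stem <- function(words) {
  stopifnot(is.character(words))
  vapply(words, porter_stem1, character(1), USE.NAMES = FALSE)
}

# --- single-word implementation -------------------------------------------

# consonant/vowel map: y is a vowel iff preceded by a consonant
.cv_map <- function(chars) {
  n <- length(chars)
  cons <- logical(n)
  for (i in seq_len(n)) {
    ch <- chars[i]
    if (ch %in% c("a", "e", "i", "o", "u")) {
      cons[i] <- FALSE
    } else if (ch == "y") {
      cons[i] <- if (i == 1L) TRUE else !cons[i - 1L]
    } else {
      cons[i] <- TRUE
    }
  }
  cons
}

# measure m of a stem: number of VC sequences in [C](VC)^m[V]
.measure <- function(stem) {
  if (nchar(stem) == 0L) return(0L)
  cons <- .cv_map(strsplit(stem, "", fixed = TRUE)[[1]])
  rle_k <- rle(cons)$values
  # count transitions vowel -> consonant
  sum(rle_k[-length(rle_k)] == FALSE & rle_k[-1] == TRUE)
}

.has_vowel <- function(stem) {
  if (nchar(stem) == 0L) return(FALSE)
  any(!.cv_map(strsplit(stem, "", fixed = TRUE)[[1]]))
}

.ends_double_cons <- function(w) {
  n <- nchar(w)
  if (n < 2L) return(FALSE)
  a <- substr(w, n - 1L, n - 1L)
  b <- substr(w, n, n)
  if (a != b) return(FALSE)
  cons <- .cv_map(strsplit(w, "", fixed = TRUE)[[1]])
  cons[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.ends_cvc <- function(w) {
  n <- nchar(w)
  if (n < 3L) return(FALSE)
  cons <- .cv_map(strsplit(w, "", fixed = TRUE)[[1]])
  last <- substr(w, n, n)
  cons[n - 2L] && !cons[n - 1L] && cons[n] && !(last %in% c("w", "x", "y"))
}

.ends_with <- function(w, suf) {
  nw <- nchar(w); ns <- nchar(suf)
  nw >= ns && substr(w, nw - ns + 1L, nw) == suf
}

.chop <- function(w, k) substr(w, 1L, nchar(w) - k)

porter_stem1 <- function(w) {
  if (nchar(w) <= 2L) return(w)
  if (!grepl("^[a-z]+$", w)) return(w)  # leave codes/numbers untouched

  # Step 1a
  if (.ends_with(w, "sses")) w <- .chop(w, 2L)
  else if (.ends_with(w, "ies")) w <- .chop(w, 2L)
  else if (.ends_with(w, "ss")) w <- w
  else if (.ends_with(w, "s")) w <- .chop(w, 1L)

  # Step 1b
  step1b_cleanup <- FALSE
  if (.ends_with(w, "eed")) {
    if (.measure(.chop(w, 3L)) > 0L) w <- .chop(w, 1L)
  } else if (.ends_with(w, "ed")) {
    if (.has_vowel(.chop(w, 2L))) { w <- .chop(w, 2L); step1b_cleanup <- TRUE }
  } else if (.ends_with(w, "ing")) {
    if (.has_vowel(.chop(w, 3L))) { w <- .chop(w, 3L); step1b_cleanup <- TRUE }
  }
  if (step1b_cleanup) {
    if (.ends_with(w, "at") || .ends_with(w, "bl") || .ends_with(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.ends_double_cons(w) &&
               !(substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z"))) {
      w <- .chop(w, 1L)
    } else if (.measure(w) == 1L && .ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }

  # Step 1c
  if (.ends_with(w, "y") && .has_vowel(.chop(w, 1L))) {
    w <- paste0(.chop(w, 1L), "i")
  }

  # Step 2 (m > 0)
  s2 <- c(ational = "ate", tional = "tion", enci = "ence", anci = "ance",
          izer = "ize", abli = "able", alli = "al", entli = "ent", eli = "e",
          ousli = "ous", ization = "ize", ation = "ate", ator = "ate",
          alism = "al", iveness = "ive", fulness = "ful", ousness = "ous",
          aliti = "al", iviti = "ive", biliti = "ble")
  for (suf in names(s2)) {
    if (.ends_with(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.measure(stem) > 0L) w <- paste0(stem, s2[[suf]])
      break
    }
  }

  # Step 3 (m > 0)
  s3 <- c(icate = "ic", ative = "", alize = "al", iciti = "ic", ical = "ic",
          ful = "", ness = "")
  for (suf in names(s3)) {
    if (.ends_with(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (.measure(stem) > 0L) w <- paste0(stem, s3[[suf]])
      break
    }
  }

  # Step 4 (m > 1)
  s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
          "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize")
  for (suf in s4) {
    if (.ends_with(w, suf)) {
      stem <- .chop(w, nchar(suf))
      if (suf == "ion" &&
          !(substr(stem, nchar(stem), nchar(stem)) %in% c("s", "t"))) break
      if (.measure(stem) > 1L) w <- stem
      break
    }
  }

  # Step 5a
  if (.ends_with(w, "e")) {
    stem <- .chop(w, 1L)
    m <- .measure(stem)
    if (m > 1L || (m == 1L && !.ends_cvc(stem))) w <- stem
  }
  # Step 5b
  if (.measure(w) > 1L && .ends_double_cons(w) &&
      .ends_with(w, "l")) {
    w <- .chop(w, 1L)
  }
  w
}
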