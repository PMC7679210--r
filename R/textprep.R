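#' @useDynLib lettertopics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbinom rgamma rmultinom rnbinom runif uniroot setNames
#'   quantile sd
#' @importFrom utils head read.delim write.csv combn
NULL

#' Reserved surface form of the personal-name mask token
#'
#' Honorific-triggered name sequences are replaced by this single token so
#' that personal names can never emerge as topic descriptors. It is purely
#' alphabetic, so it survives punctuation normalization and tokenization,
#' and it is excluded from the topic-model vocabulary by default.
#'
#' @return a single string.
#' @export
person_mask_token <- function() "zzperson"

#' Construct a raw referral letter
#'
#' @param id opaque document identifier, unique within a corpus.
#' @param text free text of the letter; must be non-empty after whitespace
#'   stripping.
#' @param treatments optional character vector of treatment codes (O1..O9).
#' @return an object of class `raw_letter`.
#' @export
raw_letter <- function(id, text, treatments = character()) {
  if (length(text) != 1L || is.na(text) || !nzchar(trimws(text))) {
    stop("empty_letter: letter text must be non-empty", call. = FALSE)
  }
  structure(list(id = as.character(id), text = text,
                 treatments = as.character(treatments)),
            class = "raw_letter")
}

#' @export
print.raw_letter <- function(x, ...) {
  cat(sprintf("<raw_letter %s: %d chars>\n", x$id, nchar(x$text)))
  invisible(x)
}

.extdata <- function(file) {
  system.file("extdata", file, package = "lettertopics", mustWork = TRUE)
}

# memoize shipped configuration tables (they are read once per session)
.cfg_cache <- new.env(parent = emptyenv())
.cached <- function(key, compute) {
  if (!exists(key, envir = .cfg_cache)) {
    assign(key, compute(), envir = .cfg_cache)
  }
  get(key, envir = .cfg_cache)
}

#' Read a variant lexicon (surface form to canonical representative)
#'
#' Two-column tab-separated file: surface TAB canonical. Lines starting
#' with `#` are comments. Keys are case-insensitive (stored lowercase)
#' and mappings are one-step: a canonical form may not itself be a key.
#'
#' @param path path to the TSV file.
#' @return a named character vector (names = surface keys, values =
#'   canonical forms), class `variant_lexicon`.
#' @export
read_variant_lexicon <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed variant lexicon line(s): ",
                     paste(which(bad), collapse = ", "), call. = FALSE)
  keys <- tolower(trimws(vapply(parts, `[[`, "", 1L)))
  vals <- tolower(trimws(vapply(parts, `[[`, "", 2L)))
  variant_lexicon(setNames(vals, keys))
}

#' @rdname read_variant_lexicon
#' @param entries named character vector mapping surface keys to canonical
#'   forms.
#' @export
variant_lexicon <- function(entries) {
  keys <- names(entries)
  if (anyDuplicated(keys)) stop("duplicate variant lexicon keys", call. = FALSE)
  if (any(entries %in% keys)) {
    stop("variant lexicon must be one-step: canonical form(s) ",
         paste(unique(entries[entries %in% keys]), collapse = ", "),
         " are themselves keys", call. = FALSE)
  }
  structure(entries, class = "variant_lexicon")
}

# Default honorifics and patient-pattern triggers ship as editable files.
.default_honorifics <- function() {
  .cached("honorifics", function()
    readLines(.extdata("honorifics.txt"), warn = FALSE))
}
.default_patient_triggers <- function() {
  .cached("patient_triggers", function()
    readLines(.extdata("patient_triggers.txt"), warn = FALSE))
}

#' Mask personal names using honorific cues
#'
#' Referral letters use a formal register in which personal names follow
#' honorifics ("Dr Jane Doe", "Mrs Smith"). Capitalized name sequences
#' triggered by an honorific are replaced, honorific included, by one
#' reserved mask token ([person_mask_token()]). A second trigger family
#' catches patient-name patterns such as "Thank you for seeing John Smith".
#' Eponymous clinical terms with no honorific (Baker cyst, McMurray test)
#' are left untouched. Must run before lowercasing: capitalization is the
#' cue.
#'
#' @param letter a [raw_letter()].
#' @param honorifics character vector of honorific triggers.
#' @param patient_triggers character vector of phrase triggers preceding a
#'   patient name.
#' @return a `raw_letter` with names masked.
#' @export
mask_personal_names <- function(letter,
                                honorifics = .default_honorifics(),
                                patient_triggers = .default_patient_triggers()) {
  stopifnot(inherits(letter, "raw_letter"))
  txt <- letter$text
  mask <- person_mask_token()
  name_seq <- "(?:[A-Z][A-Za-z'-]+(?:\\s+[A-Z][A-Za-z'-]+){0,3})"
  hon <- paste0(gsub(".", "\\.", honorifics, fixed = TRUE), collapse = "|")
  # honorific (with optional period) + 1-4 capitalized words
  re_hon <- paste0("\\b(?:", hon, ")\\.?\\s+", name_seq)
  txt <- gsub(re_hon, mask, txt, perl = TRUE)
  # patient patterns: trigger phrase followed by a capitalized full name
  for (trig in patient_triggers) {
    re_pat <- paste0("(?<=\\b", trig, "\\s)",
                     "[A-Z][A-Za-z'-]+(?:\\s+[A-Z][A-Za-z'-]+){1,3}")
    txt <- gsub(re_pat, mask, txt, perl = TRUE, ignore.case = FALSE)
  }
  raw_letter(letter$id, txt, letter$treatments)
}

.enclitic_table <- function() {
  .cached("enclitics", function() {
    tab <- read.delim(.extdata("enclitics.tsv"), header = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE)
    setNames(tab[[2]], tab[[1]])
  })
}

.expand_enclitics <- function(txt) {
  tab <- .enclitic_table()
  for (k in names(tab)) {
    txt <- gsub(paste0("\\b", k, "\\b"), tab[[k]], txt, perl = TRUE)
  }
  # generic fallbacks
  txt <- gsub("(\\w)n't\\b", "\\1 not", txt, perl = TRUE)
  txt <- gsub("'re\\b", " are", txt, perl = TRUE)
  txt <- gsub("'ve\\b", " have", txt, perl = TRUE)
  txt <- gsub("'ll\\b", " will", txt, perl = TRUE)
  txt <- gsub("'m\\b", " am", txt, perl = TRUE)
  txt <- gsub("'s\\b", "", txt, perl = TRUE)  # residual possessives
  txt
}

#' Regularize the text of a referral letter
#'
#' Applies, in order: honorific-based personal-name masking (capitalization
#' is the cue, so this precedes lowercasing), lowercasing, enclitic
#' expansion, replacement of lexicon surface forms by their canonical
#' representatives (longest key first, whole-word), and punctuation
#' normalization (non-sentence-final punctuation becomes a single space;
#' `.`, `!`, `?` are kept as free-standing sentence marks). The operation
#' is idempotent.
#'
#' @param letter a [raw_letter()].
#' @param lex a [variant_lexicon()] (keys lowercase) or `NULL`.
#' @param mask mask personal names first? Set `FALSE` if the letter was
#'   already masked.
#' @return the regularized `raw_letter`.
#' @export
regularize <- function(letter, lex = NULL, mask = TRUE) {
  stopifnot(inherits(letter, "raw_letter"))
  if (mask) letter <- mask_personal_names(letter)
  txt <- tolower(letter$text)
  txt <- .expand_enclitics(txt)
  # punctuation: keep sentence-final marks, collapse runs, space them out
  txt <- gsub("[!?]", ".", txt)
  txt <- gsub("[^a-z0-9. ]+", " ", txt)
  txt <- gsub("\\.{2,}", ".", txt)
  txt <- gsub("\\.", " . ", txt)
  txt <- gsub("\\s+", " ", txt)
  txt <- trimws(txt)
  if (!is.null(lex)) {
    stopifnot(inherits(lex, "variant_lexicon"))
    keys <- names(lex)
    if (length(keys)) {
      keys <- keys[order(-nchar(keys), keys)]  # longest-first
      pat <- paste0("\\b(?:",
                    paste(gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", keys),
                          collapse = "|"), ")\\b")
      m <- gregexpr(pat, txt, perl = TRUE)[[1]]
      if (m[1] != -1L) {
        matched <- regmatches(txt, list(m))[[1]]
        regmatches(txt, list(m)) <- list(unname(unclass(lex)[matched]))
      }
    }
    txt <- gsub("\\s+", " ", txt)
  }
  if (!nzchar(trimws(gsub("[. ]", "", txt)))) {
    stop("empty_letter: no content remains after regularization",
         call. = FALSE)
  }
  raw_letter(letter$id, txt, letter$treatments)
}

.default_stopwords <- function() {
  .cached("stopwords", function()
    readLines(.extdata("stopwords_en.txt"), warn = FALSE))
}

.lemma_exceptions <- function() {
  .cached("lemma_exceptions", function() {
    tab <- read.delim(.extdata("lemma_exceptions.tsv"), header = FALSE,
                      comment.char = "#", stringsAsFactors = FALSE)
    setNames(tab[[2]], tab[[1]])
  })
}

#' Rule-plus-lookup English lemmatizer
#'
#' A lightweight lemmatizer: an exceptions table of irregular forms is
#' consulted first, then inflectional suffix rules (-ies/-es/-s plurals,
#' -ing/-ed verb forms with consonant-doubling and silent-e restoration).
#' Words it cannot analyse are returned unchanged.
#'
#' @param words character vector of lowercase words.
#' @return character vector of lemmas.
#' @export
lemmatize <- function(words) {
  exc <- .lemma_exceptions()
  out <- words
  hit <- words %in% names(exc)
  out[hit] <- exc[words[hit]]
  todo <- which(!hit & grepl("^[a-z]+$", words))
  for (i in todo) {
    w <- words[i]
    n <- nchar(w)
    if (n > 4L && grepl("ies$", w)) {
      out[i] <- sub("ies$", "y", w)
    } else if (n > 4L && grepl("(ss|sh|ch|x|z)es$", w)) {
      out[i] <- sub("es$", "", w)
    } else if (n > 3L && grepl("[^su]s$", w)) {
      out[i] <- sub("s$", "", w)
    } else if (n > 5L && grepl("([b-df-hj-np-tv-z])\\1ing$", w)) {
      out[i] <- sub("(.)\\1ing$", "\\1", w)
    } else if (n > 5L && grepl("[b-df-hj-np-tv-z]ing$", w)) {
      base <- sub("ing$", "", w)
      out[i] <- if (grepl("[b-df-hj-np-tv-z][aeiou][b-df-hj-np-tv-z]$", base) &&
                    !grepl("[aeiou][aeiou][b-df-hj-np-tv-z]$", base))
        paste0(base, "e") else base
    } else if (n > 4L && grepl("([b-df-hj-np-tv-z])\\1ed$", w)) {
      out[i] <- sub("(.)\\1ed$", "\\1", w)
    } else if (n > 4L && grepl("ied$", w)) {
      out[i] <- sub("ied$", "y", w)
    } else if (n > 4L && grepl("[b-df-hj-np-tv-z]ed$", w)) {
      out[i] <- sub("ed$", "", w)
    }
  }
  out
}

#' Tokenize a regularized letter into a token stream
#'
#' Splits the regularized text on whitespace, drops sentence marks and
#' stop-words, reduces each word according to `mode` (Porter stemming or
#' dictionary lemmatization), and records the character span of every
#' surviving token in the regularized text (0-based, half-open). Sentence
#' boundaries are retained as an attribute so coherence can use
#' sentence-sized virtual documents.
#'
#' @param letter a regularized [raw_letter()].
#' @param mode `"stem"` or `"lemma"`.
#' @param stopwords character vector of stop-words to drop. The shipped
#'   default is a standard English list minus clinical negation cues
#'   ("no", "not").
#' @param keep_mask keep the personal-name mask token in the stream?
#' @return a `token_stream`: list with `doc_id`, `tokens` (data.frame with
#'   columns surface, kind, start, end), attribute `sentence_id`.
#' @export
tokenize <- function(letter, mode = c("stem", "lemma"),
                     stopwords = .default_stopwords(), keep_mask = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(letter, "raw_letter"))
  txt <- letter$text
  m <- gregexpr("[^ ]+", txt)[[1]]
  if (m[1] == -1L) {
    return(token_stream(letter$id, character(), character(),
                        integer(), integer(), integer()))
  }
  raw <- regmatches(txt, list(m))[[1]]
  start <- as.integer(m) - 1L             # 0-based
  end <- start + attr(m, "match.length")  # half-open
  sent <- cumsum(raw == ".")
  sent <- c(0L, sent[-length(sent)])      # id of sentence each token is in
  keep <- raw != "." & !(raw %in% stopwords)
  if (!keep_mask) keep <- keep & raw != person_mask_token()
  raw <- raw[keep]; start <- start[keep]; end <- end[keep]; sent <- sent[keep]
  u <- unique(raw)
  red <- if (mode == "stem") porter_stem(u) else lemmatize(u)
  surf <- red[match(raw, u)]
  kind <- ifelse(raw == person_mask_token(), "PERSON_MASK", "WORD")
  surf[kind == "PERSON_MASK"] <- person_mask_token()
  token_stream(letter$id, surf, kind, start, end, sent)
}

#' Construct a token stream
#'
#' @param doc_id document identifier.
#' @param surface lowercase token surfaces.
#' @param kind one of WORD, CONCEPT, SEMTYPE, PERSON_MASK per token.
#' @param start,end 0-based half-open character spans into the regularized
#'   text (CONCEPT/SEMTYPE tokens inherit the span of their match).
#' @param sentence_id integer sentence index per token.
#' @return an object of class `token_stream`.
#' @export
token_stream <- function(doc_id, surface, kind, start, end,
                         sentence_id = integer(length(surface))) {
  stopifnot(length(surface) == length(kind),
            length(surface) == length(start),
            length(surface) == length(end))
  if (length(start) > 1L && any(diff(start) < 0L)) {
    stop("token spans must be non-decreasing by start", call. = FALSE)
  }
  tok <- data.frame(surface = as.character(surface),
                    kind = as.character(kind),
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  structure(list(doc_id = as.character(doc_id), tokens = tok),
            sentence_id = as.integer(sentence_id), class = "token_stream")
}

#' @export
print.token_stream <- function(x, ...) {
  cat(sprintf("<token_stream %s: %d tokens>\n", x$doc_id, nrow(x$tokens)))
  if (nrow(x$tokens)) print(head(x$tokens, 10L))
  invisible(x)
}

#' Read a corpus of referral letters
#'
#' Accepts either a directory of UTF-8 `.txt` files (one letter each, file
#' name minus extension is the id) or a JSON-lines file with fields
#' `id`, `text` and optional `treatments`.
#'
#' @param path directory or `.jsonl` file.
#' @return list of [raw_letter()] objects.
#' @export
read_corpus <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
    if (!length(files)) stop("no .txt files in ", path, call. = FALSE)
    letters <- lapply(files, function(f) {
      raw_letter(sub("\\.txt$", "", basename(f)),
                 paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                       collapse = "\n"))
    })
  } else {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    letters <- lapply(lines, function(l) {
      rec <- jsonlite::fromJSON(l)
      raw_letter(rec$id, rec$text,
                 if (!is.null(rec$treatments)) unlist(rec$treatments)
                 else character())
    })
  }
  ids <- vapply(letters, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate letter ids", call. = FALSE)
  letters
}

#' Write a corpus as JSON-lines
#'
#' @param letters list of [raw_letter()] objects.
#' @param path output file.
#' @export
write_corpus_jsonl <- function(letters, path) {
  lines <- vapply(letters, function(l) {
    jsonlite::toJSON(list(id = l$id, text = l$text,
                          treatments = l$treatments),
                     auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Prepare a whole corpus: mask, regularize, tokenize
#'
#' @param letters list of [raw_letter()].
#' @param lex optional [variant_lexicon()].
#' @param mode `"stem"` or `"lemma"`.
#' @param ... passed to [tokenize()].
#' @return list of `token_stream`.
#' @export
prepare_corpus <- function(letters, lex = NULL, mode = "stem", ...) {
  lapply(letters, function(l) tokenize(regularize(l, lex), mode = mode, ...))
}
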