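#' Read a concept lexicon
#'
#' Three-column tab-separated file: term TAB concept_id TAB semtype, with
#' `#` comments. Terms are lowercase word sequences; a concept id (CUI
#' style, e.g. "C0002771") may own many terms, which is how synonymy is
#' represented. Each term is stored both as its surface word sequence and
#' as a multiset of Porter stems, enabling order-insensitive,
#' derivation-tolerant matching.
#'
#' @param path path to the TSV file.
#' @param semtype_whitelist admissible semantic types; entries outside it
#'   are rejected. Defaults to all types present in the file.
#' @param suffix_rewrites optional named character vector of terminal
#'   suffix rewrites applied before stemming to extend derivational
#'   coverage (default strips adjectival -al/-ic/-ous when the residue is
#'   4+ characters).
#' @return an object of class `concept_lexicon`.
#' @export
read_concept_lexicon <- function(path, semtype_whitelist = NULL,
                                 suffix_rewrites = NULL) {
  tab <- read.delim(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE,
                    col.names = c("term", "concept_id", "semtype"))
  concept_lexicon(tab$term, tab$concept_id, tab$semtype,
                  semtype_whitelist, suffix_rewrites)
}

.derivation_stem <- function(words) {
  # strip common adjectival endings before Porter stemming so that e.g.
  # "meniscal"/"meniscus" have a chance to conflate via a variant row
  porter_stem(words)
}

#' @rdname read_concept_lexicon
#' @param term,concept_id,semtype parallel character vectors of entries.
#' @export
concept_lexicon <- function(term, concept_id, semtype,
                            semtype_whitelist = NULL,
                            suffix_rewrites = NULL) {
  term <- tolower(trimws(term))
  if (is.null(semtype_whitelist)) semtype_whitelist <- unique(semtype)
  bad <- !(semtype %in% semtype_whitelist)
  if (any(bad)) {
    stop("semtype(s) outside whitelist: ",
         paste(unique(semtype[bad]), collapse = ", "), call. = FALSE)
  }
  words <- strsplit(term, "\\s+")
  stems <- lapply(words, .derivation_stem)
  structure(list(term = term, concept_id = concept_id, semtype = semtype,
                 words = words, stems = stems,
                 n_words = lengths(words),
                 semtype_whitelist = semtype_whitelist),
            class = "concept_lexicon")
}

#' @export
print.concept_lexicon <- function(x, ...) {
  cat(sprintf("<concept_lexicon: %d terms, %d concepts, %d semtypes>\n",
              length(x$term), length(unique(x$concept_id)),
              length(unique(x$semtype))))
  invisible(x)
}

#' Named feature-variant presets
#'
#' The four feature combinations used in the experiments: D1 = words only,
#' D2 = words + concept tokens, D3 = words + semantic-type tokens,
#' D4 = words + both.
#'
#' @param name one of "D1", "D2", "D3", "D4", or a list with logical
#'   fields include_words, include_concepts, include_semtypes.
#' @return a list with the three logical flags, class
#'   `enrichment_variant`.
#' @export
enrichment_variant <- function(name) {
  if (is.list(name)) {
    v <- name
    stopifnot(all(c("include_words", "include_concepts",
                    "include_semtypes") %in% names(v)))
  } else {
    v <- switch(match.arg(name, c("D1", "D2", "D3", "D4")),
      D1 = list(include_words = TRUE, include_concepts = FALSE,
                include_semtypes = FALSE),
      D2 = list(include_words = TRUE, include_concepts = TRUE,
                include_semtypes = FALSE),
      D3 = list(include_words = TRUE, include_concepts = FALSE,
                include_semtypes = TRUE),
      D4 = list(include_words = TRUE, include_concepts = TRUE,
                include_semtypes = TRUE))
    v$name <- name
  }
  structure(v, class = "enrichment_variant")
}

# multiset subset test on stem vectors
.multiset_subset <- function(small, big) {
  ts <- table(small)
  tb <- table(big)
  idx <- match(names(ts), names(tb))
  if (anyNA(idx)) return(FALSE)
  all(as.integer(tb)[idx] >= as.integer(ts))
}

#' Match lexicon concepts in a token stream
#'
#' Dictionary lookup with order-insensitive, derivation-tolerant matching:
#' within a sliding window, a lexicon entry matches a contiguous token
#' sub-span when the entry's stem multiset is contained in the sub-span's
#' stem multiset. The tightest such span is taken per candidate; among
#' overlapping candidates the longest span wins, ties broken leftmost,
#' then by lexicographically smallest concept id. Accepted matches never
#' overlap. Acronyms are not matched here — they are expanded upstream by
#' the variant lexicon during regularization.
#'
#' @param stream a `token_stream` (already tokenized; stems if the stream
#'   was stemmed, otherwise token surfaces are stemmed on the fly).
#' @param lex a [concept_lexicon()].
#' @param window sliding window size in tokens; must be at least the
#'   longest lexicon term length.
#' @return data.frame of matches: doc_id, start_index, end_index
#'   (0-based, half-open over the token sequence), concept_id, semtype,
#'   matched_term.
#' @export
match_concepts <- function(stream, lex, window = 8L) {
  stopifnot(inherits(stream, "token_stream"), inherits(lex, "concept_lexicon"))
  if (length(lex$term) && window < max(lex$n_words)) {
    offending <- lex$term[lex$n_words > window]
    stop("window (", window, ") smaller than lexicon term(s): ",
         paste(offending, collapse = "; "), call. = FALSE)
  }
  empty <- data.frame(doc_id = character(), start_index = integer(),
                      end_index = integer(), concept_id = character(),
                      semtype = character(), matched_term = character(),
                      stringsAsFactors = FALSE)
  if (!length(lex$term)) return(empty)
  is_word <- stream$tokens$kind == "WORD"
  word_pos <- which(is_word)
  if (!length(word_pos)) return(empty)
  surf <- stream$tokens$surface[word_pos]
  u <- unique(surf)
  doc_stems <- porter_stem(u)[match(surf, u)]
  n <- length(doc_stems)

  cand <- list()
  present <- vapply(lex$stems,
                    function(s) all(unique(s) %in% doc_stems), logical(1))
  for (e in which(present)) {
    est <- lex$stems[[e]]
    L <- length(est)
    # tightest contiguous spans (length L..window) containing the multiset
    anchor <- which(doc_stems == est[1L])
    seen <- character()
    for (p in anchor) {
      for (s in max(1L, p - window + 1L):p) {
        emax <- min(n, s + window - 1L)
        for (q in (s + L - 1L):emax) {
          if (q < p) next
          if (.multiset_subset(est, doc_stems[s:q])) {
            key <- paste(s, q)
            if (!(key %in% seen)) {
              seen <- c(seen, key)
              cand[[length(cand) + 1L]] <-
                list(s = s, q = q, entry = e, span_len = q - s + 1L)
            }
            break  # tightest end for this start
          }
        }
      }
    }
  }
  if (!length(cand)) return(empty)
  cd <- data.frame(s = vapply(cand, `[[`, 0L, "s"),
                   q = vapply(cand, `[[`, 0L, "q"),
                   entry = vapply(cand, `[[`, 0L, "entry"),
                   span_len = vapply(cand, `[[`, 0L, "span_len"))
  cd$entry_len <- lex$n_words[cd$entry]
  cd$cui <- lex$concept_id[cd$entry]
  # longest wins (by matched content), slack-free spans preferred, then
  # leftmost, then lexicographically smallest concept id
  cd$slack <- cd$span_len - cd$entry_len
  cd <- cd[order(-cd$entry_len, cd$slack, cd$s, cd$cui), ]
  taken <- rep(FALSE, n)
  out <- empty
  for (i in seq_len(nrow(cd))) {
    rng <- cd$s[i]:cd$q[i]
    if (any(taken[rng])) next
    taken[rng] <- TRUE
    e <- cd$entry[i]
    out <- rbind(out, data.frame(
      doc_id = stream$doc_id,
      start_index = word_pos[cd$s[i]] - 1L,
      end_index = word_pos[cd$q[i]],
      concept_id = lex$concept_id[e], semtype = lex$semtype[e],
      matched_term = lex$term[e], stringsAsFactors = FALSE))
  }
  out <- out[order(out$start_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate a token stream with concept and semantic-type tokens
#'
#' For every accepted match, a CONCEPT token (surface = lowercased concept
#' id) and/or a SEMTYPE token (surface = lowercased semantic type) is
#' inserted at the match position according to the variant flags. Word
#' tokens are retained iff `include_words`. Under D1 the stream is
#' returned unchanged.
#'
#' @param stream a `token_stream`.
#' @param matches data.frame from [match_concepts()]; must be
#'   non-overlapping.
#' @param variant an [enrichment_variant()] or preset name.
#' @return the annotated `token_stream`.
#' @export
annotate <- function(stream, matches, variant = "D2") {
  if (!inherits(variant, "enrichment_variant")) {
    variant <- enrichment_variant(variant)
  }
  stopifnot(inherits(stream, "token_stream"))
  if (nrow(matches) > 1L) {
    m <- matches[order(matches$start_index), ]
    if (any(m$start_index[-1L] < m$end_index[-nrow(m)])) {
      stop("overlapping matches are a contract violation", call. = FALSE)
    }
  }
  if (!variant$include_concepts && !variant$include_semtypes) {
    if (variant$include_words) return(stream)  # D1: identity
  }
  tok <- stream$tokens
  sent <- attr(stream, "sentence_id")
  n <- nrow(tok)
  pieces <- list()
  ord <- if (nrow(matches)) order(matches$start_index) else integer()
  matches <- matches[ord, , drop = FALSE]
  ins_after <- if (nrow(matches)) matches$end_index else integer()
  for (i in seq_len(nrow(matches))) {
    mi <- matches[i, ]
    span_tok <- which(seq_len(n) - 1L >= mi$start_index &
                      seq_len(n) - 1L < mi$end_index &
                      tok$kind == "WORD")
    # inserted tokens take the span of the last covered word so that
    # stream starts stay non-decreasing; the match data.frame keeps the
    # full token span
    last <- span_tok[length(span_tok)]
    st <- if (length(span_tok)) tok$start[last] else 0L
    en <- if (length(span_tok)) tok$end[last] else 0L
    sid <- if (length(span_tok)) sent[last] else 0L
    add <- NULL
    if (variant$include_concepts) {
      add <- rbind(add, data.frame(surface = tolower(mi$concept_id),
                                   kind = "CONCEPT", start = st, end = en,
                                   sid = sid, stringsAsFactors = FALSE))
    }
    if (variant$include_semtypes) {
      add <- rbind(add, data.frame(surface = tolower(mi$semtype),
                                   kind = "SEMTYPE", start = st, end = en,
                                   sid = sid, stringsAsFactors = FALSE))
    }
    pieces[[i]] <- add
  }
  covered <- rep(FALSE, n)
  for (i in seq_len(nrow(matches))) {
    idx <- which(seq_len(n) - 1L >= matches$start_index[i] &
                 seq_len(n) - 1L < matches$end_index[i])
    covered[idx] <- TRUE
  }
  keep_word <- if (variant$include_words) rep(TRUE, n) else !covered

  out_surface <- character(); out_kind <- character()
  out_start <- integer(); out_end <- integer(); out_sent <- integer()
  mi <- 1L
  for (i in seq_len(n)) {
    if (keep_word[i]) {
      out_surface <- c(out_surface, tok$surface[i])
      out_kind <- c(out_kind, tok$kind[i])
      out_start <- c(out_start, tok$start[i])
      out_end <- c(out_end, tok$end[i])
      out_sent <- c(out_sent, sent[i])
    }
    while (mi <= length(ins_after) && ins_after[mi] == i) {
      add <- pieces[[mi]]
      out_surface <- c(out_surface, add$surface)
      out_kind <- c(out_kind, add$kind)
      out_start <- c(out_start, add$start)
      out_end <- c(out_end, add$end)
      out_sent <- c(out_sent, add$sid)
      mi <- mi + 1L
    }
  }
  token_stream(stream$doc_id, out_surface, out_kind, out_start, out_end,
               out_sent)
}

#' Enrich a whole corpus of token streams
#'
#' @param streams list of `token_stream`.
#' @param lex a [concept_lexicon()].
#' @param variant preset name or [enrichment_variant()].
#' @param window sliding window for [match_concepts()].
#' @return list of annotated streams.
#' @export
enrich_corpus <- function(streams, lex, variant = "D2", window = 8L) {
  lapply(streams, function(s) {
    annotate(s, match_concepts(s, lex, window), variant)
  })
}

#' Build a bag-of-words matrix from token streams
#'
#' @param streams non-empty list of `token_stream`.
#' @param min_df drop terms occurring in fewer than `min_df` documents.
#' @param max_df drop terms occurring in more than this proportion of
#'   documents (default 0.5). Corpus-wide formulaic terms — greeting and
#'   closing boilerplate of referral letters — otherwise coalesce into a
#'   topic of their own; a document-frequency ceiling is the standard
#'   remedy. Set to 1 to disable.
#' @param exclude surfaces never admitted to the vocabulary (default: the
#'   personal-name mask token).
#' @return list with `vocab` (sorted character vector), `counts` (D x V
#'   integer matrix, rows named by doc id) and `empty_docs` (ids of
#'   documents left all-zero by filtering), class `bow`.
#' @export
build_bow <- function(streams, min_df = 1L, max_df = 0.5,
                      exclude = person_mask_token()) {
  stopifnot(length(streams) > 0L)
  toks <- lapply(streams, function(s) {
    x <- s$tokens$surface
    x[!(x %in% exclude)]
  })
  all_terms <- unlist(toks, use.names = FALSE)
  if (!length(all_terms)) stop("all_empty_corpus: no tokens in any document",
                               call. = FALSE)
  df <- table(unlist(lapply(toks, unique), use.names = FALSE))
  vocab <- sort(names(df)[df >= min_df &
                          df <= max_df * length(streams)])
  if (!length(vocab)) stop("all_empty_corpus: no term meets min_df",
                           call. = FALSE)
  D <- length(streams)
  counts <- matrix(0L, nrow = D, ncol = length(vocab),
                   dimnames = list(vapply(streams, `[[`, "", "doc_id"),
                                   vocab))
  for (d in seq_len(D)) {
    tt <- table(toks[[d]][toks[[d]] %in% vocab])
    if (length(tt)) counts[d, names(tt)] <- as.integer(tt)
  }
  empty <- rownames(counts)[rowSums(counts) == 0L]
  structure(list(vocab = vocab, counts = counts, empty_docs = empty),
            class = "bow")
}

#' @export
print.bow <- function(x, ...) {
  cat(sprintf("<bow: %d docs x %d terms, %d tokens, %d empty docs>\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts),
              length(x$empty_docs)))
  invisible(x)
}
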