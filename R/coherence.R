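#' Build Boolean-document co-occurrence statistics
#'
#' Word and word-pair probabilities for coherence are estimated from
#' Boolean virtual documents: the number of virtual documents containing a
#' word (or both words of a pair) divided by the total number of virtual
#' documents. Multiplicity within a virtual document is ignored. A virtual
#' document is the full document, a sentence, or a sliding text window.
#'
#' @param streams list of `token_stream` (or list of character token
#'   vectors).
#' @param window `"document"`, `"sentence"`, or an integer sliding-window
#'   width in tokens.
#' @param eps smoothing constant added inside logarithms downstream.
#' @return object of class `cooc_stats`: list with `n_vdocs`, `vdocs`
#'   (list of unique-token character vectors), `df` (named word counts),
#'   `eps`, `window`.
#' @export
build_cooc <- function(streams, window = "document", eps = 1e-12) {
  toks <- lapply(streams, function(s) {
    if (inherits(s, "token_stream")) s$tokens$surface else as.character(s)
  })
  sents <- lapply(streams, function(s) {
    if (inherits(s, "token_stream")) attr(s, "sentence_id") else NULL
  })
  vdocs <- list()
  if (identical(window, "document")) {
    vdocs <- toks
  } else if (identical(window, "sentence")) {
    for (i in seq_along(toks)) {
      sid <- sents[[i]]
      if (is.null(sid) || !length(sid)) sid <- rep(0L, length(toks[[i]]))
      vdocs <- c(vdocs, unname(split(toks[[i]], sid)))
    }
  } else {
    w <- as.integer(window)
    stopifnot(w >= 2L)
    for (tk in toks) {
      n <- length(tk)
      if (n == 0L) next
      if (n <= w) {
        vdocs[[length(vdocs) + 1L]] <- tk
      } else {
        for (s in seq_len(n - w + 1L)) {
          vdocs[[length(vdocs) + 1L]] <- tk[s:(s + w - 1L)]
        }
      }
    }
  }
  vdocs <- lapply(vdocs, unique)
  vdocs <- vdocs[lengths(vdocs) > 0L]
  if (!length(vdocs)) stop("zero virtual documents", call. = FALSE)
  flat <- unlist(vdocs, use.names = FALSE)
  df <- table(flat)
  # inverted index word -> sorted virtual-document ids, for fast df2
  index <- split(rep(seq_along(vdocs), lengths(vdocs)), flat)
  structure(list(n_vdocs = length(vdocs), vdocs = vdocs,
                 df = setNames(as.integer(df), names(df)),
                 index = index, eps = eps, window = window),
            class = "cooc_stats")
}

#' @export
print.cooc_stats <- function(x, ...) {
  cat(sprintf("<cooc_stats: %d virtual documents, %d words, window=%s>\n",
              x$n_vdocs, length(x$df), paste(x$window)))
  invisible(x)
}

.df_lookup <- function(stats, w) {
  v <- stats$df[w]
  if (anyNA(v)) {
    stop("unknown word(s): ", paste(w[is.na(v)], collapse = ", "),
         call. = FALSE)
  }
  as.integer(v)
}

#' Joint virtual-document count of a word pair
#'
#' @param stats a [build_cooc()] object.
#' @param w_i,w_j words (both must be known to `stats`).
#' @return integer count of virtual documents containing both.
#' @export
df2 <- function(stats, w_i, w_j) {
  .df_lookup(stats, c(w_i, w_j))
  length(intersect(stats$index[[w_i]], stats$index[[w_j]]))
}

#' Pairwise word coherence primitives
#'
#' Probabilities are Boolean-document relative frequencies. With a small
#' smoothing constant `eps` (from `stats`) to avoid log of zero:
#' `PMI = log((P(wi,wj)+eps) / (P(wi) P(wj)))`;
#' `NPMI = PMI / (-log(P(wi,wj)+eps))`, bounded in [-1, 1];
#' `LCP(i|j) = log((P(wi,wj)+eps) / P(wj))` — directed: the first argument
#' is conditioned on the second.
#'
#' @param stats a [build_cooc()] object.
#' @param w_i,w_j words present in `stats` (unknown words are an error).
#' @return a single numeric value.
#' @export
pmi <- function(stats, w_i, w_j) {
  n <- stats$n_vdocs
  pi_ <- .df_lookup(stats, w_i) / n
  pj <- .df_lookup(stats, w_j) / n
  pij <- df2(stats, w_i, w_j) / n
  log((pij + stats$eps) / (pi_ * pj))
}

#' @rdname pmi
#' @export
npmi <- function(stats, w_i, w_j) {
  n <- stats$n_vdocs
  pij <- df2(stats, w_i, w_j) / n
  # abs() keeps the normalizer positive at P(wi,wj) = 1, where the raw
  # -log(P + eps) crosses zero from below; the result is then clipped to
  # the theoretical [-1, 1] range to absorb eps-order smoothing error
  val <- pmi(stats, w_i, w_j) / abs(log(pij + stats$eps))
  max(-1, min(1, val))
}

#' @rdname pmi
#' @export
lcp <- function(stats, w_i, w_j) {
  n <- stats$n_vdocs
  pj <- .df_lookup(stats, w_j) / n
  pij <- df2(stats, w_i, w_j) / n
  log((pij + stats$eps) / pj)
}

#' Coherence configuration
#'
#' @param measure one of `"c_uci"`, `"c_npmi"`, `"c_umass"`, `"c_cos"`,
#'   `"c_v"`.
#' @param top_n words per topic entering the average (>= 2).
#' @param window virtual-document policy for [build_cooc()]; defaults per
#'   measure follow the coherence literature: full documents for C_UMass,
#'   sliding 10 for C_UCI/C_NPMI, sliding 110 for C_V/C_cos.
#' @param eps smoothing constant (> 0).
#' @return list of class `coherence_config`.
#' @export
coherence_config <- function(measure = c("c_v", "c_uci", "c_npmi",
                                         "c_umass", "c_cos"),
                             top_n = 10L, window = NULL, eps = 1e-12) {
  measure <- match.arg(measure)
  stopifnot(top_n >= 2L, eps > 0)
  if (is.null(window)) {
    window <- switch(measure,
                     c_umass = "document",
                     c_uci = 10L, c_npmi = 10L,
                     c_cos = 110L, c_v = 110L)
  }
  structure(list(measure = measure, top_n = as.integer(top_n),
                 window = window, eps = eps),
            class = "coherence_config")
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# coherence of one ranked word set under one config; words assumed known
.wordset_coherence <- function(words, stats, cfg) {
  n <- length(words)
  prs <- combn(n, 2L)
  switch(cfg$measure,
    c_uci = mean(apply(prs, 2L, function(p)
      pmi(stats, words[p[1L]], words[p[2L]]))),
    c_npmi = mean(apply(prs, 2L, function(p)
      npmi(stats, words[p[1L]], words[p[2L]]))),
    # higher-ranked word conditioned on lower-ranked: LCP(w_i | w_j), i<j
    c_umass = mean(apply(prs, 2L, function(p)
      lcp(stats, words[p[1L]], words[p[2L]]))),
    c_cos = {
      ctx <- vapply(words, function(wi)
        vapply(words, function(wj) npmi(stats, wi, wj), numeric(1)),
        numeric(n))             # column i = context vector of word i
      mean(apply(prs, 2L, function(p)
        .cosine(ctx[, p[1L]], ctx[, p[2L]])))
    },
    c_v = {
      ctx <- vapply(words, function(wi)
        vapply(words, function(wj) npmi(stats, wi, wj), numeric(1)),
        numeric(n))
      total <- rowSums(ctx)
      mean(vapply(seq_len(n), function(i)
        .cosine(ctx[, i], total), numeric(1)))
    })
}

#' Topic coherence of a fitted model
#'
#' Scores each topic's `top_n` highest-probability words with the
#' configured measure and returns per-topic scores and their mean. Direct
#' measures (C_UCI, C_NPMI, C_UMass) average the pairwise primitive over
#' word pairs; C_cos averages pairwise cosine of NPMI context vectors
#' (dimensions = the topic's own top words); C_V averages, over the top
#' words, the cosine between each word's context vector and the summed
#' context vector of the whole set.
#'
#' @param model a [fit_lda()] model.
#' @param stats a [build_cooc()] object (its window should match
#'   `cfg$window`).
#' @param cfg a [coherence_config()].
#' @return list with `per_topic` (numeric, NA for undefined topics),
#'   `mean` (over defined topics), `dropped` (words unseen in `stats`,
#'   per topic).
#' @export
topic_coherence <- function(model, stats, cfg = coherence_config()) {
  stopifnot(inherits(model, "topic_model"), inherits(stats, "cooc_stats"),
            inherits(cfg, "coherence_config"))
  per <- rep(NA_real_, model$K)
  dropped <- vector("list", model$K)
  for (k in seq_len(model$K)) {
    words <- rank_words(model, k, n = cfg$top_n, mode = "probability")$word
    known <- words %in% names(stats$df)
    dropped[[k]] <- words[!known]
    words <- words[known]
    if (length(words) < 2L) next
    per[k] <- .wordset_coherence(words, stats, cfg)
  }
  if (any(lengths(dropped) > 0L)) {
    warning("dropped words unseen in co-occurrence stats for ",
            sum(lengths(dropped) > 0L), " topic(s)")
  }
  if (all(is.na(per))) {
    warning("no topic had 2 usable words; mean coherence undefined")
  }
  list(per_topic = per, mean = mean(per, na.rm = TRUE), dropped = dropped)
}

#' Choose the number of topics by coherence
#'
#' Fits one model per K per seed, scores mean topic coherence, averages
#' over seeds and returns the argmax along with the full curve. A constant
#' curve returns the smallest K with `flag = "constant"`.
#'
#' @param bow a `bow` or count matrix.
#' @param stats a [build_cooc()] object built from the same corpus.
#' @param k_grid candidate K values (>= 3).
#' @param cfg a [coherence_config()].
#' @param seeds integer vector of seeds averaged over.
#' @param ... passed to [fit_lda()].
#' @return list with `K`, `table` (K x mean coherence), `flag`, `errors`
#'   (per-K error messages, if any).
#' @export
select_k_by_coherence <- function(bow, stats, k_grid,
                                  cfg = coherence_config(), seeds = 1L,
                                  ...) {
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) < 3L) {
    stop("k_grid needs at least 3 values", call. = FALSE)
  }
  errors <- list()
  score <- vapply(k_grid, function(K) {
    vals <- vapply(seeds, function(s) {
      tryCatch({
        m <- fit_lda(bow, K = K, seed = s, ...)
        suppressWarnings(topic_coherence(m, stats, cfg)$mean)
      }, error = function(e) {
        errors[[as.character(K)]] <<- conditionMessage(e)
        NA_real_
      })
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  tab <- data.frame(K = k_grid, coherence = score)
  ok <- !is.na(score)
  if (!any(ok)) stop("no K could be scored", call. = FALSE)
  if (max(score[ok]) - min(score[ok]) < 1e-12) {
    list(K = k_grid[ok][1L], table = tab, flag = "constant",
         errors = errors)
  } else {
    list(K = k_grid[ok][which.max(score[ok])], table = tab, flag = "max",
         errors = errors)
  }
}
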