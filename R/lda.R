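#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Each document is a finite mixture over K latent topics and each topic a
#' distribution over the vocabulary. Token-topic assignments are sampled
#' by collapsed Gibbs; `phi` (K x V topic-word) and `theta` (D x K
#' document-topic) are posterior means over thinned post-burn-in samples,
#' or final-state count estimates when `estimate = "final"`. Fully
#' reproducible from `seed` (the sampler uses its own generator and never
#' touches R's RNG state).
#'
#' @param bow a [build_bow()] object or a D x V count matrix with dimnames.
#' @param K number of topics (>= 2). The shipped default for the
#'   referral-letter configuration is 11.
#' @param alpha symmetric document-topic Dirichlet prior (default 50/K).
#' @param beta symmetric topic-word prior (default 0.01).
#' @param iterations,burn_in Gibbs sweeps; `iterations > burn_in >= 0`.
#' @param n_samples thinned post-burn-in samples averaged into the
#'   estimates (default 10); 0 requests the final-state estimate.
#' @param seed integer seed (mandatory for reproducibility).
#' @param estimate `"mean"` (posterior mean of thinned samples) or
#'   `"final"`.
#' @return an object of class `topic_model` with fields K, phi, theta,
#'   alpha, beta, vocabulary, seed, iterations, burn_in, assignments,
#'   term_freq (corpus marginal counts), doc_ids, excluded_docs.
#' @export
fit_lda <- function(bow, K = 11L, alpha = 50 / K, beta = 0.01,
                    iterations = 1000L, burn_in = 500L, n_samples = 10L,
                    seed = 1L, estimate = c("mean", "final")) {
  estimate <- match.arg(estimate)
  counts <- if (inherits(bow, "bow")) bow$counts else bow
  stopifnot(is.matrix(counts), nrow(counts) > 0L, ncol(counts) > 0L)
  if (K < 2L) stop("K must be >= 2", call. = FALSE)
  if (K > ncol(counts)) stop("K (", K, ") exceeds vocabulary size (",
                             ncol(counts), ")", call. = FALSE)
  stopifnot(alpha > 0, beta > 0, iterations > burn_in, burn_in >= 0)
  zero <- rowSums(counts) == 0L
  excluded <- rownames(counts)[zero]
  if (any(zero)) {
    warning("excluding ", sum(zero), " all-zero document(s): ",
            paste(excluded, collapse = ", "))
    counts <- counts[!zero, , drop = FALSE]
  }
  D <- nrow(counts); V <- ncol(counts)
  # expand counts to token vectors
  idx <- which(counts > 0L, arr.ind = TRUE)
  reps <- counts[idx]
  doc <- rep(idx[, 1L] - 1L, reps)
  word <- rep(idx[, 2L] - 1L, reps)
  ord <- order(doc, word)
  doc <- doc[ord]; word <- word[ord]
  res <- .lda_gibbs(as.integer(word), as.integer(doc), D, V, as.integer(K),
                    alpha, beta, as.integer(iterations), as.integer(burn_in),
                    if (estimate == "mean") as.integer(n_samples) else 0L,
                    as.double(seed))
  phi <- res$phi
  theta <- res$theta
  colnames(phi) <- colnames(counts)
  rownames(theta) <- rownames(counts)
  structure(list(K = as.integer(K), phi = phi, theta = theta,
                 alpha = alpha, beta = beta,
                 vocabulary = colnames(counts),
                 seed = as.integer(seed),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 n_samples = res$samples_used,
                 estimate = estimate,
                 assignments = res$assignments,
                 term_freq = colSums(counts),
                 doc_ids = rownames(counts),
                 excluded_docs = excluded),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf(
    "<topic_model: K=%d, V=%d, D=%d, alpha=%.4g, beta=%.4g, seed=%d>\n",
    x$K, length(x$vocabulary), nrow(x$theta), x$alpha, x$beta, x$seed))
  invisible(x)
}

#' Infer the topic distribution of a new document
#'
#' Fold-in Gibbs sampling with `phi` frozen. Out-of-vocabulary tokens are
#' dropped; a document empty after vocabulary projection yields the
#' uniform distribution with attribute `uniform_fallback = TRUE` and a
#' warning.
#'
#' @param model a fitted [fit_lda()] model.
#' @param new_doc_bow named integer vector of token counts, or a 1 x V
#'   matrix aligned to the model vocabulary.
#' @param iterations,burn_in,n_samples fold-in sampling controls.
#' @param seed integer seed.
#' @return a length-K simplex vector.
#' @export
infer_theta <- function(model, new_doc_bow, iterations = 200L,
                        burn_in = 100L, n_samples = 10L, seed = 1L) {
  stopifnot(inherits(model, "topic_model"))
  V <- length(model$vocabulary)
  if (is.matrix(new_doc_bow)) {
    stopifnot(ncol(new_doc_bow) == V)
    cnt <- as.integer(new_doc_bow[1L, ])
    wid <- which(cnt > 0L)
    word <- rep(wid - 1L, cnt[wid])
  } else {
    keep <- names(new_doc_bow) %in% model$vocabulary
    x <- new_doc_bow[keep]
    word <- rep(match(names(x), model$vocabulary) - 1L, as.integer(x))
  }
  if (!length(word)) {
    warning("document empty after vocabulary projection; returning uniform")
    out <- rep(1 / model$K, model$K)
    attr(out, "uniform_fallback") <- TRUE
    return(out)
  }
  th <- .lda_foldin(as.integer(word), model$phi, model$alpha,
                    as.integer(iterations), as.integer(burn_in),
                    as.integer(n_samples), as.double(seed))
  as.numeric(th)
}

#' Perplexity of a topic model on a corpus
#'
#' The inverse geometric mean per-word likelihood,
#' `exp(- sum_d sum_w n_dw log p(w|d) / N)` with
#' `p(w|d) = sum_k theta_dk phi_kw`. Lower is better.
#'
#' @param model a [fit_lda()] model.
#' @param bow a `bow` or count matrix whose rows align with `theta`; pass
#'   `theta` explicitly for held-out documents.
#' @param theta optional D x K matrix overriding the model's training
#'   theta (required when `bow` rows are not the training documents).
#' @return a positive number.
#' @export
perplexity <- function(model, bow, theta = NULL) {
  stopifnot(inherits(model, "topic_model"))
  counts <- if (inherits(bow, "bow")) bow$counts else bow
  if (is.null(theta)) {
    stopifnot(nrow(counts) == nrow(model$theta))
    theta <- model$theta
  }
  stopifnot(nrow(theta) == nrow(counts), ncol(counts) == ncol(model$phi))
  pwd <- theta %*% model$phi           # D x V
  if (any(pwd[counts > 0L] <= 0)) {
    stop("zero-probability word encountered despite smoothing",
         call. = FALSE)
  }
  N <- sum(counts)
  if (N == 0L) stop("empty corpus has no perplexity", call. = FALSE)
  obs <- counts > 0L          # avoid 0 * log(0) for unobserved words
  ll <- sum(counts[obs] * log(pwd[obs]))
  exp(-ll / N)
}

#' Rank a topic's words by probability, lift, or relevance
#'
#' Relevance interpolates log within-topic probability and log lift:
#' `r = lambda * log phi_kw + (1 - lambda) * log(phi_kw / p(w))`, where
#' `p(w)` is the empirical corpus marginal. `lambda = 1` reduces to
#' probability order, `lambda = 0` to lift order.
#'
#' @param model a [fit_lda()] model.
#' @param topic 1-based topic index.
#' @param n number of words (<= V).
#' @param mode `"probability"`, `"lift"`, or `"relevance"`.
#' @param lambda relevance parameter in [0, 1].
#' @return data.frame (word, score) sorted by descending score, class
#'   `ranked_topic_words` with attributes topic and mode.
#' @export
rank_words <- function(model, topic, n = 30L,
                       mode = c("probability", "lift", "relevance"),
                       lambda = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "topic_model"),
            topic >= 1L, topic <= model$K, n <= length(model$vocabulary),
            lambda >= 0, lambda <= 1)
  phi_k <- model$phi[topic, ]
  pw <- model$term_freq / sum(model$term_freq)
  score <- switch(mode,
    probability = log(phi_k),
    lift = log(phi_k / pw),
    relevance = lambda * log(phi_k) + (1 - lambda) * log(phi_k / pw))
  ord <- order(-score, model$vocabulary)
  out <- data.frame(word = model$vocabulary[ord][seq_len(n)],
                    score = score[ord][seq_len(n)],
                    stringsAsFactors = FALSE)
  structure(out, topic = topic, mode = mode, lambda = lambda,
            class = c("ranked_topic_words", "data.frame"))
}

#' Choose the number of topics by the rate of perplexity change
#'
#' Computes held-out perplexity on a seeded 90/10 document split for every
#' K in the grid, then locates the elbow of the perplexity curve as the
#' maximum second difference. Returns the chosen K together with the full
#' table so callers can override.
#'
#' @param bow a `bow` or count matrix.
#' @param k_grid ascending grid of candidate K (>= 3 values).
#' @param seed integer seed controlling the split and all fits.
#' @param holdout fraction of documents held out (default 0.1).
#' @param ... passed to [fit_lda()] (e.g. iterations).
#' @return list with `K` (chosen), `table` (data.frame K, perplexity),
#'   `flag` ("elbow" or "no_elbow"), `rejected` (grid values > V).
#' @export
select_k_by_perplexity <- function(bow, k_grid, seed = 1L, holdout = 0.1,
                                   ...) {
  counts <- if (inherits(bow, "bow")) bow$counts else bow
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) < 3L) {
    stop("k_grid needs at least 3 values", call. = FALSE)
  }
  rejected <- k_grid[k_grid > ncol(counts)]
  k_grid <- k_grid[k_grid <= ncol(counts)]
  if (length(k_grid) < 3L) {
    stop("fewer than 3 admissible k_grid values; rejected: ",
         paste(rejected, collapse = ", "), call. = FALSE)
  }
  D <- nrow(counts)
  rng <- .seeded_sample(D, max(1L, round(holdout * D)), seed)
  test <- counts[rng, , drop = FALSE]
  train <- counts[-rng, , drop = FALSE]
  perp <- vapply(k_grid, function(K) {
    m <- fit_lda(train, K = K, seed = seed, ...)
    th <- t(vapply(seq_len(nrow(test)), function(i) {
      suppressWarnings(
        infer_theta(m, test[i, , drop = FALSE], seed = seed + i))
    }, numeric(K)))
    perplexity(m, test, theta = th)
  }, numeric(1))
  tab <- data.frame(K = k_grid, perplexity = perp)
  el <- elbow_k(k_grid, perp)
  list(K = el$K, table = tab, flag = el$flag, rejected = rejected)
}

#' Locate the elbow of a perplexity curve
#'
#' The elbow is the grid point with the maximum second difference of the
#' curve (the sharpest change in the rate of perplexity change). A
#' strictly linear curve has no elbow: the smallest K is returned with
#' `flag = "no_elbow"`.
#'
#' @param k_grid ascending grid of K values (>= 3).
#' @param values perplexity per grid point.
#' @return list with `K` and `flag` ("elbow" or "no_elbow").
#' @export
elbow_k <- function(k_grid, values) {
  stopifnot(length(k_grid) >= 3L, length(values) == length(k_grid))
  d2 <- diff(diff(values))
  if (all(abs(d2) < 1e-9)) {
    list(K = k_grid[1L], flag = "no_elbow")
  } else {
    list(K = k_grid[which.max(d2) + 1L], flag = "elbow")
  }
}

# deterministic sample of k from n given integer seed, without touching
# the caller's RNG state
.seeded_sample <- function(n, k, seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(n, k)
}

#' Save / load a topic model
#'
#' A model directory holds `meta.json` (K, priors, seed, iteration
#' counts, vocabulary, doc ids, term frequencies) and `phi.txt` /
#' `theta.txt` (matrices, one row per line, `%.17g` formatting so the
#' round trip is bit-exact).
#'
#' @param model a `topic_model`.
#' @param dir target directory (created if needed).
#' @return `dir`, invisibly (`save_model`); the model (`load_model`).
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "topic_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- model[c("K", "alpha", "beta", "vocabulary", "seed", "iterations",
                  "burn_in", "n_samples", "estimate", "doc_ids",
                  "excluded_docs")]
  meta$term_freq <- as.numeric(model$term_freq)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  .write_mat <- function(m, path) {
    writeLines(apply(m, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " ")), path)
  }
  .write_mat(model$phi, file.path(dir, "phi.txt"))
  .write_mat(model$theta, file.path(dir, "theta.txt"))
  writeLines(as.character(model$assignments),
             file.path(dir, "assignments.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  .read_mat <- function(path) {
    rows <- strsplit(readLines(path), " ", fixed = TRUE)
    do.call(rbind, lapply(rows, as.numeric))
  }
  phi <- .read_mat(file.path(dir, "phi.txt"))
  theta <- .read_mat(file.path(dir, "theta.txt"))
  colnames(phi) <- meta$vocabulary
  rownames(theta) <- meta$doc_ids
  structure(list(K = as.integer(meta$K), phi = phi, theta = theta,
                 alpha = meta$alpha, beta = meta$beta,
                 vocabulary = meta$vocabulary,
                 seed = as.integer(meta$seed),
                 iterations = as.integer(meta$iterations),
                 burn_in = as.integer(meta$burn_in),
                 n_samples = meta$n_samples, estimate = meta$estimate,
                 assignments = as.integer(
                   readLines(file.path(dir, "assignments.txt"))),
                 term_freq = setNames(meta$term_freq, meta$vocabulary),
                 doc_ids = meta$doc_ids,
                 excluded_docs = as.character(meta$excluded_docs)),
            class = "topic_model")
}
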