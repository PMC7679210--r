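# Independent brute-force oracles. These deliberately re-derive every
# quantity from first principles with naive loops, sharing no code with
# the implementation they check.

naive_cooc_counts <- function(vdocs) {
  words <- sort(unique(unlist(vdocs)))
  df <- setNames(integer(length(words)), words)
  for (w in words) {
    df[w] <- sum(vapply(vdocs, function(v) w %in% v, logical(1)))
  }
  df2 <- matrix(0L, length(words), length(words),
                dimnames = list(words, words))
  for (i in seq_along(words)) {
    for (j in seq_along(words)) {
      df2[i, j] <- sum(vapply(vdocs, function(v)
        (words[i] %in% v) && (words[j] %in% v), logical(1)))
    }
  }
  list(df = df, df2 = df2, n = length(vdocs))
}

naive_pmi <- function(cc, a, b, eps = 1e-12) {
  log((cc$df2[a, b] / cc$n + eps) /
        ((cc$df[a] / cc$n) * (cc$df[b] / cc$n)))
}
naive_npmi <- function(cc, a, b, eps = 1e-12) {
  # same stated convention as the implementation: positive normalizer,
  # result clipped to the theoretical range
  v <- naive_pmi(cc, a, b, eps) / abs(log(cc$df2[a, b] / cc$n + eps))
  max(-1, min(1, v))
}
naive_lcp <- function(cc, a, b, eps = 1e-12) {
  log((cc$df2[a, b] / cc$n + eps) / (cc$df[b] / cc$n))
}

naive_cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) 0 else sum(a * b) / (na * nb)
}

# all five aggregates on an explicit ranked word list
naive_topic_coherence <- function(words, cc, measure, eps = 1e-12) {
  n <- length(words)
  pair_vals <- c()
  if (measure %in% c("c_uci", "c_npmi", "c_umass")) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        v <- switch(measure,
                    c_uci = naive_pmi(cc, words[i], words[j], eps),
                    c_npmi = naive_npmi(cc, words[i], words[j], eps),
                    c_umass = naive_lcp(cc, words[i], words[j], eps))
        pair_vals <- c(pair_vals, v)
      }
    }
    return(mean(pair_vals))
  }
  ctx <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    ctx[j, i] <- naive_npmi(cc, words[i], words[j], eps)
  }
  if (measure == "c_cos") {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      pair_vals <- c(pair_vals, naive_cosine(ctx[, i], ctx[, j]))
    }
    return(mean(pair_vals))
  }
  if (measure == "c_v") {
    tot <- rowSums(ctx)
    return(mean(vapply(1:n, function(i) naive_cosine(ctx[, i], tot),
                       numeric(1))))
  }
  stop("unknown measure")
}

# per-token perplexity by direct summation
naive_perplexity <- function(phi, theta, counts) {
  ll <- 0; N <- 0
  for (d in seq_len(nrow(counts))) {
    for (w in seq_len(ncol(counts))) {
      n_dw <- counts[d, w]
      if (n_dw > 0) {
        p <- sum(theta[d, ] * phi[, w])
        ll <- ll + n_dw * log(p)
        N <- N + n_dw
      }
    }
  }
  exp(-ll / N)
}

# minimal reference collapsed Gibbs sampler in plain R (slow, tiny inputs)
reference_gibbs <- function(counts, K, alpha, beta, iterations, seed) {
  set.seed(seed)
  D <- nrow(counts); V <- ncol(counts)
  doc <- c(); word <- c()
  for (d in seq_len(D)) for (w in seq_len(V)) {
    if (counts[d, w] > 0) {
      doc <- c(doc, rep(d, counts[d, w]))
      word <- c(word, rep(w, counts[d, w]))
    }
  }
  N <- length(doc)
  z <- sample.int(K, N, replace = TRUE)
  ndk <- matrix(0L, D, K); nkw <- matrix(0L, K, V); nk <- integer(K)
  for (i in seq_len(N)) {
    ndk[doc[i], z[i]] <- ndk[doc[i], z[i]] + 1L
    nkw[z[i], word[i]] <- nkw[z[i], word[i]] + 1L
    nk[z[i]] <- nk[z[i]] + 1L
  }
  theta_acc <- matrix(0, D, K); taken <- 0
  for (it in seq_len(iterations)) {
    for (i in seq_len(N)) {
      d <- doc[i]; w <- word[i]; k0 <- z[i]
      ndk[d, k0] <- ndk[d, k0] - 1L
      nkw[k0, w] <- nkw[k0, w] - 1L
      nk[k0] <- nk[k0] - 1L
      p <- (ndk[d, ] + alpha) * (nkw[, w] + beta) / (nk + V * beta)
      k1 <- sample.int(K, 1L, prob = p)
      z[i] <- k1
      ndk[d, k1] <- ndk[d, k1] + 1L
      nkw[k1, w] <- nkw[k1, w] + 1L
      nk[k1] <- nk[k1] + 1L
    }
    if (it > iterations / 2) {
      taken <- taken + 1
      theta_acc <- theta_acc + (ndk + alpha) / (rowSums(ndk) + K * alpha)
    }
  }
  list(theta = theta_acc / taken)
}
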