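mkstream <- function(id, toks) {
  token_stream(id, toks, rep("WORD", length(toks)),
               seq_along(toks), seq_along(toks))
}

test_that("build_cooc counts Boolean documents per window policy", {
  docs <- list(mkstream("1", c("a", "b")), mkstream("2", c("a", "c")),
               mkstream("3", c("b", "c")))
  st <- build_cooc(docs, window = "document")
  expect_identical(st$n_vdocs, 3L)
  expect_identical(unname(st$df["a"]), 2L)
  expect_identical(df2(st, "a", "b"), 1L)
  expect_identical(df2(st, "a", "b"), df2(st, "b", "a"))

  sl <- build_cooc(list(mkstream("1", c("a", "b", "c"))), window = 2L)
  expect_identical(sl$n_vdocs, 2L)          # {ab}, {bc}
  expect_identical(df2(sl, "a", "c"), 0L)
  expect_identical(unname(sl$df["b"]), 2L)

  expect_error(build_cooc(list(mkstream("1", character()))),
               "zero virtual documents")
  expect_error(pmi(st, "zzz", "a"), "zzz")
})

test_that("df/df2 match a brute-force recount on 50 synthetic docs", {
  streams <- fixture("streams_small")[1:50]
  for (win in list("document", 5L)) {
    st <- build_cooc(streams, window = win)
    cc <- naive_cooc_counts(st$vdocs)
    expect_identical(st$n_vdocs, cc$n)
    expect_identical(st$df[order(names(st$df))], cc$df[order(names(cc$df))])
    words <- head(names(sort(-st$df)), 12L)
    for (i in 1:11) for (j in (i + 1):12) {
      expect_identical(df2(st, words[i], words[j]),
                       as.integer(cc$df2[words[i], words[j]]))
    }
  }
})

test_that("pmi/npmi/lcp arithmetic matches hand computation", {
  docs <- list(mkstream("1", c("a", "b")), mkstream("2", c("a", "c")),
               mkstream("3", c("b", "c")))
  st <- build_cooc(docs, window = "document")
  expect_equal(pmi(st, "a", "b"), log((1 / 3) / ((2 / 3) * (2 / 3))),
               tolerance = 1e-9)

  # words always co-occurring: NPMI -> 1
  all2 <- build_cooc(list(mkstream("1", c("x", "y")),
                          mkstream("2", c("x", "y"))), "document")
  expect_equal(npmi(all2, "x", "y"), 1, tolerance = 1e-6)

  # independence: P(ab) = P(a)P(b) exactly -> PMI ~ 0
  ind <- build_cooc(list(mkstream("1", c("a", "b")), mkstream("2", "a"),
                         mkstream("3", "b"), mkstream("4", "z")),
                    "document")
  expect_equal(pmi(ind, "a", "b"), 0, tolerance = 1e-6)

  # LCP directionality: a counter-example
  st2 <- build_cooc(list(mkstream("1", c("p", "q")), mkstream("2", "p"),
                         mkstream("3", "p"), mkstream("4", "q")),
                    "document")
  expect_false(isTRUE(all.equal(lcp(st2, "p", "q"), lcp(st2, "q", "p"))))
  expect_equal(lcp(st2, "p", "q"), log((1 / 4 + st2$eps) / (2 / 4)),
               tolerance = 1e-9)
})

test_that("npmi is bounded and pmi/npmi symmetric on random corpora", {
  streams <- fixture("streams_small")[1:40]
  st <- build_cooc(streams, window = "document", eps = 1e-6)
  words <- head(names(sort(-st$df)), 15L)
  for (i in 1:14) for (j in (i + 1):15) {
    v <- npmi(st, words[i], words[j])
    expect_gte(v, -1)
    expect_lte(v, 1)
    expect_equal(v, npmi(st, words[j], words[i]), tolerance = 1e-12)
    expect_equal(pmi(st, words[i], words[j]),
                 pmi(st, words[j], words[i]), tolerance = 1e-12)
  }
})

test_that("pairwise measures increase strictly with df2, marginals fixed", {
  # n=10 vdocs, df(a)=df(b)=5, df2 from 1 to 5 by construction
  build_with_joint <- function(j) {
    vd <- list()
    for (i in seq_len(j)) vd <- c(vd, list(c("a", "b")))
    for (i in seq_len(5 - j)) vd <- c(vd, list(c("a", "f"), c("b", "g")))
    while (length(vd) < 12L) vd <- c(vd, list("z"))  # fixed n_vdocs = 12
    build_cooc(lapply(seq_along(vd), function(i) mkstream(i, vd[[i]])),
               "document")
  }
  for (fn in list(pmi, npmi, lcp)) {
    vals <- vapply(1:5, function(j) fn(build_with_joint(j), "a", "b"),
                   numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})

test_that("all five aggregates match the brute-force oracle", {
  # 20 random small models: random word sets over a synthetic corpus
  streams <- fixture("streams_small")[1:40]
  st <- build_cooc(streams, window = "document")
  cc <- naive_cooc_counts(st$vdocs)
  pool <- names(st$df[st$df >= 2L])
  set.seed(17)
  for (rep in 1:20) {
    words <- sample(pool, 5L)
    for (msr in c("c_uci", "c_npmi", "c_umass", "c_cos", "c_v")) {
      cfg <- coherence_config(msr, top_n = 5L, window = "document")
      got <- lettertopics:::.wordset_coherence(words, st, cfg)
      want <- naive_topic_coherence(words, cc, msr)
      expect_equal(got, want, tolerance = 1e-10,
                   label = paste(msr, "rep", rep))
    }
  }
})

test_that("two always-co-occurring words: C_NPMI ~ 1 and C_COS = 1", {
  st <- build_cooc(list(mkstream("1", c("x", "y")),
                        mkstream("2", c("x", "y")),
                        mkstream("3", c("x", "y"))), "document")
  cfgn <- coherence_config("c_npmi", top_n = 2L, window = "document")
  cfgc <- coherence_config("c_cos", top_n = 2L, window = "document")
  expect_equal(lettertopics:::.wordset_coherence(c("x", "y"), st, cfgn), 1,
               tolerance = 1e-6)
  expect_equal(lettertopics:::.wordset_coherence(c("x", "y"), st, cfgc), 1,
               tolerance = 1e-12)
})

test_that("topic_coherence drops unknown words and flags thin topics", {
  m <- fixture("model_small")
  streams <- fixture("enriched_small")
  st <- build_cooc(streams[1:10], window = "document")  # partial corpus
  cfg <- coherence_config("c_npmi", top_n = 8L, window = "document")
  res <- suppressWarnings(topic_coherence(m, st, cfg))
  expect_length(res$per_topic, m$K)
  expect_true(is.finite(res$mean) || all(is.na(res$per_topic)))
})

test_that("planted topics out-score random word sets on C_V", {
  sim <- fixture("sim_small")
  enr <- fixture("enriched_small")
  m <- fixture("model_small")
  st <- build_cooc(enr, window = "document")
  cfg <- coherence_config("c_v", top_n = 6L, window = "document")
  real <- suppressWarnings(topic_coherence(m, st, cfg))$mean
  pool <- names(st$df[st$df >= 2L])
  set.seed(23)
  wins <- 0L
  for (t in 1:100) {
    words <- sample(pool, 6L)
    rnd <- lettertopics:::.wordset_coherence(words, st, cfg)
    if (real > rnd) wins <- wins + 1L
  }
  expect_gte(wins, 95L)
})

test_that("select_k_by_coherence validates and flags constant curves", {
  bow <- fixture("bow_small")
  st <- build_cooc(fixture("enriched_small"), window = "document")
  expect_error(select_k_by_coherence(bow, st, k_grid = 4L), "at least 3")
})
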