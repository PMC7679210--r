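clex <- read_concept_lexicon(
  system.file("extdata", "concept_lexicon.tsv", package = "lettertopics"))

stream_of <- function(txt) tokenize(regularize(raw_letter("d", txt)), "stem")

test_that("matching is order-insensitive and prefers the longest span", {
  m <- match_concepts(stream_of("there is a tear of meniscus on imaging"),
                      clex)
  expect_identical(m$matched_term[m$concept_id == "C0240126"],
                   "meniscus tear")

  # "ligament tear" must win over the bare "tear" entry
  m2 <- match_concepts(stream_of("a complete ligament tear was seen"), clex)
  expect_identical(m2$concept_id, "C0262560")
  expect_identical(nrow(m2), 1L)

  # empty lexicon yields an empty match list
  empty <- concept_lexicon(character(), character(), character())
  expect_identical(nrow(match_concepts(stream_of("knee pain"), empty)), 0L)

  # accepted matches never overlap
  m3 <- match_concepts(
    stream_of("medial joint line tenderness and knee pain with swelling"),
    clex)
  if (nrow(m3) > 1L) {
    m3 <- m3[order(m3$start_index), ]
    expect_true(all(m3$start_index[-1L] >= m3$end_index[-nrow(m3)]))
  }
})

test_that("window smaller than a lexicon term is a configuration error", {
  expect_error(match_concepts(stream_of("knee pain"), clex, window = 2L),
               "medial joint line tenderness")
})

test_that("matching is deterministic under lexicon entry reordering", {
  txts <- c("swelling and knee pain after playing rugby",
            "tear of meniscus with medial joint line tenderness",
            "painkillers offered for the ligament tear")
  perm <- rev(seq_along(clex$term))
  rlex <- concept_lexicon(clex$term[perm], clex$concept_id[perm],
                          clex$semtype[perm])
  for (tx in txts) {
    s <- stream_of(tx)
    a <- match_concepts(s, clex)
    b <- match_concepts(s, rlex)
    expect_identical(a[order(a$start_index), c("start_index", "concept_id")],
                     b[order(b$start_index), c("start_index", "concept_id")])
  }
})

test_that("annotate injects the variant's tokens; D1 is the identity", {
  s <- stream_of("he was tackled playing rugby and takes painkillers")
  m <- match_concepts(s, clex)

  d1 <- annotate(s, m, "D1")
  expect_identical(d1$tokens, s$tokens)

  d2 <- annotate(s, m, "D2")
  expect_true("c0002771" %in% d2$tokens$surface)       # concept token
  expect_false("dora" %in% d2$tokens$surface)

  d3 <- annotate(s, m, "D3")
  expect_true("dora" %in% d3$tokens$surface)           # semtype token
  expect_false("c0035096" %in% d3$tokens$surface)

  d4 <- annotate(s, m, "D4")
  expect_true(all(c("c0035096", "dora", "c0002771", "phsu") %in%
                    d4$tokens$surface))
  # original word tokens retained in all four variants
  expect_true(all(s$tokens$surface %in% d4$tokens$surface))

  # overlapping matches are rejected
  bad <- m[c(1, 1), ]
  bad$end_index[1] <- bad$end_index[1] + 1L
  expect_error(annotate(s, bad, "D2"), "overlap")
})

test_that("exactly the four presets exist with the stated flags", {
  flags <- t(vapply(c("D1", "D2", "D3", "D4"), function(v) {
    ev <- enrichment_variant(v)
    c(ev$include_words, ev$include_concepts, ev$include_semtypes)
  }, logical(3)))
  expect_identical(unname(flags),
                   matrix(c(TRUE, FALSE, FALSE,
                            TRUE, TRUE, FALSE,
                            TRUE, FALSE, TRUE,
                            TRUE, TRUE, TRUE), 4, byrow = TRUE))
  expect_error(enrichment_variant("D5"), "arg")
})

test_that("synonym aggregation: D2 shares the concept token, D1 nothing", {
  sim <- fixture("sim_small")
  cl <- sim$lexica$clusters
  cid <- cl$concept_id[1]
  surfaces <- cl$surface[cl$concept_id == cid]
  expect_identical(length(surfaces), 2L)
  sa <- tokenize(regularize(raw_letter("a", paste("patient reports",
                                                  surfaces[1]))), "stem")
  sb <- tokenize(regularize(raw_letter("b", paste("patient reports",
                                                  surfaces[2]))), "stem")
  for (variant in c("D1", "D2")) {
    ea <- annotate(sa, match_concepts(sa, sim$lexica$concept), variant)
    eb <- annotate(sb, match_concepts(sb, sim$lexica$concept), variant)
    shared <- intersect(ea$tokens$surface, eb$tokens$surface)
    shared <- setdiff(shared, c("patient", "report"))
    if (variant == "D2") {
      expect_identical(shared, tolower(cid))
    } else {
      expect_identical(shared, character(0))
    }
  }
})

test_that("build_bow counts, filters and conserves totals", {
  mk <- function(id, toks) token_stream(id, toks, rep("WORD", length(toks)),
                                        seq_along(toks), seq_along(toks))
  s1 <- mk("d1", c("a", "b", "a"))
  s2 <- mk("d2", c("b", "c"))
  b1 <- build_bow(list(s1, s2), min_df = 1L, max_df = 1)
  expect_identical(b1$vocab, c("a", "b", "c"))
  expect_identical(unname(b1$counts),
                   matrix(c(2L, 1L, 0L, 0L, 1L, 1L), 2, byrow = TRUE))

  b2 <- build_bow(list(s1, s2), min_df = 2L, max_df = 1)
  expect_identical(b2$vocab, "b")
  expect_identical(b2$empty_docs, character(0))

  # count conservation against a direct recount on 100 synthetic docs
  enr <- fixture("enriched_small")
  bow <- build_bow(enr, min_df = 1L, max_df = 1)
  recount <- sum(vapply(enr, function(s)
    sum(s$tokens$surface != person_mask_token()), integer(1)))
  expect_identical(sum(bow$counts), recount)
  rs <- rowSums(bow$counts)
  per_doc <- vapply(enr, function(s)
    sum(s$tokens$surface != person_mask_token()), integer(1))
  expect_identical(unname(rs), as.numeric(per_doc))

  expect_error(build_bow(list(mk("d", character()))), "all_empty_corpus")
})
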