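vlex <- read_variant_lexicon(
  system.file("extdata", "variant_lexicon.tsv", package = "lettertopics"))

test_that("regularize expands abbreviations and enclitics, lowercases", {
  l <- raw_letter("a", "He had a TKR and attends physio, but hasn't improved!")
  r <- regularize(l, vlex)
  expect_match(r$text, "total knee replacement")
  expect_match(r$text, "physiotherapy")
  expect_match(r$text, "has not improved")
  expect_false(grepl("[A-Z]", r$text))
  expect_false(grepl("'", r$text))

  # identity case: lowercase text, no lexicon keys, no enclitics
  plain <- regularize(raw_letter("b", "knee pain for months"), vlex)
  expect_identical(plain$text, "knee pain for months")

  expect_error(raw_letter("c", "   "), "empty_letter")
})

test_that("regularize is idempotent on random synthetic letters", {
  sim <- fixture("sim_small")
  lets <- c(fixture("sim_small")$letters[1:50], random_letters(150, 31L))
  for (l in lets) {
    r1 <- regularize(l, sim$lexica$variant)
    r2 <- regularize(r1, sim$lexica$variant)
    expect_identical(r2$text, r1$text)
  }
})

test_that("honorific-triggered names are masked, eponyms survive", {
  mask <- person_mask_token()
  r <- mask_personal_names(raw_letter("a", "She was referred to Dr Jane Doe."))
  expect_identical(r$text, sprintf("She was referred to %s.", mask))

  r <- mask_personal_names(raw_letter("b", "There is pain with McMurray test."))
  expect_identical(r$text, "There is pain with McMurray test.")

  r <- mask_personal_names(raw_letter("c", "a baker cyst was found"))
  expect_identical(r$text, "a baker cyst was found")

  # patient pattern trigger family
  r <- mask_personal_names(raw_letter("d", "Thank you for seeing John Smith today."))
  expect_identical(r$text, sprintf("Thank you for seeing %s today.", mask))

  # honorific with trailing period, multiple names
  r <- mask_personal_names(raw_letter("e", "seen by Mr. David Rhys Jones in clinic"))
  expect_identical(r$text, sprintf("seen by %s in clinic", mask))
})

test_that("masking never touches tokens outside honorific windows", {
  lets <- fixture("sim_small")$letters[1:40]
  for (l in lets) {
    masked <- mask_personal_names(l)
    # strip matched windows from the original: remaining word sequences
    # must appear unchanged, in order
    orig_words <- strsplit(l$text, "\\s+")[[1]]
    new_words <- strsplit(masked$text, "\\s+")[[1]]
    # the mask may inherit trailing punctuation of the replaced window
    kept <- new_words[!startsWith(new_words, person_mask_token())]
    expect_true(all(kept %in% orig_words))
  }
})

test_that("tokenize reduces per mode, drops stop-words, keeps spans", {
  l <- regularize(raw_letter("a", "the injuries were not improving"))
  st <- tokenize(l, "stem")
  expect_true("injuri" %in% st$tokens$surface)     # Porter stem
  lm <- tokenize(l, "lemma")
  expect_true("injury" %in% lm$tokens$surface)     # lemma lookup
  expect_false("the" %in% st$tokens$surface)       # stop-word removed
  expect_true("not" %in% st$tokens$surface)        # negation cue retained
  expect_error(tokenize(l, "porter"), "arg")

  # spans index the regularized text (0-based, half-open): the raw text
  # at each span must stem to the token surface
  pieces <- substring(l$text, st$tokens$start + 1L, st$tokens$end)
  expect_identical(porter_stem(pieces), st$tokens$surface)

  # empty stream after stop-word removal is not an error
  e <- tokenize(regularize(raw_letter("b", "the of and")), "stem")
  expect_identical(nrow(e$tokens), 0L)
})

test_that("token spans round-trip to the regularized text", {
  sim <- fixture("sim_small")
  for (l in sim$letters[1:30]) {
    r <- regularize(l, sim$lexica$variant)
    st <- tokenize(r, "stem", keep_mask = TRUE)
    pieces <- substring(r$text, st$tokens$start + 1L, st$tokens$end)
    # each span recovers one whitespace-delimited token of the text
    expect_true(all(pieces %in% strsplit(r$text, " ")[[1]]))
    expect_true(all(diff(st$tokens$start) >= 0))
  }
})

test_that("porter stemmer matches canonical reference outputs", {
  ref <- c(caresses = "caress", ponies = "poni", ties = "ti", cats = "cat",
           feed = "feed", agreed = "agre", plastered = "plaster",
           motoring = "motor", sing = "sing", conflated = "conflat",
           hopping = "hop", tanned = "tan", falling = "fall",
           hissing = "hiss", failing = "fail", filing = "file",
           happy = "happi", sky = "sky", relational = "relat",
           conditional = "condit", rational = "ration",
           valenci = "valenc", digitizer = "digit", radicalli = "radic",
           differentli = "differ", vileli = "vile",
           analogousli = "analog", predication = "predic",
           operator = "oper", feudalism = "feudal",
           decisiveness = "decis", hopefulness = "hope",
           callousness = "callous", formaliti = "formal",
           sensitiviti = "sensit", sensibiliti = "sensibl",
           triplicate = "triplic", formative = "form",
           formalize = "formal", electriciti = "electr",
           electrical = "electr", hopeful = "hope", goodness = "good",
           revival = "reviv", allowance = "allow", inference = "infer",
           airliner = "airlin", gyroscopic = "gyroscop",
           adjustable = "adjust", defensible = "defens",
           irritant = "irrit", replacement = "replac",
           adjustment = "adjust", dependent = "depend",
           adoption = "adopt", communism = "commun", activate = "activ",
           effective = "effect", probate = "probat", rate = "rate",
           cease = "ceas", controll = "control", roll = "roll",
           injuries = "injuri")
  expect_identical(porter_stem(names(ref)), unname(ref))
})

test_that("corpus IO round-trips through JSON lines", {
  sim <- fixture("sim_small")
  lets <- sim$letters[1:5]
  lets[[1]]$treatments <- c("O5", "O8")
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(lets, path)
  back <- read_corpus(path)
  expect_identical(vapply(back, `[[`, "", "id"),
                   vapply(lets, `[[`, "", "id"))
  expect_identical(back[[1]]$text, lets[[1]]$text)
  expect_identical(back[[1]]$treatments, c("O5", "O8"))
})

test_that("variant lexicon rejects chained mappings and duplicates", {
  expect_error(variant_lexicon(c(a = "b", b = "c")), "one-step")
  expect_error(variant_lexicon(setNames(c("x", "y"), c("a", "a"))),
               "duplicate")
})
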