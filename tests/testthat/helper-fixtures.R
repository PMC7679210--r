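# Shared fixtures, built lazily once per test run. Everything is generated
# in code from fixed seeds; nothing is read from disk except the shipped
# extdata configuration files.

.fx <- new.env(parent = emptyenv())

fixture <- function(name) {
  if (!exists(name, envir = .fx)) {
    assign(name, switch(name,
      # small world: quick pipeline / property tests
      sim_small = generate_all(sim_config(K_true = 4L, D = 80L,
                                          n_core = 150L, n_clusters = 8L,
                                          n_abbrev = 6L,
                                          doc_len_mean = 60,
                                          seed = 2024L)),
      streams_small = {
        s <- fixture("sim_small")
        prepare_corpus(s$letters, s$lexica$variant, mode = "stem")
      },
      enriched_small = {
        s <- fixture("sim_small")
        enrich_corpus(fixture("streams_small"), s$lexica$concept, "D2")
      },
      bow_small = build_bow(fixture("enriched_small")),
      model_small = suppressWarnings(
        fit_lda(fixture("bow_small"), K = 4L, seed = 7L,
                iterations = 300L, burn_in = 150L)),
      # default world: the stated conditions (D = 500, K_true = 11)
      sim_default = generate_all(sim_config(seed = 42L)),
      streams_default = {
        s <- fixture("sim_default")
        prepare_corpus(s$letters, s$lexica$variant, mode = "stem")
      },
      enriched_default = {
        s <- fixture("sim_default")
        enrich_corpus(fixture("streams_default"), s$lexica$concept, "D2")
      },
      bow_default = build_bow(fixture("enriched_default")),
      model_default = suppressWarnings(
        fit_lda(fixture("bow_default"), K = 11L, seed = 7L,
                iterations = 1000L, burn_in = 500L)),
      # five-planted-topic world for K selection
      sim_k5 = generate_all(sim_config(K_true = 5L, D = 300L,
                                       seed = 11L)),
      enriched_k5 = {
        s <- fixture("sim_k5")
        enrich_corpus(prepare_corpus(s$letters, s$lexica$variant),
                      s$lexica$concept, "D2")
      },
      bow_k5 = build_bow(fixture("enriched_k5")),
      stop("unknown fixture: ", name)), envir = .fx)
  }
  get(name, envir = .fx)
}

# deterministic pseudo-letters without the generator, for textprep tests
random_letters <- function(n, seed) {
  words <- c("knee", "pain", "swelling", "injury", "physio", "tkr",
             "mri", "ligament", "meniscus", "tear", "clinic", "injection",
             "exercise", "history", "chronic", "acute", "left", "right")
  out <- vector("list", n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(n)) {
    body <- paste(sample(words, 25, replace = TRUE), collapse = " ")
    out[[i]] <- raw_letter(paste0("r", i),
                           sprintf("Dear Dr %s. Thank you for seeing %s %s. %s.",
                                   sample(c("Evans", "Jones"), 1),
                                   sample(c("Alice", "Tom"), 1),
                                   sample(c("Hughes", "Price"), 1), body))
  }
  out
}
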