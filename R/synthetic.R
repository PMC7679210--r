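# run expr with a temporary, seeded RNG state; the caller's state is
# untouched, so generation is fully determined by the explicit seed
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Configuration of the synthetic referral-letter generator
#'
#' The stated world of the generator: documents are drawn from a K-topic
#' mixture (Dirichlet document-topic prior, multinomial word emission)
#' over a vocabulary of core pseudo-words plus synonym clusters sharing a
#' concept identifier; a subset of words has abbreviations expanded back
#' by the variant lexicon; letters are wrapped in boilerplate with
#' honorific-prefixed personal names; nine binary treatment outcomes have
#' prevalences matching the study's treatment distribution (53, 173, 101,
#' 15, 152, 112, 99, 223, 16 positives of 576) and probabilities that
#' depend on the document's topic mixture through a logistic link.
#'
#' @param K_true number of planted topics (default 11, the study's
#'   selected topic count).
#' @param D number of documents (default 500, near the study's 576).
#' @param n_core core vocabulary size (default 480; with clusters the
#'   effective vocabulary is about 600 surface forms).
#' @param n_clusters synonym clusters (default 25, two surfaces each).
#' @param n_eponyms eponymous clinical terms inserted without honorifics.
#' @param n_abbrev core words that also have an abbreviated surface form.
#' @param doc_len_mean,doc_len_disp negative-binomial document length
#'   (mean 120 tokens, dispersion 20).
#' @param alpha_true symmetric Dirichlet document-topic prior (0.1:
#'   letters are dominated by few themes).
#' @param beta_true topic-word concentration (0.05: sparse, well
#'   separated topics).
#' @param p_synonym probability that a cluster emission uses the second
#'   synonym surface.
#' @param p_abbrev probability that an abbreviated word is emitted in its
#'   short form.
#' @param prevalence target treatment prevalences (defaults: the study's
#'   nine treatment counts over 576 patients).
#' @param effect per-treatment log-odds weight vectors over topics
#'   (9 x K_true matrix); default gives treatment t weight 3 on topic
#'   1 + (t-1) mod K_true and 0 elsewhere.
#' @param seed mandatory integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(K_true = 11L, D = 500L, n_core = 480L,
                       n_clusters = 25L, n_eponyms = 8L, n_abbrev = 15L,
                       doc_len_mean = 120, doc_len_disp = 20,
                       alpha_true = 0.1, beta_true = 0.05,
                       p_synonym = 0.5, p_abbrev = 0.3,
                       prevalence = c(53, 173, 101, 15, 152, 112, 99,
                                      223, 16) / 576,
                       effect = NULL, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(K_true >= 2L, all(prevalence > 0), all(prevalence < 1),
            length(prevalence) == 9L)
  if (is.null(effect)) {
    effect <- matrix(0, nrow = 9L, ncol = K_true)
    for (t in 1:9) effect[t, 1L + (t - 1L) %% K_true] <- 3
  }
  stopifnot(nrow(effect) == 9L, ncol(effect) == K_true)
  structure(list(K_true = as.integer(K_true), D = as.integer(D),
                 n_core = as.integer(n_core),
                 n_clusters = as.integer(n_clusters),
                 n_eponyms = as.integer(n_eponyms),
                 n_abbrev = as.integer(n_abbrev),
                 doc_len_mean = doc_len_mean, doc_len_disp = doc_len_disp,
                 alpha_true = alpha_true, beta_true = beta_true,
                 p_synonym = p_synonym, p_abbrev = p_abbrev,
                 prevalence = prevalence, effect = effect,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# pronounceable pseudo-words that are fixed points of the stemmer and the
# lemmatizer, so they pass unchanged through the preprocessing pipeline
.make_pseudowords <- function(n, seed, min_syl = 2L, max_syl = 3L,
                              avoid = character()) {
  onset <- c("b", "br", "c", "cl", "d", "dr", "f", "fl", "g", "gr", "h",
             "j", "k", "l", "m", "n", "p", "pr", "r", "s", "st", "t",
             "tr", "v", "w", "z")
  nucleus <- c("a", "e", "i", "o", "u", "ar", "or", "an", "en", "on",
               "un", "el", "ol", "ur")
  .with_seed(seed, {
    out <- character(0)
    guard <- 0L
    while (length(out) < n && guard < 60L) {
      guard <- guard + 1L
      cand <- vapply(seq_len(2L * n), function(i) {
        k <- sample(min_syl:max_syl, 1L)
        paste0(paste0(sample(onset, k, TRUE), sample(nucleus, k, TRUE),
                      collapse = ""), sample(c("d", "k", "m", "p", "t", "x"),
                                             1L))
      }, character(1))
      cand <- setdiff(unique(cand), c(out, avoid))
      ok <- porter_stem(cand) == cand & lemmatize(cand) == cand
      out <- c(out, cand[ok])
    }
    if (length(out) < n) stop("could not generate enough pseudo-words")
    out[seq_len(n)]
  })
}

.first_names <- c("James", "Oliver", "Harry", "George", "Thomas", "Jack",
                  "Emily", "Olivia", "Amelia", "Isla", "Sophie", "Grace",
                  "Megan", "Daniel", "Rhys", "Carys", "Owen", "Ffion")
.surnames <- c("Jones", "Davies", "Williams", "Evans", "Thomas", "Roberts",
               "Lewis", "Hughes", "Morgan", "Griffiths", "Owen", "Rees",
               "Jenkins", "Price", "Morris", "Edwards")
.eponym_pool <- c("baker cyst", "mcmurray test", "hoffa fat pad",
                  "lachman test", "ege test", "trendelenburg gait",
                  "osgood schlatter disease", "thessaly test",
                  "apley grind test", "noble test")

#' Generate the toy lexica for a synthetic corpus
#'
#' Emits a concept lexicon containing the published markup-example term
#' clusters (synonyms sharing one CUI, sports terms sharing the DORA
#' semantic type) from the bundled file, plus `n_clusters` random synonym
#' clusters whose two surfaces map to one synthetic concept id, and a
#' variant lexicon with the standard abbreviations (tkr, physio, ...)
#' plus generated abbreviation pairs.
#'
#' @param cfg a [sim_config()].
#' @return list with `concept` ([concept_lexicon()]), `variant`
#'   ([variant_lexicon()]), `clusters` (data.frame surface, concept_id),
#'   `abbrev` (data.frame short, full), `core_words`, `eponyms`.
#' @export
generate_lexicon <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  base <- read.delim(.extdata("concept_lexicon.tsv"), header = FALSE,
                     comment.char = "#", stringsAsFactors = FALSE,
                     col.names = c("term", "concept_id", "semtype"))
  avoid <- c(.default_stopwords(),
             unlist(strsplit(base$term, "\\s+")), "no", "not")
  words <- .make_pseudowords(cfg$n_core + 2L * cfg$n_clusters,
                             seed = cfg$seed + 101L, avoid = avoid)
  core <- words[seq_len(cfg$n_core)]
  syn <- matrix(words[cfg$n_core + seq_len(2L * cfg$n_clusters)],
                ncol = 2L)
  cluster_ids <- sprintf("C9%06d", seq_len(cfg$n_clusters))
  clusters <- data.frame(surface = c(syn[, 1L], syn[, 2L]),
                         concept_id = rep(cluster_ids, 2L),
                         stringsAsFactors = FALSE)
  # abbreviations: short forms of emitted core words, so the variant
  # lexicon actually gets exercised by the corpus
  full <- .with_seed(cfg$seed + 201L, sample(core, cfg$n_abbrev))
  shipped <- read_variant_lexicon(.extdata("variant_lexicon.tsv"))
  reserved <- c(names(shipped), .default_stopwords(),
                "dear", "thank", "seeing", "presents", "follows",
                "yours", "sincerely")
  short <- .with_seed(cfg$seed + 202L, {
    s <- vapply(full, function(w) {
      ch <- strsplit(w, "")[[1]]
      paste0(ch[1L], paste(sample(ch[-1L], 2L), collapse = ""))
    }, character(1))
    # de-duplicate (and keep clear of shipped keys and boilerplate)
    while (anyDuplicated(s) || any(s %in% reserved)) {
      d <- which(duplicated(s) | s %in% reserved)
      s[d] <- paste0(s[d], sample(c("q", "x", "z"), length(d), TRUE))
    }
    s
  })
  abbrev <- data.frame(short = unname(short), full = full,
                       stringsAsFactors = FALSE)
  concept <- concept_lexicon(
    term = c(base$term, clusters$surface),
    concept_id = c(base$concept_id, clusters$concept_id),
    semtype = c(base$semtype, rep("fndg", nrow(clusters))))
  variant <- variant_lexicon(c(unclass(shipped),
                               setNames(abbrev$full, abbrev$short)))
  eponyms <- .with_seed(cfg$seed + 303L,
                        sample(.eponym_pool, cfg$n_eponyms))
  list(concept = concept, variant = variant, clusters = clusters,
       abbrev = abbrev, core_words = core, eponyms = eponyms)
}

#' Generate a synthetic referral-letter corpus with ground truth
#'
#' Per document: draw theta from Dirichlet(alpha_true); draw tokens from
#' the planted topic-word distributions over the semantic vocabulary
#' (core words + synonym-cluster concepts); cluster emissions surface as
#' one of the cluster's synonyms; abbreviated words surface in their
#' short form with probability `p_abbrev`; the body is wrapped in
#' boilerplate containing an honorific plus a fabricated capitalized
#' name (always recorded), with occasional eponyms and sentence marks.
#'
#' @param cfg a [sim_config()].
#' @param lexica optional result of [generate_lexicon()] (regenerated
#'   from `cfg` if omitted).
#' @return list with `letters` (list of [raw_letter()]) and `truth`
#'   (class `ground_truth`: phi (K x V_sem), theta (D x K),
#'   semantic_vocab, synonym_map, name_spans, doc_lengths, lexica, cfg).
#' @export
generate_corpus <- function(cfg, lexica = generate_lexicon(cfg)) {
  stopifnot(inherits(cfg, "sim_config"))
  core <- lexica$core_words
  cluster_ids <- unique(lexica$clusters$concept_id)
  sem_vocab <- c(core, tolower(cluster_ids))
  V <- length(sem_vocab)
  K <- cfg$K_true
  syn1 <- lexica$clusters$surface[seq_along(cluster_ids)]
  syn2 <- lexica$clusters$surface[length(cluster_ids) + seq_along(cluster_ids)]
  abbrev_of <- setNames(lexica$abbrev$short, lexica$abbrev$full)

  .with_seed(cfg$seed, {
    phi <- .rdirichlet(K, rep(cfg$beta_true, V))
    colnames(phi) <- sem_vocab
    theta <- .rdirichlet(cfg$D, rep(cfg$alpha_true, K))
    lens <- pmax(30L, rnbinom(cfg$D, mu = cfg$doc_len_mean,
                              size = cfg$doc_len_disp))
    letters <- vector("list", cfg$D)
    name_spans <- vector("list", cfg$D)
    for (d in seq_len(cfg$D)) {
      z <- sample.int(K, lens[d], replace = TRUE, prob = theta[d, ])
      wid <- integer(lens[d])
      for (k in unique(z)) {
        sel <- z == k
        wid[sel] <- sample.int(V, sum(sel), replace = TRUE,
                               prob = phi[k, ])
      }
      toks <- sem_vocab[wid]
      is_cluster <- wid > length(core)
      if (any(is_cluster)) {
        ci <- wid[is_cluster] - length(core)
        use2 <- runif(sum(is_cluster)) < cfg$p_synonym
        toks[is_cluster] <- ifelse(use2, syn2[ci], syn1[ci])
      }
      has_abbr <- toks %in% names(abbrev_of)
      if (any(has_abbr)) {
        flip <- has_abbr & runif(length(toks)) < cfg$p_abbrev
        toks[flip] <- abbrev_of[toks[flip]]
      }
      if (length(lexica$eponyms) && runif(1) < 0.4) {
        pos <- sample.int(length(toks), 1L)
        toks <- append(toks, sample(lexica$eponyms, 1L), after = pos)
      }
      # sentence marks roughly every 12 tokens
      nb <- max(1L, length(toks) %/% 12L)
      brk <- sort(sample.int(length(toks) - 1L, min(nb, length(toks) - 1L)))
      toks[brk] <- paste0(toks[brk], ".")
      gp <- sample(.surnames, 1L)
      first <- sample(.first_names, 1L)
      last <- sample(.surnames, 1L)
      body <- paste(toks, collapse = " ")
      txt <- sprintf(
        "Dear Dr %s. Thank you for seeing %s %s who presents as follows. %s Yours sincerely. Dr %s %s",
        gp, first, last, body,
        sample(.first_names, 1L), sample(.surnames, 1L))
      name_spans[[d]] <- c(paste("Dr", gp), paste(first, last))
      letters[[d]] <- raw_letter(sprintf("doc%04d", d), txt)
    }
    truth <- structure(list(phi = phi, theta = theta,
                            semantic_vocab = sem_vocab,
                            synonym_map = setNames(
                              tolower(lexica$clusters$concept_id),
                              lexica$clusters$surface),
                            name_spans = name_spans,
                            doc_lengths = lens, lexica = lexica,
                            cfg = cfg),
                       class = "ground_truth")
    list(letters = letters, truth = truth)
  })
}

#' Draw treatment labels from the planted topic mixtures
#'
#' For document d and treatment t,
#' `P(t) = logistic(intercept_t + effect_t . theta_d)`; the intercepts
#' are auto-calibrated by one-dimensional root finding so the expected
#' prevalence over the corpus matches the target within 0.005. Labels
#' are drawn independently across treatments.
#'
#' @param truth a `ground_truth` from [generate_corpus()].
#' @param cfg the same [sim_config()].
#' @return named list doc id -> character vector of treatment codes,
#'   with attributes `intercepts` and `probabilities` (D x 9).
#' @export
generate_treatments <- function(truth, cfg = truth$cfg) {
  stopifnot(inherits(truth, "ground_truth"))
  theta <- truth$theta
  D <- nrow(theta)
  codes <- names(treatment_codes())
  probs <- matrix(0, D, 9L, dimnames = list(NULL, codes))
  intercepts <- numeric(9L)
  for (t in 1:9) {
    eta <- as.numeric(theta %*% cfg$effect[t, ])
    f <- function(b) mean(stats::plogis(b + eta)) - cfg$prevalence[t]
    if (f(-30) > 0 || f(30) < 0) {
      stop("calibration error: prevalence ", cfg$prevalence[t],
           " unattainable for treatment ", codes[t], call. = FALSE)
    }
    b <- uniroot(f, c(-30, 30), tol = 1e-10)$root
    if (abs(f(b)) > 0.005) {
      stop("calibration error: residual above tolerance for ", codes[t],
           call. = FALSE)
    }
    intercepts[t] <- b
    probs[, t] <- stats::plogis(b + eta)
  }
  labels <- .with_seed(cfg$seed + 404L, {
    draw <- matrix(rbinom(D * 9L, 1L, as.numeric(probs)), D, 9L)
    lapply(seq_len(D), function(d) codes[draw[d, ] == 1L])
  })
  names(labels) <- sprintf("doc%04d", seq_len(D))
  attr(labels, "intercepts") <- setNames(intercepts, codes)
  attr(labels, "probabilities") <- probs
  labels
}

#' Generate corpus, lexica and labels in one call
#'
#' @param cfg a [sim_config()].
#' @return list with `letters`, `truth`, `labels`, `lexica`.
#' @export
generate_all <- function(cfg) {
  lexica <- generate_lexicon(cfg)
  corp <- generate_corpus(cfg, lexica)
  labels <- generate_treatments(corp$truth, cfg)
  list(letters = corp$letters, truth = corp$truth, labels = labels,
       lexica = lexica)
}

#' Match planted to learned topics by cosine similarity
#'
#' Each planted topic is compared to every learned topic on the shared
#' dimensions (planted semantic vocabulary mapped into the learned
#' vocabulary; absent dimensions contribute zero), and greedily matched
#' to its nearest unused learned topic, best pairs first.
#'
#' @param truth a `ground_truth`.
#' @param model a fitted [fit_lda()] model.
#' @return list with `pairs` (planted, learned, cosine) and
#'   `mean_cosine`.
#' @export
match_topics <- function(truth, model) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(model, "topic_model"))
  dims <- truth$semantic_vocab
  learned <- matrix(0, nrow = model$K, ncol = length(dims))
  hit <- dims %in% model$vocabulary
  learned[, hit] <- model$phi[, dims[hit], drop = FALSE]
  planted <- truth$phi
  K <- nrow(planted)
  sim <- matrix(0, K, model$K)
  for (i in seq_len(K)) {
    for (j in seq_len(model$K)) {
      sim[i, j] <- .cosine(planted[i, ], learned[j, ])
    }
  }
  pairs <- data.frame(planted = integer(), learned = integer(),
                      cosine = numeric())
  s <- sim
  for (step in seq_len(min(K, model$K))) {
    ij <- arrayInd(which.max(s), dim(s))
    pairs <- rbind(pairs, data.frame(planted = ij[1L], learned = ij[2L],
                                     cosine = s[ij]))
    s[ij[1L], ] <- -Inf
    s[, ij[2L]] <- -Inf
  }
  list(pairs = pairs[order(pairs$planted), ],
       mean_cosine = mean(pairs$cosine))
}
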