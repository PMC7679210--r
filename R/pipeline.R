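#' Experiment configuration
#'
#' Describes one full experiment grid: which feature variants to build
#' (D1-D4), the preprocessing mode, the number of topics (or a grid to
#' search), which coherence measures to report, the classifier settings,
#' and explicit seeds. All settings are recorded in the run manifest so
#' any report can be reproduced bit-identically.
#'
#' @param corpus path to a JSON-lines corpus, or a list of
#'   [raw_letter()] objects.
#' @param concept_lexicon path to a concept lexicon TSV, or a
#'   [concept_lexicon()] object (default: the bundled toy lexicon).
#' @param variant_lexicon path or [variant_lexicon()] object (default:
#'   the bundled abbreviation lexicon).
#' @param variants subset of c("D1","D2","D3","D4").
#' @param mode `"stem"` or `"lemma"`.
#' @param K number of topics, or an integer grid (length >= 3) to search
#'   by coherence.
#' @param measures coherence measures to report.
#' @param knn_k,folds classifier settings.
#' @param labels optional named list doc id -> treatment codes; when
#'   present the triage cross-validation runs.
#' @param window concept-matching window.
#' @param min_df bag-of-words document-frequency floor.
#' @param iterations,burn_in sampler settings.
#' @param seed explicit integer seed.
#' @param out_dir output directory, or `NULL` for no files.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(corpus, concept_lexicon = NULL,
                              variant_lexicon = NULL,
                              variants = c("D1", "D2", "D3", "D4"),
                              mode = "stem", K = 11L,
                              measures = c("c_uci", "c_npmi", "c_umass",
                                           "c_v"),
                              knn_k = 5L, folds = 10L, labels = NULL,
                              window = 8L, min_df = 1L,
                              iterations = 400L, burn_in = 200L,
                              seed, out_dir = NULL) {
  if (missing(seed)) stop("seeds must be explicit", call. = FALSE)
  stopifnot(length(variants) >= 1L,
            all(variants %in% c("D1", "D2", "D3", "D4")))
  if (is.character(corpus) && !file.exists(corpus)) {
    stop("corpus path does not exist: ", corpus, call. = FALSE)
  }
  structure(list(corpus = corpus,
                 concept_lexicon = concept_lexicon,
                 variant_lexicon = variant_lexicon,
                 variants = variants, mode = mode, K = as.integer(K),
                 measures = measures, knn_k = as.integer(knn_k),
                 folds = as.integer(folds), labels = labels,
                 window = as.integer(window), min_df = as.integer(min_df),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

.log_stage <- function(stage, msg) {
  message(sprintf("[%s] %s | %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, msg))
}

#' Run a full experiment grid
#'
#' For each feature variant: preprocess the corpus, enrich it, build the
#' bag of words, fit the topic model (or search a K grid by coherence),
#' score every configured coherence measure, and — when labels are
#' present — run the per-treatment cross-validated classifier with its
#' stratified random baseline. The returned bundle carries a manifest
#' (all seeds and parameters) from which [rerun_manifest()] reproduces
#' every number exactly. A stage failure is recorded and the remaining
#' variants still run.
#'
#' @param cfg an [experiment_config()].
#' @return list of class `experiment_report`: `coherence` (variant x
#'   measure data.frame), `accuracy` (treatment x variant, with
#'   baseline), `models`, `chosen_K`, `errors`, `manifest`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  letters <- if (is.character(cfg$corpus)) read_corpus(cfg$corpus)
             else cfg$corpus
  clex <- cfg$concept_lexicon
  if (is.null(clex)) clex <- read_concept_lexicon(.extdata("concept_lexicon.tsv"))
  if (!inherits(clex, "concept_lexicon")) clex <- read_concept_lexicon(clex)
  vlex <- cfg$variant_lexicon
  if (is.null(vlex)) vlex <- read_variant_lexicon(.extdata("variant_lexicon.tsv"))
  if (!inherits(vlex, "variant_lexicon")) vlex <- read_variant_lexicon(vlex)

  labels <- cfg$labels
  if (is.null(labels)) {
    has <- vapply(letters, function(l) length(l$treatments) > 0L,
                  logical(1))
    if (any(has)) {
      labels <- lapply(letters, `[[`, "treatments")
      names(labels) <- vapply(letters, `[[`, "", "id")
    }
  }

  .log_stage("prep", sprintf("%d letters, mode=%s", length(letters),
                             cfg$mode))
  streams <- prepare_corpus(letters, vlex, mode = cfg$mode)

  coh_rows <- list(); acc_tabs <- list(); models <- list()
  chosen_K <- list(); errors <- list()
  for (v in cfg$variants) {
    res <- tryCatch({
      .log_stage("enrich", v)
      enriched <- enrich_corpus(streams, clex, variant = v,
                                window = cfg$window)
      bow <- build_bow(enriched, min_df = cfg$min_df)
      stats_doc <- build_cooc(enriched, window = "document")
      if (length(cfg$K) >= 3L) {
        .log_stage("select-k", sprintf("%s grid %s", v,
                                       paste(range(cfg$K), collapse = ":")))
        sel <- select_k_by_coherence(bow, stats_doc, cfg$K,
                                     coherence_config("c_v",
                                                      window = "document"),
                                     seeds = cfg$seed,
                                     iterations = cfg$iterations,
                                     burn_in = cfg$burn_in)
        Kv <- sel$K
      } else Kv <- cfg$K
      chosen_K[[v]] <- Kv
      .log_stage("fit", sprintf("%s K=%d seed=%d", v, Kv, cfg$seed))
      model <- suppressWarnings(
        fit_lda(bow, K = Kv, seed = cfg$seed,
                iterations = cfg$iterations, burn_in = cfg$burn_in))
      models[[v]] <- model
      row <- list(variant = v)
      for (msr in cfg$measures) {
        ccfg <- coherence_config(msr, window = "document")
        row[[msr]] <- suppressWarnings(
          topic_coherence(model, stats_doc, ccfg)$mean)
      }
      coh_rows[[v]] <- as.data.frame(row, stringsAsFactors = FALSE)
      if (!is.null(labels)) {
        .log_stage("triage", v)
        ds <- make_dataset(model, labels)
        tt <- triage_table(ds, k = cfg$knn_k, folds = cfg$folds,
                           seed = cfg$seed)
        tt$variant <- v
        acc_tabs[[v]] <- tt
      }
      TRUE
    }, error = function(e) {
      errors[[v]] <<- conditionMessage(e)
      .log_stage("error", sprintf("%s: %s", v, conditionMessage(e)))
      FALSE
    })
    invisible(res)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("lettertopics")),
    variants = cfg$variants, mode = cfg$mode, K = cfg$K,
    measures = cfg$measures, knn_k = cfg$knn_k, folds = cfg$folds,
    window = cfg$window, min_df = cfg$min_df,
    iterations = cfg$iterations, burn_in = cfg$burn_in, seed = cfg$seed,
    corpus_hash = .corpus_hash(letters),
    labels = labels,
    # the exact lexica are part of the reproducibility contract
    concept_lexicon = clex, variant_lexicon = vlex)
  report <- structure(list(
    coherence = do.call(rbind, coh_rows),
    accuracy = if (length(acc_tabs)) do.call(rbind, acc_tabs) else NULL,
    models = models, chosen_K = chosen_K, errors = errors,
    manifest = manifest, letters = letters), class = "experiment_report")
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(report$coherence,
              file.path(cfg$out_dir, "coherence.csv"), row.names = FALSE)
    if (!is.null(report$accuracy)) {
      write.csv(report$accuracy,
                file.path(cfg$out_dir, "accuracy.csv"), row.names = FALSE)
    }
    man <- manifest
    man$concept_lexicon <- data.frame(term = clex$term,
                                      concept_id = clex$concept_id,
                                      semtype = clex$semtype,
                                      stringsAsFactors = FALSE)
    man$variant_lexicon <- as.list(unclass(vlex))
    jsonlite::write_json(man, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

# order-stable content hash of a corpus (no external digest dependency)
.corpus_hash <- function(letters) {
  txt <- paste(vapply(letters, function(l)
    paste(l$id, l$text, sep = "\r"), character(1)), collapse = "\n")
  # FNV-1a over UTF-8 bytes, reported as hex
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes %% 256) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\nCoherence:\n")
  print(x$coherence)
  if (!is.null(x$accuracy)) {
    cat("Accuracy (mean over folds):\n")
    print(x$accuracy)
  }
  if (length(x$errors)) {
    cat("Errors:\n"); print(unlist(x$errors))
  }
  invisible(x)
}

#' Re-run an experiment from its manifest
#'
#' Rebuilds the experiment configuration recorded in a report's manifest
#' and runs it on the same letters; with the recorded seeds the resulting
#' report is bit-identical.
#'
#' @param report an `experiment_report` (or a manifest list plus
#'   `letters`).
#' @param letters corpus; defaults to the letters carried by the report.
#' @return a new `experiment_report`.
#' @export
rerun_manifest <- function(report, letters = report$letters) {
  man <- report$manifest
  cfg <- experiment_config(corpus = letters,
                           concept_lexicon = man$concept_lexicon,
                           variant_lexicon = man$variant_lexicon,
                           variants = man$variants,
                           mode = man$mode, K = man$K,
                           measures = man$measures, knn_k = man$knn_k,
                           folds = man$folds, labels = man$labels,
                           window = man$window, min_df = man$min_df,
                           iterations = man$iterations,
                           burn_in = man$burn_in, seed = man$seed)
  run_experiment(cfg)
}
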