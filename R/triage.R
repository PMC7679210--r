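#' Treatment outcome codes
#'
#' The nine binary treatment outcomes used throughout: orthopedic
#' referral, discharge, injection, nutritionist, physiotherapy,
#' diagnostic imaging, surgery, review appointment, any other referral.
#'
#' @return named character vector code -> description.
#' @export
treatment_codes <- function() {
  c(O1 = "orthopedic referral", O2 = "discharge", O3 = "injection",
    O4 = "nutritionist", O5 = "physiotherapy", O6 = "diagnostic imaging",
    O7 = "surgery", O8 = "review appointment", O9 = "any other referral")
}

#' Assemble a triage dataset from a topic model and treatment labels
#'
#' `X` is the D x K document-topic matrix (training theta by default, or
#' re-inferred via [infer_theta()]); `Y` is the D x 9 binary outcome
#' matrix with one column per treatment code. Multiple positives per
#' document are allowed. Unlabeled documents are excluded and counted.
#'
#' @param model a [fit_lda()] model.
#' @param labels named list: doc id -> character vector of treatment
#'   codes (empty vector = labeled with no treatments; absent id =
#'   unlabeled).
#' @param streams optional list of `token_stream` for re-inference.
#' @param use `"training"` (default: take rows of the model's theta) or
#'   `"infer"` (fold-in each labeled document; requires `streams`).
#' @param seed seed for re-inference.
#' @return object of class `triage_dataset`: list with `X`, `Y`,
#'   `doc_ids`, `n_unlabeled`.
#' @export
make_dataset <- function(model, labels, streams = NULL,
                         use = c("training", "infer"), seed = 1L) {
  use <- match.arg(use)
  stopifnot(inherits(model, "topic_model"))
  codes <- names(treatment_codes())
  bad <- setdiff(unique(unlist(labels)), codes)
  if (length(bad)) {
    stop("unknown treatment code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ids <- intersect(model$doc_ids, names(labels))
  n_unlabeled <- length(model$doc_ids) - length(ids)
  if (!length(ids)) stop("empty_dataset: no labeled documents",
                         call. = FALSE)
  if (use == "training") {
    X <- model$theta[ids, , drop = FALSE]
  } else {
    stopifnot(!is.null(streams))
    sid <- vapply(streams, `[[`, "", "doc_id")
    X <- t(vapply(seq_along(ids), function(i) {
      s <- streams[[match(ids[i], sid)]]
      cnt <- table(s$tokens$surface)
      suppressWarnings(
        infer_theta(model, setNames(as.integer(cnt), names(cnt)),
                    seed = seed + i))
    }, numeric(model$K)))
    rownames(X) <- ids
  }
  Y <- matrix(0L, nrow = length(ids), ncol = length(codes),
              dimnames = list(ids, codes))
  for (i in seq_along(ids)) {
    Y[i, labels[[ids[i]]]] <- 1L
  }
  structure(list(X = X, Y = Y, doc_ids = ids, n_unlabeled = n_unlabeled),
            class = "triage_dataset")
}

#' @export
print.triage_dataset <- function(x, ...) {
  cat(sprintf("<triage_dataset: %d docs x %d topics, prevalences: %s>\n",
              nrow(x$X), ncol(x$X),
              paste(colSums(x$Y), collapse = "/")))
  invisible(x)
}

# stratified fold assignment: positives and negatives are split round-robin
# after a seeded shuffle, so every fold mirrors the class balance
.stratified_folds <- function(y, folds, seed) {
  assign_fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[.seeded_sample(length(idx), length(idx), seed + cls)]
    assign_fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign_fold
}

.knn_predict <- function(Xtr, ytr, Xte, k, metric = "euclidean") {
  dist_fun <- switch(metric,
    euclidean = function(a, B) sqrt(colSums((t(B) - a)^2)),
    cosine = function(a, B) {
      1 - as.numeric(B %*% a) /
        (sqrt(sum(a^2)) * sqrt(rowSums(B^2)))
    },
    jensen_shannon = function(a, B) {
      vapply(seq_len(nrow(B)), function(i) {
        m <- (a + B[i, ]) / 2
        kl <- function(p, q) sum(ifelse(p > 0, p * log(p / q), 0))
        sqrt((kl(a, m) + kl(B[i, ], m)) / 2)
      }, numeric(1))
    },
    stop("unknown metric: ", metric, call. = FALSE))
  apply(Xte, 1L, function(a) {
    d <- dist_fun(a, Xtr)
    nb <- order(d)[seq_len(k)]
    as.integer(mean(ytr[nb]) > 0.5)   # majority vote; k odd => no ties
  })
}

#' Cross-validated k-nearest-neighbour triage classifier
#'
#' One binary classifier per treatment: neighbours by Euclidean distance
#' on the document-topic simplex (cosine and Jensen-Shannon available),
#' majority vote of `k = 5`, accuracy `A = (TP + TN) / N` per fold.
#' Folds are stratified on the treatment column and seeded.
#'
#' @param ds a [make_dataset()] object.
#' @param treatment a treatment code (column of `Y`).
#' @param k number of neighbours (odd; default 5).
#' @param folds number of CV folds (default 10).
#' @param seed fold-assignment seed.
#' @param metric `"euclidean"`, `"cosine"`, or `"jensen_shannon"`.
#' @return object of class `cv_result`: treatment, per-fold accuracies,
#'   mean accuracy, baseline accuracy, confusion counts, seed, flags.
#' @export
crossval_knn <- function(ds, treatment, k = 5L, folds = 10L, seed = 1L,
                         metric = "euclidean") {
  stopifnot(inherits(ds, "triage_dataset"),
            treatment %in% colnames(ds$Y))
  D <- nrow(ds$X)
  if (folds > D) stop("more folds than documents", call. = FALSE)
  y <- ds$Y[, treatment]
  degenerate <- length(unique(y)) < 2L
  fold_id <- .stratified_folds(y, folds, seed)
  if (any(tabulate(fold_id, folds) == 0L)) {
    stop("fold specification yields an empty test fold", call. = FALSE)
  }
  acc <- numeric(folds)
  conf <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  const_flag <- FALSE
  for (f in seq_len(folds)) {
    te <- fold_id == f
    ytr <- y[!te]
    if (length(unique(ytr)) < 2L) const_flag <- TRUE
    pred <- .knn_predict(ds$X[!te, , drop = FALSE], ytr,
                         ds$X[te, , drop = FALSE], k, metric)
    yt <- y[te]
    tp <- sum(pred == 1L & yt == 1L); tn <- sum(pred == 0L & yt == 0L)
    conf <- conf + c(TP = tp, TN = tn,
                     FP = sum(pred == 1L & yt == 0L),
                     FN = sum(pred == 0L & yt == 1L))
    acc[f] <- (tp + tn) / sum(te)
  }
  structure(list(treatment = treatment, fold_accuracy = acc,
                 mean_accuracy = mean(acc),
                 overall_accuracy = (conf[["TP"]] + conf[["TN"]]) / D,
                 baseline = stratified_random_baseline(ds, treatment),
                 confusion = conf, folds = folds, k = k, seed = seed,
                 metric = metric, degenerate = degenerate,
                 constant_fold = const_flag),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result %s: mean accuracy %.3f (baseline %.3f, %d-fold)>\n",
              x$treatment, x$mean_accuracy, x$baseline, x$folds))
  invisible(x)
}

#' Expected accuracy of the stratified random classifier
#'
#' The baseline predicts the positive class with probability equal to its
#' prevalence `p`; its expected accuracy is `p^2 + (1 - p)^2`, returned
#' analytically. `mc` requests an additional Monte-Carlo check.
#'
#' @param ds a [make_dataset()] object, or a single prevalence in [0, 1].
#' @param treatment treatment code (ignored when `ds` is a prevalence).
#' @param mc number of Monte-Carlo draws (0 = analytic only).
#' @param seed seed for the Monte-Carlo check.
#' @return expected accuracy; if `mc > 0`, attribute `mc_estimate`.
#' @export
stratified_random_baseline <- function(ds, treatment = NULL, mc = 0L,
                                       seed = 1L) {
  p <- if (inherits(ds, "triage_dataset")) {
    stopifnot(treatment %in% colnames(ds$Y))
    mean(ds$Y[, treatment])
  } else {
    stopifnot(is.numeric(ds), ds >= 0, ds <= 1)
    ds
  }
  out <- p^2 + (1 - p)^2
  if (mc > 0L) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old))
      assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    truth <- rbinom(mc, 1L, p)
    pred <- rbinom(mc, 1L, p)
    attr(out, "mc_estimate") <- mean(truth == pred)
  }
  out
}

#' Run the triage cross-validation for every treatment
#'
#' @param ds a [make_dataset()] object.
#' @param ... passed to [crossval_knn()].
#' @return data.frame: treatment, mean_accuracy, baseline, degenerate.
#' @export
triage_table <- function(ds, ...) {
  codes <- colnames(ds$Y)
  rows <- lapply(codes, function(tc) {
    r <- crossval_knn(ds, tc, ...)
    data.frame(treatment = tc, mean_accuracy = r$mean_accuracy,
               baseline = as.numeric(r$baseline),
               prevalence = mean(ds$Y[, tc]),
               degenerate = r$degenerate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
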