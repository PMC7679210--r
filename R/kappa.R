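#' Encode Likert labels as numeric codes
#'
#' Confidence is a 5-point scale: 0 (not confident at all), 1 (slightly
#' confident), 2 (somewhat confident), 3 (moderately confident), 4 (very
#' confident). Similarity is a 6-point scale with no zero: -3 (very
#' dissimilar), -2 (moderately dissimilar), -1 (slightly dissimilar),
#' 1 (slightly similar), 2 (moderately similar), 3 (very similar).
#'
#' @param labels character vector of scale terms (case-insensitive).
#' @param scale `"confidence"` or `"similarity"`.
#' @return integer codes, same length as `labels`.
#' @export
encode_likert <- function(labels, scale = c("confidence", "similarity")) {
  scale <- match.arg(scale)
  map <- switch(scale,
    confidence = c("not confident at all" = 0L, "slightly confident" = 1L,
                   "somewhat confident" = 2L, "moderately confident" = 3L,
                   "very confident" = 4L),
    similarity = c("very dissimilar" = -3L, "moderately dissimilar" = -2L,
                   "slightly dissimilar" = -1L, "slightly similar" = 1L,
                   "moderately similar" = 2L, "very similar" = 3L))
  if (!length(labels)) return(integer())
  key <- tolower(trimws(labels))
  unknown <- !(key %in% names(map))
  if (any(unknown)) {
    stop("unknown ", scale, " label(s): ",
         paste(unique(labels[unknown]), collapse = ", "), call. = FALSE)
  }
  unname(map[key])
}

#' Likert scale categories
#'
#' @param scale `"confidence"` or `"similarity"`.
#' @return ordered integer vector of valid codes.
#' @export
likert_categories <- function(scale = c("confidence", "similarity")) {
  switch(match.arg(scale),
         confidence = 0:4,
         similarity = c(-3L, -2L, -1L, 1L, 2L, 3L))
}

#' Linearly weighted Cohen kappa for two raters
#'
#' Categories are treated as consecutive ordinal ranks (so the similarity
#' scale's -1 to 1 gap collapses to adjacent ranks; linear-weight kappa is
#' invariant to any affine re-indexing of the ranks). With m categories
#' the weights are `w_ij = 1 - |i - j| / (m - 1)`. Observed and expected
#' weighted agreement come from the paired ratings and the marginal
#' products; `kappa = (P_o - P_e) / (1 - P_e)`. The standard error is the
#' Fleiss-Cohen large-sample (non-null) variance for weighted kappa, and
#' the 95% CI is `kappa +/- 1.96 SE` (optionally clipped at 0 for
#' display).
#'
#' @param r1,r2 equal-length (>= 2) vectors of codes, all in `categories`.
#' @param categories ordered vector of all valid codes.
#' @param clip_ci_at_zero clip the lower CI bound at 0 for reporting?
#' @return object of class `kappa_result`: kappa, P_o, P_e, se, ci,
#'   n_items, n_categories, weights.
#' @export
weighted_kappa <- function(r1, r2, categories, clip_ci_at_zero = FALSE) {
  n <- length(r1)
  stopifnot(length(r2) == n, n >= 2L)
  i1 <- match(r1, categories)
  i2 <- match(r2, categories)
  if (anyNA(i1) || anyNA(i2)) {
    stop("rating(s) outside the category set", call. = FALSE)
  }
  m <- length(categories)
  if (m < 2L) {
    stop("kappa_undefined: fewer than 2 categories", call. = FALSE)
  }
  w <- 1 - abs(outer(seq_len(m), seq_len(m), "-")) / (m - 1)
  O <- matrix(0, m, m)
  for (t in seq_len(n)) O[i1[t], i2[t]] <- O[i1[t], i2[t]] + 1
  O <- O / n
  p1 <- rowSums(O)
  p2 <- colSums(O)
  Po <- sum(w * O)
  Pe <- sum(w * outer(p1, p2))
  if (1 - Pe < .Machine$double.eps^0.5) {
    stop("kappa_undefined: expected weighted agreement is 1", call. = FALSE)
  }
  kappa <- (Po - Pe) / (1 - Pe)
  # Fleiss-Cohen asymptotic (non-null) variance for weighted kappa
  wbar_i <- as.numeric(w %*% p2)   # row-wise expected weight
  wbar_j <- as.numeric(p1 %*% w)   # column-wise expected weight
  term <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      term <- term +
        O[i, j] * (w[i, j] - (wbar_i[i] + wbar_j[j]) * (1 - kappa))^2
    }
  }
  var_k <- (term - (kappa - Pe * (1 - kappa))^2) / (n * (1 - Pe)^2)
  se <- sqrt(max(var_k, 0))
  ci <- kappa + c(-1, 1) * 1.96 * se
  if (clip_ci_at_zero) ci[1] <- max(0, ci[1])
  structure(list(kappa = kappa, P_o = Po, P_e = Pe, se = se, ci = ci,
                 n_items = n, n_categories = m, weights = w),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf(
    "<weighted kappa: %.4f (SE %.4f, 95%% CI %.4f-%.4f, n=%d, m=%d)>\n",
    x$kappa, x$se, x$ci[1], x$ci[2], x$n_items, x$n_categories))
  invisible(x)
}

#' Mean of numeric Likert codes
#'
#' @param codes non-empty numeric vector.
#' @return arithmetic mean.
#' @export
average_rating <- function(codes) {
  stopifnot(length(codes) > 0L)
  mean(codes)
}

#' Read a paired-rater ratings table
#'
#' Comma-separated file with columns topic, rater, confidence_label,
#' similarity_label. The interpretability-questionnaire fixture (11
#' topics, raters A and B) ships with the package and is the default.
#'
#' @param path CSV path; default is the bundled fixture.
#' @return object of class `rating_table`: data.frame plus encoded code
#'   columns.
#' @export
read_ratings <- function(path = .extdata("table5_ratings.csv")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("topic", "rater", "confidence_label", "similarity_label")
  stopifnot(all(need %in% names(tab)))
  if (length(unique(tab$rater)) != 2L) {
    stop("rating table must have exactly 2 raters", call. = FALSE)
  }
  tab$confidence <- encode_likert(tab$confidence_label, "confidence")
  tab$similarity <- encode_likert(tab$similarity_label, "similarity")
  structure(tab, class = c("rating_table", "data.frame"))
}

#' Inter-rater agreement report for a ratings table
#'
#' Computes, for each scale, the linearly weighted Cohen kappa between
#' the two raters across topics, plus each rater's average rating.
#'
#' @param ratings a [read_ratings()] table.
#' @param scale `"confidence"` or `"similarity"`.
#' @param clip_ci_at_zero passed to [weighted_kappa()].
#' @return a `kappa_result` with an `averages` attribute (named by
#'   rater).
#' @export
rater_agreement <- function(ratings, scale = c("confidence", "similarity"),
                            clip_ci_at_zero = TRUE) {
  scale <- match.arg(scale)
  stopifnot(inherits(ratings, "rating_table"))
  raters <- sort(unique(ratings$rater))
  topics <- unique(ratings$topic)
  col <- scale
  get_codes <- function(r) {
    sub <- ratings[ratings$rater == r, ]
    sub[[col]][match(topics, sub$topic)]
  }
  c1 <- get_codes(raters[1]); c2 <- get_codes(raters[2])
  res <- weighted_kappa(c1, c2, likert_categories(scale),
                        clip_ci_at_zero = clip_ci_at_zero)
  attr(res, "averages") <- setNames(c(average_rating(c1),
                                      average_rating(c2)), raters)
  res
}
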