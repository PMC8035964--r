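#' Example-based multi-label metrics
#'
#' Per-instance agreement between true and predicted label sets, averaged over
#' the N instances:
#'
#' * accuracy: Jaccard index `|Y ∩ Ŷ| / |Y ∪ Ŷ|`
#' * precision: `|Y ∩ Ŷ| / |Ŷ|` (0 when the predicted set is empty)
#' * recall: `|Y ∩ Ŷ| / |Y|`
#' * f1: `2 |Y ∩ Ŷ| / (|Y| + |Ŷ|)`
#' * subset_accuracy: exact-match indicator
#' * hamming_loss: fraction of the Q label positions that disagree
#'
#' @param truth,prediction Label tibbles (`id` + 0/1 code columns) or binary
#'   matrices with identical shape; `prediction` may be an `scl_prediction`.
#' @param universe Label universe (defaults to the code columns of `truth`).
#' @return A one-row tibble with the six metrics.
#' @export
example_metrics <- function(truth, prediction, universe = NULL) {
  m <- align_pair(truth, prediction, universe)
  Y <- m$Y; P <- m$P
  inter <- rowSums(Y & P)
  uni <- rowSums(Y | P)
  sy <- rowSums(Y)
  sp <- rowSums(P)
  tibble(
    accuracy = mean(ifelse(uni == 0, 1, inter / pmax(uni, 1))),
    precision = mean(ifelse(sp == 0, 0, inter / pmax(sp, 1))),
    recall = mean(inter / sy),
    f1 = mean(ifelse(sy + sp == 0, 1, 2 * inter / pmax(sy + sp, 1))),
    subset_accuracy = mean(rowSums(Y != P) == 0),
    hamming_loss = mean(rowMeans(Y != P))
  )
}

#' Pairwise ranking loss
#'
#' For each instance, the fraction of (relevant, irrelevant) label pairs whose
#' scores are ordered incorrectly -- an irrelevant label scoring above a
#' relevant one counts 1, a tie counts 1/2 -- averaged over instances that
#' have at least one relevant and one irrelevant label.  Degenerate instances
#' (all labels relevant, or none) are excluded from the average; their count
#' is reported in the `"n_excluded"` attribute.
#'
#' @param truth Label tibble or binary matrix.
#' @param scores Matrix or tibble of per-label scores aligned with `truth`,
#'   or an `scl_prediction` (its score matrix is used).
#' @param universe Label universe.
#' @return The ranking loss in \[0, 1\].
#' @export
rank_loss <- function(truth, scores, universe = NULL) {
  universe <- universe %||% default_universe(truth)
  Y <- as_binary_matrix(truth, universe)
  S <- as_score_matrix(scores, universe)
  stopifnot(all(dim(Y) == dim(S)))
  per <- rep(NA_real_, nrow(Y))
  for (i in seq_len(nrow(Y))) {
    rel <- which(Y[i, ] == 1)
    irr <- which(Y[i, ] == 0)
    if (!length(rel) || !length(irr)) next
    s_rel <- S[i, rel]
    s_irr <- S[i, irr]
    bad <- outer(s_rel, s_irr, function(a, b) (b > a) + 0.5 * (a == b))
    per[i] <- sum(bad) / (length(rel) * length(irr))
  }
  out <- mean(per, na.rm = TRUE)
  attr(out, "n_excluded") <- sum(is.na(per))
  out
}

#' Label-based multi-label metrics
#'
#' Computes per-label binary confusion counts and aggregates them two ways:
#' *macro* averages the per-label ratios with equal label weight (a label with
#' a zero denominator contributes 0 and triggers a warning), *micro* pools the
#' counts over labels before taking ratios.  `macro_f1` is the harmonic mean
#' of `macro_precision` and `macro_recall`; the alternative convention -- the
#' unweighted mean of per-label F1 scores -- is reported alongside as
#' `macro_f1_per_label`.
#'
#' @inheritParams example_metrics
#' @return A one-row tibble with `macro_precision`, `macro_recall`,
#'   `macro_f1`, `macro_f1_per_label`, `micro_precision`, `micro_recall`,
#'   `micro_f1`.
#' @export
label_metrics <- function(truth, prediction, universe = NULL) {
  m <- align_pair(truth, prediction, universe)
  Y <- m$Y; P <- m$P
  TP <- colSums(Y == 1 & P == 1)
  FP <- colSums(Y == 0 & P == 1)
  FN <- colSums(Y == 1 & P == 0)
  TN <- colSums(Y == 0 & P == 0)
  label_metrics_from_counts(TP, FP, FN, TN)
}

#' Label-based metrics from per-label confusion counts
#'
#' The same aggregation as [label_metrics()], but starting from per-location
#' TP/FP/FN/TN counts -- the layout of a published per-location confusion
#' table -- so a metric report can be checked for internal consistency
#' without the underlying matrices.  Also derives the pooled Hamming loss
#' through the identity `(sum FP + sum FN) / (N * Q)` with
#' `N = TP + FP + FN + TN` (constant over labels).
#'
#' @param TP,FP,FN,TN Non-negative integer vectors, one entry per label.
#' @return A one-row tibble with the seven macro/micro metrics of
#'   [label_metrics()] plus `hamming_loss`.
#' @export
label_metrics_from_counts <- function(TP, FP, FN, TN) {
  Q <- length(TP)
  stopifnot(length(FP) == Q, length(FN) == Q, length(TN) == Q)
  N <- unique(TP + FP + FN + TN)
  safe_ratio <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warn(paste0(sum(bad), " label(s) with zero ", what,
                  " denominator contribute 0 to the macro average"))
    }
    ifelse(bad, 0, num / pmax(den, 1))
  }
  prec_j <- safe_ratio(TP, TP + FP, "precision")
  rec_j <- safe_ratio(TP, TP + FN, "recall")
  f1_j <- ifelse(2 * TP + FP + FN == 0, 0,
                 2 * TP / pmax(2 * TP + FP + FN, 1))
  macro_p <- mean(prec_j)
  macro_r <- mean(rec_j)
  micro_p <- sum(TP) / sum(TP + FP)
  micro_r <- sum(TP) / sum(TP + FN)
  tibble(
    macro_precision = macro_p,
    macro_recall = macro_r,
    macro_f1 = harmonic_mean(macro_p, macro_r),
    macro_f1_per_label = mean(f1_j),
    micro_precision = micro_p,
    micro_recall = micro_r,
    micro_f1 = harmonic_mean(micro_p, micro_r),
    hamming_loss = if (length(N) == 1) sum(FP + FN) / (N * Q) else NA_real_
  )
}

harmonic_mean <- function(a, b) if (a + b == 0) 0 else 2 * a * b / (a + b)

#' Per-location confusion table
#'
#' Tallies, for every location, the four binary outcomes over all proteins --
#' TP (true and predicted), FP (predicted only), FN (true only), TN
#' (neither) -- plus the derived `Correct = TP + TN` and `Wrong = FP + FN`
#' columns and their fractions of N (rounded to 2 decimals for display).
#' `TP + FP + FN + TN = N` holds for every row.
#'
#' @inheritParams example_metrics
#' @return A tibble with one row per location.
#' @export
location_confusion <- function(truth, prediction, universe = NULL) {
  universe <- universe %||% default_universe(truth)
  m <- align_pair(truth, prediction, universe)
  Y <- m$Y; P <- m$P
  N <- nrow(Y)
  nm <- uni_names(universe)
  tibble(
    location = unname(nm[uni_codes(universe)]),
    code = uni_codes(universe),
    TP = unname(colSums(Y == 1 & P == 1)),
    FP = unname(colSums(Y == 0 & P == 1)),
    FN = unname(colSums(Y == 1 & P == 0)),
    TN = unname(colSums(Y == 0 & P == 0))
  ) |>
    dplyr::mutate(
      Correct = .data$TP + .data$TN,
      Wrong = .data$FP + .data$FN,
      pct_TP = round(.data$TP / N, 2),
      pct_FP = round(.data$FP / N, 2),
      pct_FN = round(.data$FN / N, 2),
      pct_TN = round(.data$TN / N, 2),
      pct_Correct = round(.data$Correct / N, 2)
    )
}

#' Micro-averaged ROC curve and AUC
#'
#' Flattens the N x Q truth and score matrices into one binary classification
#' problem, sweeps the score thresholds, and integrates the curve by the
#' trapezoid rule (equivalent to the Mann-Whitney U statistic with 1/2 credit
#' for ties).
#'
#' @inheritParams rank_loss
#' @return An object of class `scl_roc`: list with `auc` and `points`
#'   (tibble `threshold`, `fpr`, `tpr`).
#' @export
roc_curve <- function(truth, scores, universe = NULL) {
  universe <- universe %||% default_universe(truth)
  y <- as.vector(as_binary_matrix(truth, universe))
  s <- as.vector(as_score_matrix(scores, universe))
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("ROC undefined: flattened truth is all-positive or all-negative")
  }
  ord <- order(s, decreasing = TRUE)
  y_ord <- y[ord]
  s_ord <- s[ord]
  last <- !duplicated(s_ord, fromLast = TRUE)  # last index of each threshold
  tp <- cumsum(y_ord)[last]
  fp <- cumsum(1 - y_ord)[last]
  points <- tibble(threshold = c(Inf, s_ord[last]),
                   fpr = c(0, fp / n0), tpr = c(0, tp / n1))
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + points$tpr[-1]) / 2)
  structure(list(auc = auc, points = points), class = "scl_roc")
}

#' @rdname roc_curve
#' @export
roc_auc <- function(truth, scores, universe = NULL) {
  roc_curve(truth, scores, universe)$auc
}

#' @export
print.scl_roc <- function(x, ...) {
  cat("<scl_roc> AUC =", format(x$auc, digits = 4),
      "over", nrow(x$points), "points\n")
  invisible(x)
}

#' Full multi-label metric report
#'
#' One row with all example-based metrics, the label-based macro/micro
#' metrics, and -- when `prediction` carries scores or `scores` is supplied --
#' the ranking loss and micro-averaged AUC.
#'
#' @inheritParams example_metrics
#' @param scores Optional score matrix/tibble (taken from `prediction` when it
#'   is an `scl_prediction`).
#' @return A one-row tibble.
#' @export
multilabel_metrics <- function(truth, prediction, universe = NULL, scores = NULL) {
  universe <- universe %||% default_universe(truth)
  if (inherits(prediction, "scl_prediction") && is.null(scores)) {
    scores <- prediction$scores
  }
  lbl <- label_metrics(truth, prediction, universe)
  # the pooled hamming identity duplicates the example-based value exactly
  lbl$hamming_loss <- NULL
  out <- dplyr::bind_cols(example_metrics(truth, prediction, universe), lbl)
  if (!is.null(scores)) {
    rl <- rank_loss(truth, scores, universe)
    out$rank_loss <- as.numeric(rl)
    out$auc <- roc_auc(truth, scores, universe)
  } else {
    out$rank_loss <- NA_real_
    out$auc <- NA_real_
  }
  out
}

# ---- coercion helpers -------------------------------------------------------

default_universe <- function(truth) {
  if (is.data.frame(truth)) setdiff(names(truth), "id") else colnames(truth)
}

as_binary_matrix <- function(x, universe) {
  if (inherits(x, "scl_prediction")) return(x$predicted)
  if (is.data.frame(x)) return(lbl_matrix(x, universe))
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  m
}

as_score_matrix <- function(x, universe) {
  if (inherits(x, "scl_prediction")) return(x$scores)
  if (is.data.frame(x)) {
    cols <- intersect(c(uni_codes(universe)), names(x))
    if (length(cols) == length(uni_codes(universe))) return(as.matrix(x[cols]))
    return(as.matrix(dplyr::select(x, -dplyr::any_of("id"))))
  }
  as.matrix(x)
}

align_pair <- function(truth, prediction, universe = NULL) {
  universe <- universe %||% default_universe(truth)
  Y <- as_binary_matrix(truth, universe)
  P <- as_binary_matrix(prediction, universe)
  if (!all(dim(Y) == dim(P))) {
    abort(paste0("shape mismatch: truth is ", nrow(Y), "x", ncol(Y),
                 ", prediction is ", nrow(P), "x", ncol(P)))
  }
  list(Y = Y, P = P, universe = universe)
}
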