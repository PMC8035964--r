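#' Fit a Label Powerset multi-label model
#'
#' The Label Powerset (LP) transformation turns a multi-label problem into a
#' multi-class one: every distinct label subset observed in the training data
#' becomes one class, so label co-occurrence is modelled directly.  A base
#' classifier is then fitted on the multi-class problem -- a probability
#' random forest by default (`base = "rf"`), or an RBF-kernel SVM with
#' probability estimates (`base = "svm"`).
#'
#' @param features Feature tibble (`id` + numeric columns), rows aligned with
#'   `labels`.
#' @param labels Label tibble (`id` + 0/1 code columns).
#' @param universe Label universe; defaults to the code columns of `labels`.
#' @param base `"rf"` or `"svm"`.
#' @param num_trees Number of trees for the random forest base.
#' @param seed Integer seed; fits are reproducible bit-for-bit for a fixed
#'   seed.
#' @param view Optional view name recorded on the model.
#'
#' @return An object of class `scl_lp` with elements `universe`, `classes`
#'   (K x Q binary matrix of observed subsets), `class_counts`, `base`,
#'   `fit`, `features` (training column names), `view`, `seed`.
#' @export
lp_fit <- function(features, labels, universe = NULL,
                   base = c("rf", "svm"), num_trees = 500,
                   seed = 1L, view = "features") {
  base <- match.arg(base)
  if (!nrow(features)) abort("empty feature matrix")
  if (!identical(features$id, labels$id)) {
    abort("features and labels disagree on protein id order")
  }
  universe <- universe %||% setdiff(names(labels), "id")
  codes <- uni_codes(universe)
  Y <- lbl_matrix(labels, universe)
  if (any(rowSums(Y) == 0)) abort("every training protein needs at least one label")

  key <- apply(Y, 1, codes_of_row, codes = codes)
  classes_key <- sort(unique(key))
  classes <- t(vapply(classes_key,
                      function(k) as.integer(codes %in% strsplit(k, "/")[[1]]),
                      integer(length(codes))))
  colnames(classes) <- codes
  class_counts <- as.integer(table(factor(key, levels = classes_key)))
  if (any(class_counts == 1)) {
    warn(paste0(sum(class_counts == 1),
                " label-powerset class(es) have a single training example; ",
                "cross-validation folds may miss them"))
  }

  X <- as.matrix(dplyr::select(features, -"id"))
  y <- factor(key, levels = classes_key)
  fit <- NULL
  if (length(classes_key) > 1) {
    if (base == "rf") {
      fit <- ranger::ranger(x = X, y = y, probability = TRUE,
                            num.trees = num_trees, seed = seed,
                            num.threads = 1)
    } else {
      set.seed(seed)
      fit <- e1071::svm(x = X, y = y, kernel = "radial", probability = TRUE)
    }
  }
  structure(
    list(universe = codes, names = uni_names(universe), classes = classes,
         class_keys = classes_key, class_counts = class_counts,
         base = base, fit = fit, features = colnames(X),
         view = view, seed = seed),
    class = "scl_lp"
  )
}

#' Predict label sets with a fitted Label Powerset model
#'
#' Computes the base classifier's posterior over the powerset classes; the
#' hard prediction is the label subset of the argmax class (ties broken by
#' higher training frequency, then lexicographic class key), and the per-label
#' marginal score of label `j` is the summed posterior of all classes whose
#' subset contains `j`.
#'
#' @param object An `scl_lp` model.
#' @param newdata Feature tibble with the training columns.
#' @param ... Unused.
#' @return An `scl_prediction` object: `ids`, `universe`, `predicted`
#'   (N x Q binary matrix), `scores` (N x Q marginals in \[0, 1\]).
#' @export
predict.scl_lp <- function(object, newdata, ...) {
  X <- as.matrix(dplyr::select(newdata, -"id"))
  missing <- setdiff(object$features, colnames(X))
  extra <- setdiff(colnames(X), object$features)
  if (length(missing) || length(extra)) {
    abort(paste0("feature schema mismatch; missing: ",
                 paste(head(missing, 3), collapse = ", "),
                 if (length(missing) > 3) ", ...",
                 "; extra: ", paste(head(extra, 3), collapse = ", "),
                 if (length(extra) > 3) ", ..."))
  }
  X <- X[, object$features, drop = FALSE]
  K <- length(object$class_keys)
  if (K == 1) {
    probs <- matrix(1, nrow(X), 1, dimnames = list(NULL, object$class_keys))
  } else if (object$base == "rf") {
    probs <- predict(object$fit, data = X, num.threads = 1)$predictions
    probs <- probs[, object$class_keys, drop = FALSE]
  } else {
    pr <- predict(object$fit, newdata = X, probability = TRUE)
    probs <- attr(pr, "probabilities")[, object$class_keys, drop = FALSE]
  }

  best <- argmax_class(probs, object$class_counts)
  predicted <- object$classes[best, , drop = FALSE]
  scores <- probs %*% object$classes
  scores <- pmin(pmax(scores, 0), 1)
  rownames(predicted) <- rownames(scores) <- NULL
  new_scl_prediction(newdata$id, object$universe, predicted, scores,
                     model = paste0("lp_", object$view))
}

# deterministic argmax: probability, then training class frequency,
# then lexicographic class-key order (column order is sorted keys)
argmax_class <- function(probs, counts) {
  vapply(seq_len(nrow(probs)), function(r) {
    p <- probs[r, ]
    cand <- which(p == max(p))
    if (length(cand) > 1) cand <- cand[counts[cand] == max(counts[cand])]
    cand[1]
  }, integer(1))
}

new_scl_prediction <- function(ids, universe, predicted, scores, model = "") {
  storage.mode(predicted) <- "integer"
  colnames(predicted) <- colnames(scores) <- uni_codes(universe)
  structure(list(ids = ids, universe = uni_codes(universe),
                 predicted = predicted, scores = scores, model = model),
            class = "scl_prediction")
}

#' @export
print.scl_lp <- function(x, ...) {
  cat("<scl_lp> view = ", x$view, ", base = ", x$base,
      ", ", length(x$class_keys), " powerset classes over {",
      paste(x$universe, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' @export
print.scl_prediction <- function(x, ...) {
  cat("<scl_prediction> ", length(x$ids), " proteins x ",
      ncol(x$predicted), " locations (", x$model, ")\n", sep = "")
  invisible(x)
}

#' Convert a prediction set to a label tibble
#'
#' @param x An `scl_prediction`.
#' @param ... Unused.
#' @return Tibble with `id` + 0/1 code columns.
#' @export
as_tibble.scl_prediction <- function(x, ...) {
  lbl_tibble(x$ids, x$predicted, x$universe)
}

#' Per-label marginal scores of a prediction set
#'
#' @param x An `scl_prediction`.
#' @return Tibble with `id` + numeric score columns in \[0, 1\].
#' @export
prediction_scores <- function(x) {
  dplyr::bind_cols(tibble(id = x$ids), as_tibble(x$scores))
}

#' @export
tidy.scl_lp <- function(x, ...) {
  tibble(class = x$class_keys,
         n_train = x$class_counts,
         n_labels = unname(rowSums(x$classes)))
}

#' @export
glance.scl_lp <- function(x, ...) {
  tibble(view = x$view, base = x$base,
         n_classes = length(x$class_keys),
         n_features = length(x$features),
         n_labels = length(x$universe),
         seed = x$seed)
}
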