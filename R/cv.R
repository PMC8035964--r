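#' Seeded k-fold assignment
#'
#' Shuffles the N instances with the given seed and deals them round-robin
#' into k mutually exclusive, jointly exhaustive folds whose sizes differ by
#' at most one.
#'
#' @param n Number of instances.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return An integer vector of length `n` with fold indices in `1..k`.
#' @export
kfold_split <- function(n, k = 5, seed = 1L) {
  if (n < k) abort(paste0("cannot split ", n, " instances into ", k, " folds"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample.int(n)
  fold <- integer(n)
  fold[perm] <- rep(seq_len(k), length.out = n)
  fold
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

SCL_VARIANTS <- c("pseaac", "pssm", "go_binary", "go_ppv",
                  "fusion_all", "fusion_pssm_go",
                  "consensus_pssm_go", "consensus_all")

#' Cross-validated evaluation of the multi-label pipeline
#'
#' Runs seeded k-fold cross-validation over a complete dataset (sequences,
#' PSSM profiles, GO annotations, labels) and evaluates up to eight model
#' variants: the three single views (`pseaac`, `pssm`, GO in `go_binary` and
#' `go_ppv` flavours), two feature fusions (`fusion_all` =
#' PseAAC+PSSM+GO-ppv, `fusion_pssm_go` = PSSM+GO-ppv), and two decision
#' consensus models (`consensus_pssm_go` = OR of the `pssm` and `go_ppv`
#' decisions, `consensus_all` adding `pseaac`).  Within every fold the GO
#' vocabulary is rebuilt from the training proteins only, so held-out
#' annotations never leak into the feature definition.  Held-out predictions
#' are pooled over folds (every protein is predicted exactly once) before
#' computing metrics and per-location confusion tables.
#'
#' @param data A dataset list with elements `sequences` (tibble `id`,
#'   `sequence`), `pssms` (named list of `scl_pssm`), `go` (annotation
#'   tibble), `labels` (label tibble) and `universe`, as produced by
#'   [simulate_scl_dataset()] or assembled from the readers.
#' @param variants Character subset of the eight variant names.
#' @param k Number of folds.
#' @param seed Integer seed driving the fold split and every base-classifier
#'   fit.
#' @param base Base classifier for every view (`"rf"` or `"svm"`).
#' @param num_trees Trees per random forest.
#' @param lg Maximum ACC lag.
#' @param lambda,w PseAAC parameters.
#'
#' @return An object of class `scl_cv`: list with `metrics` (tibble, one row
#'   per variant in the standard column order), `confusion` (named list of
#'   per-location tibbles), `predictions` (named list of pooled
#'   `scl_prediction`s), `truth`, `fold`, `seed`.
#' @export
scl_cv <- function(data, variants = SCL_VARIANTS, k = 5, seed = 1L,
                   base = "rf", num_trees = 500, lg = 1,
                   lambda = 30, w = 0.05) {
  variants <- match.arg(variants, SCL_VARIANTS, several.ok = TRUE)
  labels <- data$labels
  universe <- data$universe
  codes <- uni_codes(universe)
  n <- nrow(labels)
  ids <- labels$id
  if (!identical(data$sequences$id, ids)) abort("sequences and labels disagree on id order")

  need_view <- function(v) any(grepl(v, variants, fixed = TRUE))
  views_needed <- c(
    pseaac = need_view("pseaac") || "consensus_all" %in% variants ||
      "fusion_all" %in% variants,
    pssm = need_view("pssm"),
    go_binary = "go_binary" %in% variants,
    go_ppv = any(c("go_ppv", "fusion_all", "fusion_pssm_go",
                   "consensus_pssm_go", "consensus_all") %in% variants)
  )

  # fold-independent encodings
  X_pse <- if (views_needed[["pseaac"]]) pseaac(data$sequences, lambda = lambda, w = w)
  X_acc <- if (views_needed[["pssm"]]) pssm_acc(data$pssms[ids], lg = lg)

  fold <- kfold_split(n, k = k, seed = seed)
  fitted_views <- c("pseaac", "pssm", "go_binary", "go_ppv",
                    "fusion_all", "fusion_pssm_go")
  fit_these <- intersect(fitted_views, c(
    variants,
    if (any(c("consensus_pssm_go", "consensus_all") %in% variants)) c("pssm", "go_ppv"),
    if ("consensus_all" %in% variants) "pseaac"
  ))

  pooled <- purrr::map(setNames(fit_these, fit_these), function(v) {
    list(predicted = matrix(NA_integer_, n, length(codes)),
         scores = matrix(NA_real_, n, length(codes)))
  })

  missing_classes <- 0L
  for (f in seq_len(k)) {
    test_i <- which(fold == f)
    train_i <- which(fold != f)
    vocab <- build_go_vocabulary(data$go, ids[train_i])
    go_ppv_X <- if (views_needed[["go_ppv"]]) go_features(data$go, vocab, ids, mode = "ppv")
    go_bin_X <- if (views_needed[["go_binary"]]) go_features(data$go, vocab, ids, mode = "binary")

    view_X <- list(
      pseaac = X_pse,
      pssm = X_acc,
      go_binary = go_bin_X,
      go_ppv = go_ppv_X,
      fusion_all = if ("fusion_all" %in% fit_these)
        feature_fusion(list(pseaac = X_pse, pssm = X_acc, go = go_ppv_X)),
      fusion_pssm_go = if ("fusion_pssm_go" %in% fit_these)
        feature_fusion(list(pssm = X_acc, go = go_ppv_X))
    )

    n_subsets_all <- nrow(unique(lbl_matrix(labels, universe)))
    n_subsets_train <- nrow(unique(lbl_matrix(labels[train_i, ], universe)))
    if (n_subsets_train < n_subsets_all) {
      missing_classes <- missing_classes + (n_subsets_all - n_subsets_train)
    }

    for (v in fit_these) {
      X <- view_X[[v]]
      model <- suppressWarnings(
        lp_fit(X[train_i, ], labels[train_i, ], universe,
               base = base, num_trees = num_trees,
               seed = seed + f, view = v)
      )
      pr <- predict(model, X[test_i, ])
      pooled[[v]]$predicted[test_i, ] <- pr$predicted
      pooled[[v]]$scores[test_i, ] <- pr$scores
    }
  }
  if (missing_classes > 0) {
    inform(paste0(missing_classes, " fold-level powerset class absences ",
                  "(rare subsets unseen in some training folds)"))
  }

  predictions <- purrr::imap(pooled, function(p, v) {
    new_scl_prediction(ids, universe, p$predicted, p$scores, model = v)
  })
  if ("consensus_pssm_go" %in% variants) {
    predictions$consensus_pssm_go <-
      consensus_or(predictions[c("pssm", "go_ppv")])
  }
  if ("consensus_all" %in% variants) {
    predictions$consensus_all <-
      consensus_or(predictions[c("pseaac", "pssm", "go_ppv")])
  }
  predictions <- predictions[intersect(SCL_VARIANTS, variants)]

  metrics <- purrr::imap(predictions, function(p, v) {
    dplyr::bind_cols(tibble(variant = v),
                     suppressWarnings(multilabel_metrics(labels, p, universe)))
  }) |> purrr::list_rbind()
  confusion <- purrr::map(predictions, function(p) {
    location_confusion(labels, p, universe)
  })

  structure(list(metrics = metrics, confusion = confusion,
                 predictions = predictions, truth = labels,
                 fold = fold, seed = seed, k = k),
            class = "scl_cv")
}

#' @export
print.scl_cv <- function(x, ...) {
  cat("<scl_cv> ", x$k, "-fold cross-validation, seed ", x$seed, "\n", sep = "")
  print(dplyr::mutate(x$metrics,
                      dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3))))
  invisible(x)
}

#' Tidy the cross-validation metric table
#'
#' @param x An `scl_cv` object.
#' @param ... Unused.
#' @return The metrics tibble, one row per model variant.
#' @export
tidy.scl_cv <- function(x, ...) x$metrics

#' @export
glance.scl_cv <- function(x, ...) {
  tibble(n = nrow(x$truth), k = x$k, seed = x$seed,
         n_variants = nrow(x$metrics))
}
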