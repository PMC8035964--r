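#' Plot a micro-averaged ROC curve
#'
#' @param object An [`scl_roc`][roc_curve] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scl_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.7, colour = "#2166AC") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("micro-averaged ROC (AUC = %.3f)", object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot cross-validated metrics per model variant
#'
#' @param object An [`scl_cv`][scl_cv] object.
#' @param metrics Which metric columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scl_cv <- function(object,
                            metrics = c("accuracy", "f1", "subset_accuracy",
                                        "micro_f1", "macro_f1"),
                            ...) {
  long <- object$metrics |>
    dplyr::select("variant", dplyr::all_of(metrics)) |>
    tidyr::pivot_longer(-"variant", names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$variant, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "score") +
    ggplot2::theme_minimal()
}

#' Write a cross-validation metric table as TSV
#'
#' Columns follow the standard report order (example-based metrics first,
#' then the label-based macro/micro block), values rounded to 3 decimals;
#' full precision stays available in the `scl_cv` object.
#'
#' @param cv An `scl_cv` object (or a plain metrics tibble).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_tsv <- function(cv, path) {
  metrics <- if (inherits(cv, "scl_cv")) cv$metrics else cv
  out <- dplyr::mutate(metrics,
                       dplyr::across(dplyr::where(is.numeric), ~ round(.x, 3)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write per-location confusion tables as TSV
#'
#' @param confusion A confusion tibble from [location_confusion()], or the
#'   named list held by an `scl_cv` object (variant column added).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_confusion_tsv <- function(confusion, path) {
  if (!is.data.frame(confusion)) {
    confusion <- purrr::imap(confusion, function(tbl, v) {
      dplyr::bind_cols(tibble(variant = v), tbl)
    }) |> purrr::list_rbind()
  }
  readr::write_tsv(confusion, path, progress = FALSE)
  invisible(path)
}
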