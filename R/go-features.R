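#' Build a GO-term vocabulary from training annotations
#'
#' The GO feature space is the union of all distinct GO ids annotated on the
#' *training* proteins, across the three sub-ontologies (MF, BP, CC).  Taking
#' the union maximizes the chance that a query protein carries at least one
#' known term; building it from training proteins only (the default inside the
#' cross-validation harness) keeps held-out information out of the feature
#' definition.  Ids unseen at training time are simply ignored by
#' [go_features()].
#'
#' @param annotations GO annotation tibble from [read_go_annotations()].
#' @param training_ids Protein ids the vocabulary may be built from.
#'
#' @return A sorted character vector of GO ids with an `"ontology_counts"`
#'   attribute (named count of distinct ids per sub-ontology).
#' @export
build_go_vocabulary <- function(annotations, training_ids) {
  ann <- dplyr::filter(annotations, .data$id %in% training_ids)
  vocab <- sort(unique(ann$go_id))
  counts <- ann |>
    dplyr::distinct(.data$go_id, .data$ontology) |>
    dplyr::count(.data$ontology)
  oc <- setNames(rep(0L, 3), c("MF", "BP", "CC"))
  oc[counts$ontology] <- counts$n
  attr(vocab, "ontology_counts") <- oc
  vocab
}

#' GO-term feature matrix
#'
#' Encodes each protein over a fixed vocabulary either as presence/absence
#' (`mode = "binary"`) or as the predictor's PPV confidence score
#' (`mode = "ppv"`, the default): the annotated value where a vocabulary term
#' is present, 0 elsewhere.  Proteins without annotations get an all-zero
#' row -- annotation absence is a legal state, not an error.
#'
#' @param annotations GO annotation tibble.
#' @param vocabulary Character vector from [build_go_vocabulary()].
#' @param ids Protein ids (row order of the output).
#' @param mode `"ppv"` or `"binary"`.
#'
#' @return A tibble with `id` plus one column per vocabulary term.
#' @export
go_features <- function(annotations, vocabulary, ids,
                        mode = c("ppv", "binary")) {
  mode <- match.arg(mode)
  X <- matrix(0, length(ids), length(vocabulary),
              dimnames = list(NULL, vocabulary))
  ann <- dplyr::filter(annotations, .data$id %in% ids,
                       .data$go_id %in% vocabulary)
  if (nrow(ann)) {
    ridx <- match(ann$id, ids)
    cidx <- match(ann$go_id, vocabulary)
    X[cbind(ridx, cidx)] <- if (mode == "binary") 1 else ann$ppv
  }
  dplyr::bind_cols(tibble(id = ids), as_tibble(X))
}

#' Fuse feature views by column-wise concatenation
#'
#' Concatenates several aligned feature tibbles into one wide view; feature
#' names are prefixed by the (named) view they came from, so a fused matrix
#' can always be sliced back into its parts.
#'
#' @param views Named list of feature tibbles sharing the same `id` order.
#' @return A fused feature tibble.
#' @export
feature_fusion <- function(views) {
  if (!length(views)) abort("need at least one view")
  ids <- views[[1]]$id
  for (v in views[-1]) {
    if (!identical(v$id, ids)) abort("feature views disagree on protein id order")
  }
  vnames <- names(views) %||% paste0("view", seq_along(views))
  blocks <- purrr::imap(views, function(v, nm) {
    b <- dplyr::select(v, -"id")
    names(b) <- paste(nm, names(b), sep = ".")
    b
  })
  dplyr::bind_cols(tibble(id = ids), blocks)
}
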