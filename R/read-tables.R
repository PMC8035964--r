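#' Read a location-label table
#'
#' Reads the tab-separated label dialect used throughout the package: columns
#' `protein_id` and `locations`, where `locations` is a slash-joined string of
#' single-letter codes (`"C/I"` marks a dual-compartment protein).  Lines
#' starting with `#` are comments.  Each row becomes a binary vector over the
#' universe's code order; multi-location rows set several bits, mirroring the
#' bitwise-OR encoding of multi-site annotations.
#'
#' @param path Path to the TSV file.
#' @param universe Label universe (see [scl_universe()]).
#'
#' @return A tibble with column `id` and one 0/1 integer column per code, in
#'   universe order.
#' @export
read_labels <- function(path, universe) {
  codes <- uni_codes(universe)
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("protein_id", "locations") %in% names(tbl))) {
    abort("label table needs columns 'protein_id' and 'locations'")
  }
  rows <- label_rows(tbl$protein_id, tbl$locations, codes, allow_empty = FALSE)
  lbl_tibble(tbl$protein_id, rows, universe)
}

label_rows <- function(ids, locs, codes, allow_empty) {
  Y <- matrix(0L, length(ids), length(codes))
  for (k in seq_along(ids)) {
    field <- trimws(locs[k] %||% "")
    if (is.na(field) || !nzchar(field)) {
      abort(paste0("empty location field for protein ", ids[k]))
    }
    if (identical(field, "-")) {
      if (allow_empty) next
      abort(paste0("empty location set for protein ", ids[k]))
    }
    parts <- strsplit(field, "/", fixed = TRUE)[[1]]
    bad <- setdiff(parts, codes)
    if (length(bad)) {
      abort(paste0("unknown location code '", bad[1], "' for protein ", ids[k],
                   "; universe is ", paste(codes, collapse = ",")))
    }
    Y[k, match(parts, codes)] <- 1L
  }
  Y
}

#' Read a GO annotation table
#'
#' Reads a tab-separated table of predicted GO terms with columns
#' `protein_id`, `ontology` (one of MF/BP/CC), `go_id` and `ppv` -- the
#' predictor's positive-predictive-value confidence in \[0, 1\].  Repeated
#' (protein, GO id) rows are collapsed keeping the maximum PPV.  A protein
#' absent from the table simply has no annotations; that is a legal state the
#' downstream encoder maps to an all-zero feature vector.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `id`, `ontology`, `go_id`, `ppv`.
#' @export
read_go_annotations <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(
                           protein_id = "c", ontology = "c",
                           go_id = "c", ppv = "d"),
                         progress = FALSE)
  need <- c("protein_id", "ontology", "go_id", "ppv")
  if (!all(need %in% names(tbl))) {
    abort(paste0("GO table needs columns ", paste(need, collapse = ", ")))
  }
  bad_ont <- setdiff(unique(tbl$ontology), c("MF", "BP", "CC"))
  if (length(bad_ont)) {
    abort(paste0("unknown ontology '", bad_ont[1], "' (expected MF, BP or CC)"))
  }
  if (any(is.na(tbl$ppv) | tbl$ppv < 0 | tbl$ppv > 1)) {
    abort("ppv values must lie in [0, 1]")
  }
  tbl |>
    dplyr::rename(id = "protein_id") |>
    dplyr::group_by(.data$id, .data$go_id) |>
    dplyr::slice_max(.data$ppv, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$id, .data$go_id)
}

#' Write predicted label sets to a TSV file
#'
#' Serializes one row per protein as `id <TAB> slash-joined codes` in universe
#' order; an empty prediction (possible only for externally supplied
#' matrices, not Label Powerset output) is written as `"-"` to keep the table
#' rectangular.
#'
#' @param predictions A label tibble (`id` + code columns) or an
#'   [`scl_prediction`][lp_fit] object.
#' @param universe Label universe.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, universe, path) {
  codes <- uni_codes(universe)
  if (inherits(predictions, "scl_prediction")) {
    predictions <- as_tibble(predictions)
  }
  Y <- lbl_matrix(predictions, universe)
  loc <- apply(Y, 1, codes_of_row, codes = codes)
  readr::write_tsv(tibble(protein_id = predictions$id, locations = loc), path,
                   progress = FALSE)
  invisible(path)
}

#' Read a predictions TSV written by [write_predictions()]
#'
#' Unlike [read_labels()], a `"-"` location field is accepted and decodes to
#' an all-zero row.
#'
#' @inheritParams read_labels
#' @return A label tibble.
#' @export
read_predictions <- function(path, universe) {
  codes <- uni_codes(universe)
  tbl <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  rows <- label_rows(tbl$protein_id, tbl$locations, codes, allow_empty = TRUE)
  lbl_tibble(tbl$protein_id, rows, universe)
}

#' Write a GO annotation table
#'
#' @param annotations Tibble with columns `id`, `ontology`, `go_id`, `ppv`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_go_annotations <- function(annotations, path) {
  out <- tibble(protein_id = annotations$id,
                ontology = annotations$ontology,
                go_id = annotations$go_id,
                ppv = sprintf("%.4f", annotations$ppv))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a location-label table
#'
#' @param labels Label tibble (`id` + code columns).
#' @param universe Label universe.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, universe, path) {
  codes <- uni_codes(universe)
  Y <- lbl_matrix(labels, universe)
  if (any(rowSums(Y) == 0)) abort("every labelled protein needs at least one location")
  loc <- apply(Y, 1, codes_of_row, codes = codes)
  readr::write_tsv(tibble(protein_id = labels$id, locations = loc), path,
                   progress = FALSE)
  invisible(path)
}
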