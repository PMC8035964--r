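#' Subcellular-location label universes
#'
#' A label universe fixes the ordered set of single-letter location codes a
#' dataset is annotated with; every binary label vector in the package is laid
#' out in this order.  Two presets cover the bacterial benchmarks: Gram-negative
#' proteins localize to cytoplasm, inner membrane, outer membrane, periplasm,
#' extracellular space and (rarely) gas vesicles, while Gram-positive bacteria
#' lack an outer membrane and periplasm but add the cell wall.
#'
#' @param preset `"gram_negative"` or `"gram_positive"`.
#'
#' @return A tibble with columns `code` (single letter, ordered) and `name`.
#' @examples
#' scl_universe("gram_negative")
#' @export
scl_universe <- function(preset = c("gram_negative", "gram_positive")) {
  preset <- match.arg(preset)
  switch(preset,
    gram_negative = tibble(
      code = c("C", "I", "O", "P", "S", "V"),
      name = c("Cytoplasm", "Inner membrane", "Outer membrane",
               "Periplasm", "Extracellular", "Vacuole")
    ),
    gram_positive = tibble(
      code = c("C", "I", "S", "W", "V"),
      name = c("Cytoplasm", "Inner membrane", "Extracellular",
               "Cell wall", "Vacuole")
    )
  )
}

# Accept a universe tibble or a bare character vector of codes.
uni_codes <- function(universe) {
  if (is.data.frame(universe)) {
    codes <- universe$code
  } else {
    codes <- as.character(universe)
  }
  if (anyDuplicated(codes) || length(codes) < 2) {
    abort("label universe must hold at least two unique codes")
  }
  codes
}

uni_names <- function(universe) {
  if (is.data.frame(universe) && !is.null(universe$name)) {
    setNames(universe$name, universe$code)
  } else {
    codes <- uni_codes(universe)
    setNames(codes, codes)
  }
}

# label tibble (id + one 0/1 column per code) -> binary matrix
lbl_matrix <- function(labels, universe) {
  codes <- uni_codes(universe)
  missing <- setdiff(codes, names(labels))
  if (length(missing)) {
    abort(paste0("label table lacks columns: ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(labels[codes])
  storage.mode(m) <- "integer"
  rownames(m) <- labels$id
  m
}

# binary matrix -> label tibble
lbl_tibble <- function(ids, Y, universe) {
  codes <- uni_codes(universe)
  stopifnot(ncol(Y) == length(codes))
  out <- as_tibble(as.data.frame(Y))
  names(out) <- codes
  dplyr::bind_cols(tibble(id = ids), out)
}

# slash-joined codes of set bits ("-" when empty)
codes_of_row <- function(bits, codes) {
  on <- codes[bits != 0]
  if (!length(on)) "-" else paste(on, collapse = "/")
}
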