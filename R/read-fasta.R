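#' Read protein sequences from a FASTA file
#'
#' Parses a FASTA file into a tibble of protein records.  Benchmark curation
#' keeps only sequences over the 20 standard amino acids: with
#' `filter_nonstandard = TRUE` (the default) any record containing a
#' non-standard letter -- including the ambiguity symbol `X` -- is dropped and
#' the number of dropped records is reported via a message and the
#' `"n_dropped"` attribute.
#'
#' Record ids are the first whitespace-delimited token of each header and must
#' be unique within the file.
#'
#' @param path Path to a FASTA file.
#' @param filter_nonstandard Drop records with residues outside the 20
#'   standard amino acids?
#'
#' @return A tibble with columns `id` and `sequence`, attribute `n_dropped`.
#' @export
read_fasta <- function(path, filter_nonstandard = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), ";"))
  if (!length(content)) {
    out <- tibble(id = character(), sequence = character())
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  first <- content[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    abort(paste0("malformed FASTA: sequence data before any header at line ",
                 first))
  }
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")))
  }
  sequence <- unname(toupper(as.character(seqs)))
  keep <- rep(TRUE, length(ids))
  n_dropped <- 0L
  if (filter_nonstandard) {
    standard <- paste0("^[", paste(AA_ORDER, collapse = ""), "]*$")
    keep <- grepl(standard, sequence)
    n_dropped <- sum(!keep)
    if (n_dropped > 0) {
      inform(paste0("dropped ", n_dropped,
                    " sequence(s) containing non-standard residues"))
    }
  }
  out <- tibble(id = ids[keep], sequence = sequence[keep])
  out <- dplyr::filter(out, nchar(.data$sequence) >= 1)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences$sequence)
  names(set) <- sequences$id
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(path)
}
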