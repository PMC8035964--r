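#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the plain-text profile written by `psiblast -out_ascii_pssm` (or
#' legacy `blastpgp -Q`).  Each residue row carries 20 log-odds scores followed
#' by 20 weighted observed percentages; `block` selects which half feeds the
#' downstream auto-cross covariance transform.  Columns are reordered to the
#' package's canonical amino-acid order `ARNDCQEGHILKMFPSTWYV` using the
#' alphabet declared in the file header.
#'
#' @param path Path to an ASCII PSSM file.
#' @param block `"logodds"` (default, the conventional profile) or
#'   `"percent"`.
#'
#' @return An object of class `scl_pssm`: a list with `id` (file stem),
#'   `scores` (L x 20 numeric matrix, canonical column order) and `block`.
#' @export
read_pssm <- function(path, block = c("logodds", "percent")) {
  block <- match.arg(block)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)

  header_i <- NA_integer_
  alphabet <- NULL
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) %in% c(20L, 40L) && all(tok %in% AA_ORDER)) {
      header_i <- i
      alphabet <- tok[seq_len(20)]
      break
    }
  }
  if (is.na(header_i)) abort("not a PSI-BLAST ASCII PSSM: no amino-acid column header found")

  rows <- list()
  r <- 0L
  for (i in seq.int(header_i + 1L, length(lines))) {
    line <- trimws(lines[i])
    if (!nzchar(line)) break
    tok <- strsplit(line, "\\s+")[[1]]
    if (is.na(suppressWarnings(as.integer(tok[1])))) break
    r <- r + 1L
    num <- suppressWarnings(as.numeric(tok[-(1:2)]))
    # psiblast appends per-position information content and relative weight
    if (length(num) %in% c(41L, 42L)) num <- num[seq_len(40)]
    if (length(num) != 40L || anyNA(num)) {
      abort(paste0("PSSM row ", r, " does not contain 40 numeric score fields"))
    }
    rows[[r]] <- num
  }
  if (!length(rows)) abort("PSSM file has an empty body")

  m <- do.call(rbind, rows)
  scores <- if (block == "logodds") m[, 1:20, drop = FALSE] else m[, 21:40, drop = FALSE]
  colnames(scores) <- alphabet
  scores <- scores[, AA_ORDER, drop = FALSE]
  structure(
    list(id = sub("\\.[^.]*$", "", basename(path)), scores = scores, block = block),
    class = "scl_pssm"
  )
}

#' Construct a PSSM profile object from a matrix
#'
#' @param scores L x 20 numeric matrix; columns either named by amino acid or
#'   assumed to already be in canonical `ARNDCQEGHILKMFPSTWYV` order.
#' @param id Protein identifier.
#' @param block Score block the matrix came from.
#' @return An `scl_pssm` object.
#' @export
pssm_profile <- function(scores, id = "protein", block = "logodds") {
  scores <- as.matrix(scores)
  if (ncol(scores) != 20) abort("a PSSM profile needs exactly 20 columns")
  if (nrow(scores) < 1) abort("a PSSM profile needs at least one row")
  if (!is.null(colnames(scores))) {
    if (!setequal(colnames(scores), AA_ORDER)) {
      abort("PSSM column names must be the 20 standard amino acids")
    }
    scores <- scores[, AA_ORDER, drop = FALSE]
  } else {
    colnames(scores) <- AA_ORDER
  }
  structure(list(id = id, scores = scores, block = block), class = "scl_pssm")
}

#' @export
print.scl_pssm <- function(x, ...) {
  cat("<scl_pssm> ", x$id, ": L = ", nrow(x$scores),
      ", block = ", x$block, "\n", sep = "")
  invisible(x)
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Emits the two-block (log-odds + percentages) layout that [read_pssm()]
#' consumes.  The supplied matrix fills the chosen block; the other block is
#' written as zeros.  Used by the synthetic-data generator to produce
#' format-realistic fixtures.
#'
#' @param profile An `scl_pssm` object.
#' @param path Output path.
#' @param residues Optional character vector of residues for the row labels
#'   (defaults to `"A"`).
#' @return `path`, invisibly.
#' @export
write_pssm <- function(profile, path, residues = NULL) {
  m <- profile$scores
  L <- nrow(m)
  if (is.null(residues)) residues <- rep("A", L)
  logodds <- if (identical(profile$block, "percent")) matrix(0L, L, 20) else round(m)
  percent <- if (identical(profile$block, "percent")) round(m) else matrix(0L, L, 20)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
    "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
    paste0("            ", paste(sprintf("%3s", AA_ORDER), collapse = " "), "  ",
           paste(sprintf("%3s", AA_ORDER), collapse = " "))), con)
  for (j in seq_len(L)) {
    writeLines(paste0(sprintf("%5d %s  ", j, residues[j]),
                      paste(sprintf("%3d", as.integer(logodds[j, ])), collapse = " "),
                      "  ",
                      paste(sprintf("%3d", as.integer(percent[j, ])), collapse = " "),
                      sprintf("  %5.2f %9.2f", 0, 0)), con)
  }
  writeLines("", con)
  invisible(path)
}
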