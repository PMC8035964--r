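#' Auto-cross covariance transform of a PSSM profile
#'
#' Converts a variable-length L x 20 PSSM into a fixed-length vector of lagged
#' covariances, so profiles of different lengths become comparable feature
#' vectors.  Writing `p[j, i]` for the score of amino acid `i` at position `j`
#' and `pbar_i` for the mean of column `i`, the transform collects
#'
#' * auto covariances `AC(i, lag) = sum_j (p[j,i] - pbar_i) (p[j+lag,i] - pbar_i) / (L - lag)`
#'   for every amino acid `i` and `lag = 1..lg`, and
#' * cross covariances `CC(i, j, lag) = sum_k (p[k,i] - pbar_i) (p[k+lag,j] - pbar_j) / (L - lag)`
#'   for every ordered pair `i != j` (the definition is asymmetric, so both
#'   orientations are kept).
#'
#' The vector has length `400 * lg` (20 AC + 380 CC entries per lag), laid out
#' AC block first (by amino acid, then lag) followed by the CC block (by
#' ordered pair `(i, j)`, then lag).  The default maximum lag is `lg = 1`,
#' which keeps the representation compact while still encoding
#' nearest-neighbour sequence order.
#'
#' @param profile An [`scl_pssm`][pssm_profile] object.
#' @param lg Maximum lag (positive integer, must be `< L`).
#'
#' @return A named numeric vector of length `400 * lg` with names like
#'   `AC_A_1` and `CC_A_R_1`.
#' @export
acc_transform <- function(profile, lg = 1) {
  m <- profile$scores
  L <- nrow(m)
  if (lg < 1) abort("lg must be a positive integer")
  if (lg >= L) {
    abort(paste0("sequence shorter than lag+1 for protein ", profile$id,
                 " (L = ", L, ", lg = ", lg, ")"))
  }
  centred <- sweep(m, 2, colMeans(m))
  aa <- colnames(m)

  ac <- matrix(NA_real_, 20, lg, dimnames = list(aa, NULL))
  cc <- array(NA_real_, c(20, 20, lg), dimnames = list(aa, aa, NULL))
  for (lag in seq_len(lg)) {
    a <- centred[seq_len(L - lag), , drop = FALSE]
    b <- centred[seq_len(L - lag) + lag, , drop = FALSE]
    cov_all <- crossprod(a, b) / (L - lag)   # [i, j] = CC(i, j, lag)
    ac[, lag] <- diag(cov_all)
    cc[, , lag] <- cov_all
  }

  ac_names <- as.vector(t(outer(aa, seq_len(lg),
                                function(i, l) paste("AC", i, l, sep = "_"))))
  ac_vals <- as.vector(t(ac))

  pair_i <- rep(seq_len(20), each = 20)
  pair_j <- rep(seq_len(20), times = 20)
  keep <- pair_i != pair_j
  pair_i <- pair_i[keep]; pair_j <- pair_j[keep]
  cc_vals <- numeric(380 * lg)
  cc_names <- character(380 * lg)
  pos <- 1L
  for (p in seq_along(pair_i)) {
    for (lag in seq_len(lg)) {
      cc_vals[pos] <- cc[pair_i[p], pair_j[p], lag]
      cc_names[pos] <- paste("CC", aa[pair_i[p]], aa[pair_j[p]], lag, sep = "_")
      pos <- pos + 1L
    }
  }
  setNames(c(ac_vals, cc_vals), c(ac_names, cc_names))
}

#' Mean score of one PSSM column
#'
#' @param profile An `scl_pssm` object.
#' @param i Amino-acid index (1-20, canonical order) or single-letter code.
#' @return The arithmetic mean of column `i` over all L positions.
#' @export
pssm_column_mean <- function(profile, i) {
  mean(profile$scores[, aa_index(i)])
}

#' Lagged auto covariance of one PSSM column
#'
#' @inheritParams pssm_column_mean
#' @param lag Positive integer lag, `lag < L`.
#' @return `AC(i, lag)` as defined in [acc_transform()].
#' @export
pssm_auto_covariance <- function(profile, i, lag) {
  x <- profile$scores[, aa_index(i)]
  L <- length(x)
  if (lag >= L) abort("sequence shorter than lag+1")
  d <- x - mean(x)
  sum(d[seq_len(L - lag)] * d[seq_len(L - lag) + lag]) / (L - lag)
}

#' Lagged cross covariance of two PSSM columns
#'
#' @inheritParams pssm_auto_covariance
#' @param j Second amino-acid index, `j != i`.
#' @return `CC(i, j, lag)` as defined in [acc_transform()]; note
#'   `CC(i, j, lag) != CC(j, i, lag)` in general.
#' @export
pssm_cross_covariance <- function(profile, i, j, lag) {
  ii <- aa_index(i); jj <- aa_index(j)
  if (ii == jj) abort("i and j must differ; use pssm_auto_covariance()")
  x <- profile$scores[, ii]
  y <- profile$scores[, jj]
  L <- length(x)
  if (lag >= L) abort("sequence shorter than lag+1")
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx[seq_len(L - lag)] * dy[seq_len(L - lag) + lag]) / (L - lag)
}

aa_index <- function(i) {
  if (is.character(i)) {
    idx <- match(i, AA_ORDER)
    if (is.na(idx)) abort(paste0("unknown amino acid '", i, "'"))
    return(idx)
  }
  if (i < 1 || i > 20) abort("amino-acid index must be in 1..20")
  as.integer(i)
}

#' ACC feature matrix for a set of PSSM profiles
#'
#' Applies [acc_transform()] to every profile and assembles the results into
#' a feature tibble aligned by protein id.
#'
#' @param pssms Named list of `scl_pssm` objects (names are protein ids), or
#'   an unnamed list whose elements carry their own `id`.
#' @param lg Maximum lag.
#' @return A tibble with `id` plus `400 * lg` feature columns.
#' @export
pssm_acc <- function(pssms, lg = 1) {
  ids <- names(pssms) %||% vapply(pssms, function(p) p$id, character(1))
  if (is.null(names(pssms))) names(pssms) <- ids
  rows <- purrr::map(pssms, acc_transform, lg = lg)
  X <- do.call(rbind, rows)
  dplyr::bind_cols(tibble(id = ids), as_tibble(X))
}
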