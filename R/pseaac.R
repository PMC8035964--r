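# Standard physicochemical property scales used by Type-I pseudo amino acid
# composition: hydrophobicity (Tanford), hydrophilicity (Hopp-Woods) and
# side-chain mass, indexed in canonical ARNDCQEGHILKMFPSTWYV order.
PSE_PROPERTIES <- list(
  hydrophobicity = c(
    A = 0.62, R = -2.53, N = -0.78, D = -0.90, C = 0.29, Q = -0.85,
    E = -0.74, G = 0.48, H = -0.40, I = 1.38, L = 1.06, K = -1.50,
    M = 0.64, F = 1.19, P = 0.12, S = -0.18, T = -0.05, W = 0.81,
    Y = 0.26, V = 1.08),
  hydrophilicity = c(
    A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2,
    E = 3.0, G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0,
    M = -1.3, F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4,
    Y = -2.3, V = -1.5),
  side_chain_mass = c(
    A = 15, R = 101, N = 58, D = 59, C = 47, Q = 72,
    E = 73, G = 1, H = 82, I = 57, L = 57, K = 73,
    M = 75, F = 91, P = 42, S = 31, T = 45, W = 130,
    Y = 107, V = 43)
)

# zero-mean, unit (population) variance standardization over the 20 residues
normalize_property <- function(h) {
  (h - mean(h)) / sqrt(sum((h - mean(h))^2) / length(h))
}

#' Type-I pseudo amino acid composition of a single sequence
#'
#' Chou's Type-I PseAAC extends the 20-component amino-acid composition with
#' `lambda` sequence-order correlation factors.  The k-th factor is the mean
#' coupling `theta_k = mean over i of Theta(R_i, R_(i+k))`, where
#' `Theta(a, b)` averages the squared differences of the standardized
#' physicochemical property values of residues `a` and `b`.  The composition
#' and correlation blocks are combined with weight `w` and normalized so the
#' `20 + lambda` components sum to one.
#'
#' With `lambda = 0` the encoding degenerates to the plain amino-acid
#' composition.
#'
#' @param sequence A string over the 20 standard amino-acid letters.
#' @param lambda Number of correlation factors (`lambda < nchar(sequence)`).
#' @param w Weight of the sequence-order block (default 0.05).
#' @param properties Named list of 20-value property vectors (defaults to
#'   hydrophobicity, hydrophilicity and side-chain mass).
#'
#' @return A named numeric vector of length `20 + lambda`, components summing
#'   to 1.
#' @export
pseaac_encode <- function(sequence, lambda = 30, w = 0.05,
                          properties = PSE_PROPERTIES) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, AA_ORDER)
  if (anyNA(idx)) {
    abort(paste0("unknown residue '", chars[which(is.na(idx))[1]],
                 "' (filter non-standard sequences first)"))
  }
  L <- length(idx)
  if (L <= lambda) {
    abort(paste0("sequence of length ", L, " is too short for lambda = ", lambda))
  }
  freq <- tabulate(idx, nbins = 20) / L

  theta <- numeric(lambda)
  if (lambda > 0) {
    H <- vapply(properties, function(h) normalize_property(h[AA_ORDER]),
                numeric(20))            # 20 x n_properties
    prof <- H[idx, , drop = FALSE]      # L x n_properties
    for (k in seq_len(lambda)) {
      d <- prof[seq_len(L - k), , drop = FALSE] -
        prof[seq_len(L - k) + k, , drop = FALSE]
      theta[k] <- mean(rowMeans(d^2))
    }
  }
  denom <- sum(freq) + w * sum(theta)
  out <- c(freq, w * theta) / denom
  names(out) <- c(AA_ORDER, if (lambda > 0) paste0("lambda_", seq_len(lambda)))
  out
}

#' PseAAC feature matrix for a set of sequences
#'
#' Encodes every sequence with [pseaac_encode()].  To keep the feature space
#' rectangular, `lambda` is capped at `min(lambda, min(L) - 1)` over the
#' batch; the effective value is recorded in the `"lambda"` attribute.
#'
#' @param sequences Tibble with columns `id` and `sequence` (as returned by
#'   [read_fasta()]).
#' @inheritParams pseaac_encode
#' @return A tibble with `id` plus `20 + lambda` feature columns.
#' @export
pseaac <- function(sequences, lambda = 30, w = 0.05,
                   properties = PSE_PROPERTIES) {
  lam <- min(lambda, min(nchar(sequences$sequence)) - 1L)
  lam <- max(lam, 0L)
  X <- t(vapply(sequences$sequence, pseaac_encode, numeric(20 + lam),
                lambda = lam, w = w, properties = properties,
                USE.NAMES = FALSE))
  colnames(X) <- c(AA_ORDER, if (lam > 0) paste0("lambda_", seq_len(lam)))
  out <- dplyr::bind_cols(tibble(id = sequences$id), as_tibble(X))
  attr(out, "lambda") <- lam
  out
}
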