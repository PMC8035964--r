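# Label-set distributions emulating the curated bacterial benchmarks: heavily
# imbalanced singleton classes plus a <1% mass of dual-location proteins
# concentrated on a few compartment pairs.
labelset_preset <- function(preset) {
  switch(preset,
    gram_negative = c(
      "C" = 4125, "I" = 1393, "O" = 339, "P" = 410, "S" = 262, "V" = 10,
      "C/I" = 18, "C/P" = 6, "O/S" = 4, "P/S" = 4,
      "C/S" = 2, "I/O" = 2, "I/P" = 2, "C/O" = 1),
    gram_positive = c(
      "C" = 344, "I" = 1775, "S" = 285, "W" = 32, "V" = 4,
      "C/I" = 3, "C/S" = 2, "S/W" = 2, "I/S" = 1),
    abort(paste0("unknown preset '", preset, "'"))
  )
}

#' Simulate a complete synthetic localization dataset
#'
#' Generates a seeded synthetic dataset with the statistical structure the
#' prediction pipeline assumes, so every stage can be exercised without
#' external databases or services:
#'
#' * label sets drawn from an imbalanced distribution over singleton classes
#'   plus a small mass of dual-location pairs, following the class balance of
#'   the curated Gram-negative / Gram-positive benchmarks;
#' * sequences of i.i.d. residues with a mild per-location compositional
#'   tilt (`seq_signal`), making the sequence view weakly informative;
#' * integer PSSM profiles in the PSI-BLAST log-odds range \[-10, 12\] whose
#'   location-designated columns are mean-shifted by `pssm_signal`;
#' * GO annotations where each true location emits its indicative terms with
#'   probability `go_emission` and a PPV drawn from a right-skewed
#'   `Beta(5, 2)` (clipped to (0, 1\]), plus uniform noise terms at rate
#'   `noise_rate` with weak `Beta(2, 5)` PPVs.
#'
#' With a fixed seed the generator is fully deterministic, and when
#' `out_dir` is given the four artifacts (FASTA, per-protein ASCII PSSMs,
#' GO TSV, labels TSV) are written byte-identically run-to-run.
#'
#' @param n Number of proteins.
#' @param preset `"gram_negative"` or `"gram_positive"` (fixes the universe
#'   and the label-set distribution).
#' @param seed Integer seed.
#' @param pssm_signal Mean shift (log-odds units) applied to each location's
#'   designated PSSM columns; 0 removes all PSSM information.
#' @param go_emission Probability that a true location emits each of its
#'   indicative GO terms; 0 removes all GO information.
#' @param seq_signal Multiplicative tilt on each location's favoured residues
#'   during sequence sampling.
#' @param noise_rate Expected number of random noise GO terms per protein.
#' @param go_vocab_sizes Named integer vector: distinct GO ids available per
#'   sub-ontology.
#' @param length_range Sequence length range (uniform).
#' @param labelset_probs Optional named probability vector over label-set
#'   strings (overrides the preset distribution; must sum to 1).
#'
#' @return A dataset list (`sequences`, `pssms`, `go`, `labels`, `universe`,
#'   `config`) ready for [scl_cv()]; with `out_dir` set, the file paths are
#'   recorded in `$paths`.
#' @param out_dir Optional directory to write FASTA/PSSM/TSV artifacts into.
#' @export
simulate_scl_dataset <- function(n, preset = "gram_negative", seed = 1L,
                                 pssm_signal = 2, go_emission = 0.9,
                                 seq_signal = 0.5, noise_rate = 0.5,
                                 go_vocab_sizes = c(MF = 40, BP = 50, CC = 20),
                                 length_range = c(60, 200),
                                 labelset_probs = NULL, out_dir = NULL) {
  universe <- scl_universe(preset)
  codes <- universe$code
  Q <- length(codes)

  if (!is.null(labelset_probs) &&
      (abs(sum(labelset_probs) - 1) > 1e-6 || any(labelset_probs < 0))) {
    abort("label-set probabilities must be non-negative and sum to 1")
  }
  counts <- labelset_probs %||% labelset_preset(preset)
  probs <- counts / sum(counts)
  if (pssm_signal < 0 || go_emission < 0 || go_emission > 1 || noise_rate < 0) {
    abort("signal parameters must be non-negative (go_emission in [0,1])")
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  ids <- sprintf("SYN%04d", seq_len(n))

  # labels
  sets <- sample(names(probs), n, replace = TRUE, prob = probs)
  Y <- label_rows(ids, sets, codes, allow_empty = FALSE)
  labels <- lbl_tibble(ids, Y, universe)

  # sequences: iid residues, favoured residues of each true location up-weighted
  fav <- lapply(seq_len(Q), function(j) ((2 * (j - 1)) %% 20) + c(1L, 2L))
  L <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  sequences <- tibble(id = ids, sequence = vapply(seq_len(n), function(i) {
    wt <- rep(1, 20)
    for (j in which(Y[i, ] == 1)) wt[fav[[j]]] <- wt[fav[[j]]] * (1 + seq_signal)
    paste(sample(AA_ORDER, L[i], replace = TRUE, prob = wt / sum(wt)),
          collapse = "")
  }, character(1)))

  # PSSMs: designated columns per location get a +pssm_signal mean shift over
  # motif-like segments (persistent two-state occupancy) rather than uniformly,
  # so the shift creates lagged covariance that the shift-invariant ACC
  # transform can recover.
  sig_cols <- lapply(seq_len(Q), function(j) ((3 * (j - 1)) %% 20) + c(1L, 2L, 3L))
  pssms <- setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    occ <- integer(L[i])
    occ[1] <- sample(0:1, 1)
    flip <- runif(L[i] - 1) > 0.9
    for (t in seq_len(L[i] - 1)) occ[t + 1] <- if (flip[t]) 1L - occ[t] else occ[t]
    shift <- matrix(0, L[i], 20)
    for (j in which(Y[i, ] == 1)) {
      shift[occ == 1L, sig_cols[[j]]] <- shift[occ == 1L, sig_cols[[j]]] + pssm_signal
    }
    m <- matrix(rnorm(L[i] * 20, sd = 2), L[i], 20) + shift
    m <- pmin(pmax(round(m), -10), 12)
    pssms[[i]] <- pssm_profile(m, id = ids[i])
  }

  # GO annotations: indicative terms per location + uniform noise
  vocab_by_ont <- purrr::imap(as.list(go_vocab_sizes), function(sz, ont) {
    sprintf("GO:%02d%05d", match(ont, c("MF", "BP", "CC")), seq_len(sz))
  })
  if (go_vocab_sizes[["MF"]] < 2 * Q || go_vocab_sizes[["BP"]] < 2 * Q ||
      go_vocab_sizes[["CC"]] < Q) {
    abort("go_vocab_sizes too small to assign disjoint indicative terms")
  }
  all_terms <- unlist(vocab_by_ont, use.names = FALSE)
  all_onts <- rep(names(vocab_by_ont), lengths(vocab_by_ont))
  # 2 MF + 2 BP + 1 CC indicative terms per location, disjoint across locations
  indic <- lapply(seq_len(Q), function(j) {
    c(vocab_by_ont$MF[(2 * (j - 1) + 1):(2 * j)],
      vocab_by_ont$BP[(2 * (j - 1) + 1):(2 * j)],
      vocab_by_ont$CC[j])
  })
  ann <- vector("list", n)
  for (i in seq_len(n)) {
    terms <- character(0)
    for (j in which(Y[i, ] == 1)) {
      emit <- indic[[j]][runif(length(indic[[j]])) < go_emission]
      terms <- c(terms, emit)
    }
    n_noise <- rpois(1, noise_rate)
    noise <- if (n_noise > 0) sample(all_terms, min(n_noise, length(all_terms)))
    ppv_sig <- pmin(pmax(rbeta(length(terms), 5, 2), 1e-4), 1)
    ppv_noise <- pmin(pmax(rbeta(length(noise), 2, 5), 1e-4), 1)
    go_id <- c(terms, noise)
    if (!length(go_id)) next
    ann[[i]] <- tibble(id = ids[i],
                       ontology = all_onts[match(go_id, all_terms)],
                       go_id = go_id,
                       ppv = round(c(ppv_sig, ppv_noise), 4))
  }
  go <- purrr::list_rbind(purrr::compact(ann)) |>
    dplyr::group_by(.data$id, .data$go_id) |>
    dplyr::slice_max(.data$ppv, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$id, .data$go_id)

  config <- list(n = n, preset = preset, seed = seed,
                 pssm_signal = pssm_signal, go_emission = go_emission,
                 seq_signal = seq_signal, noise_rate = noise_rate,
                 go_vocab_sizes = go_vocab_sizes, length_range = length_range)
  data <- list(sequences = sequences, pssms = pssms, go = go,
               labels = labels, universe = universe, config = config)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      fasta = file.path(out_dir, "proteins.fasta"),
      labels = file.path(out_dir, "labels.tsv"),
      go = file.path(out_dir, "go_annotations.tsv"),
      pssm_dir = file.path(out_dir, "pssm")
    )
    write_fasta(sequences, paths$fasta)
    write_labels(labels, universe, paths$labels)
    write_go_annotations(go, paths$go)
    for (i in seq_len(n)) {
      write_pssm(pssms[[i]], file.path(paths$pssm_dir, paste0(ids[i], ".pssm")),
                 residues = strsplit(sequences$sequence[i], "")[[1]])
    }
    data$paths <- paths
  }
  data
}

#' Recovery benchmark on synthetic data
#'
#' Simulates a dataset with [simulate_scl_dataset()] and immediately runs the
#' cross-validated pipeline on it -- the standard way to verify that the
#' models recover planted location signal and that the consensus superset
#' property holds end-to-end.
#'
#' @inheritParams simulate_scl_dataset
#' @inheritParams scl_cv
#' @param ... Further arguments passed to [simulate_scl_dataset()].
#' @return An [`scl_cv`][scl_cv] object.
#' @export
recovery_benchmark <- function(n = 500, preset = "gram_negative", seed = 1L,
                               variants = SCL_VARIANTS, k = 5,
                               num_trees = 500, ...) {
  data <- simulate_scl_dataset(n = n, preset = preset, seed = seed, ...)
  scl_cv(data, variants = variants, k = k, seed = seed, num_trees = num_trees)
}
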