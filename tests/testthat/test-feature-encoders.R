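test_that("column means match direct summation", {
  prof <- pssm_profile(matrix(0.5, 9, 20), id = "c")
  expect_equal(pssm_column_mean(prof, 3), 0.5)

  m <- matrix(0, 3, 20); m[, 1] <- c(1, 0, 1)
  expect_equal(pssm_column_mean(pssm_profile(m), 1), 2 / 3)

  set.seed(7)
  prof <- toy_profile(L = 7, seed = 7)
  for (i in c(1, 8, 20)) {
    expect_equal(pssm_column_mean(prof, i),
                 sum(prof$scores[, i]) / 7, tolerance = 1e-12)
  }
})

test_that("auto covariance follows the lagged-deviation definition", {
  const <- pssm_profile(matrix(2.5, 10, 20))
  for (lag in 1:3) expect_equal(pssm_auto_covariance(const, 4, lag), 0)

  m <- matrix(0, 3, 20); m[, 1] <- c(1, 0, 1)
  # hand oracle: deviations (1/3, -2/3, 1/3), lag 1 ->
  # ((1/3)(-2/3) + (-2/3)(1/3)) / 2 = -2/9
  expect_equal(pssm_auto_covariance(pssm_profile(m), 1, 1), -2 / 9)

  # shift invariance: adding a constant to a column leaves AC unchanged
  prof <- toy_profile(L = 12, seed = 3)
  shifted <- prof$scores; shifted[, 5] <- shifted[, 5] + 7
  expect_equal(pssm_auto_covariance(pssm_profile(shifted), 5, 2),
               pssm_auto_covariance(prof, 5, 2), tolerance = 1e-12)

  expect_error(pssm_auto_covariance(pssm_profile(m), 1, 5), "shorter than lag")
})

test_that("cross covariance is asymmetric and vanishes for constant columns", {
  m <- matrix(0, 3, 20)
  m[, 1] <- c(1, 0, 1)   # deviations ( 1/3, -2/3,  1/3)
  m[, 2] <- c(0, 1, 0)   # deviations (-1/3,  2/3, -1/3)
  prof <- pssm_profile(m)
  # ((1/3)(2/3) + (-2/3)(-1/3)) / 2 = 2/9
  expect_equal(pssm_cross_covariance(prof, 1, 2, 1), 2 / 9)
  expect_equal(pssm_cross_covariance(prof, 1, 3, 1), 0)  # constant partner

  p2 <- toy_profile(L = 9, seed = 11)
  expect_false(isTRUE(all.equal(pssm_cross_covariance(p2, 1, 2, 1),
                                pssm_cross_covariance(p2, 2, 1, 1))))
  expect_error(pssm_cross_covariance(p2, 4, 4, 1), "must differ")
})

test_that("acc_transform has length 400*lg and matches the naive oracle", {
  prof <- toy_profile(L = 10, seed = 5)
  expect_length(acc_transform(prof, 1), 400)
  v2 <- acc_transform(prof, 2)
  expect_length(v2, 800)
  expect_equal(v2, oracle_acc(prof$scores, 2), tolerance = 1e-12)

  # identical rows -> all deviations zero
  flat <- pssm_profile(matrix(rep(rnorm(20), each = 6), 6, 20))
  expect_true(all(acc_transform(flat, 2) == 0))

  expect_error(acc_transform(toy_profile(L = 3), 3), "shorter than lag")
})

test_that("acc_transform length and oracle agreement hold over random sizes", {
  set.seed(99)
  for (rep in 1:12) {
    lg <- sample(1:3, 1)
    L <- sample((lg + 1):60, 1)
    prof <- pssm_profile(matrix(rnorm(L * 20), L, 20))
    v <- acc_transform(prof, lg)
    expect_length(v, 400 * lg)
    expect_equal(v, oracle_acc(prof$scores, lg), tolerance = 1e-12)
  }
})

test_that("PseAAC with lambda 0 is the amino-acid composition", {
  v <- pseaac_encode("AAAA", lambda = 0)
  expect_equal(unname(v["A"]), 1)
  expect_equal(sum(v), 1)
  expect_true(all(v[-1] == 0))

  comp <- pseaac_encode("ACCD", lambda = 0)
  expect_equal(unname(comp[c("A", "C", "D")]), c(0.25, 0.5, 0.25))
})

test_that("PseAAC matches an independent evaluation of the definition", {
  v <- pseaac_encode("ACDEFGHIK", lambda = 2, w = 0.05)
  expect_length(v, 22)
  expect_equal(sum(v), 1, tolerance = 1e-12)
  expect_equal(unname(v), oracle_pseaac("ACDEFGHIK", 2, 0.05), tolerance = 1e-12)

  set.seed(21)
  for (rep in 1:5) {
    s <- paste(sample(sclconsensus:::AA_ORDER, 40, replace = TRUE), collapse = "")
    lam <- sample(0:5, 1)
    v <- pseaac_encode(s, lambda = lam, w = 0.1)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1, tolerance = 1e-12)
    if (lam > 0) expect_equal(unname(v), oracle_pseaac(s, lam, 0.1), tolerance = 1e-12)
  }
})

test_that("PseAAC rejects short sequences and unknown residues", {
  expect_error(pseaac_encode("ACD", lambda = 3), "too short")
  expect_error(pseaac_encode("ACXDE", lambda = 0), "unknown residue 'X'")
})

test_that("batch PseAAC caps lambda at min(L) - 1", {
  seqs <- tibble::tibble(id = c("a", "b"),
                         sequence = c("ACDEF", strrep("MK", 30)))
  X <- pseaac(seqs, lambda = 30)
  expect_equal(attr(X, "lambda"), 4L)
  expect_equal(ncol(X), 1 + 20 + 4)
})

test_that("GO vocabulary is the de-duplicated union over training proteins", {
  ann <- tibble::tibble(
    id = c("P1", "P2", "P2", "P3"),
    ontology = c("MF", "BP", "CC", "BP"),
    go_id = c("G1", "G2", "G2", "G3"),
    ppv = c(0.9, 0.8, 0.7, 0.6))
  v <- build_go_vocabulary(ann, c("P1", "P2", "P3"))
  expect_equal(as.character(v), c("G1", "G2", "G3"))
  expect_equal(sum(attr(v, "ontology_counts")), 4)  # G2 counted in BP and CC

  expect_length(build_go_vocabulary(ann, character(0)), 0)

  # count oracle by independent scan, training subset only
  v2 <- build_go_vocabulary(ann, c("P1", "P2"))
  expect_equal(length(v2), length(unique(ann$go_id[ann$id %in% c("P1", "P2")])))
})

test_that("GO encoding respects mode and vocabulary closure", {
  ann <- tibble::tibble(id = c("P1", "P1", "P2"),
                        ontology = c("MF", "CC", "MF"),
                        go_id = c("G1", "G3", "G9"),
                        ppv = c(0.8, 0.3, 0.99))
  vocab <- c("G1", "G2", "G3")
  ppv <- go_features(ann, vocab, c("P1", "P2", "P3"), mode = "ppv")
  bin <- go_features(ann, vocab, c("P1", "P2", "P3"), mode = "binary")
  expect_equal(unname(unlist(ppv[1, vocab])), c(0.8, 0, 0.3))
  expect_equal(unname(unlist(bin[1, vocab])), c(1, 0, 1))
  # P2 carries only an unseen term; P3 is unannotated -> zero vectors
  expect_true(all(ppv[2:3, vocab] == 0))
  # binary is the indicator of a positive ppv entry
  expect_equal(as.matrix(bin[vocab]) > 0, as.matrix(ppv[vocab]) > 0)
})

test_that("feature fusion concatenates aligned views and slices back", {
  ids <- c("a", "b", "c")
  v1 <- dplyr::bind_cols(tibble::tibble(id = ids),
                         tibble::as_tibble(matrix(rnorm(9), 3,
                                                  dimnames = list(NULL, paste0("x", 1:3)))))
  v2 <- dplyr::bind_cols(tibble::tibble(id = ids),
                         tibble::as_tibble(matrix(rnorm(6), 3,
                                                  dimnames = list(NULL, paste0("y", 1:2)))))
  fused <- feature_fusion(list(a = v1, b = v2))
  expect_equal(ncol(fused), 1 + 3 + 2)
  expect_equal(unname(as.matrix(fused[paste0("a.x", 1:3)])),
               unname(as.matrix(v1[paste0("x", 1:3)])))
  expect_equal(unname(as.matrix(feature_fusion(list(only = v2))[, -1])),
               unname(as.matrix(v2[, -1])))
  v3 <- v2; v3$id <- rev(ids)
  expect_error(feature_fusion(list(v1, v3)), "id order")
})
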