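# small separable two-view fixture: features carry one indicator column per
# label subset, so a forest can fit the training data perfectly
make_separable <- function(n = 60, seed = 1) {
  set.seed(seed)
  uni <- scl_universe("gram_negative")
  sets <- sample(c("C", "I", "C/I"), n, replace = TRUE, prob = c(.5, .3, .2))
  Y <- sclconsensus:::label_rows(sprintf("P%03d", 1:n), sets, uni$code, FALSE)
  labels <- sclconsensus:::lbl_tibble(sprintf("P%03d", 1:n), Y, uni)
  X <- matrix(rnorm(n * 5, sd = 0.1), n, 5)
  key <- factor(sets, levels = c("C", "I", "C/I"))
  X[cbind(1:n, as.integer(key))] <- X[cbind(1:n, as.integer(key))] + 5
  feats <- dplyr::bind_cols(tibble::tibble(id = labels$id),
                            tibble::as_tibble(`colnames<-`(X, paste0("f", 1:5))))
  list(features = feats, labels = labels, universe = uni)
}

test_that("label powerset classes are the distinct observed subsets", {
  d <- make_separable()
  fit <- lp_fit(d$features, d$labels, d$universe, seed = 4)
  expect_setequal(fit$class_keys, c("C", "I", "C/I"))
  expect_equal(sum(fit$class_counts), nrow(d$labels))
  td <- tidy(fit)
  expect_equal(td$n_labels[td$class == "C/I"], 2)
  expect_equal(glance(fit)$n_classes, 3)
})

test_that("a separable problem is fitted to training subset-accuracy 1", {
  d <- make_separable(n = 80, seed = 2)
  fit <- lp_fit(d$features, d$labels, d$universe, num_trees = 300, seed = 9)
  pred <- predict(fit, d$features)
  m <- example_metrics(d$labels, pred, d$universe)
  expect_equal(m$subset_accuracy, 1)
})

test_that("degenerate single-class training predicts that class constantly", {
  uni <- scl_universe("gram_positive")
  ids <- paste0("P", 1:8)
  Y <- matrix(rep(c(1L, 0L, 0L, 0L, 0L), each = 8), 8)
  labels <- sclconsensus:::lbl_tibble(ids, Y, uni)
  feats <- dplyr::bind_cols(tibble::tibble(id = ids),
                            tibble::as_tibble(matrix(rnorm(16), 8,
                                                     dimnames = list(NULL, c("a", "b")))))
  fit <- lp_fit(feats, labels, uni, seed = 1)
  pred <- predict(fit, feats)
  expect_true(all(pred$predicted[, "C"] == 1))
  expect_true(all(pred$scores[, "C"] == 1))
  expect_true(all(pred$scores[, setdiff(uni$code, "C")] == 0))
})

test_that("predicted sets are always members of the trained class list", {
  d <- make_separable(n = 50, seed = 5)
  fit <- lp_fit(d$features, d$labels, d$universe, num_trees = 100, seed = 5)
  noise <- d$features
  noise[, -1] <- noise[, -1] + matrix(rnorm(50 * 5, sd = 4), 50, 5)
  pred <- predict(fit, noise)
  keys <- apply(pred$predicted, 1, sclconsensus:::codes_of_row,
                codes = d$universe$code)
  expect_true(all(keys %in% fit$class_keys))
  expect_true(all(pred$scores >= 0 & pred$scores <= 1))
})

test_that("marginal scores sum posteriors over classes containing each label", {
  # posterior {C: .2, I: .3, C/I: .5} -> predict C/I; score(C)=.7, score(I)=.8
  classes <- rbind(C = c(1, 0), I = c(0, 1), `C/I` = c(1, 1))
  probs <- matrix(c(0.2, 0.3, 0.5), 1)
  scores <- probs %*% classes
  expect_equal(as.vector(scores), c(0.7, 0.8))
  best <- sclconsensus:::argmax_class(probs, counts = c(10L, 10L, 10L))
  expect_equal(best, 3L)
  expect_equal(unname(classes[best, ]), c(1, 1))
  # tie on probability broken by the larger training class
  best2 <- sclconsensus:::argmax_class(matrix(c(0.4, 0.4, 0.2), 1),
                                       counts = c(3L, 9L, 1L))
  expect_equal(best2, 2L)
})

test_that("fits are reproducible for a fixed seed and schema is enforced", {
  d <- make_separable(n = 40, seed = 8)
  f1 <- lp_fit(d$features, d$labels, d$universe, num_trees = 50, seed = 11)
  f2 <- lp_fit(d$features, d$labels, d$universe, num_trees = 50, seed = 11)
  expect_identical(predict(f1, d$features)$scores,
                   predict(f2, d$features)$scores)

  bad <- dplyr::rename(d$features, zz = "f1")
  expect_error(predict(f1, bad), "schema mismatch")
  expect_error(lp_fit(d$features[0, ], d$labels[0, ], d$universe), "empty")
})

test_that("OR-consensus reproduces the worked dual-location example", {
  uni <- scl_universe("gram_negative")
  mk <- function(bits, model) {
    sclconsensus:::new_scl_prediction("P1", uni$code, rbind(as.integer(bits)),
                                      rbind(as.numeric(bits)), model)
  }
  pssm <- mk(c(0, 0, 0, 0, 1, 0), "pssm")   # extracellular call
  go <- mk(c(1, 0, 0, 0, 0, 0), "go")       # single-membrane-side call
  cons <- consensus_or(list(pssm, go))
  expect_equal(as.vector(cons$predicted), c(1, 0, 0, 0, 1, 0))
  # serializes to exactly two location codes
  f <- withr::local_tempfile(fileext = ".tsv")
  write_predictions(cons, uni, f)
  expect_equal(readLines(f)[2], "P1\tC/S")
})

test_that("consensus is idempotent, absorbs zero members, and is a superset", {
  set.seed(31)
  uni <- scl_universe("gram_positive")
  n <- 25
  rand_pred <- function() {
    P <- matrix(rbinom(n * 5, 1, 0.3), n)
    sclconsensus:::new_scl_prediction(paste0("P", 1:n), uni$code, P,
                                      matrix(runif(n * 5), n), "m")
  }
  a <- rand_pred(); b <- rand_pred(); c3 <- rand_pred()
  expect_equal(consensus_or(list(a, a))$predicted, a$predicted)
  zero <- sclconsensus:::new_scl_prediction(paste0("P", 1:n), uni$code,
                                            matrix(0L, n, 5), matrix(0, n, 5), "z")
  expect_equal(consensus_or(list(zero, b))$predicted, b$predicted)

  cons2 <- consensus_or(list(a, b))
  cons3 <- consensus_or(list(a, b, c3))
  for (m in list(a, b)) {
    expect_true(all(cons2$predicted >= m$predicted))
  }
  # set size is monotone in the number of members
  expect_true(all(rowSums(cons3$predicted) >= rowSums(cons2$predicted)))

  mismatch <- sclconsensus:::new_scl_prediction(rev(paste0("P", 1:n)), uni$code,
                                                a$predicted, a$scores, "r")
  expect_error(consensus_or(list(a, mismatch)), "id order")
  expect_error(consensus_or(list(a)), "at least two")
})
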