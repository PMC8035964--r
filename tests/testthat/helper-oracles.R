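# Independent brute-force oracles, deliberately written as plain loops so they
# share no code with the package implementations they check.

oracle_example_metrics <- function(Y, P) {
  n <- nrow(Y)
  acc <- prec <- rec <- f1 <- subs <- ham <- numeric(n)
  for (i in seq_len(n)) {
    y <- which(Y[i, ] == 1); p <- which(P[i, ] == 1)
    inter <- length(intersect(y, p)); uni <- length(union(y, p))
    acc[i] <- if (uni == 0) 1 else inter / uni
    prec[i] <- if (length(p) == 0) 0 else inter / length(p)
    rec[i] <- inter / length(y)
    f1[i] <- if (length(y) + length(p) == 0) 1 else 2 * inter / (length(y) + length(p))
    subs[i] <- as.numeric(setequal(y, p))
    ham[i] <- sum(Y[i, ] != P[i, ]) / ncol(Y)
  }
  c(accuracy = mean(acc), precision = mean(prec), recall = mean(rec),
    f1 = mean(f1), subset_accuracy = mean(subs), hamming_loss = mean(ham))
}

oracle_rank_loss <- function(Y, S) {
  vals <- c()
  for (i in seq_len(nrow(Y))) {
    rel <- which(Y[i, ] == 1); irr <- which(Y[i, ] == 0)
    if (length(rel) == 0 || length(irr) == 0) next
    bad <- 0
    for (j in rel) for (l in irr) {
      if (S[i, l] > S[i, j]) bad <- bad + 1
      else if (S[i, l] == S[i, j]) bad <- bad + 0.5
    }
    vals <- c(vals, bad / (length(rel) * length(irr)))
  }
  mean(vals)
}

oracle_label_metrics <- function(Y, P) {
  Q <- ncol(Y)
  tp <- fp <- fn <- tn <- integer(Q)
  for (j in seq_len(Q)) {
    tp[j] <- sum(Y[, j] == 1 & P[, j] == 1)
    fp[j] <- sum(Y[, j] == 0 & P[, j] == 1)
    fn[j] <- sum(Y[, j] == 1 & P[, j] == 0)
    tn[j] <- sum(Y[, j] == 0 & P[, j] == 0)
  }
  prec_j <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  rec_j <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1_j <- ifelse(2 * tp + fp + fn == 0, 0, 2 * tp / (2 * tp + fp + fn))
  mp <- mean(prec_j); mr <- mean(rec_j)
  up <- sum(tp) / sum(tp + fp); ur <- sum(tp) / sum(tp + fn)
  c(macro_precision = mp, macro_recall = mr,
    macro_f1 = if (mp + mr == 0) 0 else 2 * mp * mr / (mp + mr),
    macro_f1_per_label = mean(f1_j),
    micro_precision = up, micro_recall = ur,
    micro_f1 = if (up + ur == 0) 0 else 2 * up * ur / (up + ur))
}

# Mann-Whitney U formulation of the micro AUC (ties counted half)
oracle_auc <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  wins <- 0
  for (a in pos) for (b in neg) {
    if (a > b) wins <- wins + 1 else if (a == b) wins <- wins + 0.5
  }
  wins / (length(pos) * length(neg))
}

# naive double-loop ACC transform, following the covariance definitions
# term by term
oracle_acc <- function(scores, lg) {
  L <- nrow(scores)
  aa <- colnames(scores)
  pbar <- sapply(seq_len(20), function(i) sum(scores[, i]) / L)
  out <- c()
  for (i in seq_len(20)) for (lag in seq_len(lg)) {
    s <- 0
    for (j in seq_len(L - lag)) {
      s <- s + (scores[j, i] - pbar[i]) * (scores[j + lag, i] - pbar[i])
    }
    out <- c(out, setNames(s / (L - lag), paste("AC", aa[i], lag, sep = "_")))
  }
  for (i in seq_len(20)) for (jj in seq_len(20)) {
    if (i == jj) next
    for (lag in seq_len(lg)) {
      s <- 0
      for (k in seq_len(L - lag)) {
        s <- s + (scores[k, i] - pbar[i]) * (scores[k + lag, jj] - pbar[jj])
      }
      out <- c(out, setNames(s / (L - lag),
                             paste("CC", aa[i], aa[jj], lag, sep = "_")))
    }
  }
  out
}

# reference Type-I PseAAC evaluated directly from the published definition
oracle_pseaac <- function(seq, lambda, w) {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  props <- sclconsensus:::PSE_PROPERTIES
  Hn <- lapply(props, function(h) {
    h <- h[aa]
    (h - mean(h)) / sqrt(mean((h - mean(h))^2))
  })
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  f <- sapply(aa, function(a) sum(chars == a) / L)
  theta <- numeric(lambda)
  for (k in seq_len(lambda)) {
    tot <- 0
    for (i in seq_len(L - k)) {
      a <- chars[i]; b <- chars[i + k]
      tot <- tot + mean(sapply(Hn, function(h) (h[b] - h[a])^2))
    }
    theta[k] <- tot / (L - k)
  }
  denom <- sum(f) + w * sum(theta)
  unname(c(f, w * theta) / denom)
}

# random multi-label truth/prediction/score triple with non-empty truth rows
random_mll_case <- function(n, q) {
  Y <- matrix(rbinom(n * q, 1, 0.35), n, q)
  empty <- rowSums(Y) == 0
  Y[cbind(which(empty), sample(q, sum(empty), replace = TRUE))] <- 1L
  P <- matrix(rbinom(n * q, 1, 0.35), n, q)
  S <- matrix(round(runif(n * q), 2), n, q)  # rounding forces some ties
  list(Y = Y, P = P, S = S)
}

toy_profile <- function(L = 5, seed = 1) {
  set.seed(seed)
  pssm_profile(matrix(rnorm(L * 20), L, 20), id = "toy")
}
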