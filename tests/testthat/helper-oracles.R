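# Independent oracles used across the suite. These deliberately avoid the
# package code paths they check: brute-force scans, textbook formulas and
# base-R model machinery.

# does `item` equal any contiguous window of `stream`? (brute force)
oracle_window_match <- function(item, stream) {
  L <- length(item)
  if (length(stream) < L) return(FALSE)
  for (i in seq_len(length(stream) - L + 1)) {
    if (all(stream[i:(i + L - 1)] == item)) return(TRUE)
  }
  FALSE
}

# violation count by direct successor-map lookup
oracle_count_violations <- function(g, seq) {
  n <- 0
  for (i in seq_len(length(seq) - 1)) {
    if (!(seq[i + 1] %in% g$successors[[seq[i]]])) n <- n + 1
  }
  n
}

# per-transition (relation, status) labels by direct lookup
oracle_labels <- function(g, seq) {
  dom <- function(e) g$elements$domain[g$elements$label == e]
  t(vapply(seq_len(length(seq) - 1), function(i) {
    c(relation = if (dom(seq[i]) == dom(seq[i + 1])) "within" else "cross",
      status = if (seq[i + 1] %in% g$successors[[seq[i]]])
        "grammatical" else "violation")
  }, c(relation = "", status = "")))
}

# textbook equal-variance two-sample t
oracle_two_sample_t <- function(w, x) {
  sp2 <- (sum((w - mean(w))^2) + sum((x - mean(x))^2)) /
    (length(w) + length(x) - 2)
  (mean(w) - mean(x)) / sqrt(sp2 * (1 / length(w) + 1 / length(x)))
}

# textbook paired t
oracle_paired_t <- function(a, b) {
  d <- a - b
  mean(d) / (sd(d) / sqrt(length(d)))
}

# exact mean of Binomial(5, 1/2) truncated at zero: the expected number of
# targeted-relation transitions per accepted violation item
oracle_truncated_mean <- 2.5 / (1 - 2^-5)

# long accuracy table from a wide participant x condition matrix
acc_table <- function(Y, group = "all",
                      conds = c("grammatical", "within_violation",
                                "cross_violation")[seq_len(ncol(Y))]) {
  tab <- data.frame(
    participant = rep(seq_len(nrow(Y)), each = ncol(Y)),
    group = group,
    condition = rep(conds, nrow(Y)),
    percent_correct = as.vector(t(Y)),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("agl_accuracy", "data.frame")
  tab
}

# participant x condition matrix with exactly spherical contrast covariance
oracle_spherical_data <- function(n, k, seed = 1) {
  set.seed(seed)
  Z <- matrix(rnorm(n * (k - 1)), n, k - 1)
  Z <- sweep(Z, 2, colMeans(Z))
  Z <- Z %*% solve(chol(cov(Z)))        # empirical whitening: cov(Z) == I
  C <- contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  Z %*% t(C)
}
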