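#' Score a response log into per-participant accuracies
#'
#' @param log a response-log data.frame (columns `participant`, `group`,
#'   `item_id`, `condition`, `endorse`, `correct`).
#' @return an `agl_accuracy` data.frame: one row per participant x
#'   condition with `percent_correct` in [0, 100].
#' @export
score_responses <- function(log) {
  needed <- c("participant", "group", "item_id", "condition", "correct")
  missing_cols <- setdiff(needed, names(log))
  if (length(missing_cols)) {
    stop_invalid("response log lacks column(s): %s",
                 paste(missing_cols, collapse = ", "))
  }
  log$group <- ifelse(is.na(log$group), "all", as.character(log$group))
  key <- interaction(log$group, log$participant, drop = TRUE)
  tab <- table(key, log$item_id)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop_invalid("incomplete log: %d participant/item cell(s) not judged exactly once (first: %s / %s)",
                 nrow(bad), rownames(tab)[bad[1, 1]], colnames(tab)[bad[1, 2]])
  }
  agg <- stats::aggregate(correct ~ participant + group + condition,
                          data = log, FUN = function(z) 100 * mean(z))
  names(agg)[names(agg) == "correct"] <- "percent_correct"
  agg <- agg[order(agg$group, agg$participant, agg$condition), ]
  rownames(agg) <- NULL
  class(agg) <- c("agl_accuracy", "data.frame")
  agg
}

#' Per-condition means and standard deviations
#'
#' @param table an `agl_accuracy` data.frame.
#' @return data.frame with `group`, `condition`, `M`, `SD`, `n`.
#' @export
condition_summary <- function(table) {
  out <- do.call(rbind, lapply(
    split(table, list(table$group, table$condition), drop = TRUE),
    function(d) data.frame(group = d$group[1], condition = d$condition[1],
                           M = mean(d$percent_correct),
                           SD = stats::sd(d$percent_correct),
                           n = nrow(d), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out[order(out$group, out$condition), ]
}

condition_order <- c("grammatical", "within_violation", "cross_violation")

# wide participant x condition matrix (+ group vector) from the long table
acc_wide <- function(table) {
  conds <- intersect(condition_order, unique(table$condition))
  if (!length(conds)) conds <- sort(unique(table$condition))
  key <- interaction(table$group, table$participant, drop = TRUE)
  ids <- unique(key)
  Y <- matrix(NA_real_, length(ids), length(conds),
              dimnames = list(as.character(ids), conds))
  for (r in seq_len(nrow(table))) {
    Y[as.character(key[r]), table$condition[r]] <- table$percent_correct[r]
  }
  if (anyNA(Y)) stop_invalid("accuracy table is unbalanced")
  groups <- table$group[match(ids, key)]
  list(Y = Y, groups = groups)
}

#' One-sample t test against chance with Cohen's d
#'
#' Either supply a raw vector `x`, or summary statistics `M`, `SD`, `n`.
#' `t = (M - mu0) / (SD / sqrt(n))`, `df = n - 1`, two-sided p, and
#' `d = (M - mu0) / SD` (so `d = t / sqrt(n)` identically).
#'
#' @param x optional numeric vector of per-participant scores.
#' @param M,SD,n mean, standard deviation and sample size (used when `x`
#'   is NULL).
#' @param mu0 comparison value; 50 = chance for a two-alternative
#'   judgment.
#' @return an `agl_ttest` list: `t`, `df`, `p`, `d`, `M`, `SD`, `n`,
#'   `mu0`.
#' @export
#' @examples
#' one_sample_t(M = 64.00, SD = 12.98, n = 15) # t = 4.18, d = 1.08
one_sample_t <- function(x = NULL, M = NULL, SD = NULL, n = NULL,
                         mu0 = 50) {
  if (!is.null(x)) {
    M <- mean(x); SD <- stats::sd(x); n <- length(x)
  }
  if (is.null(M) || is.null(SD) || is.null(n)) {
    stop_invalid("supply either x or all of M, SD, n")
  }
  if (n < 2) stop_invalid("n must be >= 2")
  if (SD <= 0) stop_invalid("SD must be > 0: t is undefined")
  t <- (M - mu0) / (SD / sqrt(n))
  structure(list(t = t, df = n - 1,
                 p = 2 * stats::pt(-abs(t), n - 1),
                 d = (M - mu0) / SD,
                 M = M, SD = SD, n = n, mu0 = mu0),
            class = "agl_ttest")
}

#' @export
print.agl_ttest <- function(x, ...) {
  cat(sprintf("One-sample t vs %g: t(%d) = %.3f, p = %.4g, d = %.3f (M = %.2f, SD = %.2f, n = %d)\n",
              x$mu0, x$df, x$t, x$p, x$d, x$M, x$SD, x$n))
  invisible(x)
}

#' Mauchly's test of sphericity
#'
#' Computes W from the covariance of orthonormalized Helmert contrasts of
#' the within-subject scores, pooled within groups when a grouping vector
#' is given, with the standard chi-square approximation.
#'
#' @param x an `agl_accuracy` table or a participant x condition matrix.
#' @param groups optional between-subjects group labels (one per row of
#'   the matrix); taken from the table when `x` is an `agl_accuracy`.
#' @return list with `W`, `chisq`, `df`, `p`, `k`, `df_error`.
#' @export
mauchly_test <- function(x, groups = NULL) {
  A <- contrast_covariance(x, groups)
  k <- attr(A, "k"); dfe <- attr(A, "df_error")
  q <- k - 1
  W <- det(A) / (sum(diag(A)) / q)^q
  d <- 1 - (2 * q^2 + q + 2) / (6 * q * dfe)
  chisq <- -dfe * d * log(W)
  df <- k * (k - 1) / 2 - 1
  list(W = W, chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE),
       k = k, df_error = dfe)
}

#' Greenhouse-Geisser epsilon
#'
#' `epsilon = tr(A)^2 / ((k - 1) tr(A^2))` for the (pooled) contrast
#' covariance A; ranges from `1/(k-1)` (maximal non-sphericity) to 1.
#'
#' @inheritParams mauchly_test
#' @return a single numeric epsilon.
#' @export
gg_epsilon <- function(x, groups = NULL) {
  A <- contrast_covariance(x, groups)
  k <- attr(A, "k")
  unname(sum(diag(A))^2 / ((k - 1) * sum(A * A)))
}

# covariance of orthonormal contrasts, pooled within groups
contrast_covariance <- function(x, groups = NULL) {
  if (inherits(x, "agl_accuracy")) {
    w <- acc_wide(x)
    Y <- w$Y
    if (is.null(groups) && length(unique(w$groups)) > 1) groups <- w$groups
  } else {
    Y <- as.matrix(x)
  }
  k <- ncol(Y)
  if (k < 3) stop_invalid("sphericity requires >= 3 within conditions")
  if (is.null(groups)) groups <- rep(1, nrow(Y))
  g <- length(unique(groups))
  dfe <- nrow(Y) - g
  if (dfe < k) {
    stop_invalid("insufficient data: need more participants than conditions")
  }
  C <- stats::contr.helmert(k)
  C <- sweep(C, 2, sqrt(colSums(C^2)), "/")
  Z <- Y %*% C
  S <- matrix(0, k - 1, k - 1)
  for (gr in unique(groups)) {
    Zg <- Z[groups == gr, , drop = FALSE]
    S <- S + crossprod(sweep(Zg, 2, colMeans(Zg)))
  }
  A <- S / dfe
  attr(A, "k") <- k
  attr(A, "df_error") <- dfe
  A
}

#' One-way repeated-measures ANOVA
#'
#' Subjects x conditions decomposition:
#' `F = MS_condition / MS_(condition x subject)` with partial eta squared
#' `SS_cond / (SS_cond + SS_error)`. For three or more conditions the
#' report carries Mauchly's W and the Greenhouse-Geisser epsilon; the
#' epsilon-corrected p-value is flagged as the headline test whenever
#' Mauchly's p <= 0.05 (both p-values are always reported).
#'
#' @param table an `agl_accuracy` data.frame for a single group.
#' @return an `agl_anova` object.
#' @export
rm_anova_oneway <- function(table) {
  w <- acc_wide(table)
  if (length(unique(w$groups)) > 1) {
    stop_invalid("table has multiple groups: use mixed_anova()")
  }
  Y <- w$Y
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2 || k < 2) stop_invalid("need >= 2 participants and conditions")
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (n - 1) * (k - 1)
  eff <- anova_effect_row("condition", ss_cond, df1, ss_err, df2)
  out <- list(effects = eff, design = "one-way repeated measures",
              n = n, k = k)
  if (k >= 3 && n > k) {
    out <- add_sphericity(out, Y, groups = NULL, within = "condition")
  }
  class(out) <- "agl_anova"
  out
}

anova_effect_row <- function(effect, ss, df1, ss_err, df2) {
  ms <- ss / df1
  ms_err <- ss_err / df2
  f <- if (ms_err == 0) {
    if (ms == 0) 0 else Inf
  } else {
    ms / ms_err
  }
  data.frame(
    effect = effect, df1 = df1, df2 = df2, SS = ss, SS_error = ss_err,
    F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
    partial_eta_sq = if (ss + ss_err == 0) 0 else ss / (ss + ss_err),
    stringsAsFactors = FALSE
  )
}

# attach Mauchly + GG columns for the within-subject effects
add_sphericity <- function(out, Y, groups, within) {
  mau <- mauchly_test(Y, groups)
  eps <- gg_epsilon(Y, groups)
  ef <- out$effects
  ef$gg_epsilon <- NA_real_
  ef$df1_gg <- NA_real_
  ef$df2_gg <- NA_real_
  ef$p_gg <- NA_real_
  idx <- grepl(within, ef$effect)
  ef$gg_epsilon[idx] <- eps
  ef$df1_gg[idx] <- eps * ef$df1[idx]
  ef$df2_gg[idx] <- eps * ef$df2[idx]
  ef$p_gg[idx] <- stats::pf(ef$F[idx], eps * ef$df1[idx],
                            eps * ef$df2[idx], lower.tail = FALSE)
  out$effects <- ef
  out$mauchly <- mau
  out$gg_epsilon <- eps
  out$sphericity_correction_applied <- mau$p <= 0.05
  out
}

#' Mixed two-factor ANOVA (between group x within condition)
#'
#' Classical split-plot decomposition: the group effect is tested against
#' subjects-within-groups, the condition and group:condition effects
#' against the condition x subject(group) residual. Mauchly's test runs
#' on the within-group pooled contrast covariance; Greenhouse-Geisser
#' corrected dfs and p-values are reported for the within-subject
#' effects, and flagged as the headline tests when Mauchly's p <= 0.05.
#'
#' @param table an `agl_accuracy` data.frame with a `group` column
#'   holding two or more levels; every group needs >= 2 participants and
#'   the same conditions.
#' @return an `agl_anova` object.
#' @export
mixed_anova <- function(table) {
  w <- acc_wide(table)
  Y <- w$Y
  groups <- w$groups
  lev <- unique(groups)
  if (length(lev) < 2) stop_invalid("mixed_anova needs >= 2 groups")
  nj <- table(factor(groups, levels = lev))
  if (any(nj < 2)) {
    stop_invalid("every group needs >= 2 participants (got: %s)",
                 paste(nj, collapse = ", "))
  }
  N <- nrow(Y); k <- ncol(Y); gnum <- length(lev)
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  group_means <- tapply(subj_means, factor(groups, levels = lev), mean)

  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_group <- k * sum(nj * (group_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_group

  cond_means <- colMeans(Y)
  ss_cond <- N * sum((cond_means - grand)^2)
  cell_means <- apply(Y, 2, function(col) {
    tapply(col, factor(groups, levels = lev), mean)
  }) # gnum x k
  ss_cells <- sum(as.vector(nj) * (cell_means - grand)^2)
  ss_gxc <- ss_cells - ss_group - ss_cond
  ss_tot <- sum((Y - grand)^2)
  ss_err_within <- ss_tot - ss_between_subj - ss_cond - ss_gxc

  df_group <- gnum - 1
  df_subj <- N - gnum
  df_cond <- k - 1
  df_err <- (N - gnum) * (k - 1)

  eff <- rbind(
    anova_effect_row("group", ss_group, df_group, ss_subj_within, df_subj),
    anova_effect_row("condition", ss_cond, df_cond, ss_err_within, df_err),
    anova_effect_row("group:condition", ss_gxc, df_group * df_cond,
                     ss_err_within, df_err)
  )
  out <- list(effects = eff, design = "mixed (between group x within condition)",
              n = N, k = k, groups = as.vector(nj))
  if (k >= 3 && N - gnum >= k) {
    out <- add_sphericity(out, Y, groups = groups, within = "condition")
  }
  class(out) <- "agl_anova"
  out
}

#' @export
print.agl_anova <- function(x, ...) {
  cat(sprintf("ANOVA (%s): n = %d, k = %d conditions\n", x$design, x$n, x$k))
  ef <- x$effects
  for (i in seq_len(nrow(ef))) {
    cat(sprintf("  %-16s F(%g, %g) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
                ef$effect[i], ef$df1[i], ef$df2[i], ef$F[i], ef$p[i],
                ef$partial_eta_sq[i]))
    if (!is.null(ef$p_gg) && !is.na(ef$p_gg[i])) {
      cat(sprintf("  %-16s   GG-corrected: F(%.2f, %.2f), p = %.4g (epsilon = %.3f)\n",
                  "", ef$df1_gg[i], ef$df2_gg[i], ef$p_gg[i],
                  ef$gg_epsilon[i]))
    }
  }
  if (!is.null(x$mauchly)) {
    cat(sprintf("  Mauchly's W = %.3f, chi^2(%g) = %.3f, p = %.4g%s\n",
                x$mauchly$W, x$mauchly$df, x$mauchly$chisq, x$mauchly$p,
                if (isTRUE(x$sphericity_correction_applied))
                  " -> sphericity violated, GG correction applied" else ""))
  }
  invisible(x)
}

#' Bonferroni-corrected pairwise paired t tests
#'
#' All condition pairs, paired within participant (participants matched
#' on group x participant id), `p_adj = min(1, m * p)` with m = number of
#' pairs.
#'
#' @param table an `agl_accuracy` data.frame.
#' @param conditions optional subset/order of conditions to compare.
#' @return data.frame: one row per pair with `t`, `df`, `p`, `p_adj`, `m`.
#' @export
bonferroni_pairwise <- function(table, conditions = NULL) {
  w <- acc_wide(table)
  Y <- w$Y
  if (!is.null(conditions)) {
    missing_c <- setdiff(conditions, colnames(Y))
    if (length(missing_c)) {
      stop_invalid("unknown condition(s): %s", paste(missing_c, collapse = ", "))
    }
    Y <- Y[, conditions, drop = FALSE]
  }
  k <- ncol(Y)
  if (k < 2) stop_invalid("need >= 2 conditions")
  pairs <- utils::combn(colnames(Y), 2)
  m <- ncol(pairs)
  out <- lapply(seq_len(m), function(j) {
    a <- Y[, pairs[1, j]]; b <- Y[, pairs[2, j]]
    d <- a - b
    if (stats::sd(d) == 0) {
      t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
      p <- if (mean(d) == 0) 1 else 0
    } else {
      t <- mean(d) / (stats::sd(d) / sqrt(length(d)))
      p <- 2 * stats::pt(-abs(t), length(d) - 1)
    }
    data.frame(condition_1 = pairs[1, j], condition_2 = pairs[2, j],
               mean_diff = mean(d), t = t, df = length(d) - 1, p = p,
               p_adj = min(1, m * p), m = m, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
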