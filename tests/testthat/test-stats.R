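test_that("score_responses tallies correctly and detects gaps", {
  # two hand-built participants: one endorses everything, one alternates
  items <- sprintf("I%02d", 1:6)
  conds <- rep(c("grammatical", "within_violation", "cross_violation"), 2)
  mk <- function(p, endorse) {
    data.frame(participant = p, group = NA, item_id = items,
               condition = conds, endorse = endorse,
               correct = ifelse(conds == "grammatical", endorse, !endorse))
  }
  log <- rbind(mk(1, rep(TRUE, 6)), mk(2, c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)))
  acc <- score_responses(log)
  a1 <- acc[acc$participant == 1, ]
  expect_equal(a1$percent_correct[a1$condition == "grammatical"], 100)
  expect_equal(a1$percent_correct[a1$condition == "within_violation"], 0)
  expect_equal(a1$percent_correct[a1$condition == "cross_violation"], 0)
  # manual tally for participant 2: gram TRUE,FALSE -> 50; within FALSE,TRUE
  # judged as correct = !endorse -> 100, 0 -> within 0+? compute by oracle
  a2 <- acc[acc$participant == 2, ]
  for (cc in unique(conds)) {
    rows <- log$participant == 2 & log$condition == cc
    expect_equal(a2$percent_correct[a2$condition == cc],
                 100 * mean(log$correct[rows]))
  }
  expect_error(score_responses(log[-1, ]), "incomplete")
  expect_error(score_responses(log[, setdiff(names(log), "correct")]),
               "lacks column")
})

test_that("one-sample t matches t.test and the d = t/sqrt(n) identity", {
  set.seed(20)
  for (i in 1:20) {
    x <- rnorm(sample(5:30, 1), 55, 12)
    r <- one_sample_t(x)
    o <- t.test(x, mu = 50)
    expect_equal(r$t, unname(o$statistic), tolerance = 1e-12)
    expect_equal(r$p, o$p.value, tolerance = 1e-12)
    expect_equal(r$d, r$t / sqrt(r$n), tolerance = 1e-12)
    # summary-statistic route agrees with the raw-vector route
    r2 <- one_sample_t(M = mean(x), SD = sd(x), n = length(x))
    expect_equal(r2$t, r$t)
  }
  expect_equal(one_sample_t(M = 50, SD = 7, n = 10)$t, 0)
  expect_equal(one_sample_t(M = 50, SD = 7, n = 10)$d, 0)
  expect_error(one_sample_t(M = 55, SD = 0, n = 10), "undefined")
  expect_error(one_sample_t(M = 55, SD = 3, n = 1), "n must be")
})

test_that("one-way RM ANOVA matches the aov oracle and paired-t identity", {
  set.seed(21)
  Y <- matrix(rnorm(12, 60, 10), 4, 3)
  tab <- acc_table(Y)
  r <- rm_anova_oneway(tab)
  av <- summary(aov(percent_correct ~ condition +
                      Error(factor(participant) / condition), data = tab))
  o <- av[["Error: factor(participant):condition"]][[1]]
  expect_equal(r$effects$F, o["condition", "F value"], tolerance = 1e-10)
  expect_equal(r$effects$p, o["condition", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(r$effects$partial_eta_sq,
               o["condition", "Sum Sq"] /
                 (o["condition", "Sum Sq"] + o["Residuals", "Sum Sq"]),
               tolerance = 1e-10)

  # constant table: no effect at all
  expect_equal(rm_anova_oneway(acc_table(matrix(70, 5, 3)))$effects$F, 0)

  # k = 2: F equals the squared paired t
  Y2 <- matrix(rnorm(20, 60, 8), 10, 2)
  r2 <- rm_anova_oneway(acc_table(Y2, conds = c("a", "b")))
  expect_equal(r2$effects$F, oracle_paired_t(Y2[, 1], Y2[, 2])^2,
               tolerance = 1e-10)

  bad <- acc_table(Y)[-1, ]
  expect_error(rm_anova_oneway(bad), "unbalanced")
})

test_that("Mauchly's W and GG epsilon match the base-R mlm oracle", {
  set.seed(22)
  n <- 18; k <- 4
  Y <- matrix(rnorm(n * k), n, k) %*% matrix(rnorm(k * k, sd = 0.6) + diag(k), k, k)
  m <- mauchly_test(Y)
  fit <- lm(Y ~ 1)
  idata <- data.frame(cond = factor(seq_len(k)))
  o <- mauchly.test(fit, X = ~1, idata = idata, M = ~cond)
  expect_equal(m$W, unname(o$statistic), tolerance = 1e-10)
  expect_equal(m$p, o$p.value, tolerance = 1e-10)
  # the mlm anova exposes only the GG-corrected p; our epsilon must
  # reproduce it through the epsilon-shrunk F reference distribution
  a <- anova(fit, X = ~1, idata = idata, M = ~cond, test = "Spherical")
  eps <- gg_epsilon(Y)
  expect_equal(pf(a$F[1], eps * a[["num Df"]][1], eps * a[["den Df"]][1],
                  lower.tail = FALSE),
               a[["G-G Pr"]][1], tolerance = 1e-10)
})

test_that("Mauchly edge cases: exact sphericity, shift invariance, violation", {
  Y <- oracle_spherical_data(15, 3, seed = 23)
  expect_equal(mauchly_test(Y)$W, 1, tolerance = 1e-10)
  expect_equal(gg_epsilon(Y), 1, tolerance = 1e-10)

  set.seed(24)
  Y2 <- matrix(rnorm(60, 60, 5), 20, 3)
  m1 <- mauchly_test(Y2)
  m2 <- mauchly_test(Y2 + rnorm(20, 0, 30)) # per-participant constant shifts
  expect_equal(m1$W, m2$W, tolerance = 1e-10)

  # grossly heteroscedastic conditions: W small, p small
  Y3 <- cbind(rnorm(40, 0, 0.5), rnorm(40, 0, 1), rnorm(40, 0, 12))
  m3 <- mauchly_test(Y3)
  expect_lt(m3$W, 0.7)
  expect_lt(m3$p, 0.001)

  expect_error(mauchly_test(matrix(rnorm(9), 3, 3)), "insufficient")
  expect_error(mauchly_test(matrix(rnorm(10), 5, 2)), ">= 3")
})

test_that("mixed ANOVA matches the aov oracle and validates input", {
  set.seed(25)
  n <- 8
  mkY <- function(shift) matrix(rnorm(n * 3, 60, 9), n, 3) + shift
  tab <- rbind(acc_table(mkY(0), group = "visual"),
               acc_table(mkY(6), group = "auditory"))
  class(tab) <- c("agl_accuracy", "data.frame")
  r <- mixed_anova(tab)
  av <- summary(aov(percent_correct ~ group * condition +
                      Error(interaction(group, participant) / condition),
                    data = tab))
  btw <- av[[1]][[1]]
  win <- av[[2]][[1]]
  ef <- r$effects
  expect_equal(ef$F[ef$effect == "group"], btw["group", "F value"],
               tolerance = 1e-10)
  expect_equal(ef$F[ef$effect == "condition"], win["condition", "F value"],
               tolerance = 1e-10)
  expect_equal(ef$F[ef$effect == "group:condition"],
               win["group:condition", "F value"], tolerance = 1e-10)
  expect_equal(ef$p[ef$effect == "group"], btw["group", "Pr(>F)"],
               tolerance = 1e-10)
  # GG-corrected p uses epsilon-shrunk dfs
  eps <- r$gg_epsilon
  i <- which(ef$effect == "condition")
  expect_equal(ef$p_gg[i],
               pf(ef$F[i], eps * ef$df1[i], eps * ef$df2[i], lower.tail = FALSE),
               tolerance = 1e-12)

  one <- acc_table(matrix(rnorm(3), 1, 3), group = "tiny")
  expect_error(mixed_anova(rbind(acc_table(mkY(0), "g1"), one)),
               ">= 2 participants")
  expect_error(mixed_anova(acc_table(mkY(0), group = "only")), ">= 2 groups")
})

test_that("group-effect type-I error is calibrated under the null", {
  set.seed(26)
  rej <- replicate(2000, {
    tab <- rbind(acc_table(matrix(rnorm(24, 60, 10), 8, 3), "g1"),
                 acc_table(matrix(rnorm(24, 60, 10), 8, 3), "g2"))
    class(tab) <- c("agl_accuracy", "data.frame")
    ef <- mixed_anova(tab)$effects
    ef$p[ef$effect == "group"] < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("Bonferroni pairwise comparisons match independent paired t's", {
  set.seed(27)
  Y <- matrix(rnorm(36, 60, 10), 12, 3)
  colnames(Y) <- c("grammatical", "within_violation", "cross_violation")
  tab <- acc_table(Y)
  pw <- bonferroni_pairwise(tab)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$m == 3))
  for (i in seq_len(nrow(pw))) {
    a <- Y[, pw$condition_1[i]]; b <- Y[, pw$condition_2[i]]
    expect_equal(pw$t[i], oracle_paired_t(a, b), tolerance = 1e-10)
    o <- t.test(a, b, paired = TRUE)
    expect_equal(pw$p_adj[i], min(1, 3 * o$p.value), tolerance = 1e-10)
  }
  expect_true(all(pw$p_adj <= 1))
  expect_error(bonferroni_pairwise(tab, conditions = "nope"), "unknown")
})

test_that("GG epsilon sits near 1 under compound symmetry", {
  set.seed(28)
  eps <- replicate(200, {
    subj <- rnorm(30, 0, 5)
    gg_epsilon(matrix(rnorm(90, 60, 6), 30, 3) + subj)
  })
  expect_true(all(eps <= 1 + 1e-12))
  expect_gt(mean(eps), 0.9)
})
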