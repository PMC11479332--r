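test_that("macro F1 matches hand-computed confusion values", {
  expect_equal(macro_f1(c("a", "b"), c("a", "b")), 1.0)
  # binary confusion TP=2 FP=1 FN=1 TN=2: per-class F1 = 2/3 each
  pred <- c("p", "p", "p", "n", "n", "n")
  truth <- c("p", "p", "n", "p", "n", "n")
  expect_equal(macro_f1(pred, truth), 2 / 3, tolerance = 1e-12)
  # constant prediction over 3 balanced classes: (0.5 + 0 + 0)/3
  pred3 <- rep("a", 9)
  truth3 <- rep(c("a", "b", "c"), each = 3)
  expect_equal(macro_f1(pred3, truth3), 0.5 / 3, tolerance = 1e-12)
  expect_error(macro_f1(character(0), character(0)), "non-empty")
})

test_that("macro F1 is invariant to sample order and label renaming", {
  set.seed(11)
  pred <- sample(c("x", "y", "z"), 60, replace = TRUE)
  truth <- sample(c("x", "y", "z"), 60, replace = TRUE)
  o <- sample(60)
  expect_equal(macro_f1(pred[o], truth[o]), macro_f1(pred, truth))
  ren <- c(x = "1", y = "2", z = "3")
  expect_equal(macro_f1(unname(ren[pred]), unname(ren[truth])),
               macro_f1(pred, truth))
})

test_that("normality and homogeneity checks behave under null and alternative", {
  ok <- mean(replicate(50, {
    normality_check(rnorm(500))$p.value > 0.05
  }))
  expect_gte(ok, 0.9)
  reject <- mean(replicate(50, {
    normality_check(rexp(100))$p.value < 0.05
  }))
  expect_gte(reject, 0.95)
  expect_error(normality_check(rep(1, 10)), "constant")

  g <- rep(c("a", "b"), each = 20)
  v <- c(rnorm(20), rnorm(20))
  lev <- homogeneity_check(c(v[1:20], v[1:20]), g)
  expect_lt(lev$statistic, 1e-9)   # identical groups
})

test_that("Friedman matches the closed-form rank statistic", {
  # identical columns: statistic 0, p = 1
  m <- matrix(rep(1:6, 3), ncol = 3)
  ft <- friedman_test(m)
  expect_equal(ft$statistic, 0, tolerance = 1e-12)
  expect_equal(ft$p.value, 1, tolerance = 1e-12)

  # strictly ordered conditions for all 18 participants: chi2 = 2n = 36
  set.seed(3)
  base <- matrix(runif(18), ncol = 1)
  m2 <- cbind(base, base + 0.1, base + 0.2)
  ft2 <- friedman_test(m2)
  expect_equal(ft2$statistic, 36, tolerance = 1e-9)
  expect_equal(ft2$df, 2)
  expect_lt(ft2$p.value, 1e-7)

  # closed-form oracle 12/(nk(k+1)) sum Rj^2 - 3n(k+1) on a random matrix
  m3 <- matrix(runif(8 * 4), ncol = 4)
  R <- colSums(t(apply(m3, 1, rank)))
  n <- nrow(m3); k <- ncol(m3)
  chi <- 12 / (n * k * (k + 1)) * sum(R^2) - 3 * n * (k + 1)
  expect_equal(friedman_test(m3)$statistic, chi, tolerance = 1e-9)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3), 2)), "complete")
})

test_that("Friedman and signed-rank p-values are calibrated under the null", {
  set.seed(21)
  pf <- replicate(200, friedman_test(matrix(rnorm(30 * 3), ncol = 3))$p.value)
  pw <- replicate(200, paired_wilcoxon(rnorm(15), rnorm(15))$p.value)
  # rank-based p-values are discrete; check coverage at coarse quantiles
  for (p in list(pf, pw)) {
    expect_lt(abs(mean(p < 0.5) - 0.5), 0.12)
    expect_lt(abs(mean(p < 0.2) - 0.2), 0.10)
    expect_lt(mean(p < 0.05), 0.12)
  }
})

test_that("paired signed-rank matches hand ranks and the enumeration oracle", {
  # a = b + constant: V = n(n+1)/2
  b <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  w <- paired_wilcoxon(b + 0.05, b)
  expect_equal(w$statistic, 15)
  # differences {+1, -2, +3}: V = 1 + 3 = 4
  w2 <- paired_wilcoxon(c(1, 0, 3), c(0, 2, 0))
  expect_equal(w2$statistic, 4)
  expect_error(paired_wilcoxon(b, b), "zero")

  # enumeration oracle for n <= 8: exact two-sided p over all sign vectors
  enum_p <- function(d) {
    n <- length(d)
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    v_all <- as.matrix(signs) %*% r
    p_ge <- mean(v_all >= v_obs); p_le <- mean(v_all <= v_obs)
    min(1, 2 * min(p_ge, p_le))
  }
  set.seed(13)
  for (rep in 1:5) {
    d <- round(rnorm(7), 2)
    d <- d[d != 0]
    if (anyDuplicated(abs(d))) next
    w3 <- paired_wilcoxon(d, rep(0, length(d)))
    expect_equal(w3$p.value, enum_p(d), tolerance = 1e-9)
  }
})

test_that("condition comparison applies the Bonferroni threshold", {
  set.seed(5)
  base <- runif(12, 0.5, 0.7)
  m <- cbind(a = base + 0.2, b = base + 0.1, c = base)
  rep3 <- compare_conditions(m)
  expect_equal(rep3$threshold, 0.025)  # two adjacent pairs
  rep2 <- compare_conditions(m, pairs = list(c("a", "b"), c("b", "c"),
                                             c("a", "c")))
  expect_equal(rep2$threshold, 0.05 / 3, tolerance = 1e-9)
  expect_equal(nrow(rep2$pairwise), 3L)
  expect_true(all(rep2$pairwise$significant ==
                    (rep2$pairwise$p.value < rep2$threshold)))
})

test_that("hypothetical end-to-end F1 is the rounded product", {
  expect_equal(hypothetical_max_f1(0.8343, 0.919), 0.767)
  expect_equal(hypothetical_max_f1(0.8343, 0.740), 0.617)
  expect_equal(hypothetical_max_f1(1.0, 0.5321), 0.532)
  expect_error(hypothetical_max_f1(1.2, 0.5), "0, 1")
})

test_that("summaries aggregate hand-built results correctly", {
  scores <- data.frame(
    participant = c("p1", "p2", "p3"), backend = "LGB", il_level = 0.3,
    phase = "two", scheme = "bins45", side = "left",
    f1 = c(0.9, 0.8, 0.7), accuracy = c(0.95, 0.85, 0.75), n_test = 10)
  s <- summarize_lopo(scores)
  expect_equal(s$mean_f1, 0.8)
  expect_equal(s$sd_f1, 0.1)
  expect_equal(s$mean_accuracy, 0.85)
  expect_equal(s$n_participants, 3L)
  single <- summarize_lopo(scores[1, ])
  expect_equal(single$sd_f1, 0)
  expect_true(single$single_participant)
})
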