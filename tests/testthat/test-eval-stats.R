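test_that("overlap metrics on canonical cases", {
  a <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  expect_equal(jaccard(a, a), 1)
  expect_equal(dice(a, a), 1)
  b <- matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2)
  expect_equal(jaccard(a, b), 0)
  expect_equal(dice(a, b), 0)
  # |A|=2, |B|=2, |A n B|=1
  c1 <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  c2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  expect_equal(jaccard(c1, c2), 1 / 3)
  expect_equal(dice(c1, c2), 1 / 2)
  # empty vs empty is perfect agreement by decision
  e <- matrix(FALSE, 2, 2)
  expect_equal(jaccard(e, e), 1)
  expect_equal(dice(e, e), 1)
  expect_error(jaccard(a, matrix(TRUE, 3, 2)), class = "boclahe_argument_error")
})

test_that("dice = 2J/(1+J) on fuzzed mask pairs", {
  set.seed(19)
  for (i in 1:200) {
    a <- matrix(runif(100) < runif(1), 10, 10)
    b <- matrix(runif(100) < runif(1), 10, 10)
    J <- jaccard(a, b)
    expect_equal(dice(a, b), 2 * J / (1 + J), tolerance = 1e-12)
  }
})

test_that("classification metrics match definitions", {
  d <- diag(c(5, 8, 2))
  m <- classification_metrics(d)
  expect_equal(m$accuracy, 1)
  expect_equal(unname(m$f1), rep(1, 3))

  # all predictions to class 1, two balanced classes
  tb <- rbind(c(10, 0), c(10, 0))
  m <- classification_metrics(tb)
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$macro_f1, 1 / 3)

  set.seed(23)
  for (rep in 1:20) {
    tb <- matrix(sample(0:30, 9, TRUE), 3, 3)
    if (sum(tb) == 0) next
    m <- classification_metrics(tb)
    # brute-force per-definition oracle
    acc <- sum(diag(tb)) / sum(tb)
    prec <- rec <- f1 <- numeric(3)
    for (k in 1:3) {
      prec[k] <- if (sum(tb[, k]) > 0) tb[k, k] / sum(tb[, k]) else 0
      rec[k] <- if (sum(tb[k, ]) > 0) tb[k, k] / sum(tb[k, ]) else 0
      f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
    }
    expect_equal(m$accuracy, acc)
    expect_equal(unname(m$precision), prec)
    expect_equal(unname(m$recall), rec)
    expect_equal(unname(m$f1), f1)
    expect_equal(m$macro_f1, mean(f1))
    expect_lte(m$macro_f1, max(f1) + 1e-14)
  }
  expect_error(classification_metrics(matrix(0, 2, 2)),
               class = "boclahe_argument_error")
})

test_that("AUC equals all-pairs counting with half-credit ties", {
  expect_equal(auc_roc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc_roc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  labels <- c(0, 0, 0, 1, 1, 1)
  scores <- c(0.2, 0.5, 0.5, 0.5, 0.7, 0.9)  # one three-way tie at 0.5
  pairs <- 0
  for (i in which(labels == 1)) for (j in which(labels == 0))
    pairs <- pairs + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  expect_equal(auc_roc(labels, scores), pairs / 9)
  # invariance under strictly monotone transforms
  set.seed(3)
  l <- sample(c(0, 1), 30, TRUE, prob = c(0.5, 0.5))
  l[1:2] <- c(0, 1)
  s <- rnorm(30)
  expect_equal(auc_roc(l, s), auc_roc(l, exp(s)))
  expect_equal(auc_roc(l, s), auc_roc(l, rank(s, ties.method = "average")))
  expect_error(auc_roc(rep(1, 4), rnorm(4)), class = "boclahe_argument_error")
})

test_that("one-way ANOVA matches oracles", {
  g_same <- list(a = c(1, 2, 3), b = c(3, 1, 2))
  expect_equal(anova_oneway(g_same)$F, 0)

  # two groups: F equals the square of the pooled t statistic
  set.seed(5)
  x <- rnorm(8); y <- rnorm(10, 0.7)
  res <- anova_oneway(list(x = x, y = y))
  tt <- stats::t.test(x, y, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(res$p, tt$p.value, tolerance = 1e-12)

  # three groups vs direct sums-of-squares and stats::aov
  g <- list(a = rnorm(5), b = rnorm(6, 0.5), c = rnorm(4, 1))
  res <- anova_oneway(g)
  v <- unlist(g); f <- factor(rep(names(g), lengths(g)))
  ref <- summary(stats::aov(v ~ f))[[1]]
  expect_equal(res$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(res$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)

  expect_error(anova_oneway(list(a = c(1, 1), b = c(1, 1))),
               class = "boclahe_degenerate_error")
  expect_error(anova_oneway(list(a = 1:3)), class = "boclahe_argument_error")
})
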