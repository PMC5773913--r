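test_that("confusion counts split the ranking at the cutoff", {
  rk <- c("E1", "E2", "N1", "N2")
  ess <- c("E1", "E2")
  expect_equal(confusion_at_k(rk, ess, 2), c(tp = 2L, fp = 0L, tn = 2L,
                                             fn = 0L))
  expect_equal(confusion_at_k(rk, ess, 0), c(tp = 0L, fp = 0L, tn = 2L,
                                             fn = 2L))
  expect_equal(confusion_at_k(c("N1", "E1"), "E1", 1),
               c(tp = 0L, fp = 1L, tn = 0L, fn = 1L))
  expect_error(confusion_at_k(rk, ess, 5), "between")
  # conservation at every cutoff: TP+FP = k and TP+FN = P
  set.seed(31)
  scores <- stats::setNames(stats::runif(40), paste0("P", 1:40))
  ess2 <- sample(names(scores), 12)
  rk2 <- rank_scores(scores)$protein
  for (k in 0:40) {
    cm <- confusion_at_k(rk2, ess2, k)
    expect_equal(unname(cm["tp"] + cm["fp"]), k)
    expect_equal(unname(cm["tp"] + cm["fn"]), 12L)
  }
})

test_that("ROC endpoints and degenerate rankings behave as defined", {
  perfect <- stats::setNames(c(4, 3, 2, 1), c("E1", "E2", "N1", "N2"))
  ess <- c("E1", "E2")
  roc <- roc_curve(perfect, ess)
  expect_equal(roc$auc, 1.0)
  expect_equal(utils::head(roc$points, 1), data.frame(x = 0, y = 0))
  expect_equal(unlist(utils::tail(roc$points, 1), use.names = FALSE),
               c(1, 1))
  expect_true(all(diff(roc$points$x) >= 0))
  expect_true(all(diff(roc$points$y) >= 0))
  reversed <- roc_curve(stats::setNames(1:4, c("E1", "E2", "N1", "N2")), ess)
  expect_equal(reversed$auc, 0.0)
  expect_error(roc_curve(perfect, character(0)), "essential")
  expect_error(roc_curve(perfect, names(perfect)), "non-essential")
})

test_that("untruncated ROC AUC equals the Mann-Whitney statistic", {
  set.seed(32)
  for (i in 1:10) {
    n <- sample(30:80, 1)
    scores <- stats::setNames(stats::rnorm(n), paste0("P", 1:n))
    ess <- sample(names(scores), sample(5:15, 1))
    auc <- roc_curve(scores, ess)$auc
    pos <- scores[names(scores) %in% ess]
    neg <- scores[!names(scores) %in% ess]
    u <- sum(rank(c(pos, neg))[seq_along(pos)]) -
      length(pos) * (length(pos) + 1) / 2
    expect_equal(auc, u / (length(pos) * length(neg)), tolerance = 1e-12)
  }
})

test_that("random scores calibrate the ROC null at one half", {
  set.seed(33)
  aucs <- replicate(50, {
    scores <- stats::setNames(stats::rnorm(2000), paste0("P", 1:2000))
    ess <- sample(names(scores), 400)
    roc_curve(scores, ess)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("PR sweep matches the confusion definition pointwise", {
  perfect <- stats::setNames(c(4, 3, 2, 1), c("E1", "E2", "N1", "N2"))
  ess <- c("E1", "E2")
  pr <- pr_curve(perfect, ess)
  # perfect ranking: precision 1 while essentials last, i.e. first 2 points
  expect_equal(pr$points$y[1:2], c(1, 1))
  set.seed(34)
  scores <- stats::setNames(stats::runif(30), paste0("P", 1:30))
  ess2 <- sample(names(scores), 10)
  pr2 <- pr_curve(scores, ess2)
  rk <- rank_scores(scores)$protein
  for (k in seq_len(30)) {
    cm <- confusion_at_k(rk, ess2, k)
    expect_equal(pr2$points$y[k], cm[["tp"]] / k)
    expect_equal(pr2$points$x[k], cm[["tp"]] / 10)
  }
})

test_that("jackknife counts accumulate and close with the confusion count", {
  rk <- c("E", "N", "E2")
  jk <- jackknife_curve(rk, c("E", "E2"), top_n = 3)
  expect_equal(jk$points$y, c(1, 1, 2))
  expect_true(all(diff(jk$points$y) >= 0))
  expect_equal(jk$points$y == floor(jk$points$y), rep(TRUE, 3))
  set.seed(35)
  scores <- stats::setNames(stats::runif(25), paste0("P", 1:25))
  ess <- sample(names(scores), 8)
  top_n <- 15
  jk2 <- jackknife_curve(scores, ess, top_n)
  cm <- confusion_at_k(rank_scores(scores)$protein, ess, top_n)
  expect_equal(utils::tail(jk2$points$y, 1), cm[["tp"]])
  expect_error(jackknife_curve(scores, ess, 26), "top_n")
})

test_that("top-percent counts use round-half-up and are monotone", {
  set.seed(36)
  scores <- stats::setNames(stats::runif(200), sprintf("P%03d", 1:200))
  ess <- sample(names(scores), 40)
  counts <- top_percent_counts(scores, ess, c(1, 5, 10, 25))
  # N = 200, 1% -> k = 2
  rk <- rank_scores(scores)$protein
  expect_equal(counts[["1%"]], sum(rk[1:2] %in% ess))
  expect_true(all(diff(counts) >= 0))
  # perfect ranking with 20% essentials recovers all at 20%
  perf <- stats::setNames(200:1, rk)
  ess_top <- rk[1:40]
  expect_equal(top_percent_counts(perf, ess_top, 20)[["20%"]], 40L)
  expect_error(top_percent_counts(scores, ess, 0), "percents")
})

test_that("link proportions classify induced edges and sum to one", {
  tri <- graph_from_pairs("E1", "E2", "E2", "E3", "E1", "E3")
  ess <- c("E1", "E2", "E3")
  row <- link_proportions(tri, c("E1", "E2", "E3"), ess, 3)
  expect_equal(row$ess_ess, 1.0)
  expect_equal(row$ess_noness + row$noness_noness, 0)

  path <- graph_from_pairs("E1", "N1", "N1", "E2")
  row2 <- link_proportions(path, c("E1", "N1", "E2"), c("E1", "E2"), 3)
  expect_equal(row2$ess_noness, 1.0)

  cyc <- graph_from_pairs("E1", "E2", "E2", "N1", "N1", "N2", "N2", "E1")
  row3 <- link_proportions(cyc, c("E1", "E2", "N1", "N2"), c("E1", "E2"), 4)
  expect_equal(row3$ess_ess, 0.25)
  expect_equal(row3$ess_noness, 0.5)
  expect_equal(row3$noness_noness, 0.25)
  expect_equal(row3$ess_ess + row3$ess_noness + row3$noness_noness, 1,
               tolerance = 1e-12)

  # no induced edges: flagged, not an error
  g <- graph_from_pairs("A", "B", "C", "D")
  row4 <- link_proportions(g, c("A", "C"), "A", 2)
  expect_equal(row4$n_edges, 0L)
  expect_equal(row4$ess_ess + row4$ess_noness + row4$noness_noness, 0)
})
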