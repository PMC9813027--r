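test_that("POM score completes the scale below every elicited value", {
  expect_equal(pom_score(c(4, 1, 3), c(65, NA, 0)), c(65, -2, 0))
  expect_equal(pom_score(2, NA), -1)
  # BI-RADS 3 with POM 0 still ranks above every BI-RADS 1-2 case
  expect_true(pom_score(3, 0) > pom_score(2, NA))
  expect_true(pom_score(2, NA) > pom_score(1, NA))
  expect_error(pom_score(4, NA), "without a POM")
  # pooling collapses 1 and 2 to a single tie group
  expect_equal(pom_score(c(1, 2), c(NA, NA), pool_negatives = TRUE),
               c(-1, -1))
})

test_that("forced BI-RADS scoring is the identity on the ordinal scale", {
  expect_equal(birads_score(c(5, 1, 3)), c(5, 1, 3))
  r <- empirical_roc(birads_score(c(5, 4, 3, 2, 1)), c(1, 1, 0, 0, 0))
  # 5 distinct categories -> at most 4 interior operating points
  expect_lte(nrow(r$points) - 2, 4)
})

test_that("empirical ROC reproduces hand-computable AUCs", {
  expect_equal(empirical_roc(c(0.9, 0.8, 0.7, 0.3), c(1, 1, 0, 0))$auc, 1)
  expect_equal(empirical_roc(rep(2, 6), c(1, 1, 0, 0, 0, 1))$auc, 0.5)
  # pos (0.9, 0.7), neg (0.8, 0.3): 3 wins of 4 pairs, no ties
  expect_equal(empirical_roc(c(0.9, 0.7, 0.8, 0.3), c(1, 1, 0, 0))$auc,
               0.75)
  expect_error(empirical_roc(1:3, c(1, 1, 1)), "one positive and one negative")
})

test_that("operating points are monotone and bracket (0,0) and (1,1)", {
  set.seed(42)
  for (i in 1:50) {
    inst <- random_score_instance(sample(4:40, 1))
    r <- empirical_roc(inst$scores, inst$labels)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("trapezoidal AUC equals pair counting and the midrank statistic", {
  set.seed(7)
  for (i in 1:300) {
    inst <- random_score_instance(sample(3:30, 1))
    expected <- brute_auc(inst$scores, inst$labels)
    expect_equal(empirical_roc(inst$scores, inst$labels)$auc, expected)
    expect_equal(mrmcboot:::auc_mw(inst$scores, inst$labels), expected)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  set.seed(11)
  for (i in 1:20) {
    inst <- random_score_instance(30)
    expect_equal(empirical_roc(inst$scores, inst$labels)$auc,
                 as.numeric(pROC::auc(inst$labels, inst$scores,
                                      direction = "<", quiet = TRUE)))
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(13)
  for (i in 1:50) {
    inst <- random_score_instance(sample(4:30, 1))
    a0 <- empirical_roc(inst$scores, inst$labels)$auc
    expect_equal(empirical_roc(exp(inst$scores / 3), inst$labels)$auc, a0)
    expect_equal(empirical_roc(rank(inst$scores, ties.method = "average"),
                               inst$labels)$auc, a0)
  }
})

test_that("reversing labels maps AUC to its complement", {
  set.seed(17)
  for (i in 1:50) {
    inst <- random_score_instance(sample(4:30, 1))
    a <- empirical_roc(inst$scores, inst$labels)$auc
    b <- empirical_roc(inst$scores, 1L - inst$labels)$auc
    expect_equal(a + b, 1)
  }
})

test_that("an added tied positive-negative pair receives exactly half credit", {
  # the tied pair itself contributes 0.5 of one pair weight; the rest of
  # the change is the new cases' ordinary cross-terms with existing cases
  set.seed(19)
  for (i in 1:30) {
    inst <- random_score_instance(sample(6:30, 1))
    s <- inst$scores; l <- inst$labels
    n1 <- sum(l); n0 <- sum(1 - l)
    a <- empirical_roc(s, l)$auc
    v <- s[sample(length(s), 1)]
    a2 <- empirical_roc(c(s, v, v), c(l, 1L, 0L))$auc
    neg <- s[l == 0]; pos <- s[l == 1]
    cross_new_pos <- sum(v > neg) + 0.5 * sum(v == neg)
    cross_new_neg <- sum(pos > v) + 0.5 * sum(pos == v)
    expect_equal(a2, (a * n1 * n0 + cross_new_pos + cross_new_neg + 0.5) /
                   ((n1 + 1) * (n0 + 1)))
  }
  # in the all-tied limit the statistic is exactly 0.5 however many tied
  # pairs are appended
  expect_equal(empirical_roc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
})

test_that("per-reader AUC table averages with equal weight", {
  ds <- tiny_sim_study(seed = 2)
  tab <- reader_auc_table(ds, "DM", "pom")
  expect_length(tab$auc, 4)
  expect_equal(tab$mean, mean(tab$auc))
  expect_named(tab$auc, c("R1", "R2", "R3", "R4"))

  # readers scoring truth perfectly give AUC exactly 1
  rt <- ds$ratings
  lab <- ds$truth$truth[match(rt$case_id, ds$truth$case_id)] == "malignant"
  rt$bi_rads <- ifelse(lab, 5L, 1L)
  rt$pom <- ifelse(lab, 100L, NA_integer_)
  perfect <- mrmc_study(ds$truth, rt)
  ptab <- reader_auc_table(perfect, "DM", "pom")
  expect_equal(unname(ptab$auc), rep(1, 4))
  expect_equal(ptab$mean, 1)
})

test_that("ROC operating points export as CSV", {
  r <- empirical_roc(c(0.9, 0.7, 0.8, 0.3), c(1, 1, 0, 0))
  f <- withr::local_tempfile(fileext = ".csv")
  write_roc_points(r, f)
  back <- read.csv(f)
  expect_equal(back$fpr, r$points$fpr)
  expect_equal(back$tpr, r$points$tpr)
})
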