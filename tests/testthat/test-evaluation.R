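test_that("perfectly separated scores give AUC 1 and perfect metrics", {
  scores <- tibble::tibble(
    score = c(rep(10, 5), rep(0, 5)),
    label = rep(c("case", "control"), each = 5)
  )
  ev <- roc_and_cutoff(scores)
  expect_equal(ev$auc, 1)
  expect_equal(ev$metrics$sensitivity, 1)
  expect_equal(ev$metrics$specificity, 1)
  expect_error(roc_and_cutoff(scores[scores$label == "case", ]), "control")
})

test_that("random labels on a common score distribution give AUC near 1/2", {
  set.seed(101)
  scores <- tibble::tibble(
    score = rnorm(2000),
    label = sample(c("case", "control"), 2000, replace = TRUE)
  )
  ev <- roc_and_cutoff(scores)
  expect_gt(ev$auc, 0.45)
  expect_lt(ev$auc, 0.55)
})

test_that("trapezoid AUC equals exhaustive Mann-Whitney pair counting", {
  # tiny fixture with ties across classes
  s <- tibble::tibble(
    score = c(30, 30, 5, 4, 3),
    label = c("case", "case", "case", "control", "control")
  )
  expect_equal(roc_and_cutoff(s)$auc, auc_by_pairs(s$score, s$label))

  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(5:20, 2)
    s <- tibble::tibble(
      score = sample.int(8, sum(n), replace = TRUE), # integer scores force ties
      label = rep(c("case", "control"), n)
    )
    expect_equal(roc_and_cutoff(s)$auc, auc_by_pairs(s$score, s$label))
  }
})

test_that("AUC agrees with pROC on a noisy cohort", {
  skip_if_not_installed("pROC")
  set.seed(102)
  s <- tibble::tibble(
    score = c(rnorm(40, 1), rnorm(60)),
    label = rep(c("case", "control"), c(40, 60))
  )
  expect_equal(
    roc_and_cutoff(s)$auc,
    as.numeric(pROC::auc(pROC::roc(s$label, s$score,
      levels = c("control", "case"), direction = "<", quiet = TRUE
    )))
  )
})

test_that("the chosen cutoff maximizes Youden's J, ties broken upward", {
  # two thresholds tie on J; the larger (more specific) must win
  s <- tibble::tibble(
    score = c(10, 2, 8, 1),
    label = c("case", "case", "control", "control")
  )
  ev <- roc_and_cutoff(s)
  j <- with(ev$roc, sensitivity + specificity - 1)
  expect_equal(max(j), ev$metrics$sensitivity + ev$metrics$specificity - 1)
  expect_equal(ev$cutoff, max(ev$roc$threshold[j == max(j)]))
  # reported metrics equal confusion_metrics on strict-greater calls
  calls <- s$score > ev$cutoff
  expect_equal(ev$metrics, confusion_metrics(
    tp = sum(calls & s$label == "case"), fp = sum(calls & s$label == "control"),
    tn = sum(!calls & s$label == "control"), fn = sum(!calls & s$label == "case")
  ))
})

test_that("metrics with empty denominators are absent, not zero", {
  m <- confusion_metrics(tp = 0, fp = 3, tn = 7, fn = 0)
  expect_true(is.na(m$sensitivity))
  expect_equal(m$specificity, 0.7)
  expect_error(confusion_metrics(-1, 0, 0, 1), "non-negative")
})

test_that("kappa matches an independent marginal recomputation", {
  expect_equal(cohens_kappa(c(10, 0, 0, 10))$kappa, 1)
  expect_equal(cohens_kappa(c(25, 25, 25, 25))$kappa, 0)
  # degenerate marginals: kappa undefined
  expect_true(is.na(cohens_kappa(c(20, 0, 0, 0))$kappa))

  skip_if_not_installed("e1071")
  for (seed in 1:10) {
    set.seed(seed)
    tab <- matrix(sample.int(30, 4, replace = TRUE), 2)
    got <- cohens_kappa(tab)
    # oracle 1: direct marginal arithmetic
    n <- sum(tab)
    po <- sum(diag(tab)) / n
    pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
    expect_equal(got$kappa, (po - pe) / (1 - pe))
    # oracle 2: e1071
    expect_equal(got$kappa, e1071::classAgreement(tab)$kappa)
  }
})

test_that("exact McNemar equals the binomial tail and is symmetric", {
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(5, 2), 58 / 128)
  for (seed in 1:10) {
    set.seed(seed)
    b <- sample(0:15, 1); c <- sample(0:15, 1)
    p <- mcnemar_exact(b, c)
    expect_equal(p, mcnemar_exact(c, b))
    k <- min(b, c); n <- b + c
    expect_equal(p, min(1, 2 * sum(choose(n, 0:k)) / 2^n))
  }
  # at fixed n, p shrinks as the split grows more lopsided
  p_seq <- vapply(0:5, function(b) mcnemar_exact(b, 10 - b), 0)
  expect_true(all(diff(p_seq) >= 0))
})

test_that("Fisher's exact test matches exhaustive margin-preserving enumeration", {
  expect_equal(fisher_exact(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(
    fisher_exact(matrix(c(10, 0, 0, 10), 2))$p_value,
    2 / choose(20, 10)
  )
  for (seed in 1:5) {
    set.seed(seed)
    tab <- matrix(sample.int(6, 6, replace = TRUE) - 1, nrow = 2) # 2x3, total <= 30
    got <- fisher_exact(tab)
    expect_equal(got$method, "exact")
    expect_equal(got$p_value, fisher_by_enumeration(tab), tolerance = 1e-8)
  }
  big <- matrix(c(300, 200, 250, 250), 2)
  expect_equal(fisher_exact(big)$method, "monte_carlo")
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("concordance() assembles agreement, kappa and McNemar from paired calls", {
  calls <- readr::read_tsv(
    system.file("extdata", "table2_paired_calls.tsv", package = "ciascore"),
    show_col_types = FALSE
  )
  con <- concordance(calls, "urine_cia", "tissue_cia")
  expect_equal(con$n, 54)
  g <- glance(con)
  expect_equal(g$agreement, 47 / 54)
  expect_equal(g$kappa, cohens_kappa(as.matrix(unclass(con$table)))$kappa)
  expect_equal(round(g$kappa_p_value, 3), 0.003) # Fleiss null variance
  expect_equal(g$mcnemar_p_value, mcnemar_exact(5, 2))
})
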