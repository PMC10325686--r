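test_that("confusion metrics match hand arithmetic on a small table", {
  # TP=3, FP=1, FN=1, TN=5
  y <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  p <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  m <- confusion_metrics(y, p)
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$npv, 5 / 6)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 1, 5))
  expect_length(m$undefined, 0)
  perfect <- confusion_metrics(y, y)
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "ppv", "npv")]),
               c(accuracy = 1, sensitivity = 1, ppv = 1, npv = 1))
})

test_that("zero-denominator rates are flagged undefined, not reported as 0", {
  m <- confusion_metrics(c(1, 1, 0), c(0, 0, 0))
  expect_true(is.na(m$ppv))
  expect_true("ppv" %in% m$undefined)
  expect_false("npv" %in% m$undefined)
})

test_that("AUC equals exhaustive pair enumeration, ties counted one half", {
  auc_oracle <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
    tot / (length(pos) * length(neg))
  }
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0)
  # 4 positives / 4 negatives with tied pairs
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  s <- c(0.9, 0.7, 0.5, 0.5, 0.5, 0.5, 0.3, 0.1)
  expect_equal(roc_auc(y, s), auc_oracle(y, s))
  set.seed(31)
  for (rep in 1:5) {
    y <- c(rep(1, 7), rep(0, 9))
    s <- round(stats::runif(16), 1)  # ties likely
    expect_equal(roc_auc(y, s), auc_oracle(y, s))
  }
  expect_error(roc_auc(rep(1, 4), runif(4)), "both classes")
})

test_that("AUC agrees with pROC and is invariant to monotone transforms", {
  set.seed(12)
  y <- rbinom(60, 1, 0.4)
  y[1:2] <- c(0, 1)
  s <- stats::rnorm(60) + y
  expect_equal(roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(roc_auc(y, s), roc_auc(y, exp(s)))
  expect_equal(roc_auc(y, s), roc_auc(y, 3 * s - 100))
})

test_that("fold mean CI is a symmetric t-interval", {
  same <- fold_mean_ci(rep(0.75, 5))
  expect_equal(same$mean, 0.75)
  expect_equal(same$ci_low, 0.75)
  expect_equal(same$ci_high, 0.75)
  v <- c(0.7, 0.75, 0.8, 0.75, 0.75)
  ci <- fold_mean_ci(v)
  half <- stats::qt(0.975, 4) * stats::sd(v) / sqrt(5)
  expect_equal(ci$mean, 0.75)
  expect_equal(ci$ci_low, 0.75 - half)
  expect_equal(ci$ci_high, 0.75 + half)
  expect_equal(ci$mean - ci$ci_low, ci$ci_high - ci$mean)
  expect_error(fold_mean_ci(0.7), "at least 2")
})

test_that("AHA aggregation uses majority with ties to scar and 16 entries", {
  segs <- c(7, 7, 7, 8, 8, 13)
  pos <- c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE)
  m <- aggregate_aha(segs, pos)
  expect_length(m, 16L)
  expect_setequal(names(m), as.character(1:16))
  expect_equal(unname(m["7"]), "scar")      # 2 of 3
  expect_equal(unname(m["8"]), "healthy")
  expect_equal(unname(m["13"]), "scar")
  expect_equal(unname(m["1"]), "excluded")  # no retained sectors
  tie <- aggregate_aha(c(4, 4), c(TRUE, FALSE))
  expect_equal(unname(tie["4"]), "scar")
  tie2 <- aggregate_aha(c(4, 4), c(TRUE, FALSE), tie = "healthy")
  expect_equal(unname(tie2["4"]), "healthy")
})

test_that("Cohen's kappa matches the closed form on a hand table", {
  # a=10, b=2, c=3, d=35
  k <- cohen_kappa2(10, 2, 3, 35)
  n <- 50
  po <- 45 / 50
  pe <- (12 * 13 + 38 * 37) / 2500
  expect_equal(k$po, po)
  expect_equal(k$pe, pe)
  expect_equal(k$kappa, (po - pe) / (1 - pe))
  expect_lte(k$ci_low, k$kappa)
  expect_gte(k$ci_high, k$kappa)
})

test_that("identical map sets give kappa 1 everywhere represented and full agreement", {
  set.seed(5)
  maps <- lapply(1:12, function(i)
    aggregate_aha(1:16, stats::runif(16) < 0.5))
  ag <- segment_agreement(maps, maps)
  expect_equal(ag$overall_agreement, 1)
  both <- !is.na(ag$per_segment$kappa)
  expect_true(any(both))
  expect_true(all(ag$per_segment$kappa[both] == 1 |
                    is.na(ag$per_segment$kappa[both])))
})

test_that("independent maps give near-zero kappa", {
  set.seed(17)
  pred <- lapply(1:2000, function(i) aggregate_aha(1:16, stats::runif(16) < 0.5))
  ref <- lapply(1:2000, function(i) aggregate_aha(1:16, stats::runif(16) < 0.5))
  ag <- segment_agreement(pred, ref)
  expect_true(all(abs(ag$per_segment$kappa) < 0.1))
})

test_that("excluded segments are dropped pairwise from agreement", {
  p1 <- aggregate_aha(c(1, 2), c(TRUE, TRUE))    # 3..16 excluded
  r1 <- aggregate_aha(c(1, 3), c(TRUE, FALSE))
  ag <- segment_agreement(list(p1), list(r1))
  # only segment 1 is non-excluded in both
  expect_equal(sum(ag$per_segment$n), 1L)
  expect_equal(ag$overall_agreement, 1)
})

test_that("mean ROC vertical averaging stays within [0,1] and hits corners", {
  set.seed(3)
  ft <- list(rbinom(30, 1, 0.5), rbinom(30, 1, 0.5))
  ft[[1]][1:2] <- c(0, 1); ft[[2]][1:2] <- c(0, 1)
  fs <- list(stats::rnorm(30) + ft[[1]], stats::rnorm(30) + ft[[2]])
  roc <- mean_roc(ft, fs)
  expect_true(all(roc$tpr_mean >= 0 & roc$tpr_mean <= 1))
  expect_equal(roc$tpr_mean[roc$fpr == 1], 1)
  expect_true(all(diff(roc$tpr_mean) >= -1e-12))
})
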