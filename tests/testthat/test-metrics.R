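test_that("PSNR matches hand-evaluated reference cases", {
  x <- rnorm(100)
  expect_identical(psnr(x, x), Inf)
  # every sample off by L-1: ratio is 1, PSNR 0 dB
  expect_equal(psnr(rep(0, 50), rep(255, 50), L = 256), 0)
  # every sample off by exactly 1: 20*log10(255)
  expect_equal(psnr(rep(0, 50), rep(1, 50), L = 256), 20 * log10(255), tolerance = 1e-12)
  expect_error(psnr(rnorm(5), rnorm(6)), class = "ecgkit_length_mismatch")
  expect_error(psnr(rnorm(5), rnorm(5), L = 1), class = "ecgkit_invalid_config")
})

test_that("PSNR decreases with MSE and never rises when noise is added", {
  set.seed(41)
  ref <- rnorm(500)
  noise <- rnorm(500)
  scales <- c(0.01, 0.1, 0.5, 1, 2)
  vals <- vapply(scales, function(s) psnr(ref, ref + s * noise), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("confusion counts match an element-by-element tally", {
  c0 <- confusion(c(1, 0), c(1, 0))
  expect_equal(unlist(c0[c("TP", "FP", "TN", "FN")]), c(TP = 1, FP = 0, TN = 1, FN = 0))
  c1 <- confusion(c(1, 0, 1), c(0, 1, 0))
  expect_equal(c1$TP + c1$TN, 0)
  set.seed(42)
  for (rep in 1:10) {
    yt <- sample(0:1, 100, replace = TRUE)
    yp <- sample(0:1, 100, replace = TRUE)
    cc <- confusion(yt, yp)
    tally <- table(factor(yt, c(0, 1)), factor(yp, c(0, 1)))
    expect_equal(cc$TP, unname(tally["1", "1"]))
    expect_equal(cc$FP, unname(tally["0", "1"]))
    expect_equal(cc$TN, unname(tally["0", "0"]))
    expect_equal(cc$FN, unname(tally["1", "0"]))
  }
  expect_error(confusion(c(0, 2), c(0, 1)), class = "ecgkit_invalid_input")
})

test_that("classification metrics reproduce the defining formulas", {
  m <- classification_metrics(structure(list(TP = 1, FP = 1, TN = 1, FN = 1),
                                        class = "confusion_counts"))
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity", "precision")]),
               c(accuracy = 0.5, sensitivity = 0.5, specificity = 0.5, precision = 0.5))
  m2 <- classification_metrics(structure(list(TP = 40, FP = 5, TN = 45, FN = 10),
                                         class = "confusion_counts"))
  expect_equal(m2$accuracy, 0.85)
  expect_equal(m2$sensitivity, 0.80)
  expect_equal(m2$specificity, 0.90)
  expect_equal(m2$precision, 8 / 9)
  expect_identical(m2$recall, m2$sensitivity)
  # perfect classifier
  m3 <- classification_metrics(structure(list(TP = 10, FP = 0, TN = 20, FN = 0),
                                         class = "confusion_counts"))
  expect_true(all(unlist(m3) == 1))
  # undefined ratios surface as NA, not zero
  m4 <- classification_metrics(structure(list(TP = 0, FP = 0, TN = 5, FN = 0),
                                         class = "confusion_counts"))
  expect_true(is.na(m4$precision))
  expect_error(classification_metrics(structure(list(TP = 0, FP = 0, TN = 0, FN = 0),
                                                class = "confusion_counts")),
               class = "ecgkit_invalid_input")
})

test_that("recall equals sensitivity on random confusion counts", {
  set.seed(43)
  for (rep in 1:25) {
    cc <- confusion(sample(0:1, 50, replace = TRUE), sample(0:1, 50, replace = TRUE))
    m <- classification_metrics(cc)
    expect_identical(m$recall, m$sensitivity)
  }
})

test_that("ROC handles canonical separation patterns", {
  r <- roc_curve(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(c(0, 1, 0, 1), rep(0.5, 4))
  expect_equal(r2$auc, 0.5)
  # 2 concordant of 4 comparable pairs
  r3 <- roc_curve(c(0, 1, 0, 1), c(0.2, 0.3, 0.5, 0.4))
  expect_equal(r3$auc, 0.5)
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3)), class = "ecgkit_single_class")
})

test_that("ROC endpoints and monotonicity hold along the threshold sweep", {
  set.seed(44)
  for (rep in 1:20) {
    y <- c(0, 1, sample(0:1, 30, replace = TRUE))
    s <- round(runif(32), 2)  # force ties
    r <- roc_curve(y, s)
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(r$points$fpr[nrow(r$points)], 1)
    expect_equal(r$points$tpr[nrow(r$points)], 1)
    expect_true(all(diff(r$points$tpr) >= 0))
    expect_true(all(diff(r$points$fpr) >= 0))
  }
})

test_that("trapezoidal AUC equals pairwise concordance with ties counted half", {
  concordance <- function(y, s) {
    pos <- s[y == 1]; neg <- s[y == 0]
    total <- 0
    for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
    total / (length(pos) * length(neg))
  }
  set.seed(45)
  for (rep in 1:30) {
    n <- sample(4:50, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- round(runif(n), 1)
    r <- roc_curve(y, s)
    expect_equal(r$auc, concordance(y, s), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(46)
  for (rep in 1:10) {
    y <- c(0, 1, sample(0:1, 100, replace = TRUE))
    s <- runif(102)
    ours <- roc_curve(y, s)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE, direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("evaluate_predictions assembles counts, metrics, loss and AUC", {
  y <- c(0, 0, 1, 1, 1)
  s <- c(0.1, 0.6, 0.7, 0.9, 0.4)
  rep <- evaluate_predictions(y, s)
  expect_equal(rep$counts$TP, 2)
  expect_equal(rep$counts$FP, 1)
  expect_equal(rep$counts$TN, 1)
  expect_equal(rep$counts$FN, 1)
  expect_equal(rep$metrics$accuracy, 3 / 5)
  expect_equal(rep$metrics$loss, bce_loss(y, s))
  expect_equal(rep$metrics$auc, roc_curve(y, s)$auc)
  td <- tidy(rep)
  expect_true(all(c("metric", "value") %in% names(td)))
})
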