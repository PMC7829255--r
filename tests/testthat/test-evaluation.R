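test_that("mean absolute error and within-level fractions match hand computation", {
  expect_identical(mean_abs_error(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_identical(mean_abs_error(0.5, 0), 0.5)
  expect_equal(mean_abs_error(c(0.1, 0.9), c(0, 1)), 0.1)
  expect_error(mean_abs_error(1:3 / 10, 1:2 / 10),
               class = "mwlfuse_invalid_argument")

  expect_identical(within_fraction(c(0.2, 0.4), c(0.2, 0.4), 0), 1)
  # errors 0.1 and 0.2 against one level (0.1667): only the first qualifies
  expect_equal(within_fraction(c(0.1, 0.2), c(0, 0), 1), 0.5)
  # nested events: larger tolerance can only increase the fraction
  set.seed(5)
  p <- stats::runif(50); l <- stats::runif(50)
  expect_gte(within_fraction(p, l, 1.5), within_fraction(p, l, 1))
  expect_identical(within_fraction(p, l, 6), 1)
})

test_that("nearest-label binning picks the closest class, lower on ties", {
  labels7 <- (0:6) / 6
  # 0.40 is nearer 2/6 = 0.3333 (0.0667) than 0.5 (0.1)
  expect_identical(bin_to_nearest_label(0.40, labels7), 3L)
  expect_identical(bin_to_nearest_label(0.5, labels7), 4L)
  grp <- c(0, 0.33, 0.38, 0.65, 1)
  # 0.50: |0.50-0.38| = 0.12 < |0.50-0.65| = 0.15
  expect_identical(bin_to_nearest_label(0.50, grp), 3L)
  # exact midpoint ties go to the lower label
  expect_identical(bin_to_nearest_label(0.5, c(0.4, 0.6)), 1L)
  # brute-force linear-scan oracle on random predictions
  set.seed(9)
  preds <- stats::runif(100)
  oracle <- vapply(preds, function(p) {
    best <- 1L
    for (i in seq_along(labels7)) {
      if (abs(labels7[i] - p) < abs(labels7[best] - p)) best <- i
    }
    best
  }, integer(1))
  expect_identical(bin_to_nearest_label(preds, labels7), oracle)
})

test_that("confusion matrix counts, proportions and accuracies are consistent", {
  labels7 <- (0:6) / 6
  truth <- labels7[c(1, 1, 4, 4, 7)]
  perfect <- confusion_matrix(truth, truth, labels7)
  expect_identical(sum(perfect$counts) - sum(diag(perfect$counts)), 0L)
  expect_identical(perfect$accuracy, 1)
  # two-class toy set with a hand-counted accuracy of 3/4
  cm <- confusion_matrix(c(0.1, 0.9, 0.9, 0.2), c(0, 1, 0, 0), c(0, 1))
  expect_identical(cm$counts, matrix(c(2L, 0L, 1L, 1L), 2,
                                     dimnames = dimnames(cm$counts)))
  expect_equal(cm$accuracy, 0.75)
  # row proportions sum to one for non-empty rows; counts sum to n
  set.seed(13)
  p <- stats::runif(60); l <- sample(labels7, 60, replace = TRUE)
  cm <- confusion_matrix(p, l, labels7)
  expect_identical(sum(cm$counts), 60L)
  nonempty <- rowSums(cm$counts) > 0
  expect_equal(unname(rowSums(cm$proportions)[nonempty]),
               rep(1, sum(nonempty)))
  # accuracy equals an independent recount from binned predictions
  expect_equal(cm$accuracy,
               mean(bin_to_nearest_label(p, labels7) ==
                      bin_to_nearest_label(l, labels7)))
  expect_error(confusion_matrix(0.5, 0.42, labels7),
               class = "mwlfuse_invalid_argument")
})

test_that("chance accuracy handles neighbourhoods and edge classes", {
  expect_equal(chance_accuracy(7, 0), 100 / 7)
  expect_equal(chance_accuracy(5, 0), 20)
  expect_equal(chance_accuracy(7, 0, "exact-edge-aware"), 100 / 7)
  # the conventional 3/7 off-by-one approximation
  expect_equal(chance_accuracy(7, 1), 300 / 7)
  # exact edge-aware enumeration over the 49 outcome pairs
  expect_equal(chance_accuracy(7, 1, "exact-edge-aware"), 100 * 19 / 49)
  # oracle: full enumeration for arbitrary n and neighbourhood
  for (n in c(3, 5, 7)) {
    for (nb in 0:2) {
      hits <- 0
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (abs(i - j) <= nb) hits <- hits + 1
      }
      expect_equal(chance_accuracy(n, nb, "exact-edge-aware"), 100 * hits / n^2)
    }
  }
  expect_identical(chance_accuracy(7, 10), 100)
})

test_that("error histogram reports the signed-error distribution around zero", {
  p <- c(0.2, 0.4, 0.6); l <- p
  h <- error_histogram(p, l)
  expect_identical(sum(h$counts), 3L)
  expect_identical(h$mu, 0)
  expect_identical(h$sigma, 0)
  # constant positive bias shifts the mean by exactly that bias
  h2 <- error_histogram(l + 0.05, l)
  expect_equal(h2$mu, 0.05)
  # mu and sigma agree with direct computation on random data
  set.seed(17)
  p <- stats::runif(80); l <- stats::runif(80)
  h3 <- error_histogram(p, l)
  expect_equal(h3$mu, mean(p - l))
  expect_equal(h3$sigma, stats::sd(p - l))
  expect_identical(sum(h3$counts), 80L)
  expect_equal(h3$level_bounds, c(-1, 1) / 6)
})

test_that("label distribution percentages are conserved", {
  counts <- c(a = 3, b = 1)
  d <- label_distribution(counts)
  expect_equal(sum(d$percent), 100)
  expect_equal(d$percent, c(75, 25))
  single <- label_distribution(c(x = 12))
  expect_equal(single$percent, 100)
})
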