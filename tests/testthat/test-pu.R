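# PU learning: non-traditional SVM, Platt calibration, prior conversion
# and estimation, empirical frequency, stability features.

# linear-kernel matrix over 1-D points: two well-separated clusters
cluster_kernel <- function(x) {
  K <- outer(x, x) + 1   # linear kernel with offset, PSD
  K / sqrt(outer(diag(K), diag(K)))
}

test_that("well-separated clusters are perfectly separated by the SVM", {
  x <- c(rnorm(20, 5, 0.1), rnorm(20, -5, 0.1))
  y <- rep(c(1, -1), each = 20)
  set.seed(1)
  fit <- train_nontraditional(cluster_kernel(x), y, C = 1)
  expect_true(all(fit$decision[y == 1] > 0))
  expect_true(all(fit$decision[y == -1] < 0))
})

test_that("labeled points duplicated in the unlabeled set score between the cluster extremes", {
  set.seed(2)
  xpos <- rnorm(15, 3, 0.2)
  xneg <- rnorm(15, -3, 0.2)
  xdup <- sort(xpos)[6:10]          # mid-range positives hidden in the unlabeled set
  x <- c(xpos, xneg, xdup)
  y <- c(rep(1, 15), rep(-1, 20))
  fit <- train_nontraditional(cluster_kernel(x), y)
  dup_scores <- fit$decision[31:35]
  expect_true(all(dup_scores > min(fit$decision[16:30])))
  expect_true(all(dup_scores < max(fit$decision[1:15])))
})

test_that("training is deterministic: identical inputs give identical scores", {
  set.seed(3)
  x <- rnorm(40)
  y <- rep(c(1, -1), 20)
  K <- cluster_kernel(x)
  f1 <- train_nontraditional(K, y)
  f2 <- train_nontraditional(K, y)
  expect_identical(f1$decision, f2$decision)
})

test_that("a non-PSD kernel is rejected with a jitter hint", {
  K <- matrix(c(1, 2, 2, 1), 2, 2)  # eigenvalues 3, -1
  expect_error(train_nontraditional(K, c(1, -1)), "jitter")
})

test_that("Platt calibration is monotone and centers symmetric data at zero", {
  s <- c(3, 4, 5, -3, -4, -5)
  y <- c(1, 1, 1, -1, -1, -1)
  sig <- platt_calibrate(s, y)
  p <- platt_apply(sort(s), sig)
  expect_true(all(diff(p) >= 0))
  expect_true(all(platt_apply(c(3, 4, 5), sig) >= 0.5))
  expect_equal(platt_apply(0, sig), 0.5, tolerance = 1e-6)
})

test_that("Platt calibration recovers the generating slope on logistic data", {
  set.seed(42)
  n <- 2000
  s <- rnorm(n, 0, 2)
  slope <- 1.7
  y <- ifelse(runif(n) < 1 / (1 + exp(-slope * s)), 1, -1)
  sig <- platt_calibrate(s, y)
  expect_lt(abs(-sig$A - slope) / slope, 0.1)  # A is the negated slope
})

test_that("single-class input to Platt calibration errors", {
  expect_error(platt_calibrate(c(1, 2), c(1, 1)), "both classes")
})

test_that("pu_convert reproduces the worked arithmetic and the clip rule", {
  expect_equal(pu_convert(0.5, 0.5, 10, 10), 0.5)
  expect_equal(pu_convert(2 / 3, 0.5, 10, 10), 1.0)    # raw value exactly 1
  expect_equal(pu_convert(0.9, 0.5, 10, 20), 1.0)      # raw 9, clipped
  expect_equal(pu_convert(1, 0.3, 5, 5), 1.0)          # p_l = 1 maps to 1
  expect_equal(pu_convert(0, 0.3, 5, 5), 0)
})

test_that("pu_convert is monotone in p_l and linear in alpha before clipping", {
  p <- seq(0, 0.9, by = 0.05)
  out <- pu_convert(p, 0.2, 10, 10)
  expect_true(all(diff(out) >= 0))
  small <- c(0.05, 0.1, 0.2)  # far from the clip for these sizes
  expect_equal(pu_convert(small, 0.4, 10, 10),
               2 * pu_convert(small, 0.2, 10, 10))
})

test_that("the prior estimate approaches one when unlabeled matches labeled", {
  pu <- synth_pu_scores(1, 3000, 3000, seed = 5)
  a <- pu_prior_from_scores(pu$labeled, pu$unlabeled)
  expect_gt(a, 0.9)
})

test_that("the e1 estimator recovers a 0.3 mixture prior from 5000 draws", {
  pu <- synth_pu_scores(0.3, 5000, 5000, seed = 6)
  a <- pu_prior_from_scores(pu$labeled, pu$unlabeled)
  expect_gte(a, 0.25)
  expect_lte(a, 0.35)
})

test_that("a user-supplied prior passes through unchanged", {
  expect_identical(estimate_class_prior(method = "given", value = 0.13), 0.13)
})

test_that("empty score sets are rejected by the prior estimator", {
  expect_error(estimate_class_prior(numeric(), c(0.5)), "nonempty")
})

test_that("empirical frequency is the arithmetic mean of posteriors", {
  expect_equal(empirical_frequency(c(0, 0, 0)), 0)
  expect_equal(empirical_frequency(c(0.2, 0.4)), 0.3)
  expect_error(empirical_frequency(numeric()), "empty")
})

test_that("well-calibrated posteriors recover the true positive fraction", {
  # analytic P(l|x) on the Beta mixture, converted with the true prior
  alpha <- 0.14; m <- 5000; n <- 5000
  pu <- synth_pu_scores(alpha, m, n, seed = 3)
  fL <- dbeta(pu$unlabeled, 9, 1)
  fU <- alpha * dbeta(pu$unlabeled, 9, 1) +
    (1 - alpha) * dbeta(pu$unlabeled, 1, 9)
  p_l <- m * fL / (m * fL + n * fU)
  post <- pu_convert(p_l, alpha, m, n)
  expect_lt(abs(empirical_frequency(post) - alpha), 0.02)
})

test_that("mean converted posterior over unlabeled approximates the prior", {
  for (alpha in c(0.1, 0.5)) {
    m <- 4000; n <- 4000
    pu <- synth_pu_scores(alpha, m, n, seed = 9)
    fL <- dbeta(pu$unlabeled, 9, 1)
    fU <- alpha * dbeta(pu$unlabeled, 9, 1) +
      (1 - alpha) * dbeta(pu$unlabeled, 1, 9)
    p_l <- m * fL / (m * fL + n * fU)
    post <- pu_convert(p_l, alpha, m, n)
    expect_lt(abs(mean(post) - alpha), 0.03)
  }
})

test_that("the stability feature vector has the documented structure", {
  v <- stability_features("A", "G",
                          property_table = matrix(0, 20, 13,
                                                  dimnames = list(aa_alphabet(), paste0("p", 1:13))))
  expect_length(v, 33)
  expect_equal(sum(v != 0), 2)
  expect_equal(unname(v["A"]), -1)
  expect_equal(unname(v["G"]), 1)
})

test_that("stability features are antisymmetric over all ordered pairs", {
  tab <- aa_property_table()
  aas <- aa_alphabet()
  for (wt in aas) for (mt in aas) {
    if (wt == mt) next
    expect_equal(stability_features(wt, mt, tab),
                 -stability_features(mt, wt, tab),
                 ignore_attr = TRUE)
  }
})

test_that("identity substitutions and unknown residues are rejected", {
  expect_error(stability_features("A", "A"), "differ")
  expect_error(stability_features("B", "A"), "unknown")
})

test_that("the stability positive rule excludes the 0.5 boundary exactly", {
  ddG <- c(-1.2, -0.5, -0.49, 0, 0.5, 0.500001, 2)
  expect_equal(label_stability_positives(ddG),
               c(TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
})

test_that("PU model bundles round-trip through the plain-text directory format", {
  set.seed(8)
  x <- c(rnorm(10, 3), rnorm(20, -3))
  K <- cluster_kernel(x)
  fit <- pu_fit(K, labeled = 1:10)
  dir <- file.path(tempdir(), "pu_bundle")
  save_pu_model(fit, dir)
  back <- load_pu_model(dir)
  expect_equal(back$alpha, fit$alpha)
  expect_equal(back$sigmoid$A, fit$sigmoid$A)
  expect_equal(back$svm$sv_coef, fit$svm$sv_coef)
  # predictions through the reloaded model agree
  expect_equal(predict(back, K_new = K), predict(fit, K_new = K))
})

test_that("the fitted pu_model exposes the standard S3 surface", {
  set.seed(10)
  x <- c(rnorm(10, 3), rnorm(20, -3))
  fit <- pu_fit(cluster_kernel(x), labeled = 1:10)
  expect_output(print(fit), "pu_model")
  s <- summary(fit)
  expect_output(print(s), "class prior")
  expect_true(length(coef(fit)) >= 1)
  expect_true(all(predict(fit) >= 0 & predict(fit) <= 1))
})
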