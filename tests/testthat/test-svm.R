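test_that("cost heuristic is 1 / mean squared norm, with its homogeneity", {
  x <- rbind(c(2, 0), c(0, 2), c(2, 0))        # ||x||^2 = 4 each
  expect_equal(estimate_cost(x), 0.25)
  u <- rbind(c(1, 0), c(0, 1))                  # unit rows
  expect_equal(estimate_cost(u), 1)
  set.seed(3)
  r <- matrix(rpois(60, 2), 10, 6)
  expect_equal(estimate_cost(2 * r), estimate_cost(r) / 4)
  expect_error(estimate_cost(matrix(0, 3, 2)), "all-zero")
})

test_that("the 1-D separable problem recovers the analytic solution w = 1, b = 0", {
  x <- matrix(c(-1, 1), 2, 1)
  m <- train_svm(x, c(-1, 1), C = 100, w1 = 1, tolerance = 1e-6)
  expect_equal(unname(m$w), 1, tolerance = 1e-4)
  expect_equal(m$b, 0, tolerance = 1e-4)
})

test_that("label flip negates the decision function", {
  set.seed(4)
  x <- matrix(rnorm(80), 20, 4)
  y <- rep(c(1, -1), 10)
  m1 <- train_svm(x, y, C = 1)
  m2 <- train_svm(x, -y, C = 1)
  expect_equal(unname(m1$w), -unname(m2$w), tolerance = 1e-6)
  expect_equal(m1$b, -m2$b, tolerance = 1e-6)
  expect_error(train_svm(x, rep(1, 20)), "both classes")
  expect_error(train_svm(x, rep(c(1, 2), 10)), "\\+1/-1")
})

test_that("the solver's primal objective beats random feasible probes", {
  set.seed(5)
  x <- matrix(rnorm(200), 50, 4)
  y <- sign(x[, 1] + 0.5 * rnorm(50)); y[y == 0] <- 1
  for (w1 in c(1, 2.5)) {
    m <- train_svm(x, y, C = 0.7, w1 = w1)
    obj <- svm_objective(m$w, m$b, x, y, 0.7, w1)
    for (k in 1:60) {
      probe_w <- m$w + rnorm(4, sd = 0.2)
      probe_b <- m$b + rnorm(1, sd = 0.2)
      expect_gte(svm_objective(probe_w, probe_b, x, y, 0.7, w1),
                 obj - 1e-5)
    }
  }
})

test_that("class weighting moves the boundary toward the favored class", {
  set.seed(6)
  x <- matrix(rnorm(200, sd = 0.7), 100, 2)
  x[1:50, 1] <- x[1:50, 1] + 1.2
  y <- c(rep(1, 50), rep(-1, 50))
  m_bal <- train_svm(x, y, C = 1, w1 = 1)
  m_w <- train_svm(x, y, C = 1, w1 = 4)
  f_bal <- decision_score(m_bal, x)
  f_w <- decision_score(m_w, x)
  # heavier positive penalty: fewer misclassified positives
  expect_lte(sum(f_w[y == 1] < 0), sum(f_bal[y == 1] < 0))
})

test_that("duplicating every sample keeps the separable large-C boundary", {
  set.seed(7)
  x <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  y <- c(rep(1, 20), rep(-1, 20))
  m1 <- train_svm(x, y, C = 50)
  m2 <- train_svm(rbind(x, x), c(y, y), C = 50)
  expect_equal(unname(m1$w), unname(m2$w), tolerance = 1e-3)
  expect_equal(m1$b, m2$b, tolerance = 1e-3)
})

test_that("decision scores are exact linear forms", {
  m <- structure(list(w = c(1, 2), b = -1), class = "linear_model")
  expect_equal(decision_score(m, c(1, 1)), 2)
  expect_equal(decision_score(m, c(0, 0)), -1)   # x = 0 -> b
  x1 <- c(0.3, -2); x2 <- c(4, 0.5)
  expect_equal(decision_score(m, x1 + x2),
               decision_score(m, x1) + decision_score(m, x2) - m$b)
  expect_equal(decision_score(m, rbind(x1, x2)),
               c(decision_score(m, x1), decision_score(m, x2)))
  expect_error(decision_score(m, c(1, 2, 3)), "dimension")
})

test_that("weight scaling maps extremes to +/-1, preserves signs and zeros", {
  s1 <- scale_weights(c(2, -4, 0))
  expect_equal(unname(s1$scaled), c(1, -1, 0))
  s2 <- scale_weights(c(2, -4, 1))
  expect_equal(unname(s2$scaled), c(1, -1, 0.5))
  s3 <- scale_weights(c(3, -1))
  expect_equal(unname(s3$scaled), c(1, -1))
  expect_equal(scale_weights(c(0, 0))$scaled, c(0, 0))
  # one-sided vectors use only their branch
  expect_equal(scale_weights(c(-2, -1, -4))$scaled, -(1 - (c(-2, -1, -4) + 4) / 4))
  expect_equal(scale_weights(c(4, 2))$scaled, c(1, 0.5))
  set.seed(8)
  w <- rnorm(50); w[sample(50, 5)] <- 0
  sc <- scale_weights(w)$scaled
  expect_equal(sign(sc), sign(w))
  expect_true(all(sc >= -1 & sc <= 1))
})

test_that("AUC equals pair counting with half ties, and the trapezoidal ROC area", {
  expect_equal(auc(c(2, 3), c(0, 1)), 1)
  expect_equal(auc(c(1, 1), c(1, 1)), 0.5)
  expect_equal(auc(1, c(0, 2)), 0.5)
  set.seed(9)
  pos <- rpois(120, 4); neg <- rpois(80, 3)     # heavy ties
  expect_equal(auc(pos, neg), auc_pairs(pos, neg))
  if (requireNamespace("pROC", quietly = TRUE)) {
    r <- pROC::roc(response = c(rep(1, 120), rep(0, 80)),
                   predictor = c(pos, neg), quiet = TRUE,
                   direction = "<")
    expect_equal(auc(pos, neg), as.numeric(pROC::auc(r)))
  }
  expect_error(auc(numeric(0), 1), "non-empty")
})

test_that("reliability is an inclusive 0.6 cutoff on the median AUC", {
  expect_equal(is_reliable(list(median_auc = 0.60)), "reliable")
  expect_equal(is_reliable(list(median_auc = 0.59)), "unreliable")
  expect_equal(is_reliable(list(median_auc = 0.98)), "reliable")
})
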