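# feature-space fixtures: a tight healthy cloud near 0.6 and clear
# low-correlation outliers near 0.25, mirroring the generator's contrast
cloud <- function(n, centre = 0.6, sd = 0.05, seed = 1) {
  m <- with(list(), {
    set.seed(seed)
    matrix(rnorm(n * 6, centre, sd), n, 6)
  })
  colnames(m) <- cc_columns()
  m
}

as_features <- function(m, prefix = "P") {
  out <- tibble::as_tibble(m)
  out$subject_id <- sprintf("%s%03d", prefix, seq_len(nrow(m)))
  out
}

test_that("training split is a disjoint deterministic partition", {
  hc <- as_features(cloud(74))
  sp <- split_training(hc, 50, seed = 3)
  expect_equal(nrow(sp$train), 50)
  expect_equal(nrow(sp$test), 24)
  expect_length(intersect(sp$train$subject_id, sp$test$subject_id), 0)
  sp2 <- split_training(hc, 50, seed = 3)
  expect_identical(sp$train$subject_id, sp2$train$subject_id)
  expect_error(split_training(hc, 74), "non-empty test")
})

test_that("one-class grid search honours a single-point grid and nu's rejection bound", {
  tr <- as_features(cloud(50))
  fit1 <- ocsvm_fit(tr, nu_grid = 0.01, gamma_grid = 0.009, folds = 7)
  expect_equal(fit1$nu, 0.01)
  expect_equal(fit1$gamma, 0.009)

  # tight single cluster: held-out acceptance of the selected model sits at
  # the ceiling attainable for a 6-D Gaussian hull of 50 points (~0.87,
  # measured by grid-wide Monte-Carlo)
  fit <- ocsvm_fit(tr, folds = 7, seed = 2)
  accs <- vapply(1:20, function(s) {
    test <- cloud(30, seed = 100 + s)
    mean(predict(fit, test) == 1)
  }, numeric(1))
  expect_gte(mean(accs), 0.85)

  # nu = 0.01 upper-bounds the margin-error fraction on the training data
  big <- as_features(cloud(200, seed = 20))
  own <- ocsvm_fit(big, nu_grid = 0.01, gamma_grid = 1, folds = 7)
  expect_lte(mean(predict(own, big) == -1), 0.03)

  expect_error(ocsvm_fit(tr, folds = 51), "exceed")
  expect_error(ocsvm_fit(tr, nu_grid = numeric(0)), "non-empty")
})

test_that("one-class predictions flag far outliers and return empty on empty input", {
  tr <- as_features(cloud(50))
  fit <- ocsvm_fit(tr, folds = 7)
  far <- cloud(5, centre = 0.6 - 10 * 0.05, seed = 9)  # 10 SD away
  expect_true(all(predict(fit, far) == -1))
  expect_identical(predict(fit, cloud(0)), integer(0))
  # nu bounds the training rejection fraction near 1%
  expect_lte(mean(predict(fit, tr) == -1), 0.05)
})

test_that("the two-fold loop recovers planted outliers and terminates monotonically", {
  train <- as_features(cloud(50), "H")
  pool <- as_features(rbind(cloud(40, seed = 4),
                            cloud(10, centre = 0.25, sd = 0.05, seed = 5)), "S")
  fit <- tfsvm_fit(train, pool, seed = 6)
  planted <- sprintf("S%03d", 41:50)
  expect_true(all(planted %in% fit$negative_ids))
  log <- tidy(fit)
  expect_true(all(diff(log$n_negative_total) >= 0))
  expect_equal(log$n_new_negative[nrow(log)], 0)
  expect_lte(max(log$round), nrow(pool))

  # determinism
  fit2 <- tfsvm_fit(train, pool, seed = 6)
  expect_identical(fit$negative_ids, fit2$negative_ids)
  expect_equal(tidy(fit), tidy(fit2))

  g <- glance(fit)
  expect_equal(g$n_negative, length(fit$negative_ids))
})

test_that("an all-positive pool yields few negatives and a fast stable loop", {
  train <- as_features(cloud(50), "H")
  pool <- as_features(cloud(30, seed = 7), "S")
  fit <- tfsvm_fit(train, pool, seed = 8)
  expect_lte(length(fit$negative_ids), 6)   # ~ nu-level false alarms at most
  expect_lte(max(tidy(fit)$round), 2)
  if (length(fit$negative_ids) == 0) {
    expect_null(fit$tcsvm)
  }
})

test_that("a single obvious outlier is caught in one refinement round", {
  train <- as_features(cloud(50), "H")
  pool <- as_features(cloud(1, centre = 0, sd = 0.01, seed = 11), "S")
  fit <- tfsvm_fit(train, pool, seed = 12)
  expect_identical(fit$negative_ids, "S001")
  expect_equal(tidy(fit)$n_new_negative[nrow(tidy(fit))], 0)
})

test_that("two-class stage agrees with an independent SVM implementation", {
  skip_if_not_installed("kernlab")
  set.seed(13)
  x <- rbind(cloud(50), cloud(10, centre = 0.25, seed = 14))
  y <- rep(c(1, -1), c(50, 10))
  probe <- rbind(cloud(20, seed = 15), cloud(20, centre = 0.25, seed = 16))
  m1 <- e1071::svm(x, factor(y, levels = c(-1, 1)), type = "C-classification",
                   kernel = "radial", cost = 4, gamma = 0.5, scale = FALSE)
  p1 <- as.integer(as.character(predict(m1, probe)))
  m2 <- kernlab::ksvm(x, factor(y, levels = c(-1, 1)), type = "C-svc",
                      kernel = "rbfdot", kpar = list(sigma = 0.5), C = 4,
                      scaled = FALSE)
  p2 <- as.integer(as.character(kernlab::predict(m2, probe)))
  expect_gte(mean(p1 == p2), 0.95)
})

test_that("screening metrics follow the all-positive test-set definitions", {
  m <- evaluate_screening(c(rep(1, 22), -1, -1), rep(1, 24))
  expect_equal(m$accuracy, 100 * 22 / 24)
  expect_equal(m$fpr, 100 * 2 / 24)
  expect_equal(m$tpr, m$accuracy)
  expect_equal(m$accuracy + m$fpr, 100)

  m1 <- evaluate_screening(c(rep(1, 23), -1), rep(1, 24))
  expect_equal(round(m1$accuracy, 2), 95.83)
  expect_equal(round(m1$fpr, 2), 4.17)

  perfect <- evaluate_screening(rep(1, 24), rep(1, 24))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$fpr, 0)

  expect_error(evaluate_screening(integer(0), integer(0)), "empty")
  expect_error(evaluate_screening(c(1, 1), c(1, -1)), "all-positive")
})
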