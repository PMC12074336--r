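test_that("bootstrap resampling has the right exclusion rate and determinism", {
  d <- tibble::tibble(x = 1:5, label = letters[1:5])
  set.seed(1)
  single <- bootstrap_sample(d[1, ])
  expect_equal(single$indices, 1L)
  # expected fraction of instances absent from a resample: (1 - 1/5)^5
  set.seed(7)
  absent <- replicate(10000, {
    idx <- bootstrap_sample(d)$indices
    mean(!(1:5 %in% idx))
  })
  expect_equal(mean(absent), (1 - 1 / 5)^5, tolerance = 0.02)
  r1 <- withr::with_seed(3, bootstrap_sample(d)$indices)
  r2 <- withr::with_seed(3, bootstrap_sample(d)$indices)
  expect_identical(r1, r2)
  expect_error(bootstrap_sample(d[0, ]), "empty")
})

test_that("feature subsets are distinct, uniform and seed-stable", {
  set.seed(2)
  expect_equal(select_features(6, 6), 1:6)
  expect_error(select_features(4, 5), "range")
  # single-feature draws are uniform over 1..M within binomial bounds
  M <- 8
  draws <- replicate(10000, select_features(M, 1))
  freq <- tabulate(draws, M) / 10000
  se <- sqrt((1 / M) * (1 - 1 / M) / 10000)
  expect_true(all(abs(freq - 1 / M) < 5 * se))
  s1 <- withr::with_seed(9, select_features(10, 4))
  s2 <- withr::with_seed(9, select_features(10, 4))
  expect_identical(s1, s2)
  expect_equal(length(unique(s1)), 4)
})

test_that("trees split at the Gini-optimal midpoint and grow to purity", {
  # pure sample collapses to one leaf
  x <- matrix(c(1, 2, 3), dimnames = list(NULL, "f1"))
  t1 <- grow_tree(x, factor(c("A", "A", "A")))
  expect_equal(nrow(t1), 1)
  expect_equal(t1$label, "A")
  # 1-D two-class: unique impurity-minimizing threshold at 1.5
  x2 <- matrix(c(0, 1, 2, 3), dimnames = list(NULL, "f1"))
  t2 <- grow_tree(x2, factor(c("A", "A", "B", "B")))
  expect_equal(nrow(t2), 3)
  expect_equal(t2$threshold[1], 1.5)
  expect_true(all(t2$leaf[2:3]))
  # linearly separable duplicate-free data trains to zero error
  set.seed(4)
  x3 <- cbind(f1 = c(stats::runif(10, 0, 1), stats::runif(10, 2, 3)),
              f2 = stats::runif(20))
  y3 <- factor(rep(c("A", "B"), each = 10))
  t3 <- grow_tree(x3, y3)
  expect_equal(predict(train_forest(
    tibble::tibble(f1 = x3[, 1], f2 = x3[, 2], label = y3),
    trees = 1, mtry = 2, bootstrap = FALSE), data.frame(x3)),
    as.character(y3))
  # leaves are pure or conflicting-duplicate majorities
  leaf_labels <- t3$label[t3$leaf]
  expect_true(all(!is.na(leaf_labels)))
})

test_that("fully-grown trees reach the exhaustive minimal training error on tiny binary data", {
  set.seed(11)
  for (i in 1:300) {
    d <- random_tiny_dataset()
    tree <- grow_tree(d$x, d$y)
    pred <- plmwatch:::predict_tree(tree, d$x)
    err <- sum(pred != as.character(d$y))
    expect_equal(err, min_error_oracle(d$x, d$y))
  }
  # the parity (XOR) labelling is resolved by zero-gain splits
  xx <- cbind(f1 = c(0, 0, 1, 1), f2 = c(0, 1, 0, 1))
  yy <- factor(c("A", "B", "B", "A"))
  tr <- grow_tree(xx, yy)
  expect_equal(plmwatch:::predict_tree(tr, xx), as.character(yy))
})

test_that("tree structure is invariant to instance order without bootstrap", {
  set.seed(6)
  d <- tibble::tibble(f1 = stats::rnorm(30), f2 = stats::rnorm(30),
                      label = factor(sample(c("A", "B", "C"), 30, TRUE)))
  fit <- train_forest(d, trees = 1, mtry = 2, seed = 5, bootstrap = FALSE)
  perm <- d[sample.int(30), ]
  fit_p <- train_forest(perm, trees = 1, mtry = 2, seed = 5,
                        bootstrap = FALSE)
  expect_equal(as.data.frame(fit$members[[1]]$tree),
               as.data.frame(fit_p$members[[1]]$tree))
})

test_that("forests vote conservatively, break ties by class order and reproduce", {
  set.seed(8)
  d <- tibble::tibble(f1 = stats::rnorm(40), f2 = stats::rnorm(40),
                      f3 = stats::rnorm(40),
                      label = sample(c("A", "B", "C"), 40, TRUE))
  fit <- train_forest(d, trees = 7, seed = 2)
  votes <- predict(fit, d, type = "votes")
  expect_true(all(rowSums(votes[, fit$classes]) == 7))
  single <- forest_predict(fit, as.numeric(d[1, 1:3]))
  expect_equal(sum(single$tally$votes), 7)
  expect_equal(single$label,
               single$tally$class[which.max(single$tally$votes)])
  # identical config twice => identical forests
  fit2 <- train_forest(d, trees = 7, seed = 2)
  expect_equal(fit, fit2)
  expect_error(forest_predict(fit, c(1, 2)), "length")
  # declared tie-break: equal votes go to the lowest class in label order
  tiny <- tibble::tibble(f1 = c(0, 1), label = c("B", "A"))
  ft <- train_forest(tiny, trees = 2, mtry = 1, seed = 1, bootstrap = FALSE)
  p <- predict(ft, tibble::tibble(f1 = 0.5), type = "votes")
  if (p$A == p$B) expect_equal(p$.pred, "A")
})

test_that("a zero-noise posture session is classified without error", {
  train_cfg <- zero_noise_config(duration_s = 12 * 15,
                                 schedule = posture_schedule_all(15),
                                 seed = 21)
  train_sess <- simulate_session(train_cfg)
  baseline <- plm_baseline(
    early_normalize(empty_bed_session(zero_noise_config(duration_s = 30))),
    encoded_normalize(train_sess))
  feats <- build_features(train_sess$frames, baseline)
  feats$label <- plmwatch:::label_at_second(train_cfg$posture_schedule,
                                            feats$t_s)
  fit <- train_forest(feats[, c(feature_names(), "label")], seed = 31)
  expect_equal(glance(fit)$mtry, ceiling(sqrt(24)))
  # fresh session: same labels in a different order
  test_cfg <- zero_noise_config(
    duration_s = 12 * 15,
    schedule = posture_schedule_all(15, rev(posture_labels())), seed = 22)
  test_sess <- simulate_session(test_cfg)
  tf <- build_features(test_sess$frames, baseline)
  truth <- plmwatch:::label_at_second(test_cfg$posture_schedule, tf$t_s)
  pred <- predict(fit, tf)
  expect_equal(mean(pred == truth), 1)
})

test_that("held-out accuracy under sensor noise matches an independent ensemble oracle", {
  skip_if_not_installed("randomForest")
  train_cfg <- sim_config(duration_s = 12 * 15, noise_sd_mm = 3,
                          posture_schedule = posture_schedule_all(15),
                          seed = 41)
  train_sess <- simulate_session(train_cfg)
  baseline <- plm_baseline(
    early_normalize(empty_bed_session(zero_noise_config(duration_s = 30))),
    encoded_normalize(train_sess))
  feats <- build_features(train_sess$frames, baseline)
  feats$label <- plmwatch:::label_at_second(train_cfg$posture_schedule,
                                            feats$t_s)
  test_cfg <- sim_config(duration_s = 12 * 15, noise_sd_mm = 3,
                         posture_schedule =
                           posture_schedule_all(15, rev(posture_labels())),
                         seed = 42)
  test_sess <- simulate_session(test_cfg)
  tf <- build_features(test_sess$frames, baseline)
  truth <- plmwatch:::label_at_second(test_cfg$posture_schedule, tf$t_s)

  fit <- train_forest(feats[, c(feature_names(), "label")], seed = 51)
  acc <- mean(predict(fit, tf) == truth)
  expect_gt(acc, 0.9)

  oracle <- randomForest::randomForest(
    x = as.data.frame(feats[, feature_names()]), y = factor(feats$label),
    ntree = 10)
  acc_oracle <- mean(as.character(
    predict(oracle, as.data.frame(tf[, feature_names()]))) == truth)
  expect_gt(acc_oracle, 0.9)
  expect_lt(abs(acc - acc_oracle), 0.1)
})

test_that("forest tidiers summarise trees and fit", {
  d <- tibble::tibble(f1 = c(0, 1, 2, 3), f2 = c(3, 2, 1, 0),
                      label = c("A", "A", "B", "B"))
  fit <- train_forest(d, trees = 3, seed = 1)
  td <- tidy(fit)
  expect_equal(nrow(td), 3)
  expect_true(all(td$n_leaves >= 1))
  gl <- glance(fit)
  expect_equal(gl$trees, 3)
  expect_equal(gl$n_features, 2)
})
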