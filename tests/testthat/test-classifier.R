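# shared fixtures: a separable corpus and a small trained model (training is
# the expensive step, so the suite trains once and reuses the model)
corpus <- make_classifier_corpus(120, seed = 2)
train_set <- corpus[1:100]
test_set <- corpus[101:120]
cfg <- classifier_config(epochs = 120, seed = 4)
model <- train_sequence_classifier(train_set, cfg)

test_that("classify_threshold equals elementwise comparison", {
  nr <- nrms_sequence("t", seq(-2, 0, by = 0.5), c(1.0, 1.0, 2.5, 2.6, 1.1))
  expect_identical(classify_threshold(nr, 1.5)$label, c(0L, 0L, 1L, 1L, 0L))
  expect_identical(classify_threshold(nr, 5)$label, rep(0L, 5))
  # brute-force comparison over random sequences
  withr::with_seed(9, {
    for (k in 1:50) {
      v <- runif(sample(3:40, 1), 0.2, 4)
      tau <- runif(1, 0.5, 3)
      nr <- nrms_sequence("r", seq_along(v), v)
      expect_identical(classify_threshold(nr, tau)$label, as.integer(v >= tau))
    }
  })
})

test_that("training is seeded-deterministic with a non-increasing best trace", {
  model2 <- train_sequence_classifier(train_set, cfg)
  expect_identical(model$params, model2$params)
  p1 <- lapply(test_set, function(tr) classify_sequence(model, tr$nrms))
  p2 <- lapply(test_set, function(tr) classify_sequence(model2, tr$nrms))
  expect_identical(p1, p2)
  expect_true(all(diff(model$best_trace) <= 0))
})

test_that("sequence model separates the synthetic corpus and rejects controls", {
  preds <- lapply(test_set, function(tr) classify_sequence(model, tr$nrms))
  truth <- lapply(test_set, function(tr) tr$labels)
  ev <- evaluate_classifier(preds, truth)
  expect_gte(ev$accuracy, 0.95)

  # agreement with the threshold rule on the well-separated corpus
  thr <- lapply(test_set, function(tr) classify_threshold(tr$nrms, 1.5))
  agree <- evaluate_classifier(preds, thr)
  expect_gte(agree$accuracy, 0.99)

  # a constant baseline track is classified fully non-STN
  flat <- nrms_sequence("flat", seq(-10, 5, by = 0.5), rep(1, 31))
  expect_identical(classify_sequence(model, flat)$label, rep(0L, 31))

  # a single-depth sequence yields exactly one label
  one <- nrms_sequence("one", 0, 3.0)
  out1 <- classify_sequence(model, one)
  expect_length(out1$label, 1)
})

test_that("permuted-label training drops to chance", {
  # class-balanced corpus (STN run covers ~half the track), so that chance
  # level is 0.5 regardless of what degenerate rule the null model learns
  balanced <- make_classifier_corpus(80, seed = 21, run_range = c(13, 18))
  permuted <- withr::with_seed(31, lapply(balanced, function(tr) {
    tr$labels$label <- sample(tr$labels$label)
    tr
  }))
  null_model <- train_sequence_classifier(
    permuted[1:60], classifier_config(epochs = 60, seed = 4))
  # held-out tracks of the same permuted corpus: labels carry no signal, so
  # any rule the null model learned scores at chance
  preds <- lapply(permuted[61:80], function(tr) classify_sequence(null_model, tr$nrms))
  truth <- lapply(permuted[61:80], function(tr) tr$labels)
  ev <- evaluate_classifier(preds, truth)
  expect_gte(ev$accuracy, 0.4)
  expect_lte(ev$accuracy, 0.6)
})

test_that("training input validation", {
  single_class <- lapply(train_set[1:5], function(tr) {
    tr$labels$label[] <- 0L
    tr
  })
  expect_error(train_sequence_classifier(single_class, cfg), "single class")
  broken <- train_set[1:3]
  broken[[1]]$labels <- depth_labels("x", 1:3, c(0, 1, 0))
  expect_error(train_sequence_classifier(broken, cfg), "lengths differ")
})

test_that("evaluate_classifier matches hand-computed confusion matrices", {
  t1 <- depth_labels("a", 1:10, c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  same <- evaluate_classifier(t1, t1)
  expect_equal(same$accuracy, 1)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$specificity, 1)

  # all-zero predictions vs 30% STN truth
  p0 <- depth_labels("a", 1:10, rep(0, 10))
  ev <- evaluate_classifier(p0, t1)
  expect_equal(ev$accuracy, 0.7)
  expect_equal(ev$sensitivity, 0)
  expect_equal(ev$specificity, 1)

  # random case against an explicit hand count
  withr::with_seed(13, {
    pr <- depth_labels("a", 1:20, rbinom(20, 1, 0.5))
    tr <- depth_labels("a", 1:20, rbinom(20, 1, 0.3))
  })
  ev2 <- evaluate_classifier(pr, tr)
  tp <- sum(pr$label == 1 & tr$label == 1)
  tn <- sum(pr$label == 0 & tr$label == 0)
  expect_equal(ev2$accuracy, (tp + tn) / 20)
  expect_equal(ev2$sensitivity, tp / sum(tr$label == 1))
  expect_equal(ev2$specificity, tn / sum(tr$label == 0))

  # class-relabelling symmetry swaps sensitivity and specificity exactly
  flip <- function(d) depth_labels(d$trajectory_id, d$depth, 1L - d$label)
  ev3 <- evaluate_classifier(flip(pr), flip(tr))
  expect_equal(ev3$sensitivity, ev2$specificity)
  expect_equal(ev3$specificity, ev2$sensitivity)

  expect_error(evaluate_classifier(list(p0), list(t1, t1)), "lengths differ")
})

test_that("classifier checkpoints reproduce predictions exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(model, path)
  back <- read_classifier(path)
  expect_equal(back$config$seed, model$config$seed)
  for (tr in test_set[1:5]) {
    expect_equal(classify_sequence(back, tr$nrms)$probability,
                 classify_sequence(model, tr$nrms)$probability)
  }
})

test_that("depth_labels validates probability consistency", {
  expect_error(depth_labels("a", 1:3, c(0, 1, 0), probability = c(0.1, 0.4, 0.2)),
               "inconsistent")
  ok <- depth_labels("a", 1:3, c(0, 1, 0), probability = c(0.1, 0.9, 0.2))
  expect_s3_class(ok, "depth_labels")
  expect_error(depth_labels("a", 1:2, c(0, 2)), "0 or 1")
})
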