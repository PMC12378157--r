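# AUC/ACC conventions and the evaluation report

test_that("binary AUC reproduces the concordant-pair worked example", {
  task <- kd_task("binary", 2)
  s <- c(0.9, 0.8, 0.4, 0.2)
  y <- c(1, 0, 1, 0)
  expect_equal(auc_score(cbind(1 - s, s), y, task), 0.75)
  # perfect separation and all-ties
  expect_equal(auc_score(cbind(0, c(3, 2, 1, 0)), c(1, 1, 0, 0), task), 1)
  expect_equal(auc_score(cbind(0, rep(0.4, 6)), c(1, 0, 1, 0, 1, 0), task), 0.5)
  expect_error(auc_score(cbind(0, s), c(1, 1, 1, 1), task), "one outcome",
               class = "kd_metric_error")
})

test_that("AUC is invariant to strictly monotone score transforms", {
  set.seed(31)
  task <- kd_task("binary", 2)
  for (i in 1:20) {
    s <- rnorm(30)
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    a1 <- auc_score(cbind(-s, s), y, task)
    a2 <- auc_score(cbind(0, exp(s / 2)), y, task)
    a3 <- auc_score(cbind(0, 5 * s + 3), y, task)
    expect_equal(a1, a2, tolerance = 1e-12)
    expect_equal(a1, a3, tolerance = 1e-12)
    # complement property (no ties in continuous scores)
    expect_equal(a1 + auc_score(cbind(0, -s), y, task), 1, tolerance = 1e-12)
  }
})

test_that("macro AUC agrees with the pairwise-concordance oracle", {
  set.seed(32)
  worst <- 0
  for (i in 1:200) {
    n <- sample(8:50, 1)
    m <- sample(2:5, 1)
    scores <- matrix(rnorm(n * m), n, m)
    if (runif(1) < 0.3) scores <- round(scores) # force ties sometimes
    y <- sample(0:(m - 1), n, replace = TRUE)
    present <- vapply(0:(m - 1), function(k) {
      any(y == k) && any(y != k)
    }, logical(1))
    if (!any(present)) next
    ref <- mean(vapply(which(present) - 1L, function(k) {
      oracle_auc(scores[, k + 1], as.integer(y == k))
    }, numeric(1)))
    got <- auc_score(scores, y, kd_task("multiclass", m))
    worst <- max(worst, abs(got - ref))
  }
  expect_lt(worst, 1e-9)
})

test_that("multilabel AUC averages labels with both outcomes and skips others", {
  task <- kd_task("multilabel", 3)
  y <- cbind(c(1, 0, 1, 0), c(1, 1, 1, 1), c(0, 1, 0, 1))
  s <- cbind(c(.9, .8, .4, .2), runif(4), c(.1, .9, .2, .8))
  got <- auc_score(s, y, task)
  expect_equal(as.numeric(got), (0.75 + 1) / 2)
  expect_equal(attr(got, "skipped"), 2L)
})

test_that("accuracy follows the per-task conventions", {
  mc <- kd_task("multiclass", 3)
  scores <- rbind(c(.6, .3, .1), c(.2, .5, .3), c(.5, .4, .1))
  expect_equal(accuracy_score(scores, c(0, 1, 2), mc), 2 / 3, tolerance = 1e-9)
  # argmax ties resolve to the lowest class index
  expect_equal(accuracy_score(matrix(c(.5, .5, 0), 1), 0, mc), 1)
  expect_equal(accuracy_score(matrix(c(.5, .5, 0), 1), 1, mc), 0)
  # multilabel: mean over labels of per-label accuracy
  ml <- kd_task("multilabel", 2)
  probs <- rbind(c(0.9, 0.2), c(0.6, 0.4))
  yml <- rbind(c(1, 0), c(0, 1))
  expect_equal(accuracy_score(probs, yml, ml), 0.5)
  # binary: positive-class probability thresholded at 0.5
  bi <- kd_task("binary", 2)
  expect_equal(accuracy_score(cbind(c(.4, .8), c(.6, .2)), c(1, 0), bi), 1)
})

test_that("single-label accuracy ignores per-sample logit shifts", {
  set.seed(33)
  task <- kd_task("multiclass", 4)
  z <- matrix(rnorm(40), 10, 4)
  y <- sample(0:3, 10, replace = TRUE)
  shifted <- z + rnorm(10)
  expect_equal(accuracy_score(temperature_softmax(z, 1), y, task),
               accuracy_score(temperature_softmax(shifted, 1), y, task))
})

test_that("evaluation reports are deterministic and sane at the extremes", {
  b <- generate_dataset(synthetic_spec("multiclass", 4, 16, 8, 60, seed = 12))
  mod <- build_student("tiny", b$task, seed = 2)
  r1 <- evaluate_model(mod, b, "test")
  r2 <- evaluate_model(mod, b, "test")
  expect_identical(r1, r2)
  expect_true(r1$auc >= 0 && r1$auc <= 1)
  expect_true(r1$acc >= 0 && r1$acc <= 1)
  # an oracle that emits the labels as logits is perfect
  task <- kd_task("multiclass", 4)
  y <- b$test$labels[, 1]
  z <- matrix(0, length(y), 4)
  z[cbind(seq_along(y), y + 1)] <- 50
  p <- temperature_softmax(z, 1)
  expect_equal(as.numeric(auc_score(p, y, task)), 1)
  expect_equal(accuracy_score(p, y, task), 1)
})

test_that("a random-weight model scores near chance on balanced classes", {
  m <- 4
  b <- generate_dataset(synthetic_spec("multiclass", m, 16, 8, 2000,
                                       noise_sigma = 20, seed = 21))
  mod <- build_student("tiny", b$task, seed = 77)
  rep <- evaluate_model(mod, b, "test")
  expect_lt(abs(rep$acc - 1 / m), 0.05)
})

test_that("metrics reports serialize to the declared JSON schema", {
  b <- generate_dataset(synthetic_spec("binary", 2, 16, 8, 12, seed = 3))
  mod <- build_student("tiny", b$task, seed = 1)
  rep <- evaluate_model(mod, b, "test")
  f <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, f)
  back <- jsonlite::read_json(f)
  expect_setequal(names(back), c("model", "task", "split", "n", "auc", "acc"))
  expect_equal(back$auc, rep$auc)
})
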