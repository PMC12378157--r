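# schedule, early stopping, probing, distillation mechanics

test_that("the multi-step schedule yields the documented learning rates", {
  cfg <- train_config()
  expect_identical(lr_at_epoch(cfg, 10), 0.001)
  expect_identical(lr_at_epoch(cfg, 49), 0.001)
  expect_identical(lr_at_epoch(cfg, 50), 1e-4)
  expect_identical(lr_at_epoch(cfg, 60), 1e-4)
  expect_identical(lr_at_epoch(cfg, 75), 1e-5)
  expect_identical(lr_at_epoch(cfg, 80), 1e-5)
  expect_error(lr_at_epoch(cfg, 100), "range", class = "kd_validation_error")
  expect_error(lr_at_epoch(cfg, -1), class = "kd_validation_error")
})

test_that("train_config enforces its invariants", {
  expect_error(train_config(milestones = c(75, 50)),
               "milestones", class = "kd_validation_error")
  expect_error(train_config(milestones = c(50, 150)),
               "milestones", class = "kd_validation_error")
  expect_error(train_config(gamma = 0), class = "kd_validation_error")
  expect_error(train_config(patience = 0), class = "kd_validation_error")
  cfg <- train_config(alpha = 0.25)
  expect_equal(cfg$beta, 0.75)
})

test_that("early stopping fires on stagnation and resets on improvement", {
  expect_false(early_stop_check(c(0.1, 0.2, 0.3, 0.4), patience = 2))
  expect_true(early_stop_check(c(0.5, 0.5, 0.5), patience = 2))
  # improvement on the last allowed epoch resets the counter
  expect_false(early_stop_check(c(0.5, 0.5, 0.6), patience = 2))
  expect_true(early_stop_check(c(0.5, 0.5, 0.6, 0.6, 0.6), patience = 2))
  # loss direction: decreasing is improvement
  expect_false(early_stop_check(c(1, 0.8, 0.6), patience = 2,
                                monitor = "loss"))
  expect_true(early_stop_check(c(1, 1, 1), patience = 2, monitor = "loss"))
  expect_error(early_stop_check(c(1, 2), patience = 2, monitor = "f1"),
               "unknown", class = "kd_validation_error")
  expect_error(early_stop_check(numeric(0), 2), class = "kd_validation_error")
})

test_that("linear probing trains only the head and is seed-deterministic", {
  bundle <- quick_bundle("binary", m = 2, noise = 20, seed = 2)
  teacher <- build_teacher("tiny", bundle$task, seed = 7)
  before <- serialize(teacher$params[teacher$frozen], NULL)
  probed <- fit_linear_probe(teacher, bundle, quick_config(epochs = 15, seed = 7,
                                                           alpha = 1))
  after <- serialize(probed$params[probed$frozen], NULL)
  expect_identical(before, after)
  expect_false(identical(teacher$params$head.weight,
                         probed$params$head.weight))
  # random frozen features of blob data are linearly separable enough
  rep <- evaluate_model(probed, bundle, "val")
  expect_gte(rep$acc, 0.9)
  probed2 <- fit_linear_probe(teacher, bundle, quick_config(epochs = 15,
                                                            seed = 7,
                                                            alpha = 1))
  expect_identical(probed$params$head.weight, probed2$params$head.weight)
})

test_that("distillation leaves every teacher byte untouched", {
  bundle <- quick_bundle(seed = 3)
  teacher <- fit_linear_probe(build_teacher("tiny", bundle$task, seed = 1),
                              bundle, quick_config(epochs = 8, seed = 1,
                                                   alpha = 1))
  before <- serialize(teacher$params, NULL)
  fit <- distill(teacher, build_student("tiny", bundle$task), bundle,
                 quick_config(epochs = 4, seed = 2))
  expect_identical(serialize(teacher$params, NULL), before)
  expect_s3_class(fit, "kd_fit")
})

test_that("history satisfies loss accounting and schedule conformance", {
  bundle <- quick_bundle(seed = 4)
  teacher <- fit_linear_probe(build_teacher("tiny", bundle$task, seed = 2),
                              bundle, quick_config(epochs = 6, seed = 2,
                                                   alpha = 1))
  cfg <- quick_config(epochs = 6, seed = 3, alpha = 0.3, milestones = c(2, 4))
  fit <- distill(teacher, build_student("tiny", bundle$task), bundle, cfg)
  h <- fit$history
  expect_true(all(abs(h$train_total -
                        (0.3 * h$train_hard + 0.7 * h$train_distill)) < 1e-6))
  expect_true(all(abs(h$val_total -
                        (0.3 * h$val_hard + 0.7 * h$val_distill)) < 1e-6))
  for (i in seq_len(nrow(h))) {
    expect_identical(h$lr[i], lr_at_epoch(cfg, h$epoch[i]))
  }
  expect_true(all(h$train_distill >= 0))
})

test_that("same seed, config and data give identical runs", {
  bundle <- quick_bundle(seed = 5)
  teacher <- fit_linear_probe(build_teacher("tiny", bundle$task, seed = 4),
                              bundle, quick_config(epochs = 6, seed = 4,
                                                   alpha = 1))
  cfg <- quick_config(epochs = 4, seed = 9)
  f1 <- distill(teacher, build_student("tiny", bundle$task), bundle, cfg)
  f2 <- distill(teacher, build_student("tiny", bundle$task), bundle, cfg)
  expect_identical(f1$student$params, f2$student$params)
  expect_identical(f1$history, f2$history)
})

test_that("cached and recomputed teacher logits give identical trajectories", {
  bundle <- quick_bundle(seed = 6)
  teacher <- fit_linear_probe(build_teacher("tiny", bundle$task, seed = 5),
                              bundle, quick_config(epochs = 6, seed = 5,
                                                   alpha = 1))
  cfg_on <- quick_config(epochs = 3, seed = 1)
  cfg_off <- cfg_on
  cfg_off$cache_teacher_logits <- FALSE
  f1 <- distill(teacher, build_student("tiny", bundle$task), bundle, cfg_on)
  f2 <- distill(teacher, build_student("tiny", bundle$task), bundle, cfg_off)
  expect_identical(f1$student$params, f2$student$params)
  expect_identical(f1$history, f2$history)
})

test_that("task mismatches are rejected", {
  bundle <- quick_bundle("multiclass", m = 4, seed = 7)
  other <- kd_task("multiclass", 5)
  teacher <- build_teacher("tiny", other, seed = 1)
  expect_error(distill(teacher, build_student("tiny", other), bundle,
                       quick_config()),
               "task", class = "kd_validation_error")
  expect_error(fit_linear_probe(teacher, bundle, quick_config()),
               "task", class = "kd_validation_error")
})

test_that("training rejects architectures without gradient support", {
  bundle <- quick_bundle(seed = 8, n_train = 32, n_val = 8, n_test = 8)
  rn <- build_student("resnet50", bundle$task, seed = 1)
  expect_error(train_supervised(rn, bundle, quick_config()),
               "tiny", class = "kd_validation_error")
})

test_that("fit objects expose methods: print, summary, predict, plot, residuals", {
  fx <- trained_tiny_fixture()
  expect_output(print(fx$fit), "kd_fit")
  s <- summary(fx$fit)
  expect_output(print(s), "best epoch")
  pr <- predict(fx$fit, fx$bundle$test$images, type = "prob")
  expect_equal(dim(pr), c(dim(fx$bundle$test$images)[1], 4L))
  expect_lt(max(abs(rowSums(pr) - 1)), 1e-6)
  cls <- predict(fx$fit, fx$bundle$test$images, type = "class")
  expect_true(all(cls %in% 0:3))
  r <- residuals(fx$fit, fx$bundle, "val")
  expect_length(r, dim(fx$bundle$val$images)[1])
  expect_true(all(r >= 0))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_silent(plot(fx$fit))
  grDevices::dev.off()
})
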