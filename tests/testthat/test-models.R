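# model constructors, parameter counting, features, checkpoints

test_that("student construction honors the head dimension and seed determinism", {
  task <- kd_task("multiclass", 9)
  m1 <- build_student("tiny", task, seed = 4)
  m2 <- build_student("tiny", task, seed = 4)
  expect_identical(m1$params, m2$params)
  m3 <- build_student("tiny", task, seed = 5)
  expect_false(identical(m1$params, m3$params))
  b <- generate_dataset(synthetic_spec("multiclass", 9, 3, 2, 2, seed = 1))
  z <- predict(m1, b$train$images, type = "logit")
  expect_equal(dim(z), c(3L, 9L))
  expect_error(build_student("vgg", task), "arg")
})

test_that("parameter counts have the closed-form head contribution", {
  # linear head d = 2048, m = 9 -> 2048*9 + 9
  rn <- build_student("resnet50", kd_task("multiclass", 9))
  expect_equal(prod(rn$shapes$head.weight) + rn$shapes$head.bias, 18441)
  # independent per-tensor walk over a materialized model
  tiny <- build_student("tiny", kd_task("multiclass", 4), seed = 1)
  expect_equal(count_parameters(tiny),
               sum(vapply(tiny$params, length, numeric(1))))
})

test_that("reference architectures land on their published sizes", {
  for (m in c(2L, 9L, 14L)) {
    rn <- build_student("resnet50", kd_task("multiclass", m))
    expect_equal(param_millions(rn), 23L)
  }
  expect_equal(param_millions(build_vit_backbone("s14")), 22L)
  expect_equal(param_millions(build_vit_backbone("b14")), 86L)
  expect_equal(param_millions(build_vit_backbone("l14")), 304L)
})

test_that("trainable-only counting excludes the frozen teacher backbone", {
  te <- build_teacher("tiny", kd_task("multiclass", 4))
  d <- te$feature_dim
  expect_equal(count_parameters(te, trainable_only = TRUE), 4 * d + 4)
  expect_lt(count_parameters(te, trainable_only = TRUE),
            count_parameters(te))
  trainable <- setdiff(names(te$shapes), te$frozen)
  expect_equal(sort(trainable), c("head.bias", "head.weight"))
})

test_that("feature extraction is pure and respects duplicates", {
  b <- generate_dataset(synthetic_spec("multiclass", 4, 6, 2, 2, seed = 2))
  mod <- build_student("tiny", b$task, seed = 3)
  f1 <- extract_features(mod, b$train$images)
  f2 <- extract_features(mod, b$train$images)
  expect_identical(unname(f1), unname(f2))
  expect_equal(dim(f1), c(6L, mod$feature_dim))
  imgs <- b$train$images[c(1, 1, 2), , , drop = FALSE]
  fd <- extract_features(mod, imgs)
  expect_identical(fd[1, ], fd[2, ])
  expect_false(identical(fd[1, ], fd[3, ]))
})

test_that("features of a trained model are linearly separable on easy data", {
  fx <- trained_tiny_fixture()
  # refit a fresh linear probe on the trained backbone's features
  teacher <- build_teacher("tiny", fx$bundle$task, seed = 9,
                           backbone_params = fx$fit$student$params)
  probed <- fit_linear_probe(teacher, fx$bundle, quick_config(epochs = 20,
                                                              seed = 9,
                                                              alpha = 1))
  rep <- evaluate_model(probed, fx$bundle, "train")
  expect_gte(rep$acc, 0.95)
})

test_that("ResNet-50 evaluation-mode forward yields b x m logits", {
  b <- generate_dataset(synthetic_spec("multiclass", 9, 2, 2, 2, seed = 1))
  rn <- build_student("resnet50", kd_task("multiclass", 9), seed = 1)
  z <- predict(rn, b$train$images, type = "logit")
  expect_equal(dim(z), c(2L, 9L))
  expect_true(all(is.finite(z)))
  rm(rn); gc(verbose = FALSE)
})

test_that("ViT forward works off-grid through position-embedding interpolation", {
  vb <- build_vit_backbone("s14", seed = 1)
  b <- generate_dataset(synthetic_spec("multiclass", 3, 2, 2, 2, seed = 1))
  batch <- preprocess_batch(b$train$images, target_side = 28,
                            normalization = "none")
  ns <- asNamespace("meddistill")
  fw <- ns$forward_vit(vb, batch)
  expect_equal(dim(fw$features), c(2L, 384L))
  expect_true(all(is.finite(fw$features)))
  fw2 <- ns$forward_vit(vb, batch)
  expect_identical(fw$features, fw2$features)
  rm(vb); gc(verbose = FALSE)
})

test_that("checkpoints round-trip and validate tensor shapes", {
  mod <- build_student("tiny", kd_task("multiclass", 4), seed = 2)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(mod, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, mod$params)
  expect_equal(back$arch, "tiny")
  # corrupt one tensor: the first offending name is reported
  ck <- readRDS(f)
  ck$params$conv2.weight <- matrix(0, 2, 2)
  saveRDS(ck, f)
  expect_error(load_checkpoint(f), "conv2.weight",
               class = "kd_checkpoint_error")
})

test_that("ViT weight files must match the declared architecture", {
  vb <- build_vit_backbone("s14", seed = 3)
  f <- withr::local_tempfile(fileext = ".ckpt")
  save_checkpoint(vb, f)
  vb2 <- build_vit_backbone("s14", pretrained_weights = f)
  expect_identical(vb2$params, vb$params)
  # a b14 constructor must reject s14 weights, naming the first bad tensor
  err <- tryCatch(build_vit_backbone("b14", pretrained_weights = f),
                  error = function(e) conditionMessage(e))
  expect_match(err, "cls_token|pos_embed|patch_embed")
  rm(vb, vb2); gc(verbose = FALSE)
})
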