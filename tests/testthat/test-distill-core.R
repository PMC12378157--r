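# loss mathematics: frozen oracle values, invariants, brute-force agreement

test_that("temperature softmax matches direct evaluation and its limits", {
  expect_equal(temperature_softmax(c(0, 0, 0), 3), rep(1 / 3, 3))
  expect_equal(round(temperature_softmax(c(2, 0), 2), 4), c(0.7311, 0.2689))
  expect_equal(temperature_softmax(c(2, 0), 2), oracle_softmax(c(2, 0), 2),
               tolerance = 1e-12)
  # very large temperature flattens toward uniform
  expect_lt(max(abs(temperature_softmax(c(1, 2, 3), 1e6) - 1 / 3)), 1e-5)
  # overflow safety across magnitudes
  set.seed(1)
  for (mag in c(1, 100, 1e4)) {
    z <- matrix(runif(200 * 6, -mag, mag), 200, 6)
    p <- temperature_softmax(z, 2)
    expect_true(all(is.finite(p)))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-6)
  }
  expect_error(temperature_softmax(c(1, 2), 0), class = "kd_validation_error")
})

test_that("KL divergence has its closed-form values and is non-negative", {
  expect_equal(kl_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(round(kl_divergence(c(0.9, 0.1), c(0.5, 0.5)), 4), 0.3681)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-9)
  expect_error(kl_divergence(c(1, 0), c(0, 1)), "support",
               class = "kd_numeric_error")
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0, 0)),
               class = "kd_validation_error")
})

test_that("soft-target loss reproduces oracle values and the zero case", {
  expect_equal(soft_target_kl_loss(c(3, -1), c(3, -1), 2), 0)
  # teacher (2,0), student (0,0), t = 2: t^2 * KL((0.7311,0.2689)||(0.5,0.5))
  expect_equal(soft_target_kl_loss(c(2, 0), c(0, 0), 2),
               oracle_soft_loss(c(2, 0), c(0, 0), 2), tolerance = 1e-12)
  expect_equal(round(soft_target_kl_loss(c(2, 0), c(0, 0), 2), 4), 0.4438)
  # teacher (0,0), student (2,0), t = 1
  expect_equal(round(soft_target_kl_loss(c(0, 0), c(2, 0), 1), 4), 0.4338)
  # asymmetry of KL
  expect_false(isTRUE(all.equal(soft_target_kl_loss(c(2, 0), c(0, 0), 2),
                                soft_target_kl_loss(c(0, 0), c(2, 0), 2))))
})

test_that("hard-label loss covers CE and BCE conventions", {
  mc <- kd_task("multiclass", 2)
  expect_equal(hard_label_loss(c(0, 0), 0, mc), log(2), tolerance = 1e-9)
  expect_lt(hard_label_loss(c(50, 0), 0, mc), 1e-6)
  ml <- kd_task("multilabel", 2)
  expect_equal(hard_label_loss(matrix(c(0, 0), 1), matrix(c(1, 0), 1), ml),
               log(2), tolerance = 1e-9)
  bi <- kd_task("binary", 2)
  expect_equal(hard_label_loss(matrix(c(0, 0), 1), 1, bi), log(2),
               tolerance = 1e-9)
  expect_error(hard_label_loss(c(0, 0), 5, mc), "range",
               class = "kd_validation_error")
  expect_error(hard_label_loss(c(0, 0, 0), 0, mc), "m = 2",
               class = "kd_validation_error")
})

test_that("multi-label soft loss reduces to the binary two-point case", {
  expect_equal(multilabel_soft_loss(c(1, -2), c(1, -2), 3), 0)
  expect_equal(multilabel_soft_loss(2, 0, 2), oracle_ml_soft(2, 0, 2),
               tolerance = 1e-12)
  expect_equal(round(multilabel_soft_loss(2, 0, 2), 4), 0.4438)
  expect_false(isTRUE(all.equal(multilabel_soft_loss(c(2, 1), c(0, 0), 2),
                                multilabel_soft_loss(c(0, 0), c(2, 1), 2))))
})

test_that("total loss is the stated convex combination", {
  expect_equal(total_loss(0.7, 0.3, distill_config(2, 1))$total, 0.7)
  expect_equal(total_loss(0.7, 0.3, distill_config(2, 0))$total, 0.3)
  tl <- total_loss(0.6931, 0.4441, distill_config(2, 0.2))
  expect_equal(round(tl$total, 4), 0.4939)
  expect_equal(tl$total, 0.2 * 0.6931 + 0.8 * 0.4441, tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    h <- runif(1, 0, 3); d <- runif(1, 0, 3); a <- runif(1)
    tot <- total_loss(h, d, distill_config(1.5, a))$total
    expect_gte(tot, min(h, d) - 1e-12)
    expect_lte(tot, max(h, d) + 1e-12)
  }
})

test_that("beta is derived from alpha and never free", {
  cfg <- distill_config(4, 0.3)
  expect_equal(cfg$beta, 0.7)
  expect_error(distill_config(0, 0.5), class = "kd_validation_error")
  expect_error(distill_config(2, 1.2), class = "kd_validation_error")
})

test_that("all loss operations agree with brute-force oracles on random instances", {
  set.seed(99)
  worst <- 0
  for (i in 1:200) {
    m <- sample(2:10, 1)
    t <- runif(1, 1, 8)
    zT <- rnorm(m, sd = 3)
    zS <- rnorm(m, sd = 3)
    y <- sample(0:(m - 1), 1)
    yv <- rbinom(m, 1, 0.5)
    worst <- max(
      worst,
      max(abs(temperature_softmax(zS, t) - oracle_softmax(zS, t))),
      abs(soft_target_kl_loss(zT, zS, t) - oracle_soft_loss(zT, zS, t)),
      abs(hard_label_loss(zS, y, kd_task("multiclass", m)) -
            oracle_ce(zS, y)),
      abs(hard_label_loss(matrix(zS, 1), matrix(yv, 1),
                          kd_task("multilabel", m)) - oracle_bce(zS, yv)),
      abs(multilabel_soft_loss(zT, zS, t) - oracle_ml_soft(zT, zS, t)),
      abs(kl_divergence(oracle_softmax(zT, t), oracle_softmax(zS, t)) -
            oracle_kl(oracle_softmax(zT, t), oracle_softmax(zS, t)))
    )
  }
  expect_lt(worst, 1e-8)
})

test_that("soft loss is non-negative, zero only at matching distributions", {
  set.seed(7)
  for (i in 1:50) {
    m <- sample(2:6, 1)
    zT <- rnorm(m, sd = 2); zS <- rnorm(m, sd = 2)
    t <- runif(1, 0.5, 6)
    v <- soft_target_kl_loss(zT, zS, t)
    expect_gte(v, 0)
  }
  # shifting all logits by a constant leaves the distribution unchanged
  expect_equal(soft_target_kl_loss(c(1, 2), c(3, 4), 2), 0, tolerance = 1e-12)
})

test_that("soft-loss gradient pushes the student gap toward the teacher gap", {
  # 2-class: derivative w.r.t. the student logit gap is negative below the
  # teacher gap and positive above (finite differences)
  t <- 2
  teacher_gap <- 1.5
  dloss <- function(gap) {
    eps <- 1e-5
    (soft_target_kl_loss(c(teacher_gap, 0), c(gap + eps, 0), t) -
       soft_target_kl_loss(c(teacher_gap, 0), c(gap - eps, 0), t)) / (2 * eps)
  }
  expect_lt(dloss(0.5), 0)
  expect_lt(dloss(1.0), 0)
  expect_gt(dloss(2.5), 0)
  expect_gt(dloss(4.0), 0)
  expect_lt(abs(dloss(teacher_gap)), 1e-6)
})

test_that("batch losses are per-sample means", {
  zT <- rbind(c(2, 0), c(0, 1))
  zS <- rbind(c(0, 0), c(1, 1))
  expect_equal(soft_target_kl_loss(zT, zS, 2),
               (oracle_soft_loss(zT[1, ], zS[1, ], 2) +
                  oracle_soft_loss(zT[2, ], zS[2, ], 2)) / 2,
               tolerance = 1e-12)
  task <- kd_task("multiclass", 2)
  expect_equal(hard_label_loss(zS, c(0L, 1L), task),
               (oracle_ce(zS[1, ], 0) + oracle_ce(zS[2, ], 1)) / 2,
               tolerance = 1e-12)
})
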