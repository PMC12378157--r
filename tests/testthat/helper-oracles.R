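# Independent brute-force oracles and shared fixtures. The oracles are
# direct summations/enumerations, written without reference to the package
# internals they check.

oracle_softmax <- function(z, t) {
  e <- exp(z / t)
  e / sum(e)
}

oracle_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) s <- s + p[i] * log(p[i] / q[i])
  }
  s
}

oracle_soft_loss <- function(zT, zS, t) {
  t^2 * oracle_kl(oracle_softmax(zT, t), oracle_softmax(zS, t))
}

oracle_ce <- function(z, y) {
  p <- oracle_softmax(z, 1)
  -log(p[y + 1])
}

oracle_bce <- function(z, yvec) {
  p <- 1 / (1 + exp(-z))
  -mean(yvec * log(p) + (1 - yvec) * log(1 - p))
}

oracle_ml_soft <- function(zT, zS, t) {
  s <- 0
  for (l in seq_along(zT)) {
    pT <- 1 / (1 + exp(-zT[l] / t))
    pS <- 1 / (1 + exp(-zS[l] / t))
    s <- s + oracle_kl(c(pT, 1 - pT), c(pS, 1 - pS))
  }
  t^2 * s / length(zT)
}

# pairwise-concordance AUC: fraction of (positive, negative) pairs ranked
# correctly, ties worth 0.5
oracle_auc <- function(scores, y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  s <- 0
  for (i in pos) {
    for (j in neg) {
      s <- s + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
  }
  s / (length(pos) * length(neg))
}

# small synthetic bundle shared by several test files
quick_bundle <- function(kind = "multiclass", m = 4, n_train = 160,
                         n_val = 48, n_test = 48, noise = 40, seed = 1) {
  generate_dataset(synthetic_spec(kind, m, n_train, n_val, n_test,
                                  noise_sigma = noise, seed = seed))
}

quick_config <- function(epochs = 6, seed = 1, alpha = 0.2, temperature = 2,
                         batch_size = 64, monitor = "acc", patience = 10,
                         milestones = integer(0)) {
  train_config(temperature = temperature, alpha = alpha, epochs = epochs,
               batch_size = batch_size, probe_batch_size = 32,
               patience = patience, monitor = monitor,
               milestones = milestones, seed = seed)
}

# one trained tiny student on an easy task, built once per test run
.fixture_env <- new.env(parent = emptyenv())

# a multi-label model for heatmap tests: each label's only evidence is its
# own blob, so class-evidence maps must localize
multilabel_fixture <- function() {
  if (is.null(.fixture_env$ml_fit)) {
    bundle <- generate_dataset(synthetic_spec("multilabel", 4, 600, 100, 100,
                                              noise_sigma = 20, seed = 7))
    cfg <- train_config(alpha = 1, epochs = 30, batch_size = 128,
                        milestones = integer(0), patience = 30,
                        monitor = "acc", seed = 7)
    .fixture_env$ml_fit <- train_supervised(build_student("tiny", bundle$task),
                                            bundle, cfg)
    .fixture_env$ml_bundle <- bundle
  }
  list(fit = .fixture_env$ml_fit, bundle = .fixture_env$ml_bundle)
}

trained_tiny_fixture <- function() {
  if (is.null(.fixture_env$fit)) {
    bundle <- quick_bundle("multiclass", m = 4, n_train = 240, n_val = 60,
                           n_test = 60, noise = 20, seed = 5)
    fit <- train_supervised(build_student("tiny", bundle$task),
                            bundle, quick_config(epochs = 25, seed = 5,
                                                 alpha = 1, patience = 25))
    .fixture_env$fit <- fit
    .fixture_env$bundle <- bundle
  }
  list(fit = .fixture_env$fit, bundle = .fixture_env$bundle)
}
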