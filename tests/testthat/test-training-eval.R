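test_that("cross-entropy matches its closed forms and clamps zero probabilities", {
  expect_equal(cross_entropy(c(1, 0, 0, 0) + 1e-300, 1), 0, tolerance = 1e-12)
  expect_equal(cross_entropy(rep(0.25, 4), 3), log(4))
  expect_equal(cross_entropy(c(0.5, 0.2, 0.2, 0.1), 1), log(2))
  expect_warning(l0 <- cross_entropy(c(0, 1, 0, 0), 1), "clamped")
  expect_equal(l0, -log(1e-12))
  # matrix form: one loss per sample, all non-negative
  p <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE)
  expect_equal(cross_entropy(p, c(1, 2)), c(-log(0.7), log(4)))
})

test_that("evaluation metrics derive from the confusion matrix exactly", {
  ns <- asNamespace("specphenonet")
  truth <- factor(rep(PHENO, each = 10), levels = PHENO)
  # perfect predictions
  rep1 <- ns$confusion_report(truth, truth)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$recall, 1)
  expect_true(all(rep1$confusion[upper.tri(rep1$confusion)] == 0))
  expect_equal(diag(rep1$confusion), setNames(rep(10L, 4), PHENO),
               ignore_attr = TRUE)
  # everything predicted as one class on a balanced set
  rep2 <- ns$confusion_report(truth, factor(rep("CNT", 40), levels = PHENO))
  expect_equal(rep2$accuracy, 0.25)
  # random predictions against an independent formula oracle
  set.seed(21)
  pred <- factor(sample(PHENO, 40, replace = TRUE), levels = PHENO)
  rep3 <- ns$confusion_report(truth, pred)
  cm <- rep3$confusion
  expect_equal(sum(cm), 40)
  expect_equal(rep3$accuracy, sum(diag(cm)) / sum(cm))
  for (k in seq_along(PHENO)) {
    tp <- cm[k, k]
    oracle_prec <- if (sum(cm[, k]) > 0) tp / sum(cm[, k]) else 0
    oracle_rec <- tp / sum(cm[k, ])
    expect_equal(rep3$per_class$precision[k], oracle_prec)
    expect_equal(rep3$per_class$recall[k], oracle_rec)
    denom <- oracle_prec + oracle_rec
    expect_equal(rep3$per_class$f1[k],
                 if (denom > 0) 2 * oracle_prec * oracle_rec / denom else 0)
  }
  expect_equal(rep3$recall, mean(rep3$per_class$recall))
  expect_equal(rep3$f1, mean(rep3$per_class$f1))
})

test_that("an untrained 4-class model scores near ln 4 cross-entropy", {
  m <- build_1d_model(model_1d_spec(reduced = TRUE), seed = 8)
  set.seed(8)
  x <- array(rnorm(8 * 4 * 512), c(8, 4, 512))
  y <- rep(1:4, 2)
  p <- model_predict_proba(m, x)
  expect_equal(mean(cross_entropy(p, y)), log(4), tolerance = 0.3 / log(4))
})

test_that("training records history, reduces the LR by halving, and learns", {
  set.seed(30)
  mk_set <- function(n_per_class) {
    y <- rep(PHENO, each = n_per_class)
    xs <- lapply(seq_along(y), function(i) {
      base <- matrix(0.05 * rnorm(4 * 512), 4, 512)
      k <- match(y[i], PHENO)
      base[2, seq(k * 90, k * 90 + 60)] <- base[2, seq(k * 90, k * 90 + 60)] + 1.5
      base
    })
    list(x = xs, y = y)
  }
  train <- mk_set(5)
  test <- mk_set(3)
  m <- build_1d_model(model_1d_spec(reduced = TRUE), seed = 9)
  res <- train_model(m, train, test,
                     train_config(epochs = 6, batch_size = 10, seed = 2))
  h <- res$history
  expect_equal(nrow(h), 12)  # train + test rows per epoch
  expect_equal(unique(h$epoch), 1:6)
  # learning rates form a non-increasing sequence initial_lr * 0.5^k
  lrs <- h$lr[h$split == "train"]
  expect_true(all(diff(lrs) <= 0))
  ks <- log(lrs / 1e-3) / log(0.5)
  expect_equal(ks, round(ks), tolerance = 1e-9)
  # learning happened on a separable problem
  first_acc <- h$accuracy[h$split == "train"][1]
  last_acc <- tail(h$accuracy[h$split == "train"], 1)
  expect_gt(last_acc, first_acc)
  expect_error(train_model(m, list(x = list(), y = character(0)), test),
               "empty")
})

test_that("a plateau halves the learning rate after `patience` flat epochs", {
  # unlearnable labels guarantee a test-accuracy plateau
  set.seed(31)
  xs <- lapply(1:8, function(i) matrix(rnorm(4 * 512, sd = 0.01), 4, 512))
  y <- rep(PHENO, 2)
  m <- build_1d_model(model_1d_spec(reduced = TRUE), seed = 10)
  res <- train_model(m, list(x = xs, y = y), list(x = xs, y = y),
                     train_config(epochs = 5, plateau_patience = 2,
                                  batch_size = 8, seed = 3))
  lrs <- res$history$lr[res$history$split == "train"]
  expect_true(5e-4 %in% lrs)
})

test_that("distance matrices are symmetric, zero-diagonal, and recover geometry", {
  # all embeddings identical -> all-zero matrix
  emb <- matrix(1, 8, 5)
  lab <- rep(PHENO, 2)
  expect_true(all(centroid_distance_matrix(emb, lab) == 0))
  # planted centroids offset by v -> distance |v|
  v <- c(3, 4)
  emb2 <- rbind(matrix(0, 2, 2), matrix(v, 2, 2, byrow = TRUE),
                matrix(0, 2, 2), matrix(v, 2, 2, byrow = TRUE))
  lab2 <- rep(PHENO, each = 2)
  d <- centroid_distance_matrix(emb2, lab2)
  expect_equal(d["CNT", "OVC"], 5)
  expect_equal(d["CNT", "RNC"], 0)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  expect_error(centroid_distance_matrix(emb[1:4, ], rep("CNT", 4)), "OVC")
  # cosine option
  dc <- centroid_distance_matrix(rbind(c(1, 0), c(0, 1), c(1, 0), c(1, 0)),
                                 c("CNT", "OVC", "RNC", "PRC"),
                                 metric = "cosine")
  expect_equal(dc["CNT", "OVC"], 1)
  expect_equal(dc["CNT", "RNC"], 0)
})
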