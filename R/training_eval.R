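#' Training configuration
#'
#' Defaults follow the published training protocol: 25 epochs, Adam with an
#' initial learning rate of 1e-3, halved (factor 0.5) whenever the test
#' accuracy has not improved for `plateau_patience` consecutive epochs.
#'
#' @param epochs Number of epochs.
#' @param initial_lr Initial Adam learning rate.
#' @param lr_reduce_factor Multiplier applied to the learning rate on a
#'   plateau; in (0, 1).
#' @param plateau_patience Epochs without test-accuracy improvement before
#'   the learning rate is reduced.
#' @param batch_size Minibatch size.
#' @param weight_decay Decoupled weight decay on convolution/dense weight
#'   matrices (0 disables; useful on small cohorts where memorization is
#'   otherwise cheaper than generalization).
#' @param seed Integer seed covering shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 25L, initial_lr = 1e-3,
                         lr_reduce_factor = 0.5, plateau_patience = 2L,
                         batch_size = 8L, weight_decay = 0, seed = 1L) {
  stopifnot(epochs >= 1, lr_reduce_factor > 0, lr_reduce_factor < 1,
            plateau_patience >= 1, batch_size >= 1, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), initial_lr = initial_lr,
                 lr_reduce_factor = lr_reduce_factor,
                 plateau_patience = as.integer(plateau_patience),
                 batch_size = as.integer(batch_size),
                 weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Multiclass cross-entropy of predicted probabilities
#'
#' `-sum_c y_c log(p_c)` with natural logarithm, which for a one-hot truth
#' reduces to `-log(p_true)`. Probabilities of exactly zero are clamped at
#' 1e-12 with a warning.
#'
#' @param probabilities Numeric probability vector (or matrix, one row per
#'   sample) summing to 1.
#' @param true_class Integer class index (or vector, per sample).
#' @return The loss per sample (vector), non-negative.
#' @export
cross_entropy <- function(probabilities, true_class) {
  p <- if (is.matrix(probabilities)) {
    probabilities[cbind(seq_len(nrow(probabilities)), true_class)]
  } else probabilities[true_class]
  if (any(p <= 0)) {
    warning("zero predicted probability clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  -log(p)
}

onehot <- function(idx, k) {
  m <- matrix(0, length(idx), k)
  m[cbind(seq_along(idx), idx)] <- 1
  m
}

#' Train a classifier with Adam and plateau learning-rate reduction
#'
#' @param model An `ms_model` from [build_1d_model()] or [build_3d_model()].
#' @param train,test Lists with elements `x` (input batch, see
#'   [model_predict_proba()]) and `y` (factor of phenotype labels).
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress?
#' @return A list with the trained `model` and a `history` data frame
#'   (epoch, split, loss, accuracy, lr).
#' @export
train_model <- function(model, train, test, cfg = train_config(),
                        verbose = FALSE) {
  xs <- coerce_batch(model, train$x)
  y <- as.integer(factor(train$y, levels = PHENOTYPE_LEVELS))
  if (length(xs) == 0) stop("empty training split")
  test_xs <- coerce_batch(model, test$x)
  test_y <- as.integer(factor(test$y, levels = PHENOTYPE_LEVELS))
  k <- model$spec$n_classes
  opt <- adam_init(model$layers)
  lr <- cfg$initial_lr
  best_acc <- -Inf
  stall <- 0L
  t_step <- 0L
  set.seed(cfg$seed)
  history <- list()
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(length(xs))
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, length(perm), by = cfg$batch_size)) {
      idx <- perm[start:min(start + cfg$batch_size - 1, length(perm))]
      bxs <- xs[idx]
      by <- y[idx]
      fw <- forward_layers(model$layers, bxs, training = TRUE)
      probs <- do.call(rbind, lapply(fw$out, softmax))
      ep_loss <- ep_loss + sum(cross_entropy(probs, by))
      ep_correct <- ep_correct + sum(max.col(probs) == by)
      dlogits <- (probs - onehot(by, k)) / length(idx)
      dys <- lapply(seq_along(idx), function(i) dlogits[i, ])
      bw <- backward_layers(model$layers, fw$caches, dys)
      t_step <- t_step + 1L
      up <- adam_update(model$layers, bw$grads, opt, lr, t_step,
                        weight_decay = cfg$weight_decay)
      model$layers <- up$layers
      opt <- up$state
    }
    train_loss <- ep_loss / length(xs)
    train_acc <- ep_correct / length(xs)
    tp <- model_predict_proba(model, test_xs)
    test_loss <- mean(cross_entropy(tp, test_y))
    test_acc <- mean(max.col(tp) == test_y)
    history[[length(history) + 1]] <- data.frame(
      epoch = epoch, split = c("train", "test"),
      loss = c(train_loss, test_loss),
      accuracy = c(train_acc, test_acc), lr = lr)
    if (verbose)
      message(sprintf("epoch %2d  lr %.2e  train %.3f/%.3f  test %.3f/%.3f",
                      epoch, lr, train_loss, train_acc, test_loss, test_acc))
    if (test_acc > best_acc + 1e-12) {
      best_acc <- test_acc
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= cfg$plateau_patience) {
        lr <- lr * cfg$lr_reduce_factor
        stall <- 0L
      }
    }
  }
  list(model = model, history = do.call(rbind, history))
}

#' Evaluate a classifier: accuracy, recall, F1, confusion matrix
#'
#' Predictions are the argmax of the softmax output. The confusion matrix
#' uses the fixed label order CNT, OVC, RNC, PRC (rows = true, columns =
#' predicted); overall recall and F1 are macro averages over classes.
#'
#' @param model An `ms_model`.
#' @param x Input batch.
#' @param y Factor (or character) of true phenotype labels.
#' @return A list of class `eval_report`: `accuracy`, `recall`, `f1`,
#'   `per_class` data frame (precision, recall, f1), `confusion` 4 x 4
#'   count matrix.
#' @export
evaluate_model <- function(model, x, y) {
  xs <- coerce_batch(model, x)
  if (length(xs) == 0) stop("empty evaluation dataset")
  yt <- factor(y, levels = PHENOTYPE_LEVELS)
  probs <- model_predict_proba(model, xs)
  pred <- factor(PHENOTYPE_LEVELS[max.col(probs)], levels = PHENOTYPE_LEVELS)
  confusion_report(yt, pred)
}

confusion_report <- function(truth, pred) {
  cm <- table(true = truth, predicted = pred)
  cm <- unclass(cm)[PHENOTYPE_LEVELS, PHENOTYPE_LEVELS]
  total <- sum(cm)
  accuracy <- sum(diag(cm)) / total
  precision <- diag(cm) / pmax(colSums(cm), 1)
  recall <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  present <- rowSums(cm) > 0
  structure(list(accuracy = accuracy,
                 recall = mean(recall[present]),
                 f1 = mean(f1[present]),
                 per_class = data.frame(class = PHENOTYPE_LEVELS,
                                        precision = as.numeric(precision),
                                        recall = as.numeric(recall),
                                        f1 = as.numeric(f1)),
                 confusion = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("accuracy %.3f  macro recall %.3f  macro F1 %.3f\n",
              x$accuracy, x$recall, x$f1))
  print(x$confusion)
  invisible(x)
}

#' Pairwise distance matrix between embedding centroids
#'
#' @param embeddings Matrix (n x d) of penultimate embeddings.
#' @param labels Factor/character of class labels, length n.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return Symmetric matrix with zero diagonal over the 4 phenotype labels.
#' @export
centroid_distance_matrix <- function(embeddings, labels,
                                     metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  labels <- factor(labels, levels = PHENOTYPE_LEVELS)
  missing <- PHENOTYPE_LEVELS[!PHENOTYPE_LEVELS %in% labels]
  if (length(missing) > 0)
    stop("class(es) with no samples: ", paste(missing, collapse = ", "))
  centroids <- t(vapply(PHENOTYPE_LEVELS, function(cl)
    colMeans(embeddings[labels == cl, , drop = FALSE]),
    numeric(ncol(embeddings))))
  k <- nrow(centroids)
  d <- matrix(0, k, k, dimnames = list(PHENOTYPE_LEVELS, PHENOTYPE_LEVELS))
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      if (i == j) next
      d[i, j] <- if (metric == "euclidean") {
        sqrt(sum((centroids[i, ] - centroids[j, ])^2))
      } else {
        1 - sum(centroids[i, ] * centroids[j, ]) /
          (sqrt(sum(centroids[i, ]^2)) * sqrt(sum(centroids[j, ]^2)))
      }
    }
  d
}

#' Inter-phenotype distance matrix from a trained classifier
#'
#' For each class, the centroid of the penultimate-layer embeddings over
#' the given (typically test) dataset is computed; the reported distance
#' between two phenotypes is the distance between their centroids. The
#' matrix is symmetric with a zero diagonal.
#'
#' @param model A trained `ms_model`.
#' @param x Input batch.
#' @param y True labels; every class must be represented.
#' @param metric `"euclidean"` (default) or `"cosine"`.
#' @return A 4 x 4 symmetric distance matrix labeled by phenotype.
#' @export
class_distance_matrix <- function(model, x, y,
                                  metric = c("euclidean", "cosine")) {
  emb <- model_embed(model, x)
  centroid_distance_matrix(emb, y, match.arg(metric))
}
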