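#' Supported classifier families
#'
#' Seven backends for window-fragment classification: a pruned decision
#' tree, k-nearest neighbours and a small random forest on flattened
#' fragments, plus four neural backends (dense stack, two-layer LSTM,
#' four-block 1-D convolutional network, and a simplified convolution +
#' multi-head-attention stack) on fragment sequences.
#'
#' @return Character vector of family names.
#' @export
classifier_families <- function() {
  c("decision-tree", "k-nearest-neighbours", "random-forest",
    "dense-network", "recurrent-lstm", "conv-1d", "conv-attention")
}

# fragments (n, m, q, 3) -> sequence batch (n, q, m*3)
windows_to_sequence <- function(arr) {
  d <- dim(arr)
  array(aperm(arr, c(1, 3, 2, 4)), c(d[1], d[3], d[2] * d[4]))
}

# grouped stratified split: all fragments of one source record stay on the
# same side; records are stratified by class
grouped_split <- function(labels, provenance, split) {
  recs <- unique(provenance)
  rec_label <- labels[match(recs, provenance)]
  test_recs <- integer(0)
  for (cl in levels(droplevels(rec_label))) {
    rc <- recs[rec_label == cl]
    n_test <- max(1L, round((1 - split) * length(rc)))
    test_recs <- c(test_recs, sample(rc, n_test))
  }
  list(train = which(!provenance %in% test_recs),
       test = which(provenance %in% test_recs))
}

standardize_fit <- function(x) {
  if (is.matrix(x)) {
    mu <- colMeans(x)
    sd_ <- apply(x, 2, stats::sd); sd_[sd_ < 1e-12] <- 1
  } else {
    d <- dim(x)
    xm <- matrix(aperm(x, c(1, 2, 3)), d[1] * d[2], d[3])
    mu <- colMeans(xm)
    sd_ <- apply(xm, 2, stats::sd); sd_[sd_ < 1e-12] <- 1
  }
  list(mu = mu, sd = sd_)
}

standardize_apply <- function(x, st) {
  if (is.matrix(x)) {
    sweep(sweep(x, 2, st$mu), 2, st$sd, `/`)
  } else {
    d <- dim(x)
    xm <- matrix(x, d[1] * d[2], d[3])
    xm <- sweep(sweep(xm, 2, st$mu), 2, st$sd, `/`)
    array(xm, d)
  }
}

build_network <- function(family, input_dim, seq_channels, q, n_classes,
                          dropout = 0.2) {
  switch(family,
    "dense-network" = list(
      nn_dense(input_dim, 200), nn_relu(),
      nn_dense(200, 200), nn_relu(),
      nn_dense(200, 200), nn_relu(),
      nn_dense(200, 200), nn_relu(),
      nn_dropout(dropout),
      nn_dense(200, n_classes)),
    "recurrent-lstm" = list(
      nn_lstm(seq_channels, 20, return_sequences = TRUE),
      nn_lstm(20, 50, return_sequences = FALSE),
      nn_dense(50, 100), nn_relu(),
      nn_dense(100, 100), nn_relu(),
      nn_dropout(dropout),
      nn_dense(100, n_classes)),
    "conv-1d" = list(
      nn_conv1d(seq_channels, 32), nn_batchnorm(32), nn_relu(),
      nn_conv1d(32, 64), nn_batchnorm(64), nn_relu(),
      nn_conv1d(64, 128), nn_batchnorm(128), nn_relu(),
      nn_conv1d(128, 256), nn_batchnorm(256), nn_relu(),
      nn_global_avg_pool(),
      nn_dense(256, 100), nn_relu(),
      nn_dense(100, n_classes)),
    "conv-attention" = list(
      nn_conv1d(seq_channels, 32), nn_batchnorm(32), nn_relu(),
      nn_conv1d(32, 64), nn_batchnorm(64), nn_relu(),
      nn_mha(64, n_heads = 4),
      nn_global_avg_pool(),
      nn_dense(64, 100), nn_relu(),
      nn_dropout(dropout),
      nn_dense(100, n_classes)),
    stop("unknown network family ", family)
  )
}

#' Train a classifier family on a window dataset and evaluate it
#'
#' Splits fragments 80/20 (by default) with a grouped, class-stratified
#' split: every fragment of one source record stays on one side, so
#' overlapping windows cannot leak between train and test. Features are
#' standardised with statistics fitted on the training side only. The
#' tabular families (decision tree, k-nearest neighbours, random forest)
#' see flattened fragments; the neural families see the fragment sequence
#' (window length x channels).
#'
#' @param ds A [make_windows()] dataset with at least two classes.
#' @param family One of [classifier_families()].
#' @param split Training fraction in (0, 1).
#' @param epochs Training epochs for the neural families.
#' @param seed Integer seed; fixes the split, initialisation and training
#'   order, making the report reproducible.
#' @param hyper Named list of family-specific overrides: `k` (neighbours),
#'   `max_depth`, `n_trees`, `batch_size`, `lr`, `dropout`.
#' @return An `eval_report` (see [confusion_and_f1()]) with the family,
#'   seed and split sizes attached.
#' @export
train_and_evaluate <- function(ds, family = "random-forest", split = 0.8,
                               epochs = 50L, seed = 1L, hyper = list()) {
  stopifnot(inherits(ds, "window_dataset"))
  family <- match.arg(family, classifier_families())
  if (!(split > 0 && split < 1)) stop("`split` must be in (0, 1)", call. = FALSE)
  if (nlevels(droplevels(ds$labels)) < 2L)
    stop("need at least two classes to train a classifier", call. = FALSE)
  set.seed(seed)
  sp <- grouped_split(ds$labels, ds$provenance, split)
  y <- droplevels(ds$labels)
  lv <- levels(y)
  y_train <- y[sp$train]; y_test <- y[sp$test]
  flat_input <- family %in% c("decision-tree", "k-nearest-neighbours",
                              "random-forest", "dense-network")
  xa <- if (flat_input) flatten_for_tabular(ds) else windows_to_sequence(ds$fragments)
  x_train <- if (is.matrix(xa)) xa[sp$train, , drop = FALSE] else {
    d <- dim(xa); array(xa[sp$train, , , drop = FALSE], c(length(sp$train), d[2], d[3]))
  }
  x_test <- if (is.matrix(xa)) xa[sp$test, , drop = FALSE] else {
    d <- dim(xa); array(xa[sp$test, , , drop = FALSE], c(length(sp$test), d[2], d[3]))
  }
  st <- standardize_fit(x_train)
  x_train <- standardize_apply(x_train, st)
  x_test <- standardize_apply(x_test, st)
  pred <- switch(family,
    "decision-tree" = {
      depth <- hyper$max_depth %||% 10L
      df_train <- as.data.frame(x_train); df_train$.y <- y_train
      fit <- rpart::rpart(.y ~ ., df_train, method = "class",
                          control = rpart::rpart.control(maxdepth = depth,
                                                         cp = 0, xval = 0))
      predict(fit, as.data.frame(x_test), type = "class")
    },
    "k-nearest-neighbours" = {
      class::knn(x_train, x_test, y_train, k = hyper$k %||% 5L)
    },
    "random-forest" = {
      fit <- ranger::ranger(x = x_train, y = y_train,
                            num.trees = hyper$n_trees %||% 20L,
                            max.depth = hyper$max_depth %||% 10L,
                            seed = seed, num.threads = 1)
      predict(fit, data = x_test, num.threads = 1)$predictions
    },
    {
      input_dim <- if (is.matrix(x_train)) ncol(x_train) else NA_integer_
      seq_ch <- if (is.matrix(x_train)) NA_integer_ else dim(x_train)[3]
      net <- build_network(family, input_dim, seq_ch, ds$q, length(lv),
                           dropout = hyper$dropout %||% 0.2)
      net <- nn_train(net, x_train, as.integer(y_train), epochs = epochs,
                      batch_size = hyper$batch_size %||% 32L,
                      lr = hyper$lr %||% 1e-3)
      factor(lv[max.col(nn_predict_logits(net, x_test))], levels = lv)
    }
  )
  rep <- confusion_and_f1(y_test, factor(pred, levels = lv))
  rep$family <- family
  rep$seed <- seed
  rep$n_train <- length(sp$train)
  rep$n_test <- length(sp$test)
  rep$test_records <- sort(unique(ds$provenance[sp$test]))
  rep$train_records <- sort(unique(ds$provenance[sp$train]))
  rep
}

#' Confusion matrix, accuracy and per-class F1
#'
#' @param truth,predicted Factors (or vectors) of equal length.
#' @return An `eval_report` list: `accuracy` (percent), `f1` (named
#'   per-class vector, percent; 0 when precision + recall is 0),
#'   `confusion` (truth rows x prediction columns), `n_test`.
#' @export
confusion_and_f1 <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predictions must have equal length", call. = FALSE)
  lv <- union(levels(factor(truth)), levels(factor(predicted)))
  truth <- factor(truth, levels = lv)
  predicted <- factor(predicted, levels = lv)
  cm <- table(truth = truth, predicted = predicted)
  acc <- 100 * sum(diag(cm)) / sum(cm)
  f1 <- vapply(lv, function(cl) {
    tp <- cm[cl, cl]
    prec_den <- sum(cm[, cl]); rec_den <- sum(cm[cl, ])
    p <- if (prec_den > 0) tp / prec_den else 0
    r <- if (rec_den > 0) tp / rec_den else 0
    if (p + r == 0) 0 else 100 * 2 * p * r / (p + r)
  }, numeric(1))
  structure(list(accuracy = acc, f1 = f1, confusion = cm,
                 n_test = length(truth)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("# Evaluation%s: accuracy %.2f%% on %d fragments\n",
              if (!is.null(x$family)) paste0(" [", x$family, "]") else "",
              x$accuracy, x$n_test))
  print(x$confusion)
  invisible(x)
}

#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(class = names(x$f1),
                 f1 = unname(x$f1),
                 n = as.integer(rowSums(x$confusion)))
}

#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(family = x$family %||% NA_character_,
                 accuracy = x$accuracy,
                 macro_f1 = mean(x$f1),
                 n_test = x$n_test)
}
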