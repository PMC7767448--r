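#' deSNN output-layer configuration
#'
#' One output neuron is created per training sample, fully connected to the
#' reservoir. Its weight to reservoir neuron r is initialised by the
#' rank-order rule `mod^order(r)` (order 0 for the earliest-firing neuron;
#' never-firing neurons get weight 0) and incremented by `drift` on every
#' subsequent firing of r. Classification is k-nearest-neighbour on the
#' Euclidean distance between output-neuron weight vectors.
#'
#' @param mod Rank-order modulation factor in `(0, 1]` (default 0.9; 1
#'   gives binary fired/never-fired weights when `drift = 0`).
#' @param drift Per-spike drift increment (default 0.25).
#' @param k_neighbors Neighbourhood size for kNN labelling (default 1).
#' @return A list of class `desnn_config`.
#' @export
desnn_config <- function(mod = 0.9, drift = 0.25, k_neighbors = 1) {
  if (mod <= 0 || mod > 1 || drift < 0 || k_neighbors < 1) {
    stop_snnerp("invalid desnn_config parameters", "snnerp_config_error")
  }
  structure(list(mod = mod, drift = drift,
                 k_neighbors = as.integer(k_neighbors)),
            class = "desnn_config")
}

#' Build one output neuron's weight vector from a firing log
#'
#' @param firing_log Data frame with `neuron` and `t` columns.
#' @param n_neurons Reservoir size.
#' @param config A [desnn_config()].
#' @return Numeric weight vector of length `n_neurons`.
#' @export
desnn_weights <- function(firing_log, n_neurons, config = desnn_config()) {
  w <- numeric(n_neurons)
  if (nrow(firing_log)) {
    first_t <- tapply(firing_log$t, firing_log$neuron, min)
    counts <- tapply(firing_log$t, firing_log$neuron, length)
    ids <- as.integer(names(first_t))
    ord <- order(first_t, ids)          # earliest first, index breaks ties
    w[ids[ord]] <- config$mod^(seq_along(ord) - 1)
    w[ids] <- w[ids] + config$drift * (counts - 1)
  }
  w
}

#' Train a deSNN classifier from per-sample firing logs
#'
#' @param firing_logs List of firing logs (one per training sample).
#' @param labels Class labels, one per sample.
#' @param n_neurons Reservoir size.
#' @param config A [desnn_config()].
#' @param sample_ids Optional sample identifiers.
#' @return An object of class `desnn_classifier` holding one output neuron
#'   (weight vector + label) per training sample.
#' @export
train_desnn <- function(firing_logs, labels, n_neurons,
                        config = desnn_config(),
                        sample_ids = names(firing_logs)) {
  if (length(firing_logs) == 0) {
    stop_snnerp("empty training set", "snnerp_training_error")
  }
  stopifnot(length(labels) == length(firing_logs))
  W <- t(vapply(firing_logs, desnn_weights, numeric(n_neurons),
                n_neurons = n_neurons, config = config))
  structure(list(weights = W, labels = as.character(labels),
                 sample_ids = sample_ids, n_neurons = n_neurons,
                 config = config),
            class = "desnn_classifier")
}

#' Classify a test sample with a trained deSNN
#'
#' The test sample's output neuron is formed by the same rank-order/drift
#' rule, then labelled by the majority class among its k nearest trained
#' output neurons (Euclidean distance). Majority ties are broken by the
#' smaller mean distance within the tied classes, then by class order.
#'
#' @param test Either a firing log (data.frame) or an already-built weight
#'   vector of length `n_neurons`.
#' @param classifier A `desnn_classifier`.
#' @param k Neighbourhood size; defaults to the classifier's configuration.
#' @return List with `label` and `neighbors` (data.frame of the k nearest:
#'   `sample_id`, `label`, `distance`).
#' @export
classify_desnn <- function(test, classifier, k = NULL) {
  stopifnot(inherits(classifier, "desnn_classifier"))
  if (is.null(k)) k <- classifier$config$k_neighbors
  if (k > nrow(classifier$weights)) {
    stop_snnerp("k exceeds the number of trained output neurons",
                "snnerp_config_error")
  }
  w <- if (is.data.frame(test)) {
    desnn_weights(test, classifier$n_neurons, classifier$config)
  } else {
    stopifnot(length(test) == classifier$n_neurons)
    as.numeric(test)
  }
  d <- sqrt(colSums((t(classifier$weights) - w)^2))
  ord <- order(d)[seq_len(k)]
  nb <- data.frame(sample_id = if (is.null(classifier$sample_ids)) ord
                               else classifier$sample_ids[ord],
                   label = classifier$labels[ord], distance = d[ord])
  votes <- table(nb$label)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1) {
    md <- vapply(top, function(cl) mean(nb$distance[nb$label == cl]), 0)
    top <- top[md == min(md)]
    top <- sort(top)[1]  # final tie-break: class order
  }
  list(label = top, neighbors = nb)
}

#' Summarise classification results
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param labels Optional fixed class order.
#' @return List of class `classification_report`: `confusion` (true x
#'   predicted counts), `per_class_accuracy`, `total_accuracy`, `macro_f1`
#'   (all accuracies as fractions in `[0, 1]`).
#' @export
classification_report <- function(truth, pred,
                                  labels = sort(unique(c(truth, pred)))) {
  truth <- factor(truth, levels = labels)
  pred <- factor(pred, levels = labels)
  cm <- table(truth = truth, predicted = pred)
  per_class <- diag(cm) / pmax(rowSums(cm), 1)
  f1 <- vapply(labels, function(cl) {
    tp <- cm[cl, cl]
    prec <- if (sum(cm[, cl]) > 0) tp / sum(cm[, cl]) else 0
    rec <- if (sum(cm[cl, ]) > 0) tp / sum(cm[cl, ]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, 0)
  structure(list(confusion = cm, per_class_accuracy = per_class,
                 total_accuracy = sum(diag(cm)) / sum(cm),
                 macro_f1 = mean(f1)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  print(x$confusion)
  cat(sprintf("total accuracy: %.1f%%  macro F1: %.1f%%\n",
              100 * x$total_accuracy, 100 * x$macro_f1))
  invisible(x)
}

# internal: per-fold deSNN weight vectors under leave-one-out.
# For each fold: fresh reservoir seeded by the held-out sample id, STDP on
# the n-1 training samples in canonical (sorted-id) order, then plasticity-
# off propagation to collect every sample's firing log.
loocv_vectors <- function(samples, labels, grid, encoder, swc, lif, stdp,
                          desnn, base_seed, passes = 1) {
  n <- length(samples)
  ids <- vapply(seq_len(n), function(i) {
    s <- samples[[i]]
    if (!is.null(s$participant_id))
      paste(s$participant_id, s$time_point, s$stimulus, sep = "_")
    else sprintf("sample_%03d", i)
  }, "")
  if (anyDuplicated(ids)) ids <- sprintf("%s#%d", ids, seq_len(n))
  enc <- lapply(samples, encode_sample, config = encoder)
  canon <- order(ids)
  off <- stdp_config(0, 0, stdp$tau_ms, stdp$w_max)
  lapply(seq_len(n), function(i) {
    swc_i <- swc
    swc_i$seed <- seed_for(base_seed, "fold", ids[i])
    res <- build_reservoir(grid, swc = swc_i)
    train_idx <- setdiff(canon, i)
    res <- train_reservoir(res, enc[train_idx], lif, stdp, passes)
    logs <- lapply(enc[train_idx], function(e)
      run_stdp(res, e, lif, off)$firing_log)
    W <- t(vapply(logs, desnn_weights, numeric(nrow(res$coords)),
                  n_neurons = nrow(res$coords), config = desnn))
    w_test <- desnn_weights(run_stdp(res, enc[[i]], lif, off)$firing_log,
                            nrow(res$coords), desnn)
    list(test_id = ids[i], test_index = i, train_index = train_idx,
         train_ids = ids[train_idx], W = W, w_test = w_test,
         n_neurons = nrow(res$coords))
  })
}

#' Leave-one-out cross-validation of the full SNN pipeline
#'
#' For every fold the reservoir is re-initialised from scratch (seeded by
#' the held-out sample's identity, so sample order does not matter), trained
#' with unsupervised STDP on the remaining samples, passed through once more
#' without plasticity to build the deSNN output layer, and evaluated on the
#' held-out sample.
#'
#' @param samples List of `erp_sample` objects (or channel x time matrices).
#' @param labels Class labels, one per sample (>= 2 classes).
#' @param grid Reservoir coordinates (default the packaged 1471-site grid).
#' @param encoder,swc,lif,stdp,desnn Stage configurations.
#' @param base_seed Integer base seed.
#' @param passes STDP passes per sample.
#' @param return_folds If `TRUE`, attach the per-fold output-neuron vectors
#'   (used e.g. for label-permutation controls).
#' @return A `classification_report`; with `return_folds = TRUE`, also
#'   `folds` and `labels` attached as attributes-free list members.
#' @export
run_loocv <- function(samples, labels, grid = load_fixture("grid1471"),
                      encoder = encoder_config(), swc = swc_config(),
                      lif = lif_config(), stdp = stdp_config(),
                      desnn = desnn_config(), base_seed = 1, passes = 1,
                      return_folds = FALSE) {
  n <- length(samples)
  if (n < 2 || length(unique(labels)) < 2) {
    stop_snnerp("need >= 2 samples and >= 2 classes", "snnerp_input_error")
  }
  singles <- names(which(table(labels) == 1))
  if (length(singles)) {
    warning("class(es) with a single sample: ", paste(singles, collapse = ", "))
  }
  labels <- as.character(labels)
  folds <- loocv_vectors(samples, labels, grid, encoder, swc, lif, stdp,
                         desnn, base_seed, passes)
  pred <- vapply(folds, function(f) {
    clf <- structure(list(weights = f$W, labels = labels[f$train_index],
                          sample_ids = f$train_ids, n_neurons = f$n_neurons,
                          config = desnn),
                     class = "desnn_classifier")
    classify_desnn(f$w_test, clf)$label
  }, "")
  truth <- vapply(folds, function(f) labels[f$test_index], "")
  rep <- classification_report(truth, pred, labels = sort(unique(labels)))
  if (return_folds) {
    rep$folds <- folds
    rep$fold_truth <- truth
  }
  rep
}

#' Label-permutation chance control for the deSNN LOOCV pipeline
#'
#' Reuses the per-fold output-neuron vectors of a leave-one-out run (the
#' reservoir and deSNN encodings do not depend on the labels) and evaluates
#' the classifier under shuffled labels. Predictions are scored against the
#' original labels, so for a balanced c-class design the chance level is
#' exactly 1/c; scoring against the shuffled labels themselves
#' (`score_against = "shuffled"`) gives the slightly smaller leave-one-out
#' chance level `(n_c - 1) / (n - 1)` because the held-out sample's own
#' label is removed from the training pool.
#'
#' @param report A `classification_report` from
#'   `run_loocv(..., return_folds = TRUE)`.
#' @param labels The original labels, in sample order.
#' @param n_replicates Number of label shuffles.
#' @param desnn A [desnn_config()] (for `k_neighbors`).
#' @param seed Integer seed for the shuffles.
#' @param score_against `"original"` (default) or `"shuffled"`.
#' @return Numeric vector of per-replicate accuracies (fractions).
#' @export
permutation_chance <- function(report, labels, n_replicates = 100,
                               desnn = desnn_config(), seed = 1,
                               score_against = c("original", "shuffled")) {
  score_against <- match.arg(score_against)
  stopifnot(!is.null(report$folds))
  labels <- as.character(labels)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  vapply(seq_len(n_replicates), function(r) {
    perm <- sample(labels)
    hits <- vapply(report$folds, function(f) {
      clf <- structure(list(weights = f$W, labels = perm[f$train_index],
                            sample_ids = f$train_ids,
                            n_neurons = f$n_neurons, config = desnn),
                       class = "desnn_classifier")
      truth <- if (score_against == "original") labels[f$test_index]
               else perm[f$test_index]
      classify_desnn(f$w_test, clf)$label == truth
    }, TRUE)
    mean(hits)
  }, 0)
}

# minimal-norm least squares one-vs-rest linear regression (argmax labelling)
mlr_fit_predict <- function(X, y, Xtest) {
  classes <- sort(unique(y))
  Y <- outer(y, classes, `==`) * 1
  xm <- colMeans(X)
  ym <- colMeans(Y)
  Xc <- sweep(X, 2, xm)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d) * 1e-10
  # coef in the row space of Xc; predicts Y from centred X
  proj <- sv$v[, pos, drop = FALSE] %*%
    (diag(1 / sv$d[pos], sum(pos)) %*%
       (t(sv$u[, pos, drop = FALSE]) %*% sweep(Y, 2, ym)))
  scores <- sweep(sweep(Xtest, 2, xm) %*% proj, 2, ym, `+`)
  classes[max.col(scores, ties.method = "first")]
}

#' Conventional baseline classifiers under leave-one-out cross-validation
#'
#' Each sample is flattened to one feature vector (losing the explicit
#' spatiotemporal structure the reservoir preserves) and classified with
#' standard implementations: `svm` (RBF kernel, [e1071::svm()] defaults),
#' `mlp` (single hidden layer of 20 units via [nnet::nnet()], fitted on the
#' training fold's principal-component scores when features outnumber
#' samples), and `mlr` (one-vs-rest linear least squares with argmax
#' labelling, minimal-norm solution when features outnumber samples).
#'
#' @param samples List of `erp_sample` objects or numeric matrices/vectors.
#' @param labels Class labels.
#' @param methods Subset of `c("mlp", "svm", "mlr")`.
#' @param seed Integer seed (MLP initialisation).
#' @return Named numeric vector of LOOCV accuracies (fractions).
#' @export
run_baselines <- function(samples, labels, methods = c("mlp", "svm", "mlr"),
                          seed = 1) {
  bad <- setdiff(methods, c("mlp", "svm", "mlr"))
  if (length(bad)) {
    stop_snnerp(paste("unknown method(s):", paste(bad, collapse = ", ")),
                "snnerp_config_error")
  }
  X <- t(vapply(samples, function(s) {
    as.numeric(if (inherits(s, "erp_sample")) s$data else s)
  }, numeric(length(as.numeric(
    if (inherits(samples[[1]], "erp_sample")) samples[[1]]$data
    else samples[[1]])))))
  y <- as.character(labels)
  n <- nrow(X)
  acc <- stats::setNames(numeric(length(methods)), methods)
  for (m in methods) {
    pred <- character(n)
    for (i in seq_len(n)) {
      Xtr <- X[-i, , drop = FALSE]
      ytr <- y[-i]
      Xte <- X[i, , drop = FALSE]
      pred[i] <- switch(m,
        svm = {
          fit <- e1071::svm(Xtr, factor(ytr))
          as.character(stats::predict(fit, Xte))
        },
        mlr = mlr_fit_predict(Xtr, ytr, Xte),
        mlp = {
          if (ncol(Xtr) > nrow(Xtr)) {
            pc <- stats::prcomp(Xtr, center = TRUE, scale. = FALSE)
            keep <- which(pc$sdev > pc$sdev[1] * 1e-8)
            Ztr <- pc$x[, keep, drop = FALSE]
            Zte <- stats::predict(pc, Xte)[, keep, drop = FALSE]
          } else {
            Ztr <- Xtr; Zte <- Xte
          }
          old <- if (exists(".Random.seed", globalenv()))
            get(".Random.seed", globalenv())
          set.seed(seed_for(seed, "mlp", i))
          fit <- nnet::nnet(Ztr, class.ind_local(ytr), size = 20,
                            decay = 0.01, maxit = 200, trace = FALSE,
                            MaxNWts = 1e5, softmax = TRUE)
          if (!is.null(old)) assign(".Random.seed", old, globalenv())
          colnames(fit$fitted.values)[
            max.col(stats::predict(fit, Zte), ties.method = "first")]
        })
    }
    acc[m] <- mean(pred == y)
  }
  acc
}

# one-hot indicator matrix (avoids depending on nnet::class.ind's export)
class.ind_local <- function(y) {
  classes <- sort(unique(y))
  out <- outer(y, classes, `==`) * 1
  colnames(out) <- classes
  out
}
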