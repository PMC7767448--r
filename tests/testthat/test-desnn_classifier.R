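test_that("rank-order initial weights follow mod^order of first firing", {
  # first-firing order: neuron 3, then 1, then 2; neuron 4 never fires
  log <- data.frame(neuron = c(3L, 1L, 2L), t = c(1L, 2L, 3L),
                    polarity = 1L)
  w <- desnn_weights(log, 4, desnn_config(mod = 0.9, drift = 0))
  expect_equal(w, c(0.9, 0.81, 1, 0))
  # later firings add drift
  log2 <- rbind(log, data.frame(neuron = c(3L, 3L), t = c(5L, 9L),
                                polarity = 1L))
  w2 <- desnn_weights(log2, 4, desnn_config(mod = 0.9, drift = 0.25))
  expect_equal(w2, c(0.9, 0.81, 1 + 2 * 0.25, 0))
  # mod = 1 with no drift is a fired/never-fired indicator
  expect_equal(desnn_weights(log, 4, desnn_config(mod = 1, drift = 0)),
               c(1, 1, 1, 0))
  # ordering property: weights non-increasing in first-firing order (3,1,2)
  expect_true(all(diff(w[c(3, 1, 2)]) <= 0))
})

test_that("an empty firing log yields an all-zero output neuron", {
  log <- data.frame(neuron = integer(0), t = integer(0), polarity = integer(0))
  expect_equal(desnn_weights(log, 5), numeric(5))
  clf <- train_desnn(list(a = log), labels = "X", n_neurons = 5)
  expect_equal(unname(clf$weights[1, ]), numeric(5))
  expect_equal(clf$labels, "X")
})

test_that("one output neuron is generated per training sample", {
  logs <- lapply(1:12, function(i)
    data.frame(neuron = sample(5, 3), t = sample(10, 3), polarity = 1L))
  clf <- train_desnn(logs, labels = rep(c("A", "B", "C"), 4), n_neurons = 5)
  expect_equal(nrow(clf$weights), 12)
  expect_error(train_desnn(list(), labels = character(0), n_neurons = 5),
               class = "snnerp_training_error")
})

test_that("kNN labelling, unanimity and tie-breaking", {
  clf <- structure(list(weights = rbind(c(1, 0), c(0, 1)),
                        labels = c("A", "B"), sample_ids = c("s1", "s2"),
                        n_neurons = 2, config = desnn_config()),
                   class = "desnn_classifier")
  expect_equal(classify_desnn(c(0.9, 0.1), clf, k = 1)$label, "A")
  # unanimity
  clf2 <- clf; clf2$labels <- c("Z", "Z")
  expect_equal(classify_desnn(c(5, -3), clf2, k = 2)$label, "Z")
  # k = 2 vote tie resolved by the smaller mean distance
  clf3 <- structure(list(weights = rbind(c(1, 0), c(2.5, 0)),
                         labels = c("A", "B"), sample_ids = c("s1", "s2"),
                         n_neurons = 2, config = desnn_config()),
                    class = "desnn_classifier")
  expect_equal(classify_desnn(c(0, 0), clf3, k = 2)$label, "A")
  expect_equal(classify_desnn(c(4, 0), clf3, k = 2)$label, "B")
  # equal mean distances fall back to class order
  clf4 <- structure(list(weights = rbind(c(1, 0), c(-1, 0)),
                         labels = c("B", "A"), sample_ids = c("s1", "s2"),
                         n_neurons = 2, config = desnn_config()),
                    class = "desnn_classifier")
  expect_equal(classify_desnn(c(0, 0), clf4, k = 2)$label, "A")
  expect_error(classify_desnn(c(0, 0), clf, k = 3),
               class = "snnerp_config_error")
})

test_that("classification report arithmetic is internally consistent", {
  set.seed(5)
  truth <- sample(c("A", "B", "C"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.6, truth, sample(c("A", "B", "C"), 60, TRUE))
  rep <- classification_report(truth, pred)
  expect_equal(sum(rep$confusion), 60)
  expect_equal(as.numeric(rowSums(rep$confusion)),
               as.numeric(table(factor(truth, levels = c("A", "B", "C")))))
  expect_equal(rep$total_accuracy, mean(truth == pred))
  for (cl in c("A", "B", "C")) {
    expect_equal(unname(rep$per_class_accuracy[cl]),
                 rep$confusion[cl, cl] / sum(rep$confusion[cl, ]))
  }
  # brute-force macro F1 from the confusion matrix
  cm <- rep$confusion
  f1 <- sapply(c("A", "B", "C"), function(cl) {
    p <- cm[cl, cl] / sum(cm[, cl])
    r <- cm[cl, cl] / sum(cm[cl, ])
    if (is.nan(p) || p + r == 0) 0 else 2 * p * r / (p + r)
  })
  expect_equal(rep$macro_f1, mean(f1))
})

make_topo_toy <- function(per_class = 3) {
  coh <- generate_cohort(cohort_spec(n_per_group = 1, time_points = "T1",
                                     stimuli = "target", noise_sd_uv = 0,
                                     latent_gain_sd = 0,
                                     frontal_gain_delta = 0, epoch_len = 400,
                                     seed = 1))
  base <- coh$samples[[1]]
  reg <- load_fixture("regions_fig5")
  bands <- list(reg$channel[!is.na(reg$site) & reg$site == "frontal"],
                reg$channel[!is.na(reg$site) & reg$site == "centroparietal"],
                reg$channel[!is.na(reg$site) & reg$site == "temporal"])
  samples <- list(); labels <- character(0)
  for (k in 1:3) for (j in seq_len(per_class)) {
    s <- base
    s$data[bands[[k]], ] <- s$data[bands[[k]], ] * 3
    s$participant_id <- sprintf("c%d_%d", k, j)
    samples[[length(samples) + 1]] <- s
    labels <- c(labels, paste0("C", k))
  }
  list(samples = samples, labels = labels)
}

test_that("LOOCV is perfect on duplicated, separable zero-noise classes", {
  toy <- make_topo_toy(3)
  rep <- run_loocv(toy$samples, toy$labels, grid = subsample_grid(80),
                   base_seed = 3)
  expect_equal(sum(rep$confusion), 9)
  expect_equal(rep$total_accuracy, 1)
  expect_equal(rep$macro_f1, 1)
})

test_that("shuffling sample order does not change LOOCV results", {
  toy <- make_topo_toy(2)
  r1 <- run_loocv(toy$samples, toy$labels, grid = subsample_grid(80),
                  base_seed = 7)
  set.seed(1)
  perm <- sample(length(toy$samples))
  r2 <- run_loocv(toy$samples[perm], toy$labels[perm],
                  grid = subsample_grid(80), base_seed = 7)
  expect_equal(r1$confusion, r2$confusion)
})

test_that("LOOCV input validation and single-sample class warning", {
  toy <- make_topo_toy(2)
  expect_error(run_loocv(toy$samples[1], toy$labels[1]),
               class = "snnerp_input_error")
  expect_warning(
    run_loocv(c(toy$samples[c(1, 2, 3)]), c("A", "A", "B"),
              grid = subsample_grid(80), base_seed = 1),
    "single sample")
})

test_that("baselines separate Gaussian blobs and respect the interface", {
  set.seed(9)
  n <- 8
  samples <- c(lapply(1:n, function(i) rnorm(5, 0, 1)),
               lapply(1:n, function(i) rnorm(5, 10, 1)))
  labels <- rep(c("lo", "hi"), each = n)
  acc <- run_baselines(samples, labels, methods = c("svm", "mlr"), seed = 2)
  expect_equal(unname(acc["svm"]), 1)
  expect_equal(unname(acc["mlr"]), 1)
  one <- run_baselines(samples, labels, methods = "svm")
  expect_length(one, 1)
  expect_named(one, "svm")
  expect_error(run_baselines(samples, labels, methods = "forest"),
               class = "snnerp_config_error")
})

test_that("the mlp baseline handles more features than samples", {
  set.seed(10)
  n <- 6
  samples <- c(lapply(1:n, function(i) rnorm(50, 0, 1)),
               lapply(1:n, function(i) rnorm(50, 8, 1)))
  labels <- rep(c("lo", "hi"), each = n)
  acc <- run_baselines(samples, labels, methods = "mlp", seed = 3)
  expect_gte(unname(acc["mlp"]), 0.9)
})

test_that("label permutation drives accuracy to chance", {
  toy <- make_topo_toy(3)
  rep <- run_loocv(toy$samples, toy$labels, grid = subsample_grid(80),
                   base_seed = 11, return_folds = TRUE)
  acc <- permutation_chance(rep, toy$labels, n_replicates = 60, seed = 4)
  # scored against the original labels: expectation exactly 1/3
  expect_lt(abs(mean(acc) - 1 / 3), 0.1)
  # scored against the shuffled labels: expectation (n_c - 1)/(n - 1) = 1/4
  acc2 <- permutation_chance(rep, toy$labels, n_replicates = 60, seed = 4,
                             score_against = "shuffled")
  expect_lt(abs(mean(acc2) - 2 / 8), 0.12)
})
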