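# long-format random table for a balanced design
make_long <- function(n_per_group = 10, sites = 5, stims = 2, times = 1,
                      seed = 1) {
  set.seed(seed)
  g <- expand.grid(participant_id = sprintf("p%02d", 1:(2 * n_per_group)),
                   site = paste0("s", seq_len(sites)),
                   stimulus = c("target", "distractor")[seq_len(stims)],
                   time = paste0("T", seq_len(times)),
                   stringsAsFactors = FALSE)
  g$group <- ifelse(as.integer(sub("p", "", g$participant_id)) <= n_per_group,
                    "experimental", "waitlist")
  g$w <- rnorm(nrow(g))
  g
}

test_that("design-matched dfs: Site x Stimuli (4, 72) and Time x Group (1, 18)", {
  long <- make_long(n_per_group = 10, sites = 5, stims = 2)
  res <- rm_anova_gg(long, dv = "w", id = "participant_id",
                     within = c("site", "stimulus"), between = "group")
  row <- res[res$effect == "site:stimulus", ]
  expect_equal(row$df_num, 4)
  expect_equal(row$df_den, 72)
  long2 <- make_long(n_per_group = 10, sites = 1, stims = 1, times = 2)
  res2 <- rm_anova_gg(long2, dv = "w", id = "participant_id",
                      within = "time", between = "group")
  row2 <- res2[res2$effect == "group:time", ]
  expect_equal(row2$df_num, 1)
  expect_equal(row2$df_den, 18)
})

test_that("two-level within factors have epsilon 1 and unchanged dfs", {
  long <- make_long(n_per_group = 8, sites = 1, stims = 2, seed = 3)
  res <- rm_anova_gg(long, dv = "w", id = "participant_id",
                     within = "stimulus", between = "group")
  row <- res[res$effect == "stimulus", ]
  expect_equal(row$gg_epsilon, 1)
  expect_equal(row$df_num_gg, row$df_num)
  expect_equal(row$df_den_gg, row$df_den)
  expect_equal(row$p_gg, row$p)
})

test_that("a one-way repeated-measures toy matches hand sums of squares", {
  set.seed(7)
  n <- 6; k <- 3
  Y <- matrix(rnorm(n * k, mean = rep(c(0, 0.5, 1), each = n)), n, k)
  long <- data.frame(participant_id = rep(sprintf("p%d", 1:n), k),
                     cond = rep(paste0("c", 1:k), each = n),
                     w = as.numeric(Y))
  res <- rm_anova_gg(long, dv = "w", id = "participant_id", within = "cond")
  row <- res[res$effect == "cond", ]
  # brute-force univariate RM sums of squares
  grand <- mean(Y)
  ss_cond <- n * sum((colMeans(Y) - grand)^2)
  ss_subj <- k * sum((rowMeans(Y) - grand)^2)
  ss_tot <- sum((Y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  F_hand <- (ss_cond / (k - 1)) / (ss_err / ((n - 1) * (k - 1)))
  expect_equal(row$F, F_hand, tolerance = 1e-10)
  expect_equal(row$df_num, k - 1)
  expect_equal(row$df_den, (n - 1) * (k - 1))
  expect_equal(row$p, stats::pf(F_hand, k - 1, (n - 1) * (k - 1),
                                lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(row$partial_eta2, ss_cond / (ss_cond + ss_err),
               tolerance = 1e-10)
  # Greenhouse-Geisser epsilon from the double-centred covariance matrix
  S <- stats::cov(Y)
  Sc <- sweep(sweep(S, 1, rowMeans(S)), 2, colMeans(S)) + mean(S)
  eps_hand <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
  expect_equal(row$gg_epsilon, eps_hand, tolerance = 1e-10)
  expect_gte(row$gg_epsilon, 1 / (k - 1))
  expect_equal(row$p_gg,
               stats::pf(F_hand, eps_hand * (k - 1),
                         eps_hand * (n - 1) * (k - 1), lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("GG correction is conservative for F >= 1 and epsilon is bounded", {
  long <- make_long(n_per_group = 6, sites = 4, stims = 2, seed = 9)
  # add real site structure so the effects of interest have F >= 1
  long$w <- long$w + 2 * as.integer(factor(long$site)) +
    as.integer(factor(long$site)) * (long$stimulus == "target")
  res <- rm_anova_gg(long, dv = "w", id = "participant_id",
                     within = c("site", "stimulus"), between = "group")
  multi <- res[res$df_num > 1 & !is.na(res$gg_epsilon) & res$F >= 1, ]
  expect_gt(nrow(multi), 0)
  # reducing both dfs by epsilon can only raise p when F >= 1
  expect_true(all(multi$p_gg >= multi$p - 1e-12))
  expect_true(all(multi$gg_epsilon <= 1 + 1e-12))
  expect_true(all(multi$gg_epsilon >= 1 / multi$df_num - 1e-12))
  expect_true(all(res$partial_eta2 >= 0 & res$partial_eta2 <= 1))
})

test_that("incomplete designs are rejected with the offending cell named", {
  long <- make_long(n_per_group = 4, sites = 3)
  long <- long[-1, ]
  err <- tryCatch(rm_anova_gg(long, dv = "w", id = "participant_id",
                              within = c("site", "stimulus"),
                              between = "group"),
                  error = identity)
  expect_s3_class(err, "snnerp_design_error")
  expect_match(conditionMessage(err), "p01")
})

test_that("Kendall tau matches exhaustive pair enumeration", {
  w <- data.frame(participant_id = sprintf("p%d", 1:3), rf = c(1, 2, 3))
  psy <- data.frame(participant_id = sprintf("p%d", 1:3),
                    FFMQ = c(3, 1, 2))
  res <- kendall_tau_matrix(w, psy, weight_vars = "rf",
                            psych_vars = "FFMQ")
  expect_equal(res$tau, -1 / 3, tolerance = 1e-12)
  # perfect concordance under a strictly monotone transform
  psy2 <- data.frame(participant_id = sprintf("p%d", 1:10), FFMQ = exp(1:10))
  w2 <- data.frame(participant_id = sprintf("p%d", 1:10), rf = (1:10)^2)
  res2 <- kendall_tau_matrix(w2, psy2, weight_vars = "rf",
                             psych_vars = "FFMQ")
  expect_equal(res2$tau, 1)
})

test_that("Kendall tau is symmetric and flags constant variables", {
  set.seed(4)
  x <- rnorm(15); y <- rnorm(15)
  a <- data.frame(id = 1:15, v = x)
  b <- data.frame(id = 1:15, s = y)
  r1 <- kendall_tau_matrix(a, b, weight_vars = "v", psych_vars = "s")
  r2 <- kendall_tau_matrix(b, a, weight_vars = "s", psych_vars = "v")
  expect_equal(r1$tau, r2$tau, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  const <- data.frame(id = 1:15, s = rep(2, 15))
  r3 <- kendall_tau_matrix(a, const, weight_vars = "v", psych_vars = "s")
  expect_true(r3$undefined)
  expect_true(is.na(r3$tau))
  expect_error(kendall_tau_matrix(a[1:2, ], b[1:2, ], weight_vars = "v",
                                  psych_vars = "s"),
               class = "snnerp_input_error")
  # optional Benjamini-Hochberg column
  r4 <- kendall_tau_matrix(a, b, weight_vars = "v", psych_vars = "s",
                           p_adjust = "BH")
  expect_true("p_adj" %in% names(r4))
})
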