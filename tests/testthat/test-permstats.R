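test_that("repeated-measures F matches the aov() oracle on balanced tables", {
  set.seed(71)
  df <- expand.grid(participant_id = paste0("s", 1:6),
                    A = c("a1", "a2"), B = c("b1", "b2", "b3"),
                    stringsAsFactors = FALSE)
  df$value <- rnorm(nrow(df)) + ifelse(df$A == "a2", 0.8, 0)
  res <- perm_rm_anova(df, "value", c("A", "B"), n_perm = 50, seed = 1)
  fit <- summary(stats::aov(value ~ A * B + Error(participant_id / (A * B)),
                            data = df))
  f_oracle <- c(
    A = fit[["Error: participant_id:A"]][[1]]["A", "F value"],
    B = fit[["Error: participant_id:B"]][[1]]["B", "F value"],
    `A:B` = fit[["Error: participant_id:A:B"]][[1]]["A:B", "F value"]
  )
  expect_equal(res$statistic, unname(f_oracle[res$effect]), tolerance = 1e-8)
  expect_equal(res$df1, c(1L, 2L, 2L))
  expect_equal(res$df2, c(5L, 10L, 10L))
})

test_that("a huge main effect hits the permutation floor", {
  df <- expand.grid(participant_id = paste0("s", 1:6),
                    A = c("a1", "a2", "a3"), stringsAsFactors = FALSE)
  set.seed(72)
  df$value <- rnorm(nrow(df), sd = 0.1) +
    c(a1 = 0, a2 = 50, a3 = 100)[df$A]
  res <- perm_rm_anova(df, "value", "A", n_perm = 200, seed = 2)
  expect_equal(res$p[res$effect == "A"], 1 / 200)
  expect_error(perm_rm_anova(df[-1, ], "value", "A"), "balanced")
})

test_that("paired permutation t-test behaves at its fixed points", {
  df <- expand.grid(participant_id = paste0("s", 1:7), run_id = 1:6,
                    condition = c("a", "b"), stringsAsFactors = FALSE)
  set.seed(73)
  df$value <- rnorm(nrow(df))
  # identical conditions: t = 0, p near 1
  df_eq <- df
  df_eq$value <- rep(df$value[df$condition == "a"], 2)
  tt <- perm_paired_ttest(df_eq, "value", "condition", "run_id",
                          n_perm = 200, seed = 3)
  expect_equal(tt$statistic, 0, tolerance = 1e-12)
  expect_gt(tt$p, 0.5)
  # a constant offset hits the floor (two-tailed: 2/n_perm)
  df_off <- df
  df_off$value <- df_off$value + ifelse(df_off$condition == "b", 10, 0)
  tt2 <- perm_paired_ttest(df_off, "value", "condition", "run_id",
                           n_perm = 200, seed = 4)
  expect_equal(tt2$p, 2 / 200)
  expect_error(
    perm_paired_ttest(df[df$condition == "a", ], "value", "condition",
                      "run_id"),
    "two levels")
})

test_that("shuffled-training-label nulls are centered and separable", {
  datasets <- lapply(1:4, function(i) {
    w <- small_world(seed = 80 + i, n_runs = 3, noise_sd = 0.8,
                     distractor_gain = 0)
    list(ts_train = w$ts_train, angles_train = w$train$target_angle,
         ts_test = w$ts_test, trials_test = w$design)
  })
  res <- shuffled_label_fidelity_null(datasets, n_perm = 40, seed = 5)
  null <- attr(res, "null")
  delay <- which(res$time >= 5.25 & res$time < 12)
  # null fidelity-t distribution centered at zero (within 3 SE)
  mu <- mean(null[, delay])
  se <- stats::sd(null[, delay]) / sqrt(length(null[, delay]))
  expect_lt(abs(mu), 3 * se + 0.2)
  # intact labels beat every shuffle during the delay
  expect_true(all(res$p[delay] == 1 / 40))
  # smoke-mode floor
  expect_true(all(res$p >= 1 / 40))
})

test_that("FDR step-up matches hand-computed adjustments", {
  out <- fdr_correct(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$p_adj, rep(0.04, 4))
  expect_equal(fdr_correct(0.03)$p_adj, 0.03)     # single p unchanged
  expect_equal(fdr_correct(rep(0.2, 5))$p_adj, rep(0.2, 5))
  expect_true(all(diff(fdr_correct(sort(runif(10)))$p_adj) >= 0))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})
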