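test_that("additive null draws are constituent-replicate means", {
  # degenerate: all constituents constant -> every draw equals the constant
  degen <- build_null(list(a = rep(0.2, 4), b = rep(0.2, 3)),
                      n_permutations = 500, seed = 1)
  expect_true(all(degen$draws == 0.2))
  expect_equal(permutation_pvalue(0.2, degen), 1)

  # two constituents with replicate AIs {-1, +1}: draws in {-1, 0, +1}
  # with long-run frequencies 1/4, 1/2, 1/4
  null <- build_null(list(a = c(-1, 1), b = c(-1, 1)),
                     n_permutations = 10000, seed = 2)
  expect_true(all(null$draws %in% c(-1, 0, 1)))
  freq <- table(factor(null$draws, levels = c(-1, 0, 1))) / 10000
  se <- sqrt(c(0.25, 0.5, 0.25) * c(0.75, 0.5, 0.75) / 10000)
  expect_true(all(abs(freq - c(0.25, 0.5, 0.25)) < 3 * se))

  # draws never leave the envelope of the constituent replicate AIs
  set.seed(5)
  ais <- list(x = runif(5, -1, 1), y = runif(3, -1, 1), z = runif(6, -1, 1))
  nl <- build_null(ais, 2000, seed = 3)
  expect_gte(min(nl$draws), min(vapply(ais, min, 1)))
  expect_lte(max(nl$draws), max(vapply(ais, max, 1)))
})

test_that("null construction is deterministic and order-invariant", {
  ais <- list(a = c(0.1, 0.3, 0.5), b = c(-0.2, 0.4), c = c(0, 0.2, 0.6))
  n1 <- build_null(ais, 1000, seed = 42)
  n2 <- build_null(ais, 1000, seed = 42)
  expect_identical(n1$draws, n2$draws)
  n3 <- build_null(ais[c("c", "a", "b")], 1000, seed = 42)
  expect_identical(n1$draws, n3$draws)
})

test_that("unknown or empty constituents are named in errors", {
  expect_error(build_null(list(a = c(0.1, 0.2), ghost = numeric())),
               "ghost")
  expect_error(build_null(list(c(0.1))), "named list")
})

test_that("permutation p matches exhaustive enumeration on small designs", {
  # worked case: two {-1,+1} constituents, observed +1 -> exact p = 0.5
  ais <- list(a = c(-1, 1), b = c(-1, 1))
  expect_equal(enum_additive_p(ais, 1), 0.5)
  null <- build_null(ais, 10000, seed = 7)
  p_hat <- permutation_pvalue(1, null)
  expect_lt(abs(p_hat - 0.5), 3 * 2 * sqrt(0.25 * 0.75 / 10000) + 2e-4)

  # random small designs: <= 3 constituents x <= 4 replicates
  set.seed(17)
  for (i in 1:8) {
    k <- sample(1:3, 1)
    ais <- lapply(seq_len(k), function(j)
      round(runif(sample(1:4, 1), -1, 1), 2))
    names(ais) <- paste0("c", seq_len(k))
    obs <- round(runif(1, -1, 1), 2)
    exact <- enum_additive_p(ais, obs)
    est <- permutation_pvalue(obs, build_null(ais, 10000, seed = i))
    tail_se <- sqrt(max(exact / 2 * (1 - exact / 2), 0.25 / 10000) / 10000)
    expect_lt(abs(est - exact), 3 * 2 * tail_se + 2e-4)
  }
  # add-one correction: p never exactly zero
  far <- build_null(list(a = c(0.1, 0.2)), 100, seed = 1)
  expect_gt(permutation_pvalue(-1, far), 0)
})

test_that("linear-model contrast matches closed-form least squares", {
  # blend exactly at the constituent average with zero noise
  exact <- lm_interaction_test(list(a = c(0.2, 0.2), b = c(0.4, 0.4)),
                               c(0.3, 0.3))
  expect_equal(exact$t, 0)
  expect_equal(exact$p_value, 1)

  # tiny design against hand-computed normal equations: cell-means fit,
  # contrast = blend mean - average of constituent means,
  # SE^2 = s2 * (1/n_blend + sum(w^2/n_i))
  cons <- list(a = c(0.1, 0.3), b = c(0.2, 0.6))
  blend <- c(0.15, 0.45)
  r <- lm_interaction_test(cons, blend)
  est_hand <- mean(blend) - mean(c(mean(cons$a), mean(cons$b)))
  s2 <- (var(cons$a) + var(cons$b) + var(blend)) * 1 / 3
  se_hand <- sqrt(s2 * (1 / 2 + (0.25 / 2 + 0.25 / 2)))
  expect_equal(r$estimate, est_hand)
  expect_equal(r$se, se_hand)
  expect_equal(r$df, 3)
  expect_equal(r$p_value, 2 * pt(-abs(est_hand / se_hand), 3))

  # weights shift the contrast target
  rw <- lm_interaction_test(cons, blend, weights = c(1, 3))
  expect_equal(rw$estimate,
               mean(blend) - (0.25 * mean(cons$a) + 0.75 * mean(cons$b)))

  expect_error(lm_interaction_test(list(a = 0.1, b = c(0.2, 0.3)),
                                   c(0.1, 0.2)), ">= 2 replicates")
})

test_that("blend-vs-single t-test follows the pooled-variance formula", {
  same <- blend_vs_single_ttest(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  sep <- blend_vs_single_ttest(c(1, 1, 1, 1.0001), c(0, 0, 0, 0.0001))
  expect_gt(abs(sep$t), 50)
  expect_lt(sep$p_value, 1e-6)

  x <- c(0.1, 0.3, 0.5); y <- c(0.2, 0.4, 0.6)
  r <- blend_vs_single_ttest(x, y)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  expect_equal(r$t, t_hand)
  expect_equal(r$p_value, 2 * pt(-abs(t_hand), 4))

  expect_error(blend_vs_single_ttest(c(1, 1), c(0, 0)),
               "zero pooled variance")
})

test_that("permutation p is approximately uniform when observed and null share a law", {
  # a single-constituent "blend" with one replicate is one more draw from
  # the null's own law; with enough constituent replicates to pin down
  # that law, its two-sided p is near-uniform (with few replicates the
  # granular empirical null distorts the tails; see the methods vignette)
  set.seed(23)
  n_sim <- 600
  p <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    reps <- simulate_tmaze(c(y = 0.2), n_replicates = 101, retention = 0.5,
                           seed = NULL)
    ai <- compute_ai(reps$n_treatment_arm, reps$n_control_arm)
    null <- build_null(list(y = ai[1:100]), 2000, seed = NULL)
    p[i] <- permutation_pvalue(ai[101], null)
  }
  expect_lt(abs(mean(p) - 0.5), 3 * sqrt(1 / 12 / n_sim) + 0.02)
  rej <- mean(p < 0.05)
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim) + 0.02)
})

test_that("permutation-test power grows with the interaction offset", {
  set.seed(29)
  rej_rate <- function(delta, n_sim = 150) {
    rej <- logical(n_sim)
    for (i in seq_len(n_sim)) {
      sim <- simulate_blend_study(
        c(a = 0.3, b = 0.3), list(ab = c("a", "b")), delta = delta,
        n_replicates = 6, retention = 0.69, n_flies = 70, seed = NULL)
      ai_s <- ai_table(sim$singles)
      ai_b <- ai_table(sim$blends)
      res <- additivity_test(
        split(ai_s$ai, ai_s$treatment_id), ai_b$ai,
        n_permutations = 2000, seed = NULL)
      rej[i] <- res$p_permutation < 0.05
    }
    mean(rej)
  }
  r0 <- rej_rate(0)
  r2 <- rej_rate(-0.2)
  r4 <- rej_rate(-0.4)
  expect_lte(r0, r2 + 0.05)
  expect_lte(r2, r4 + 0.05)
  expect_gt(r4, r0)
})

test_that("additivity_test assembles both routes and calls direction", {
  set.seed(37)
  cons <- list(a = c(0.30, 0.35, 0.25), b = c(0.20, 0.25, 0.30))
  res <- additivity_test(cons, c(-0.5, -0.45, -0.55), seed = 5,
                         n_permutations = 4000)
  expect_identical(res$direction, "below_additive")
  expect_lt(res$p_permutation, 0.05)
  expect_lt(res$p_linear_model, 0.05)
  expect_equal(res$predicted_mean_ai, 0.275, tolerance = 0.02)

  mid <- additivity_test(cons, c(0.27, 0.28), seed = 5)
  expect_identical(mid$direction, "consistent")
})
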