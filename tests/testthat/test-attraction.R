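test_that("AI follows the arm-count formula and its bounds", {
  expect_equal(compute_ai(34, 16), 0.36)
  expect_equal(compute_ai(10, 10), 0)
  expect_equal(compute_ai(0, 20), -1)
  expect_equal(compute_ai(20, 0), 1)
  expect_error(compute_ai(0, 0), "no fly made a choice")
})

test_that("relabelling arms negates AI and preserves binomial p", {
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:120, 1)
    k <- sample(0:n, 1)
    expect_equal(compute_ai(k, n - k), -compute_ai(n - k, k))
    a <- binomial_choice_test(k, n)
    b <- binomial_choice_test(n - k, n)
    expect_equal(a$p_value, b$p_value)
    expect_true(abs(compute_ai(k, n - k)) <= 1)
  }
})

test_that("treatment summaries give unweighted mean, SE and pooled counts", {
  three <- make_reps(rep(30, 3), rep(10, 3), 20)
  s <- summarize_treatment(three)
  expect_equal(s$mean_ai, 0.5)
  expect_equal(s$se_ai, 0)
  expect_equal(s$pooled_k, 90)
  expect_equal(s$pooled_n, 120)

  # AIs 0.2 and 0.4: mean 0.3, se = sd/sqrt(2) = 0.1
  two <- make_reps(c(30, 35), c(20, 15))
  s2 <- summarize_treatment(two)
  expect_equal(s2$mean_ai, 0.3)
  expect_equal(s2$se_ai, 0.1)

  # pooling is by counts, not by averaging proportions
  pool <- make_reps(c(3, 1), c(1, 3))
  s3 <- summarize_treatment(pool)
  expect_equal(s3$pooled_k, 4)
  expect_equal(s3$pooled_n, 8)
  expect_equal(s3$mean_ai, 0)

  one <- make_reps(5, 3)
  expect_true(is.na(summarize_treatment(one)$se_ai))
  expect_error(summarize_treatment(make_reps(integer(), integer())),
               "empty")
  mixed <- rbind(make_reps(5, 3, treatment = "a"),
                 make_reps(5, 3, treatment = "b"))
  expect_error(summarize_treatment(mixed), "share one treatment")
})

test_that("exact binomial choice test matches the minimum-likelihood oracle", {
  centre <- binomial_choice_test(25, 50)
  expect_equal(centre$p_value, 1)
  expect_identical(centre$direction, "none")

  rep10 <- binomial_choice_test(0, 10)
  expect_equal(rep10$p_value, 2 * 0.5^10)
  expect_identical(rep10$direction, "repulsion")

  expect_equal(binomial_choice_test(60, 100)$p_value, enum_binom_p(60, 100))

  set.seed(3)
  for (i in 1:40) {
    n <- sample(1:200, 1)
    k <- sample(0:n, 1)
    expect_equal(binomial_choice_test(k, n)$p_value, enum_binom_p(k, n),
                 tolerance = 1e-10)
  }
  # one-sided tails are plain binomial tails
  expect_equal(binomial_choice_test(8, 10, "greater")$p_value,
               pbinom(7, 10, 0.5, lower.tail = FALSE))
})

test_that("treatment deviance test matches the analytic log-likelihood gap", {
  # identical pooled proportions in both treatments: no treatment signal
  same <- rbind(make_reps(c(26, 24), c(24, 26), treatment = "a"),
                make_reps(c(25, 25), c(25, 25), treatment = "b"))
  r <- treatment_effect_test(same)
  expect_equal(r$delta_deviance, 0, tolerance = 1e-8)
  expect_equal(r$p_value, 1, tolerance = 1e-6)

  # tiny two-treatment set against the closed-form likelihood-ratio
  tiny <- rbind(make_reps(c(8, 6), c(2, 4), treatment = "a"),
                make_reps(c(3, 2), c(7, 8), treatment = "b"))
  d <- ai_table(tiny)
  p_grp <- ave(d$n_treatment_arm, d$treatment_id, FUN = sum) /
    ave(d$n_choosing, d$treatment_id, FUN = sum)
  p_all <- sum(d$n_treatment_arm) / sum(d$n_choosing)
  oracle <- 2 * (binom_loglik(d$n_treatment_arm, d$n_choosing, p_grp) -
                 binom_loglik(d$n_treatment_arm, d$n_choosing, p_all))
  r2 <- treatment_effect_test(tiny)
  expect_equal(r2$delta_deviance, oracle, tolerance = 1e-8)
  expect_identical(r2$delta_df, 1L)
  expect_equal(r2$p_value, pchisq(oracle, 1, lower.tail = FALSE))

  # invariant to replicate order and treatment relabelling
  shuffled <- tiny[sample(nrow(tiny)), ]
  relab <- tiny
  relab$treatment_id <- c(a = "zzz", b = "aaa")[relab$treatment_id]
  expect_equal(treatment_effect_test(shuffled)$delta_deviance,
               r2$delta_deviance)
  expect_equal(treatment_effect_test(relab)$delta_deviance,
               r2$delta_deviance)

  expect_warning(
    treatment_effect_test(rbind(make_reps(c(5, 5), c(0, 0), treatment = "a"),
                                make_reps(c(2, 3), c(3, 2), treatment = "b"))),
    "separation")
})

test_that("two-way ANOVA on AI decomposes a balanced toy design correctly", {
  # constant response: no variance anywhere
  const <- rbind(
    make_reps(c(6, 6), c(2, 2), treatment = "a", species = "s1"),
    make_reps(c(6, 6), c(2, 2), treatment = "b", species = "s1"),
    make_reps(c(6, 6), c(2, 2), treatment = "a", species = "s2"),
    make_reps(c(6, 6), c(2, 2), treatment = "b", species = "s2"))
  tab <- species_by_yeast_anova(const)
  expect_equal(tab$F, rep(0, 3))
  expect_equal(tab$p, rep(1, 3))

  # balanced 2x2 with noise: type-II F equals the direct SS decomposition
  set.seed(21)
  n_choose <- 50
  cells <- expand.grid(sp = c("s1", "s2"), tr = c("a", "b"),
                       rep = 1:5, stringsAsFactors = FALSE)
  p_cell <- with(cells, 0.5 + 0.1 * (sp == "s2") + 0.15 * (tr == "b"))
  k <- rbinom(nrow(cells), n_choose, p_cell)
  toy <- make_reps(k, n_choose - k)
  toy$fly_species <- cells$sp
  toy$treatment_id <- cells$tr
  toy$replicate_id <- sprintf("r%02d", seq_len(nrow(toy)))
  tab2 <- species_by_yeast_anova(toy)

  d <- ai_table(toy)
  g <- aggregate(ai ~ fly_species + treatment_id, d, mean)
  grand <- mean(d$ai)
  sp_m <- tapply(d$ai, d$fly_species, mean)
  tr_m <- tapply(d$ai, d$treatment_id, mean)
  ss_sp <- 10 * sum((sp_m - grand)^2)
  ss_tr <- 10 * sum((tr_m - grand)^2)
  cell_m <- tapply(d$ai, list(d$fly_species, d$treatment_id), mean)
  ss_int <- 5 * sum((cell_m - outer(sp_m - grand, tr_m - grand, `+`) -
                     grand)^2)
  ss_res <- sum((d$ai - cell_m[cbind(d$fly_species, d$treatment_id)])^2)
  ms_res <- ss_res / 16
  expect_equal(tab2$F, c(ss_sp, ss_tr, ss_int) / ms_res, tolerance = 1e-8)
  expect_equal(tab2$df_num, c(1, 1, 1))
  expect_equal(tab2$df_den, rep(16, 3))

  # empty design cell is named in the error
  holes <- toy[!(toy$fly_species == "s2" & toy$treatment_id == "b"), ]
  expect_error(species_by_yeast_anova(holes), "s2 x b")
})

test_that("ANOVA species test is calibrated under label permutation", {
  set.seed(31)
  base <- simulate_tmaze(
    c(a = 0.3, b = 0.1, c = -0.1), n_replicates = 8, retention = 0.3,
    fly_species = "sp", seed = NULL)
  n_sim <- 400
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    d <- base
    # random but cell-filling label assignment within each treatment
    d$fly_species <- ave(seq_len(nrow(d)), d$treatment_id,
                         FUN = function(ix)
                           sample(rep(1:3, length.out = length(ix))))
    d$fly_species <- paste0("s", d$fly_species)
    tab <- species_by_yeast_anova(d)
    rej[i] <- tab$p[tab$term == "fly_species"] < 0.05
  }
  mc_se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(mean(rej), 0.05 + 3 * mc_se)
  expect_gt(mean(rej), 0.05 - 3 * mc_se)
})

test_that("retention proportions and species comparison behave", {
  ident <- rbind(make_reps(c(10, 10), c(10, 10), 20, species = "s1"),
                 make_reps(c(10, 10), c(10, 10), 20, species = "s2"))
  r <- retention_test(ident)
  expect_equal(r$test$delta_deviance, 0, tolerance = 1e-8)

  extreme <- rbind(make_reps(0, 0, 40, species = "stay"),
                   make_reps(20, 20, 0, species = "go"))
  re <- retention_test(extreme)
  props <- setNames(re$proportions$retention, re$proportions$fly_species)
  expect_equal(unname(props["stay"]), 1)
  expect_equal(unname(props["go"]), 0)

  three <- rbind(make_reps(c(5, 5), c(5, 5), c(30, 30), species = "s1"),
                 make_reps(c(10, 10), c(10, 10), c(20, 20), species = "s2"),
                 make_reps(c(15, 15), c(15, 15), c(10, 10), species = "s3"))
  rt <- retention_test(three)
  got <- setNames(rt$proportions$retention, rt$proportions$fly_species)
  expect_equal(unname(got[c("s1", "s2", "s3")]),
               c(60 / 80, 40 / 80, 20 / 80))
})
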