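# Interaction ANOVA, Wald contrasts, static/conditional labelling.

# Stacked design with explicit per-condition effects on marker m1.
effect_design <- function(betas, noise_sd, n_per = 12, seed = 1,
                          p_markers = 3) {
  set.seed(seed)
  conds <- names(betas)
  n <- n_per
  calls <- matrix(rbinom(n * p_markers, 1, 0.5), n, p_markers)
  calls[, 1] <- rep(c(0L, 1L), length.out = n)
  geno <- toy_panel(calls)
  panels <- lapply(conds, function(t) {
    y <- betas[[t]] * calls[, 1] + rnorm(n, 0, noise_sd)
    toy_expression(matrix(y, 1), condition = t, genes = "g1",
                   strains = rownames(calls))
  })
  build_stacked_design(panels, geno, "g1")
}

test_that("F and Wald statistics match a brute-force least-squares oracle", {
  for (seed in 1:50) {
    des <- random_interaction_design(seed)
    ours <- anova_interaction_test(des, "m1")
    oracle <- brute_force_interaction(des, "m1")
    expect_equal(ours$F_stat, oracle$F_stat, tolerance = 1e-8)
    expect_equal(ours$p_interaction, oracle$p, tolerance = 1e-8)
    ct <- active_celltypes(ours, alpha = 0.05)
    ok <- !is.na(ct$z) & !is.na(oracle$z)
    expect_equal(ct$z[ok], oracle$z[ok], tolerance = 1e-8)
  }
})

test_that("a uniform genotype effect yields no interaction signal", {
  # noiseless, exactly additive: zero-residual degenerate rule gives p = 1
  des0 <- effect_design(c(A = 1, B = 1), noise_sd = 0)
  a0 <- anova_interaction_test(des0, "m1")
  expect_true(a0$degenerate)
  expect_equal(a0$p_interaction, 1)

  # with noise, the interaction p-value is null-distributed
  big <- replicate(60, {
    des <- effect_design(c(A = 1, B = 1), noise_sd = 0.1,
                         seed = sample.int(1e6, 1))
    anova_interaction_test(des, "m1")$p_interaction
  })
  expect_gt(mean(big > 0.5), 0.35)  # ~Uniform(0,1) under the null
  expect_gt(mean(big > 0.1), 0.80)
})

test_that("a condition-specific effect produces overwhelming interaction", {
  des <- effect_design(c(A = 0, B = 2), noise_sd = 0.1, n_per = 12, seed = 3)
  a <- anova_interaction_test(des, "m1")
  expect_lt(a$p_interaction, 1e-6)
})

test_that("markers constant in every condition are flagged degenerate", {
  des <- effect_design(c(A = 1, B = 1), noise_sd = 0.1, seed = 5)
  des$X[, "m2"] <- 1L
  a <- anova_interaction_test(des, "m2")
  expect_true(a$degenerate)
  expect_true(is.na(a$p_interaction))
})

test_that("post-hoc contrasts identify the active conditions", {
  hits <- 0
  reps <- 25
  for (r in 1:reps) {
    des <- effect_design(c(S = 0, P = 0, E = 2, M = 0), noise_sd = 0.1,
                         n_per = 12, seed = 100 + r)
    a <- anova_interaction_test(des, "m1")
    ct <- active_celltypes(a, alpha = 0.05)
    if (identical(ct$active, "E")) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})

test_that("effects in all conditions with changing sizes activate all contrasts", {
  des <- effect_design(c(S = 1, P = 2, E = 3, M = 4), noise_sd = 0.1,
                       n_per = 14, seed = 7)
  a <- anova_interaction_test(des, "m1")
  expect_lt(a$p_interaction, 1e-6)
  ct <- active_celltypes(a, alpha = 0.05)
  expect_setequal(ct$active, c("S", "P", "E", "M"))
})

test_that("exactly zero per-condition slopes give an empty active set", {
  # y depends on condition only; within-condition group means are equal by
  # construction, so every estimated slope is exactly 0
  calls <- matrix(c(0L, 0L, 1L, 1L), 4, 2)
  geno <- toy_panel(calls)
  panels <- lapply(c("A", "B"), function(t) {
    y <- c(1, 2, 1, 2) + (t == "B") * 10
    toy_expression(matrix(y, 1), condition = t, genes = "g1",
                   strains = rownames(calls))
  })
  des <- build_stacked_design(panels, geno, "g1")
  a <- anova_interaction_test(des, "m1")
  ct <- active_celltypes(a, alpha = 0.05)
  expect_equal(unname(ct$beta), c(0, 0))
  expect_length(ct$active, 0)
})

test_that("classification thresholds and label exclusivity hold", {
  fx <- make_fixture("tiny", seed = 4)
  sig <- data.frame(
    gene_id = c("gene001", "gene003"),
    marker_id = fx$geno$markers$marker_id[c(2, 5)],
    stringsAsFactors = FALSE
  )
  out <- suppressMessages(
    classify_static_conditional(sig, fx$panels, fx$geno)
  )
  expect_true(all(out$class %in% c("static", "conditional")))
  expect_equal(out$class == "conditional",
               !is.na(out$q_interaction) & out$q_interaction <= 0.1)
  expect_true(all(c("contrast_p_A", "contrast_p_B") %in% names(out)))
})
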