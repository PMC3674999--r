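# RIL genotype simulation and planted-effect expression generation.

test_that("zero recombination gives constant chromosomes", {
  cfg <- ril_sim_config(20, list(list(name = "chr1", n_markers = 15,
                                      marker_spacing_bp = 1e6)),
                        recomb_prob = 0, seed = 3)
  panel <- simulate_ril_genotypes(cfg)
  for (s in panel$strains) {
    expect_length(unique(panel$calls[s, ]), 1)
  }
})

test_that("free recombination decorrelates adjacent markers", {
  cfg <- ril_sim_config(500, list(list(name = "chr1", n_markers = 10,
                                       marker_spacing_bp = 1e6)),
                        recomb_prob = 0.5, seed = 11)
  panel <- simulate_ril_genotypes(cfg)
  for (j in 2:10) {
    r <- cor(panel$calls[, j - 1], panel$calls[, j])
    expect_lt(abs(r), 0.1)
  }
})

test_that("marginal allele frequencies stay near one half", {
  n <- 400
  cfg <- ril_sim_config(n, list(list(name = "chr1", n_markers = 20,
                                     marker_spacing_bp = 1e6)),
                        recomb_prob = 0.2, seed = 5)
  panel <- simulate_ril_genotypes(cfg)
  freq <- colMeans(panel$calls)
  bound <- 3 * sqrt(0.25 / n)
  expect_true(all(abs(freq - 0.5) <= bound))
})

test_that("genotype and expression generation are seed-deterministic", {
  fx1 <- make_fixture("tiny", seed = 9)
  fx2 <- make_fixture("tiny", seed = 9)
  expect_identical(fx1$geno$calls, fx2$geno$calls)
  expect_identical(fx1$panels[["A"]]$values, fx2$panels[["A"]]$values)

  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  make_fixture("tiny", seed = 9, dir = d1)
  make_fixture("tiny", seed = 9, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("planted effects obey the generative algebra", {
  calls <- matrix(rep(c(0L, 1L), each = 10), 20, 1,
                  dimnames = list(sprintf("s%02d", 1:20), "m1"))
  geno <- toy_panel(calls)
  conds <- c("A", "B", "C", "D")

  # noiseless static effect: group-mean difference exactly beta everywhere
  st <- effect_spec("g1", "m1", "static",
                    setNames(rep(1, 4), conds), noise_sd = 0)
  tr <- truth_set(list(st), character(0))
  panels <- simulate_expression_panels(geno, tr, conds, seed = 2)
  for (t in conds) {
    v <- panels[[t]]$values["g1", ]
    expect_equal(mean(v[11:20]) - mean(v[1:10]), 1)
  }

  # conditional effect beta = (0,0,2,0): gap ~2 in C, ~0 elsewhere
  noise <- 0.2
  co <- effect_spec("g1", "m1", "conditional",
                    setNames(c(0, 0, 2, 0), conds), noise_sd = noise)
  tr <- truth_set(list(co), character(0))
  panels <- simulate_expression_panels(geno, tr, conds, seed = 4)
  tol <- 4 * noise / sqrt(10)
  gap <- vapply(conds, function(t) {
    v <- panels[[t]]$values["g1", ]
    mean(v[11:20]) - mean(v[1:10])
  }, numeric(1))
  expect_equal(unname(gap), c(0, 0, 2, 0), tolerance = 1,
               ignore_attr = TRUE)
  expect_true(all(abs(gap - c(0, 0, 2, 0)) <= tol))

  # dynamic swap (+1, -1): pooled means cancel, difference trait gap = 2
  dy <- effect_spec("g1", "m1", "dynamic",
                    setNames(c(1, -1), c("A", "B")), noise_sd = 0)
  tr <- truth_set(list(dy), character(0))
  panels <- simulate_expression_panels(geno, tr, c("A", "B"), seed = 6)
  pooled_gap <- mean(c(panels$A$values["g1", 11:20],
                       panels$B$values["g1", 11:20])) -
    mean(c(panels$A$values["g1", 1:10], panels$B$values["g1", 1:10]))
  expect_equal(pooled_gap, 0)
  diff_trait <- panels$B$values["g1", ] - panels$A$values["g1", ]
  expect_equal(mean(diff_trait[11:20]) - mean(diff_trait[1:10]), -2)
})

test_that("effect spec class invariants are enforced", {
  b <- setNames(c(1, 1), c("A", "B"))
  expect_error(effect_spec("g", "m", "static", setNames(c(1, 2), c("A", "B")),
                           1), "equal nonzero")
  expect_error(effect_spec("g", "m", "conditional", b, 1), "unequal")
  expect_error(truth_set(list(effect_spec("g", "m", "static", b, 1)), "g"),
               "disjoint")
})

test_that("fixture presets have the documented shapes", {
  fx <- make_fixture("tiny", seed = 1)
  expect_equal(length(fx$geno$strains), 6)
  expect_equal(nrow(fx$geno$markers), 10)
  expect_equal(length(fx$panels), 2)

  nl <- make_fixture("null-only", seed = 1)
  expect_length(nl$truth$effects, 0)
  expect_length(nl$truth$null_genes, 120)
  expect_equal(nrow(nl$geno$markers), 100)
  # 22-24 strains measured per condition
  ns <- vapply(nl$panels, function(p) length(p$strains), numeric(1))
  expect_true(all(ns >= 22 & ns <= 24))

  df <- make_fixture("default", seed = 1)
  classes <- vapply(df$truth$effects, function(e) e$eqtl_class, character(1))
  expect_equal(unname(table(classes)[c("static", "conditional", "dynamic")]),
               c(20L, 20L, 10L), ignore_attr = TRUE)
  expect_length(df$truth$null_genes, 70)
  expect_error(make_fixture("nope"), "arg")
})
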