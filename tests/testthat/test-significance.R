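# Pooled permutation nulls, exponential tails, hybrid p-values, FDR.

make_profile <- function(gene, sf_values, markers = NULL) {
  if (is.null(markers)) markers <- sprintf("m%d", seq_along(sf_values))
  structure(list(gene_id = gene, sf = setNames(sf_values, markers),
                 n_splits = 100L, constant = FALSE), class = "sf_profile")
}

test_that("pooling collects one value per gene x permutation per marker", {
  perms <- list(
    list(make_profile("g1", c(0.1, 0.9)), make_profile("g1", c(0.2, 0.8))),
    list(make_profile("g2", c(0.3, 0.7)), make_profile("g2", c(0.4, 0.6)))
  )
  nulls <- pool_null(perms)
  expect_named(nulls, c("m1", "m2"))
  expect_length(nulls$m1$pooled_sfs, 4)
  expect_setequal(nulls$m1$pooled_sfs, c(0.1, 0.2, 0.3, 0.4))
})

test_that("indicator columns are excluded from pooled nulls", {
  pr <- make_profile("g1", c(0.5, 0.3, 0.2), markers = c("m1", "m2", "ct_A"))
  nulls <- pool_null(list(list(pr)))
  expect_named(nulls, c("m1", "m2"))
})

test_that("an all-zero pooled null disables the tail and gives p = 1 at 0", {
  pr <- lapply(1:3, function(i) make_profile("g1", c(0, 0)))
  nulls <- suppressWarnings(pool_null(list(pr)))
  expect_equal(nulls$m1$s0, 0)
  expect_false(nulls$m1$tail_enabled)
  expect_equal(hybrid_pvalue(0, nulls$m1), 1)
  # but a positive observed SF is still in the smallest resolvable bin
  expect_equal(hybrid_pvalue(0.2, nulls$m1), 1 / 4)
})

test_that("the tail threshold follows the type-7 quantile convention", {
  tail100 <- suppressWarnings(fit_exponential_tail((1:100) / 100))
  expect_equal(tail100$s0, 0.9901)
  # a single exceedance cannot support a tail fit
  expect_false(tail100$tail_enabled)

  tail1000 <- fit_exponential_tail((1:1000) / 1000)
  expect_equal(tail1000$s0, 0.99001)
  expect_true(tail1000$tail_enabled)
  # mean exceedance of the ten values above s0, computed by hand
  expect_equal(tail1000$lambda, 0.00549)
})

test_that("identical pooled values disable the tail", {
  tl <- suppressWarnings(fit_exponential_tail(rep(0.25, 500)))
  expect_false(tl$tail_enabled)
})

test_that("the exponential tail recovers the scale of an exponential null", {
  set.seed(123)
  sigma <- 0.02
  pooled <- rexp(1e5, rate = 1 / sigma)
  tl <- fit_exponential_tail(pooled)
  # memorylessness: exceedances over any threshold are Exponential(sigma)
  expect_lt(abs(tl$lambda - sigma) / sigma, 0.05)
})

test_that("hybrid p-values follow the add-one empirical and tail formulas", {
  null <- structure(list(marker_id = "m", pooled_sfs = c(0.1, 0.2, 0.3),
                         s0 = 0.3, p0 = 0.01, lambda = NA_real_,
                         tail_enabled = FALSE), class = "marker_null")
  expect_equal(hybrid_pvalue(0.25, null), (1 + 1) / (1 + 3))

  tnull <- structure(list(marker_id = "m", pooled_sfs = runif(1000, 0, 0.3),
                          s0 = 0.3, p0 = 0.01, lambda = 0.05,
                          tail_enabled = TRUE), class = "marker_null")
  # closed form at one lambda above the threshold
  expect_equal(hybrid_pvalue(0.35, tnull), 0.01 * exp(-1))

  # boundary: with s0 the true 99th percentile, the empirical branch at s0
  # returns ~p0, so the two branches are continuous up to discreteness
  set.seed(77)
  pooled <- runif(2000)
  tl <- fit_exponential_tail(pooled)
  bnull <- structure(list(marker_id = "m", pooled_sfs = pooled, s0 = tl$s0,
                          p0 = 0.01, lambda = tl$lambda,
                          tail_enabled = tl$tail_enabled),
                     class = "marker_null")
  p_s0 <- hybrid_pvalue(tl$s0, bnull)
  expect_lt(abs(p_s0 - 0.01), 3 / 2001)
})

test_that("hybrid p-values are monotone non-increasing in the observed SF", {
  set.seed(9)
  pooled <- rexp(5000, 50)
  tl <- fit_exponential_tail(pooled)
  null <- structure(list(marker_id = "m", pooled_sfs = pooled, s0 = tl$s0,
                         p0 = 0.01, lambda = tl$lambda,
                         tail_enabled = tl$tail_enabled),
                    class = "marker_null")
  grid <- seq(0, max(pooled) * 1.5, length.out = 200)
  p <- hybrid_pvalue(grid, null)
  expect_true(all(diff(p) <= 1e-12))
  expect_true(all(p > 0 & p <= 1))
})

test_that("tail and empirical p-values agree near the threshold", {
  set.seed(21)
  pooled <- rexp(20000, 40)
  tl <- fit_exponential_tail(pooled)
  null <- structure(list(marker_id = "m", pooled_sfs = pooled, s0 = tl$s0,
                         p0 = 0.01, lambda = tl$lambda, tail_enabled = TRUE),
                    class = "marker_null")
  for (s in tl$s0 * c(1.01, 1.05, 1.1)) {
    p_tail <- hybrid_pvalue(s, null)
    p_emp <- (1 + sum(pooled >= s)) / (1 + length(pooled))
    expect_lt(max(p_tail / p_emp, p_emp / p_tail), 2)
  }
})

test_that("BH adjustment reproduces hand-executed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(1, 1)), c(1, 1))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  # ordering of p-values is preserved in q-values
  set.seed(2)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("eqtl_test assembles one row per pair with consistent q-values", {
  obs <- list(make_profile("g1", c(0.6, 0.4)), make_profile("g2", c(0.5, 0.5)))
  perms <- lapply(1:2, function(g) lapply(1:30, function(b)
    make_profile(paste0("g", g), runif(2, 0, 0.45))))
  nulls <- suppressWarnings(pool_null(perms))
  res <- eqtl_test(obs, nulls)
  expect_equal(nrow(res), 4)
  expect_named(res, c("gene_id", "marker_id", "sf", "p", "q", "branch"))
  expect_equal(res$q, bh_fdr(res$p))
  # a profile missing a pooled marker is an error
  bad <- list(make_profile("g1", 0.5, markers = "m1"))
  expect_error(eqtl_test(bad, nulls), "absent")
})
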