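# Shared fixtures built in code at test time.

# Small forest settings keep unit tests fast; acceptance tests use the
# full-size configuration.
tiny_forest <- function(seed = 1, n_trees = 100) {
  forest_config(n_trees = n_trees, min_node_size = 2, seed = seed)
}

# Write the 3-strain x 2-marker toy genotype table; returns the path.
write_toy_genotype <- function(path = tempfile(fileext = ".tsv"),
                               extra_rows = NULL) {
  lines <- c(
    "Chr\tLocus\tPosition\tBXD1\tBXD2\tBXD3",
    "chr1\tm1\t1000\tB\tD\tB",
    "chr1\tm2\t2000\tD\tD\tB",
    extra_rows
  )
  writeLines(lines, path)
  path
}

# Hand-built genotype panel: calls given strains x markers.
toy_panel <- function(calls, chromosome = "chr1",
                      positions = NULL) {
  m <- ncol(calls)
  if (is.null(positions)) positions <- seq_len(m) * 1000
  if (length(chromosome) == 1) chromosome <- rep(chromosome, m)
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("s%d", seq_len(nrow(calls)))
  }
  if (is.null(colnames(calls))) {
    colnames(calls) <- sprintf("m%d", seq_len(m))
  }
  markers <- data.frame(marker_id = colnames(calls), chromosome = chromosome,
                        interval_start_bp = positions,
                        interval_end_bp = positions,
                        stringsAsFactors = FALSE)
  genotype_panel(calls, markers)
}

# Expression panel from a plain matrix with default dimnames.
toy_expression <- function(values, condition = "A",
                           genes = NULL, strains = NULL) {
  if (is.null(genes)) genes <- sprintf("g%d", seq_len(nrow(values)))
  if (is.null(strains)) strains <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, strains)
  expression_panel(values, condition)
}

# Random small stacked design for oracle comparisons: n_cond conditions,
# n_per strains each, one marker of interest plus noise trait.
random_interaction_design <- function(seed, n_cond = NULL, n_per = NULL) {
  set.seed(seed)
  if (is.null(n_cond)) n_cond <- sample(2:4, 1)
  if (is.null(n_per)) n_per <- sample(6:12, 1)
  conds <- LETTERS[seq_len(n_cond)]
  n_strains <- n_per
  calls <- matrix(rbinom(n_strains * 3, 1, 0.5), n_strains, 3)
  # ensure the tested marker has both genotype groups
  calls[1, 1] <- 0L; calls[2, 1] <- 1L
  geno <- toy_panel(calls)
  panels <- lapply(conds, function(t) {
    v <- matrix(rnorm(n_strains, mean = match(t, conds)), 1, n_strains)
    toy_expression(v, condition = t, genes = "g1",
                   strains = rownames(calls))
  })
  build_stacked_design(panels, geno, "g1")
}

# Independent least-squares oracle: model matrices built by hand, normal
# equations solved directly (no lm), F for the interaction block and Wald
# z per condition.
brute_force_interaction <- function(design, marker_id) {
  x <- design$X[, marker_id]
  cond <- factor(design$row_meta$condition, levels = design$conditions)
  cond <- droplevels(cond)
  k <- nlevels(cond)
  n <- length(design$Y)
  D <- outer(cond, levels(cond), "==") * 1  # n x k indicator
  X_red <- cbind(1, x, D[, -1, drop = FALSE])
  X_full <- cbind(X_red, x * D[, -1, drop = FALSE])
  fit_ls <- function(M, y) {
    b <- solve(crossprod(M), crossprod(M, y))
    r <- y - M %*% b
    list(beta = drop(b), rss = sum(r^2), XtX_inv = solve(crossprod(M)))
  }
  full <- fit_ls(X_full, design$Y)
  red <- fit_ls(X_red, design$Y)
  df_full <- n - ncol(X_full)
  df_delta <- ncol(X_full) - ncol(X_red)
  F_stat <- ((red$rss - full$rss) / df_delta) / (full$rss / df_full)
  sigma2 <- full$rss / df_full
  V <- sigma2 * full$XtX_inv
  # per-condition slope: beta_x (+ interaction for non-reference levels)
  z <- setNames(rep(NA_real_, k), levels(cond))
  for (i in seq_len(k)) {
    w <- numeric(ncol(X_full))
    w[2] <- 1
    if (i > 1) w[ncol(X_red) + i - 1] <- 1
    est <- sum(w * full$beta)
    se <- sqrt(drop(t(w) %*% V %*% w))
    z[i] <- est / se
  }
  list(F_stat = F_stat,
       p = pf(F_stat, df_delta, df_full, lower.tail = FALSE),
       z = z)
}

# Textbook Friedman statistic with midranks and tie correction, written
# independently of the package (and of stats::friedman.test).
textbook_friedman <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  r <- t(apply(mat, 1, rank))
  Rj <- colSums(r)
  correction <- 0
  for (i in seq_len(n)) {
    t_sizes <- as.numeric(table(r[i, ]))
    correction <- correction + sum(t_sizes^3 - t_sizes)
  }
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  den <- n * k * (k + 1) - correction / (k - 1)
  num / den
}
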