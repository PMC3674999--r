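# From selection frequencies to p-values: pooled permutation nulls with an
# exponential upper tail, and Benjamini-Hochberg FDR.
#
# Raw SFs are not comparable across markers: tree learners prefer some
# markers even under the null (allele-frequency and linkage effects), so
# each marker gets its own null distribution, pooled over all genes and all
# permutations. A small number of permutations (default 10) times the gene
# count already gives thousands of null draws per marker; the top 1% of
# that pooled distribution is then replaced by a fitted exponential tail so
# that small p-values are resolved far beyond the permutation resolution.

#' Fit an exponential tail to pooled null selection frequencies
#'
#' The tail threshold s0 is the empirical 99th percentile (type-7,
#' linear-interpolation quantile, so s0 is reproducible across
#' implementations); the scale lambda is the maximum-likelihood estimate
#' for a shifted exponential: the mean exceedance over s0. With fewer than
#' 2 distinct exceedances the tail is disabled and p-values fall back to
#' the empirical estimator everywhere.
#'
#' @param pooled_sfs numeric vector of null selection frequencies.
#' @return list with `s0`, `lambda` (NA when disabled), `tail_enabled`.
#' @export
fit_exponential_tail <- function(pooled_sfs) {
  stopifnot(length(pooled_sfs) >= 1)
  if (length(pooled_sfs) < 100) {
    warning("fewer than 100 pooled null values; tail fit will be unstable")
  }
  s0 <- unname(stats::quantile(pooled_sfs, 0.99, type = 7))
  exceed <- pooled_sfs[pooled_sfs > s0] - s0
  if (length(exceed) < 2 || length(unique(exceed)) < 2) {
    return(list(s0 = s0, lambda = NA_real_, tail_enabled = FALSE))
  }
  list(s0 = s0, lambda = mean(exceed), tail_enabled = TRUE)
}

#' Pool permuted selection frequencies into per-marker null distributions
#'
#' Under the null, the SF distribution of a marker is the same for every
#' gene, so permuted SFs are pooled over genes and permutations into one
#' null distribution per marker, and the exponential tail is fitted to
#' each. Indicator columns are not markers and are skipped.
#'
#' @param permuted_profiles list (over genes) of lists (over permutations)
#'   of `sf_profile` objects, or a flat list of `sf_profile`s.
#' @return named list of `marker_null` objects: `marker_id`, `pooled_sfs`,
#'   `s0`, `p0` (= 0.01), `lambda`, `tail_enabled`.
#' @export
pool_null <- function(permuted_profiles) {
  flat <- flatten_profiles(permuted_profiles)
  if (length(flat) == 0) stop("no permutation profiles to pool")
  predictors <- names(flat[[1]]$sf)
  markers <- predictors[!is_indicator(predictors)]
  sf_mat <- vapply(flat, function(pr) pr$sf[markers],
                   numeric(length(markers)))
  if (length(markers) == 1) sf_mat <- matrix(sf_mat, nrow = 1)
  nulls <- lapply(seq_along(markers), function(i) {
    pooled <- unname(sf_mat[i, ])
    tail <- suppressWarnings(fit_exponential_tail(pooled))
    structure(list(marker_id = markers[i], pooled_sfs = pooled,
                   s0 = tail$s0, p0 = 0.01, lambda = tail$lambda,
                   tail_enabled = tail$tail_enabled),
              class = "marker_null")
  })
  names(nulls) <- markers
  nulls
}

flatten_profiles <- function(x) {
  if (inherits(x, "sf_profile")) return(list(x))
  out <- list()
  for (el in x) {
    if (inherits(el, "sf_profile")) out[[length(out) + 1]] <- el
    else out <- c(out, flatten_profiles(el))
  }
  out
}

#' Hybrid empirical/exponential-tail permutation p-value
#'
#' Below the tail threshold s0 the p-value is the add-one empirical
#' estimator `(1 + #{pooled >= sf_obs}) / (1 + N)` — it never returns 0,
#' which is required for valid BH adjustment, and uses `>=` so ties count
#' conservatively. Above s0 (when the tail is enabled) the fitted tail
#' gives `p = p0 * exp(-(sf_obs - s0) / lambda)`, continuous with the
#' empirical branch at s0 up to discreteness.
#'
#' @param sf_obs numeric vector of observed selection frequencies.
#' @param null a `marker_null`.
#' @return numeric vector of p-values in (0, 1].
#' @export
hybrid_pvalue <- function(sf_obs, null) {
  stopifnot(inherits(null, "marker_null"))
  n <- length(null$pooled_sfs)
  vapply(sf_obs, function(s) {
    if (null$tail_enabled && s > null$s0) {
      null$p0 * exp(-(s - null$s0) / null$lambda)
    } else {
      (1 + sum(null$pooled_sfs >= s)) / (1 + n)
    }
  }, numeric(1))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values over all tested pairs of a mapping run (genome-wide
#' family). Thin wrapper over the standard step-up procedure; order is
#' preserved.
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return numeric vector of q-values, same order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH")
}

#' Assemble eQTL test results from profiles and pooled nulls
#'
#' One row per (gene, marker) pair: observed SF, hybrid p-value with its
#' branch, and BH q-value computed over all pairs in the run.
#'
#' @param observed_profiles list of observed `sf_profile` objects (one per
#'   gene).
#' @param nulls named list of `marker_null` objects from [pool_null()].
#' @return data.frame with columns gene_id, marker_id, sf, p, q, branch.
#' @export
eqtl_test <- function(observed_profiles, nulls) {
  markers <- names(nulls)
  rows <- lapply(observed_profiles, function(pr) {
    missing <- setdiff(markers, names(pr$sf))
    if (length(missing) > 0) {
      stop("marker absent from profile: ", missing[1])
    }
    sf <- pr$sf[markers]
    p <- vapply(seq_along(markers), function(i)
      hybrid_pvalue(sf[i], nulls[[i]]), numeric(1))
    branch <- vapply(seq_along(markers), function(i) {
      if (nulls[[i]]$tail_enabled && sf[i] > nulls[[i]]$s0) "tail"
      else "empirical"
    }, character(1))
    data.frame(gene_id = pr$gene_id, marker_id = markers,
               sf = unname(sf), p = unname(p), branch = branch,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$q <- bh_fdr(res$p)
  res[, c("gene_id", "marker_id", "sf", "p", "q", "branch")]
}
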