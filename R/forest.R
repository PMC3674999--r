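# Random-Forest selection frequencies for observed and permuted traits.

#' Random-Forest hyperparameters
#'
#' Defaults follow standard regression-forest practice: 1000 trees, mtry =
#' ceiling(p/3) candidate predictors per split, minimum node size 5,
#' unlimited depth.
#'
#' @param n_trees number of trees (>= 1).
#' @param mtry candidate predictors per split; `NULL` for ceiling(p/3), or a
#'   fraction in (0,1) of the predictor count, or an integer.
#' @param min_node_size minimal terminal node size.
#' @param max_depth maximal tree depth; 0 = unlimited.
#' @param seed integer seed; forests are deterministic given it.
#' @return an object of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000, mtry = NULL, min_node_size = 5,
                          max_depth = 0, seed = 1) {
  stopifnot(n_trees >= 1, min_node_size >= 1)
  structure(list(n_trees = n_trees, mtry = mtry,
                 min_node_size = min_node_size, max_depth = max_depth,
                 seed = seed),
            class = "forest_config")
}

resolve_mtry <- function(mtry, p) {
  if (is.null(mtry)) return(max(1L, as.integer(ceiling(p / 3))))
  if (mtry > 0 && mtry < 1) return(max(1L, as.integer(ceiling(mtry * p))))
  min(as.integer(mtry), p)
}

#' Fit a regression forest and return per-predictor selection frequencies
#'
#' The selection frequency (SF) of a predictor is the number of internal
#' split nodes using it, across all trees, divided by the total number of
#' internal split nodes in the forest. SFs sum to 1 whenever any split
#' occurred, which is what lets per-marker null SFs be pooled across genes.
#' A marker used more often than expected under the permutation null is an
#' eQTL of the gene.
#'
#' Condition-indicator columns are ordinary predictors (they receive SF
#' mass and appear in the profile) but are excluded from eQTL candidate
#' reporting downstream.
#'
#' @param design a `stacked_design`.
#' @param cfg a `forest_config`.
#' @param y optional replacement trait vector (used internally for
#'   permutations); defaults to `design$Y`.
#' @param seed optional seed override.
#' @return an object of class `sf_profile`: list with `gene_id`, `sf`
#'   (named numeric over all predictors), `n_splits`, and `constant`
#'   (TRUE when the trait had < 2 distinct values and no forest was grown).
#' @importFrom ranger ranger
#' @export
fit_selection_frequencies <- function(design, cfg = forest_config(),
                                      y = NULL, seed = NULL) {
  stopifnot(inherits(design, "stacked_design"), inherits(cfg, "forest_config"))
  if (is.null(y)) y <- design$Y
  if (is.null(seed)) seed <- cfg$seed
  p <- ncol(design$X)
  if (length(y) < 2 * cfg$min_node_size) {
    stop("insufficient samples: ", length(y), " rows for min_node_size ",
         cfg$min_node_size)
  }
  if (length(unique(y)) < 2) {
    log_event("constant_trait", "gene '", design$gene_id,
              "': constant trait, all-zero SF profile")
    return(structure(list(gene_id = design$gene_id,
                          sf = setNames(rep(0, p), colnames(design$X)),
                          n_splits = 0L, constant = TRUE),
                     class = "sf_profile"))
  }
  rf <- ranger::ranger(
    x = design$X, y = y,
    num.trees = cfg$n_trees,
    mtry = resolve_mtry(cfg$mtry, p),
    min.node.size = cfg$min_node_size,
    max.depth = if (cfg$max_depth > 0) cfg$max_depth else NULL,
    num.threads = 1, seed = seed,
    oob.error = FALSE, write.forest = TRUE
  )
  counts <- count_split_vars(rf, p)
  total <- sum(counts)
  sf <- if (total > 0) counts / total else rep(0, p)
  structure(list(gene_id = design$gene_id,
                 sf = setNames(sf, colnames(design$X)),
                 n_splits = as.integer(total), constant = FALSE),
            class = "sf_profile")
}

# Count internal split nodes per predictor from a stored ranger forest.
# split.varIDs are 0-based; terminal nodes (both child ids 0) are excluded.
count_split_vars <- function(rf, p) {
  fo <- rf$forest
  counts <- numeric(p)
  for (tr in seq_len(rf$num.trees)) {
    internal <- fo$child.nodeIDs[[tr]][[1]] != 0 | fo$child.nodeIDs[[tr]][[2]] != 0
    counts <- counts + tabulate(fo$split.varIDs[[tr]][internal] + 1L, p)
  }
  counts
}

#' Permute the trait and recompute selection frequencies
#'
#' Under the null hypothesis of no marker-trait association, permuting the
#' trait over strains destroys genotype signal while keeping the SF
#' machinery identical. The `within_condition` policy (default for stacked
#' designs) shuffles Y only within each condition block, preserving
#' condition means so the null targets the genotype association rather
#' than the condition main effects; `global` permutes the whole vector.
#' Permutation seeds are derived deterministically from `cfg$seed`, so
#' results do not depend on execution order.
#'
#' @param design a `stacked_design`.
#' @param n_perm number of permutations (>= 0).
#' @param cfg a `forest_config`.
#' @param policy "within_condition" or "global".
#' @return list of `sf_profile` objects, one per permutation.
#' @export
permute_and_refit <- function(design, n_perm, cfg = forest_config(),
                              policy = c("within_condition", "global")) {
  policy <- match.arg(policy)
  if (n_perm < 1) return(list())
  lapply(seq_len(n_perm), function(b) {
    pseed <- derive_seed(cfg$seed, b)
    yp <- permute_trait(design$Y, design$row_meta$condition, policy, pseed)
    fit_selection_frequencies(design, cfg, y = yp,
                              seed = derive_seed(pseed, 1))
  })
}

permute_trait <- function(y, condition, policy, seed) {
  set.seed(seed)
  if (policy == "global") return(y[sample.int(length(y))])
  yp <- y
  for (t in unique(condition)) {
    idx <- which(condition == t)
    yp[idx] <- y[idx[sample.int(length(idx))]]
  }
  yp
}

#' Map one gene: observed and permuted selection-frequency profiles
#'
#' Convenience driver used by the pipeline: builds the per-gene forest for
#' the observed trait and for `n_perm` permuted traits, with a per-gene
#' seed stream derived from `cfg$seed` and the gene's index so gene-level
#' work units are order-independent.
#'
#' @param design a `stacked_design`.
#' @param cfg a `forest_config`.
#' @param n_perm number of permutations.
#' @param policy permutation policy, see [permute_and_refit()].
#' @param gene_index integer index used to derive the per-gene seed.
#' @return list with `observed` (`sf_profile`) and `permuted` (list).
#' @export
map_gene <- function(design, cfg = forest_config(), n_perm = 10,
                     policy = "within_condition", gene_index = 1) {
  gcfg <- cfg
  gcfg$seed <- derive_seed(cfg$seed, gene_index)
  obs <- fit_selection_frequencies(design, gcfg)
  perm <- permute_and_refit(design, n_perm, gcfg, policy)
  list(observed = obs, permuted = perm)
}
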