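# Validation studies on synthetic data with known truth.
#
# These functions run the full mapping pipeline on generated fixtures and
# score the results against the planted truth. They are what the package's
# acceptance checks and reproducibility script execute; exposing them as
# ordinary functions lets users rerun the same studies under their own
# seeds and sizes.

#' Tabulate the planted truth of a fixture
#'
#' @param fixture a bundle from [make_fixture()].
#' @return data.frame: gene_id, marker_id, class, active_condition (for
#'   single-condition conditional effects), chromosome, pos_bp of the
#'   causal marker (coordinates from the unmerged map).
#' @export
truth_table <- function(fixture) {
  eff <- fixture$truth$effects
  if (length(eff) == 0) {
    return(data.frame(gene_id = character(0), marker_id = character(0),
                      class = character(0), active_condition = character(0),
                      chromosome = character(0), pos_bp = numeric(0),
                      stringsAsFactors = FALSE))
  }
  tab <- data.frame(
    gene_id = vapply(eff, function(e) e$gene_id, character(1)),
    marker_id = vapply(eff, function(e) e$marker_id, character(1)),
    class = vapply(eff, function(e) e$eqtl_class, character(1)),
    active_condition = vapply(eff, function(e) {
      nz <- names(e$beta)[unlist(e$beta) != 0]
      if (e$eqtl_class == "conditional" && length(nz) == 1) nz else NA_character_
    }, character(1)),
    stringsAsFactors = FALSE
  )
  i <- match(tab$marker_id, fixture$geno$markers$marker_id)
  tab$chromosome <- fixture$geno$markers$chromosome[i]
  tab$pos_bp <- fixture$geno$markers$interval_start_bp[i]
  tab
}

#' Is a planted locus hit by any listed result pair?
#'
#' A locus counts as detected when any pair for the gene falls on a marker
#' whose (possibly merged) interval lies within `window_bp` of the causal
#' marker position on the same chromosome. Matching by genomic window
#' rather than marker id makes the scoring robust to marker merging and to
#' linkage neighbors carrying the signal.
#'
#' @param pairs data.frame of result pairs (gene_id, marker_id).
#' @param gene_id,chromosome,pos_bp the planted locus.
#' @param markers marker map of the mapped (merged) panel.
#' @param window_bp matching window (default 5 Mb).
#' @return TRUE/FALSE.
#' @export
locus_detected <- function(pairs, gene_id, chromosome, pos_bp, markers,
                           window_bp = 5e6) {
  sub <- pairs[pairs$gene_id == gene_id, , drop = FALSE]
  if (nrow(sub) == 0) return(FALSE)
  i <- match(sub$marker_id, markers$marker_id)
  any(markers$chromosome[i] == chromosome &
        markers$interval_end_bp[i] >= pos_bp - window_bp &
        markers$interval_start_bp[i] <= pos_bp + window_bp)
}

#' Planted-class recovery study on the default fixture
#'
#' Generates the default fixture (120 genes: 20 static, 20 single-condition
#' conditional, 10 dynamic-swap, 70 null over 4 conditions), runs the full
#' simultaneous mapping + classification pipeline, and scores recovery
#' against the truth: locus recall at mapping FDR 0.1, label accuracy among
#' detected loci, active-condition accuracy, and the false-discovery
#' proportion (a discovery is false when its gene is null or its marker is
#' outside the 5 Mb window of the gene's causal locus).
#'
#' @param seed study seed.
#' @param n_trees forest size (study default 1000).
#' @param n_perm permutations per gene (study default 10).
#' @param window_bp locus-matching window.
#' @return list of scores; see Details in the vignette.
#' @export
eval_planted_recovery <- function(seed, n_trees = 1000, n_perm = 10,
                                  window_bp = 5e6) {
  fx <- make_fixture("default", seed = seed)
  geno <- merge_identical_markers(fx$geno)
  run <- run_simultaneous(fx$panels, geno,
                          forest_config(n_trees = n_trees, seed = seed),
                          n_perm = n_perm)
  truth <- truth_table(fx)
  sig <- run$significant
  mk <- geno$markers

  det <- function(i, pairs) locus_detected(pairs, truth$gene_id[i],
                                           truth$chromosome[i],
                                           truth$pos_bp[i], mk, window_bp)
  sc <- which(truth$class %in% c("static", "conditional"))
  detected <- vapply(sc, det, logical(1), pairs = sig)

  st <- which(truth$class == "static")
  st_det <- st[vapply(st, det, logical(1), pairs = sig)]
  st_ok <- vapply(st_det, det, logical(1),
                  pairs = sig[sig$class == "static", , drop = FALSE])

  co <- which(truth$class == "conditional")
  co_det <- co[vapply(co, det, logical(1), pairs = sig)]
  co_pairs <- sig[sig$class == "conditional", , drop = FALSE]
  co_ok <- vapply(co_det, det, logical(1), pairs = co_pairs)
  co_act <- vapply(co_det, function(i) {
    sub <- co_pairs[co_pairs$gene_id == truth$gene_id[i], , drop = FALSE]
    if (nrow(sub) == 0) return(FALSE)
    any(vapply(strsplit(sub$active_conditions, ","), function(a)
      truth$active_condition[i] %in% a, logical(1)))
  }, logical(1))

  # false-discovery proportion over all significant pairs
  if (nrow(sig) > 0) {
    ti <- match(sig$gene_id, truth$gene_id)
    mi <- match(sig$marker_id, mk$marker_id)
    true_pair <- !is.na(ti) &
      mk$chromosome[mi] == truth$chromosome[ti] &
      mk$interval_end_bp[mi] >= truth$pos_bp[ti] - window_bp &
      mk$interval_start_bp[mi] <= truth$pos_bp[ti] + window_bp
    fdp <- mean(!true_pair)
  } else {
    fdp <- 0
  }

  list(recall_overall = mean(detected),
       n_loci = length(sc),
       recall_static = mean(vapply(st, det, logical(1), pairs = sig)),
       recall_conditional = mean(vapply(co, det, logical(1), pairs = sig)),
       label_static_acc = if (length(st_det)) mean(st_ok) else NA_real_,
       label_conditional_acc = if (length(co_det)) mean(co_ok) else NA_real_,
       active_condition_acc = if (length(co_det)) mean(co_act) else NA_real_,
       n_detected_static = length(st_det),
       n_detected_conditional = length(co_det),
       fdp = fdp, n_significant = nrow(sig))
}

#' Null-calibration study on the null-only fixture
#'
#' Runs the simultaneous mapping on a fixture with no planted effects and
#' reports the empirical p-value calibration (fraction of hybrid p-values
#' below 0.05 over all gene-marker pairs) and the number of discoveries at
#' FDR 0.1 (expected: usually zero).
#'
#' @param seed study seed.
#' @param n_trees forest size.
#' @param n_perm permutations per gene.
#' @return list with `frac_p05`, `n_pairs`, `n_discoveries`.
#' @export
eval_null_calibration <- function(seed, n_trees = 200, n_perm = 10) {
  fx <- make_fixture("null-only", seed = seed)
  geno <- merge_identical_markers(fx$geno)
  run <- run_simultaneous(fx$panels, geno,
                          forest_config(n_trees = n_trees, seed = seed),
                          n_perm = n_perm)
  list(frac_p05 = mean(run$results$p < 0.05),
       n_pairs = nrow(run$results),
       n_discoveries = sum(run$results$q <= 0.1))
}

#' Dynamic-vs-conditional power study for sign-swapping eQTL
#'
#' Each replicate dataset plants two sign-swapping eQTL (allelic effect +1
#' in the "from" condition, -1 in the "to" condition, residual SD 0.3, 24
#' strains) among null genes, then maps the same data twice at matched FDR
#' 0.1: (a) dynamic mapping on the per-strain difference trait and (b)
#' simultaneous mapping followed by static/conditional classification. A
#' swap gene counts as found when a marker within 5 Mb of its causal locus
#' is significant (and, for arm (b), classified conditional).
#'
#' @param seed study seed.
#' @param n_datasets number of replicate datasets (2 swap genes each).
#' @param n_null null genes per dataset.
#' @param noise_sd residual SD (study default 0.3).
#' @param beta swap effect magnitude (study default 1).
#' @param n_trees,n_perm forest size and permutations per gene.
#' @param run_conditional_arm set FALSE to skip arm (b) (it dominates the
#'   study's runtime).
#' @return list with `dynamic_rate`, `conditional_rate`, `n_swap_genes`.
#' @export
eval_swap_power <- function(seed, n_datasets = 25, n_null = 18,
                            noise_sd = 0.3, beta = 1,
                            n_trees = 300, n_perm = 20,
                            run_conditional_arm = TRUE) {
  dyn_hits <- logical(0); cond_hits <- logical(0)
  for (d in seq_len(n_datasets)) {
    ds <- derive_seed(seed, d)
    cfg <- ril_sim_config(
      24, list(list(name = "chr1", n_markers = 10, marker_spacing_bp = 2.5e6),
               list(name = "chr2", n_markers = 10, marker_spacing_bp = 2.5e6)),
      recomb_prob = 0.1, seed = ds)
    geno <- simulate_ril_genotypes(cfg)
    mids <- geno$markers$marker_id
    causal <- c(mids[4], mids[15])
    effs <- list(
      effect_spec("swap1", causal[1], "dynamic",
                  c(P = beta, M = -beta), noise_sd = noise_sd),
      effect_spec("swap2", causal[2], "dynamic",
                  c(P = beta, M = -beta), noise_sd = noise_sd))
    nulls <- sprintf("null%02d", seq_len(n_null))
    truth <- truth_set(effs, nulls, null_noise_sd = noise_sd)
    genes <- c("swap1", "swap2", nulls)
    set.seed(derive_seed(ds, 1))
    bl <- matrix(stats::rnorm(length(genes) * 2), length(genes), 2,
                 dimnames = list(genes, c("P", "M")))
    spc <- list(P = sort(sample(geno$strains, 23)),
                M = sort(sample(geno$strains, 23)))
    panels <- simulate_expression_panels(geno, truth, c("P", "M"), spc,
                                         baselines = bl,
                                         seed = derive_seed(ds, 2))
    geno_m <- merge_identical_markers(geno)
    fc <- forest_config(n_trees, seed = ds)
    dyn <- map_dynamic(panels$P, panels$M, geno_m, fc, n_perm = n_perm)
    truth_pos <- match(causal, geno$markers$marker_id)
    hit <- function(pairs, k) locus_detected(
      pairs, c("swap1", "swap2")[k],
      geno$markers$chromosome[truth_pos[k]],
      geno$markers$interval_start_bp[truth_pos[k]], geno_m$markers)
    dsig <- dyn[dyn$q <= 0.1, , drop = FALSE]
    dyn_hits <- c(dyn_hits, hit(dsig, 1), hit(dsig, 2))
    if (run_conditional_arm) {
      sim <- run_simultaneous(panels, geno_m, fc, n_perm = n_perm)
      csig <- sim$significant
      if (nrow(csig) > 0 && "class" %in% names(csig)) {
        csig <- csig[csig$class == "conditional", , drop = FALSE]
      }
      cond_hits <- c(cond_hits, hit(csig, 1), hit(csig, 2))
    }
  }
  list(dynamic_rate = mean(dyn_hits),
       conditional_rate = if (run_conditional_arm) mean(cond_hits) else NA_real_,
       n_swap_genes = length(dyn_hits))
}
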