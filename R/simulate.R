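# Synthetic recombinant-inbred-line (RIL) data with planted eQTL.
#
# The generator emulates a BXD-like panel: homozygous diallelic strains,
# markers laid out along chromosomes with Markov-chain linkage, and
# multi-condition expression with planted static, conditional and dynamic
# (sign-swapping) effects plus a machine-readable truth set.

#' Configuration for the RIL genotype simulator
#'
#' @param n_strains number of inbred strains.
#' @param chromosomes list of chromosome descriptors, each a list with
#'   `name`, `n_markers` (>= 1) and `marker_spacing_bp`.
#' @param recomb_prob probability in [0, 0.5] that the allele flips between
#'   adjacent markers (per strain, per pair).
#' @param seed integer RNG seed.
#' @return an object of class `ril_sim_config`.
#' @export
ril_sim_config <- function(n_strains, chromosomes, recomb_prob, seed = 1) {
  stopifnot(n_strains >= 1, recomb_prob >= 0, recomb_prob <= 0.5)
  for (ch in chromosomes) {
    stopifnot(!is.null(ch$name), ch$n_markers >= 1, ch$marker_spacing_bp > 0)
  }
  structure(list(n_strains = n_strains, chromosomes = chromosomes,
                 recomb_prob = recomb_prob, seed = seed),
            class = "ril_sim_config")
}

#' Simulate RIL genotypes
#'
#' Each strain's alleles along a chromosome form a two-state Markov chain:
#' the first marker is Bernoulli(0.5) and each subsequent marker flips with
#' probability `recomb_prob`. Strains are independent. This produces
#' realistic linkage blocks (and, at small strain counts, runs of identical
#' marker columns that exercise marker merging) without modelling meiosis
#' explicitly.
#'
#' @param cfg a `ril_sim_config`.
#' @return a `genotype_panel`.
#' @export
simulate_ril_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "ril_sim_config"))
  set.seed(cfg$seed)
  strains <- sprintf("RIL%02d", seq_len(cfg$n_strains))
  blocks <- list()
  meta <- list()
  for (ch in cfg$chromosomes) {
    m <- ch$n_markers
    calls <- matrix(0L, cfg$n_strains, m)
    calls[, 1] <- stats::rbinom(cfg$n_strains, 1, 0.5)
    if (m > 1) {
      for (j in 2:m) {
        flip <- stats::rbinom(cfg$n_strains, 1, cfg$recomb_prob)
        calls[, j] <- ifelse(flip == 1, 1L - calls[, j - 1], calls[, j - 1])
      }
    }
    pos <- as.integer(seq_len(m)) * as.integer(ch$marker_spacing_bp)
    ids <- sprintf("%s_m%03d", ch$name, seq_len(m))
    blocks[[ch$name]] <- calls
    meta[[ch$name]] <- data.frame(
      marker_id = ids, chromosome = ch$name,
      interval_start_bp = pos, interval_end_bp = pos,
      stringsAsFactors = FALSE
    )
  }
  calls <- do.call(cbind, blocks)
  markers <- do.call(rbind, meta)
  rownames(markers) <- NULL
  dimnames(calls) <- list(strains, markers$marker_id)
  markers$member_ids <- as.list(markers$marker_id)
  genotype_panel(calls, markers)
}

#' Specify a planted eQTL effect
#'
#' Effect classes follow the three-way taxonomy: a static eQTL has the same
#' nonzero allelic effect in every condition; a conditional eQTL has
#' condition-dependent effects (some zero, or unequal); a dynamic eQTL is
#' specified so that between-condition expression *differences* depend on
#' genotype (e.g. opposite-sign effects in the two conditions of a
#' transition).
#'
#' @param gene_id,marker_id target gene and causal marker id.
#' @param eqtl_class one of "static", "conditional", "dynamic".
#' @param beta named numeric vector, condition -> allelic effect (in
#'   expression-SD units: expression change for allele 1 vs allele 0).
#' @param noise_sd residual Gaussian noise SD (> 0 unless constructing
#'   noiseless algebra checks).
#' @param baseline named numeric vector, condition -> baseline expression.
#' @return an object of class `effect_spec`.
#' @export
effect_spec <- function(gene_id, marker_id, eqtl_class, beta, noise_sd,
                        baseline = NULL) {
  eqtl_class <- match.arg(eqtl_class, c("static", "conditional", "dynamic"))
  stopifnot(!is.null(names(beta)), noise_sd >= 0)
  b <- unname(beta)
  if (eqtl_class == "static" &&
      !(all(b == b[1]) && b[1] != 0)) {
    stop("static effect requires equal nonzero betas in all conditions")
  }
  if (eqtl_class == "conditional" &&
      all(b == b[1])) {
    stop("conditional effect requires unequal betas (or some zero)")
  }
  if (is.null(baseline)) baseline <- setNames(rep(0, length(beta)), names(beta))
  structure(list(gene_id = gene_id, marker_id = marker_id,
                 eqtl_class = eqtl_class, beta = beta,
                 noise_sd = noise_sd, baseline = baseline),
            class = "effect_spec")
}

#' Bundle effect specs and null genes into a truth set
#'
#' @param effects list of `effect_spec` objects.
#' @param null_genes character vector of gene ids with no genetic effect.
#' @param null_noise_sd noise SD used for null genes.
#' @return an object of class `truth_set`.
#' @export
truth_set <- function(effects, null_genes, null_noise_sd = 1) {
  eff_genes <- vapply(effects, function(e) e$gene_id, character(1))
  if (length(intersect(eff_genes, null_genes)) > 0) {
    stop("gene ids must be disjoint between effect and null lists")
  }
  if (anyDuplicated(eff_genes)) stop("duplicate effect gene ids")
  structure(list(effects = effects, null_genes = null_genes,
                 null_noise_sd = null_noise_sd),
            class = "truth_set")
}

#' Simulate multi-condition expression with planted effects
#'
#' The generative model per gene g, strain s, condition t is
#' `value = baseline[g,t] + beta[g,t] * call(s, marker_g) + eps`,
#' `eps ~ Normal(0, noise_sd^2)` i.i.d.; null genes have beta = 0
#' everywhere. Per-condition strain subsets emulate incomplete panels
#' (e.g. 22-24 of 25 strains measured per cell type).
#'
#' @param panel a `genotype_panel`.
#' @param truth a `truth_set`.
#' @param conditions character vector of condition labels (declared order).
#' @param strains_per_condition optional named list, condition -> strain id
#'   subset; default all panel strains in every condition.
#' @param baselines optional genes x conditions numeric matrix of
#'   additional per-gene condition baselines (added to every gene,
#'   including null genes, on top of any `effect_spec` baseline). Real
#'   cell-type panels show strong per-gene expression-level differences
#'   between cell types even after joint normalization — this is the
#'   between-condition structure that the stacked design's indicator
#'   predictors absorb.
#' @param seed integer RNG seed.
#' @return named list of `expression_panel` objects, one per condition.
#' @export
simulate_expression_panels <- function(panel, truth, conditions,
                                       strains_per_condition = NULL,
                                       baselines = NULL,
                                       seed = 1) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(truth, "truth_set"))
  for (e in truth$effects) {
    if (!e$marker_id %in% colnames(panel$calls)) {
      stop("effect marker not in genotype panel: ", e$marker_id)
    }
    if (!all(names(e$beta) %in% conditions)) {
      stop("unknown condition in effect spec for gene ", e$gene_id)
    }
  }
  if (is.null(strains_per_condition)) {
    strains_per_condition <- setNames(
      rep(list(panel$strains), length(conditions)), conditions)
  }
  genes <- c(vapply(truth$effects, function(e) e$gene_id, character(1)),
             truth$null_genes)
  if (!is.null(baselines)) {
    stopifnot(all(genes %in% rownames(baselines)),
              all(conditions %in% colnames(baselines)))
  }
  set.seed(seed)
  out <- list()
  for (t in conditions) {
    strains <- strains_per_condition[[t]]
    stopifnot(all(strains %in% panel$strains))
    values <- matrix(NA_real_, length(genes), length(strains),
                     dimnames = list(genes, strains))
    for (e in truth$effects) {
      g <- panel$calls[strains, e$marker_id]
      base <- if (t %in% names(e$baseline)) e$baseline[[t]] else 0
      b <- if (t %in% names(e$beta)) e$beta[[t]] else 0
      values[e$gene_id, ] <- base + b * g +
        stats::rnorm(length(strains), 0, e$noise_sd)
    }
    for (g0 in truth$null_genes) {
      values[g0, ] <- stats::rnorm(length(strains), 0, truth$null_noise_sd)
    }
    if (!is.null(baselines)) {
      values <- values + baselines[genes, t]
    }
    out[[t]] <- expression_panel(values, t)
  }
  out
}

#' Write a truth set as TSV
#'
#' Columns: gene_id, marker_id, class, one `beta_<condition>` column per
#' condition, noise_sd. Null genes appear with class "null" and empty
#' marker.
#'
#' @param truth a `truth_set`.
#' @param path output path.
#' @param conditions condition labels defining the beta columns.
#' @export
write_truth_set <- function(truth, path, conditions) {
  rows <- lapply(truth$effects, function(e) {
    betas <- vapply(conditions, function(t)
      if (t %in% names(e$beta)) e$beta[[t]] else 0, numeric(1))
    c(gene_id = e$gene_id, marker_id = e$marker_id, class = e$eqtl_class,
      setNames(as.character(betas), paste0("beta_", conditions)),
      noise_sd = as.character(e$noise_sd))
  })
  null_rows <- lapply(truth$null_genes, function(g) {
    c(gene_id = g, marker_id = "", class = "null",
      setNames(rep("0", length(conditions)), paste0("beta_", conditions)),
      noise_sd = as.character(truth$null_noise_sd))
  })
  tab <- as.data.frame(do.call(rbind, c(rows, null_rows)),
                       stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate a named fixture bundle
#'
#' Presets:
#' \describe{
#'   \item{default}{24 strains, 4 conditions (S, P, E, M), 100 markers on 5
#'     chromosomes, 120 genes: 20 static (beta = 1.5 SD), 20 single-condition
#'     conditional (beta = 2 SD), 10 dynamic sign-swap (beta = +1/-1 SD on
#'     the P/M pair), 70 null; 22-24 strains measured per condition.}
#'   \item{null-only}{same shape as default with no planted effects.}
#'   \item{tiny}{6 strains, 2 conditions, 10 markers, 8 genes; smoke-test
#'     scale.}
#' }
#' Effect sizes are in units of the per-gene noise SD (1.0 here), matching
#' what a well-powered microarray eQTL panel of this size can plausibly
#' resolve.
#'
#' @param preset "tiny", "default" or "null-only".
#' @param seed integer seed; the whole bundle is deterministic given it.
#' @param dir optional directory; when given, the TSV dialects plus
#'   `truth_set.tsv` and `gene_loci.tsv` are written there.
#' @return list with `geno` (`genotype_panel`), `panels` (list of
#'   `expression_panel`), `truth` (`truth_set`), `conditions`, and
#'   `gene_loci` (data.frame: gene_id, chromosome, start_bp, end_bp).
#' @export
make_fixture <- function(preset = c("default", "tiny", "null-only"),
                         seed = 1, dir = NULL) {
  preset <- match.arg(preset)
  if (preset == "tiny") {
    cfg <- ril_sim_config(
      n_strains = 6,
      chromosomes = list(list(name = "chr1", n_markers = 5,
                              marker_spacing_bp = 2.5e6),
                         list(name = "chr2", n_markers = 5,
                              marker_spacing_bp = 2.5e6)),
      recomb_prob = 0.2, seed = derive_seed(seed, 1))
    conditions <- c("A", "B")
    n_static <- 2; n_cond <- 2; n_dyn <- 1; n_null <- 3
    swap_pair <- c("A", "B")
    strains_k <- c(6, 6)
  } else {
    cfg <- ril_sim_config(
      n_strains = 24,
      chromosomes = lapply(1:5, function(i)
        list(name = paste0("chr", i), n_markers = 20,
             marker_spacing_bp = 2.5e6)),
      recomb_prob = 0.1, seed = derive_seed(seed, 1))
    conditions <- c("S", "P", "E", "M")
    if (preset == "default") {
      n_static <- 20; n_cond <- 20; n_dyn <- 10; n_null <- 70
    } else {
      n_static <- 0; n_cond <- 0; n_dyn <- 0; n_null <- 120
    }
    swap_pair <- c("P", "M")
    strains_k <- c(23, 24, 22, 23)
  }
  geno <- simulate_ril_genotypes(cfg)
  noise_sd <- 1
  n_eff <- n_static + n_cond + n_dyn
  n_genes <- n_eff + n_null
  gene_ids <- sprintf("gene%03d", seq_len(n_genes))

  # spread causal markers over the genome, deterministically
  set.seed(derive_seed(seed, 2))
  n_mark <- nrow(geno$markers)
  causal <- if (n_eff > 0) {
    idx <- round(seq(1, n_mark, length.out = n_eff + 2))[-c(1, n_eff + 2)]
    geno$markers$marker_id[idx]
  } else character(0)

  effects <- list()
  k <- 0
  for (i in seq_len(n_static)) {
    k <- k + 1
    effects[[k]] <- effect_spec(
      gene_ids[k], causal[k], "static",
      setNames(rep(1.5 * noise_sd, length(conditions)), conditions),
      noise_sd)
  }
  for (i in seq_len(n_cond)) {
    k <- k + 1
    active <- conditions[(i - 1) %% length(conditions) + 1]
    beta <- setNames(rep(0, length(conditions)), conditions)
    beta[active] <- 2 * noise_sd
    effects[[k]] <- effect_spec(gene_ids[k], causal[k], "conditional",
                                beta, noise_sd)
  }
  for (i in seq_len(n_dyn)) {
    k <- k + 1
    beta <- setNames(rep(0, length(conditions)), conditions)
    beta[swap_pair[1]] <- 1 * noise_sd
    beta[swap_pair[2]] <- -1 * noise_sd
    effects[[k]] <- effect_spec(gene_ids[k], causal[k], "dynamic",
                                beta, noise_sd)
  }
  truth <- truth_set(effects, gene_ids[seq_len(n_null) + n_eff],
                     null_noise_sd = noise_sd)

  # per-condition strain subsets (deterministic under seed)
  strains_per_condition <- list()
  for (i in seq_along(conditions)) {
    strains_per_condition[[conditions[i]]] <-
      sort(sample(geno$strains, strains_k[i]))
  }
  # per-gene cell-type baselines, SD 1 in noise units: cell types differ in
  # expression level for most genes even after joint normalization
  baselines <- matrix(stats::rnorm(n_genes * length(conditions)),
                      n_genes, length(conditions),
                      dimnames = list(gene_ids, conditions))
  panels <- simulate_expression_panels(
    geno, truth, conditions, strains_per_condition, baselines = baselines,
    seed = derive_seed(seed, 3))

  gene_loci <- fixture_gene_loci(geno, truth, gene_ids, seed)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_genotype_table(geno, file.path(dir, "genotypes.tsv"))
    for (t in conditions) {
      write_expression_table(panels[[t]],
                             file.path(dir, paste0("expression_", t, ".tsv")))
    }
    write_truth_set(truth, file.path(dir, "truth_set.tsv"), conditions)
    utils::write.table(gene_loci, file.path(dir, "gene_loci.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(geno = geno, panels = panels, truth = truth,
       conditions = conditions, gene_loci = gene_loci)
}

# Gene coordinates for cis/trans annotation: effect genes alternate between
# a locus at their causal marker (cis) and a locus on another chromosome
# (trans); null genes are placed uniformly.
fixture_gene_loci <- function(geno, truth, gene_ids, seed) {
  set.seed(derive_seed(seed, 4))
  chroms <- unique(geno$markers$chromosome)
  chr_len <- vapply(chroms, function(ch)
    max(geno$markers$interval_end_bp[geno$markers$chromosome == ch]),
    numeric(1))
  loci <- data.frame(gene_id = gene_ids, chromosome = NA_character_,
                     start_bp = NA_real_, end_bp = NA_real_,
                     stringsAsFactors = FALSE)
  eff_genes <- vapply(truth$effects, function(e) e$gene_id, character(1))
  for (i in seq_along(gene_ids)) {
    g <- gene_ids[i]
    ei <- match(g, eff_genes)
    if (!is.na(ei) && ei %% 2 == 1) {  # cis placement at the causal marker
      mrow <- match(truth$effects[[ei]]$marker_id, geno$markers$marker_id)
      loci$chromosome[i] <- geno$markers$chromosome[mrow]
      loci$start_bp[i] <- geno$markers$interval_start_bp[mrow]
      loci$end_bp[i] <- loci$start_bp[i] + 2e4
    } else {
      ch <- if (!is.na(ei)) {
        mrow <- match(truth$effects[[ei]]$marker_id, geno$markers$marker_id)
        sample(setdiff(chroms, geno$markers$chromosome[mrow]), 1)
      } else sample(chroms, 1)
      loci$chromosome[i] <- ch
      loci$start_bp[i] <- sample.int(max(chr_len[[ch]] - 2e4, 1), 1)
      loci$end_bp[i] <- loci$start_bp[i] + 2e4
    }
  }
  loci
}
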