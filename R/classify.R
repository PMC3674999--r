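# Static vs conditional discrimination: marker x condition interaction
# ANOVA on the stacked design, plus post-hoc per-condition Wald contrasts.

#' Full-vs-reduced interaction ANOVA for one marker
#'
#' Fits the full linear model `y ~ genotype * condition` (genotype vector
#' of the marker in the stacked design, condition as a factor) against the
#' reduced main-effects model `y ~ genotype + condition` and returns the
#' F test for the interaction:
#' `F = [(RSS_reduced - RSS_full)/df_delta] / [RSS_full/df_full]`.
#' A significant interaction means the marker's predictive value depends on
#' the condition — the signature of a conditional eQTL. Treatment
#' (reference-level) coding is used for the condition factor; F and the
#' Wald contrasts are invariant to the choice of full-rank coding.
#'
#' Degenerate rules (documented, deliberate): a zero-residual full fit
#' cannot support a claim of conditionality and reports p = 1; a marker
#' whose genotype is constant within every condition has no testable
#' interaction and reports NA with `degenerate = TRUE`.
#'
#' @param design a `stacked_design` with >= 2 conditions.
#' @param marker_id marker column to test.
#' @return list with `F_stat`, `p_interaction`, `df` (c(delta, full)),
#'   `fit` (the full `lm` fit, or NULL), `degenerate` flag.
#' @export
anova_interaction_test <- function(design, marker_id) {
  stopifnot(inherits(design, "stacked_design"),
            marker_id %in% colnames(design$X))
  cond <- factor(design$row_meta$condition, levels = design$conditions)
  if (nlevels(droplevels(cond)) < 2) stop("need >= 2 conditions")
  x <- design$X[, marker_id]
  by_cond <- tapply(x, cond, function(v) length(unique(v)))
  if (all(by_cond[!is.na(by_cond)] <= 1)) {
    return(list(F_stat = NA_real_, p_interaction = NA_real_,
                df = c(NA_real_, NA_real_), fit = NULL, degenerate = TRUE))
  }
  dat <- data.frame(y = design$Y, x = x, cond = droplevels(cond))
  fit_full <- stats::lm(y ~ x * cond, data = dat)
  fit_red <- stats::lm(y ~ x + cond, data = dat)
  rss_full <- sum(stats::residuals(fit_full)^2)
  rss_red <- sum(stats::residuals(fit_red)^2)
  df_full <- fit_full$df.residual
  df_delta <- fit_red$df.residual - df_full
  if (df_full < 1 || df_delta < 1) {
    return(list(F_stat = NA_real_, p_interaction = NA_real_,
                df = c(df_delta, df_full), fit = fit_full, degenerate = TRUE))
  }
  if (rss_full <= .Machine$double.eps * max(1, rss_red)) {
    # zero-residual fit: interaction untestable, never called conditional
    return(list(F_stat = NA_real_, p_interaction = 1,
                df = c(df_delta, df_full), fit = fit_full, degenerate = TRUE))
  }
  F_stat <- ((rss_red - rss_full) / df_delta) / (rss_full / df_full)
  p <- stats::pf(F_stat, df_delta, df_full, lower.tail = FALSE)
  list(F_stat = F_stat, p_interaction = p, df = c(df_delta, df_full),
       fit = fit_full, degenerate = FALSE)
}

#' Post-hoc Wald contrasts: which conditions is the eQTL active in?
#'
#' For each condition t, tests H0: beta_t = 0, where beta_t is the
#' per-condition genotype effect recovered from the full interaction model
#' (main genotype coefficient plus the interaction coefficient of t; for
#' the reference condition just the main coefficient), with its standard
#' error from the model covariance. Wald z = beta_t / se, two-sided normal
#' p, Bonferroni-corrected by the number of testable conditions of this
#' eQTL (the post-hoc family, not genome-wide). A condition with a single
#' genotype group has an undefined contrast: reported NA and excluded from
#' the Bonferroni count.
#'
#' @param anova result of [anova_interaction_test()] (needs `fit`).
#' @param alpha significance level for the adjusted p-values.
#' @return list with `beta` (named per-condition effects), `se`, `z`,
#'   `p_raw`, `p_adj` (Bonferroni), `active` (character vector of
#'   conditions with p_adj <= alpha).
#' @export
active_celltypes <- function(anova, alpha = 0.05) {
  fit <- anova$fit
  if (is.null(fit)) stop("ANOVA fit unavailable (degenerate marker)")
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  conds <- levels(fit$model$cond)
  x <- fit$model$x
  ccond <- fit$model$cond
  beta <- se <- setNames(rep(NA_real_, length(conds)), conds)
  for (i in seq_along(conds)) {
    t <- conds[i]
    if (length(unique(x[ccond == t])) < 2) next  # contrast undefined
    term <- paste0("x:cond", t)
    w <- setNames(numeric(length(cf)), names(cf))
    w["x"] <- 1
    if (term %in% names(cf)) w[term] <- 1
    if (anyNA(cf[w != 0])) next  # aliased coefficient
    beta[i] <- sum(w * cf)
    se[i] <- sqrt(drop(t(w) %*% V %*% w))
  }
  z <- beta / se
  p_raw <- 2 * stats::pnorm(-abs(z))
  n_test <- sum(!is.na(p_raw))
  p_adj <- pmin(1, p_raw * n_test)
  active <- conds[!is.na(p_adj) & p_adj <= alpha]
  list(beta = beta, se = se, z = z, p_raw = p_raw, p_adj = p_adj,
       active = active)
}

#' Label significant eQTL as static or conditional
#'
#' For every significant simultaneous (gene, marker) pair, computes the
#' interaction ANOVA, adjusts the interaction p-values by BH over exactly
#' that set of pairs, and labels a pair conditional iff its interaction
#' q-value is at most `fdr_threshold`, static otherwise (pairs with an
#' untestable interaction are labelled static: conditionality cannot be
#' claimed without a testable interaction). Conditional pairs get their
#' active-condition set from [active_celltypes()]; a conditional pair with
#' an empty active set is kept and flagged in the `no_active_flag` column.
#'
#' @param significant data.frame of significant pairs (columns gene_id,
#'   marker_id, and typically sf/p/q from [eqtl_test()]).
#' @param panels list of `expression_panel` objects.
#' @param geno a `genotype_panel`.
#' @param fdr_threshold interaction FDR threshold (default 0.1).
#' @param alpha post-hoc Wald contrast level (default 0.05).
#' @return the input data.frame with added columns: F_interaction,
#'   p_interaction, q_interaction, class ("static"/"conditional"),
#'   active_conditions (comma-joined), no_active_flag, and one
#'   `contrast_p_<condition>` column per condition (Bonferroni-adjusted).
#' @export
classify_static_conditional <- function(significant, panels, geno,
                                        fdr_threshold = 0.1, alpha = 0.05) {
  conditions <- vapply(panels, function(p) p$condition, character(1))
  n <- nrow(significant)
  out <- significant
  out$F_interaction <- NA_real_
  out$p_interaction <- NA_real_
  anovas <- vector("list", n)
  designs <- list()
  for (i in seq_len(n)) {
    g <- significant$gene_id[i]
    if (is.null(designs[[g]])) {
      designs[[g]] <- build_stacked_design(panels, geno, g)
    }
    a <- anova_interaction_test(designs[[g]], significant$marker_id[i])
    anovas[[i]] <- a
    out$F_interaction[i] <- a$F_stat
    out$p_interaction[i] <- a$p_interaction
  }
  testable <- !is.na(out$p_interaction)
  out$q_interaction <- NA_real_
  out$q_interaction[testable] <- bh_fdr(out$p_interaction[testable])
  out$class <- ifelse(!is.na(out$q_interaction) &
                        out$q_interaction <= fdr_threshold,
                      "conditional", "static")
  out$active_conditions <- ""
  out$no_active_flag <- FALSE
  for (t in conditions) out[[paste0("contrast_p_", t)]] <- NA_real_
  for (i in seq_len(n)) {
    if (is.null(anovas[[i]]$fit)) next
    # contrasts are computed for every testable pair (the region analysis
    # compares contrast p-value profiles of all targets of a locus); the
    # active-condition set is only meaningful for conditional pairs
    ct <- active_celltypes(anovas[[i]], alpha)
    for (t in names(ct$p_adj)) {
      out[[paste0("contrast_p_", t)]][i] <- ct$p_adj[[t]]
    }
    if (out$class[i] != "conditional") next
    out$active_conditions[i] <- paste(ct$active, collapse = ",")
    out$no_active_flag[i] <- length(ct$active) == 0
    if (out$no_active_flag[i]) {
      log_event("no_active_condition", "conditional pair ",
                out$gene_id[i], " / ", out$marker_id[i],
                " has no significant contrast")
    }
  }
  out
}
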