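#' Pooled two-proportion z-test
#'
#' Compares two binomial proportions with the pooled z statistic
#' \eqn{z = (\hat p_1 - \hat p_2) / \sqrt{\hat p (1-\hat p)(1/n_1 + 1/n_2)}}
#' and a two-sided normal p-value. When the pooled proportion is 0 or 1
#' the comparison is degenerate and `z = 0`, `p = 1` is returned with a
#' warning.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @return List with elements `z` and `p`.
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  pooled <- (x1 + x2) / (n1 + n2)
  if (pooled <= 0 || pooled >= 1) {
    warning("degenerate pooled proportion (all successes or all failures)")
    return(list(z = 0, p = 1))
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up BH adjustment (monotonicity enforced) of p-values in
#' (0, 1].
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values <= 0 | p_values > 1 | is.na(p_values)))
    stop("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Fisher's exact test on a 2x2 table with the cross-product odds ratio
#'
#' The p-value is the exact hypergeometric probability (one-sided greater,
#' or the usual two-sided sum of tables at most as probable); the odds
#' ratio is the sample cross-product \eqn{ad/bc}, reported as `Inf` when
#' `bc = 0` and `ad > 0`, and `NaN` when both products vanish.
#'
#' @param tab 2x2 matrix of non-negative integer counts
#'   (rows: condition yes/no, columns: outcome yes/no).
#' @param sided `"greater"` (enrichment) or `"two"`.
#' @return List with `odds_ratio` and `p`.
#' @export
fisher_exact <- function(tab, sided = c("greater", "two")) {
  sided <- match.arg(sided)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2)) || any(tab < 0) || any(tab != round(tab)))
    stop("tab must be a 2x2 matrix of non-negative integer counts")
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  odds_ratio <- if (b * c_ > 0) (a * d) / (b * c_)
  else if (a * d > 0) Inf else NaN
  p <- if (sided == "greater") {
    phyper(a - 1, a + b, c_ + d, a + c_, lower.tail = FALSE)
  } else {
    fisher.test(tab)$p.value
  }
  list(odds_ratio = odds_ratio, p = min(p, 1))
}

#' TF enrichment in cytokines expressed in specific immune cell types
#'
#' For every (TF, cell type) pair, compares the proportion of the TF's
#' cytokine targets expressed in that cell type against the corresponding
#' proportion among all other TFs' target PDIs, with a pooled
#' two-proportion z-test; p-values are BH-adjusted across all pairs.
#' TFs with fewer than `min_targets` targets are skipped (degenerate
#' proportions) and listed in the `"skipped"` attribute.
#'
#' @param grn A [cytokine_grn()].
#' @param cyt_celltypes Data frame with columns `cytokine` and `cell_type`
#'   (one row per cytokine/cell-type membership; cytokines may be absent).
#' @param fdr FDR threshold for the `significant` flag (default 0.1).
#' @param min_targets Minimum TF degree to be tested.
#' @return Data frame: `tf`, `cell_type`, `x1`, `n1`, `x2`, `n2`, `z`,
#'   `p`, `p_adj`, `significant`.
#' @export
celltype_enrichment <- function(grn, cyt_celltypes, fdr = 0.1,
                                min_targets = 2) {
  if (nrow(cyt_celltypes) == 0) {
    warning("empty cell-type annotation; no enrichment computed")
    return(data.frame())
  }
  cell_types <- unique(cyt_celltypes$cell_type)
  member <- lapply(setNames(cell_types, cell_types), function(ct)
    unique(cyt_celltypes$cytokine[cyt_celltypes$cell_type == ct]))
  targets_of <- split(grn$records$cytokine, grn$records$tf)
  deg <- lengths(targets_of)
  skipped <- names(deg)[deg < min_targets]
  tfs <- names(deg)[deg >= min_targets]
  rows <- list()
  for (tf in tfs) {
    t_tf <- targets_of[[tf]]
    others <- unlist(targets_of[setdiff(names(targets_of), tf)],
                     use.names = FALSE)
    for (ct in cell_types) {
      x1 <- sum(t_tf %in% member[[ct]]); n1 <- length(t_tf)
      x2 <- sum(others %in% member[[ct]]); n2 <- length(others)
      pt <- suppressWarnings(proportion_test(x1, n1, x2, n2))
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, cell_type = ct, x1 = x1, n1 = n1, x2 = x2, n2 = n2,
        z = pt$z, p = pt$p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    warning("no testable (TF, cell type) pair")
    return(data.frame())
  }
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < fdr
  attr(out, "skipped") <- skipped
  out
}

#' TF-disease enrichment over disease-upregulated cytokine sets
#'
#' For each (TF, disease) pair a 2x2 table is built over the cytokine
#' universe (upregulated in the disease yes/no by target of the TF yes/no)
#' and tested with a one-sided (greater) Fisher's exact test; BH adjustment
#' is applied jointly across all TF-by-disease pairs, with significance
#' called at adjusted p below `fdr` (default 0.1).
#'
#' @param grn A [cytokine_grn()].
#' @param disease_sets Named list: disease -> character vector of
#'   upregulated cytokines (subsets of the universe). Empty sets skipped.
#' @param cytokine_universe Character vector of all considered cytokines.
#' @param fdr FDR threshold.
#' @param sided Passed to [fisher_exact()].
#' @return Data frame: `tf`, `disease`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p`, `p_adj`, `significant`.
#' @export
disease_enrichment <- function(grn, disease_sets, cytokine_universe,
                               fdr = 0.1, sided = "greater") {
  cytokine_universe <- unique(toupper(cytokine_universe))
  disease_sets <- disease_sets[lengths(disease_sets) > 0]
  targets_of <- lapply(split(grn$records$cytokine, grn$records$tf),
                       unique)
  rows <- list()
  for (tf in names(targets_of)) {
    targ <- intersect(targets_of[[tf]], cytokine_universe)
    for (dis in names(disease_sets)) {
      up <- intersect(toupper(disease_sets[[dis]]), cytokine_universe)
      a <- length(intersect(up, targ))
      b <- length(up) - a
      c_ <- length(targ) - a
      d <- length(cytokine_universe) - length(up) - c_
      ft <- fisher_exact(matrix(c(a, c_, b, d), 2, 2), sided = sided)
      rows[[length(rows) + 1L]] <- data.frame(
        tf = tf, disease = dis, a = a, b = b, c = c_, d = d,
        odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out$significant <- out$p_adj < fdr
  out
}

#' Compare per-group PDI shares against a reference GRN
#'
#' Computes, for each TF group (family or PSA flag), the percentage of all
#' PDIs in the cytokine GRN involving the group's TFs and the corresponding
#' percentage in a reference network given as per-TF PDI counts, plus the
#' Pearson correlation of the two percentage vectors across groups.
#'
#' @param grn A [cytokine_grn()].
#' @param reference_pdi_counts Named numeric vector: TF -> PDI count in the
#'   reference GRN.
#' @param groups Named character vector: TF -> group label.
#' @return List with `table` (data frame `group`, `pct_grn`, `pct_ref`)
#'   and `pearson_r`.
#' @export
family_comparison <- function(grn, reference_pdi_counts, groups) {
  if (length(reference_pdi_counts) == 0 || sum(reference_pdi_counts) == 0)
    stop("empty reference network")
  total_grn <- sum(grn$tf_degree)
  total_ref <- sum(reference_pdi_counts)
  gl <- sort(unique(groups))
  tab <- do.call(rbind, lapply(gl, function(g) {
    tfs <- names(groups)[groups == g]
    data.frame(
      group = g,
      pct_grn = 100 * sum(grn$tf_degree[intersect(tfs, names(grn$tf_degree))]) /
        total_grn,
      pct_ref = 100 * sum(reference_pdi_counts[intersect(tfs, names(reference_pdi_counts))]) /
        total_ref,
      stringsAsFactors = FALSE)
  }))
  r <- if (nrow(tab) >= 3 && stats::sd(tab$pct_grn) > 0 &&
           stats::sd(tab$pct_ref) > 0)
    cor(tab$pct_grn, tab$pct_ref) else NA_real_
  list(table = tab, pearson_r = r)
}

#' Fraction of phenotype-flagged TFs per connectivity bin
#'
#' Bins TFs by cytokine-target degree and reports the fraction carrying a
#' phenotype flag (e.g. immune knockout phenotype, HGMD or GWAS immune
#' disorder, or PSA status) in each bin. TFs named in `tf_flags` but
#' absent from the network populate the degree-0 bin; network TFs missing
#' from `tf_flags` are treated as unflagged and counted in the
#' `"unflagged_missing"` attribute.
#'
#' @param grn A [cytokine_grn()].
#' @param tf_flags Named logical vector: TF -> flag.
#' @param edges Degree bin edges, see [degree_bin()].
#' @return Data frame `bin`, `n`, `n_flagged`, `fraction`, with a
#'   `"spearman_rho"` attribute (degree vs flag).
#' @export
connectivity_phenotype <- function(grn, tf_flags,
                                   edges = c(0, 1, 2, 5, 10)) {
  tfs <- union(names(grn$tf_degree), names(tf_flags))
  degree <- ifelse(tfs %in% names(grn$tf_degree), grn$tf_degree[tfs], 0L)
  flag <- tf_flags[tfs]
  missing <- tfs[is.na(flag)]
  flag[is.na(flag)] <- FALSE
  bin <- degree_bin(degree, edges)
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    idx <- bin == b
    data.frame(bin = b, n = sum(idx), n_flagged = sum(flag[idx]),
               fraction = if (any(idx)) mean(flag[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  attr(out, "spearman_rho") <-
    suppressWarnings(cor(degree, as.numeric(flag), method = "spearman"))
  attr(out, "unflagged_missing") <- missing
  out
}

#' Cofactor usage across cytokines and TF classes
#'
#' Counts, for every (cytokine, cofactor) pair, the distinct TFs that both
#' interact with the cytokine gene in the GRN and bind the cofactor; and,
#' per cofactor, the fraction of its classified TF partners that are PSA
#' vs TS.
#'
#' @param grn A [cytokine_grn()].
#' @param tf_cofactor Data frame with columns `tf` and `cofactor`
#'   (optionally `domain`, used instead of `cofactor` when
#'   `by_domain = TRUE`).
#' @param tf_class Named character vector: TF -> `"PSA"`, `"TS"` or
#'   `"other"`.
#' @param by_domain Count by cofactor domain instead of cofactor.
#' @return List with `cytokine_cofactor_counts` (data frame `cytokine`,
#'   `cofactor`, `n_tfs`) and `cofactor_class_fractions` (data frame
#'   `cofactor`, `n_classified`, `frac_psa`, `frac_ts`).
#' @export
cofactor_usage <- function(grn, tf_cofactor, tf_class, by_domain = FALSE) {
  unit <- if (by_domain) tf_cofactor$domain else tf_cofactor$cofactor
  links <- unique(data.frame(tf = tf_cofactor$tf, cofactor = unit,
                             stringsAsFactors = FALSE))
  tf_by_cyt <- split(grn$records$tf, grn$records$cytokine)
  counts <- list()
  for (cyt in names(tf_by_cyt)) {
    for (cof in unique(links$cofactor)) {
      n <- length(intersect(tf_by_cyt[[cyt]],
                            links$tf[links$cofactor == cof]))
      if (n > 0)
        counts[[length(counts) + 1L]] <- data.frame(
          cytokine = cyt, cofactor = cof, n_tfs = n,
          stringsAsFactors = FALSE)
    }
  }
  fr <- do.call(rbind, lapply(unique(links$cofactor), function(cof) {
    partners <- unique(links$tf[links$cofactor == cof])
    cls <- tf_class[intersect(partners, names(tf_class))]
    cls <- cls[cls %in% c("PSA", "TS")]
    data.frame(cofactor = cof, n_classified = length(cls),
               frac_psa = if (length(cls)) mean(cls == "PSA") else NA_real_,
               frac_ts = if (length(cls)) mean(cls == "TS") else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(cytokine_cofactor_counts =
         if (length(counts)) do.call(rbind, counts) else data.frame(),
       cofactor_class_fractions = fr)
}

#' Per-cytokine counts of drug-targetable TFs
#'
#' Drug actions are grouped: agonists and activators count as agonists,
#' antagonists and inhibitors as antagonists; other labels are logged and
#' ignored. For every cytokine the number of distinct interacting TFs
#' targetable in each mode is reported (TFs with drugs of both modes count
#' in both).
#'
#' @param grn A [cytokine_grn()].
#' @param tf_drugs Data frame with columns `tf`, `drug`, `action`.
#' @return Data frame `cytokine`, `n_agonist_tfs`, `n_antagonist_tfs`,
#'   with unknown action labels in the `"unknown_actions"` attribute.
#' @export
drug_targetability <- function(grn, tf_drugs) {
  action <- tolower(tf_drugs$action)
  mode <- rep(NA_character_, length(action))
  mode[action %in% c("agonist", "activator")] <- "agonist"
  mode[action %in% c("antagonist", "inhibitor")] <- "antagonist"
  unknown <- unique(action[is.na(mode) & !action %in% "other"])
  agonist_tfs <- unique(tf_drugs$tf[mode == "agonist" & !is.na(mode)])
  antagonist_tfs <- unique(tf_drugs$tf[mode == "antagonist" & !is.na(mode)])
  tf_by_cyt <- split(grn$records$tf, grn$records$cytokine)
  out <- do.call(rbind, lapply(names(tf_by_cyt), function(cyt) {
    tfs <- unique(tf_by_cyt[[cyt]])
    data.frame(cytokine = cyt,
               n_agonist_tfs = length(intersect(tfs, agonist_tfs)),
               n_antagonist_tfs = length(intersect(tfs, antagonist_tfs)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "unknown_actions") <- unknown
  out
}
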