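#' Read a gene-by-tissue expression matrix
#'
#' @param path TSV with genes in the first column and one column per tissue
#'   (TPM or equivalent, non-negative).
#' @return Numeric matrix, rows = genes (upper-cased), columns = tissues.
#' @export
read_expression_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- toupper(trimws(df[[1]]))
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  m
}

#' Read tissue immune/non-immune flags
#'
#' @param path Two-column TSV: tissue, flag (`immune` / `non_immune`).
#' @return Named character vector of flags.
#' @export
read_tissue_flags <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1, 2]) %in% c("flag", "class")) df <- df[-1, , drop = FALSE]
  setNames(df[[2]], df[[1]])
}

#' Tissue-specificity score (TSPS)
#'
#' Entropy-based divergence of a gene's expression ratios from uniform
#' across tissues, in bits:
#' \deqn{TSPS = \sum_i p_i \log_2(p_i / p)}
#' where \eqn{p_i} is the ratio between the expression level in tissue
#' \eqn{i} and the sum across all \eqn{T} tissues and \eqn{p = 1/T} is the
#' expected ratio under uniform expression. Zero ratios contribute 0
#' (the usual entropy convention). A gene is called tissue-specific (TS)
#' when its TSPS meets the threshold (default 0.7).
#'
#' @param profile Non-negative per-tissue expression vector, length >= 2.
#' @param threshold TS call cut-off in bits.
#' @return List of class `tsps_result`: `tsps`, `p_i`, `p`, `is_ts`.
#' @export
tsps <- function(profile, threshold = 0.7) {
  profile <- as.numeric(profile)
  if (length(profile) < 2) stop("profile must cover at least 2 tissues")
  if (any(profile < 0) || anyNA(profile)) stop("profile must be non-negative")
  total <- sum(profile)
  if (total == 0)
    stop("TSPS undefined for an all-zero expression profile")
  p_i <- profile / total
  p <- 1 / length(profile)
  terms <- ifelse(p_i > 0, p_i * log2(p_i / p), 0)
  score <- sum(terms)
  structure(list(tsps = score, p_i = p_i, p = p,
                 is_ts = score >= threshold),
            class = "tsps_result")
}

#' TSPS for every row of an expression matrix
#'
#' Genes with all-zero profiles (score undefined) are dropped with a
#' message, mirroring the exclusion of genes without usable expression.
#'
#' @param expr Gene-by-tissue matrix.
#' @inheritParams tsps
#' @return Named numeric vector of scores.
#' @export
tsps_scores <- function(expr, threshold = 0.7) {
  ok <- rowSums(expr) > 0
  if (any(!ok))
    message(sum(!ok), " gene(s) with all-zero profiles excluded from TSPS")
  vapply(rownames(expr)[ok],
         function(g) tsps(expr[g, ], threshold)$tsps, numeric(1))
}

#' Expression enrichment score (EES) in immune vs non-immune tissues
#'
#' A pseudocount of 1 is added to every expression value (damping noise
#' from low-abundance transcripts), each tissue's value is divided by the
#' gene's mean pseudocounted expression across all tissues, and the
#' per-tissue enrichments are averaged within the immune and the
#' non-immune tissue sets.
#'
#' @param profile Per-tissue expression vector with tissue names.
#' @param tissue_flags Named character vector, `immune` / `non_immune`,
#'   covering every tissue in `profile`.
#' @return Named numeric vector `c(immune = ..., non_immune = ...)`.
#' @export
expression_enrichment <- function(profile, tissue_flags) {
  tissues <- names(profile)
  if (is.null(tissues)) stop("profile must have tissue names")
  missing <- setdiff(tissues, names(tissue_flags))
  if (length(missing) > 0)
    stop("no immune flag for tissue(s): ", paste(missing, collapse = ", "))
  flags <- tissue_flags[tissues]
  if (!any(flags == "immune") || !any(flags == "non_immune"))
    stop("need at least one immune and one non-immune tissue")
  e <- as.numeric(profile) + 1
  enr <- e / mean(e)
  c(immune = mean(enr[flags == "immune"]),
    non_immune = mean(enr[flags == "non_immune"]))
}

#' Inflammatory score (IS) of a TF
#'
#' The difference between the fraction of the TF's distinct cytokine
#' targets that are canonical pro-inflammatory cytokines and the fraction
#' that are anti-inflammatory cytokines, on the \eqn{[-1, 1]} scale.
#' TFs with IS >= 0.5 are banded `pro`, IS <= -0.5 `anti`.
#'
#' @param grn A [cytokine_grn()].
#' @param tf TF symbol present in the network.
#' @param pro_list,anti_list Disjoint cytokine panels; defaults are
#'   [pro_inflammatory_cytokines] and [anti_inflammatory_cytokines].
#' @return List of class `inflammatory_score`: `is_value`, `n_pro`,
#'   `n_anti`, `n_total`, `band` (`pro` / `anti` / `none`).
#' @export
inflammatory_score <- function(grn, tf,
                               pro_list = pro_inflammatory_cytokines,
                               anti_list = anti_inflammatory_cytokines) {
  if (length(intersect(pro_list, anti_list)) > 0)
    stop("pro and anti cytokine lists must be disjoint")
  targets <- unique(grn$records$cytokine[grn$records$tf == tf])
  if (length(targets) == 0) stop("TF not present in the network: ", tf)
  n_pro <- sum(targets %in% pro_list)
  n_anti <- sum(targets %in% anti_list)
  is_value <- n_pro / length(targets) - n_anti / length(targets)
  band <- if (is_value >= 0.5) "pro" else if (is_value <= -0.5) "anti" else "none"
  structure(list(is_value = is_value, n_pro = n_pro, n_anti = n_anti,
                 n_total = length(targets), band = band),
            class = "inflammatory_score")
}

#' Label degrees with the default connectivity bins
#'
#' Bin edges are the lower bounds of each bin; the default
#' `c(0, 1, 2, 5, 10)` yields bins 0, 1, 2-4, 5-9 and 10+.
#'
#' @param degree Integer vector of degrees.
#' @param edges Increasing integer lower bin bounds starting at 0.
#' @return Factor of bin labels.
#' @export
degree_bin <- function(degree, edges = c(0, 1, 2, 5, 10)) {
  if (length(edges) == 0) stop("empty bin set")
  edges <- sort(unique(as.integer(edges)))
  upper <- c(edges[-1] - 1L, Inf)
  labels <- ifelse(is.infinite(upper), paste0(edges, "+"),
                   ifelse(upper == edges, as.character(edges),
                          paste0(edges, "-", upper)))
  cut(degree, breaks = c(edges, Inf), labels = labels, right = FALSE)
}

#' Median immune-cell expression of TFs grouped by connectivity
#'
#' For each TF in the expression matrix, takes the median expression across
#' the immune cell columns (all columns when no flags are given) and groups
#' TFs by their cytokine-target degree bin. TFs present in the matrix but
#' absent from the network form the degree-0 bin; network TFs missing from
#' the matrix are skipped and counted in the `"skipped"` attribute.
#'
#' @param grn A [cytokine_grn()].
#' @param expr TF-by-tissue expression matrix.
#' @param tissue_flags Optional named flags selecting `immune` columns.
#' @param edges Degree bin edges, see [degree_bin()].
#' @return Data frame with columns `tf`, `degree`, `bin`, `median_expr`.
#' @export
expression_by_degree <- function(grn, expr, tissue_flags = NULL,
                                 edges = c(0, 1, 2, 5, 10)) {
  cols <- colnames(expr)
  if (!is.null(tissue_flags))
    cols <- cols[tissue_flags[cols] == "immune"]
  if (length(cols) == 0) stop("no immune columns available")
  tfs <- rownames(expr)
  degree <- ifelse(tfs %in% names(grn$tf_degree),
                   grn$tf_degree[tfs], 0L)
  skipped <- setdiff(names(grn$tf_degree), tfs)
  out <- data.frame(
    tf = tfs, degree = as.integer(degree),
    bin = degree_bin(degree, edges),
    median_expr = apply(expr[, cols, drop = FALSE], 1, median),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped") <- skipped
  out
}
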