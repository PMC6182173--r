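#' Co-expression provider over an expression compendium
#'
#' Emulates a co-expression search service: given a query gene set, every
#' other gene in the compendium is scored by its mean Fisher-z-transformed
#' Pearson correlation with the query genes across samples, and genes are
#' returned best first. The ranking is deterministic for fixed inputs;
#' query genes are excluded and zero-variance genes are dropped.
#'
#' @param expr Gene-by-sample numeric matrix (log-scale expression).
#' @return A function `(query, top_n)` of class `coexpression_provider`
#'   returning a character vector of ranked genes.
#' @export
coexpression_provider <- function(expr) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  force(expr)
  structure(function(query, top_n = 100) {
    query <- intersect(toupper(query), rownames(expr))
    if (length(query) == 0) stop("no query gene present in the compendium")
    if (top_n <= 0) return(character(0))
    others <- setdiff(rownames(expr), query)
    cm <- suppressWarnings(
      cor(t(expr[others, , drop = FALSE]), t(expr[query, , drop = FALSE])))
    z <- atanh(pmin(pmax(cm, -1 + 1e-12), 1 - 1e-12))
    score <- rowMeans(z, na.rm = FALSE)
    score <- score[is.finite(score)]
    ranked <- names(score)[order(-score, names(score))]
    head(ranked, top_n)
  }, class = c("coexpression_provider", "function"))
}

#' Rank genes co-expressed with a TF's known targets
#'
#' Queries the provider with the TF's known cytokine targets (at least
#' two required) and returns the top `top_n` co-expressed genes, best
#' first (the reference workflow used the top 100).
#'
#' @param provider A [coexpression_provider()] (or compatible function).
#' @param known_targets Character vector of the TF's known targets
#'   (length >= 2).
#' @param top_n Cut-off (default 100).
#' @return Character vector of ranked genes (shorter than `top_n` with a
#'   warning when the compendium is exhausted).
#' @export
rank_coexpressed <- function(provider, known_targets, top_n = 100) {
  if (length(unique(known_targets)) < 2)
    stop("need at least two known targets to query co-expression")
  out <- provider(unique(known_targets), top_n)
  if (length(out) < top_n)
    warning("fewer than ", top_n, " co-expressed genes available")
  out
}

#' Confidence tier of a retained PDI prediction
#'
#' Tiers: `high` = two or more binding sites and evidence of the
#' interaction in the mouse GRN; `medium` = two or more sites without
#' mouse evidence, or a single site with mouse evidence; `low` = a single
#' site without mouse evidence. Candidates without any binding site are
#' filtered before tiering, so `n_sites >= 1` is required.
#'
#' @param n_sites Integer vector of binding-site counts (>= 1).
#' @param in_mouse Logical vector: orthologous PDI present in the mouse
#'   GRN.
#' @return Character vector of tiers.
#' @export
confidence_tier <- function(n_sites, in_mouse) {
  stopifnot(all(n_sites >= 1), length(n_sites) == length(in_mouse))
  ifelse(n_sites >= 2 & in_mouse, "high",
         ifelse(n_sites >= 2 | in_mouse, "medium", "low"))
}

#' Predict novel PDIs from co-expression and promoter motifs
#'
#' For every TF with at least two known human targets and an available
#' PWM: (i) the top `top_n` genes co-expressed with the known targets are
#' retrieved from the provider; (ii) cytokines among them that are not
#' already targets become candidates; (iii) candidates are retained when
#' the TF has at least one binding site (log-odds >= `threshold`) in the
#' candidate's promoter; (iv) the confidence tier combines the site count
#' with the presence of the orthologous interaction in the mouse GRN.
#' TFs without a PWM are skipped and listed in the `"skipped"` attribute.
#'
#' @param grn_human,grn_mouse [cytokine_grn()] objects.
#' @param provider A [coexpression_provider()].
#' @param pwms Named list of `pwm` objects, one per TF symbol.
#' @param promoters Named character vector of promoter sequences covering
#'   the cytokine universe.
#' @param cytokine_universe Character vector of candidate cytokines.
#' @param top_n Co-expression cut-off (default 100).
#' @param threshold Motif log-odds threshold (default 10).
#' @param ortholog_map Optional named vector mapping human symbols to
#'   mouse symbols for the mouse-evidence lookup.
#' @return Data frame of class `pdi_predictions`: `tf`, `cytokine`,
#'   `coexpr_rank`, `n_sites`, `in_mouse`, `confidence`, with the tested
#'   TFs in the `"tfs_tested"` attribute.
#' @export
predict_pdis <- function(grn_human, grn_mouse, provider, pwms, promoters,
                         cytokine_universe, top_n = 100, threshold = 10,
                         ortholog_map = NULL) {
  promoters <- as_promoter_vector(promoters)
  cytokine_universe <- unique(toupper(cytokine_universe))
  targets_of <- lapply(split(grn_human$records$cytokine,
                             grn_human$records$tf), unique)
  eligible <- names(targets_of)[lengths(targets_of) >= 2]
  skipped <- setdiff(eligible, names(pwms))
  tfs <- intersect(eligible, names(pwms))
  map_sym <- function(s) {
    if (is.null(ortholog_map)) return(s)
    hit <- s %in% names(ortholog_map)
    s[hit] <- unname(ortholog_map[s[hit]])
    s
  }
  mouse_pairs <- paste(map_sym(grn_mouse$records$tf),
                       map_sym(grn_mouse$records$cytokine), sep = "\r")
  rows <- list()
  for (tf in tfs) {
    ranked <- suppressWarnings(
      rank_coexpressed(provider, targets_of[[tf]], top_n))
    cand <- setdiff(intersect(ranked, cytokine_universe), targets_of[[tf]])
    cand <- intersect(cand, names(promoters))
    if (length(cand) == 0) next
    n_sites <- count_sites(pwms[[tf]], promoters[cand], threshold)
    keep <- n_sites >= 1
    if (!any(keep)) next
    cand <- cand[keep]
    in_mouse <- paste(map_sym(rep(tf, length(cand))), map_sym(cand),
                      sep = "\r") %in% mouse_pairs
    rows[[length(rows) + 1L]] <- data.frame(
      tf = tf, cytokine = cand,
      coexpr_rank = match(cand, ranked),
      n_sites = as.integer(n_sites[keep]),
      in_mouse = in_mouse,
      confidence = confidence_tier(n_sites[keep], in_mouse),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(tf = character(0), cytokine = character(0),
                  coexpr_rank = integer(0), n_sites = integer(0),
                  in_mouse = logical(0), confidence = character(0))
  rownames(out) <- NULL
  attr(out, "tfs_tested") <- tfs
  attr(out, "skipped") <- skipped
  class(out) <- c("pdi_predictions", "data.frame")
  out
}

#' Enrichment of predictions among mouse-reported interactions
#'
#' Builds the 2x2 table predicted yes/no by present-in-mouse yes/no over
#' the candidate universe (all testable TF-cytokine pairs minus known
#' human PDIs), and reports the cross-product odds ratio with a
#' chi-square p-value (no continuity correction by default).
#'
#' @param predictions A `pdi_predictions` data frame.
#' @param grn_human,grn_mouse [cytokine_grn()] objects.
#' @param cytokine_universe Candidate cytokines.
#' @param tfs Tested TFs (defaults to the `"tfs_tested"` attribute of
#'   `predictions`).
#' @param correct Apply Yates continuity correction.
#' @param ortholog_map Optional human-to-mouse symbol map.
#' @return List: `table` (2x2 matrix), `odds_ratio` (cross-product,
#'   `Inf` when the discordant product vanishes), `odds_ratio_ha`
#'   (Haldane-Anscombe +0.5 estimator, always finite), `statistic`, `p`.
#' @export
mouse_enrichment <- function(predictions, grn_human, grn_mouse,
                             cytokine_universe,
                             tfs = attr(predictions, "tfs_tested"),
                             correct = FALSE, ortholog_map = NULL) {
  cytokine_universe <- unique(toupper(cytokine_universe))
  if (is.null(tfs)) tfs <- unique(predictions$tf)
  map_sym <- function(s) {
    if (is.null(ortholog_map)) return(s)
    hit <- s %in% names(ortholog_map)
    s[hit] <- unname(ortholog_map[s[hit]])
    s
  }
  univ <- expand.grid(tf = tfs, cytokine = cytokine_universe,
                      stringsAsFactors = FALSE)
  known <- paste(grn_human$records$tf, grn_human$records$cytokine,
                 sep = "\r")
  key <- paste(univ$tf, univ$cytokine, sep = "\r")
  univ <- univ[!key %in% known, , drop = FALSE]
  key <- paste(univ$tf, univ$cytokine, sep = "\r")
  predicted <- key %in% paste(predictions$tf, predictions$cytokine,
                              sep = "\r")
  mouse_pairs <- paste(map_sym(grn_mouse$records$tf),
                       map_sym(grn_mouse$records$cytokine), sep = "\r")
  in_mouse <- paste(map_sym(univ$tf), map_sym(univ$cytokine),
                    sep = "\r") %in% mouse_pairs
  tab <- matrix(c(sum(predicted & in_mouse), sum(predicted & !in_mouse),
                  sum(!predicted & in_mouse), sum(!predicted & !in_mouse)),
                nrow = 2, byrow = TRUE,
                dimnames = list(predicted = c("yes", "no"),
                                in_mouse = c("yes", "no")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("odds ratio undefined: zero margin in table\n",
         paste(capture.output(print(tab)), collapse = "\n"))
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  odds_ratio <- if (b * c_ > 0) (a * d) / (b * c_)
  else if (a * d > 0) Inf else NaN
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(table = tab, odds_ratio = odds_ratio,
       odds_ratio_ha = ((a + 0.5) * (d + 0.5)) /
         ((b + 0.5) * (c_ + 0.5)),
       statistic = unname(ct$statistic), p = ct$p.value)
}
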