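#' Expand a gene alias into spelling variants
#'
#' Generates the surface-form variants used for literature triage:
#' hyphen / space / no-separator variants at each token boundary, and
#' Greek letter vs spelled-name variants (alpha, beta, gamma, delta,
#' epsilon, kappa, lambda). All variants are lower-cased and de-duplicated.
#' When an alias has more than four token boundaries only the uniform
#' separator substitutions are produced, to keep the expansion bounded.
#'
#' @param symbol Canonical gene symbol the variants map to.
#' @param aliases Character vector of surface names (defaults to the symbol).
#' @return Named character vector: names are lower-case surface variants,
#'   values are the canonical symbol.
#' @export
expand_aliases <- function(symbol, aliases = symbol) {
  stopifnot(nzchar(symbol))
  variants <- character(0)
  for (a in tolower(trimws(aliases))) {
    if (!nzchar(a)) next
    greek <- a
    for (nm in names(greek_letter_map)) {
      letter <- greek_letter_map[[nm]]
      greek <- unique(c(greek,
                        unlist(lapply(greek, gsub, pattern = nm,
                                      replacement = letter, fixed = TRUE)),
                        unlist(lapply(greek, gsub, pattern = letter,
                                      replacement = nm, fixed = TRUE))))
    }
    for (g in greek) {
      tokens <- strsplit(g, "[- ]+")[[1]]
      k <- length(tokens) - 1
      if (k == 0) {
        variants <- c(variants, g)
      } else if (k <= 4) {
        seps <- expand.grid(rep(list(c("-", " ", "")), k),
                            stringsAsFactors = FALSE)
        for (i in seq_len(nrow(seps))) {
          parts <- character(2 * k + 1)
          parts[seq(1, 2 * k + 1, by = 2)] <- tokens
          parts[seq(2, 2 * k, by = 2)] <- unlist(seps[i, ])
          variants <- c(variants, paste(parts, collapse = ""))
        }
      } else {
        variants <- c(variants,
                      gsub("[- ]+", "-", g),
                      gsub("[- ]+", " ", g),
                      gsub("[- ]+", "", g))
      }
    }
  }
  variants <- unique(variants[nzchar(variants)])
  setNames(rep(toupper(symbol), length(variants)), variants)
}

#' Build a matching lexicon for one term category
#'
#' @param entries Named character vector (surface term, lower case ->
#'   canonical symbol), e.g. concatenated [expand_aliases()] results, or a
#'   two-column data frame `(term, symbol)`.
#' @param category One of `"tf"`, `"cytokine"`, `"assay"`.
#' @return A `lexicon` object.
#' @export
build_lexicon <- function(entries, category = c("tf", "cytokine", "assay")) {
  category <- match.arg(category)
  if (is.data.frame(entries))
    entries <- setNames(toupper(entries[[2]]), tolower(entries[[1]]))
  names(entries) <- tolower(names(entries))
  if (length(entries) == 0) stop("empty lexicon for category ", category)
  dup <- tapply(entries, names(entries), function(x) length(unique(x)))
  if (any(dup > 1))
    stop("surface term(s) map to multiple symbols in ", category,
         " lexicon: ", paste(names(dup)[dup > 1], collapse = ", "))
  entries <- entries[!duplicated(names(entries))]
  structure(list(entries = entries, category = category), class = "lexicon")
}

#' Read a two-column term/symbol lexicon file
#'
#' @param path TSV with columns term and symbol (no header required if two
#'   columns; a header row `term<TAB>symbol` is accepted).
#' @inheritParams build_lexicon
#' @export
read_lexicon <- function(path, category = c("tf", "cytokine", "assay")) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) == "term") df <- df[-1, , drop = FALSE]
  build_lexicon(setNames(df[[2]], df[[1]]), category)
}

term_pattern <- function(term) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", term)
  paste0("(?<![[:alnum:]])", esc, "(?![[:alnum:]])")
}

match_lexicon <- function(text, lexicon) {
  hits <- vapply(names(lexicon$entries), function(term) {
    grepl(term_pattern(term), text, perl = TRUE)
  }, logical(1))
  lexicon$entries[hits]
}

#' Triage articles that co-mention a cytokine, a TF and an assay
#'
#' An article is flagged when its text contains at least one surface term
#' from each of the three lexicons, matched case-insensitively at word
#' boundaries (terms embedded in longer alphanumeric tokens never match).
#'
#' @param articles Data frame with columns `article_id` and `text`, or
#'   `article_id`, `title`, `abstract` (concatenated).
#' @param tf_lexicon,cytokine_lexicon,assay_lexicon `lexicon` objects.
#' @return Data frame with one row per flagged article: `article_id` plus
#'   list-columns `matched_tfs`, `matched_cytokines`, `matched_assays`
#'   (named character vectors, surface term -> canonical symbol).
#' @export
triage_articles <- function(articles, tf_lexicon, cytokine_lexicon,
                            assay_lexicon) {
  for (lex in list(tf_lexicon, cytokine_lexicon, assay_lexicon))
    if (!inherits(lex, "lexicon") || length(lex$entries) == 0)
      stop("all three lexicons must be non-empty 'lexicon' objects")
  articles$article_id <- as.character(articles$article_id)
  if (!"text" %in% names(articles))
    articles$text <- paste(articles$title, articles$abstract)
  stopifnot(all(nzchar(articles$text)))
  rows <- lapply(seq_len(nrow(articles)), function(i) {
    text <- tolower(articles$text[i])
    tfs <- match_lexicon(text, tf_lexicon)
    if (length(tfs) == 0) return(NULL)
    cyts <- match_lexicon(text, cytokine_lexicon)
    if (length(cyts) == 0) return(NULL)
    assays <- match_lexicon(text, assay_lexicon)
    if (length(assays) == 0) return(NULL)
    list(article_id = articles$article_id[i], tfs = tfs, cyts = cyts,
         assays = assays)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- data.frame(
    article_id = vapply(rows, `[[`, character(1), "article_id"),
    stringsAsFactors = FALSE)
  out$matched_tfs <- lapply(rows, `[[`, "tfs")
  out$matched_cytokines <- lapply(rows, `[[`, "cyts")
  out$matched_assays <- lapply(rows, `[[`, "assays")
  out
}
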