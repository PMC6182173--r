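DNA_BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' Accepts a 4-by-L (rows A, C, G, T) or L-by-4 matrix of counts or
#' frequencies, adds the pseudocount to every cell and renormalizes each
#' position to sum to 1.
#'
#' @param mat Non-negative numeric matrix.
#' @param motif_id Motif identifier.
#' @param tf_symbol TF the motif belongs to.
#' @param pseudo Pseudocount added per cell (default 0.01).
#' @param background Base background frequencies (A, C, G, T), default
#'   uniform.
#' @return An object of class `pwm`.
#' @export
pwm <- function(mat, motif_id = NA_character_, tf_symbol = NA_character_,
                pseudo = 0.01, background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (ncol(mat) == 4 && nrow(mat) != 4) mat <- t(mat)
  if (nrow(mat) != 4)
    stop("PWM must have 4 base rows/columns (A, C, G, T)")
  if (ncol(mat) < 4) stop("PWM length must be >= 4")
  if (any(mat < 0) || anyNA(mat)) stop("PWM entries must be non-negative")
  if (any(colSums(mat) == 0)) stop("PWM has an all-zero position")
  mat <- sweep(mat + pseudo, 2, colSums(mat) + 4 * pseudo, "/")
  rownames(mat) <- DNA_BASES
  stopifnot(length(background) == 4, all(background > 0))
  structure(list(matrix = mat, motif_id = motif_id, tf_symbol = tf_symbol,
                 pseudo = pseudo,
                 background = setNames(background, DNA_BASES)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$motif_id %||% "", "for", x$tf_symbol %||% "?",
      "- length", ncol(x$matrix), "\n")
  invisible(x)
}

#' Load a PWM from a CIS-BP-style or MEME minimal text file
#'
#' CIS-BP format: a header line `Pos A C G T` followed by one row per
#' position. MEME minimal format: a `MOTIF` line and a
#' `letter-probability matrix` block (alphabet order A, C, G, T).
#' Counts or frequencies are converted to probabilities with the
#' pseudocount and renormalized.
#'
#' @param path Path to the matrix file.
#' @inheritParams pwm
#' @return A `pwm` object.
#' @export
load_pwm <- function(path, pseudo = 0.01, tf_symbol = NA_character_,
                     background = rep(0.25, 4)) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("letter-probability matrix", lines, fixed = TRUE))) {
    motif_id <- sub("^MOTIF\\s+(\\S+).*", "\\1",
                    grep("^MOTIF", lines, value = TRUE)[1])
    start <- grep("letter-probability matrix", lines, fixed = TRUE)[1]
    body <- lines[-seq_len(start)]
    body <- body[grepl("^\\s*[0-9.eE+-]", body)]
    mat <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                                 as.numeric))
    if (ncol(mat) != 4) stop("malformed MEME matrix: expected 4 columns")
    return(pwm(t(mat), motif_id = motif_id, tf_symbol = tf_symbol,
               pseudo = pseudo, background = background))
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  names(df) <- toupper(names(df))
  if (!all(DNA_BASES %in% names(df)))
    stop("malformed PWM file: need columns A, C, G, T")
  mat <- t(as.matrix(df[, DNA_BASES]))
  pwm(mat, motif_id = sub("\\.[^.]*$", "", basename(path)),
      tf_symbol = tf_symbol, pseudo = pseudo, background = background)
}

#' Write a PWM in CIS-BP text format
#'
#' @param x A `pwm` object.
#' @param path Output path.
#' @export
write_pwm <- function(x, path) {
  df <- data.frame(Pos = seq_len(ncol(x$matrix)), t(x$matrix))
  colnames(df) <- c("Pos", DNA_BASES)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Consensus sequence (most probable base per position)
#' @param x A `pwm` object.
#' @return Character string.
#' @export
consensus_sequence <- function(x) {
  paste(DNA_BASES[apply(x$matrix, 2, which.max)], collapse = "")
}

#' Maximum attainable log-odds score of a PWM
#' @param x A `pwm` object.
#' @return Score in bits.
#' @export
max_score <- function(x) {
  sum(apply(log2(x$matrix / x$background), 2, max))
}

window_scores <- function(lom, idx) {
  L <- ncol(lom)
  nw <- length(idx) - L + 1L
  sc <- numeric(nw)
  for (i in seq_len(L)) {
    sc <- sc + lom[cbind(idx[i:(i + nw - 1L)], i)]
  }
  sc[is.na(sc)] <- -Inf
  sc
}

#' Scan a promoter sequence with a PWM (log-odds)
#'
#' Scores every window on both strands with the summed per-base log2
#' ratio of the motif probability to the background frequency
#' (the PWM-log-odds score, in bits) and returns windows scoring at least
#' `threshold` (default 10, a stringent cut-off). Windows containing `N`
#' are skipped. Offsets are 0-based starts on the supplied (coding)
#' strand; minus-strand hits are reported at their forward-strand start.
#'
#' @param x A `pwm` object.
#' @param sequence DNA string over A, C, G, T, N (case-insensitive).
#' @param threshold Minimum reported score.
#' @return Data frame `offset`, `strand`, `score`, sorted by offset.
#' @export
scan_promoter <- function(x, sequence, threshold = 10) {
  stopifnot(inherits(x, "pwm"), is.numeric(threshold), !is.na(threshold))
  L <- ncol(x$matrix)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < L) {
    warning("sequence shorter than the motif; no windows scanned")
    return(empty)
  }
  chars <- strsplit(sequence, "")[[1]]
  if (!all(chars %in% c(DNA_BASES, "N")))
    stop("sequence contains characters outside A, C, G, T, N")
  idx <- match(chars, DNA_BASES)
  lom <- log2(x$matrix / x$background)
  fwd <- window_scores(lom, idx)
  rc_idx <- rev(5L - idx)
  rev_sc <- window_scores(lom, rc_idx)
  fi <- which(fwd >= threshold)
  ri <- which(rev_sc >= threshold)
  hits <- rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi]),
    data.frame(offset = n - L - (ri - 1L), strand = rep("-", length(ri)),
               score = rev_sc[ri]))
  hits <- hits[is.finite(hits$score), , drop = FALSE]
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Count motif sites per promoter
#'
#' @param x A `pwm` object.
#' @param promoters Named character vector of promoter sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param threshold Minimum log-odds score per site.
#' @return Named integer vector: gene -> number of sites (both strands;
#'   overlapping sites counted separately).
#' @export
count_sites <- function(x, promoters, threshold = 10) {
  promoters <- as_promoter_vector(promoters)
  vapply(promoters, function(s)
    nrow(suppressWarnings(scan_promoter(x, s, threshold))), integer(1))
}

as_promoter_vector <- function(promoters) {
  if (inherits(promoters, "DNAStringSet"))
    promoters <- setNames(as.character(promoters), names(promoters))
  stopifnot(is.character(promoters), !is.null(names(promoters)))
  promoters
}

#' Read promoter sequences from a FASTA file
#'
#' Headers are taken as gene symbols (first whitespace-separated token,
#' upper-cased).
#'
#' @param path FASTA file of promoter regions (e.g. 2 kb upstream of each
#'   TSS, 5'-3' on the coding strand).
#' @return Named character vector of sequences.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss),
           toupper(sub("\\s.*$", "", names(ss))))
}

#' Write promoter sequences to FASTA
#'
#' @param promoters Named character vector of sequences.
#' @param path Output path.
#' @export
write_promoters <- function(promoters, path) {
  ss <- Biostrings::DNAStringSet(promoters)
  names(ss) <- names(promoters)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
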