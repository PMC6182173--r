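# Independent brute-force oracles used across the suite.

# Build a GRN from bare (tf, cytokine) pair vectors.
make_grn <- function(tfs, cyts, species = "human",
                     activity = rep("unknown", length(tfs))) {
  rec <- data.frame(tf = tfs, cytokine = cyts, species = species,
                    activity = activity, stringsAsFactors = FALSE)
  rec$assays <- rep(list("functional"), nrow(rec))
  rec$pmids <- rep(list("1"), nrow(rec))
  rec$evidence <- "low"
  cytokine_grn(cytgrn:::interaction_records(rec), species = species)
}

# Exact Fisher p by direct enumeration of the hypergeometric support
# (binomial coefficients only; independent of stats::fisher.test).
fisher_oracle <- function(a, b, c, d, sided = "two") {
  m <- a + b
  n_ <- c + d
  k <- a + c
  support <- max(0, k - n_):min(k, m)
  probs <- choose(m, support) * choose(n_, k - support) / choose(m + n_, k)
  if (sided == "greater") {
    sum(probs[support >= a])
  } else {
    sum(probs[probs <= probs[support == a] * (1 + 1e-7)])
  }
}

# Per-window per-strand log-odds scores by explicit loops.
scan_oracle <- function(p, sequence, threshold) {
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  L <- ncol(p$matrix)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  hits <- list()
  score_at <- function(win) {
    s <- 0
    for (i in seq_len(L)) {
      if (win[i] == "N") return(-Inf)
      s <- s + log2(p$matrix[win[i], i] / p$background[win[i]])
    }
    s
  }
  for (off in 0:(n - L)) {
    win <- chars[(off + 1):(off + L)]
    s <- score_at(win)
    if (is.finite(s) && s >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "+",
                                             score = s)
    rcwin <- rev(unname(comp[win]))
    s <- score_at(rcwin)
    if (is.finite(s) && s >= threshold)
      hits[[length(hits) + 1]] <- data.frame(offset = off, strand = "-",
                                             score = s)
  }
  if (length(hits) == 0)
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  out <- do.call(rbind, hits)
  out <- out[order(out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

# Triple count by an explicit loop over edges and diseases.
triplet_oracle <- function(grn, tf_dis, cyt_dis) {
  total <- 0L
  for (i in seq_len(nrow(grn$records))) {
    tf <- grn$records$tf[i]
    cyt <- grn$records$cytokine[i]
    for (d in tf_dis[[tf]]) {
      if (d %in% cyt_dis[[cyt]]) total <- total + 1L
    }
  }
  total
}

# Smallest k top-degree nodes exceeding coverage, by a cumulative loop.
coverage_oracle <- function(deg, coverage) {
  ord <- order(-deg, names(deg))
  total <- sum(deg)
  acc <- 0
  for (k in seq_along(ord)) {
    acc <- acc + deg[ord[k]]
    if (acc > coverage * total) return(k / length(deg))
  }
  1
}
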