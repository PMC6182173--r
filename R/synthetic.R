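#' Generate a bipartite cytokine GRN with heavy-tailed TF degrees
#'
#' TF degrees are drawn from a truncated power law (exponent
#' `degree_exponent`, support 1..`n_cytokines`) and targets are attached
#' with heavy-tailed cytokine weights, producing the hub-dominated degree
#' distributions seen in curated networks. No duplicate edges are
#' produced. Assay sets and regulatory activities are sampled per record;
#' `p_activating` sets the activating share among annotated activities.
#'
#' @param n_tfs,n_cytokines Node counts (>= 2).
#' @param degree_exponent Power-law exponent of the TF degree
#'   distribution.
#' @param seed Optional integer seed.
#' @param p_activating P(activating | annotated activity).
#' @param p_annotated P(activity annotated).
#' @param species Species label for the records.
#' @param tf_names,cyt_names Node name vectors (defaults `TF001`...,
#'   `CYT001`...).
#' @return A [cytokine_grn()].
#' @export
generate_grn <- function(n_tfs, n_cytokines, degree_exponent = 2,
                         seed = NULL, p_activating = 0.8,
                         p_annotated = 0.7, species = "human",
                         tf_names = sprintf("TF%03d", seq_len(n_tfs)),
                         cyt_names = sprintf("CYT%03d", seq_len(n_cytokines))) {
  stopifnot(n_tfs >= 2, n_cytokines >= 2)
  if (!is.null(seed)) set.seed(seed)
  kprob <- seq_len(n_cytokines)^(-degree_exponent)
  deg <- sample(n_cytokines, n_tfs, replace = TRUE,
                prob = kprob / sum(kprob))
  cyt_w <- sample(seq_len(n_cytokines)^(-1))
  rows <- list()
  for (i in seq_len(n_tfs)) {
    targets <- sample(cyt_names, deg[i], prob = cyt_w)
    n <- length(targets)
    annotated <- rbinom(n, 1, p_annotated) == 1
    act <- ifelse(annotated,
                  ifelse(rbinom(n, 1, p_activating) == 1,
                         "activating", "repressing"),
                  "unknown")
    assays <- lapply(seq_len(n), function(j) {
      sort(unique(sample(assay_categories,
                         size = sample(1:3, 1, prob = c(0.4, 0.4, 0.2)),
                         replace = FALSE)))
    })
    rec <- data.frame(tf = tf_names[i], cytokine = targets,
                      species = species, activity = act,
                      stringsAsFactors = FALSE)
    rec$assays <- assays
    rec$pmids <- lapply(seq_len(n), function(j)
      as.character(sample.int(89999999L, 1) + 9999999L))
    rows[[i]] <- rec
  }
  rec <- do.call(rbind, rows)
  rec$evidence <- vapply(rec$assays, classify_evidence, character(1))
  cytokine_grn(interaction_records(rec), species = species)
}

#' Generate a gene-by-tissue expression matrix with planted
#' tissue-specific genes
#'
#' Background expression is log-normal across `n_tissues` tissues (the
#' first `n_immune` flagged immune). Each planted TS gene gets the
#' fraction `ts_mass` of its expression mass concentrated in one randomly
#' chosen home tissue, which guarantees a TSPS well above the 0.7 TS
#' threshold for the default panel sizes.
#'
#' @param genes Character vector of gene names.
#' @param n_tissues Number of tissues (default 34).
#' @param ts_genes Subset of `genes` planted as tissue-specific.
#' @param seed Optional integer seed.
#' @param ts_mass Fraction of a TS gene's expression placed in its home
#'   tissue (default 0.9).
#' @param n_immune Number of immune-flagged tissues (default 5).
#' @param meanlog,sdlog Log-normal background parameters.
#' @return List: `values` (matrix), `tissue_flags` (named character),
#'   `ts_home` (named character, home tissue per planted gene).
#' @export
generate_expression <- function(genes, n_tissues = 34,
                                ts_genes = character(0), seed = NULL,
                                ts_mass = 0.9, n_immune = 5,
                                meanlog = 2, sdlog = 0.5) {
  stopifnot(all(ts_genes %in% genes), n_tissues >= 2)
  if (!is.null(seed)) set.seed(seed)
  tissues <- sprintf("TIS%02d", seq_len(n_tissues))
  flags <- setNames(c(rep("immune", n_immune),
                      rep("non_immune", n_tissues - n_immune)), tissues)
  m <- matrix(rlnorm(length(genes) * n_tissues, meanlog, sdlog),
              nrow = length(genes), dimnames = list(genes, tissues))
  ts_home <- setNames(sample(tissues, length(ts_genes), replace = TRUE),
                      ts_genes)
  for (g in ts_genes) {
    rest <- sum(m[g, setdiff(tissues, ts_home[g])])
    m[g, ts_home[g]] <- ts_mass / (1 - ts_mass) * rest
  }
  list(values = m, tissue_flags = flags, ts_home = ts_home)
}

#' Generate a co-expression compendium with planted modules
#'
#' Log-scale expression over `n_samples` samples; each module's genes
#' share a latent factor of weight `module_strength`, so module members
#' rank at the top of a co-expression query for any of them.
#'
#' @param genes Character vector of gene names.
#' @param n_samples Number of samples (default 60).
#' @param modules List of character vectors (gene subsets).
#' @param seed Optional integer seed.
#' @param module_strength Latent-factor loading.
#' @param noise_sd Independent noise SD.
#' @return Gene-by-sample matrix.
#' @export
generate_coexpression <- function(genes, n_samples = 60, modules = list(),
                                  seed = NULL, module_strength = 2,
                                  noise_sd = 1) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rnorm(length(genes) * n_samples, sd = noise_sd),
              nrow = length(genes),
              dimnames = list(genes, sprintf("S%03d", seq_len(n_samples))))
  for (mod in modules) {
    latent <- rnorm(n_samples)
    for (g in intersect(mod, genes))
      m[g, ] <- m[g, ] + module_strength * latent
  }
  m
}

#' Generate an information-rich synthetic PWM
#'
#' Each position has one dominant base with probability `info` and the
#' remainder split evenly. At the defaults the consensus scores about 24
#' bits and a single mismatch about 15.6, so sites within one mismatch of
#' the consensus pass the default scanning threshold of 10 while windows
#' with two or more mismatches do not; in uniform background sequence
#' this leaves roughly 99% of random 2 kb promoters free of spurious
#' sites.
#'
#' @param motif_id,tf_symbol Identifiers.
#' @param length Motif length (default 12).
#' @param info Dominant base probability (default 0.99).
#' @param seed Optional integer seed.
#' @return A `pwm` object.
#' @export
generate_pwm <- function(motif_id, tf_symbol, length = 12, info = 0.99,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dominant <- sample(4, length, replace = TRUE)
  mat <- matrix((1 - info) / 3, nrow = 4, ncol = length)
  mat[cbind(dominant, seq_len(length))] <- info
  pwm(mat, motif_id = motif_id, tf_symbol = tf_symbol, pseudo = 0)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Generate promoter sequences with planted motif sites
#'
#' Promoters are i.i.d. background sequence (uniform base composition by
#' default); consensus sites of the given PWMs are inserted at recorded
#' non-overlapping offsets on random strands.
#'
#' @param genes Character vector of gene names.
#' @param length Promoter length (default 2000, i.e. 2 kb upstream).
#' @param planted_sites Named list (gene -> list of `list(pwm =, count =)`)
#'   of sites to plant.
#' @param seed Optional integer seed.
#' @param base_probs Background base probabilities (A, C, G, T).
#' @return List: `promoters` (named character vector) and `sites`
#'   (data frame `gene`, `motif_id`, `offset`, `strand`).
#' @export
generate_promoters <- function(genes, length = 2000,
                               planted_sites = list(), seed = NULL,
                               base_probs = rep(0.25, 4)) {
  if (!is.null(seed)) set.seed(seed)
  proms <- vapply(genes, function(g)
    paste(sample(DNA_BASES, length, replace = TRUE, prob = base_probs),
          collapse = ""), character(1))
  sites <- list()
  for (g in names(planted_sites)) {
    stopifnot(g %in% genes)
    occupied <- matrix(numeric(0), ncol = 2)
    for (spec in planted_sites[[g]]) {
      cons <- consensus_sequence(spec$pwm)
      L <- nchar(cons)
      if (L > length) stop("motif longer than the promoter")
      for (k in seq_len(spec$count)) {
        placed <- FALSE
        for (try in seq_len(200)) {
          off <- sample.int(length - L + 1L, 1) - 1L
          if (nrow(occupied) == 0 ||
              all(off + L <= occupied[, 1] | off >= occupied[, 2])) {
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place ", spec$count,
                          " non-overlapping sites in gene ", g)
        occupied <- rbind(occupied, c(off, off + L))
        strand <- sample(c("+", "-"), 1)
        site_seq <- if (strand == "+") cons else revcomp(cons)
        substr(proms[g], off + 1L, off + L) <- site_seq
        sites[[base::length(sites) + 1L]] <- data.frame(
          gene = g, motif_id = spec$pwm$motif_id, offset = off,
          strand = strand, stringsAsFactors = FALSE)
      }
    }
  }
  list(promoters = proms,
       sites = if (base::length(sites)) do.call(rbind, sites)
       else data.frame(gene = character(0), motif_id = character(0),
                       offset = integer(0), strand = character(0)))
}

#' Generate a corpus of abstracts with planted TF/cytokine/assay triples
#'
#' `n_planted` articles co-mention a TF, a cytokine and an assay term;
#' the remaining articles are decoys mentioning at most two of the three
#' categories (including near-miss tokens that embed gene symbols in
#' longer words).
#'
#' @param tfs,cytokines Symbol vectors to draw from.
#' @param n_articles Corpus size (default 100).
#' @param n_planted Number of planted triple articles (default 20).
#' @param seed Optional integer seed.
#' @param assay_terms Assay surface terms.
#' @return List: `articles` (data frame `article_id`, `text`) and
#'   `planted` (data frame `article_id`, `tf`, `cytokine`, `assay`).
#' @export
generate_corpus <- function(tfs, cytokines, n_articles = 100,
                            n_planted = 20, seed = NULL,
                            assay_terms = c("luciferase", "chip",
                                            "emsa", "knockdown")) {
  stopifnot(n_planted <= n_articles)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("PMID%05d", seq_len(n_articles))
  planted_idx <- sort(sample(n_articles, n_planted))
  planted <- data.frame(article_id = ids[planted_idx],
                        tf = sample(tfs, n_planted, replace = TRUE),
                        cytokine = sample(cytokines, n_planted,
                                          replace = TRUE),
                        assay = sample(assay_terms, n_planted,
                                       replace = TRUE),
                        stringsAsFactors = FALSE)
  text <- character(n_articles)
  for (i in seq_len(n_articles)) {
    if (i %in% planted_idx) {
      p <- planted[planted$article_id == ids[i], ]
      text[i] <- paste0("We show that ", p$tf, " binds the ", p$cytokine,
                        " promoter as determined by ", p$assay, " assay.")
    } else {
      kind <- sample(3, 1)
      text[i] <- switch(kind,
        paste0("Expression of ", sample(cytokines, 1),
               " in serum samples of patients."),
        paste0(sample(tfs, 1), " interacts with ", sample(cytokines, 1),
               " signaling components in a pathway model."),
        paste0("The protein X", sample(tfs, 1), "Y was analysed by ",
               sample(assay_terms, 1), " assay."))
    }
  }
  list(articles = data.frame(article_id = ids, text = text,
                             stringsAsFactors = FALSE),
       planted = planted)
}

#' Generate a complete synthetic input world with ground truth
#'
#' Produces, from one master seed, every input the pipeline consumes:
#' human and mouse GRNs, a tissue expression panel with planted TS TFs, a
#' co-expression compendium with planted modules, PWMs and promoters with
#' planted binding sites, PSA/phenotype flags correlated with TF degree,
#' pro/anti cytokine panels, disease-upregulated cytokine sets with
#' planted enriched TFs, TF/cytokine disease annotations, cofactor and
#' drug tables, and a triage corpus. The `truth` element records every
#' planted structure, sufficient to score all downstream stages. The
#' master seed fans out into independent per-generator child seeds, so
#' regeneration with the same seed is exact.
#'
#' Planted novel PDIs receive: an edge in the mouse GRN, two promoter
#' binding sites for the TF's motif, and membership of the cytokine in
#' the TF's co-expression module, so the prediction pipeline should
#' recover them as high-confidence calls.
#'
#' @param seed Master integer seed.
#' @param n_tfs,n_cytokines Network size (defaults 40 x 60).
#' @param degree_exponent TF degree power-law exponent.
#' @param n_tissues,n_immune Tissue panel shape (defaults 34 / 5).
#' @param n_ts_tfs Number of planted tissue-specific TFs.
#' @param n_pred_tfs Number of TFs with planted novel PDIs.
#' @param n_planted_per_tf Planted novel cytokine targets per such TF.
#' @param n_samples Co-expression compendium samples.
#' @param n_diseases Number of diseases with planted enriched TFs.
#' @param n_articles,n_planted_triples Corpus shape.
#' @param promoter_length Promoter length in bp (default 2000).
#' @return A list of class `synthetic_world`.
#' @export
generate_world <- function(seed, n_tfs = 40, n_cytokines = 60,
                           degree_exponent = 2, n_tissues = 34,
                           n_immune = 5, n_ts_tfs = 8, n_pred_tfs = 4,
                           n_planted_per_tf = 2, n_samples = 60,
                           n_diseases = 3, n_articles = 100,
                           n_planted_triples = 20,
                           promoter_length = 2000) {
  set.seed(seed)
  child <- sample.int(.Machine$integer.max - 1L, 12)
  tf_names <- sprintf("TF%03d", seq_len(n_tfs))
  cyt_names <- sprintf("CYT%03d", seq_len(n_cytokines))

  grn_human <- generate_grn(n_tfs, n_cytokines, degree_exponent,
                            seed = child[1], species = "human",
                            tf_names = tf_names, cyt_names = cyt_names)

  # Mouse network: a conserved subset of the human pairs plus extra
  # mouse-specific pairs (same symbol space; orthology = identity).
  set.seed(child[2])
  hrec <- grn_human$records
  keep <- sample(nrow(hrec), round(0.4 * nrow(hrec)))
  extra <- data.frame(
    tf = sample(tf_names, 30, replace = TRUE),
    cytokine = sample(cyt_names, 30, replace = TRUE),
    stringsAsFactors = FALSE)
  mrec <- unique(rbind(hrec[keep, c("tf", "cytokine")], extra))
  mrec$species <- "mouse"
  mrec$activity <- "unknown"
  mrec$assays <- rep(list("functional"), nrow(mrec))
  mrec$pmids <- rep(list("1"), nrow(mrec))
  mrec$evidence <- "low"

  # Planted novel PDIs: TFs with >= 2 human targets; novel cytokines
  # not already targeted by that TF.
  set.seed(child[3])
  targets_of <- lapply(split(hrec$cytokine, hrec$tf), unique)
  eligible <- names(targets_of)[lengths(targets_of) >= 2]
  pred_tfs <- sample(eligible, min(n_pred_tfs, length(eligible)))
  planted_pdis <- do.call(rbind, lapply(pred_tfs, function(tf) {
    pool <- setdiff(cyt_names, targets_of[[tf]])
    data.frame(tf = tf,
               cytokine = sample(pool, n_planted_per_tf),
               stringsAsFactors = FALSE)
  }))
  add <- planted_pdis[!paste(planted_pdis$tf, planted_pdis$cytokine) %in%
                        paste(mrec$tf, mrec$cytokine), ]
  if (nrow(add) > 0) {
    add$species <- "mouse"
    add$activity <- "unknown"
    add$assays <- rep(list("functional"), nrow(add))
    add$pmids <- rep(list("1"), nrow(add))
    add$evidence <- "low"
    mrec <- rbind(mrec, add)
  }
  grn_mouse <- cytokine_grn(interaction_records(mrec), species = "mouse")

  # Tissue expression panel with planted TS TFs.
  set.seed(child[4])
  ts_tfs <- sample(tf_names, n_ts_tfs)
  expression <- generate_expression(c(tf_names, cyt_names),
                                    n_tissues = n_tissues,
                                    ts_genes = ts_tfs, seed = child[5],
                                    n_immune = n_immune)

  # PWMs for the prediction TFs; promoters with two planted sites per
  # planted PDI.
  pwms <- setNames(lapply(seq_along(pred_tfs), function(i)
    generate_pwm(paste0("M", i), pred_tfs[i], seed = child[6] + i)),
    pred_tfs)
  planted_sites <- list()
  for (i in seq_len(nrow(planted_pdis))) {
    g <- planted_pdis$cytokine[i]
    planted_sites[[g]] <- c(planted_sites[[g]] %||% list(),
                            list(list(pwm = pwms[[planted_pdis$tf[i]]],
                                      count = 2)))
  }
  promoters <- generate_promoters(cyt_names, length = promoter_length,
                                  planted_sites = planted_sites,
                                  seed = child[7])

  # Co-expression compendium: one module per prediction TF containing its
  # known targets and its planted novel cytokines.
  modules <- lapply(pred_tfs, function(tf)
    c(targets_of[[tf]],
      planted_pdis$cytokine[planted_pdis$tf == tf]))
  compendium <- generate_coexpression(cyt_names, n_samples = n_samples,
                                      modules = modules, seed = child[8])

  # Degree-linked PSA and phenotype flags.
  set.seed(child[9])
  deg <- setNames(rep(0L, n_tfs), tf_names)
  deg[names(grn_human$tf_degree)] <- grn_human$tf_degree
  psa_flags <- setNames(rbinom(n_tfs, 1, plogis(-2.2 + 0.45 * deg)) == 1,
                        tf_names)
  phenotype_flags <- setNames(rbinom(n_tfs, 1,
                                     plogis(-2 + 0.35 * deg)) == 1,
                              tf_names)
  tf_class <- setNames(rep("other", n_tfs), tf_names)
  tf_class[psa_flags] <- "PSA"
  tf_class[ts_tfs] <- "TS"

  # Pro / anti inflammatory cytokine panels (synthetic labels); panel
  # sizes mirror the 10 + 13 canonical lists, clamped for small worlds.
  set.seed(child[10])
  pro <- sample(cyt_names, min(10, floor(n_cytokines / 3)))
  anti <- sample(setdiff(cyt_names, pro),
                 min(13, floor(n_cytokines / 3)))

  # Disease sets planted around hub TFs + disease annotations that put
  # genuine sharing on the network's edges.
  set.seed(child[11])
  diseases <- sprintf("DIS%d", seq_len(n_diseases))
  hubs <- names(sort(grn_human$tf_degree, decreasing = TRUE))
  disease_sets <- list()
  enriched_pairs <- list()
  tf_diseases <- setNames(vector("list", n_tfs), tf_names)
  cyt_diseases <- setNames(vector("list", n_cytokines), cyt_names)
  for (i in seq_len(n_diseases)) {
    tf <- hubs[i]
    up <- sample(targets_of[[tf]],
                 min(8, length(targets_of[[tf]])))
    disease_sets[[diseases[i]]] <- up
    enriched_pairs[[i]] <- data.frame(tf = tf, disease = diseases[i],
                                      stringsAsFactors = FALSE)
    tf_diseases[[tf]] <- c(tf_diseases[[tf]], diseases[i])
    for (cyt in up)
      cyt_diseases[[cyt]] <- c(cyt_diseases[[cyt]], diseases[i])
  }

  # Cofactor and drug tables.
  set.seed(child[12])
  cofactors <- sprintf("COF%02d", 1:8)
  tf_cofactor <- unique(data.frame(
    tf = sample(tf_names, 60, replace = TRUE),
    cofactor = sample(cofactors, 60, replace = TRUE),
    stringsAsFactors = FALSE))
  tf_drugs <- data.frame(
    tf = sample(tf_names, 30, replace = TRUE),
    drug = sprintf("DRUG%02d", 1:30),
    action = sample(c("agonist", "activator", "antagonist", "inhibitor"),
                    30, replace = TRUE),
    stringsAsFactors = FALSE)

  corpus <- generate_corpus(tf_names, cyt_names, n_articles = n_articles,
                            n_planted = n_planted_triples,
                            seed = child[6])

  structure(list(
    seed = seed,
    grn_human = grn_human,
    grn_mouse = grn_mouse,
    expression = expression,
    compendium = compendium,
    pwms = pwms,
    promoters = promoters$promoters,
    annotations = list(psa_flags = psa_flags,
                       phenotype_flags = phenotype_flags,
                       tf_class = tf_class,
                       pro_list = pro, anti_list = anti,
                       disease_sets = disease_sets,
                       tf_diseases = tf_diseases,
                       cyt_diseases = cyt_diseases,
                       tf_cofactor = tf_cofactor,
                       tf_drugs = tf_drugs),
    corpus = corpus$articles,
    cytokine_universe = cyt_names,
    truth = list(ts_tfs = ts_tfs,
                 ts_home = expression$ts_home,
                 planted_pdis = planted_pdis,
                 planted_sites = promoters$sites,
                 enriched_pairs = do.call(rbind, enriched_pairs),
                 planted_triage = corpus$planted,
                 modules = setNames(modules, pred_tfs))),
    class = "synthetic_world")
}

#' Write a synthetic world as an on-disk input bundle
#'
#' Writes every input in the exact plain-text formats the package readers
#' consume: interaction TSVs, expression and flag TSVs, the co-expression
#' compendium, one CIS-BP-format PWM file per TF, a promoter FASTA, the
#' annotation TSVs, the article corpus, and `truth.json`.
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_interaction_table(world$grn_human,
                          file.path(dir, "interactions_human.tsv"))
  write_interaction_table(world$grn_mouse,
                          file.path(dir, "interactions_mouse.tsv"))
  expr <- world$expression$values
  write.table(data.frame(gene = rownames(expr), expr,
                         check.names = FALSE),
              file.path(dir, "expression_tissues.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(tissue = names(world$expression$tissue_flags),
                         flag = world$expression$tissue_flags),
              file.path(dir, "tissue_flags.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(gene = rownames(world$compendium),
                         world$compendium, check.names = FALSE),
              file.path(dir, "compendium.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  pwm_dir <- file.path(dir, "pwms")
  dir.create(pwm_dir, showWarnings = FALSE)
  for (tf in names(world$pwms))
    write_pwm(world$pwms[[tf]], file.path(pwm_dir, paste0(tf, ".txt")))
  write_promoters(world$promoters, file.path(dir, "promoters.fasta"))
  write.table(world$corpus, file.path(dir, "corpus.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(world$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
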