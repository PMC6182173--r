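test_that("pooled two-proportion z-test matches hand computations", {
  r <- proportion_test(8, 10, 2, 10)
  expect_equal(r$z, 0.6 / sqrt(0.05), tolerance = 1e-9)
  expect_equal(r$p, 2 * pnorm(-abs(r$z)), tolerance = 1e-12)

  expect_equal(proportion_test(5, 10, 5, 10)$z, 0)
  expect_equal(proportion_test(5, 10, 5, 10)$p, 1)

  r2 <- proportion_test(10, 10, 0, 10)
  expect_equal(r2$z, sqrt(20), tolerance = 1e-9)
  expect_lt(r2$p, 1e-4)

  expect_warning(r3 <- proportion_test(0, 10, 0, 10), "degenerate")
  expect_equal(r3$p, 1)

  # z^2 equals the uncorrected chi-square statistic
  set.seed(2)
  for (rep in 1:10) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    z <- proportion_test(x1, n1, x2, n2)$z
    ct <- suppressWarnings(
      prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
    expect_equal(z^2, unname(ct$statistic), tolerance = 1e-9)
  }
})

test_that("BH adjustment reproduces the step-up example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04, 0.8)),
               c(0.04, 0.04, 0.04 * 4 / 3, 0.8), tolerance = 1e-12)
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  p <- sort(runif(20))
  adj <- bh_adjust(p)
  expect_true(all(diff(adj) >= -1e-12))
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
})

test_that("fisher_exact matches hypergeometric enumeration and the ad/bc OR", {
  ft <- fisher_exact(matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE), "two")
  expect_equal(ft$p, 34 / 70, tolerance = 1e-9)
  expect_equal(ft$odds_ratio, 9)

  gt <- fisher_exact(matrix(c(0, 5, 5, 0), 2, 2, byrow = TRUE), "greater")
  expect_equal(gt$p, 1)
  expect_equal(gt$odds_ratio, 0)

  inf <- fisher_exact(matrix(c(4, 0, 0, 6), 2, 2, byrow = TRUE), "greater")
  expect_equal(inf$odds_ratio, Inf)

  set.seed(5)
  for (rep in 1:200) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(1, 4)))
    tab <- matrix(cells, 2, 2)
    for (sided in c("greater", "two")) {
      expect_equal(fisher_exact(tab, sided)$p,
                   fisher_oracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                 tab[2, 2], sided),
                   tolerance = 1e-9)
    }
  }
  expect_error(fisher_exact(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})

test_that("cell-type enrichment flags a TF whose targets define a cell type", {
  # TF A: 6 targets, all of them the only Th17 cytokines; B-E: 20 PDIs
  # with other cytokines
  tfs <- c(rep("A", 6), rep(c("B", "C", "D", "E"), each = 5))
  cyts <- c(paste0("TH", 1:6), paste0("OC", 1:20))
  g <- make_grn(tfs, cyts)
  ann <- data.frame(cytokine = paste0("TH", 1:6), cell_type = "Th17",
                    stringsAsFactors = FALSE)
  res <- celltype_enrichment(g, ann, fdr = 0.1)
  hit <- res[res$tf == "A" & res$cell_type == "Th17", ]
  expect_equal(hit$x1, 6)
  expect_equal(hit$x2, 0)
  expect_true(hit$significant)

  expect_warning(empty <- celltype_enrichment(g, ann[0, ]), "empty")
  expect_equal(nrow(empty), 0)

  # TFs below the target floor are skipped
  g2 <- make_grn(c("A", "A", "Z"), c("TH1", "TH2", "OC1"))
  res2 <- celltype_enrichment(g2, ann)
  expect_true("Z" %in% attr(res2, "skipped"))
  expect_false("Z" %in% res2$tf)
})

test_that("cell-type enrichment controls the significant fraction under the null", {
  set.seed(77)
  frac <- replicate(60, {
    g <- generate_grn(12, 15)
    cyts <- sprintf("CYT%03d", 1:15)
    ann <- data.frame(
      cytokine = sample(cyts, 20, replace = TRUE),
      cell_type = sample(paste0("CT", 1:4), 20, replace = TRUE),
      stringsAsFactors = FALSE)
    res <- celltype_enrichment(g, ann, fdr = 0.1)
    if (nrow(res) == 0) 0 else mean(res$significant)
  })
  expect_lt(mean(frac), 0.1 + 0.03)
})

test_that("disease enrichment recovers planted associations via one-sided Fisher", {
  univ <- paste0("C", 1:100)
  g <- make_grn(c(rep("A", 5), rep("B", 5)),
                c(paste0("C", 1:5), paste0("C", 50:54)))
  sets <- list(DIS = paste0("C", 1:5))
  res <- disease_enrichment(g, sets, univ, fdr = 0.1)
  a_row <- res[res$tf == "A", ]
  expect_equal(a_row$a, 5)
  expect_equal(a_row$odds_ratio, Inf)
  expect_true(a_row$significant)
  b_row <- res[res$tf == "B", ]
  expect_equal(b_row$odds_ratio, 0)
  expect_false(b_row$significant)

  # empty disease sets are skipped
  res2 <- disease_enrichment(g, list(DIS = character(0)), univ)
  expect_null(res2)
})

test_that("family comparison puts identical networks on the diagonal", {
  g <- generate_grn(12, 20, seed = 6)
  groups <- setNames(rep(c("F1", "F2", "F3"), length.out = 12),
                     sprintf("TF%03d", 1:12))
  fc <- family_comparison(g, g$tf_degree, groups)
  expect_equal(fc$table$pct_grn, fc$table$pct_ref, tolerance = 1e-12)
  expect_equal(fc$pearson_r, 1, tolerance = 1e-9)

  # group with no PDIs anywhere is retained at (0, 0)
  groups2 <- c(groups, ZZTOP = "F4")
  fc2 <- family_comparison(g, g$tf_degree, groups2)
  expect_true(all(c(fc2$table$pct_grn[fc2$table$group == "F4"],
                    fc2$table$pct_ref[fc2$table$group == "F4"]) == 0))
  expect_error(family_comparison(g, numeric(0), groups), "empty reference")
})

test_that("connectivity-phenotype fractions track a degree-linked flag", {
  g <- make_grn(c("T1", rep("T2", 3), rep("T3", 12)),
                c("C1", paste0("C", 1:3), paste0("C", 1:12)))
  flags <- c(T1 = TRUE, T2 = TRUE, T3 = TRUE, T0 = TRUE)
  cp <- connectivity_phenotype(g, flags)
  expect_true(all(cp$fraction[cp$n > 0] == 1))

  w <- generate_world(13)
  cp2 <- connectivity_phenotype(w$grn_human, w$annotations$psa_flags)
  expect_gt(attr(cp2, "spearman_rho"), 0)
  nz <- cp2[cp2$n > 0, ]
  expect_gt(nz$fraction[nrow(nz)], nz$fraction[1])
})

test_that("cofactor usage and drug targetability aggregate distinct TFs", {
  g <- make_grn(c("A", "B", "B"), c("C1", "C1", "C2"))
  cof <- data.frame(tf = c("A", "B", "B"),
                    cofactor = c("X", "X", "Y"), stringsAsFactors = FALSE)
  cls <- c(A = "PSA", B = "PSA")
  cu <- cofactor_usage(g, cof, cls)
  c1x <- cu$cytokine_cofactor_counts
  expect_equal(c1x$n_tfs[c1x$cytokine == "C1" & c1x$cofactor == "X"], 2)
  fr <- cu$cofactor_class_fractions
  expect_equal(fr$frac_psa[fr$cofactor == "X"], 1.0)

  drugs <- data.frame(tf = c("A", "A", "B"),
                      drug = c("d1", "d2", "d3"),
                      action = c("activator", "inhibitor", "mystery"),
                      stringsAsFactors = FALSE)
  dt <- drug_targetability(g, drugs)
  # A has one agonist-class and one antagonist-class drug: counted in both
  expect_equal(dt$n_agonist_tfs[dt$cytokine == "C1"], 1)
  expect_equal(dt$n_antagonist_tfs[dt$cytokine == "C1"], 1)
  expect_equal(dt$n_agonist_tfs[dt$cytokine == "C2"], 0)
  expect_equal(attr(dt, "unknown_actions"), "mystery")
})
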