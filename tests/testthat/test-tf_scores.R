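test_that("TSPS matches closed forms and handles degenerate profiles", {
  u <- tsps(rep(5, 7))
  expect_equal(u$tsps, 0, tolerance = 1e-12)
  expect_false(u$is_ts)

  single <- tsps(c(10, rep(0, 33)))
  expect_equal(single$tsps, log2(34), tolerance = 1e-9)
  expect_true(single$is_ts)

  hand <- tsps(c(3, 1, 0, 0))
  expect_equal(hand$tsps, 0.75 * log2(3), tolerance = 1e-9)
  expect_true(hand$is_ts)
  expect_equal(sum(hand$p_i), 1, tolerance = 1e-9)

  expect_error(tsps(rep(0, 5)), "all-zero")
  expect_error(tsps(3), "at least 2")
})

test_that("TSPS equals log2(T) minus the Shannon entropy and is scale invariant", {
  set.seed(4)
  for (rep in 1:25) {
    T <- sample(3:40, 1)
    prof <- rlnorm(T)
    prof[sample(T, sample(0:2, 1))] <- 0
    if (sum(prof) == 0) next
    p <- prof / sum(prof)
    entropy <- -sum(ifelse(p > 0, p * log2(p), 0))
    s <- tsps(prof)$tsps
    expect_equal(s, log2(T) - entropy, tolerance = 1e-9)
    expect_equal(tsps(prof * runif(1, 0.01, 100))$tsps, s,
                 tolerance = 1e-9)
    expect_true(s >= 0 && s <= log2(T) + 1e-12)
  }
})

test_that("expression enrichment follows the pseudocount formula", {
  flags <- setNames(c(rep("immune", 5), rep("non_immune", 27)),
                    paste0("T", 1:32))
  const <- setNames(rep(7, 32), paste0("T", 1:32))
  expect_equal(expression_enrichment(const, flags),
               c(immune = 1, non_immune = 1))

  prof <- setNames(c(rep(9, 5), rep(0, 27)), paste0("T", 1:32))
  ees <- expression_enrichment(prof, flags)
  expect_equal(unname(ees["immune"]), 10 / (77 / 32), tolerance = 1e-12)
  expect_equal(unname(ees["non_immune"]), 1 / (77 / 32), tolerance = 1e-12)

  # pseudocount breaks linear scaling
  ees2 <- expression_enrichment(prof * 2, flags)
  expect_false(isTRUE(all.equal(unname(ees2["immune"]),
                                unname(ees["immune"]))))

  # count-weighted mean of the two group enrichments is exactly 1
  set.seed(8)
  for (rep in 1:10) {
    prof <- setNames(rlnorm(32), paste0("T", 1:32))
    e <- expression_enrichment(prof, flags)
    expect_equal(unname(5 * e["immune"] + 27 * e["non_immune"]) / 32, 1,
                 tolerance = 1e-12)
  }

  expect_error(expression_enrichment(setNames(1:3, c("T1", "T2", "ZZ")),
                                     flags), "ZZ")
})

test_that("inflammatory score counts pro/anti membership with bands at half", {
  g <- make_grn(rep("T1", 4), c("TNF", "IL6", "CCL2", "CCL5"))
  is1 <- inflammatory_score(g, "T1")
  expect_equal(is1$is_value, 0.5)
  expect_equal(is1$band, "pro")
  expect_equal(is1$n_pro, 2)
  expect_equal(is1$n_total, 4)

  g2 <- make_grn("T1", "IL10")
  is2 <- inflammatory_score(g2, "T1")
  expect_equal(is2$is_value, -1)
  expect_equal(is2$band, "anti")

  g3 <- make_grn("T1", "CCL2")
  expect_equal(inflammatory_score(g3, "T1")$is_value, 0)
  expect_equal(inflammatory_score(g3, "T1")$band, "none")

  # swapping the panels flips the sign
  swapped <- inflammatory_score(g, "T1",
                                pro_list = anti_inflammatory_cytokines,
                                anti_list = pro_inflammatory_cytokines)
  expect_equal(swapped$is_value, -is1$is_value)

  expect_error(inflammatory_score(g, "NOPE"), "not present")
  expect_error(inflammatory_score(g, "T1", pro_list = "IL10",
                                  anti_list = "IL10"), "disjoint")
})

test_that("expression by degree bins TFs including a degree-0 bin", {
  g <- make_grn(c("T1", "T1", "T1", "T2"), c("C1", "C2", "C3", "C1"))
  expr <- rbind(T1 = c(1, 3, 5), T2 = c(2, 2, 2), T9 = c(10, 10, 10))
  colnames(expr) <- paste0("TIS", 1:3)
  out <- expression_by_degree(g, expr, edges = c(0, 1, 2, 5, 10))
  expect_equal(out$median_expr[out$tf == "T1"], 3)
  expect_equal(as.character(out$bin[out$tf == "T9"]), "0")
  expect_equal(as.character(out$bin[out$tf == "T1"]), "2-4")
  expect_equal(as.character(out$bin[out$tf == "T2"]), "1")

  # network TF missing from the matrix is skipped and reported
  g2 <- make_grn(c("T1", "TX"), c("C1", "C2"))
  out2 <- expression_by_degree(g2, expr)
  expect_equal(attr(out2, "skipped"), "TX")
})

test_that("planted high-degree expression produces increasing bin medians", {
  w <- generate_world(31)
  expr <- w$expression$values
  deg <- w$grn_human$tf_degree
  # lift immune expression of high-degree TFs to emulate the trend
  hubs <- names(deg)[deg >= 5]
  imm <- names(w$expression$tissue_flags)[w$expression$tissue_flags == "immune"]
  expr[hubs, imm] <- expr[hubs, imm] * 20
  out <- expression_by_degree(w$grn_human, expr[startsWith(rownames(expr), "TF"), ],
                              tissue_flags = w$expression$tissue_flags)
  med <- tapply(out$median_expr, out$bin, median)
  med <- med[!is.na(med)]
  expect_true(med[["10+"]] > med[["1"]] || med[["5-9"]] > med[["1"]])
})
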