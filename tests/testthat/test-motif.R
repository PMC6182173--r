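test_that("PWM loading applies the pseudocount and validates shape", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT",
               "1\t4\t0\t0\t0",
               "2\t0\t4\t0\t0",
               "3\t0\t0\t4\t0",
               "4\t4\t0\t0\t0",
               "5\t0\t0\t0\t4"), path)
  p <- load_pwm(path, pseudo = 0.01)
  expect_equal(unname(p$matrix["A", 1]), 4.01 / 4.04, tolerance = 1e-12)
  expect_equal(unname(p$matrix["C", 1]), 0.01 / 4.04, tolerance = 1e-12)
  expect_equal(unname(colSums(p$matrix)), rep(1, 5), tolerance = 1e-9)
  expect_equal(consensus_sequence(p), "ACGAT")

  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG", "1\t1\t1\t1"), bad)
  expect_error(load_pwm(bad), "A, C, G, T")

  zero <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Pos\tA\tC\tG\tT", "1\t1\t0\t0\t0", "2\t0\t0\t0\t0",
               "3\t1\t0\t0\t0", "4\t1\t0\t0\t0"), zero)
  expect_error(load_pwm(zero), "all-zero")

  short <- matrix(0.25, 4, 3)
  expect_error(pwm(short), "length")
})

test_that("MEME minimal format parses to the same probabilities", {
  path <- withr::local_tempfile(fileext = ".meme")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "MOTIF M0001 TFX",
               "letter-probability matrix: alength= 4 w= 4 nsites= 20",
               " 0.970 0.010 0.010 0.010",
               " 0.010 0.970 0.010 0.010",
               " 0.010 0.010 0.970 0.010",
               " 0.010 0.010 0.010 0.970"), path)
  p <- load_pwm(path, pseudo = 0)
  expect_equal(p$motif_id, "M0001")
  expect_equal(consensus_sequence(p), "ACGT")
  expect_equal(unname(p$matrix["A", 1]), 0.97, tolerance = 1e-9)
})

test_that("a uniform PWM scores every window zero", {
  u <- pwm(matrix(0.25, 4, 6), pseudo = 0)
  seqc <- paste(rep("ACGT", 10), collapse = "")
  expect_equal(nrow(scan_promoter(u, seqc, threshold = 10)), 0)
  all0 <- scan_promoter(u, seqc, threshold = 0)
  expect_equal(nrow(all0), 2 * (nchar(seqc) - 6 + 1))
  expect_true(all(abs(all0$score) < 1e-12))
})

test_that("scanning equals the brute-force window/strand oracle", {
  set.seed(31)
  for (rep in 1:20) {
    p <- generate_pwm("M", "T", length = sample(4:8, 1),
                      info = runif(1, 0.5, 0.95))
    seqc <- paste(sample(c("A", "C", "G", "T", "N"), 30, replace = TRUE,
                         prob = c(0.24, 0.24, 0.24, 0.24, 0.04)),
                  collapse = "")
    for (thr in c(-5, 0, 3, 10)) {
      got <- scan_promoter(p, seqc, threshold = thr)
      want <- scan_oracle(p, seqc, threshold = thr)
      expect_equal(got$offset, want$offset)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-9)
    }
  }
})

test_that("scanning is strand symmetric", {
  set.seed(7)
  p <- generate_pwm("M", "T", length = 6, info = 0.8)
  seqc <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                collapse = "")
  fwd <- scan_promoter(p, seqc, threshold = 2)
  rc <- scan_promoter(p, cytgrn:::revcomp(seqc), threshold = 2)
  n <- nchar(seqc); L <- 6
  mirrored <- data.frame(offset = n - L - rc$offset,
                         strand = ifelse(rc$strand == "+", "-", "+"),
                         score = rc$score)
  mirrored <- mirrored[order(mirrored$offset, mirrored$strand), ]
  expect_equal(fwd$offset, mirrored$offset)
  expect_equal(fwd$strand, mirrored$strand)
  expect_equal(fwd$score, mirrored$score, tolerance = 1e-9)
})

test_that("windows containing N are skipped and N spacers isolate segments", {
  p <- generate_pwm("M", "T", length = 5, seed = 2)
  cons <- consensus_sequence(p)
  expect_equal(nrow(scan_promoter(p, strrep("N", 40), threshold = -100)), 0)

  left <- paste0(strrep("A", 10), cons)
  right <- paste0(cons, strrep("C", 10))
  joined <- paste0(left, strrep("N", 4), right)
  hits_l <- scan_promoter(p, left, threshold = 10)
  hits_r <- scan_promoter(p, right, threshold = 10)
  hits_j <- scan_promoter(p, joined, threshold = 10)
  expect_equal(nrow(hits_j), nrow(hits_l) + nrow(hits_r))
  # no hit starts inside the N spacer junction
  expect_true(all(hits_j$offset + 5 <= nchar(left) |
                    hits_j$offset >= nchar(left) + 4))
})

test_that("no score exceeds the PWM maximum and the consensus attains it", {
  set.seed(12)
  for (rep in 1:10) {
    p <- generate_pwm("M", "T", length = 6, info = runif(1, 0.5, 0.99))
    seqc <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
    hits <- scan_promoter(p, seqc, threshold = -50)
    expect_true(all(hits$score <= max_score(p) + 1e-9))
    cons_hits <- scan_promoter(p, consensus_sequence(p), threshold = -50)
    expect_equal(max(cons_hits$score), max_score(p), tolerance = 1e-9)
  }
})

test_that("site counting matches planted sites and degenerate thresholds", {
  p <- generate_pwm("M", "TFX", seed = 5)
  pr <- generate_promoters(c("G1", "G2"), length = 500,
                           planted_sites = list(G1 = list(list(pwm = p,
                                                               count = 2))),
                           seed = 6)
  cnt <- count_sites(p, pr$promoters, threshold = 10)
  expect_equal(unname(cnt["G1"]), 2)
  expect_equal(unname(count_sites(p, c(GN = strrep("N", 100)))[["GN"]]), 0)
  expect_equal(unname(count_sites(p, pr$promoters, threshold = Inf)),
               c(0L, 0L))
  expect_warning(scan_promoter(p, "ACGT"), "shorter")
})

test_that("promoter FASTA round-trips through Biostrings", {
  pr <- generate_promoters(c("GENE1", "GENE2"), length = 100, seed = 8)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_promoters(pr$promoters, path)
  back <- read_promoters(path)
  expect_equal(back, pr$promoters)
})
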