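uniform_pwm <- function(w) {
  matrix(0.25, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
}

sharp_pwm <- function(consensus, p = 0.91) {
  w <- nchar(consensus)
  m <- matrix((1 - p) / 3, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
  cons <- strsplit(consensus, "")[[1]]
  for (j in seq_len(w)) m[cons[j], j] <- p
  m
}

test_that("promoter windows are symmetric and clipped at zero", {
  w <- promoter_window(10000)
  expect_equal(c(w$start, w$end), c(8000L, 12000L))
  w2 <- promoter_window(500)
  expect_equal(c(w2$start, w2$end), c(0L, 2500L))
  w3 <- promoter_window(10000, strand = "-")
  expect_equal(c(w3$start, w3$end), c(8000L, 12000L))  # symmetric regardless
  expect_error(promoter_window(-5), ">= 0")
})

test_that("enhancer assignment equals a brute-force overlap check", {
  tss <- 10000L
  near <- data.frame(chrom = "c", start = tss - 100L, end = tss + 100L)
  far <- data.frame(chrom = "c", start = tss + 3000L, end = tss + 3500L)
  expect_equal(nrow(assign_enhancers(near, tss)), 1L)
  expect_equal(nrow(assign_enhancers(far, tss)), 0L)
  set.seed(14)
  starts <- sample(5000:15000, 20)
  enh <- data.frame(chrom = "c", start = starts, end = starts + 300L)
  got <- assign_enhancers(enh, tss)
  lo <- tss - 2000L; hi <- tss + 2000L
  oracle <- sapply(seq_len(nrow(enh)), function(i)
    length(intersect(seq(enh$start[i], enh$end[i] - 1L), seq(lo, hi - 1L))) > 0)
  expect_equal(nrow(got), sum(oracle))
  expect_setequal(paste(got$start, got$end),
                  paste(enh$start[oracle], enh$end[oracle]))
})

test_that("TF-lncRNA pairing restricts to TFs and applies the p threshold", {
  # universe of 8 miRNAs; tf1 and l1 share 3 of 3 partners
  # (p = 1/C(8,3) * C(5,0)C(3,3) summed = 1/56), l2 overlaps tf1 in 1 of 3
  mm <- data.frame(
    regulator_id = c("mi1", "mi2", "mi3", paste0("mi", 4:8)),
    target_id = c("tf1", "tf1", "tf1", rep("g1", 5)),
    stringsAsFactors = FALSE)
  ml <- data.frame(
    regulator_id = c("mi1", "mi2", "mi3", "mi1", "mi7", "mi8"),
    target_id = c("l1", "l1", "l1", "l2", "l2", "l2"),
    stringsAsFactors = FALSE)
  ids_m <- paste0("mi", 1:8)
  cls <- c(stats::setNames(rep("miRNA", 8), ids_m),
           tf1 = "mRNA", g1 = "mRNA", l1 = "lncRNA", l2 = "lncRNA")
  g_mm <- build_network(mm, cls)
  g_ml <- build_network(ml, cls)
  # no TFs in the network: nothing returned
  expect_equal(nrow(tf_lncrna_pairs(g_mm, g_ml, "absentTF")), 0L)
  pairs <- tf_lncrna_pairs(g_mm, g_ml, "tf1", p_threshold = 1.01)
  # oracle: brute-force hypergeometric per (TF, lncRNA) pair, N = 8 miRNAs
  expect_true(all(pairs$tf_id == "tf1"))
  i1 <- which(pairs$lncrna_id == "l1")
  expect_equal(pairs$n_shared[i1], 3L)
  expect_equal(pairs$hyper_p[i1], enum_hyper_upper(3, 3, 3, 8),
               tolerance = 1e-12)
  i2 <- which(pairs$lncrna_id == "l2")
  expect_equal(pairs$hyper_p[i2], enum_hyper_upper(1, 3, 3, 8),
               tolerance = 1e-12)
  # complete overlap is retained at 0.05, the weak overlap is not
  strict <- tf_lncrna_pairs(g_mm, g_ml, "tf1", p_threshold = 0.05)
  expect_true("l1" %in% strict$lncrna_id)
  expect_false("l2" %in% strict$lncrna_id)
})

test_that("uninformative PWMs produce no hits and consensus scores maximally", {
  seqs <- "ACGTACGTAC"
  expect_equal(nrow(pwm_scan(seqs, uniform_pwm(3))), 0L)
  pwm <- sharp_pwm("TGACGT")
  hits <- pwm_scan(paste0("AAAAA", "TGACGT", "AAAAA"), pwm,
                   p_threshold = 1e-3, both_strands = FALSE)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$offset, 5L)
  expect_equal(hits$score, 6 * round(log2(0.91 / 0.25) * 1000) / 1000,
               tolerance = 1e-9)
})

test_that("reverse-strand hits are found at the reverse complement", {
  pwm <- sharp_pwm("TTTGGGCA")
  site_rc <- "TGCCCAAA"  # reverse complement of the consensus
  s <- paste0("CCCCC", site_rc, "CCCCC")
  hits <- pwm_scan(s, pwm, p_threshold = 1e-3)
  expect_true(any(hits$strand == "-" & hits$offset == 5L))
})

test_that("DP p-values equal exhaustive enumeration over all windows", {
  set.seed(9)
  for (w in c(2, 4, 6)) {
    pwm <- sharp_pwm(paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
                           collapse = ""), p = 0.7)
    seqs <- paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE),
                  collapse = "")
    # enumeration oracle: integer-discretised score of every 4^w window
    sint <- round(log2(pwm / 0.25) * 1000)
    combos <- as.matrix(expand.grid(rep(list(1:4), w)))
    all_scores <- vapply(seq_len(nrow(combos)), function(r)
      sum(sint[cbind(combos[r, ], seq_len(w))]), numeric(1))
    enum_p <- function(s) mean(all_scores >= s)
    got <- pwm_scan(seqs, pwm, p_threshold = 1 + 1e-9, both_strands = FALSE)
    expect_equal(nrow(got), 10 - w + 1)
    for (i in seq_len(nrow(got))) {
      s_i <- round(got$score[i] * 1000)
      expect_equal(got$p_value[i], enum_p(s_i), tolerance = 1e-9)
    }
    # monotonicity: p nonincreasing in score
    ord <- order(got$score)
    expect_true(all(diff(got$p_value[ord]) <= 1e-15))
  }
})

test_that("planted consensus sites in synthetic promoters are recovered", {
  s <- small_study(seed = 41)
  ms <- s$truth$motif_sites
  expect_gt(nrow(ms), 0)
  for (tf in names(s$pwms))
    expect_gte(pwm_information(s$pwms[[tf]]), 8)
  found <- sapply(seq_len(nrow(ms)), function(i) {
    h <- pwm_scan(s$promoters[[ms$sequence_id[i]]], s$pwms[[ms$motif_id[i]]],
                  p_threshold = 1e-4)
    any(h$offset == ms$offset[i] & h$strand == ms$strand[i])
  })
  expect_true(all(found))
})

test_that("PWM validation catches malformed matrices", {
  bad <- matrix(0.3, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_error(validate_pwm(bad), "sum to 1")
  expect_error(validate_pwm(matrix(0.25, 3, 4)), "4 x width")
  expect_error(pwm_scan("ACGNT", uniform_pwm(2)), "position 4")
})
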