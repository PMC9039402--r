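two_nets <- function(mm_edges, ml_edges) {
  ids_m <- unique(c(mm_edges$regulator_id, ml_edges$regulator_id))
  cls <- c(stats::setNames(rep("miRNA", length(ids_m)), ids_m),
           stats::setNames(rep("mRNA", length(unique(mm_edges$target_id))),
                           unique(mm_edges$target_id)),
           stats::setNames(rep("lncRNA", length(unique(ml_edges$target_id))),
                           unique(ml_edges$target_id)))
  list(mm = build_network(mm_edges, cls), ml = build_network(ml_edges, cls))
}

test_that("hypergeometric upper tail matches enumeration and edge cases", {
  expect_equal(hypergeom_shared(0, 5, 5, 10), 1)
  expect_equal(hypergeom_shared(5, 5, 5, 10), 1 / choose(10, 5))
  # N=20, K=6, n=8, k=4: sum over x = 4..6 of C(6,x) C(14,8-x) / C(20,8)
  expect_equal(hypergeom_shared(4, 6, 8, 20), enum_hyper_upper(4, 6, 8, 20),
               tolerance = 1e-14)
  expect_error(hypergeom_shared(6, 5, 8, 20), "inconsistent")
  expect_error(hypergeom_shared(2, 5, 8, 7), "inconsistent")
})

test_that("hypergeometric test equals enumeration over all small grids", {
  for (N in c(5, 12, 25)) for (K in seq(1, N, by = 4)) {
    for (n in seq(1, N, by = 4)) for (k in seq(0, min(K, n))) {
      expect_equal(hypergeom_shared(k, K, n, N), enum_hyper_upper(k, K, n, N),
                   tolerance = 1e-12)
    }
  }
})

test_that("shared-miRNA pairs match exhaustive enumeration on a fixture", {
  mm <- data.frame(
    regulator_id = c("mi1", "mi1", "mi2", "mi3", "mi3"),
    target_id = c("g1", "g2", "g2", "g1", "g3"), stringsAsFactors = FALSE)
  ml <- data.frame(
    regulator_id = c("mi1", "mi2", "mi2", "mi3"),
    target_id = c("l1", "l1", "l2", "l2"), stringsAsFactors = FALSE)
  nets <- two_nets(mm, ml)
  pairs <- shared_pairs(nets$mm, nets$ml)
  # brute-force double loop oracle
  oracle <- list()
  for (l in c("l1", "l2")) for (g in c("g1", "g2", "g3")) {
    mir_l <- ml$regulator_id[ml$target_id == l]
    mir_g <- mm$regulator_id[mm$target_id == g]
    sh <- intersect(mir_l, mir_g)
    if (length(sh)) oracle[[paste(l, g)]] <- sort(sh)
  }
  expect_equal(nrow(pairs), length(oracle))
  for (i in seq_len(nrow(pairs))) {
    key <- paste(pairs$lncrna_id[i], pairs$mrna_id[i])
    expect_true(key %in% names(oracle))
    expect_setequal(unlist(pairs$shared_mirnas[i]), oracle[[key]])
    expect_equal(pairs$n_shared[i], length(oracle[[key]]))
  }
  # hypergeometric p recomputed from the recorded counts
  N <- 3  # distinct miRNAs in the union
  for (i in seq_len(nrow(pairs))) {
    K <- length(ml$regulator_id[ml$target_id == pairs$lncrna_id[i]])
    n <- length(unique(mm$regulator_id[mm$target_id == pairs$mrna_id[i]]))
    expect_equal(pairs$hyper_p[i],
                 enum_hyper_upper(pairs$n_shared[i], K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("disjoint miRNA neighborhoods give no pairs", {
  mm <- data.frame(regulator_id = "mi1", target_id = "g1")
  ml <- data.frame(regulator_id = "mi2", target_id = "l1")
  nets <- two_nets(mm, ml)
  expect_equal(nrow(shared_pairs(nets$mm, nets$ml)), 0L)
  # one miRNA regulating one lncRNA and one mRNA: exactly one pair
  mm2 <- data.frame(regulator_id = "mi1", target_id = "g1")
  ml2 <- data.frame(regulator_id = "mi1", target_id = "l1")
  nets2 <- two_nets(mm2, ml2)
  p <- shared_pairs(nets2$mm, nets2$ml)
  expect_equal(nrow(p), 1L)
  expect_equal(p$n_shared, 1L)
})

test_that("ceRNA retention is strict in the PCC threshold", {
  samples <- paste0("s", 1:8)
  set.seed(2)
  base <- rnorm(8)
  # l1/g1 identical (r = 1); l2/g2 engineered to r exactly 0.9 is awkward,
  # so check the strict boundary with a pair at r computed directly
  lnc <- toy_expr(c(base, base), c("l1", "l2"), samples, "lncRNA")
  mrna <- toy_expr(c(base, -base), c("g1", "g2"), samples, "mRNA")
  pairs <- data.frame(lncrna_id = c("l1", "l2"), mrna_id = c("g1", "g2"),
                      n_shared = 1L, hyper_p = 0.5, stringsAsFactors = FALSE)
  pairs$shared_mirnas <- I(list("mi1", "mi1"))
  out <- cerna_network(pairs, lnc, mrna, pcc_threshold = 0.9)
  expect_identical(out$pairs$lncrna_id, "l1")
  expect_equal(out$pairs$pcc, 1)
  # a pair exactly at the threshold is dropped
  out2 <- cerna_network(pairs, lnc, mrna, pcc_threshold = 1)
  expect_equal(nrow(out2$pairs), 0L)
  expect_equal(nrow(out2$triplets), 0L)
})

test_that("triplet count equals the sum of shared counts over retained pairs", {
  s <- small_study(seed = 31, edge_effect = 0.9)
  l2 <- lapply(s$expr, log2_standardize)
  de_m <- select_de(de_test(s$expr$miRNA, s$groups))
  de_g <- select_de(de_test(s$expr$mRNA, s$groups))
  de_l <- select_de(de_test(s$expr$lncRNA, s$groups))
  w_m <- correlation_filter(map_de_edges(
    s$interactions[s$interactions$target_class == "mRNA", ], de_m, de_g),
    l2$miRNA, l2$mRNA)
  w_l <- correlation_filter(map_de_edges(
    s$interactions[s$interactions$target_class == "lncRNA", ], de_m, de_l),
    l2$miRNA, l2$lncRNA)
  cls <- c(stats::setNames(rep("miRNA", nrow(s$expr$miRNA)), rownames(s$expr$miRNA)),
           stats::setNames(rep("mRNA", nrow(s$expr$mRNA)), rownames(s$expr$mRNA)),
           stats::setNames(rep("lncRNA", nrow(s$expr$lncRNA)), rownames(s$expr$lncRNA)))
  pairs <- shared_pairs(build_network(w_m, cls), build_network(w_l, cls))
  out <- cerna_network(pairs, l2$lncRNA, l2$mRNA)
  expect_equal(nrow(out$triplets), sum(out$pairs$n_shared))
  # every triplet's miRNA is among its pair's shared set
  for (i in seq_len(nrow(out$triplets))) {
    j <- which(out$pairs$lncrna_id == out$triplets$lncrna_id[i] &
               out$pairs$mrna_id == out$triplets$mrna_id[i])
    expect_true(out$triplets$mirna_id[i] %in% unlist(out$pairs$shared_mirnas[j]))
  }
})
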