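#' Upper-tail hypergeometric test for shared regulators
#'
#' Probability of observing at least `k` shared miRNA partners between two
#' genes when one has `K` partners, the other `n`, drawn from a universe of
#' `N` miRNAs: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param k Observed shared count.
#' @param K Number of miRNA partners of the first gene.
#' @param n Number of miRNA partners of the second gene.
#' @param N miRNA universe size.
#' @return Upper-tail p-value in (0, 1].
#' @export
hypergeom_shared <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > min(K, n) || K > N || n > N)
    stop("inconsistent hypergeometric counts: need k <= min(K, n) and K, n <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' lncRNA-mRNA pairs sharing at least one miRNA
#'
#' From a miRNA-mRNA network and a miRNA-lncRNA network, enumerates every
#' (lncRNA, mRNA) pair with at least one common miRNA neighbor, recording
#' the shared set and the upper-tail hypergeometric p-value of the overlap
#' (universe = distinct miRNAs in the union of the two networks).
#'
#' @param mir_mrna_net,mir_lnc_net `igraph` graphs from [build_network()]
#'   with `class` vertex attributes; miRNA identifiers must be consistent
#'   between the two.
#' @param mrna_class Node class of the non-miRNA side of `mir_mrna_net`
#'   (`"mRNA"` by default; `"TF"` reuses the machinery for TF-lncRNA
#'   pairing).
#' @return Data frame with `lncrna_id`, `mrna_id`, `n_shared`, `hyper_p`
#'   and a list-column `shared_mirnas`.
#' @export
shared_pairs <- function(mir_mrna_net, mir_lnc_net, mrna_class = "mRNA") {
  nb_map <- function(net, side_class) {
    nm <- igraph::V(net)$name
    cls <- igraph::V(net)$class
    side <- nm[cls == side_class]
    out <- lapply(side, function(v) {
      nb <- igraph::neighbors(net, v)
      nb$name[nb$class == "miRNA"]
    })
    stats::setNames(out, side)
  }
  mrna_nb <- nb_map(mir_mrna_net, mrna_class)
  lnc_nb <- nb_map(mir_lnc_net, "lncRNA")
  universe <- union(
    igraph::V(mir_mrna_net)$name[igraph::V(mir_mrna_net)$class == "miRNA"],
    igraph::V(mir_lnc_net)$name[igraph::V(mir_lnc_net)$class == "miRNA"])
  N <- length(universe)
  rows <- list()
  for (l in names(lnc_nb)) {
    for (m in names(mrna_nb)) {
      sh <- intersect(lnc_nb[[l]], mrna_nb[[m]])
      if (length(sh) == 0L) next
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = l, mrna_id = m, n_shared = length(sh),
        hyper_p = hypergeom_shared(length(sh), length(lnc_nb[[l]]),
                                   length(mrna_nb[[m]]), N),
        stringsAsFactors = FALSE)
      attr(rows[[length(rows)]], "shared") <- sh
    }
  }
  if (!length(rows))
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      n_shared = integer(0), hyper_p = numeric(0),
                      shared_mirnas = I(list()), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out$shared_mirnas <- I(lapply(rows, attr, "shared"))
  rownames(out) <- NULL
  out
}

#' Build the ceRNA network and its lncRNA-miRNA-mRNA triplets
#'
#' Retains the shared-miRNA pairs whose lncRNA-mRNA expression Pearson
#' correlation strictly exceeds `pcc_threshold` (co-expression being the
#' ceRNA signature: both transcripts rise and fall together as they
#' compete for the same miRNAs), optionally also requiring the
#' hypergeometric sharing p-value to fall below `hyper_p_threshold`. One
#' triplet is emitted per retained pair and shared miRNA.
#'
#' @param pairs Data frame from [shared_pairs()].
#' @param lnc_expr,mrna_expr log2-scale `ExpressionMatrix` objects over the
#'   identical ordered sample set.
#' @param pcc_threshold Strict lower bound on the pair PCC, default 0.9.
#' @param hyper_p_threshold Optional upper bound on `hyper_p` (`NULL`
#'   disables the filter, the default).
#' @return List with `network` (lncRNA/mRNA `igraph`), `pairs` (retained
#'   pairs with their `pcc`) and `triplets` (data frame `lncrna_id`,
#'   `mirna_id`, `mrna_id`).
#' @export
cerna_network <- function(pairs, lnc_expr, mrna_expr,
                          pcc_threshold = 0.9, hyper_p_threshold = NULL) {
  if (!identical(colnames(lnc_expr), colnames(mrna_expr)))
    stop("lncRNA and mRNA matrices must share the same ordered samples")
  pcc <- rep(NA_real_, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    l <- pairs$lncrna_id[i]; m <- pairs$mrna_id[i]
    if (!l %in% rownames(lnc_expr) || !m %in% rownames(mrna_expr)) next
    x <- as.numeric(lnc_expr[l, ]); y <- as.numeric(mrna_expr[m, ])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    pcc[i] <- stats::cor(x, y)
  }
  pairs$pcc <- pcc
  keep <- !is.na(pcc) & pcc > pcc_threshold
  if (!is.null(hyper_p_threshold))
    keep <- keep & pairs$hyper_p < hyper_p_threshold
  kept <- pairs[keep, , drop = FALSE]
  rownames(kept) <- NULL
  tri <- if (nrow(kept)) do.call(rbind, lapply(seq_len(nrow(kept)), function(i)
    data.frame(lncrna_id = kept$lncrna_id[i],
               mirna_id = unlist(kept$shared_mirnas[i]),
               mrna_id = kept$mrna_id[i], stringsAsFactors = FALSE)))
  else data.frame(lncrna_id = character(0), mirna_id = character(0),
                  mrna_id = character(0), stringsAsFactors = FALSE)
  rownames(tri) <- NULL
  classes <- c(stats::setNames(rep("lncRNA", length(unique(kept$lncrna_id))),
                               unique(kept$lncrna_id)),
               stats::setNames(rep("mRNA", length(unique(kept$mrna_id))),
                               unique(kept$mrna_id)))
  net <- if (nrow(kept))
    build_network(data.frame(regulator_id = kept$lncrna_id,
                             target_id = kept$mrna_id, pcc = kept$pcc,
                             stringsAsFactors = FALSE), classes)
  else igraph::make_empty_graph(0, directed = FALSE)
  list(network = net, pairs = kept, triplets = tri)
}
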