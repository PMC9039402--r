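#' Restrict an interaction table to differentially expressed endpoints
#'
#' Keeps exactly the edges whose regulator is in `de_regulators` and whose
#' target is in `de_targets` — the curated-edge mapping step that turns a
#' database-wide table into a study-specific candidate set.
#'
#' @param table Data frame with columns `regulator_id`, `target_id`.
#' @param de_regulators,de_targets Character vectors of selected features.
#' @return The qualifying subset of `table`.
#' @export
map_de_edges <- function(table, de_regulators, de_targets) {
  keep <- table$regulator_id %in% de_regulators &
    table$target_id %in% de_targets
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

SEED_TYPES <- c("8mer", "7mer-m8", "7mer-A1", "6mer")

check_alphabet <- function(seq, alphabet, what) {
  ch <- strsplit(seq, "")[[1]]
  bad <- which(!ch %in% alphabet)
  if (length(bad))
    stop(sprintf("invalid %s character '%s' at position %d",
                 what, ch[bad[1]], bad[1]))
  ch
}

#' Canonical miRNA seed-site scan of a target sequence
#'
#' Deterministic seed matching in the TargetScan style: every occurrence on
#' the target of the reverse complement of miRNA positions 2-7 (the 6mer
#' seed match) is reported and classified by its extensions — a match
#' opposite miRNA position 8 (m8) and/or an adenosine opposite position 1
#' (A1): both = `8mer`, m8 only = `7mer-m8`, A1 only = `7mer-A1`, neither =
#' `6mer`. Offsets are 0-based positions of the site start on the target
#' (the m8-pairing base for m8-extended sites, otherwise the 6mer start).
#'
#' @param mirna_seq miRNA sequence, alphabet ACGU, length >= 8.
#' @param target_seq Target (transcript) sequence, alphabet ACGT.
#' @param mirna_id,target_id Optional identifiers carried into the result.
#' @return Data frame with columns `mirna_id`, `target_id`, `site_offset`,
#'   `site_type`.
#' @export
seed_scan <- function(mirna_seq, target_seq,
                      mirna_id = NA_character_, target_id = NA_character_) {
  if (!nzchar(mirna_seq) || !nzchar(target_seq)) stop("empty sequence")
  mch <- check_alphabet(toupper(mirna_seq), c("A", "C", "G", "U"), "miRNA")
  tch <- check_alphabet(toupper(target_seq), c("A", "C", "G", "T"), "target")
  if (length(mch) < 8L) stop("miRNA sequence must be at least 8 nt")
  comp <- c(A = "T", C = "G", G = "C", U = "A")
  # seed match = reverse complement of miRNA positions 2-7, 5'->3' on target
  seed6 <- paste(comp[mch[7:2]], collapse = "")
  m8_base <- comp[[mch[8]]]
  tlen <- length(tch)
  hits <- list()
  if (tlen >= 6L) {
    windows <- vapply(1:(tlen - 5L), function(i)
      paste(tch[i:(i + 5L)], collapse = ""), character(1))
    for (i in which(windows == seed6)) {
      m8 <- i > 1L && tch[i - 1L] == m8_base
      a1 <- i + 6L <= tlen && tch[i + 6L] == "A"
      type <- if (m8 && a1) "8mer" else if (m8) "7mer-m8"
              else if (a1) "7mer-A1" else "6mer"
      off0 <- if (m8) i - 2L else i - 1L   # 0-based site start
      hits[[length(hits) + 1L]] <- data.frame(
        mirna_id = mirna_id, target_id = target_id,
        site_offset = off0, site_type = type, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(mirna_id = character(0), target_id = character(0),
                      site_offset = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Seed-scan a set of miRNAs against a set of targets
#'
#' Convenience wrapper calling [seed_scan()] for every (miRNA, target)
#' combination and returning the edge list of pairs with at least one site.
#'
#' @param mirna_seqs,target_seqs Named character vectors.
#' @param min_type Weakest site class that counts as an interaction, one of
#'   `"6mer"`, `"7mer-A1"`, `"7mer-m8"`, `"8mer"` (ordered weakest to
#'   strongest); default `"7mer-A1"`.
#' @return List with `hits` (all sites) and `edges` (unique qualifying
#'   regulator/target pairs).
#' @export
seed_scan_all <- function(mirna_seqs, target_seqs, min_type = "7mer-A1") {
  rank <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer" = 4L)
  if (!min_type %in% names(rank)) stop("unknown site type: ", min_type)
  out <- list()
  for (mir in names(mirna_seqs))
    for (tg in names(target_seqs)) {
      h <- seed_scan(mirna_seqs[[mir]], target_seqs[[tg]], mir, tg)
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(mirna_id = character(0), target_id = character(0),
               site_offset = integer(0), site_type = character(0),
               stringsAsFactors = FALSE)
  good <- hits[rank[hits$site_type] >= rank[[min_type]], , drop = FALSE]
  edges <- unique(data.frame(regulator_id = good$mirna_id,
                             target_id = good$target_id,
                             stringsAsFactors = FALSE))
  rownames(edges) <- NULL
  list(hits = hits, edges = edges)
}

#' Retain negatively expression-correlated regulator-target edges
#'
#' Computes the Pearson correlation (and its test p-value) between each
#' edge's regulator and target across the shared, identically ordered
#' samples, and keeps edges with `r < 0`; when
#' `require_significance = TRUE` (default) the correlation-test p must also
#' fall below `p_threshold`. Zero-variance features make the correlation
#' undefined: such edges are skipped with a warning.
#'
#' @param edges Data frame with `regulator_id`, `target_id`.
#' @param regulator_expr,target_expr log2-scale `ExpressionMatrix` objects
#'   over the identical ordered sample set.
#' @param p_threshold Correlation-test p-value threshold, default 0.05.
#' @param require_significance If `FALSE`, retain on `r < 0` alone.
#' @return Data frame of retained edges with `pcc` and `pcc_p` columns.
#' @export
correlation_filter <- function(edges, regulator_expr, target_expr,
                               p_threshold = 0.05,
                               require_significance = TRUE) {
  if (!identical(colnames(regulator_expr), colnames(target_expr)))
    stop("regulator and target matrices must share the same ordered samples")
  w <- edge_correlations(edges, regulator_expr, target_expr)
  keep <- !is.na(w$pcc) & w$pcc < 0
  if (require_significance) keep <- keep & w$pcc_p < p_threshold
  out <- w[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pearson r and test p per edge; NA (with one warning) for degenerate rows
edge_correlations <- function(edges, regulator_expr, target_expr) {
  pcc <- pcc_p <- rep(NA_real_, nrow(edges))
  n_skip <- 0L
  for (i in seq_len(nrow(edges))) {
    r_id <- edges$regulator_id[i]
    t_id <- edges$target_id[i]
    if (!r_id %in% rownames(regulator_expr) ||
        !t_id %in% rownames(target_expr)) next
    x <- as.numeric(regulator_expr[r_id, ])
    y <- as.numeric(target_expr[t_id, ])
    if (stats::sd(x) == 0 || stats::sd(y) == 0) { n_skip <- n_skip + 1L; next }
    ct <- stats::cor.test(x, y, method = "pearson")
    pcc[i] <- unname(ct$estimate)
    pcc_p[i] <- ct$p.value
  }
  if (n_skip > 0L)
    warning(sprintf("%d edge(s) skipped: zero-variance feature", n_skip))
  data.frame(regulator_id = edges$regulator_id, target_id = edges$target_id,
             pcc = pcc, pcc_p = pcc_p, stringsAsFactors = FALSE)
}
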