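#' Correlate lncRNA expression with immune-infiltration scores
#'
#' Pearson correlation (and test p-value) of every lncRNA against every
#' infiltration cell type across the intersected, identically ordered
#' samples. Zero-variance columns give `NA` entries and a warning.
#'
#' @param lnc_expr log2-scale `ExpressionMatrix` (lncRNAs x samples).
#' @param infil Numeric matrix of infiltration estimation scores, samples
#'   in rows (rownames = sample ids), cell types in columns.
#' @return List with matrices `r` and `p` (lncRNA x cell type).
#' @export
infiltration_correlation <- function(lnc_expr, infil) {
  shared <- intersect(colnames(lnc_expr), rownames(infil))
  if (length(shared) < 3L) stop("need at least 3 shared samples")
  x <- unclass(lnc_expr)[, shared, drop = FALSE]
  y <- infil[shared, , drop = FALSE]
  r <- matrix(NA_real_, nrow(x), ncol(y),
              dimnames = list(rownames(x), colnames(y)))
  p <- r
  n_degen <- 0L
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(y))) {
    if (stats::sd(x[i, ]) == 0 || stats::sd(y[, j]) == 0) {
      n_degen <- n_degen + 1L
      next
    }
    ct <- stats::cor.test(x[i, ], y[, j], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  if (n_degen > 0L)
    warning(sprintf("%d correlation(s) undefined (zero variance)", n_degen))
  list(r = r, p = p)
}

#' Over-representation analysis of a feature set
#'
#' Upper-tail hypergeometric test of the overlap between a query set and
#' each collection, with Benjamini-Hochberg adjustment across collections.
#'
#' @param query Character vector, must be a subset of `universe`.
#' @param collections Named list of character vectors (the gene sets).
#' @param universe Character vector of all testable features.
#' @return Data frame with `set_id`, `set_size`, `overlap`, `p_value`,
#'   `bh_adjusted_p`, sorted by p-value.
#' @export
ora <- function(query, collections, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  if (!all(query %in% universe))
    stop("query contains features outside the universe")
  query <- unique(query)
  rows <- lapply(names(collections), function(s) {
    set <- intersect(unique(collections[[s]]), universe)
    k <- length(intersect(query, set))
    p <- hypergeom_shared(k, length(set), length(query), length(universe))
    data.frame(set_id = s, set_size = length(set), overlap = k, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bh_adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
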