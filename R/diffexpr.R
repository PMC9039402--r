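#' Two-group differential expression on count matrices
#'
#' An exact negative-binomial test for tumor-vs-normal count data. Library
#' sizes are equalised by total-count scaling (counts rescaled to the mean
#' library size), a single common dispersion is estimated by the method of
#' moments across features, and each feature's scaled group sums are
#' compared with a conditional exact test: given the total, the first
#' group's sum follows the convolution ratio of two negative binomials
#' under the null of equal means, reducing to an exact binomial test when
#' the dispersion estimate is zero. Two-sided p-values sum the
#' probabilities of all outcomes no more likely than the observed one.
#'
#' This is a deliberately compact count-model test in the spirit of the
#' classic exact NB tests used for small two-group designs; it uses one
#' common dispersion and total-count (not trimmed-mean) normalisation.
#' P-values are raw by default; set `adjust = "BH"` for
#' Benjamini-Hochberg adjustment.
#'
#' @param counts `ExpressionMatrix` of raw non-negative integer counts.
#' @param groups Two-level factor (or coercible) over the columns of
#'   `counts`; the first level is group A, the second group B.
#' @param dispersion Optional fixed common dispersion phi; by default
#'   estimated by method of moments (floored at 0).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame with one row per feature: `feature_id`, `mean_a`,
#'   `mean_b` (normalised group means), `log2fc` = log2(mean_b/mean_a),
#'   `p_value`, `is_de` (|log2fc| > 1 and p < 0.05 by default).
#' @export
de_test <- function(counts, groups, dispersion = NULL, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(counts, "ExpressionMatrix"))
  if (expr_scale(counts) != "raw") stop("de_test needs raw counts")
  m <- unclass(counts)
  if (any(m != round(m))) stop("counts must be integers")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("'groups' must have exactly two levels")
  if (length(groups) != ncol(m)) stop("one group label per sample required")
  a <- groups == levels(groups)[1L]
  b <- !a
  if (sum(a) < 1L || sum(b) < 1L) stop("each group needs at least one sample")
  lib <- colSums(m)
  if (sum(lib[a]) == 0 || sum(lib[b]) == 0)
    stop("a group has zero total counts")
  lib[lib == 0] <- 1  # empty samples contribute zeros regardless of scaling
  sf <- mean(colSums(m)) / lib
  ms <- sweep(m, 2L, sf, `*`)          # counts scaled to a common library size

  mean_a <- rowMeans(ms[, a, drop = FALSE])
  mean_b <- rowMeans(ms[, b, drop = FALSE])

  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(ms, a, b)
  if (dispersion < 0) stop("dispersion must be >= 0")

  sa <- round(rowSums(ms[, a, drop = FALSE]))
  sb <- round(rowSums(ms[, b, drop = FALSE]))
  pv <- vapply(seq_len(nrow(ms)), function(i)
    nb_exact_p(sa[i], sb[i], sum(a), sum(b), dispersion), numeric(1))
  if (adjust == "BH") pv <- stats::p.adjust(pv, method = "BH")

  log2fc <- log2(mean_b / mean_a)
  log2fc[mean_a == 0 & mean_b == 0] <- 0
  res <- data.frame(feature_id = rownames(m), mean_a = mean_a,
                    mean_b = mean_b, log2fc = log2fc, p_value = pv,
                    row.names = NULL, stringsAsFactors = FALSE)
  res$is_de <- abs(res$log2fc) > 1 & res$p_value < 0.05
  attr(res, "dispersion") <- dispersion
  res
}

# method-of-moments common dispersion on library-size-scaled counts:
# within-group mean/variance per feature, phi_i = (v - mu)/mu^2 pooled
# across groups, averaged over informative features and floored at zero
estimate_common_dispersion <- function(ms, a, b) {
  phi_of <- function(x) {
    if (ncol(x) < 2L) return(rep(NA_real_, nrow(x)))
    mu <- rowMeans(x)
    v <- apply(x, 1L, stats::var)
    ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  }
  phis <- cbind(phi_of(ms[, a, drop = FALSE]), phi_of(ms[, b, drop = FALSE]))
  est <- mean(phis, na.rm = TRUE)
  if (!is.finite(est)) est <- 0
  max(0, est)
}

# conditional exact NB test: given T = sa + sb, the group-A sum under the
# null has mass proportional to dnbinom(x; size = na/phi) * dnbinom(T - x;
# size = nb/phi) at the common mean; phi = 0 degenerates to Binomial(T,
# na/(na+nb)). Two-sided p sums masses <= observed mass (small tolerance
# for float ties, as in the standard exact binomial test).
nb_exact_p <- function(sa, sb, na, nb, phi) {
  tot <- sa + sb
  if (tot == 0) return(1)
  x <- 0:tot
  if (phi <= 0) {
    logf <- stats::dbinom(x, tot, na / (na + nb), log = TRUE)
  } else {
    mu <- tot / (na + nb)  # common per-sample mean under the null
    logf <- stats::dnbinom(x, size = na / phi, mu = na * mu, log = TRUE) +
      stats::dnbinom(tot - x, size = nb / phi, mu = nb * mu, log = TRUE)
  }
  logf <- logf - max(logf)
  f <- exp(logf)
  f <- f / sum(f)
  obs <- f[sa + 1L]
  min(1, sum(f[f <= obs * (1 + 1e-7)]))
}

#' Select differentially expressed features
#'
#' Applies the fold-change and p-value selection rule: strictly
#' `|log2fc| > log2(fc_threshold)` and `p < p_threshold`.
#'
#' @param results Data frame from [de_test()].
#' @param fc_threshold Fold-change threshold (> 0), default 2.
#' @param p_threshold P-value threshold (> 0), default 0.05.
#' @return Character vector of selected feature ids.
#' @export
select_de <- function(results, fc_threshold = 2, p_threshold = 0.05) {
  if (fc_threshold <= 0 || p_threshold <= 0)
    stop("thresholds must be positive")
  if (NROW(results) == 0) return(character(0))
  sel <- abs(results$log2fc) > log2(fc_threshold) &
    results$p_value < p_threshold
  results$feature_id[sel & !is.na(sel)]
}
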