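# shared fixtures and independent oracles used across test files

graph_from_pairs <- function(..., classes = NULL) {
  e <- matrix(c(...), ncol = 2, byrow = TRUE)
  df <- data.frame(regulator_id = e[, 1], target_id = e[, 2],
                   stringsAsFactors = FALSE)
  if (is.null(classes)) {
    ids <- unique(c(e))
    classes <- stats::setNames(rep("mRNA", length(ids)), ids)
  }
  build_network(df, classes)
}

# Floyd-Warshall all-pairs shortest paths; average over connected ordered
# pairs (the independent oracle for avg_path_length)
fw_avg_path <- function(net) {
  n <- igraph::vcount(net)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  el <- igraph::as_edgelist(net, names = FALSE)
  for (i in seq_len(nrow(el))) {
    d[el[i, 1], el[i, 2]] <- 1
    d[el[i, 2], el[i, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  vals <- d[row(d) != col(d)]
  mean(vals[is.finite(vals)])
}

# brute-force grid maximisation of the Breslow partial log-likelihood
# (independent oracle for cox_univariate on tiny fixtures)
grid_cox_beta <- function(time, event, x, lo = -8, hi = 8, tol = 1e-5) {
  pll <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  stats::optimize(pll, c(lo, hi), maximum = TRUE, tol = tol)$maximum
}

# exhaustive hypergeometric upper tail by enumeration over C(K,x)C(N-K,n-x)
enum_hyper_upper <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

toy_expr <- function(values, ids, samples, class = "mRNA", scale = "log2") {
  m <- matrix(values, nrow = length(ids), byrow = TRUE,
              dimnames = list(ids, samples))
  expression_matrix(m, feature_class = class, scale = scale)
}

small_study <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_tumor = 40L, n_normal = 10L, n_mirna = 40L, n_lncrna = 25L,
         n_mrna = 80L, frac_de = 0.4, n_true_edges = 30L, n_triplets = 5L,
         seed = seed),
    list(...))
  generate_study(do.call(synth_config, args))
}
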