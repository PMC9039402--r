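#' Build a typed regulatory network
#'
#' Constructs an undirected [igraph] graph whose vertices carry a `class`
#' attribute (`miRNA`, `lncRNA`, `mRNA` or `TF`) and whose edges may carry
#' the Pearson correlation (`pcc`) that produced them. Self-loops and
#' parallel edges are removed.
#'
#' @param edges Data frame with `regulator_id`, `target_id` and optionally
#'   `pcc`.
#' @param node_classes Named character vector mapping node id to class;
#'   nodes absent from it get class `"unknown"`.
#' @return An undirected `igraph` graph.
#' @export
build_network <- function(edges, node_classes = character(0)) {
  ids <- unique(c(edges$regulator_id, edges$target_id))
  g <- igraph::graph_from_data_frame(
    edges[, c("regulator_id", "target_id",
              intersect("pcc", names(edges))), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  g <- igraph::simplify(g, edge.attr.comb = "first")
  cls <- rep("unknown", length(ids))
  hit <- ids %in% names(node_classes)
  cls[hit] <- unname(node_classes[ids[hit]])
  igraph::V(g)$class <- cls
  g
}

#' Topology summary of a network
#'
#' Reports the degree map, mean local clustering coefficient (vertices of
#' degree < 2 contribute 0), average shortest-path length over connected
#' ordered pairs, and the R-squared of a least-squares power-law fit of
#' log10(frequency) on log10(degree) over unique positive degrees.
#'
#' @param net An `igraph` graph with at least 2 vertices.
#' @param largest_component_only If `TRUE`, restrict the path-length
#'   average to the largest connected component.
#' @return List with `degree_map`, `mean_clustering`, `avg_path_length`,
#'   `powerlaw_r2` (NA when fewer than 2 unique degrees), `n_nodes`,
#'   `n_edges`.
#' @export
topology <- function(net, largest_component_only = FALSE) {
  if (igraph::vcount(net) == 0) stop("empty graph")
  if (igraph::vcount(net) < 2) stop("topology needs at least 2 vertices")
  deg <- igraph::degree(net)
  cc <- igraph::transitivity(net, type = "local", isolates = "zero")
  g_paths <- net
  if (largest_component_only) {
    comp <- igraph::components(net)
    g_paths <- igraph::induced_subgraph(
      net, which(comp$membership == which.max(comp$csize)))
  }
  apl <- igraph::mean_distance(g_paths, directed = FALSE, unconnected = TRUE)
  list(degree_map = deg,
       mean_clustering = mean(cc),
       avg_path_length = apl,
       powerlaw_r2 = powerlaw_r2(deg),
       n_nodes = igraph::vcount(net),
       n_edges = igraph::ecount(net))
}

# least-squares R^2 of log10 degree-frequency over unique degrees >= 1
# (for simple regression, R^2 = squared Pearson correlation)
powerlaw_r2 <- function(deg) {
  deg <- deg[deg >= 1]
  tab <- table(deg)
  if (length(tab) < 2L) return(NA_real_)
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  stats::cor(x, y)^2
}

# one degree-preserving randomisation by repeated double-edge swaps;
# n_attempts proposals, rejecting any that would create a loop or
# parallel edge. Returns the rewired graph and the number of accepted swaps.
double_edge_swap <- function(net, n_attempts = 10L * igraph::ecount(net)) {
  el <- igraph::as_edgelist(net, names = FALSE)
  m <- nrow(el)
  if (m < 2L) return(list(graph = net, accepted = 0L))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(m)) assign(key(el[i, 1], el[i, 2]), TRUE, envir = present)
  acc <- 0L
  pick <- matrix(sample.int(m, 2L * n_attempts, replace = TRUE), ncol = 2L)
  flip <- stats::runif(n_attempts) < 0.5
  for (t in seq_len(n_attempts)) {
    i <- pick[t, 1]; j <- pick[t, 2]
    if (i == j) next
    a <- el[i, 1]; b <- el[i, 2]; c <- el[j, 1]; d <- el[j, 2]
    if (flip[t]) { tmp <- c; c <- d; d <- tmp }
    # propose a-d, c-b
    if (a == d || c == b) next
    if (length(unique(c(a, b, c, d))) < 4L) next
    k1 <- key(a, d); k2 <- key(c, b)
    if (exists(k1, envir = present, inherits = FALSE) ||
        exists(k2, envir = present, inherits = FALSE)) next
    rm(list = c(key(a, b), key(c, d)), envir = present)
    assign(k1, TRUE, envir = present)
    assign(k2, TRUE, envir = present)
    el[i, ] <- c(a, d); el[j, ] <- c(c, b)
    acc <- acc + 1L
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  # carry over vertex count/names for isolated vertices
  if (igraph::vcount(g) < igraph::vcount(net))
    g <- igraph::add_vertices(g, igraph::vcount(net) - igraph::vcount(g))
  if (!is.null(igraph::V(net)$name))
    igraph::V(g)$name <- igraph::V(net)$name
  if (!is.null(igraph::V(net)$class))
    igraph::V(g)$class <- igraph::V(net)$class
  list(graph = g, accepted = acc)
}

#' Degree-preserving null-model test of a topology statistic
#'
#' Compares an observed statistic (mean clustering coefficient or average
#' path length) against an ensemble of degree-preserving randomisations of
#' the graph. Each null graph is produced by attempted double-edge swaps
#' (10 x |edges| proposals, rejecting self-loops and parallel edges), which
#' leaves every vertex's degree unchanged. The empirical p-value uses the
#' add-one rank correction and follows the one-sided direction of interest:
#' clustering is tested for being *larger* than random
#' (`P(null >= observed)`) and path length for being *shorter*
#' (`P(null <= observed)`).
#'
#' @param net An `igraph` graph with >= 2 edges.
#' @param statistic `"clustering"` or `"path_length"`.
#' @param n_null Number of null graphs, default 1000.
#' @param seed Integer seed for the rewiring ensemble.
#' @return List with `observed`, `null_values` (length `n_null`),
#'   `empirical_p` and `statistic`.
#' @export
degree_preserving_null <- function(net, statistic = c("clustering", "path_length"),
                                   n_null = 1000L, seed = 1L) {
  statistic <- match.arg(statistic)
  if (igraph::ecount(net) < 2L) stop("need at least 2 edges to rewire")
  stat_fun <- if (statistic == "clustering") {
    function(g) mean(igraph::transitivity(g, type = "local", isolates = "zero"))
  } else {
    function(g) igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  }
  observed <- stat_fun(net)
  set.seed(seed)
  null_values <- numeric(n_null)
  total_acc <- 0L
  for (r in seq_len(n_null)) {
    sw <- double_edge_swap(net)
    total_acc <- total_acc + sw$accepted
    null_values[r] <- stat_fun(sw$graph)
  }
  if (total_acc == 0L)
    warning("no legal double-edge swap exists; null ensemble equals the observed graph")
  empirical_p <- if (statistic == "clustering")
    (sum(null_values >= observed) + 1) / (n_null + 1)
  else
    (sum(null_values <= observed) + 1) / (n_null + 1)
  list(observed = observed, null_values = null_values,
       empirical_p = empirical_p, statistic = statistic)
}

#' Select hub nodes per class
#'
#' Ranks the nodes of each requested class by degree (within the full
#' graph) and returns the top `ceiling(fraction x class size)`; all nodes
#' tied at the cutoff degree are included.
#'
#' @param net An `igraph` graph with a `class` vertex attribute.
#' @param fraction Top fraction in (0, 1], default 0.2.
#' @param classes Character vector of node classes to rank.
#' @return Character vector of hub node names.
#' @export
select_hubs <- function(net, fraction = 0.2, classes = c("miRNA", "lncRNA")) {
  if (fraction <= 0 || fraction > 1) stop("fraction must lie in (0, 1]")
  cls <- igraph::V(net)$class
  deg <- igraph::degree(net)
  nm <- igraph::V(net)$name
  hubs <- character(0)
  for (cl in classes) {
    in_cl <- cls == cl
    if (!any(in_cl)) stop("node class absent from network: ", cl)
    d <- deg[in_cl]
    k <- ceiling(fraction * sum(in_cl))
    cutoff <- sort(d, decreasing = TRUE)[k]
    hubs <- c(hubs, nm[in_cl][d >= cutoff])
  }
  hubs
}
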