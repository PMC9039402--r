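#' Parameters for MCODE molecular complex detection
#'
#' Defaults follow the common plug-in settings for module extraction from
#' regulatory networks: degree cut-off 2, node score cut-off 0.2, k-core 2,
#' max depth 100, and a module-score threshold of 5 (modules with score
#' strictly greater than 5 are reported). Haircut is on and fluff off, the
#' plug-in's own defaults.
#'
#' @param degree_cutoff Minimum degree for a vertex to receive a weight.
#' @param node_score_cutoff Expansion tolerance in `[0, 1]`: a neighbor
#'   joins when its weight >= seed weight x (1 - cutoff).
#' @param k_core Core level of the post-expansion haircut.
#' @param max_depth Maximum BFS depth from the seed.
#' @param min_module_score Only modules with score strictly above this are
#'   returned.
#' @param haircut,fluff Post-processing switches (fluff is not applied by
#'   default and is retained for interface completeness).
#' @return A `mcode_params` list.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L,
                         min_module_score = 5, haircut = TRUE, fluff = FALSE) {
  if (node_score_cutoff < 0 || node_score_cutoff > 1)
    stop("node_score_cutoff must lie in [0, 1]")
  structure(list(degree_cutoff = as.integer(degree_cutoff),
                 node_score_cutoff = node_score_cutoff,
                 k_core = as.integer(k_core),
                 max_depth = as.integer(max_depth),
                 min_module_score = min_module_score,
                 haircut = isTRUE(haircut), fluff = isTRUE(fluff)),
            class = "mcode_params")
}

# loop-free density 2E / (V (V - 1)); 0 for graphs with < 2 vertices
graph_density <- function(g) {
  v <- igraph::vcount(g)
  if (v < 2L) return(0)
  2 * igraph::ecount(g) / (v * (v - 1))
}

#' MCODE vertex weight
#'
#' The weight of a vertex is `k x density` of the highest k-core of its
#' closed neighborhood (the vertex plus its direct neighbors); vertices
#' whose degree falls below `degree_cutoff` get weight 0.
#'
#' @param net An `igraph` graph.
#' @param node Vertex name.
#' @param degree_cutoff Minimum degree, default 2.
#' @return Non-negative numeric weight.
#' @export
vertex_weight <- function(net, node, degree_cutoff = 2L) {
  v <- match(node, igraph::V(net)$name)
  if (is.na(v)) stop("node not in network: ", node)
  if (igraph::degree(net, v) < degree_cutoff) return(0)
  nb <- c(v, as.integer(igraph::neighbors(net, v)))
  sub <- igraph::induced_subgraph(net, nb)
  core <- igraph::coreness(sub)
  kmax <- max(core)
  if (kmax == 0L) return(0)
  hk <- igraph::induced_subgraph(sub, which(core >= kmax))
  kmax * graph_density(hk)
}

all_vertex_weights <- function(net, degree_cutoff) {
  nm <- igraph::V(net)$name
  vapply(nm, function(v) vertex_weight(net, v, degree_cutoff), numeric(1))
}

#' Find dense modules with MCODE
#'
#' Seed-and-expand complex detection: vertices are weighted by the k-core
#' density of their closed neighborhood, then complexes grow outward from
#' the highest-weight unvisited seed, admitting neighbors whose weight is
#' within `node_score_cutoff` of the seed's. Each vertex belongs to at most
#' one complex. An optional haircut trims the result to its `k_core`-core
#' (keeping the seed's component). Modules are scored density x size and
#' only those scoring strictly above `min_module_score` are returned,
#' sorted by score descending. Weight ties are broken lexicographically by
#' vertex name, making the output deterministic.
#'
#' @param net An `igraph` graph.
#' @param params A [mcode_params()].
#' @return List of modules, each a list with `nodes`, `score`, `seed_node`,
#'   `density`.
#' @export
find_modules <- function(net, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  n <- igraph::vcount(net)
  if (n == 0L) return(list())
  nm <- igraph::V(net)$name
  w <- all_vertex_weights(net, params$degree_cutoff)
  ord <- order(-w, nm)           # weight desc, lexicographic tie-break
  visited <- rep(FALSE, n)
  adj <- igraph::as_adj_list(net)
  modules <- list()
  for (s in ord) {
    if (visited[s]) next
    seed_w <- w[s]
    thresh <- seed_w * (1 - params$node_score_cutoff)
    members <- s
    visited[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- integer(0)
      for (u in frontier) {
        for (vv in as.integer(adj[[u]])) {
          if (visited[vv]) next
          if (w[vv] >= thresh && w[vv] > 0) {
            visited[vv] <- TRUE
            members <- c(members, vv)
            nxt <- c(nxt, vv)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    sub <- igraph::induced_subgraph(net, members)
    keep_names <- igraph::V(sub)$name
    if (params$haircut && igraph::vcount(sub) > 0L) {
      core <- igraph::coreness(sub)
      in_core <- core >= params$k_core
      if (any(in_core)) {
        hk <- igraph::induced_subgraph(sub, which(in_core))
        # haircut may disconnect: keep the component containing the seed,
        # or the largest if the seed itself was trimmed
        comp <- igraph::components(hk)
        seed_pos <- match(nm[s], igraph::V(hk)$name)
        cid <- if (!is.na(seed_pos)) comp$membership[seed_pos]
               else which.max(comp$csize)
        hk <- igraph::induced_subgraph(hk, which(comp$membership == cid))
        sub <- hk
        keep_names <- igraph::V(sub)$name
      } else {
        keep_names <- character(0)
      }
    }
    if (length(keep_names) == 0L) next
    dens <- graph_density(sub)
    score <- dens * igraph::vcount(sub)
    if (score > params$min_module_score) {
      modules[[length(modules) + 1L]] <- list(
        nodes = sort(keep_names), score = score,
        seed_node = nm[s], density = dens)
    }
  }
  modules[order(-vapply(modules, `[[`, numeric(1), "score"))]
}
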