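#' Module set container
#'
#' A family of node subsets produced by one partitioning method. For `mcl`
#' and `greedy` the modules are pairwise disjoint and, together with
#' `unassigned`, cover all nodes; `mcode` complexes may overlap and
#' `unassigned` holds nodes in no complex. Every module has at least
#' `min_size` members and induces a connected subgraph.
#'
#' @param method one of `"mcode"`, `"mcl"`, `"greedy"`.
#' @param modules list of character vectors (node identifiers).
#' @param unassigned character vector of unassigned nodes.
#' @param params named list of parameters actually used.
#' @param scores optional numeric vector of per-module scores.
#' @return object of class `module_set`.
#' @export
module_set <- function(method, modules, unassigned, params = list(),
                       scores = NULL) {
  stopifnot(method %in% c("mcode", "mcl", "greedy"))
  structure(list(method = method, modules = modules,
                 unassigned = unassigned, params = params, scores = scores),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> method=%s: %d module(s) of sizes [%s], %d unassigned\n",
              x$method, length(x$modules),
              paste(vapply(x$modules, length, integer(1)), collapse = ", "),
              length(x$unassigned)))
  invisible(x)
}

# density of a simple undirected graph (0 for < 2 vertices)
.density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2L) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

# MCODE vertex weight: highest-k-core density of the closed neighbourhood,
# times k (the core-clustering coefficient weighting)
.mcode_weights <- function(net) {
  vs <- sort(igraph::V(net)$name)
  w <- stats::setNames(numeric(length(vs)), vs)
  for (v in vs) {
    nb <- igraph::neighbors(net, v)$name
    sub <- igraph::induced_subgraph(net, c(v, nb))
    if (igraph::ecount(sub) == 0L) { w[v] <- 0; next }
    core <- igraph::coreness(sub)
    k <- max(core)
    top <- igraph::induced_subgraph(sub, names(core)[core == k])
    w[v] <- k * .density(top)
  }
  w
}

#' Molecular complex detection (MCODE)
#'
#' Detects densely connected complexes by the MCODE procedure: vertices are
#' weighted by the core-clustering coefficient (density of the highest
#' k-core of the closed neighbourhood, scaled by k), complexes grow outward
#' from the highest-weighted unvisited seed, admitting neighbours whose
#' weight exceeds `(1 - vwp)` of the seed weight, and are post-processed by
#' the optional haircut (2-core) and fluff steps. Complexes are scored by
#' density times size and returned in descending score order.
#'
#' @param net an undirected [igraph::graph].
#' @param vwp vertex weight percentage in `[0, 1]`; larger values grow
#'   larger, looser complexes.
#' @param haircut remove singly-connected vertices (keep the 2-core).
#' @param fluff add unvisited neighbours whose closed-neighbourhood density
#'   exceeds `fluff_density` (may create overlapping complexes).
#' @param fluff_density density threshold for the fluff step.
#' @param min_size minimum complex size retained.
#' @return a [module_set] with `method = "mcode"`.
#' @export
mcode <- function(net, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                  fluff_density = 0.1, min_size = 3L) {
  stopifnot(vwp >= 0, vwp <= 1)
  if (igraph::vcount(net) == 0L) stop("empty network")
  w <- .mcode_weights(net)
  # seed order: descending weight, lexicographic names on ties
  order_v <- names(w)[order(-w, names(w))]
  seen <- character(0)
  complexes <- list()
  for (seed in order_v) {
    if (seed %in% seen || w[seed] <= 0) next
    thr <- (1 - vwp) * w[seed]
    comp <- seed
    frontier <- seed
    while (length(frontier)) {
      nb <- unique(unlist(lapply(frontier, function(v)
        igraph::neighbors(net, v)$name)))
      nb <- sort(setdiff(nb, c(comp, seen)))
      add <- nb[w[nb] > thr]
      comp <- c(comp, add)
      frontier <- add
    }
    seen <- c(seen, comp)
    complexes[[length(complexes) + 1L]] <- comp
  }

  post <- list()
  for (comp in complexes) {
    sub <- igraph::induced_subgraph(net, comp)
    if (haircut && igraph::vcount(sub) > 1L) {
      core <- igraph::coreness(sub)
      keep <- names(core)[core >= 2L]
      sub <- igraph::induced_subgraph(net, keep)
    }
    if (fluff) {
      nb <- unique(unlist(lapply(igraph::V(sub)$name, function(v)
        igraph::neighbors(net, v)$name)))
      nb <- sort(setdiff(nb, igraph::V(sub)$name))
      nbd <- vapply(nb, function(v) {
        cl <- c(v, igraph::neighbors(net, v)$name)
        .density(igraph::induced_subgraph(net, cl))
      }, numeric(1))
      sub <- igraph::induced_subgraph(net,
        c(igraph::V(sub)$name, nb[nbd > fluff_density]))
    }
    # each complex must be connected; split if post-processing disconnected it
    if (igraph::vcount(sub) == 0L) next
    memb <- igraph::components(sub)$membership
    for (ci in sort(unique(memb))) {
      nodes <- sort(names(memb)[memb == ci])
      if (length(nodes) >= min_size)
        post[[length(post) + 1L]] <- nodes
    }
  }
  scores <- vapply(post, function(nodes) {
    sub <- igraph::induced_subgraph(net, nodes)
    .density(sub) * length(nodes)
  }, numeric(1))
  ord <- order(-scores, vapply(post, `[`, character(1), 1L))
  post <- post[ord]; scores <- scores[ord]
  unassigned <- sort(setdiff(igraph::V(net)$name, unlist(post)))
  module_set("mcode", post, unassigned,
             params = list(vwp = vwp, haircut = haircut, fluff = fluff,
                           min_size = min_size),
             scores = scores)
}

#' Markov clustering (MCL)
#'
#' Standard MCL flow simulation on the column-stochastic transition matrix
#' (self-loops of weight 1 added): expansion is a matrix power, inflation an
#' entrywise power followed by column renormalisation, with entries below
#' `prune_threshold` removed. Clusters are the connected components of the
#' converged flow matrix; clusters smaller than `min_size` go to
#' `unassigned`.
#'
#' @param net an undirected [igraph::graph] (may be disconnected).
#' @param inflation inflation exponent (> 1); larger values give finer
#'   clusters.
#' @param expansion expansion power (integer >= 2).
#' @param prune_threshold entries below this are zeroed each iteration.
#' @param max_iter iteration cap; non-convergence is flagged, not an error.
#' @param min_size minimum cluster size retained.
#' @return a [module_set] with `method = "mcl"` and attribute `converged`.
#' @export
mcl <- function(net, inflation = 2, expansion = 2L, prune_threshold = 1e-5,
                max_iter = 100L, min_size = 3L) {
  stopifnot(inflation > 1, expansion >= 2L)
  vs <- sort(igraph::V(net)$name)  # fixed node order: deterministic pruning
  n <- length(vs)
  wattr <- if ("weight" %in% igraph::edge_attr_names(net)) "weight" else NULL
  A <- igraph::as_adjacency_matrix(net, attr = wattr, sparse = FALSE)
  A <- A[vs, vs, drop = FALSE]
  diag(A) <- 1
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp^inflation
    Minf[Minf < prune_threshold] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1  # isolated columns stay zero
    Mnew <- sweep(Minf, 2L, cs, "/")
    if (max(abs(Mnew - M)) < 1e-8) { M <- Mnew; converged <- TRUE; break }
    M <- Mnew
  }
  # clusters: components of the symmetrised support of the limit matrix
  supp <- (M > prune_threshold) | t(M > prune_threshold)
  gl <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                            diag = FALSE)
  memb <- igraph::components(gl)$membership
  names(memb) <- vs
  mods <- split(names(memb), memb)
  mods <- lapply(mods, sort)
  # split any cluster not connected in the input network
  out <- list()
  for (m in mods) {
    cm <- igraph::components(igraph::induced_subgraph(net, m))$membership
    for (ci in sort(unique(cm)))
      out[[length(out) + 1L]] <- sort(names(cm)[cm == ci])
  }
  keep <- vapply(out, length, integer(1)) >= min_size
  modules <- out[keep]
  modules <- modules[order(vapply(modules, `[`, character(1), 1L))]
  unassigned <- sort(unlist(out[!keep]))
  ms <- module_set("mcl", modules, unassigned,
                   params = list(inflation = inflation, expansion = expansion,
                                 prune_threshold = prune_threshold,
                                 max_iter = max_iter, min_size = min_size))
  attr(ms, "converged") <- converged
  ms
}

#' Fast-greedy modularity community detection
#'
#' Newman fast-greedy agglomerative maximisation of modularity
#' \eqn{Q = \sum_c (e_c/m - (d_c/2m)^2)} (the community-detection core of
#' the GLay Cytoscape plugin), via [igraph::cluster_fast_greedy()].
#' Communities smaller than `min_size` are moved to `unassigned`.
#'
#' @param net an undirected [igraph::graph] with at least one edge.
#' @param min_size minimum community size retained.
#' @return a [module_set] with `method = "greedy"`.
#' @export
greedy_modularity <- function(net, min_size = 3L) {
  if (igraph::ecount(net) == 0L) stop("network has no edges")
  g <- igraph::simplify(net)
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  memb <- igraph::membership(cl)
  mods <- lapply(split(names(memb), memb), sort)
  keep <- vapply(mods, length, integer(1)) >= min_size
  modules <- unname(mods[keep])
  modules <- modules[order(vapply(modules, `[`, character(1), 1L))]
  unassigned <- sort(unlist(mods[!keep], use.names = FALSE))
  module_set("greedy", modules, as.character(unassigned),
             params = list(min_size = min_size))
}
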