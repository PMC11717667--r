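# weighted degree (strength); plain degree when the graph is unweighted
.strength <- function(net, v = igraph::V(net)) {
  if ("weight" %in% igraph::edge_attr_names(net))
    igraph::strength(net, vids = v)
  else igraph::degree(net, v = v)
}

#' Network structure entropy
#'
#' \eqn{E = -\sum_i I_i \ln I_i}, where the importance \eqn{I_i} of node i
#' is its connectivity (weighted degree) as a proportion of the total
#' connectivity over all nodes. Zero-degree nodes carry no connectivity and
#' are excluded. Lower entropy indicates a more ordered (less uniform)
#' degree structure; for a k-regular graph on N nodes E attains its maximum
#' \eqn{\ln N}.
#'
#' @param net an undirected [igraph::graph] with at least one edge.
#' @return non-negative real (natural log).
#' @export
structure_entropy <- function(net) {
  if (igraph::ecount(net) == 0L) stop("entropy undefined: network has no edges")
  k <- .strength(net)
  k <- k[k > 0]
  I <- k / sum(k)
  -sum(I * log(I))
}

#' Entropy of a modular decomposition
#'
#' Evaluates the network structure entropy implied by a module set under
#' three variants: `module_union` (entropy of the subgraph formed by all
#' within-module edges over all assigned nodes — the default used for
#' method comparison), `per_module_mean` (arithmetic mean of
#' [structure_entropy()] over each module's induced subgraph) and `global`
#' ([structure_entropy()] of the full network, method-independent, for
#' reference).
#'
#' @param net the network the modules were derived from.
#' @param ms a [module_set].
#' @param variant entropy definition variant.
#' @return a list with `entropy`, `variant`, `method` and `per_module`
#'   (per-module entropies, `NA` for edgeless modules).
#' @export
partition_entropy <- function(net, ms,
                              variant = c("module_union", "per_module_mean",
                                          "global")) {
  variant <- match.arg(variant)
  if (!length(ms$modules)) stop("module set has zero modules")
  per_mod <- vapply(ms$modules, function(m) {
    sub <- igraph::induced_subgraph(net, m)
    if (igraph::ecount(sub) == 0L) NA_real_ else structure_entropy(sub)
  }, numeric(1))
  E <- switch(variant,
    module_union = {
      # union of within-module edge sets over all assigned nodes
      keep <- igraph::E(net)[.inner_edges(net, ms$modules)]
      sub <- igraph::subgraph_from_edges(net, keep, delete.vertices = TRUE)
      structure_entropy(sub)
    },
    per_module_mean = mean(per_mod, na.rm = TRUE),
    global = structure_entropy(net)
  )
  list(entropy = E, variant = variant, method = ms$method,
       per_module = per_mod)
}

# edge ids with both endpoints inside the same module (any module)
.inner_edges <- function(net, modules) {
  el <- igraph::as_edgelist(net, names = TRUE)
  inner <- rep(FALSE, nrow(el))
  for (m in modules)
    inner <- inner | (el[, 1L] %in% m & el[, 2L] %in% m)
  which(inner)
}

#' Select the partitioning method by minimum entropy
#'
#' Returns the method attaining the minimum entropy; ties are broken by the
#' canonical method order (`mcode`, `mcl`, `greedy`) with a warning.
#'
#' @param entropies named numeric vector or list, `method -> entropy`.
#' @return the chosen method name.
#' @export
select_method <- function(entropies) {
  e <- unlist(entropies)
  e <- e[is.finite(e)]
  if (length(e) < 2L) stop("need >= 2 methods with finite entropy")
  canon <- c("mcode", "mcl", "greedy")
  ord <- c(intersect(canon, names(e)), setdiff(names(e), canon))
  e <- e[ord]
  winners <- names(e)[e == min(e)]
  if (length(winners) > 1L)
    warning("entropy tie between ", paste(winners, collapse = ", "),
            "; keeping ", winners[1L])
  winners[1L]
}

# characteristic path length: mean shortest path over reachable pairs
.char_path_length <- function(g) {
  if (igraph::vcount(g) < 2L || igraph::ecount(g) == 0L) return(NA_real_)
  d <- igraph::distances(g, weights = NA)
  d <- d[upper.tri(d)]
  d <- d[is.finite(d)]
  if (!length(d)) NA_real_ else mean(d)
}

#' Identify the main module of a module set
#'
#' Each module is scored by three aggregate node-centrality metrics
#' computed on the full network: node strength (weighted degree),
#' betweenness centrality (normalised) and PageRank (damping 0.85), each
#' aggregated over member nodes. If the top-ranked module coincides for all
#' three metrics it is the main module (`consistent = TRUE`). Otherwise
#' each candidate's disturbance of the characteristic path length of the
#' union-of-modules subgraph upon removal of its nodes is computed, and the
#' candidate with maximal disturbance wins; a removal leaving fewer than
#' two reachable pairs scores infinite disturbance (it disconnects the
#' modular network).
#'
#' @param net the full network.
#' @param ms a [module_set] with at least one module.
#' @param aggregate `"sum"` (default) or `"mean"` over member nodes.
#' @return a list (`main_module_report`) with per-module `metrics`, the
#'   per-metric `rank1` ids, `consistent`, `tie_break` disturbances and
#'   `main_module_id` (1-based index into `ms$modules`).
#' @export
main_module <- function(net, ms, aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!length(ms$modules)) stop("module set has no modules")
  agg <- if (aggregate == "sum") sum else mean
  str_all <- .strength(net)
  btw_all <- igraph::betweenness(net, weights = NA, normalized = TRUE)
  pr_all <- igraph::page_rank(net, damping = 0.85)$vector
  metrics <- t(vapply(ms$modules, function(m) c(
    strength = agg(str_all[m]),
    betweenness = agg(btw_all[m]),
    pagerank = agg(pr_all[m])
  ), numeric(3)))
  rank1 <- apply(metrics, 2L, which.max)  # ties: lowest index
  consistent <- length(unique(rank1)) == 1L
  tie_break <- rep(NA_real_, length(ms$modules))
  if (consistent) {
    main_id <- unname(rank1[1L])
  } else {
    union_nodes <- sort(unique(unlist(ms$modules)))
    gU <- igraph::induced_subgraph(net, union_nodes)
    L0 <- .char_path_length(gU)
    cands <- sort(unique(unname(rank1)))
    for (ci in cands) {
      rest <- setdiff(union_nodes, ms$modules[[ci]])
      gR <- igraph::induced_subgraph(net, rest)
      LR <- .char_path_length(gR)
      tie_break[ci] <- if (is.na(LR)) Inf else abs(L0 - LR)
    }
    main_id <- cands[which.max(tie_break[cands])]
  }
  structure(list(metrics = metrics, rank1 = rank1, consistent = consistent,
                 tie_break = tie_break, main_module_id = main_id,
                 aggregate = aggregate),
            class = "main_module_report")
}
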