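# graph builders and independent oracles used across the suite

edge_df <- function(a, b, w = NULL) {
  if (is.null(w)) data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE)
  else data.frame(node_a = a, node_b = b, weight = w, stringsAsFactors = FALSE)
}

# complete graph on labelled nodes
clique_edges <- function(nodes) {
  cmb <- utils::combn(nodes, 2L)
  edge_df(cmb[1L, ], cmb[2L, ])
}

path_net <- function(nodes) {
  interaction_network(edge_df(nodes[-length(nodes)], nodes[-1L]))
}

# K5 and K4 joined by a single bridge edge p1-q1
bridge_cliques_net <- function() {
  interaction_network(rbind(clique_edges(paste0("p", 1:5)),
                            clique_edges(paste0("q", 1:4)),
                            edge_df("p1", "q1")))
}

# independent all-pairs BFS oracle (adjacency lists, no igraph)
bfs_dist_oracle <- function(net) {
  vs <- sort(igraph::V(net)$name)
  el <- igraph::as_edgelist(net, names = TRUE)
  adj <- stats::setNames(vector("list", length(vs)), vs)
  for (i in seq_len(nrow(el))) {
    adj[[el[i, 1L]]] <- c(adj[[el[i, 1L]]], el[i, 2L])
    adj[[el[i, 2L]]] <- c(adj[[el[i, 2L]]], el[i, 1L])
  }
  d <- matrix(Inf, length(vs), length(vs), dimnames = list(vs, vs))
  for (s in vs) {
    d[s, s] <- 0
    frontier <- s; lvl <- 0
    while (length(frontier)) {
      lvl <- lvl + 1
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!is.finite(d[s, nxt])]
      d[s, nxt] <- lvl
      frontier <- nxt
    }
  }
  d
}

# separation quantities recomputed from the BFS oracle matrix
separation_oracle <- function(net, A, B) {
  d <- bfs_dist_oracle(net)
  minfin <- function(v) { v <- v[is.finite(v)]; if (length(v)) min(v) else Inf }
  dab <- c(apply(d[A, B, drop = FALSE], 1L, minfin),
           apply(d[A, B, drop = FALSE], 2L, minfin))
  d_AB <- mean(dab[is.finite(dab)])
  within <- function(S) {
    if (length(S) < 2L) return(0)
    m <- d[S, S, drop = FALSE]; diag(m) <- Inf
    v <- apply(m, 1L, minfin)
    mean(v[is.finite(v)])
  }
  d_AA <- within(A); d_BB <- within(B)
  list(d_AB = d_AB, d_AA = d_AA, d_BB = d_BB,
       s_AB = d_AB - (d_AA + d_BB) / 2)
}

# random connected-ish Erdos-Renyi network with named nodes
random_net <- function(n, p = 0.15, seed = 1L) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  igraph::E(g)$weight <- 1
  g
}

# harmonised-instrument frame built directly (bypasses allele handling)
make_instruments <- function(bx, by, se_x = 0.01, se_y = 0.01) {
  data.frame(snp = sprintf("rs%03d", seq_along(bx)),
             beta_x = bx, se_x = se_x, beta_y = by, se_y = se_y,
             eaf_x = 0.3, eaf_y = 0.3, p_x = 1e-10, p_y = 0.5,
             action = "kept", stringsAsFactors = FALSE)
}

# adjusted Rand index (contingency-table closed form; independent of any
# clustering package)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- ai * bj / n2
  (nij - exp_idx) / ((ai + bj) / 2 - exp_idx)
}

# membership vector (block index per node) from a planted-modules list
membership_of <- function(nodes, modules, unassigned_label = 0L) {
  m <- rep(unassigned_label, length(nodes))
  names(m) <- nodes
  for (i in seq_along(modules)) m[modules[[i]]] <- i
  m
}
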