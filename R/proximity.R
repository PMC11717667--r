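# unweighted hop-count distance matrix between two node sets
.hop_dist <- function(net, from, to) {
  igraph::distances(net, v = from, to = to, weights = NA)
}

#' Closest network distance d(X, Y)
#'
#' Mean, over targets y in Y, of the shortest-path (hop count) distance to
#' the nearest member of X: \eqn{d(X,Y) = |Y|^{-1} \sum_{y \in Y}
#' \min_{x \in X} d(x, y)}. A node in both sets contributes 0. Targets
#' unreachable from all of X are excluded and counted.
#'
#' @param net an undirected [igraph::graph].
#' @param X,Y target sets ([target_set] or character vectors); genes absent
#'   from the network are dropped with a count.
#' @return the mean closest distance, with attributes `n_mapped_x`,
#'   `n_mapped_y`, `n_unreachable`.
#' @export
closest_distance <- function(net, X, Y) {
  x <- map_targets(net, X); y <- map_targets(net, Y)
  if (!length(x) || !length(y)) stop("target set maps to zero network nodes")
  d <- .hop_dist(net, y, x)
  mins <- apply(d, 1L, min)
  unreach <- !is.finite(mins)
  if (all(unreach)) stop("disconnected target sets: no member of Y reaches X")
  out <- mean(mins[!unreach])
  attr(out, "n_mapped_x") <- length(x)
  attr(out, "n_mapped_y") <- length(y)
  attr(out, "n_unreachable") <- sum(unreach)
  out
}

# mean over members of S of the min distance to another member (self
# excluded); 0 for a singleton set
.d_within <- function(dmat, S) {
  if (length(S) < 2L) return(0)
  d <- dmat[S, S, drop = FALSE]
  diag(d) <- Inf
  mins <- apply(d, 1L, min)
  mean(mins[is.finite(mins)])
}

# symmetric closest distance between sets from a precomputed matrix
.d_between <- function(dmat, A, B) {
  dab <- dmat[A, B, drop = FALSE]
  ma <- apply(dab, 1L, min)
  mb <- apply(dab, 2L, min)
  v <- c(ma, mb)
  mean(v[is.finite(v)])
}

#' Separation score s_AB between two target sets
#'
#' \eqn{s_{AB} = d_{AB} - (d_{AA} + d_{BB})/2}, where \eqn{d_{AB}} is the
#' symmetric closest distance between the sets and \eqn{d_{AA}},
#' \eqn{d_{BB}} the mean within-set distances to the nearest other member.
#' `s_AB < 0` indicates topological overlap of the two target
#' neighbourhoods; `s_AB >= 0` indicates separation.
#'
#' @inheritParams closest_distance
#' @param A,B target sets.
#' @return list with `d_AB`, `d_AA`, `d_BB`, `s_AB`.
#' @export
separation <- function(net, A, B) {
  a <- map_targets(net, A); b <- map_targets(net, B)
  if (!length(a) || !length(b)) stop("target set maps to zero network nodes")
  dmat <- .hop_dist(net, union(a, b), union(a, b))
  d_AB <- .d_between(dmat, a, b)
  if (!is.finite(d_AB)) stop("disconnected target sets")
  d_AA <- .d_within(dmat, a)
  d_BB <- .d_within(dmat, b)
  list(d_AB = d_AB, d_AA = d_AA, d_BB = d_BB,
       s_AB = d_AB - (d_AA + d_BB) / 2)
}

# degree bins: log2 bins merged upward until each holds >= bin_min nodes
.degree_bins <- function(net, bin_min = 10L) {
  deg <- igraph::degree(net)
  lev <- floor(log2(pmax(deg, 1)))
  ulev <- sort(unique(lev))
  groups <- split(names(deg), factor(lev, levels = ulev))
  merged <- list(); cur <- character(0)
  for (g in groups) {
    cur <- c(cur, g)
    if (length(cur) >= bin_min) { merged[[length(merged) + 1L]] <- cur; cur <- character(0) }
  }
  if (length(cur)) {
    if (length(merged)) merged[[length(merged)]] <- c(merged[[length(merged)]], cur)
    else merged <- list(cur)
  }
  bin_of <- stats::setNames(rep(seq_along(merged),
                                vapply(merged, length, integer(1))),
                            unlist(merged))
  list(bins = merged, bin_of = bin_of)
}

# draw a random node set degree-matched to `S` (or uniform)
.sample_like <- function(S, bins, all_nodes, degree_binned) {
  if (!degree_binned) return(sample(all_nodes, length(S)))
  out <- character(0)
  tab <- table(bins$bin_of[S])
  for (b in names(tab)) {
    pool <- bins$bins[[as.integer(b)]]
    out <- c(out, sample(pool, min(tab[[b]], length(pool))))
  }
  out
}

#' Network proximity z-score between two target sets
#'
#' Standardises the observed closest distance d(X, Y) against a null
#' distribution of `n_perm` random target-set pairs matching |X| and |Y|
#' and (by default) the degree distribution of X and Y via log2-degree bins
#' merged until each bin holds at least `bin_min` network nodes:
#' \eqn{z = (d - \mu)/\sigma}. `z < 0` means the sets are closer than
#' expected by chance. The separation score is computed alongside, so both
#' the asymmetric d(X, Y) (which the z-score standardises) and the
#' symmetric s_AB are reported.
#'
#' @inheritParams closest_distance
#' @param n_perm number of null draws (>= 100).
#' @param seed integer RNG seed.
#' @param degree_binned degree-preserving null (default) or uniform
#'   resampling.
#' @param bin_min minimum nodes per degree bin.
#' @return object of class `proximity_result`: `d_XY` (asymmetric observed
#'   distance), `d_AB`, `d_AA`, `d_BB`, `s_AB`, `z`, `mu_null`, `sd_null`,
#'   `p_empirical`, `n_perm`, `n_mapped_A`, `n_mapped_B`, `n_unreachable`.
#' @export
proximity_z <- function(net, X, Y, n_perm = 1000L, seed = 1L,
                        degree_binned = TRUE, bin_min = 10L) {
  stopifnot(n_perm >= 100L)
  x <- map_targets(net, X); y <- map_targets(net, Y)
  if (!length(x) || !length(y)) stop("target set maps to zero network nodes")
  if (igraph::vcount(net) < 2L * (length(x) + length(y)))
    stop("network too small for null model")
  all_nodes <- igraph::V(net)$name
  dmat <- .hop_dist(net, all_nodes, all_nodes)

  d_xy_from <- function(xs, ys) {
    m <- apply(dmat[ys, xs, drop = FALSE], 1L, min)
    m <- m[is.finite(m)]
    if (!length(m)) NA_real_ else mean(m)
  }
  d_obs <- d_xy_from(x, y)
  if (is.na(d_obs)) stop("disconnected target sets")
  mins_y <- apply(dmat[y, x, drop = FALSE], 1L, min)
  sep <- separation(net, x, y)

  bins <- .degree_bins(net, bin_min)
  null_d <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      xr <- .sample_like(x, bins, all_nodes, degree_binned)
      yr <- .sample_like(y, bins, all_nodes, degree_binned)
      d_xy_from(xr, yr)
    }, numeric(1))
  })
  null_d <- null_d[!is.na(null_d)]
  mu <- mean(null_d); sdv <- stats::sd(null_d)
  z <- if (isTRUE(sdv > 0)) (d_obs - mu) / sdv else NA_real_
  structure(list(
    d_XY = d_obs, d_AB = sep$d_AB, d_AA = sep$d_AA, d_BB = sep$d_BB,
    s_AB = sep$s_AB, z = z, mu_null = mu, sd_null = sdv,
    sd_zero = !isTRUE(sdv > 0),
    p_empirical = (1 + sum(null_d <= d_obs)) / (1 + length(null_d)),
    n_perm = length(null_d),
    n_mapped_A = length(x), n_mapped_B = length(y),
    n_unreachable = sum(!is.finite(mins_y)),
    degree_binned = degree_binned, seed = seed
  ), class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "<proximity_result> d(X,Y)=%.4f s_AB=%.4f z=%.3f (mu=%.4f sd=%.4f) p=%.4g [%d perms]\n",
    x$d_XY, x$s_AB, x$z, x$mu_null, x$sd_null, x$p_empirical, x$n_perm))
  invisible(x)
}
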