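# normalise an r2 specification (data.frame snp_a/snp_b/r2, or function)
# into a lookup function f(s1, s2) -> r2 (0 when unknown)
.r2_fun <- function(r2_lookup) {
  if (is.null(r2_lookup)) return(function(s1, s2) 0)
  if (is.function(r2_lookup)) return(r2_lookup)
  df <- as.data.frame(r2_lookup)
  stopifnot(ncol(df) >= 3L)
  key <- function(a, b) ifelse(a < b, paste(a, b, sep = "\r"),
                               paste(b, a, sep = "\r"))
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(df)))
    assign(key(as.character(df[[1L]][i]), as.character(df[[2L]][i])),
           as.numeric(df[[3L]][i]), envir = env)
  function(s1, s2) {
    v <- mget(key(s1, s2), envir = env, ifnotfound = 0)[[1L]]
    v
  }
}

#' Greedy LD clumping of association results
#'
#' PLINK-style index-SNP selection: SNPs with `p < p1` are visited in order
#' of ascending p-value; each index SNP absorbs (removes from candidacy)
#' all SNPs with `p < p2` on the same chromosome within `window_kb` whose
#' r-squared with the index exceeds `r2`. Pairs missing from the lookup are
#' treated as unlinked (r2 = 0).
#'
#' @param records a `gwas_table` (or data.frame) carrying `snp`, `chr`,
#'   `bp`, `p`.
#' @param r2_lookup pairwise r2: a data.frame `(snp_a, snp_b, r2)`
#'   (symmetric), a function `(s1, s2) -> r2`, or `NULL` (all pairs
#'   unlinked).
#' @param p1 index-SNP significance threshold (strict).
#' @param p2 absorption significance threshold (strict).
#' @param r2 r-squared threshold (absorb when strictly greater).
#' @param window_kb absorption window, kilobases.
#' @return the index-SNP rows of `records` (ascending p).
#' @export
clump <- function(records, r2_lookup = NULL, p1 = 5e-8, p2 = 1e-5,
                  r2 = 0.2, window_kb = 500) {
  tab <- as.data.frame(records)
  r2f <- .r2_fun(r2_lookup)
  cand <- which(tab$p < p1)
  if (!length(cand)) {
    warning("no SNP below the p1 threshold; empty clump result")
    return(tab[integer(0), , drop = FALSE])
  }
  ord <- cand[order(tab$p[cand], tab$snp[cand])]
  absorbed <- rep(FALSE, nrow(tab))
  index <- integer(0)
  for (i in ord) {
    if (absorbed[i]) next
    index <- c(index, i)
    near <- which(!absorbed & seq_len(nrow(tab)) != i &
                    tab$p < p2 &
                    tab$chr == tab$chr[i] &
                    abs(tab$bp - tab$bp[i]) <= window_kb * 1000)
    for (j in near)
      if (r2f(tab$snp[i], tab$snp[j]) > r2) absorbed[j] <- TRUE
  }
  out <- tab[index, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# S_Hom for an arbitrary subset (allows a single trait, where it reduces
# to z^2); internal building block for s_hom()/s_het()
.s_hom_stat <- function(z, n) (sum(sqrt(n) * z))^2 / sum(n)

#' Cross-trait homogeneous statistic S_Hom
#'
#' Sample-size-weighted combination of per-trait association z-scores:
#' \eqn{S_{Hom} = (\sum_k \sqrt{n_k} z_k)^2 / \sum_k n_k}, compared to a
#' chi-squared distribution with 1 df. Powerful when effects are
#' homogeneous across traits; opposite-signed effects cancel.
#'
#' @param z_by_trait numeric vector of per-trait z-scores (>= 2 traits).
#' @param n_by_trait per-trait sample sizes (> 0).
#' @return list with `statistic` and `p`.
#' @export
s_hom <- function(z_by_trait, n_by_trait) {
  z <- unlist(z_by_trait); n <- unlist(n_by_trait)
  if (length(z) < 2L) stop("S_Hom requires >= 2 traits")
  stopifnot(length(n) == length(z), all(n > 0))
  s <- .s_hom_stat(z, n)
  list(statistic = s, p = stats::pchisq(s, df = 1, lower.tail = FALSE))
}

# S_Het maximisation: max over thresholds tau in {|z_k|} of S_Hom over the
# traits with |z_k| >= tau, i.e. over the top-m traits by |z|
.s_het_stat <- function(z, n) {
  ord <- order(-abs(z))
  zs <- z[ord]; ns <- n[ord]
  cz <- cumsum(sqrt(ns) * zs)
  cn <- cumsum(ns)
  max(cz^2 / cn)
}

#' Null distribution of S_Het by Monte-Carlo simulation
#'
#' Simulates independent standard-normal z-scores under the same
#' maximisation as [s_het()]. The null depends only on the trait count and
#' sample sizes, so it can be computed once and reused across many SNPs.
#'
#' @param n_by_trait per-trait sample sizes.
#' @param n_sims number of simulations.
#' @param seed RNG seed.
#' @return sorted numeric vector of simulated S_Het statistics.
#' @export
s_het_null <- function(n_by_trait, n_sims = 1e5, seed = 1L) {
  n <- unlist(n_by_trait)
  k <- length(n)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_sims * k), n_sims, k)
    sort(apply(Z, 1L, .s_het_stat, n = n))
  })
}

#' Cross-trait heterogeneity-robust statistic S_Het
#'
#' Maximises S_Hom over trait subsets selected by thresholding |z|
#' (the top-m traits by absolute z-score, for every m), which retains power
#' when only a subset of traits carries the signal. Because the full-trait
#' subset is always a candidate, \eqn{S_{Het} \ge S_{Hom}}. The p-value is
#' calibrated by Monte-Carlo simulation of the same maximisation under
#' independent standard-normal z (add-one smoothing).
#'
#' @inheritParams s_hom
#' @param n_null_sims simulations for the null (ignored when `null_stats`
#'   is supplied).
#' @param seed RNG seed for the null simulation.
#' @param null_stats optional precomputed null from [s_het_null()].
#' @return list with `statistic` and `p`.
#' @export
s_het <- function(z_by_trait, n_by_trait, n_null_sims = 1e5, seed = 1L,
                  null_stats = NULL) {
  z <- unlist(z_by_trait); n <- unlist(n_by_trait)
  if (length(z) < 2L) stop("S_Het requires >= 2 traits")
  stopifnot(length(n) == length(z), all(n > 0))
  s <- .s_het_stat(z, n)
  if (is.null(null_stats)) null_stats <- s_het_null(n, n_null_sims, seed)
  n_ge <- length(null_stats) - findInterval(s, null_stats)
  p <- (1 + n_ge) / (1 + length(null_stats))
  if (n_ge == 0L) {
    # beyond the simulated null support the add-one estimate saturates at
    # 1/(1+n_sims); the chi-square union bound over the K candidate
    # subsets supplies the far tail (each subset statistic is chi-squared
    # with 1 df under the null)
    p <- min(p, length(z) * stats::pchisq(s, df = 1, lower.tail = FALSE))
  }
  list(statistic = s, p = p)
}

#' Dual-threshold shared-SNP filter
#'
#' Keeps SNPs whose single-trait p-value passes `p_single_max` (strictly)
#' in every trait (`rule = "all"`, the default shared-SNP reading) or in at
#' least one trait (`rule = "any"`), and whose cross-trait meta p-value
#' passes `p_meta_max` strictly.
#'
#' @param p_single numeric matrix (SNP x trait) of single-trait p-values,
#'   or a vector for one trait.
#' @param p_meta numeric vector of cross-trait meta-analysis p-values.
#' @param p_single_max single-trait threshold (default 1e-5).
#' @param p_meta_max meta-analysis threshold (default 5e-8).
#' @param rule `"all"` or `"any"`.
#' @return logical vector, `TRUE` for SNPs passing the filter.
#' @export
shared_snp_filter <- function(p_single, p_meta, p_single_max = 1e-5,
                              p_meta_max = 5e-8, rule = c("all", "any")) {
  rule <- match.arg(rule)
  ps <- as.matrix(p_single)
  stopifnot(nrow(ps) == length(p_meta))
  single_ok <- if (rule == "all") apply(ps < p_single_max, 1L, all)
               else apply(ps < p_single_max, 1L, any)
  unname(single_ok & (p_meta < p_meta_max))
}

#' Cross-trait meta-analysis table
#'
#' Joins two or more GWAS tables on SNP, computes per-trait z-scores,
#' S_Hom and S_Het (with a shared Monte-Carlo null) and applies
#' [shared_snp_filter()].
#'
#' @param tables named list of `gwas_table`s (>= 2 traits).
#' @param n_by_trait per-trait sample sizes; defaults to the median `n`
#'   column of each table.
#' @param n_null_sims,seed passed to [s_het_null()].
#' @param p_single_max,p_meta_max,rule passed to [shared_snp_filter()].
#' @return data.frame with one row per shared SNP: per-trait z and p
#'   columns, `s_hom`, `p_hom`, `s_het`, `p_het`, `passes_filter`.
#' @export
cross_trait_meta <- function(tables, n_by_trait = NULL, n_null_sims = 1e5,
                             seed = 1L, p_single_max = 1e-5,
                             p_meta_max = 5e-8, rule = c("all", "any")) {
  rule <- match.arg(rule)
  stopifnot(length(tables) >= 2L)
  traits <- names(tables) %||% paste0("trait", seq_along(tables))
  snps <- Reduce(intersect, lapply(tables, function(t) t$snp))
  if (!length(snps)) stop("no shared SNPs across traits")
  if (is.null(n_by_trait))
    n_by_trait <- vapply(tables, function(t) {
      nv <- stats::median(t$n, na.rm = TRUE)
      if (is.na(nv)) 1e5 else nv
    }, numeric(1))
  Z <- sapply(seq_along(tables), function(k) {
    t <- as.data.frame(tables[[k]])
    t <- t[match(snps, t$snp), ]
    t$beta / t$se
  })
  P <- sapply(seq_along(tables), function(k) {
    t <- as.data.frame(tables[[k]])
    t[match(snps, t$snp), "p"]
  })
  Z <- matrix(Z, ncol = length(tables)); P <- matrix(P, ncol = length(tables))
  null <- s_het_null(n_by_trait, n_null_sims, seed)
  hom <- t(apply(Z, 1L, function(z) {
    r <- s_hom(z, n_by_trait); c(r$statistic, r$p)
  }))
  het <- t(apply(Z, 1L, function(z) {
    r <- s_het(z, n_by_trait, null_stats = null); c(r$statistic, r$p)
  }))
  out <- data.frame(snp = snps, stringsAsFactors = FALSE)
  for (k in seq_along(traits)) {
    out[[paste0("z_", traits[k])]] <- Z[, k]
    out[[paste0("p_", traits[k])]] <- P[, k]
  }
  out$s_hom <- hom[, 1L]; out$p_hom <- hom[, 2L]
  out$s_het <- het[, 1L]; out$p_het <- het[, 2L]
  out$passes_filter <- shared_snp_filter(P, out$p_het, p_single_max,
                                         p_meta_max, rule)
  out
}
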