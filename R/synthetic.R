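#' Stochastic-block-model network with known communities
#'
#' Planted-partition graph: `n_blocks` blocks of `block_size` nodes with
#' within-block edge probability `p_in` and between-block probability
#' `p_out`. The planted blocks are recorded as ground truth alongside the
#' graph. Identical seed and parameters regenerate an identical graph.
#'
#' @param n_blocks,block_size block count and size.
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed.
#' @return list with `net` (an [igraph::graph], nodes `n001`, `n002`, ...)
#'   and `truth` (list: `planted_modules`, `p_in`, `p_out`, `seed`).
#' @export
gen_sbm <- function(n_blocks = 4L, block_size = 25L, p_in = 0.3,
                    p_out = 0.02, seed = 1L) {
  stopifnot(p_out >= 0, p_out < p_in, p_in <= 1)
  n <- n_blocks * block_size
  pref <- matrix(p_out, n_blocks, n_blocks)
  diag(pref) <- p_in
  mean_deg <- (block_size - 1) * p_in + (n - block_size) * p_out
  if (mean_deg < 1) warning("expected mean degree < 1: likely fragmented")
  g <- with_seed(seed,
    igraph::sample_sbm(n, pref.matrix = pref,
                       block.sizes = rep(block_size, n_blocks)))
  igraph::V(g)$name <- sprintf("n%03d", seq_len(n))
  igraph::E(g)$weight <- 1
  blocks <- split(igraph::V(g)$name,
                  rep(seq_len(n_blocks), each = block_size))
  list(net = g,
       truth = list(planted_modules = unname(blocks), p_in = p_in,
                    p_out = p_out, seed = seed))
}

#' Target-set pair with controlled topological overlap
#'
#' Draws two target sets from the planted blocks of an SBM network. With
#' `overlap > 0` both sets come from one block and share exactly
#' `floor(overlap * min(size_a, size_b))` nodes (a topologically
#' overlapping pair); with `overlap = 0` the sets are drawn from two
#' disjoint blocks (a separated pair).
#'
#' @param net network from [gen_sbm()].
#' @param truth the matching ground-truth list.
#' @param overlap fraction in `[0, 1]`.
#' @param size_a,size_b set sizes (each must fit in a block).
#' @param seed RNG seed.
#' @return list with `A`, `B` ([target_set]s) and `truth` (shared nodes,
#'   blocks used, seed).
#' @export
gen_target_pair <- function(net, truth, overlap = 0.5, size_a = 10L,
                            size_b = 10L, seed = 1L) {
  stopifnot(overlap >= 0, overlap <= 1)
  blocks <- truth$planted_modules
  n_share <- floor(overlap * min(size_a, size_b))
  with_seed(seed, {
    if (overlap > 0) {
      bl <- blocks[[1L]]
      if (size_a + size_b - n_share > length(bl))
        stop("block too small for requested sizes")
      pool <- sample(bl, size_a + size_b - n_share)
      shared <- pool[seq_len(n_share)]
      rest <- pool[-seq_len(n_share)]
      A <- c(shared, rest[seq_len(size_a - n_share)])
      B <- c(shared, rest[seq_len(size_b - n_share) + (size_a - n_share)])
      used <- c(1L, 1L)
    } else {
      stopifnot(size_a <= length(blocks[[1L]]),
                size_b <= length(blocks[[2L]]))
      A <- sample(blocks[[1L]], size_a)
      B <- sample(blocks[[2L]], size_b)
      shared <- character(0)
      used <- c(1L, 2L)
    }
    list(A = target_set("set_A", sort(A)), B = target_set("set_B", sort(B)),
         truth = list(shared = sort(shared), blocks = used,
                      overlap = overlap, seed = seed))
  })
}

# non-palindromic allele pairs used by the GWAS generators
.allele_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                       c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))

#' Two-sample MR dataset with known causal effect
#'
#' Simulates instrument-level summary statistics for one exposure and one
#' outcome. Exposure effects are drawn from a half-normal with scale 0.05,
#' truncated at 0.005 to keep ratio estimates finite, with the effect
#' allele defined as the exposure-increasing allele. Outcome effects are
#' \eqn{\beta_{yj} = \theta \beta_{xj} + \alpha + \delta 1[j \in outliers]
#' + N(0, se_{yj}^2)}, where `intercept` \eqn{\alpha} is directional
#' pleiotropy and `outlier_shift` \eqn{\delta} a planted pleiotropic
#' offset. Baseline standard errors are 0.007 scaled by `se_scale`, giving
#' mean instrument F-statistics near 50. A fraction of SNPs receive
#' palindromic (A/T, G/C) alleles with ambiguous allele frequencies (drawn
#' inside the 0.42-0.58 band, where strand orientation cannot be inferred
#' from frequency), and the outcome's allele orientation is randomly
#' swapped per SNP so harmonisation is exercised.
#'
#' @param j number of instruments.
#' @param theta true causal effect.
#' @param intercept directional pleiotropy added to every outcome effect.
#' @param outlier_frac fraction of instruments made outliers.
#' @param outlier_shift pleiotropic offset added to outlier outcome
#'   effects.
#' @param se_scale multiplier on the baseline standard errors.
#' @param palindromic_frac fraction of instruments given palindromic
#'   alleles.
#' @param seed RNG seed.
#' @return list with `exposure`, `outcome` (`gwas_table`s) and `truth`
#'   (theta, intercept, outlier ids, seed).
#' @export
gen_mr_dataset <- function(j = 50L, theta = 0.3, intercept = 0,
                           outlier_frac = 0, outlier_shift = 0,
                           se_scale = 1, palindromic_frac = 0, seed = 1L) {
  with_seed(seed, {
    # truncated half-normal exposure effects (exposure-increasing allele)
    bx <- abs(stats::rnorm(j, 0, 0.05))
    while (any(bx <= 0.005))
      bx[bx <= 0.005] <- abs(stats::rnorm(sum(bx <= 0.005), 0, 0.05))
    se_x <- 0.007 * se_scale * stats::runif(j, 0.8, 1.2)
    se_y <- 0.007 * se_scale * stats::runif(j, 0.8, 1.2)
    n_out <- round(outlier_frac * j)
    outliers <- if (n_out > 0) sort(sample.int(j, n_out)) else integer(0)
    by <- theta * bx + intercept +
      outlier_shift * as.numeric(seq_len(j) %in% outliers) +
      stats::rnorm(j, 0, se_y)

    snp <- sprintf("rs%05d", seq_len(j))
    n_pal <- round(palindromic_frac * j)
    pal <- if (n_pal > 0) sort(sample.int(j, n_pal)) else integer(0)
    a1 <- character(j); a2 <- character(j); eaf <- numeric(j)
    pick <- sample.int(nrow(.allele_pairs), j, replace = TRUE)
    a1 <- .allele_pairs[pick, 1L]; a2 <- .allele_pairs[pick, 2L]
    eaf <- stats::runif(j, 0.05, 0.95)
    if (length(pal)) {
      pal_pair <- rbind(c("A", "T"), c("G", "C"))[
        sample.int(2L, length(pal), replace = TRUE), , drop = FALSE]
      a1[pal] <- pal_pair[, 1L]; a2[pal] <- pal_pair[, 2L]
      eaf[pal] <- stats::runif(length(pal), 0.42, 0.58)
    }
    exposure <- gwas_table(data.frame(
      snp = snp, chr = "1", bp = seq_len(j) * 1000000L,
      a1 = a1, a2 = a2, beta = bx, se = se_x,
      p = 2 * stats::pnorm(-abs(bx / se_x)), eaf = eaf, n = 1e5,
      stringsAsFactors = FALSE))
    # outcome reported on a randomly swapped allele orientation per SNP
    swap <- stats::runif(j) < 0.5
    out_a1 <- ifelse(swap, a2, a1)
    out_a2 <- ifelse(swap, a1, a2)
    out_beta <- ifelse(swap, -by, by)
    out_eaf <- pmin(pmax(eaf + stats::rnorm(j, 0, 0.01), 0.01), 0.99)
    out_eaf <- ifelse(swap, 1 - out_eaf, out_eaf)
    outcome <- gwas_table(data.frame(
      snp = snp, chr = "1", bp = seq_len(j) * 1000000L,
      a1 = out_a1, a2 = out_a2, beta = out_beta, se = se_y,
      p = 2 * stats::pnorm(-abs(out_beta / se_y)), eaf = out_eaf, n = 2e5,
      stringsAsFactors = FALSE))
    list(exposure = exposure, outcome = outcome,
         truth = list(theta = theta, intercept = intercept,
                      outlier_ids = snp[outliers],
                      palindromic_ids = snp[pal], seed = seed))
  })
}

#' Single-region association statistics for colocalisation
#'
#' Generates per-SNP summary statistics for one genomic region under three
#' causal scenarios: `null` (no causal variant in either trait; all
#' z-scores standard normal), `shared` (one common causal SNP with
#' |z| near `z_causal` in both traits) and `distinct` (different causal
#' SNPs per trait). SNPs are independent (no LD), matching the
#' single-causal-variant assumption of the ABF colocalisation model.
#'
#' @param n_snps SNPs in the region.
#' @param scenario `"null"`, `"shared"` or `"distinct"`.
#' @param z_causal causal-variant z-score magnitude.
#' @param seed RNG seed.
#' @return list with `trait1`, `trait2` (`gwas_table`s) and `truth`
#'   (scenario, causal SNP ids, seed).
#' @export
gen_coloc_region <- function(n_snps = 100L, scenario = c("null", "shared",
                                                         "distinct"),
                             z_causal = 10, seed = 1L) {
  scenario <- match.arg(scenario)
  with_seed(seed, {
    snp <- sprintf("rs%05d", seq_len(n_snps))
    se <- rep(0.01, n_snps)
    z1 <- stats::rnorm(n_snps); z2 <- stats::rnorm(n_snps)
    c1 <- c2 <- NA_character_
    if (scenario == "shared") {
      i <- sample.int(n_snps, 1L)
      z1[i] <- z1[i] + z_causal; z2[i] <- z2[i] + z_causal
      c1 <- c2 <- snp[i]
    } else if (scenario == "distinct") {
      idx <- sample.int(n_snps, 2L)
      z1[idx[1L]] <- z1[idx[1L]] + z_causal
      z2[idx[2L]] <- z2[idx[2L]] + z_causal
      c1 <- snp[idx[1L]]; c2 <- snp[idx[2L]]
    }
    mk <- function(z) gwas_table(data.frame(
      snp = snp, chr = "1", bp = seq_len(n_snps) * 1000L,
      a1 = "A", a2 = "G", beta = z * se, se = se,
      p = 2 * stats::pnorm(-abs(z)), eaf = 0.3, n = 1e5,
      stringsAsFactors = FALSE))
    list(trait1 = mk(z1), trait2 = mk(z2),
         truth = list(scenario = scenario, causal_trait1 = c1,
                      causal_trait2 = c2, seed = seed))
  })
}
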