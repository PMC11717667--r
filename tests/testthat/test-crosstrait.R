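test_that("greedy clumping follows the p-ordered absorption rule", {
  tab <- data.frame(snp = c("s1", "s2", "s3"), chr = "1",
                    bp = c(0, 100e3, 600e3), a1 = "A", a2 = "G",
                    beta = 1, se = 1, p = c(1e-10, 1e-9, 1e-9),
                    eaf = NA, n = NA, stringsAsFactors = FALSE)
  r2 <- data.frame(snp_a = "s1", snp_b = "s2", r2 = 0.5)
  # s2 absorbed by s1 (within window, r2 > 0.2); s3 outside the window
  expect_equal(clump(tab, r2)$snp, c("s1", "s3"))
  # unlinked SNPs all become index SNPs
  expect_equal(clump(tab, NULL)$snp, c("s1", "s2", "s3"))
  # nothing below p1: empty result plus warning (p = 1e-7 >= 5e-8 boundary)
  weak <- tab; weak$p <- 1e-7
  expect_warning(res <- clump(weak, NULL), "no SNP")
  expect_equal(nrow(res), 0L)
})

test_that("no retained clump pair violates the absorption relation", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 40
    tab <- data.frame(snp = sprintf("s%02d", 1:n), chr = sample(1:2, n, TRUE),
                      bp = sample.int(2e6, n), a1 = "A", a2 = "G", beta = 1,
                      se = 1, p = 10^runif(n, -12, -4), eaf = NA, n = NA,
                      stringsAsFactors = FALSE)
    pairs <- t(utils::combn(tab$snp, 2))
    r2df <- data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2],
                       r2 = runif(nrow(pairs)))
    kept <- clump(tab, r2df, p1 = 5e-8, p2 = 1e-5, r2 = 0.2, window_kb = 500)
    r2f <- interactomr:::.r2_fun(r2df)
    if (nrow(kept) < 2) next
    for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
      same_chr <- kept$chr[i] == kept$chr[j]
      close <- abs(kept$bp[i] - kept$bp[j]) <= 500e3
      linked <- r2f(kept$snp[i], kept$snp[j]) > 0.2
      both_sig <- all(kept$p[c(i, j)] < 1e-5)
      expect_false(same_chr && close && linked && both_sig)
    }
  }
})

test_that("S_Hom matches its closed form and cancels opposite effects", {
  r <- s_hom(c(2, 2), c(1e4, 1e4))
  expect_equal(r$statistic, 8, tolerance = 1e-12)
  expect_equal(r$p, pchisq(8, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(s_hom(c(2, -2), c(1e4, 1e4))$statistic, 0)
  expect_equal(s_hom(c(2, -2), c(1e4, 1e4))$p, 1)
  # dominant sample size: statistic approaches the dominant trait's z^2
  expect_equal(s_hom(c(3, 0.5), c(1e9, 10))$statistic, 9, tolerance = 1e-3)
  # invariant under trait reordering
  z <- c(1.2, -0.7, 2.5); n <- c(5e4, 8e4, 2e4)
  expect_equal(s_hom(z, n)$statistic, s_hom(rev(z), rev(n))$statistic,
               tolerance = 1e-12)
  expect_error(s_hom(2, 1e4), ">= 2")
})

test_that("S_Het dominates S_Hom and reduces to it for homogeneous signals", {
  expect_equal(s_het(c(3, 3), c(1e4, 1e4), n_null_sims = 500,
                     seed = 1)$statistic, 18, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    z <- rnorm(k, 0, 2); n <- runif(k, 1e3, 1e5)
    expect_gte(s_het(z, n, n_null_sims = 200, seed = i)$statistic,
               s_hom(z, n)$statistic - 1e-12)
  }
})

test_that("S_Het Monte-Carlo p-values are uniform under the null", {
  n_tr <- c(5e4, 8e4)
  null <- s_het_null(n_tr, n_sims = 4000, seed = 77)
  set.seed(123)
  pvals <- replicate(2000, {
    s_het(rnorm(2), n_tr, null_stats = null)$p
  })
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the dual-threshold shared-SNP filter is strict at both boundaries", {
  expect_true(shared_snp_filter(matrix(c(1e-6, 1e-7), 1), 1e-9))
  expect_false(shared_snp_filter(matrix(c(1e-6, 1e-4), 1), 1e-9))
  expect_false(shared_snp_filter(matrix(c(1e-6, 1e-6), 1), 5e-8))  # == fails
  expect_false(shared_snp_filter(matrix(c(1e-5, 1e-6), 1), 1e-9))  # == fails
  # "any" relaxes the single-trait rule to one trait
  expect_true(shared_snp_filter(matrix(c(1e-6, 1e-4), 1), 1e-9, rule = "any"))
})

test_that("cross-trait meta table joins traits and applies the filter", {
  mk <- function(betas, seed) {
    gwas_table(data.frame(snp = sprintf("rs%d", seq_along(betas)), chr = "1",
                          bp = seq_along(betas), a1 = "A", a2 = "G",
                          beta = betas, se = 0.1,
                          p = 2 * pnorm(-abs(betas / 0.1)),
                          eaf = 0.3, n = 5e4))
  }
  t1 <- mk(c(1.2, 0.05, 0.9), 1)
  t2 <- mk(c(1.1, 0.02, 0.01), 2)
  res <- cross_trait_meta(list(a = t1, b = t2), n_null_sims = 500, seed = 3)
  expect_equal(res$snp, c("rs1", "rs2", "rs3"))
  expect_true(res$passes_filter[1])   # strong in both traits
  expect_false(res$passes_filter[2])  # null everywhere
  expect_false(res$passes_filter[3])  # strong in one trait only
})
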