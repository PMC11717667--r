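test_that("instrument selection applies the strict p threshold and clump rule", {
  tab <- data.frame(snp = c("s1", "s2", "s3"), chr = "1",
                    bp = c(0, 5e6, 9e6), a1 = "A", a2 = "G", beta = 0.1,
                    se = 0.01, p = c(4.9e-8, 5e-8, 1e-9), eaf = 0.3, n = 1e5,
                    stringsAsFactors = FALSE)
  expect_warning(kept <- select_instruments(tab), "r2 lookup")
  expect_setequal(kept$snp, c("s1", "s3"))  # 5e-8 exactly is excluded
  # correlated pair within the window: lower p survives
  r2 <- data.frame(snp_a = "s1", snp_b = "s3", r2 = 0.5)
  kept2 <- select_instruments(tab, r2_lookup = r2)
  expect_setequal(kept2$snp, "s3")
  expect_error(select_instruments(tab[tab$p > 1e-6, ]), "no instruments")
})

test_that("harmonisation flips, drops and infers palindromic orientation", {
  ex <- gwas_table(data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5"), chr = "1", bp = 1:5,
    a1 = c("A", "A", "A", "G", "A"), a2 = c("G", "T", "T", "C", "C"),
    beta = c(0.1, 0.2, 0.15, 0.12, 0.3), se = 0.01, p = 1e-10,
    eaf = c(0.3, 0.5, 0.10, 0.50, 0.25), n = 1e5))
  out <- gwas_table(data.frame(
    snp = c("rs1", "rs2", "rs3", "rs4", "rs5"), chr = "1", bp = 1:5,
    a1 = c("G", "A", "A", "G", "C"), a2 = c("A", "T", "T", "C", "T"),
    beta = c(0.2, 0.1, 0.05, 0.07, 0.4), se = 0.01, p = 0.5,
    eaf = c(0.7, 0.5, 0.12, 0.50, 0.3), n = 1e5))
  h <- harmonise(ex, out)
  # rs1: swapped alleles -> outcome beta sign flipped
  expect_equal(h$beta_y[h$snp == "rs1"], -0.2)
  # rs2: palindromic with ambiguous frequencies -> dropped
  expect_false("rs2" %in% h$snp)
  expect_true("rs2" %in% attr(h, "dropped")$snp)
  # rs3: palindromic, both EAFs extreme and concordant -> kept
  expect_true("rs3" %in% h$snp)
  expect_equal(h$beta_y[h$snp == "rs3"], 0.05)
  # rs4: palindromic G/C ambiguous -> dropped
  expect_false("rs4" %in% h$snp)
  # rs5: A/C vs C/T is unresolvable -> dropped_missing
  expect_equal(attr(h, "dropped")$action[attr(h, "dropped")$snp == "rs5"],
               "dropped_missing")
  expect_error(harmonise(ex[1:2, ], out[3:4, ]), "empty join")
})

test_that("harmonisation orients instruments to the exposure-increasing allele", {
  ex <- gwas_table(data.frame(snp = "rs1", chr = "1", bp = 1, a1 = "A",
                              a2 = "G", beta = -0.1, se = 0.01, p = 1e-10,
                              eaf = 0.3, n = 1e5))
  out <- gwas_table(data.frame(snp = "rs1", chr = "1", bp = 1, a1 = "A",
                               a2 = "G", beta = 0.2, se = 0.01, p = 0.5,
                               eaf = 0.3, n = 1e5))
  h <- harmonise(ex, out)
  expect_equal(h$beta_x, 0.1)
  expect_equal(h$beta_y, -0.2)
})

test_that("IVW reduces to the Wald ratio and is exact on perfect-fit data", {
  one <- make_instruments(0.5, 0.15, se_y = 0.05)
  expect_warning(f <- ivw(one), "Wald")
  expect_equal(f$estimate, 0.3, tolerance = 1e-12)
  expect_equal(f$se, 0.1, tolerance = 1e-12)

  bx <- c(0.1, 0.2, 0.35, 0.5)
  f2 <- ivw(make_instruments(bx, 0.3 * bx))
  expect_equal(f2$estimate, 0.3, tolerance = 1e-12)
  expect_equal(f2$q, 0, tolerance = 1e-20)
  expect_equal(f2$or_estimate, exp(f2$estimate), tolerance = 1e-12)
  expect_error(ivw(make_instruments(c(0, 0), c(0, 0))), "zero")
})

test_that("IVW and Egger match an independent weighted-least-squares oracle", {
  set.seed(31)
  for (i in 1:100) {
    J <- sample(5:40, 1)
    bx <- abs(rnorm(J, 0, 0.1)) + 0.01
    se_y <- runif(J, 0.005, 0.05)
    by <- 0.05 + 0.4 * bx + rnorm(J, 0, se_y)
    ins <- make_instruments(bx, by, se_y = se_y)
    w <- 1 / se_y^2
    # origin-constrained WLS oracle
    o1 <- lm(by ~ 0 + bx, weights = w)
    f1 <- ivw(ins, model = "fixed")
    expect_equal(f1$estimate, unname(coef(o1)[1]), tolerance = 1e-10)
    expect_equal(f1$se,
                 unname(sqrt(diag(vcov(o1)))[1]) / summary(o1)$sigma,
                 tolerance = 1e-10)
    # intercept WLS oracle (multiplicative random-effects scale >= 1)
    o2 <- lm(by ~ bx, weights = w)
    f2 <- egger(ins)
    expect_equal(f2$estimate, unname(coef(o2)["bx"]), tolerance = 1e-10)
    expect_equal(f2$egger_intercept, unname(coef(o2)[1]), tolerance = 1e-10)
    sig <- summary(o2)$sigma
    expect_equal(f2$se,
                 unname(sqrt(diag(vcov(o2)))["bx"]) * max(1, sig) / sig,
                 tolerance = 1e-10)
  }
})

test_that("Egger recovers exact linear data and enforces >= 3 instruments", {
  bx <- c(0.1, 0.25, 0.4, 0.6)
  f <- egger(make_instruments(bx, 0.1 + 0.4 * bx, se_y = 0.001))
  expect_equal(f$estimate, 0.4, tolerance = 1e-9)
  expect_equal(f$egger_intercept, 0.1, tolerance = 1e-9)
  expect_lt(f$egger_intercept_p, 1e-3)  # t with 2 df limits the tail
  expect_error(egger(make_instruments(c(0.1, 0.2), c(0.03, 0.06))), ">= 3")
})

test_that("weighted median interpolates at cumulative weight one half", {
  ins <- make_instruments(c(1, 1, 1), c(0.1, 0.3, 0.5))
  f <- weighted_median(ins, n_boot = 200, seed = 1)
  expect_equal(f$estimate, 0.3, tolerance = 1e-12)
  # all ratios equal: estimate exact, bootstrap SE shrinks with se_y
  cns <- make_instruments(c(0.2, 0.3, 0.4), 0.25 * c(0.2, 0.3, 0.4),
                          se_x = 1e-6, se_y = 1e-6)
  fc <- weighted_median(cns, n_boot = 200, seed = 1)
  expect_equal(fc$estimate, 0.25, tolerance = 1e-9)
  expect_lt(fc$se, 1e-4)
})

test_that("weighted median resists invalid instruments better than IVW", {
  set.seed(17)
  bias_ivw <- bias_med <- numeric(60)
  for (i in 1:60) {
    J <- 20
    bx <- abs(rnorm(J, 0, 0.1)) + 0.02
    se_y <- rep(0.01, J)
    by <- 0.3 * bx + rnorm(J, 0, se_y)
    bad <- 1:6  # 30% invalid with inflated ratios
    by[bad] <- by[bad] + 1.0 * bx[bad]
    ins <- make_instruments(bx, by, se_y = se_y)
    bias_ivw[i] <- abs(ivw(ins, model = "fixed")$estimate - 0.3)
    bias_med[i] <- abs(weighted_median(ins, n_boot = 50,
                                       seed = i)$estimate - 0.3)
  }
  expect_lt(mean(bias_med), mean(bias_ivw))
})

test_that("weighted mode tracks the dominant ratio cluster", {
  ins <- make_instruments(c(1, 1, 1, 1), c(0.3, 0.3, 0.3, 2.0))
  f <- weighted_mode(ins, n_boot = 100, seed = 2)
  expect_equal(f$estimate, 0.3, tolerance = 0.05)
  cns <- make_instruments(c(0.2, 0.5, 0.8), 0.4 * c(0.2, 0.5, 0.8),
                          se_x = 1e-6, se_y = 1e-6)
  expect_equal(weighted_mode(cns, n_boot = 50, seed = 1)$estimate, 0.4,
               tolerance = 1e-6)
})

test_that("Cochran's Q is zero on perfect fits and calibrated under the null", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  q0 <- cochran_q(make_instruments(bx, 0.3 * bx), beta_hat = 0.3)
  expect_equal(q0$q, 0, tolerance = 1e-20)
  expect_equal(q0$p, 1)
  expect_equal(pchisq(3.84, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  set.seed(5)
  qn <- replicate(200, {
    J <- 20
    bx <- abs(rnorm(J, 0, 0.1)) + 0.02
    se_y <- rep(0.01, J)
    by <- 0.3 * bx + rnorm(J, 0, se_y)
    cochran_q(make_instruments(bx, by, se_y = se_y))$q / (J - 1)
  })
  expect_equal(mean(qn), 1, tolerance = 0.1)
})

test_that("leave-one-out returns one fit per dropped SNP and finds the driver", {
  bx <- abs(rnorm(10, 0, 0.1)) + 0.02
  by <- 0.3 * bx
  by[4] <- by[4] + 0.5  # dominant outlier
  ins <- make_instruments(bx, by)
  loo <- leave_one_out(ins)
  expect_equal(nrow(loo), 10L)
  full <- ivw(ins, model = "fixed")$estimate
  deltas <- abs(loo$estimate - full)
  expect_equal(which.max(deltas), 4L)
  expect_equal(nrow(leave_one_out(ins[1:3, ])), 3L)
})

test_that("MR-PRESSO flags planted outliers and its removal restores the estimate", {
  # extreme planted outliers drive outcome p-values to underflow; the
  # generator's p = 0 clamp warning is expected here
  d <- suppressWarnings(gen_mr_dataset(j = 50, theta = 0.3,
                                       outlier_frac = 0.06,
                                       outlier_shift = 1, seed = 19))
  h <- suppressWarnings(harmonise(d$exposure, d$outcome))
  res <- mr_presso(h, n_sim = 1000, seed = 3)
  expect_true(all(d$truth$outlier_ids %in% res$outlier_snps))
  expect_lt(res$global_rss_p, 0.05)
  expect_lt(abs(res$estimate_after - 0.3), abs(res$estimate_before - 0.3))
  expect_error(mr_presso(make_instruments(c(0.1, 0.2, 0.3),
                                          c(0.03, 0.06, 0.09))), ">= 4")
})

test_that("multivariable IVW recovers direct effects and detects collinearity", {
  set.seed(23)
  hits <- 0L
  for (i in 1:100) {
    J <- 40
    bx1 <- rnorm(J, 0, 0.1); bx2 <- rnorm(J, 0, 0.1)
    se_y <- rep(0.01, J)
    by <- 0.25 * bx1 + 0 * bx2 + rnorm(J, 0, se_y)
    fits <- mvmr_ivw(cbind(e1 = bx1, e2 = bx2), by, se_y, model = "fixed")
    ok1 <- abs(fits$e1$estimate - 0.25) < 2 * fits$e1$se
    ok2 <- abs(fits$e2$estimate - 0) < 2 * fits$e2$se
    hits <- hits + as.integer(ok1 && ok2)
  }
  expect_gte(hits, 85L)
  # duplicated exposure column: rank-deficiency error naming the culprit
  bx <- rnorm(10)
  expect_error(mvmr_ivw(cbind(a = bx, b = bx), rnorm(10), rep(0.01, 10)),
               "collinear")
})

test_that("mvmr on tables with a single exposure equals univariable IVW", {
  d <- gen_mr_dataset(j = 30, theta = 0.25, seed = 41)
  f_uni <- ivw(harmonise(d$exposure, d$outcome), model = "fixed")
  # p_max = 1 keeps the full instrument set on both routes
  f_mv <- mvmr(list(expo = d$exposure), d$outcome, p_max = 1,
               model = "fixed")$expo
  expect_equal(f_mv$estimate, f_uni$estimate, tolerance = 1e-12)
  expect_equal(f_mv$se, f_uni$se, tolerance = 1e-12)
})

test_that("F statistics follow the closed form and warn on weak instruments", {
  ins <- make_instruments(0.5, 0.15, se_x = 0.1)
  expect_equal(f_statistic(ins)$f, 25)
  # invariant to allele flip
  insf <- ins; insf$beta_x <- -insf$beta_x
  expect_equal(f_statistic(insf)$f, 25)
  weak <- make_instruments(c(0.01, 0.02), c(0.003, 0.006), se_x = 0.05)
  expect_warning(fw <- f_statistic(weak), "weak")
  expect_true(fw$weak)
})

test_that("estimators are invariant under instrument reordering", {
  d <- gen_mr_dataset(j = 20, theta = 0.3, seed = 13)
  h <- harmonise(d$exposure, d$outcome)
  perm <- h[sample(nrow(h)), ]
  expect_equal(ivw(h)$estimate, ivw(perm)$estimate, tolerance = 1e-12)
  expect_equal(egger(h)$estimate, egger(perm)$estimate, tolerance = 1e-12)
  expect_equal(cochran_q(h)$q, cochran_q(perm)$q, tolerance = 1e-12)
})
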