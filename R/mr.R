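#' Select genetic instruments for an exposure
#'
#' Keeps SNPs with `p < p_max` (strict) and, when a pairwise r-squared
#' lookup is supplied, prunes them to quasi-independence with
#' [clump()] at the conventional instrument-selection settings
#' (`r2 = 0.001`, 10,000 kb window). Without a lookup only the p-value
#' filter applies, with a warning.
#'
#' @param exposure a `gwas_table`.
#' @param p_max genome-wide significance threshold (strict; default 5e-8).
#' @param r2_lookup pairwise r2 lookup (see [clump()]), or `NULL`.
#' @param r2,window_kb clumping parameters.
#' @return the instrument rows of `exposure`.
#' @export
select_instruments <- function(exposure, p_max = 5e-8, r2_lookup = NULL,
                               r2 = 0.001, window_kb = 10000) {
  tab <- as.data.frame(exposure)
  tab <- tab[tab$p < p_max, , drop = FALSE]
  if (!nrow(tab)) stop("no instruments: no SNP passes p < ", p_max)
  if (is.null(r2_lookup)) {
    warning("no r2 lookup supplied; instruments selected by p-value only")
    rownames(tab) <- NULL
    return(tab)
  }
  clump(tab, r2_lookup, p1 = p_max, p2 = p_max, r2 = r2,
        window_kb = window_kb)
}

.complement <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonise exposure and outcome summary statistics
#'
#' Joins the two tables on SNP id and places the outcome effect on the
#' exposure's effect allele: matching alleles are kept; swapped alleles
#' (a1/a2 reversed, directly or on the opposite strand) flip the sign of
#' the outcome beta; palindromic SNPs (A/T or G/C) are dropped when
#' `drop_palindromic`, unless both effect-allele frequencies are present
#' and both fall outside `[0.5 - w, 0.5 + w]`, in which case the
#' orientation is inferred by frequency matching; unresolvable allele
#' mismatches are dropped. Finally every instrument is oriented so the
#' effect allele is the exposure-increasing allele (`beta_x >= 0`).
#'
#' @param exposure,outcome `gwas_table`s.
#' @param drop_palindromic drop strand-ambiguous SNPs (default `TRUE`).
#' @param palindrome_eaf_window half-width `w` of the ambiguous frequency
#'   band around 0.5.
#' @return data.frame of kept instruments (`snp`, `beta_x`, `se_x`,
#'   `beta_y`, `se_y`, `eaf_x`, `eaf_y`, `p_x`, `p_y`, `action`), with
#'   attribute `dropped` recording excluded SNPs and reasons.
#' @export
harmonise <- function(exposure, outcome, drop_palindromic = TRUE,
                      palindrome_eaf_window = 0.08) {
  ex <- as.data.frame(exposure); out <- as.data.frame(outcome)
  snps <- intersect(ex$snp, out$snp)
  if (!length(snps)) stop("empty join: no shared SNPs")
  ex <- ex[match(snps, ex$snp), ]; out <- out[match(snps, out$snp), ]

  w <- palindrome_eaf_window
  n <- length(snps)
  beta_y <- out$beta; eaf_y <- out$eaf
  action <- character(n)
  for (i in seq_len(n)) {
    e1 <- ex$a1[i]; e2 <- ex$a2[i]; o1 <- out$a1[i]; o2 <- out$a2[i]
    if (.is_palindromic(e1, e2)) {
      # allele letters cannot resolve strand; use frequencies if informative
      if (!drop_palindromic) {
        same <- (o1 == e1 && o2 == e2) || (o1 == .complement(e1) && o2 == .complement(e2))
        if (!same) { beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i] }
        action[i] <- if (same) "kept" else "flipped"
      } else if (!is.na(ex$eaf[i]) && !is.na(out$eaf[i]) &&
                 abs(ex$eaf[i] - 0.5) > w && abs(out$eaf[i] - 0.5) > w) {
        if ((ex$eaf[i] < 0.5) != (out$eaf[i] < 0.5)) {
          beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i]
          action[i] <- "flipped"
        } else action[i] <- "kept"
      } else action[i] <- "dropped_palindromic"
    } else if (o1 == e1 && o2 == e2) {
      action[i] <- "kept"
    } else if (o1 == e2 && o2 == e1) {
      beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i]
      action[i] <- "flipped"
    } else if (!is.na(.complement(o1)) && !is.na(.complement(o2)) &&
               .complement(o1) == e1 && .complement(o2) == e2) {
      action[i] <- "kept"  # strand flip, same orientation
    } else if (!is.na(.complement(o1)) && !is.na(.complement(o2)) &&
               .complement(o1) == e2 && .complement(o2) == e1) {
      beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i]
      action[i] <- "flipped"
    } else {
      action[i] <- "dropped_missing"
    }
  }
  res <- data.frame(
    snp = snps, beta_x = ex$beta, se_x = ex$se, beta_y = beta_y,
    se_y = out$se, eaf_x = ex$eaf, eaf_y = eaf_y, p_x = ex$p, p_y = out$p,
    action = action, stringsAsFactors = FALSE
  )
  kept <- res[!startsWith(res$action, "dropped"), , drop = FALSE]
  # orient to the exposure-increasing allele
  flip <- !is.na(kept$beta_x) & kept$beta_x < 0
  kept$beta_x[flip] <- -kept$beta_x[flip]
  kept$beta_y[flip] <- -kept$beta_y[flip]
  kept$eaf_x[flip] <- 1 - kept$eaf_x[flip]
  kept$eaf_y[flip] <- 1 - kept$eaf_y[flip]
  rownames(kept) <- NULL
  attr(kept, "dropped") <-
    res[startsWith(res$action, "dropped"), c("snp", "action"), drop = FALSE]
  kept
}

# assemble the common MrFit structure
.mr_fit <- function(method, estimate, se, p, nsnp, model = "fixed",
                    q = NA_real_, q_df = NA_real_, q_p = NA_real_,
                    intercept = NA_real_, intercept_se = NA_real_,
                    intercept_p = NA_real_) {
  ci <- estimate + c(-1, 1) * stats::qnorm(0.975) * se
  structure(list(
    method = method, estimate = estimate, se = se,
    ci_low = ci[1L], ci_high = ci[2L], p = p,
    or_estimate = exp(estimate), or_ci_low = exp(ci[1L]),
    or_ci_high = exp(ci[2L]), n_snps = nsnp, model = model,
    q = q, q_df = q_df, q_p = q_p,
    egger_intercept = intercept, egger_intercept_se = intercept_se,
    egger_intercept_p = intercept_p
  ), class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf(
    "<mr_fit %s (%s)> beta=%.4f se=%.4f p=%.3g | OR=%.4f (%.4f-%.4f) | J=%d\n",
    x$method, x$model, x$estimate, x$se, x$p, x$or_estimate, x$or_ci_low,
    x$or_ci_high, x$n_snps))
  if (!is.na(x$q))
    cat(sprintf("  Q=%.3f (df=%g, p=%.3g)\n", x$q, x$q_df, x$q_p))
  if (!is.na(x$egger_intercept))
    cat(sprintf("  intercept=%.4f (se=%.4f, p=%.3g)\n", x$egger_intercept,
                x$egger_intercept_se, x$egger_intercept_p))
  invisible(x)
}

#' Inverse-variance-weighted causal estimate
#'
#' The primary two-sample MR estimator: weighted regression of the outcome
#' effects on the exposure effects through the origin, weights
#' \eqn{w_j = se_{yj}^{-2}}, i.e. \eqn{\hat\beta = \sum w_j \beta_{xj}
#' \beta_{yj} / \sum w_j \beta_{xj}^2} with fixed-effect standard error
#' \eqn{(\sum w_j \beta_{xj}^2)^{-1/2}}. Under heterogeneity (Cochran's
#' Q p < 0.05, `model = "auto"`) the SE is inflated by the multiplicative
#' random-effects factor \eqn{\max(1, \sqrt{Q/(J-1)})}. A single
#' instrument degrades to the Wald ratio with a warning.
#'
#' @param instruments harmonised instrument data.frame (see [harmonise()]).
#' @param model `"auto"` (random effects when Q_p < 0.05), `"fixed"` or
#'   `"random"`.
#' @return an `mr_fit`.
#' @export
ivw <- function(instruments, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  ins <- as.data.frame(instruments)
  J <- nrow(ins)
  if (J == 0L) stop("no instruments")
  if (all(ins$beta_x == 0)) stop("all exposure effects are zero")
  if (J == 1L) {
    warning("single instrument: Wald ratio estimate")
    est <- ins$beta_y / ins$beta_x
    se <- ins$se_y / abs(ins$beta_x)
    p <- 2 * stats::pnorm(-abs(est / se))
    return(.mr_fit("ivw", est, se, p, 1L, model = "fixed"))
  }
  w <- 1 / ins$se_y^2
  est <- sum(w * ins$beta_x * ins$beta_y) / sum(w * ins$beta_x^2)
  se_fe <- 1 / sqrt(sum(w * ins$beta_x^2))
  q <- sum(w * (ins$beta_y - est * ins$beta_x)^2)
  q_df <- J - 1L
  q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  use_random <- switch(model, auto = q_p < 0.05, fixed = FALSE, random = TRUE)
  se <- if (use_random) se_fe * max(1, sqrt(q / q_df)) else se_fe
  p <- 2 * stats::pnorm(-abs(est / se))
  .mr_fit(if (use_random) "ivw_re" else "ivw_fe", est, se, p, J,
          model = if (use_random) "random" else "fixed",
          q = q, q_df = q_df, q_p = q_p)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome effects on the exposure
#' effects with an intercept (weights \eqn{se_{yj}^{-2}}), exposure
#' effects oriented positive. The slope is the pleiotropy-adjusted causal
#' estimate; the intercept estimates the average directional pleiotropic
#' effect, with its own SE and p-value (t distribution, J - 2 df).
#' Standard errors use the multiplicative random-effects scale
#' \eqn{\max(1, \hat\sigma)}.
#'
#' @param instruments harmonised instrument data.frame (>= 3 rows).
#' @return an `mr_fit` with the intercept fields populated.
#' @export
egger <- function(instruments) {
  ins <- as.data.frame(instruments)
  J <- nrow(ins)
  if (J < 3L) stop("MR-Egger requires >= 3 instruments")
  s <- ifelse(ins$beta_x < 0, -1, 1)
  bx <- abs(ins$beta_x); by <- ins$beta_y * s
  w <- 1 / ins$se_y^2
  # closed-form weighted least squares with intercept
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0) stop("degenerate design: exposure effects are constant")
  slope <- (sw * swxy - swx * swy) / det
  inter <- (swy * swxx - swx * swxy) / det
  rss <- sum(w * (by - inter - slope * bx)^2)
  sigma <- sqrt(rss / (J - 2L))
  infl <- max(1, sigma)
  se_slope <- sqrt(sw / det) * infl
  se_inter <- sqrt(swxx / det) * infl
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = J - 2L)
  p_inter <- 2 * stats::pt(-abs(inter / se_inter), df = J - 2L)
  .mr_fit("egger", slope, se_slope, p_slope, J,
          model = if (sigma > 1) "random" else "fixed",
          q = rss, q_df = J - 2L,
          q_p = stats::pchisq(rss, df = J - 2L, lower.tail = FALSE),
          intercept = inter, intercept_se = se_inter, intercept_p = p_inter)
}

# per-instrument Wald ratios and their inverse-variance weights
.ratios <- function(ins) {
  zero <- ins$beta_x == 0
  if (any(zero)) {
    warning(sprintf("%d instrument(s) with beta_x = 0 dropped from ratio estimate",
                    sum(zero)))
    ins <- ins[!zero, , drop = FALSE]
  }
  list(b = ins$beta_y / ins$beta_x,
       w = ins$beta_x^2 / ins$se_y^2,
       ins = ins)
}

# weighted median of ratio estimates by midpoint interpolation
.weighted_median_est <- function(b, w) {
  ord <- order(b)
  b <- b[ord]; w <- w[ord] / sum(w)
  S <- cumsum(w)
  pj <- S - w / 2
  if (pj[1L] >= 0.5) return(b[1L])
  j <- which(pj >= 0.5)[1L]
  if (is.na(j)) return(b[length(b)])
  b[j - 1L] + (b[j] - b[j - 1L]) * (0.5 - pj[j - 1L]) / (pj[j] - pj[j - 1L])
}

#' Weighted median causal estimate
#'
#' The inverse-variance weighted median of the per-instrument Wald ratios
#' \eqn{\beta_{yj}/\beta_{xj}}, interpolated at cumulative weight 0.5 using
#' the midpoint convention \eqn{S_j - w_j/2}. Consistent when at least half
#' the weight comes from valid instruments. SE by parametric bootstrap.
#'
#' @param instruments harmonised instrument data.frame (>= 3 rows).
#' @param n_boot bootstrap replicates for the SE.
#' @param seed RNG seed.
#' @return an `mr_fit`.
#' @export
weighted_median <- function(instruments, n_boot = 1000L, seed = 1L) {
  ins <- as.data.frame(instruments)
  if (nrow(ins) < 3L) stop("weighted median requires >= 3 instruments")
  r <- .ratios(ins)
  est <- .weighted_median_est(r$b, r$w)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(nrow(r$ins), r$ins$beta_x, r$ins$se_x)
    by <- stats::rnorm(nrow(r$ins), r$ins$beta_y, r$ins$se_y)
    ok <- bx != 0
    .weighted_median_est(by[ok] / bx[ok], bx[ok]^2 / r$ins$se_y[ok]^2)
  }, numeric(1)))
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(est / se))
  .mr_fit("weighted_median", est, se, p, nrow(r$ins))
}

#' Weighted mode causal estimate
#'
#' The mode of the weighted normal-kernel-smoothed density of the
#' per-instrument Wald ratios; consistent when the largest group of
#' instruments sharing a causal estimate are the valid ones (ZEMPA).
#' Bandwidth is `bandwidth_factor` times the MAD-based rule
#' \eqn{0.9 \, s \, J^{-1/5}} with `s` the scaled median absolute
#' deviation of the ratios. SE by parametric bootstrap.
#'
#' @inheritParams weighted_median
#' @param bandwidth_factor multiplier on the default bandwidth.
#' @return an `mr_fit`.
#' @export
weighted_mode <- function(instruments, bandwidth_factor = 1, n_boot = 1000L,
                          seed = 1L) {
  ins <- as.data.frame(instruments)
  if (nrow(ins) < 3L) stop("weighted mode requires >= 3 instruments")
  r <- .ratios(ins)
  mode_est <- function(b, w) {
    s <- stats::mad(b)
    if (s == 0) return(b[which.max(w)])
    h <- bandwidth_factor * 0.9 * s * length(b)^(-1 / 5)
    grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 512L)
    dens <- vapply(grid, function(g)
      sum(w * stats::dnorm(g, mean = b, sd = h)), numeric(1))
    grid[which.max(dens)]
  }
  est <- mode_est(r$b, r$w / sum(r$w))
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(nrow(r$ins), r$ins$beta_x, r$ins$se_x)
    by <- stats::rnorm(nrow(r$ins), r$ins$beta_y, r$ins$se_y)
    ok <- bx != 0
    w <- bx[ok]^2 / r$ins$se_y[ok]^2
    mode_est(by[ok] / bx[ok], w / sum(w))
  }, numeric(1)))
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(est / se))
  .mr_fit("weighted_mode", est, se, p, nrow(r$ins))
}

#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (\beta_{yj} - \hat\beta \beta_{xj})^2} with
#' \eqn{w_j = se_{yj}^{-2}}, compared to chi-squared with J - 1 df.
#'
#' @param instruments harmonised instrument data.frame (>= 2 rows).
#' @param beta_hat causal estimate the residuals are taken against
#'   (defaults to the fixed-effect IVW estimate).
#' @return list with `q`, `df`, `p`.
#' @export
cochran_q <- function(instruments, beta_hat = NULL) {
  ins <- as.data.frame(instruments)
  J <- nrow(ins)
  stopifnot(J >= 2L)
  if (is.null(beta_hat)) beta_hat <- ivw(ins, model = "fixed")$estimate
  w <- 1 / ins$se_y^2
  q <- sum(w * (ins$beta_y - beta_hat * ins$beta_x)^2)
  list(q = q, df = J - 1L,
       p = stats::pchisq(q, df = J - 1L, lower.tail = FALSE))
}

#' MR-PRESSO outlier, global and distortion tests
#'
#' Residual-sum-of-squares test for horizontal pleiotropy. Each SNP's
#' residual is taken against the leave-one-out IVW fit; the observed
#' global RSS (and each per-SNP RSS) is compared to `n_sim` parametric
#' simulations in which outcome effects are redrawn about the
#' leave-one-out fitted values and the leave-one-out fits recomputed, so
#' observed and simulated RSS are identically distributed under the
#' no-pleiotropy null. Per-SNP empirical p-values are
#' Bonferroni-corrected across J for outlier flagging; the distortion
#' test compares the change in the IVW estimate after removing the
#' flagged outliers with the change after removing equally many random
#' instruments.
#'
#' @param instruments harmonised instrument data.frame (>= 4 rows).
#' @param n_sim parametric simulations for the global/outlier nulls.
#' @param outlier_p familywise significance level for outlier flagging.
#' @param n_distortion random label draws for the distortion test.
#' @param seed RNG seed.
#' @return object of class `presso_result`: `global_rss_p`,
#'   `outlier_snps`, `outlier_p_by_snp` (Bonferroni-adjusted),
#'   `distortion_p`, `estimate_before`, `estimate_after`.
#' @export
mr_presso <- function(instruments, n_sim = 1000L, outlier_p = 0.05,
                      n_distortion = 1000L, seed = 1L) {
  ins <- as.data.frame(instruments)
  J <- nrow(ins)
  if (J < 4L) stop("MR-PRESSO requires >= 4 instruments")
  bx <- ins$beta_x; by <- ins$beta_y; se_y <- ins$se_y
  w <- 1 / se_y^2
  S1 <- sum(w * bx * by); S2 <- sum(w * bx^2)
  theta_loo <- (S1 - w * bx * by) / (S2 - w * bx^2)
  fitted <- theta_loo * bx
  rss_obs_j <- w * (by - fitted)^2
  rss_obs <- sum(rss_obs_j)

  sims <- with_seed(seed, {
    BY <- matrix(stats::rnorm(n_sim * J), n_sim, J)
    BY <- sweep(BY, 2L, se_y, "*")
    BY <- sweep(BY, 2L, fitted, "+")
    s1 <- BY %*% (w * bx)                       # n_sim x 1
    TH <- (as.vector(s1) - sweep(BY, 2L, w * bx, "*"))
    TH <- sweep(TH, 2L, S2 - w * bx^2, "/")      # leave-one-out estimates
    RES <- BY - sweep(TH, 2L, bx, "*")
    RSS <- sweep(RES^2, 2L, w, "*")
    list(global = rowSums(RSS), per_snp = RSS)
  })
  global_p <- (1 + sum(sims$global >= rss_obs)) / (1 + n_sim)
  p_raw <- (1 + colSums(sweep(sims$per_snp, 2L, rss_obs_j, ">="))) / (1 + n_sim)
  p_adj <- pmin(1, p_raw * J)
  outliers <- which(p_adj < outlier_p)

  est_before <- ivw(ins, model = "fixed")$estimate
  est_after <- NA_real_; distortion_p <- NA_real_
  if (length(outliers) && length(outliers) < J - 1L) {
    est_after <- ivw(ins[-outliers, , drop = FALSE], model = "fixed")$estimate
    d_obs <- (est_after - est_before) / abs(est_before)
    d_rand <- with_seed(seed + 1L, vapply(seq_len(n_distortion), function(i) {
      drop <- sample.int(J, length(outliers))
      er <- ivw(ins[-drop, , drop = FALSE], model = "fixed")$estimate
      (er - est_before) / abs(est_before)
    }, numeric(1)))
    distortion_p <- (1 + sum(abs(d_rand) >= abs(d_obs))) / (1 + n_distortion)
  }
  structure(list(
    global_rss_p = global_p,
    outlier_snps = ins$snp[outliers],
    outlier_p_by_snp = stats::setNames(p_adj, ins$snp),
    distortion_p = distortion_p,
    estimate_before = est_before, estimate_after = est_after,
    n_sim = n_sim
  ), class = "presso_result")
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Refits IVW J times, each time without one instrument, and flags SNPs
#' whose removal moves the confidence interval across zero relative to the
#' full fit.
#'
#' @param instruments harmonised instrument data.frame (>= 3 rows).
#' @return data.frame with one row per dropped SNP: `snp`, `estimate`,
#'   `ci_low`, `ci_high`, `p`, `flips_sign`.
#' @export
leave_one_out <- function(instruments) {
  ins <- as.data.frame(instruments)
  J <- nrow(ins)
  if (J < 3L) stop("leave-one-out requires >= 3 instruments")
  full <- ivw(ins)
  full_sig <- full$ci_low > 0 || full$ci_high < 0
  rows <- lapply(seq_len(J), function(j) {
    f <- ivw(ins[-j, , drop = FALSE])
    sig <- f$ci_low > 0 || f$ci_high < 0
    data.frame(snp = ins$snp[j], estimate = f$estimate, ci_low = f$ci_low,
               ci_high = f$ci_high, p = f$p, flips_sign = sig != full_sig,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Multivariable IVW Mendelian randomisation
#'
#' Weighted multiple regression (no intercept, weights
#' \eqn{se_{yj}^{-2}}) of the outcome effects on the matrix of exposure
#' effects, giving each exposure's direct (conditional) effect. With a
#' single exposure this reduces exactly to univariable IVW.
#'
#' @param bx matrix (J x K) of exposure effects, columns named by
#'   exposure.
#' @param by,se_y outcome effects and standard errors (length J).
#' @param model as in [ivw()]; heterogeneity df is J - K.
#' @return named list of `mr_fit` objects, one per exposure.
#' @export
mvmr_ivw <- function(bx, by, se_y, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  X <- as.matrix(bx)
  K <- ncol(X); J <- nrow(X)
  if (J <= K) stop("need more instruments than exposures")
  cn <- colnames(X) %||% paste0("exposure", seq_len(K))
  qrX <- qr(X)
  if (qrX$rank < K) {
    bad <- cn[setdiff(seq_len(K), qrX$pivot[seq_len(qrX$rank)])]
    stop("rank-deficient design: collinear exposure(s) ",
         paste(bad, collapse = ", "))
  }
  w <- 1 / se_y^2
  XtW <- t(X * w)
  A <- XtW %*% X
  est <- solve(A, XtW %*% by)
  covm <- solve(A)
  resid <- by - X %*% est
  q <- sum(w * resid^2)
  q_df <- J - K
  q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  use_random <- switch(model, auto = q_p < 0.05, fixed = FALSE, random = TRUE)
  infl <- if (use_random) max(1, sqrt(q / q_df)) else 1
  fits <- lapply(seq_len(K), function(k) {
    se <- sqrt(covm[k, k]) * infl
    p <- 2 * stats::pnorm(-abs(est[k] / se))
    .mr_fit("mvmr_ivw", est[k], se, p, J,
            model = if (use_random) "random" else "fixed",
            q = q, q_df = q_df, q_p = q_p)
  })
  stats::setNames(fits, cn)
}

#' Multivariable MR from exposure and outcome tables
#'
#' Builds the MVMR design from per-exposure GWAS tables: instruments are
#' the union of SNPs passing `p_max` in any exposure, restricted to SNPs
#' present in every exposure and in the outcome; each table is harmonised
#' to the first exposure's effect allele.
#'
#' @param exposures named list of `gwas_table`s.
#' @param outcome a `gwas_table`.
#' @param p_max instrument significance threshold.
#' @param model as in [ivw()].
#' @return named list of `mr_fit` objects, one per exposure.
#' @export
mvmr <- function(exposures, outcome, p_max = 5e-8,
                 model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  stopifnot(length(exposures) >= 1L)
  cn <- names(exposures) %||% paste0("exposure", seq_along(exposures))
  ref <- as.data.frame(exposures[[1L]])
  # union of instruments across exposures, present everywhere
  cand <- unique(unlist(lapply(exposures, function(t) t$snp[t$p < p_max])))
  if (!length(cand)) stop("no instruments")
  shared <- Reduce(intersect, c(lapply(exposures, function(t) t$snp),
                                list(as.data.frame(outcome)$snp)))
  snps <- intersect(cand, shared)
  if (!length(snps)) stop("no instruments shared across all tables")
  h_out <- harmonise(ref[match(snps, ref$snp), ], outcome)
  snps <- h_out$snp
  BX <- sapply(seq_along(exposures), function(k) {
    if (k == 1L) return(h_out$beta_x)
    hk <- harmonise(ref[match(snps, ref$snp), ], exposures[[k]])
    hk$beta_y[match(snps, hk$snp)]
  })
  BX <- matrix(BX, ncol = length(exposures), dimnames = list(snps, cn))
  ok <- stats::complete.cases(BX)
  mvmr_ivw(BX[ok, , drop = FALSE], h_out$beta_y[ok], h_out$se_y[ok],
           model = model)
}

#' Instrument strength F-statistics
#'
#' Per-SNP \eqn{F_j = (\beta_{xj}/se_{xj})^2} and their mean; a mean below
#' 10 is the conventional weak-instrument warning.
#'
#' @param instruments harmonised instrument data.frame (or any table with
#'   `beta_x`, `se_x`).
#' @return list with `f` (per-SNP), `mean_f`, `weak` flag.
#' @export
f_statistic <- function(instruments) {
  ins <- as.data.frame(instruments)
  f <- (ins$beta_x / ins$se_x)^2
  mf <- mean(f)
  if (isTRUE(mf < 10)) warning("mean F < 10: possible weak-instrument bias")
  list(f = f, mean_f = mf, weak = isTRUE(mf < 10))
}
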