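test_that("make_bins builds the seven disjoint default bins", {
  bins <- make_bins(n_chromosomes = 400)
  expect_equal(nrow(bins), 7)
  expect_equal(bins$lower, c(0, 0.02, 0.05, 0.10, 0.20, 0.40, 0.80))
  expect_equal(bins$upper, c(0.02, 0.05, 0.10, 0.20, 0.40, 0.80, 0.95))
  # first bin: geometric mean of 1/400 and 0.02
  expect_equal(bins$p_rep[1], sqrt(0.0025 * 0.02))
  expect_equal(bins$x[1], log(sqrt(0.0025 * 0.02) / 0.01), tolerance = 1e-12)
  expect_equal(round(bins$x[1], 3), -0.347)
  # [0.40, 0.80): p_rep = sqrt(0.32) ~ 0.566, x = ln(sqrt(0.32)/0.01)
  expect_equal(round(bins$p_rep[6], 3), 0.566)
  expect_equal(bins$x[6], log(sqrt(0.32) / 0.01), tolerance = 1e-12)
  expect_equal(round(bins$x[6], 2), 4.04)
  # anchor identity: p_rep = p0 gives x = 0
  b2 <- make_bins(c(0.005, 0.02), n_chromosomes = 50, p0 = 0.01)
  expect_equal(b2$x[2], 0)  # sqrt(.005*.02) = .01
  expect_error(make_bins(c(0.05, 0.02), 400), "increasing")
})

mk_ann <- function(p, effect) {
  data.frame(effect = effect, p = p)
}

test_that("rdnsv_by_bin assigns half-open bins and matches pooled rdnsv", {
  sites <- site_counts(random_cds(200, seed = 31))
  fac <- correction_factors(sites)
  bins <- make_bins(n_chromosomes = 400)
  # all SNVs in one bin: bin rdnsv equals pooled rdnsv
  ann <- mk_ann(rep(0.03, 30), rep(c("missense", "synonymous"), 15))
  suppressWarnings(be <- rdnsv_by_bin(ann, sites, fac, bins))
  pooled <- rdnsv_estimate(15, 15, sites, fac)$rdnsv
  expect_equal(be$rdnsv[2], pooled)
  expect_true(all(is.na(be$rdnsv[-2])))
  # boundary frequency 0.05 goes to [0.05, 0.10)
  ann2 <- mk_ann(c(0.05, 0.05), c("missense", "synonymous"))
  suppressWarnings(be2 <- rdnsv_by_bin(ann2, sites, fac, bins))
  expect_equal(be2$nsSNV[3], 1)
  expect_equal(be2$sSNV[3], 1)
  # p >= 0.95 excluded
  ann3 <- mk_ann(c(0.96, 1.0, 0.5), c("missense", "synonymous", "synonymous"))
  suppressWarnings(be3 <- rdnsv_by_bin(ann3, sites, fac, bins))
  expect_equal(sum(be3$nsSNV) + sum(be3$sSNV), 1)
  expect_equal(attr(be3, "n_excluded_high_freq"), 2)
  # empty bins warn
  expect_warning(rdnsv_by_bin(ann2, sites, fac, bins), "without synonymous")
  # cumulative mode: each bin counts all SNVs below its upper bound
  ann4 <- mk_ann(c(0.01, 0.03, 0.30), rep("synonymous", 3))
  suppressWarnings(bc <- rdnsv_by_bin(ann4, sites, fac, bins,
                                      cumulative = TRUE))
  expect_equal(bc$sSNV, c(1, 2, 2, 2, 3, 3, 3))
})

test_that("fit_spectrum recovers exact lines and its consistency relation", {
  bins <- make_bins(n_chromosomes = 400)
  be <- data.frame(lower = bins$lower, upper = bins$upper,
                   p_rep = bins$p_rep, x = bins$x,
                   nsSNV = 10, sSNV = 10,
                   rdnsv = 0.58 - 0.071 * bins$x)
  attr(be, "p0") <- 0.01
  fit <- suppressWarnings(fit_spectrum(be))  # lm warns on perfect fits
  expect_equal(fit$a, 0.58, tolerance = 1e-10)
  expect_equal(fit$b, -0.071, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # rdnsv_1 - rdnsv_0 = b * ln(100) to machine precision
  expect_equal(fit$rdnsv_1 - fit$rdnsv_0, fit$b * log(100), tolerance = 1e-12)
  expect_equal(round_half_up(fit$rdnsv_1, 2), 0.25)
  # flat line: rdnsv_1 = rdnsv_0 = a
  be$rdnsv <- rep(0.4, 7)
  flat <- suppressWarnings(fit_spectrum(be))
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$rdnsv_1, flat$rdnsv_0)
  # too few usable bins
  be$rdnsv[3:7] <- NA
  expect_error(fit_spectrum(be), "at least 3")
})

test_that("published intercept/slope pairs reproduce the rdnsv_1 anchors", {
  pairs <- list(c(0.58, -0.071, 0.25),  # random gene sample
                c(0.45, -0.061, 0.17),  # expression-based nervous system
                c(0.43, -0.061, 0.15),  # keyword-based nervous system
                c(0.58, -0.045, 0.37))  # keyword-based immune system
  for (p in pairs) {
    m <- spectrum_model(p[1], p[2])
    expect_equal(round_half_up(m$rdnsv_1, 2), p[3])
    expect_equal(predict_rdnsv(m, 1), m$rdnsv_1)
    expect_equal(predict_rdnsv(m, m$p0), p[1])
  }
  m <- spectrum_model(0.58, -0.071)
  expect_equal(predict_rdnsv(m, 0.1), 0.58 - 0.071 * log(10))
  expect_equal(round(predict_rdnsv(m, 0.1), 4), 0.4165)
  expect_error(predict_rdnsv(m, 0), "positive")
})

test_that("per-bin rdnsv is flat near 1 on neutral simulated data", {
  cfg <- sim_config(n_genes = 120, codons_min = 200, codons_max = 300,
                    pi_intolerant = 0, gamma = 0, seed = 77)
  res <- suppressWarnings(estimate_dataset(simulate_dataset(cfg), fit = TRUE))
  # bins with enough synonymous SNVs sit near 1; sparse top bins are noisy
  usable <- !is.na(res$bin_estimates$rdnsv) & res$bin_estimates$sSNV >= 20
  expect_gte(sum(usable), 5)
  expect_true(all(abs(res$bin_estimates$rdnsv[usable] - 1) < 0.5))
  # slope confidence interval (3 SE, single replicate) covers 0
  ci <- res$fit$b + c(-3, 3) * res$fit$se_b
  expect_true(ci[1] < 0 && ci[2] > 0)
  # residual of the lowest-frequency bin is reported
  expect_true(is.finite(res$fit$lowest_bin_residual))
})
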