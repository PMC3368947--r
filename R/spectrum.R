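#' Construct derived-allele-frequency bins
#'
#' Builds the disjoint half-open frequency bins used to stratify rdnsv over
#' the site frequency spectrum. The default edges give seven bins:
#' \[0, .02), \[.02, .05), \[.05, .10), \[.10, .20), \[.20, .40),
#' \[.40, .80), \[.80, .95). Each bin is represented by the geometric mean of
#' its bounds; the first bin's zero lower bound is replaced by
#' `1/n_chromosomes` (the smallest observable frequency). The regression
#' coordinate is `x = ln(p_rep / p0)` with anchor `p0 = 0.01`, so the fitted
#' intercept is the predicted rdnsv at a frequency close to 0.
#'
#' @param edges strictly increasing frequency cut points in (0, 1); variants
#'   at or above the last edge are excluded from binning
#' @param n_chromosomes number of sampled chromosomes (sets the first bin's
#'   representative frequency)
#' @param p0 anchor frequency of the log transform
#' @return data.frame of class `frequency_bins` with columns `lower`,
#'   `upper`, `p_rep`, `x`
#' @export
make_bins <- function(edges = c(0.02, 0.05, 0.10, 0.20, 0.40, 0.80, 0.95),
                      n_chromosomes, p0 = 0.01) {
  if (any(diff(edges) <= 0) || any(edges <= 0) || any(edges >= 1))
    stopf("bin edges must be strictly increasing within (0, 1)")
  stopifnot(is_count(n_chromosomes), n_chromosomes >= 2, p0 > 0)
  lower <- c(0, edges[-length(edges)])
  upper <- edges
  lo_rep <- lower
  lo_rep[1] <- 1 / n_chromosomes
  p_rep <- sqrt(lo_rep * upper)
  df <- data.frame(lower = lower, upper = upper, p_rep = p_rep,
                   x = log(p_rep / p0))
  attr(df, "p0") <- p0
  attr(df, "n_chromosomes") <- n_chromosomes
  class(df) <- c("frequency_bins", "data.frame")
  df
}

#' rdnsv per derived-allele-frequency bin
#'
#' Assigns each polarized SNV to exactly one frequency bin (half-open
#' intervals; variants with derived frequency at or above the last edge,
#' 0.95 by default, are excluded since near-fixed variants risk ancestral
#' misassignment) and computes the rdnsv estimate per bin using the same
#' site counts and correction factors as the pooled estimate.
#'
#' @param annotated an [annotate_snvs()] table with derived frequencies `p`
#' @param sites pooled [site_counts()] for the gene set
#' @param factors [correction_factors()] shared across bins
#' @param bins a [make_bins()] table
#' @param cumulative if TRUE, bins are cumulative ("frequency below upper
#'   bound") instead of the normative disjoint bins; each SNV then
#'   contributes to every bin whose upper bound exceeds its frequency
#' @return data.frame: one row per bin with lower, upper, p_rep, x, nsSNV,
#'   sSNV, rdnsv (NA with a warning for bins without synonymous SNVs, which
#'   are dropped from the regression)
#' @export
rdnsv_by_bin <- function(annotated, sites, factors, bins,
                         cumulative = FALSE) {
  stopifnot(inherits(bins, "frequency_bins"))
  if (is.null(annotated$p)) stopf("annotated SNVs lack derived frequencies")
  p <- annotated$p
  idx <- findInterval(p, c(bins$lower, bins$upper[nrow(bins)]),
                      rightmost.closed = FALSE)
  idx[p >= bins$upper[nrow(bins)]] <- NA  # excluded high-frequency tail
  ns <- s <- integer(nrow(bins))
  is_ns <- annotated$effect %in% c("missense", "nonsense")
  for (b in seq_len(nrow(bins))) {
    inb <- if (cumulative) !is.na(idx) & idx <= b else !is.na(idx) & idx == b
    ns[b] <- sum(is_ns & inb)
    s[b] <- sum(!is_ns & inb)
  }
  rd <- ifelse(s > 0,
               factors$f * (ns / sites$nsSite) / (s / sites$sSite),
               NA_real_)
  if (any(s == 0))
    warnf("%d bin(s) without synonymous SNVs dropped from the regression",
          sum(s == 0))
  out <- data.frame(lower = bins$lower, upper = bins$upper,
                    p_rep = bins$p_rep, x = bins$x,
                    nsSNV = ns, sSNV = s, rdnsv = rd)
  attr(out, "p0") <- attr(bins, "p0")
  attr(out, "n_excluded_high_freq") <- sum(p >= bins$upper[nrow(bins)])
  out
}

#' Fit the rdnsv frequency-spectrum regression
#'
#' Ordinary (unweighted) least squares of per-bin rdnsv on the
#' log-transformed representative frequency `x = ln(p_rep / p0)`. The
#' intercept `a` is `rdnsv_0`, the predicted relative density of nsSNVs at an
#' allele frequency close to 0, interpreted as the proportion of
#' nonsynonymous sites where variants are tolerated to segregate. The
#' prediction at frequency 1, `rdnsv_1 = a + b * ln(1/p0)`, is the
#' proportion of nonsynonymous sites where variants are not prevented from
#' reaching fixation. Two-sided t-tests (same residual variance) are
#' reported for slope vs 0 and intercept vs 1, together with R-squared and
#' the residual of the lowest-frequency bin, which tends to sit above the
#' fitted line in real data.
#'
#' @param bin_estimates output of [rdnsv_by_bin()]
#' @return object of class `spectrum_fit` with fields `a` (rdnsv_0), `b`
#'   (slope per natural-log unit), `rdnsv_0`, `rdnsv_1`, `r_squared`,
#'   `p_slope`, `p_intercept_vs_1`, `se_a`, `se_b`, `df_residual`, `p0`,
#'   `n_bins_used`, `lowest_bin_residual`, and the per-bin table in `bins`
#' @export
fit_spectrum <- function(bin_estimates) {
  p0 <- attr(bin_estimates, "p0") %||% 0.01
  use <- !is.na(bin_estimates$rdnsv)
  d <- bin_estimates[use, , drop = FALSE]
  if (nrow(d) < 3L)
    stopf("spectrum regression needs at least 3 usable bins (got %d)", nrow(d))
  if (length(unique(d$x)) < 2L) stopf("singular design: constant x")
  fit <- lm(rdnsv ~ x, data = d)
  cf <- summary(fit)$coefficients
  a <- cf["(Intercept)", "Estimate"]; se_a <- cf["(Intercept)", "Std. Error"]
  b <- cf["x", "Estimate"]; se_b <- cf["x", "Std. Error"]
  dfree <- fit$df.residual
  p_slope <- 2 * pt(abs(b / se_b), dfree, lower.tail = FALSE)
  p_int <- 2 * pt(abs((a - 1) / se_a), dfree, lower.tail = FALSE)
  r2 <- summary(fit)$r.squared
  res <- structure(list(
    a = a, b = b, rdnsv_0 = a, rdnsv_1 = a + b * log(1 / p0),
    se_a = se_a, se_b = se_b, df_residual = dfree,
    p_slope = p_slope, p_intercept_vs_1 = p_int, r_squared = r2,
    p0 = p0, n_bins_used = nrow(d),
    lowest_bin_residual = d$rdnsv[1] - (a + b * d$x[1]),
    bins = bin_estimates), class = "spectrum_fit")
  res
}

#' Construct a spectrum model from known coefficients
#'
#' Builds a minimal `spectrum_fit` from an intercept and slope (e.g. a
#' published regression model) so that [predict_rdnsv()] and `rdnsv_1` can be
#' evaluated without the underlying per-bin data.
#'
#' @param a intercept (rdnsv_0)
#' @param b slope per natural-log unit of frequency
#' @param p0 anchor frequency (default 0.01, i.e. rdnsv_1 = a + b ln(100))
#' @return object of class `spectrum_fit`
#' @export
spectrum_model <- function(a, b, p0 = 0.01) {
  stopifnot(is.numeric(a), is.numeric(b), p0 > 0)
  structure(list(a = a, b = b, rdnsv_0 = a, rdnsv_1 = a + b * log(1 / p0),
                 se_a = NA_real_, se_b = NA_real_, df_residual = NA_integer_,
                 p_slope = NA_real_, p_intercept_vs_1 = NA_real_,
                 r_squared = NA_real_, p0 = p0, n_bins_used = 0L,
                 lowest_bin_residual = NA_real_, bins = NULL),
            class = "spectrum_fit")
}

#' Predict rdnsv at a derived allele frequency
#'
#' @param fit a [fit_spectrum()] or [spectrum_model()] object
#' @param p derived allele frequency in (0, 1]
#' @return predicted rdnsv `a + b * ln(p / p0)`
#' @export
predict_rdnsv <- function(fit, p) {
  stopifnot(inherits(fit, "spectrum_fit"))
  if (any(p <= 0)) stopf("frequency must be positive")
  fit$a + fit$b * log(p / fit$p0)
}

#' @export
print.spectrum_fit <- function(x, ...) {
  cat(sprintf(
    "spectrum fit: rdnsv(p) = %.3f %+.4f ln(p/%g)\n  rdnsv_0 = %.2f, rdnsv_1 = %.2f, R^2 = %.2f, p(slope=0) = %.3g, p(intercept=1) = %.3g\n",
    x$a, x$b, x$p0, round_half_up(x$rdnsv_0), round_half_up(x$rdnsv_1),
    x$r_squared, x$p_slope, x$p_intercept_vs_1))
  invisible(x)
}

#' Plot per-bin rdnsv with the fitted regression line
#'
#' @param x a `spectrum_fit` from [fit_spectrum()]
#' @param ... passed to [plot()]
#' @return invisibly, `x`
#' @export
plot.spectrum_fit <- function(x, ...) {
  if (is.null(x$bins)) stopf("fit has no per-bin data to plot")
  d <- x$bins[!is.na(x$bins$rdnsv), ]
  plot(d$x, d$rdnsv, xlab = sprintf("ln(p / %g)", x$p0), ylab = "rdnsv", ...)
  graphics::abline(a = x$a, b = x$b, lty = 2)
  invisible(x)
}
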