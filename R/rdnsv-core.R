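#' Genetic-code correction factors for the nsSNV/sSNV density ratio
#'
#' The genetic code concentrates transitions among synonymous changes: about
#' half of all synonymous mutational opportunities are transitions, against
#' 1/3 expected for a random code, while the transition share of nonsynonymous
#' opportunities drops below 1/3. Because transitions occur at a higher rate
#' than transversions, the raw nsSNV/sSNV density ratio understates the
#' relative density of nonsynonymous variants. With `w` the per-opportunity
#' transition/transversion rate ratio (default 4, i.e. a per-basepair rate
#' ratio kappa = w/2 = 2, since each basepair offers 1 transition and 2
#' transversion opportunities) and `q_s = sSite_ts/sSite`,
#' `q_n = nsSite_ts/nsSite`:
#' \deqn{f_s = (w q_s + (1-q_s)) / (w/3 + 2/3)}
#' \deqn{f_{ns} = (w q_n + (1-q_n)) / (w/3 + 2/3)}
#' \deqn{f = f_s / f_{ns}}
#' `f` multiplies the observed `Rn/Rs`; equivalently one may divide by
#' `f_ns/f_s`. The shortcut multiplier `f' = (sSite/nsSite) * f` converts a
#' raw nsSNV/sSNV count ratio directly into rdnsv; on genome-wide human
#' coding sequence it is close to 0.4.
#'
#' @param sites a [site_counts()] object with positive `sSite` and `nsSite`
#' @param w per-opportunity transition/transversion rate ratio (> 0)
#' @return object of class `correction_factors` with fields `w`, `q_s`,
#'   `q_n`, `f_s`, `f_ns`, `f`, `f_prime`, `site_ratio` (= sSite/nsSite)
#' @examples
#' sc <- site_counts("ATGGGATTACGT")
#' correction_factors(sc)
#' @export
correction_factors <- function(sites, w = 4) {
  stopifnot(inherits(sites, "site_counts"))
  if (!is.numeric(w) || length(w) != 1L || w <= 0)
    stopf("w must be a positive scalar")
  if (sites$sSite <= 0 || sites$nsSite <= 0)
    stopf("correction factors need sSite > 0 and nsSite > 0")
  q_s <- sites$sSite_ts / sites$sSite
  q_n <- sites$nsSite_ts / sites$nsSite
  denom <- w / 3 + 2 / 3
  f_s <- (w * q_s + (1 - q_s)) / denom
  f_ns <- (w * q_n + (1 - q_n)) / denom
  site_ratio <- sites$sSite / sites$nsSite
  structure(list(w = w, q_s = q_s, q_n = q_n, f_s = f_s, f_ns = f_ns,
                 f = f_s / f_ns, f_prime = site_ratio * f_s / f_ns,
                 site_ratio = site_ratio, source = "computed"),
            class = "correction_factors")
}

#' Fixed (replication-mode) correction factors
#'
#' Constructs a `correction_factors` object from externally supplied
#' constants instead of computing them from site counts; the genome-wide
#' human values are f_s = 1.25, f_ns = 0.925 and sSite/nsSite ~ 0.3,
#' yielding f ~ 1.35 and f' ~ 0.4.
#'
#' @param f_s,f_ns synonymous and nonsynonymous rate factors
#' @param site_ratio sSite/nsSite ratio used only for `f_prime`
#' @param w nominal per-opportunity transition/transversion ratio (metadata)
#' @return a `correction_factors` object
#' @export
fixed_correction_factors <- function(f_s = 1.25, f_ns = 0.925,
                                     site_ratio = 0.3, w = 4) {
  stopifnot(f_s > 0, f_ns > 0, site_ratio > 0)
  structure(list(w = w, q_s = NA_real_, q_n = NA_real_, f_s = f_s,
                 f_ns = f_ns, f = f_s / f_ns,
                 f_prime = site_ratio * f_s / f_ns,
                 site_ratio = site_ratio, source = "fixed"),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf(
    "correction factors (%s, w = %g): f_s = %.4f, f_ns = %.4f, f = %.4f, f' = %.4f\n",
    x$source, x$w, x$f_s, x$f_ns, x$f, x$f_prime))
  invisible(x)
}

#' Per-opportunity transition/transversion ratio from the per-basepair ratio
#'
#' Each basepair offers 1 transition and 2 transversion mutational
#' opportunities, so a per-basepair transition/transversion rate ratio
#' `kappa` corresponds to a per-opportunity ratio `w = 2 * kappa`. The human
#' `kappa ~ 2` yields the package default `w = 4`.
#'
#' @param kappa per-basepair transition/transversion mutation rate ratio
#' @return per-opportunity ratio `w`
#' @export
opportunity_ratio <- function(kappa) {
  stopifnot(is.numeric(kappa), kappa > 0)
  2 * kappa
}

#' Estimate the relative density of nonsynonymous variants (rdnsv)
#'
#' Computes `Rn = nsSNV/nsSite`, `Rs = sSNV/sSite` and
#' `rdnsv = f * Rn / Rs`, the density of nonsynonymous variants relative to
#' the neutral expectation inferred from synonymous variants. Under
#' neutrality rdnsv is 1; it is 0 when no nonsynonymous variant is tolerated.
#'
#' @param nsSNV,sSNV non-negative integer counts of nonsynonymous
#'   (missense + nonsense) and synonymous SNVs
#' @param sites a [site_counts()] object for the same gene set
#' @param factors a [correction_factors()] object (defaults to factors
#'   computed from `sites` with w = 4)
#' @param n_chromosomes number of sampled chromosomes (metadata)
#' @return object of class `rdnsv_estimate` with the counts, `Rn`, `Rs` and
#'   `rdnsv`. With `sSNV == 0` the estimate is undefined: `rdnsv` is `NA`
#'   with a warning (not 0, not Inf).
#' @export
rdnsv_estimate <- function(nsSNV, sSNV, sites,
                           factors = correction_factors(sites),
                           n_chromosomes = NA_integer_) {
  stopifnot(is_count(nsSNV), is_count(sSNV), inherits(sites, "site_counts"),
            inherits(factors, "correction_factors"))
  if (sites$sSite <= 0 || sites$nsSite <= 0)
    stopf("rdnsv needs nonzero site counts")
  Rn <- nsSNV / sites$nsSite
  Rs <- sSNV / sites$sSite
  if (sSNV == 0) {
    warnf("sSNV = 0: rdnsv is undefined for this gene set")
    rd <- NA_real_
  } else {
    rd <- factors$f * Rn / Rs
  }
  structure(list(nsSNV = nsSNV, sSNV = sSNV, sites = sites,
                 factors = factors, Rn = Rn, Rs = Rs, rdnsv = rd,
                 n_chromosomes = n_chromosomes),
            class = "rdnsv_estimate")
}

#' @export
print.rdnsv_estimate <- function(x, ...) {
  cat(sprintf(
    "rdnsv estimate: nsSNV = %d, sSNV = %d, Rn = %.5g, Rs = %.5g, f = %.4f, rdnsv = %.4f\n",
    x$nsSNV, x$sSNV, x$Rn, x$Rs, x$factors$f, x$rdnsv))
  invisible(x)
}

#' Rule-of-thumb rdnsv approximation
#'
#' For large human gene sets, `sSite/nsSite` is close to 0.3 and the
#' code-bias factor f close to 1.35, so rdnsv is approximated by multiplying
#' the raw nsSNV/sSNV count ratio by `f_prime` (default 0.4).
#'
#' @param nsSNV,sSNV SNV counts; `sSNV` must be positive
#' @param f_prime shortcut multiplier
#' @return approximate rdnsv value
#' @export
rdnsv_rule_of_thumb <- function(nsSNV, sSNV, f_prime = 0.4) {
  stopifnot(is_count(nsSNV), is_count(sSNV))
  if (sSNV == 0) {
    warnf("sSNV = 0: rule-of-thumb rdnsv is undefined")
    return(NA_real_)
  }
  f_prime * nsSNV / sSNV
}
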