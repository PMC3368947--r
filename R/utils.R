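`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Presentation rounding for summary tables. Base `round()` rounds half to
#' even; printed two-decimal summaries here follow the half-up convention.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

#' Reverse complement of a DNA string vector
#' @param x character vector of DNA strings (ACGTN)
#' @return reverse-complemented strings
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# coerce a genome to a named character vector, keeping names
as_genome <- function(genome) {
  nm <- names(genome)
  genome <- as.character(genome)
  names(genome) <- nm
  genome
}

comp_base <- function(x) {
  unname(c(A = "T", C = "G", G = "C", T = "A", N = "N")[x])
}
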