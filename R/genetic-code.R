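#' The standard genetic code
#'
#' Returns the codon translation table used throughout the package: a named
#' character vector over all 64 codons, values are one-letter amino acids with
#' `"*"` marking the 3 stop codons. The default is the standard table from
#' Biostrings; any complete 64-codon table may be supplied to downstream
#' functions for non-standard codes.
#'
#' @return named character vector of length 64
#' @export
genetic_code <- function() {
  code <- Biostrings::GENETIC_CODE
  validate_genetic_code(code)
  code
}

validate_genetic_code <- function(code) {
  if (length(code) != 64L || is.null(names(code)))
    stopf("genetic code must map all 64 codons")
  n_stop <- sum(code == "*")
  if (identical(unname(code), unname(Biostrings::GENETIC_CODE)) &&
      n_stop != 3L)
    stopf("standard genetic code must contain exactly 3 stop codons")
  if (n_stop < 1L || n_stop > 61L)
    stopf("genetic code must contain both sense and stop codons")
  invisible(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# A<->G and C<->T changes are transitions; everything else is a transversion.
is_transition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
    (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

# Cache of lookup tables derived from a genetic code:
#  $effect : 64 x 3 x 4 character array (codon, offset+1, alt base) with
#            values synonymous/missense/nonsense, NA for ref==alt or stop ref
#  $thirds : 64 x 4 integer matrix of substitution counts per sense codon in
#            cells (s_ts, s_tv, n_ts, n_tv); stop codons are NA rows
.code_cache <- new.env(parent = emptyenv())

substitution_tables <- function(code = genetic_code()) {
  key <- paste(code, collapse = "")
  if (!is.null(.code_cache[[key]])) return(.code_cache[[key]])
  codons <- names(code)
  eff <- array(NA_character_, dim = c(64L, 3L, 4L),
               dimnames = list(codons, NULL, DNA_BASES))
  thirds <- matrix(NA_integer_, nrow = 64L, ncol = 4L,
                   dimnames = list(codons, c("s_ts", "s_tv", "n_ts", "n_tv")))
  for (i in seq_along(codons)) {
    cod <- codons[i]
    if (code[[cod]] == "*") next
    cnt <- c(s_ts = 0L, s_tv = 0L, n_ts = 0L, n_tv = 0L)
    for (off in 0:2) {
      ref <- substr(cod, off + 1L, off + 1L)
      for (alt in DNA_BASES) {
        if (alt == ref) next
        mut <- cod
        substr(mut, off + 1L, off + 1L) <- alt
        aa <- code[[mut]]
        effect <- if (aa == "*") "nonsense"
          else if (aa == code[[cod]]) "synonymous" else "missense"
        eff[i, off + 1L, alt] <- effect
        ts <- is_transition(ref, alt)
        cell <- paste0(if (effect == "synonymous") "s" else "n",
                       if (ts) "_ts" else "_tv")
        cnt[cell] <- cnt[cell] + 1L
      }
    }
    thirds[i, ] <- cnt
  }
  # stop-codon rows are never counted (coding_sequence rejects stops); zero
  # them so the codon-count matrix product stays NA-free
  thirds[is.na(thirds[, 1L]), ] <- 0L
  tab <- list(effect = eff, thirds = thirds, codons = codons, code = code)
  .code_cache[[key]] <- tab
  tab
}

#' Classify a single-basepair substitution within a codon
#'
#' Determines the coding effect (synonymous, missense, or nonsense) and the
#' mutational channel (transition or transversion) of changing one position of
#' a sense codon to an alternative base. Vectorized over equal-length inputs.
#'
#' @param codon character vector of sense codons (3-mers over ACGT)
#' @param offset integer vector, 0-based position within the codon (0..2)
#' @param alt character vector of alternative bases, each different from the
#'   reference base at `offset`
#' @param code genetic code table, see [genetic_code()]
#' @return data.frame with columns `effect` (synonymous/missense/nonsense)
#'   and `channel` (transition/transversion)
#' @examples
#' classify_substitution("ATA", 2, "G")  # Ile -> Met: missense transition
#' @export
classify_substitution <- function(codon, offset, alt, code = genetic_code()) {
  n <- max(length(codon), length(offset), length(alt))
  codon <- toupper(rep_len(codon, n))
  offset <- rep_len(as.integer(offset), n)
  alt <- toupper(rep_len(alt, n))
  if (any(is.na(offset)) || any(offset < 0L | offset > 2L))
    stopf("codon offset must be in 0..2")
  if (!all(alt %in% DNA_BASES))
    stopf("alt base must be one of A, C, G, T")
  tab <- substitution_tables(code)
  ci <- match(codon, tab$codons)
  if (anyNA(ci))
    stopf("invalid codon(s): %s",
          paste(unique(codon[is.na(ci)]), collapse = ", "))
  if (any(tab$code[ci] == "*"))
    stopf("cannot classify substitutions in a stop codon (%s)",
          paste(unique(codon[tab$code[ci] == "*"]), collapse = ", "))
  ref <- substr(codon, offset + 1L, offset + 1L)
  if (any(ref == alt))
    stopf("alt base equals the reference base at the given offset")
  effect <- tab$effect[cbind(ci, offset + 1L, match(alt, DNA_BASES))]
  channel <- ifelse(is_transition(ref, alt), "transition", "transversion")
  data.frame(effect = effect, channel = channel)
}

#' Construct a validated coding sequence
#'
#' Wraps an in-frame coding-strand DNA sequence with its identifiers.
#' The terminal stop codon, if present, is stripped; internal stop codons are
#' an error (reference CDS must be stop-free). Codons containing characters
#' outside ACGT (e.g. N) are retained but skipped by [site_counts()].
#'
#' @param sequence DNA string, length divisible by 3
#' @param gene_id,transcript_id identifiers
#' @param code genetic code table
#' @return object of class `coding_sequence`
#' @export
coding_sequence <- function(sequence, gene_id = NA_character_,
                            transcript_id = NA_character_,
                            code = genetic_code()) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) %% 3L != 0L)
    stopf("coding sequence length (%d) is not divisible by 3 [gene %s]",
          nchar(sequence), gene_id)
  codons <- codon_split(sequence)
  clean <- codons %in% names(code)
  aa <- rep(NA_character_, length(codons))
  aa[clean] <- code[codons[clean]]
  n <- length(codons)
  if (n > 0L && !is.na(aa[n]) && aa[n] == "*") {
    codons <- codons[-n]
    aa <- aa[-n]
    sequence <- substr(sequence, 1L, 3L * (n - 1L))
  }
  internal_stop <- which(!is.na(aa) & aa == "*")
  if (length(internal_stop))
    stopf("internal stop codon at codon index %d (%s) in gene %s",
          internal_stop[1], codons[internal_stop[1]], gene_id)
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 sequence = sequence),
            class = "coding_sequence")
}

codon_split <- function(sequence) {
  n <- nchar(sequence) %/% 3L
  if (n == 0L) return(character(0))
  substring(sequence, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

new_site_counts <- function(thirds, n_bp = sum(thirds) / 3) {
  thirds <- as.numeric(thirds)  # integer-valued; numeric to avoid overflow
  names(thirds) <- c("s_ts", "s_tv", "n_ts", "n_tv")
  x <- structure(list(
    sSite = (thirds[["s_ts"]] + thirds[["s_tv"]]) / 3,
    nsSite = (thirds[["n_ts"]] + thirds[["n_tv"]]) / 3,
    sSite_ts = thirds[["s_ts"]] / 3, sSite_tv = thirds[["s_tv"]] / 3,
    nsSite_ts = thirds[["n_ts"]] / 3, nsSite_tv = thirds[["n_tv"]] / 3,
    n_bp = n_bp, thirds = thirds), class = "site_counts")
  # conservation invariants, exact in integer thirds
  stopifnot(sum(thirds) == 3 * n_bp,
            thirds[["s_ts"]] + thirds[["n_ts"]] == n_bp,
            thirds[["s_tv"]] + thirds[["n_tv"]] == 2 * n_bp)
  x
}

#' Count synonymous and nonsynonymous mutational opportunities
#'
#' Enumerates, for each basepair of an in-frame coding sequence, its three
#' possible single-basepair changes; each change contributes 1/3 site to one
#' of four cells: synonymous/nonsynonymous crossed with
#' transition/transversion. Changes creating a stop codon count as
#' nonsynonymous opportunities (nonsense SNVs are pooled with missense
#' downstream). Counts are accumulated in exact integer thirds and divided by
#' 3 only at the end, so conservation identities hold exactly.
#'
#' @param x a `coding_sequence`, or a DNA string (coerced via
#'   [coding_sequence()], which strips a terminal stop and rejects internal
#'   stops)
#' @param code genetic code table
#' @param quiet suppress the message emitted when ambiguous (non-ACGT) codons
#'   are skipped
#' @return object of class `site_counts` with fields `sSite`, `nsSite`,
#'   `sSite_ts`, `sSite_tv`, `nsSite_ts`, `nsSite_tv` and `n_bp` (the number
#'   of counted coding basepairs; `sSite + nsSite == n_bp`)
#' @examples
#' site_counts("ATA")  # 2/3 sSite, 7/3 nsSite
#' @export
site_counts <- function(x, code = genetic_code(), quiet = FALSE) {
  if (!inherits(x, "coding_sequence")) x <- coding_sequence(x, code = code)
  tab <- substitution_tables(code)
  codons <- codon_split(x$sequence)
  ok <- codons %in% tab$codons
  if (any(!ok) && !quiet)
    message(sprintf("skipping %d codon(s) with ambiguity codes in gene %s",
                    sum(!ok), x$gene_id))
  codons <- codons[ok]
  if (length(codons) == 0L) return(new_site_counts(c(0L, 0L, 0L, 0L), 0))
  counts <- tabulate(match(codons, tab$codons), nbins = 64L)
  thirds <- as.vector(counts %*% tab$thirds)
  new_site_counts(thirds, n_bp = 3 * length(codons))
}

#' Aggregate site counts
#'
#' Field-wise sum of a list of [site_counts()] results; conservation
#' invariants are re-checked on the aggregate.
#'
#' @param counts list of `site_counts` objects (possibly empty)
#' @return a `site_counts` object
#' @export
aggregate_site_counts <- function(counts) {
  stopifnot(all(vapply(counts, inherits, logical(1), "site_counts")))
  if (length(counts) == 0L) return(new_site_counts(c(0L, 0L, 0L, 0L), 0))
  thirds <- Reduce(`+`, lapply(counts, `[[`, "thirds"))
  new_site_counts(thirds, n_bp = sum(vapply(counts, `[[`, numeric(1), "n_bp")))
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf(
    "site counts over %d bp: sSite = %.4f (ts %.4f, tv %.4f), nsSite = %.4f (ts %.4f, tv %.4f)\n",
    x$n_bp, x$sSite, x$sSite_ts, x$sSite_tv,
    x$nsSite, x$nsSite_ts, x$nsSite_tv))
  invisible(x)
}

#' Per-gene and aggregate site counts for a set of coding sequences
#'
#' @param cds_set named list of `coding_sequence` objects or a named character
#'   vector of sequences (names used as gene ids), e.g. from
#'   [read_cds_fasta()]
#' @param code genetic code table
#' @return data.frame with one row per gene (gene_id, n_codons, sSite, nsSite,
#'   sSite_ts, sSite_tv, nsSite_ts, nsSite_tv) and the aggregate
#'   `site_counts` object in attribute `"aggregate"`
#' @export
site_counts_table <- function(cds_set, code = genetic_code()) {
  if (is.character(cds_set)) {
    ids <- names(cds_set) %||% as.character(seq_along(cds_set))
    cds_set <- Map(coding_sequence, cds_set, ids, code = list(code))
  }
  sc <- lapply(cds_set, site_counts, code = code)
  df <- data.frame(
    gene_id = vapply(cds_set, `[[`, character(1), "gene_id"),
    n_codons = vapply(sc, function(s) s$n_bp / 3, numeric(1)),
    sSite = vapply(sc, `[[`, numeric(1), "sSite"),
    nsSite = vapply(sc, `[[`, numeric(1), "nsSite"),
    sSite_ts = vapply(sc, `[[`, numeric(1), "sSite_ts"),
    sSite_tv = vapply(sc, `[[`, numeric(1), "sSite_tv"),
    nsSite_ts = vapply(sc, `[[`, numeric(1), "nsSite_ts"),
    nsSite_tv = vapply(sc, `[[`, numeric(1), "nsSite_tv"),
    row.names = NULL)
  attr(df, "aggregate") <- aggregate_site_counts(sc)
  df
}
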