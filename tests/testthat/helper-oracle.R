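# Independent brute-force oracles. These deliberately avoid the package's
# codon-count matrix path: they enumerate every single-basepair change of a
# sequence, mutate the codon string, and translate both codons through the
# standard table from Biostrings.

ORACLE_CODE <- Biostrings::GENETIC_CODE
ORACLE_BASES <- c("A", "C", "G", "T")

oracle_classify <- function(codon, offset, alt) {
  ref <- substr(codon, offset + 1, offset + 1)
  mut <- codon
  substr(mut, offset + 1, offset + 1) <- alt
  aa_ref <- ORACLE_CODE[[codon]]
  aa_mut <- ORACLE_CODE[[mut]]
  effect <- if (aa_mut == "*") "nonsense"
    else if (aa_mut == aa_ref) "synonymous" else "missense"
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  channel <- if (purine[[ref]] == purine[[alt]]) "transition" else "transversion"
  list(effect = effect, channel = channel)
}

# counts in exact integer thirds: c(s_ts, s_tv, n_ts, n_tv)
oracle_site_thirds <- function(sequence) {
  out <- c(s_ts = 0L, s_tv = 0L, n_ts = 0L, n_tv = 0L)
  n_cod <- nchar(sequence) %/% 3
  for (ci in seq_len(n_cod)) {
    codon <- substr(sequence, 3 * ci - 2, 3 * ci)
    for (off in 0:2) {
      ref <- substr(codon, off + 1, off + 1)
      for (alt in setdiff(ORACLE_BASES, ref)) {
        cls <- oracle_classify(codon, off, alt)
        key <- paste0(if (cls$effect == "synonymous") "s" else "n",
                      if (cls$channel == "transition") "_ts" else "_tv")
        out[key] <- out[key] + 1L
      }
    }
  }
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) unname(c(A = "T", C = "G", G = "C", T = "A")[x])

random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- names(ORACLE_CODE)[ORACLE_CODE != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# hand-built two-gene toy genome used by the annotation tests:
#   gplus : plus strand, two exons
#   gminus: minus strand, one exon, CDS = revcomp of genomic segment
toy_genome <- function() {
  # gplus CDS = ATG GAT TGT GGA (M D C G), split 5 + 7 bp
  cds_plus <- "ATGGATTGTGGA"
  exon1 <- substr(cds_plus, 1, 5)
  exon2 <- substr(cds_plus, 6, 12)
  chr1 <- paste0("TTTT", exon1, "AAAAA", exon2, "CCCC")
  # gminus CDS = ATG ATA CCC (M I P); genomic = revcomp(CDS)
  cds_minus <- "ATGATACCC"
  chr2 <- paste0("GG", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(cds_minus))), "AA")
  models <- transcript_models(data.frame(
    gene_id = c("gplus", "gplus", "gminus"),
    transcript_id = c("tplus", "tplus", "tminus"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "+", "-"),
    start = c(4, 14, 2),
    end = c(9, 21, 11)))
  list(genome = c(chr1 = chr1, chr2 = chr2), models = models,
       cds = c(gplus = cds_plus, gminus = cds_minus))
}

make_snv <- function(chrom, pos, ref, alt, ac = 1, an = 400, aa = NA) {
  snv_table(data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                       ac = ac, an = an, aa = aa))
}
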