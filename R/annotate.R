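#' Construct an SNV table
#'
#' Strict biallelic SNV records with allele counts. Positions are 0-based
#' internally (VCF's 1-based positions are converted at the file boundary).
#'
#' @param df data.frame with columns `chrom`, `pos` (0-based), `ref`, `alt`
#'   (single ACGT bases), `ac` (alt allele count), `an` (total allele
#'   number >= 2), and optionally `aa` (ancestral/outgroup base, NA when
#'   unknown)
#' @return validated data.frame of class `snv_table`
#' @export
snv_table <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "ac", "an")
  if (!all(need %in% names(df)))
    stopf("snv table needs columns: %s", paste(need, collapse = ", "))
  if (is.null(df$aa)) df$aa <- NA_character_
  df <- df[, c(need, "aa")]
  df$ref <- toupper(df$ref); df$alt <- toupper(df$alt)
  df$aa <- toupper(as.character(df$aa))
  keep <- df$ref %in% DNA_BASES & df$alt %in% DNA_BASES
  if (any(!keep)) {
    message(sprintf("dropping %d non-SNV or ambiguous record(s)", sum(!keep)))
    df <- df[keep, , drop = FALSE]
  }
  if (any(df$ref == df$alt)) stopf("SNV with ref == alt")
  if (any(df$an < 2 | df$ac < 0 | df$ac > df$an))
    stopf("SNV with invalid allele counts (need 0 <= ac <= an, an >= 2)")
  rownames(df) <- NULL
  class(df) <- c("snv_table", "data.frame")
  df
}

#' Read biallelic SNVs from a VCF file
#'
#' Uses VariantAnnotation to parse VCF 4.x (plain or bgzipped).
#' Multi-allelic records are split into biallelic rows; only strict SNVs
#' (single ACGT base on both alleles) are retained. Allele counts come from
#' the `AC`/`AN` INFO fields when present, otherwise from genotypes (missing
#' genotypes reduce `AN`). The ancestral allele is read from the `AA` INFO
#' key when present, else from an optional sidecar TSV (`chrom  pos  base`,
#' 1-based positions, no header); lowercase (low-confidence) calls are used.
#'
#' @param path VCF file
#' @param ancestral_tsv optional sidecar TSV with ancestral alleles
#' @return an [snv_table()] (positions 0-based)
#' @export
read_snvs <- function(path, ancestral_tsv = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos1 <- GenomicRanges::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  n <- length(chrom)
  unwrap <- function(x) if (is.list(x) || methods::is(x, "List"))
    vapply(x, function(v) if (length(v)) v[[1]] else NA, FUN.VALUE = x[[1]][1]) else x
  ac <- an <- rep(NA_real_, n)
  if (!is.null(info$AC)) ac <- as.numeric(unwrap(info$AC))
  if (!is.null(info$AN)) an <- as.numeric(unwrap(info$AN))
  if (anyNA(ac) || anyNA(an)) {
    gt <- tryCatch(VariantAnnotation::geno(vcf)$GT, error = function(e) NULL)
    if (is.null(gt))
      stopf("%s: no AC/AN INFO fields and no genotypes", path)
    alleles <- apply(gt, 1L, function(g) {
      g <- g[!is.na(g) & g != "./." & g != "."]
      split_g <- unlist(strsplit(g, "[/|]"))
      c(sum(split_g == "1"), length(split_g))
    })
    ac[is.na(ac)] <- alleles[1L, is.na(ac)]
    an[is.na(an)] <- alleles[2L, is.na(an)]
  }
  aa <- rep(NA_character_, n)
  if (!is.null(info$AA)) aa <- toupper(as.character(unwrap(info$AA)))
  aa[!aa %in% DNA_BASES] <- NA_character_
  if (!is.null(ancestral_tsv)) {
    side <- read.table(ancestral_tsv, header = FALSE, sep = "\t",
                       col.names = c("chrom", "pos", "base"),
                       colClasses = c("character", "numeric", "character"))
    key <- paste(chrom, pos1)
    hit <- match(key, paste(side$chrom, side$pos))
    fill <- is.na(aa) & !is.na(hit)
    aa[fill] <- toupper(side$base[hit[fill]])
  }
  snv_table(data.frame(chrom = chrom, pos = pos1 - 1L, ref = ref, alt = alt,
                       ac = ac, an = an, aa = aa))
}

#' Write an SNV table as VCF 4.2
#'
#' Emits a deterministic, minimal VCF body with `AA`, `AC` and `AN` INFO
#' fields, sorted by chromosome then position.
#'
#' @param snvs an [snv_table()]
#' @param path output file
#' @param contigs optional character vector of contig names for the header
#' @return invisibly, `path`
#' @export
write_vcf <- function(snvs, path, contigs = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rdnsv",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total number of alleles\">",
    if (!is.null(contigs)) sprintf("##contig=<ID=%s>", contigs),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(snvs$chrom, snvs$pos, snvs$alt)
  s <- snvs[ord, , drop = FALSE]
  info <- sprintf("AA=%s;AC=%d;AN=%d",
                  ifelse(is.na(s$aa), ".", s$aa), s$ac, s$an)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s",
                  s$chrom, as.integer(s$pos) + 1L, s$ref, s$alt, info)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Polarize SNVs to derived alleles
#'
#' Determines the derived allele and its frequency for each SNV. When an
#' outgroup (ancestral) base is available and matches one of the two
#' alleles, the other allele is derived; otherwise the minor allele is taken
#' as the most likely derived allele (`source = "minor-allele-fallback"`).
#' Records whose derived count is 0 (monomorphic after polarization) are
#' excluded with a warning. When `ac == an - ac`, the minor allele is
#' ambiguous and the alt allele is used.
#'
#' @param snvs an [snv_table()] or data.frame with its columns
#' @return the table with added columns `derived` (base), `p` (derived
#'   allele frequency in (0, 1]) and `source`
#'   ("outgroup"/"minor-allele-fallback")
#' @export
polarize <- function(snvs) {
  aa <- toupper(snvs$aa %||% rep(NA_character_, nrow(snvs)))
  aa[!aa %in% DNA_BASES] <- NA_character_
  use_out <- !is.na(aa) & (aa == snvs$ref | aa == snvs$alt)
  derived <- ifelse(use_out,
                    ifelse(aa == snvs$ref, snvs$alt, snvs$ref),
                    ifelse(snvs$ac <= snvs$an - snvs$ac, snvs$alt, snvs$ref))
  k <- ifelse(derived == snvs$alt, snvs$ac, snvs$an - snvs$ac)
  out <- snvs
  out$derived <- derived
  out$p <- k / snvs$an
  out$source <- ifelse(use_out, "outgroup", "minor-allele-fallback")
  drop <- out$p == 0
  if (any(drop)) {
    warnf("excluding %d monomorphic record(s) with derived count 0", sum(drop))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Locate an SNV within a transcript's coding sequence
#'
#' Maps a genomic SNV position into codon coordinates on the coding strand.
#' For minus-strand transcripts the alleles and codon are
#' reverse-complemented (which preserves the transition/transversion
#' channel).
#'
#' @param model a [transcript_models()] table restricted to one transcript
#' @param snv one-row [snv_table()] (or list with chrom, pos, ref, alt)
#' @param genome named character vector or `DNAStringSet`
#' @return list with `codon`, `offset` (0..2), `cds_pos`, `ref`, `alt`
#'   (coding strand), or `NULL` if the position is not inside the CDS
#' @export
locate_in_cds <- function(model, snv, genome) {
  ann <- annotate_snvs(model,
                       snv_table(data.frame(chrom = snv$chrom, pos = snv$pos,
                                            ref = snv$ref, alt = snv$alt,
                                            ac = 1, an = 2)),
                       genome, .polarize = FALSE)
  if (nrow(ann) == 0L) return(NULL)
  list(codon = ann$codon[1], offset = ann$offset[1], cds_pos = ann$cds_pos[1],
       ref = ann$cs_ref[1], alt = ann$cs_alt[1])
}

#' Annotate SNVs against transcript models
#'
#' Maps each SNV onto the canonical transcript of each overlapping gene,
#' classifies its coding effect (synonymous/missense/nonsense) and channel
#' (transition/transversion) via [classify_substitution()], and polarizes
#' derived alleles via [polarize()]. SNVs outside any CDS are dropped (count
#' reported in attribute `"n_noncoding"`); SNVs falling in more than one
#' gene's transcript are annotated against each (logged). A mismatch between
#' the VCF reference allele and the genome sequence is an error naming the
#' site. SNVs in codons containing ambiguity codes, or in a terminal stop
#' codon, are skipped to mirror [site_counts()].
#'
#' @param models a [transcript_models()] table, one transcript per gene
#' @param snvs an [snv_table()]
#' @param genome named character vector or `DNAStringSet` of chromosomes
#' @param code genetic code table
#' @param .polarize set to FALSE to skip derived-allele polarization
#' @return data.frame of class `annotated_snvs`: chrom, pos, ref, alt,
#'   gene_id, cds_pos, codon, offset, cs_ref, cs_alt (coding strand),
#'   effect, channel, ac, an, aa, and (after polarization) derived, p, source
#' @export
annotate_snvs <- function(models, snvs, genome, code = genetic_code(),
                          .polarize = TRUE) {
  stopifnot(inherits(models, "transcript_models"))
  genome <- as_genome(genome)
  per_gene_tx <- tapply(models$transcript_id, models$gene_id,
                        function(x) length(unique(x)))
  if (any(per_gene_tx > 1L))
    stopf("gene(s) with multiple transcripts; designate one canonical transcript per gene: %s",
          paste(names(per_gene_tx)[per_gene_tx > 1L], collapse = ", "))
  lay <- cds_layout(models)
  exon_gr <- GenomicRanges::GRanges(
    lay$chrom, IRanges::IRanges(start = lay$start + 1L, end = lay$end))
  snv_gr <- GenomicRanges::GRanges(
    snvs$chrom, IRanges::IRanges(start = snvs$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(snv_gr, exon_gr)
  si <- S4Vectors::queryHits(hits)
  ei <- S4Vectors::subjectHits(hits)
  n_noncoding <- nrow(snvs) - length(unique(si))
  if (length(si) == 0L) {
    out <- empty_annotated()
    attr(out, "n_noncoding") <- n_noncoding
    return(out)
  }
  multi <- tabulate(si, nbins = nrow(snvs))
  if (any(multi > 1L))
    message(sprintf("%d SNV(s) fall in more than one gene; annotated against each",
                    sum(multi > 1L)))
  strand <- lay$strand[ei]
  asc_pos <- snvs$pos[si] - lay$start[ei] + lay$cds_before[ei]
  cds_pos <- ifelse(strand == "+", asc_pos, lay$cds_total[ei] - 1 - asc_pos)
  cds_seq <- extract_cds(models, genome)
  tx <- lay$transcript_id[ei]
  tx_ids <- unique(models$transcript_id)
  seq_of <- cds_seq[match(models$gene_id[match(tx, models$transcript_id)],
                          names(cds_seq))]
  # coding-strand alleles
  cs_ref <- ifelse(strand == "+", snvs$ref[si], comp_base(snvs$ref[si]))
  cs_alt <- ifelse(strand == "+", snvs$alt[si], comp_base(snvs$alt[si]))
  genome_base <- substr(seq_of, cds_pos + 1L, cds_pos + 1L)
  bad <- genome_base != cs_ref
  if (any(bad))
    stopf("VCF reference differs from genome at %s",
          paste(sprintf("%s:%d (vcf %s, genome %s)", snvs$chrom[si][bad],
                        snvs$pos[si][bad] + 1L, snvs$ref[si][bad],
                        ifelse(strand[bad] == "+", genome_base[bad],
                               comp_base(genome_base[bad])))[seq_len(min(5, sum(bad)))],
                collapse = "; "))
  codon_idx <- cds_pos %/% 3
  offset <- cds_pos %% 3
  codon <- substr(seq_of, codon_idx * 3 + 1L, codon_idx * 3 + 3L)
  # mirror site_counts: skip ambiguous codons and any terminal stop codon
  tabs <- substitution_tables(code)
  valid <- codon %in% tabs$codons
  is_stop <- valid & code[ifelse(valid, codon, "AAA")] == "*"
  n_cod <- nchar(seq_of) %/% 3
  terminal <- is_stop & codon_idx == n_cod - 1L
  if (any(is_stop & !terminal))
    stopf("SNV in internal stop codon at %s:%d",
          snvs$chrom[si][is_stop & !terminal][1],
          snvs$pos[si][is_stop & !terminal][1] + 1L)
  keep <- valid & !terminal
  if (any(!keep))
    message(sprintf("skipping %d SNV(s) in ambiguous or terminal-stop codons",
                    sum(!keep)))
  si <- si[keep]
  cls <- classify_substitution(codon[keep], offset[keep], cs_alt[keep], code)
  out <- data.frame(
    chrom = snvs$chrom[si], pos = snvs$pos[si], ref = snvs$ref[si],
    alt = snvs$alt[si],
    gene_id = models$gene_id[match(tx[keep], models$transcript_id)],
    cds_pos = cds_pos[keep], codon = codon[keep], offset = offset[keep],
    cs_ref = cs_ref[keep], cs_alt = cs_alt[keep],
    effect = cls$effect, channel = cls$channel,
    ac = snvs$ac[si], an = snvs$an[si], aa = snvs$aa[si])
  if (.polarize) out <- polarize(out)
  rownames(out) <- NULL
  class(out) <- c("annotated_snvs", "data.frame")
  attr(out, "n_noncoding") <- n_noncoding
  out
}

empty_annotated <- function() {
  out <- data.frame(chrom = character(0), pos = numeric(0), ref = character(0),
                    alt = character(0), gene_id = character(0),
                    cds_pos = numeric(0), codon = character(0),
                    offset = numeric(0), cs_ref = character(0),
                    cs_alt = character(0), effect = character(0),
                    channel = character(0), ac = numeric(0), an = numeric(0),
                    aa = character(0), derived = character(0), p = numeric(0),
                    source = character(0))
  class(out) <- c("annotated_snvs", "data.frame")
  out
}

#' Count SNVs by coding effect class
#'
#' Pools missense and nonsense SNVs as nonsynonymous (nsSNV) and counts
#' synonymous SNVs (sSNV), optionally restricted to a gene-set filter.
#'
#' @param annotated an [annotate_snvs()] table
#' @param genes optional character vector of gene ids to keep
#' @return named numeric vector `c(nsSNV = ..., sSNV = ...)`
#' @export
count_by_class <- function(annotated, genes = NULL) {
  if (!is.null(genes))
    annotated <- annotated[annotated$gene_id %in% genes, , drop = FALSE]
  c(nsSNV = sum(annotated$effect %in% c("missense", "nonsense")),
    sSNV = sum(annotated$effect == "synonymous"))
}
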