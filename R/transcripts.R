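#' Construct a transcript model table
#'
#' A transcript model is the ordered set of CDS intervals of one transcript
#' on a chromosome. The table is long-format: one row per CDS interval with
#' columns `gene_id`, `transcript_id`, `chrom`, `strand` (+/-), `start`,
#' `end` (0-based, half-open, genomic coordinates). Intervals of a transcript
#' must be non-overlapping and are stored sorted by genomic start; the total
#' CDS length must be divisible by 3.
#'
#' @param df data.frame with the columns above
#' @return validated data.frame of class `transcript_models`
#' @export
transcript_models <- function(df) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  if (!all(need %in% names(df)))
    stopf("transcript models need columns: %s", paste(need, collapse = ", "))
  df <- df[, need]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(df$end <= df$start)) stopf("transcript model has empty interval")
  if (!all(df$strand %in% c("+", "-")))
    stopf("strand must be '+' or '-'")
  df <- df[order(df$transcript_id, df$start), , drop = FALSE]
  for (tid in unique(df$transcript_id)) {
    rows <- df[df$transcript_id == tid, ]
    if (length(unique(rows$chrom)) != 1L || length(unique(rows$strand)) != 1L)
      stopf("transcript %s spans multiple chromosomes or strands", tid)
    if (nrow(rows) > 1L && any(rows$start[-1L] < rows$end[-nrow(rows)]))
      stopf("transcript %s has overlapping CDS intervals", tid)
    if (sum(rows$end - rows$start) %% 3 != 0)
      stopf("transcript %s CDS length not divisible by 3", tid)
  }
  rownames(df) <- NULL
  class(df) <- c("transcript_models", "data.frame")
  df
}

#' Extract coding sequences from a genome
#'
#' Concatenates the CDS intervals of each transcript in genomic order and
#' reverse-complements the result for minus-strand transcripts, yielding the
#' in-frame coding-strand sequence.
#'
#' @param models a [transcript_models()] table
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences
#' @return named character vector of CDS sequences, one per transcript,
#'   named by `gene_id`
#' @export
extract_cds <- function(models, genome) {
  genome <- as_genome(genome)
  tids <- unique(models$transcript_id)
  out <- vapply(tids, function(tid) {
    rows <- models[models$transcript_id == tid, ]
    chrom <- rows$chrom[1]
    if (!chrom %in% names(genome))
      stopf("chromosome %s not in genome", chrom)
    pieces <- substring(genome[[chrom]], rows$start + 1L, rows$end)
    s <- paste(pieces, collapse = "")
    if (rows$strand[1] == "-") s <- revcomp(s)
    s
  }, character(1))
  names(out) <- models$gene_id[match(tids, models$transcript_id)]
  out
}

#' Read transcript models from a tabular or BED12 file
#'
#' Two formats are accepted. The native tabular format is a TSV with header
#' `gene_id  transcript_id  chrom  strand  cds_starts  cds_ends` where the
#' last two columns hold comma-separated 0-based half-open interval bounds.
#' BED12 files (no header, 12 columns) are also accepted: blocks are clipped
#' to the thick (CDS) region and the `name` field is split as
#' `gene_id|transcript_id` (falling back to name for both).
#'
#' @param path file path
#' @return a [transcript_models()] table
#' @export
read_transcripts <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first)) stopf("empty transcript file: %s", path)
  fields <- strsplit(sub("\r$", "", first), "\t")[[1]]
  if (identical(fields[1], "gene_id")) {
    df <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = "character", comment.char = "#")
    rows <- lapply(seq_len(nrow(df)), function(i) {
      starts <- as.numeric(strsplit(df$cds_starts[i], ",")[[1]])
      ends <- as.numeric(strsplit(df$cds_ends[i], ",")[[1]])
      if (length(starts) != length(ends))
        stopf("%s line %d: cds_starts/cds_ends length mismatch", path, i + 1L)
      data.frame(gene_id = df$gene_id[i], transcript_id = df$transcript_id[i],
                 chrom = df$chrom[i], strand = df$strand[i],
                 start = starts, end = ends)
    })
    return(transcript_models(do.call(rbind, rows)))
  }
  if (length(fields) < 12L)
    stopf("%s: expected tabular header or BED12 (12 columns)", path)
  bed <- read.table(path, header = FALSE, sep = "\t",
                    colClasses = "character")
  rows <- lapply(seq_len(nrow(bed)), function(i) {
    chrom <- bed[i, 1]; chrom_start <- as.numeric(bed[i, 2])
    name <- bed[i, 4]; strand <- bed[i, 6]
    thick_start <- as.numeric(bed[i, 7]); thick_end <- as.numeric(bed[i, 8])
    sizes <- as.numeric(strsplit(sub(",$", "", bed[i, 11]), ",")[[1]])
    offs <- as.numeric(strsplit(sub(",$", "", bed[i, 12]), ",")[[1]])
    starts <- chrom_start + offs
    ends <- starts + sizes
    keep <- pmax(starts, thick_start) < pmin(ends, thick_end)
    ids <- strsplit(name, "|", fixed = TRUE)[[1]]
    data.frame(gene_id = ids[1],
               transcript_id = if (length(ids) > 1) ids[2] else ids[1],
               chrom = chrom, strand = strand,
               start = pmax(starts[keep], thick_start),
               end = pmin(ends[keep], thick_end))
  })
  transcript_models(do.call(rbind, rows))
}

#' Write transcript models
#'
#' @param models a [transcript_models()] table
#' @param path output file
#' @param format `"tsv"` (native tabular) or `"bed12"`
#' @return invisibly, `path`
#' @export
write_transcripts <- function(models, path, format = c("tsv", "bed12")) {
  format <- match.arg(format)
  tids <- unique(models$transcript_id)
  if (format == "tsv") {
    df <- do.call(rbind, lapply(tids, function(tid) {
      rows <- models[models$transcript_id == tid, ]
      data.frame(gene_id = rows$gene_id[1], transcript_id = tid,
                 chrom = rows$chrom[1], strand = rows$strand[1],
                 cds_starts = paste(format(rows$start, scientific = FALSE, trim = TRUE), collapse = ","),
                 cds_ends = paste(format(rows$end, scientific = FALSE, trim = TRUE), collapse = ","))
    }))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    lines <- vapply(tids, function(tid) {
      rows <- models[models$transcript_id == tid, ]
      cs <- min(rows$start); ce <- max(rows$end)
      paste(rows$chrom[1], cs, ce,
            paste0(rows$gene_id[1], "|", tid), 0, rows$strand[1],
            cs, ce, "0", nrow(rows),
            paste0(paste(rows$end - rows$start, collapse = ","), ","),
            paste0(paste(rows$start - cs, collapse = ","), ","),
            sep = "\t")
    }, character(1))
    writeLines(lines, path)
  }
  invisible(path)
}

# cumulative CDS offset table used to map genomic -> CDS coordinates
cds_layout <- function(models) {
  models <- models[order(models$transcript_id, models$start), , drop = FALSE]
  width <- models$end - models$start
  # rows are sorted by transcript then start, so split() groups align with rows
  cum <- unlist(lapply(split(width, factor(models$transcript_id,
                                           levels = unique(models$transcript_id))),
                       function(wd) cumsum(c(0, wd[-length(wd)]))),
                use.names = FALSE)
  models$cds_before <- cum
  total <- tapply(width, models$transcript_id, sum)
  models$cds_total <- as.numeric(total[models$transcript_id])
  models
}
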