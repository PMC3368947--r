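#' Read in-frame coding sequences from a FASTA file
#'
#' Headers follow the `gene_id|transcript_id` convention (configurable
#' delimiter; a header without the delimiter supplies both ids). Each record
#' is validated as an in-frame CDS: length divisible by 3, terminal stop
#' stripped, internal stops rejected.
#'
#' @param path FASTA file
#' @param delim id delimiter in headers
#' @param code genetic code table
#' @return named list of [coding_sequence()] objects (names = gene ids)
#' @export
read_cds_fasta <- function(path, delim = "|", code = genetic_code()) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(headers, delim, fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1L)
  tx <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else p[1L],
               character(1))
  out <- Map(coding_sequence, as.character(seqs), gene, tx,
             code = list(code))
  names(out) <- gene
  out
}

#' Read a genome FASTA
#'
#' @param path FASTA file
#' @return named character vector of chromosome sequences (first header
#'   word as name)
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a TSV with optional `#` metadata lines
#'
#' Machine outputs use 6 significant digits for floating point columns.
#'
#' @param df data.frame
#' @param path output file
#' @param meta character vector of metadata lines (prefixed with `# `)
#' @return invisibly, `path`
#' @export
write_tsv <- function(df, path, meta = NULL) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(meta)) writeLines(paste("#", meta), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path file path
#' @return data.frame (metadata lines skipped)
#' @export
read_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE)
}

# Run manifest: configuration + seed + package version, serialized next to
# outputs so every result is reproducible from its manifest.
write_manifest <- function(dir, config) {
  config$rdnsv_version <- as.character(utils::packageVersion("rdnsv"))
  config$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(config, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(dir, "manifest.json"))
}
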