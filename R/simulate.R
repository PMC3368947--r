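#' Configuration for the synthetic exome simulator
#'
#' The generator emulates the data the estimator consumes: in-frame coding
#' sequences without internal stops, SNVs placed on mutational opportunities
#' with a per-opportunity transition weight `w` (default 4, i.e. per-basepair
#' transition/transversion rate ratio 2), a fraction `pi_intolerant` of
#' nonsynonymous opportunities at which no variant may segregate (the
#' strongly deleterious site class), and derived allele frequencies drawn
#' from a discretized site frequency spectrum on `{1/N, ..., (N-1)/N}` with
#' mass proportional to `1/k` for neutral variants and `(1/k) exp(-gamma k/N)`
#' for deleterious tolerated nonsynonymous variants (extra skew toward rare
#' alleles). Synonymous variants are always neutral.
#'
#' @param n_genes number of genes (default 200)
#' @param codons_min,codons_max per-gene codon count range (default 250-350,
#'   i.e. ~300 codons)
#' @param n_chromosomes even number of sampled chromosomes (default 400)
#' @param w per-opportunity transition/transversion rate ratio (default 4)
#' @param s_density target expected sSNVs per synonymous site (default 0.02,
#'   the order observed in a few hundred pooled human exomes)
#' @param pi_intolerant fraction of nonsynonymous opportunities that never
#'   emit a variant
#' @param gamma deleterious frequency-skew parameter (>= 0; 0 = no skew)
#' @param frac_neutral fraction of tolerated nonsynonymous opportunities
#'   whose variants are strictly neutral (no skew)
#' @param codon_weights optional named numeric vector of sampling weights
#'   over sense codons (default uniform)
#' @param n_exons_max maximum exons per gene (1..n sampled uniformly)
#' @param intron_length,flank lengths of intronic separators and contig
#'   flanks (bp)
#' @param seed optional integer seed; identical config + seed reproduce the
#'   dataset byte for byte
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(n_genes = 200, codons_min = 250, codons_max = 350,
                       n_chromosomes = 400, w = 4, s_density = 0.02,
                       pi_intolerant = 0.45, gamma = 2, frac_neutral = 0.25,
                       codon_weights = NULL, n_exons_max = 3,
                       intron_length = 30, flank = 25, seed = NULL) {
  stopifnot(is_count(n_genes), is_count(codons_min), is_count(codons_max),
            codons_min >= 1, codons_max >= codons_min,
            is_count(n_chromosomes), n_chromosomes >= 2,
            n_chromosomes %% 2 == 0,
            w > 0, s_density > 0,
            pi_intolerant >= 0, pi_intolerant <= 1, gamma >= 0,
            frac_neutral >= 0, frac_neutral <= 1,
            is_count(n_exons_max), n_exons_max >= 1,
            is_count(intron_length), is_count(flank))
  if (!is.null(seed)) stopifnot(is_count(seed), seed < 2^31)
  structure(list(n_genes = n_genes, codons_min = codons_min,
                 codons_max = codons_max, n_chromosomes = n_chromosomes,
                 w = w, s_density = s_density,
                 pi_intolerant = pi_intolerant, gamma = gamma,
                 frac_neutral = frac_neutral, codon_weights = codon_weights,
                 n_exons_max = n_exons_max, intron_length = intron_length,
                 flank = flank, seed = seed), class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate coding sequences and transcript models
#'
#' Generates `n_genes` in-frame coding sequences from sense codons (so no
#' internal or terminal stop codons by construction), embeds them in small
#' contigs (one per gene) split into 1 or more exons with intronic
#' separators and flanks of random sequence, alternating plus and minus
#' strands.
#'
#' @param config a [sim_config()]
#' @return list of class `sim_cds`: `genome` (named character vector of
#'   contigs), `models` (a [transcript_models()] table), `cds` (named
#'   coding-strand sequences per gene), `config`
#' @export
simulate_cds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  code <- genetic_code()
  sense <- names(code)[code != "*"]
  wts <- config$codon_weights
  if (!is.null(wts)) {
    if (is.null(names(wts)) || !all(names(wts) %in% sense))
      stopf("codon_weights must be named by sense codons")
    wts <- wts[match(sense, names(wts))]
    wts[is.na(wts)] <- 0
  }
  if (config$n_genes == 0)
    return(structure(list(genome = character(0),
                          models = NULL, cds = character(0),
                          config = config), class = "sim_cds"))
  genome <- character(config$n_genes)
  cds <- character(config$n_genes)
  model_rows <- vector("list", config$n_genes)
  gid <- sprintf("g%04d", seq_len(config$n_genes))
  tid <- sprintf("t%04d", seq_len(config$n_genes))
  ctg <- sprintf("ctg%04d", seq_len(config$n_genes))
  for (i in seq_len(config$n_genes)) {
    n_cod <- sample(config$codons_min:config$codons_max, 1L)
    codons <- sample(sense, n_cod, replace = TRUE, prob = wts)
    seq_i <- paste(codons, collapse = "")
    L <- 3L * n_cod
    strand <- if (i %% 2L == 1L) "+" else "-"
    n_ex <- sample.int(config$n_exons_max, 1L)
    cuts <- if (n_ex > 1L) sort(sample.int(L - 1L, n_ex - 1L)) else integer(0)
    bounds <- c(0L, cuts, L)
    pieces <- substring(seq_i, bounds[-length(bounds)] + 1L, bounds[-1L])
    if (strand == "-") pieces <- rev(revcomp(pieces))
    introns <- vapply(seq_len(n_ex - 1L),
                      function(j) random_dna(config$intron_length),
                      character(1))
    left <- random_dna(config$flank); right <- random_dna(config$flank)
    parts <- character(2L * n_ex - 1L)
    parts[seq(1L, by = 2L, length.out = n_ex)] <- pieces
    if (n_ex > 1L) parts[seq(2L, by = 2L, length.out = n_ex - 1L)] <- introns
    genome[i] <- paste0(left, paste(parts, collapse = ""), right)
    widths <- nchar(pieces)
    starts <- config$flank +
      cumsum(c(0L, head(widths, -1L) + config$intron_length))
    model_rows[[i]] <- data.frame(gene_id = gid[i], transcript_id = tid[i],
                                  chrom = ctg[i], strand = strand,
                                  start = starts, end = starts + widths)
    cds[i] <- seq_i
  }
  names(genome) <- ctg
  names(cds) <- gid
  structure(list(genome = genome,
                 models = transcript_models(do.call(rbind, model_rows)),
                 cds = cds, config = config), class = "sim_cds")
}

# discretized SFS mass on derived counts 1..N-1
sfs_mass <- function(n_chromosomes, gamma = 0) {
  k <- seq_len(n_chromosomes - 1L)
  m <- exp(-gamma * k / n_chromosomes) / k
  m / sum(m)
}

#' Simulate SNVs with known selection structure
#'
#' Places SNVs on the mutational opportunities of simulated coding
#' sequences. Each opportunity receives an SNV independently with probability
#' proportional to its rate weight (`w` for transitions, 1 for
#' transversions), scaled so the expected synonymous SNV density matches
#' `s_density`. Nonsynonymous opportunities are first labelled intolerant
#' i.i.d. with probability `pi_intolerant`; intolerant opportunities never
#' emit, so the expected pooled rdnsv is `1 - pi_intolerant`. Derived allele
#' counts are drawn from the discretized neutral spectrum (mass ~ 1/k) for
#' synonymous and strictly neutral nonsynonymous variants, and from the
#' deleterious spectrum (mass ~ exp(-gamma k/N)/k) otherwise. The reference
#' allele is ancestral; the derived allele is emitted as ALT with `AA`, `AC`
#' and `AN` annotations.
#'
#' @param sim a [simulate_cds()] result
#' @param config a [sim_config()]; defaults to the one inside `sim`. When the
#'   config carries a seed, SNV placement is reseeded with `seed + 1` so the
#'   whole dataset is reproducible from the config alone.
#' @return list of class `sim_dataset`: `genome`, `models`, `cds`, `snvs`
#'   (an [snv_table()] with extra truth columns gene_id, effect, channel,
#'   p, selection_class), `truth` (pi_intolerant, gamma, expected rdnsv_0),
#'   `config`
#' @export
simulate_snvs <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "sim_cds"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  tabs <- substitution_tables()
  genes <- names(sim$cds)
  if (length(genes) == 0L) stopf("no genes to simulate SNVs on")
  L_g <- nchar(sim$cds)
  gene_of <- rep.int(seq_along(genes), L_g)
  pos_in_cds <- unlist(lapply(L_g, function(L) seq_len(L) - 1L),
                       use.names = FALSE)
  cds_all <- strsplit(paste(sim$cds, collapse = ""), "")[[1]]
  codon_idx <- pos_in_cds %/% 3L
  offset <- pos_in_cds %% 3L
  codon_start <- which(offset == 0L)
  codons_bp <- rep(paste0(cds_all[codon_start], cds_all[codon_start + 1L],
                          cds_all[codon_start + 2L]), each = 3L)
  # expand to 3 alternative bases per basepair
  alt_lookup <- rbind(A = c("C", "G", "T"), C = c("A", "G", "T"),
                      G = c("A", "C", "T"), T = c("A", "C", "G"))
  n_bp <- length(cds_all)
  bp_ix <- rep(seq_len(n_bp), each = 3L)
  ref <- cds_all[bp_ix]
  alt <- as.vector(t(alt_lookup[cds_all, , drop = FALSE]))
  ci <- match(codons_bp, tabs$codons)[bp_ix]
  effect <- tabs$effect[cbind(ci, offset[bp_ix] + 1L,
                              match(alt, DNA_BASES))]
  ts <- is_transition(ref, alt)
  weight <- ifelse(ts, config$w, 1)
  syn <- effect == "synonymous"
  sSite_total <- sum(syn) / 3
  mu <- config$s_density * sSite_total / sum(weight[syn])
  if (mu * config$w > 1)
    stopf("target sSNV density implies > 1 expected SNV per opportunity (mu*w = %.3f)",
          mu * config$w)
  intolerant <- !syn & runif(length(syn)) < config$pi_intolerant
  emit_p <- ifelse(intolerant, 0, mu * weight)
  emitted <- runif(length(emit_p)) < emit_p
  idx <- which(emitted)
  n_snv <- length(idx)
  e_syn <- syn[idx]
  neutral <- e_syn | runif(n_snv) < config$frac_neutral
  N <- config$n_chromosomes
  k <- integer(n_snv)
  if (any(neutral))
    k[neutral] <- sample.int(N - 1L, sum(neutral), replace = TRUE,
                             prob = sfs_mass(N, 0))
  if (any(!neutral))
    k[!neutral] <- sample.int(N - 1L, sum(!neutral), replace = TRUE,
                              prob = sfs_mass(N, config$gamma))
  # map coding positions to genomic coordinates
  g_ix <- gene_of[bp_ix[idx]]
  cp <- pos_in_cds[bp_ix[idx]]
  lay <- cds_layout(sim$models)
  snv_rows <- map_cds_to_genomic(lay, genes[g_ix], cp)
  minus <- snv_rows$strand == "-"
  g_ref <- ifelse(minus, comp_base(ref[idx]), ref[idx])
  g_alt <- ifelse(minus, comp_base(alt[idx]), alt[idx])
  snvs <- data.frame(chrom = snv_rows$chrom, pos = snv_rows$pos,
                     ref = g_ref, alt = g_alt, ac = k, an = N, aa = g_ref,
                     gene_id = genes[g_ix],
                     effect = effect[idx],
                     channel = ifelse(ts[idx], "transition", "transversion"),
                     p = k / N,
                     selection_class = ifelse(e_syn, "synonymous",
                                              ifelse(neutral, "neutral",
                                                     "deleterious")))
  ord <- order(snvs$chrom, snvs$pos, snvs$alt)
  snvs <- snvs[ord, , drop = FALSE]
  rownames(snvs) <- NULL
  truth <- list(pi_intolerant = config$pi_intolerant, gamma = config$gamma,
                frac_neutral = config$frac_neutral,
                expected_rdnsv_0 = 1 - config$pi_intolerant,
                mu = mu, n_snv = n_snv)
  structure(list(genome = sim$genome, models = sim$models, cds = sim$cds,
                 snvs = snvs, truth = truth, config = config),
            class = "sim_dataset")
}

# vectorized CDS -> genomic coordinate mapping; gene_ids and cds_pos aligned
map_cds_to_genomic <- function(lay, gene_ids, cds_pos) {
  out_chrom <- character(length(gene_ids))
  out_pos <- numeric(length(gene_ids))
  out_strand <- character(length(gene_ids))
  for (g in unique(gene_ids)) {
    rows <- lay[lay$gene_id == g, , drop = FALSE]
    sel <- gene_ids == g
    cp <- cds_pos[sel]
    L <- rows$cds_total[1]
    asc <- if (rows$strand[1] == "+") cp else L - 1 - cp
    j <- findInterval(asc, rows$cds_before)
    out_chrom[sel] <- rows$chrom[1]
    out_pos[sel] <- rows$start[j] + (asc - rows$cds_before[j])
    out_strand[sel] <- rows$strand[1]
  }
  data.frame(chrom = out_chrom, pos = out_pos, strand = out_strand)
}

#' Simulate a complete dataset (CDS + SNVs)
#'
#' @param config a [sim_config()]
#' @return a `sim_dataset`, see [simulate_snvs()]
#' @export
simulate_dataset <- function(config) {
  simulate_snvs(simulate_cds(config), config)
}

#' Expected truth values for a simulation configuration
#'
#' The expected spectrum-regression intercept is `1 - pi_intolerant`: every
#' tolerated opportunity emits at the neutral rate, so the relative density
#' of nonsynonymous variants at low frequency equals the tolerated fraction.
#' Because derived frequencies are drawn from normalized spectra (emission is
#' independent of `gamma`), the expected pooled rdnsv over all frequencies is
#' also `1 - pi_intolerant`; `gamma` only redistributes nonsynonymous
#' variants toward rare bins. The per-bin expectation is computed by
#' integrating bin occupancy under the neutral and deleterious spectra.
#'
#' @param config a [sim_config()]
#' @param bins optional [make_bins()] table for per-bin expectations
#' @return list with `expected_rdnsv_0`, `expected_pooled_rdnsv` and, when
#'   `bins` is given, a data.frame `bin_expectation` with the expected
#'   per-bin rdnsv
#' @export
expected_truth <- function(config, bins = NULL) {
  stopifnot(inherits(config, "sim_config"))
  out <- list(expected_rdnsv_0 = 1 - config$pi_intolerant,
              expected_pooled_rdnsv = 1 - config$pi_intolerant)
  if (!is.null(bins)) {
    N <- config$n_chromosomes
    k <- seq_len(N - 1L)
    m_neu <- sfs_mass(N, 0)
    m_del <- sfs_mass(N, config$gamma)
    p <- k / N
    occupancy <- function(m, lo, hi) sum(m[p >= lo & p < hi])
    exp_bin <- vapply(seq_len(nrow(bins)), function(b) {
      neu <- occupancy(m_neu, bins$lower[b], bins$upper[b])
      del <- occupancy(m_del, bins$lower[b], bins$upper[b])
      ns <- (1 - config$pi_intolerant) *
        (config$frac_neutral * neu + (1 - config$frac_neutral) * del)
      if (neu > 0) ns / neu else NA_real_
    }, numeric(1))
    out$bin_expectation <- data.frame(lower = bins$lower, upper = bins$upper,
                                      expected_rdnsv = exp_bin)
  }
  out
}

#' Write a simulated dataset to standard files
#'
#' Emits the CDS FASTA (headers `gene_id|transcript_id`), the genome
#' (contig) FASTA, the transcript model TSV, the SNV VCF (4.2, with AA/AC/AN
#' INFO) and a truth JSON.
#'
#' @param ds a [simulate_snvs()] result
#' @param dir output directory (created if needed)
#' @return invisibly, named vector of the written paths
#' @export
write_sim_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(cds = file.path(dir, "cds.fasta"),
             genome = file.path(dir, "genome.fasta"),
             models = file.path(dir, "models.tsv"),
             vcf = file.path(dir, "snvs.vcf"),
             truth = file.path(dir, "truth.json"))
  tid <- ds$models$transcript_id[match(names(ds$cds), ds$models$gene_id)]
  cds_set <- Biostrings::DNAStringSet(ds$cds)
  names(cds_set) <- paste0(names(ds$cds), "|", tid)
  Biostrings::writeXStringSet(cds_set, paths["cds"])
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$genome),
                              paths["genome"])
  write_transcripts(ds$models, paths["models"])
  write_vcf(snv_table(ds$snvs[, c("chrom", "pos", "ref", "alt", "ac", "an",
                                  "aa")]),
            paths["vcf"], contigs = names(ds$genome))
  jsonlite::write_json(ds$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}

#' Run the full rdnsv pipeline on an in-memory dataset
#'
#' Annotates the SNVs against the transcript models and genome, counts
#' sites on the extracted coding sequences, and returns the pooled rdnsv
#' estimate plus (optionally) the frequency-spectrum fit. This is the same
#' code path as the file-based CLI, without the serialization.
#'
#' @param ds a `sim_dataset` or a list with `genome`, `models` and an
#'   [snv_table()] in `snvs`
#' @param w transition/transversion opportunity rate ratio
#' @param factors optional [correction_factors()] override (e.g.
#'   [fixed_correction_factors()])
#' @param fit logical: also fit the spectrum regression
#' @param bin_edges passed to [make_bins()]
#' @return list with `sites`, `factors`, `annotated`, `estimate` and, when
#'   `fit = TRUE`, `bin_estimates` and `fit`
#' @export
estimate_dataset <- function(ds, w = 4, factors = NULL, fit = FALSE,
                             bin_edges = c(0.02, 0.05, 0.10, 0.20, 0.40,
                                           0.80, 0.95)) {
  cds <- extract_cds(ds$models, ds$genome)
  site_df <- site_counts_table(cds)
  sites <- attr(site_df, "aggregate")
  if (is.null(factors)) factors <- correction_factors(sites, w = w)
  snvs <- snv_table(as.data.frame(ds$snvs)[, c("chrom", "pos", "ref", "alt",
                                               "ac", "an", "aa")])
  annotated <- annotate_snvs(ds$models, snvs, ds$genome)
  counts <- count_by_class(annotated)
  n_chrom <- if (nrow(annotated)) max(annotated$an) else NA_integer_
  est <- rdnsv_estimate(counts[["nsSNV"]], counts[["sSNV"]], sites,
                        factors, n_chromosomes = n_chrom)
  out <- list(sites = sites, factors = factors, annotated = annotated,
              site_table = site_df, estimate = est)
  if (fit) {
    bins <- make_bins(bin_edges, n_chromosomes = n_chrom)
    out$bin_estimates <- rdnsv_by_bin(annotated, sites, factors, bins)
    out$fit <- fit_spectrum(out$bin_estimates)
  }
  out
}
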