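#' Build a per-gene count table
#'
#' Joins per-gene site counts with per-gene SNV counts into the table used by
#' the gene-set statistics ([permutation_test()], [background_quantiles()]).
#'
#' @param site_df per-gene site counts from [site_counts_table()]
#' @param annotated an [annotate_snvs()] table (SNVs in genes absent from
#'   `site_df` are ignored)
#' @return data.frame of class `gene_table`: gene_id, nsSNV, sSNV, sSite,
#'   nsSite, sSite_ts, nsSite_ts
#' @export
build_gene_table <- function(site_df, annotated) {
  is_ns <- annotated$effect %in% c("missense", "nonsense")
  ns <- table(factor(annotated$gene_id[is_ns], levels = site_df$gene_id))
  s <- table(factor(annotated$gene_id[!is_ns], levels = site_df$gene_id))
  out <- data.frame(gene_id = site_df$gene_id,
                    nsSNV = as.numeric(ns), sSNV = as.numeric(s),
                    sSite = site_df$sSite, nsSite = site_df$nsSite,
                    sSite_ts = site_df$sSite_ts,
                    nsSite_ts = site_df$nsSite_ts)
  class(out) <- c("gene_table", "data.frame")
  out
}

GENE_TABLE_COLS <- c("nsSNV", "sSNV", "sSite", "nsSite", "sSite_ts",
                     "nsSite_ts")

# Pooled statistic on column sums of a gene_table subset. `sums` may be a
# matrix with one row per (permuted) set and the 6 GENE_TABLE_COLS columns.
pooled_statistic <- function(sums, statistic, w = 4) {
  if (is.null(dim(sums))) sums <- matrix(sums, nrow = 1,
                                         dimnames = list(NULL, names(sums)))
  Rn <- sums[, "nsSNV"] / sums[, "nsSite"]
  Rs <- sums[, "sSNV"] / sums[, "sSite"]
  switch(statistic,
    Rn = Rn,
    Rs = Rs,
    Rn_Rs = Rn / Rs,
    rdnsv = {
      q_s <- sums[, "sSite_ts"] / sums[, "sSite"]
      q_n <- sums[, "nsSite_ts"] / sums[, "nsSite"]
      f <- (w * q_s + (1 - q_s)) / (w * q_n + (1 - q_n))
      f * Rn / Rs
    },
    stopf("unknown statistic '%s'", statistic))
}

set_sums <- function(tbl, genes) {
  colSums(tbl[tbl$gene_id %in% genes, GENE_TABLE_COLS, drop = FALSE])
}

#' Gene-set statistic from pooled counts
#'
#' @param tbl a [build_gene_table()] table
#' @param genes gene ids of the set
#' @param statistic one of "rdnsv", "Rn", "Rs", "Rn_Rs"; `rdnsv` uses
#'   correction factors recomputed from the set's own pooled site counts
#' @param w per-opportunity transition/transversion rate ratio
#' @return scalar statistic value
#' @export
gene_set_statistic <- function(tbl, genes, statistic = "rdnsv", w = 4) {
  unname(pooled_statistic(set_sums(tbl, genes), statistic, w))
}

#' Permutation test for a difference between two gene sets
#'
#' Compares a pooled-count statistic between two disjoint gene sets by
#' permuting the category labels over the union of genes and counting how
#' often the permuted absolute difference is at least the observed one
#' (two-sided). Statistics are recomputed from pooled counts of each permuted
#' partition, not averaged per gene. The Monte-Carlo p-value uses the add-one
#' correction `p = (1 + n_exceed) / (n_perm + 1)`, so it is never 0. With
#' `exhaustive = TRUE` all partitions are enumerated and the p-value is the
#' exact proportion of partitions (including the observed one) with
#' `|delta| >= |delta_obs|`.
#'
#' @param tbl a [build_gene_table()] table
#' @param set_a,set_b disjoint character vectors of gene ids present in `tbl`
#' @param statistic see [gene_set_statistic()]
#' @param n_perm number of label permutations (default 10000)
#' @param seed optional integer seed for reproducibility
#' @param w transition/transversion opportunity rate ratio
#' @param exhaustive enumerate all partitions (small unions only)
#' @return object of class `permutation_result`: observed values and
#'   difference, p-value, statistic name, permutation count, seed
#' @export
permutation_test <- function(tbl, set_a, set_b, statistic = "rdnsv",
                             n_perm = 10000, seed = NULL, w = 4,
                             exhaustive = FALSE) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(intersect(set_a, set_b)))
    stopf("gene sets must be disjoint (%d shared genes)",
          length(intersect(set_a, set_b)))
  missing <- setdiff(c(set_a, set_b), tbl$gene_id)
  if (length(missing))
    stopf("gene(s) absent from the count table: %s",
          paste(head(missing, 5), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  union_genes <- c(set_a, set_b)
  M <- as.matrix(tbl[match(union_genes, tbl$gene_id), GENE_TABLE_COLS])
  total <- colSums(M)
  nA <- length(set_a)
  stat_of <- function(sums_a) {
    sums_b <- sweep(-sums_a, 2, total, `+`)
    pooled_statistic(sums_a, statistic, w) -
      pooled_statistic(sums_b, statistic, w)
  }
  d_obs <- stat_of(matrix(colSums(M[seq_len(nA), , drop = FALSE]), nrow = 1,
                          dimnames = list(NULL, GENE_TABLE_COLS)))
  if (exhaustive) {
    picks <- combn(length(union_genes), nA)
    sums_a <- t(apply(picks, 2, function(ix)
      colSums(M[ix, , drop = FALSE])))
    colnames(sums_a) <- GENE_TABLE_COLS
    d_perm <- stat_of(sums_a)
    ok <- is.finite(d_perm)
    p <- sum(abs(d_perm[ok]) >= abs(d_obs) - 1e-12) / sum(ok)
    n_used <- ncol(picks)
  } else {
    n_exceed <- 0L; n_used <- 0L
    chunk <- 1000L
    remaining <- n_perm
    G <- length(union_genes)
    while (remaining > 0L) {
      m <- min(chunk, remaining)
      sums_a <- t(vapply(seq_len(m), function(i)
        colSums(M[sample.int(G, nA), , drop = FALSE]),
        numeric(length(GENE_TABLE_COLS))))
      colnames(sums_a) <- GENE_TABLE_COLS
      d_perm <- stat_of(sums_a)
      ok <- is.finite(d_perm)
      n_exceed <- n_exceed + sum(abs(d_perm[ok]) >= abs(d_obs) - 1e-12)
      n_used <- n_used + sum(ok)
      remaining <- remaining - m
    }
    if (n_used < n_perm)
      warnf("%d permutation(s) with undefined statistic dropped",
            n_perm - n_used)
    p <- (1 + n_exceed) / (n_used + 1)
  }
  structure(list(statistic = statistic,
                 value_a = gene_set_statistic(tbl, set_a, statistic, w),
                 value_b = gene_set_statistic(tbl, set_b, statistic, w),
                 observed_difference = unname(d_obs), p_value = p,
                 n_perm = n_used, exhaustive = exhaustive,
                 seed = seed %||% NA_integer_),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation test (%s, %s): A = %.4f, B = %.4f, diff = %+.4f, p = %.4g (%d permutations)\n",
    x$statistic, if (x$exhaustive) "exhaustive" else "Monte-Carlo",
    x$value_a, x$value_b, x$observed_difference, x$p_value, x$n_perm))
  invisible(x)
}

#' Background envelope from random gene sets
#'
#' Draws `n_draws` random gene sets of `set_size` genes without replacement
#' from the universe and returns the 2.5% and 97.5% quantiles (linear
#' interpolation) of the pooled statistic, the expected range for an
#' arbitrary gene set of that size.
#'
#' @param tbl a [build_gene_table()] table
#' @param set_size genes per draw (default 1500)
#' @param n_draws number of random sets (default 10000)
#' @param statistic see [gene_set_statistic()]
#' @param seed optional integer seed
#' @param w transition/transversion opportunity rate ratio
#' @param probs quantile probabilities
#' @return object of class `background_envelope` with the quantiles and the
#'   vector of drawn statistics
#' @export
background_quantiles <- function(tbl, set_size = 1500, n_draws = 10000,
                                 statistic = "rdnsv", seed = NULL, w = 4,
                                 probs = c(0.025, 0.975)) {
  G <- nrow(tbl)
  if (set_size > G)
    stopf("set_size (%d) exceeds universe size (%d)", set_size, G)
  if (!is.null(seed)) set.seed(seed)
  M <- as.matrix(tbl[, GENE_TABLE_COLS])
  draws <- vapply(seq_len(n_draws), function(i) {
    unname(pooled_statistic(colSums(M[sample.int(G, set_size), ,
                                      drop = FALSE]), statistic, w))
  }, numeric(1))
  q <- quantile(draws, probs = probs, names = FALSE, type = 7)
  structure(list(statistic = statistic, set_size = set_size,
                 n_draws = n_draws, q_lower = q[1], q_upper = q[2],
                 probs = probs, draws = draws, seed = seed %||% NA_integer_),
            class = "background_envelope")
}

#' @export
print.background_envelope <- function(x, ...) {
  cat(sprintf(
    "background envelope (%s, %d draws of %d genes): [%.4f, %.4f]\n",
    x$statistic, x$n_draws, x$set_size, x$q_lower, x$q_upper))
  invisible(x)
}

#' Select tissue-specific genes from an expression matrix
#'
#' Raw expression values are log2-transformed and Z-scored per gene across
#' all included tissues; a gene is "specifically expressed" in a tissue when
#' its Z-score there exceeds `z_threshold` (default 1.0). Genes are ranked by
#' the number of target tissues in which they are specific (ties broken by
#' total specificity count, then gene id) and the top `K` genes are returned.
#' Zero-variance genes are specific in no tissue (logged, not an error).
#'
#' @param expr numeric matrix, genes as rows, tissues as columns; values > 0
#' @param target_tissues column names defining the tissue group of interest
#' @param K number of genes to select (default 1500)
#' @param z_threshold specificity threshold on the Z-score
#' @param exclude_tissues columns dropped before the Z-transformation
#' @param name gene-set name
#' @return list of class `gene_set` with `name`, `genes` and the ranking
#'   table in `$ranking` (gene_id, n_target, n_total)
#' @export
select_tissue_specific <- function(expr, target_tissues, K = 1500,
                                   z_threshold = 1.0,
                                   exclude_tissues = character(0),
                                   name = "tissue-specific") {
  expr <- as.matrix(expr)
  keep <- setdiff(colnames(expr), exclude_tissues)
  if (length(keep) < 2L) stopf("need at least 2 included tissues")
  if (!all(target_tissues %in% keep))
    stopf("target tissue(s) not in matrix: %s",
          paste(setdiff(target_tissues, keep), collapse = ", "))
  if (any(expr[, keep] <= 0)) stopf("expression values must be positive")
  lx <- log2(expr[, keep, drop = FALSE])
  mu <- rowMeans(lx)
  sdv <- apply(lx, 1, stats::sd)
  flat <- sdv == 0
  if (any(flat))
    message(sprintf("%d zero-variance gene(s): specific in no tissue",
                    sum(flat)))
  z <- (lx - mu) / ifelse(sdv == 0, Inf, sdv)
  spec <- z > z_threshold
  n_target <- rowSums(spec[, target_tissues, drop = FALSE])
  n_total <- rowSums(spec)
  ord <- order(-n_target, -n_total, rownames(expr))
  ranking <- data.frame(gene_id = rownames(expr)[ord],
                        n_target = n_target[ord], n_total = n_total[ord],
                        row.names = NULL)
  structure(list(name = name, genes = head(ranking$gene_id, K),
                 ranking = ranking, K = K, z_threshold = z_threshold),
            class = "gene_set")
}

#' Remove genes shared between two gene sets
#'
#' Candidate sets defined by different criteria can overlap; shared genes
#' are removed from both before set comparisons.
#'
#' @param set_a,set_b character vectors of gene ids
#' @return list with `set_a`, `set_b` (disjoint) and `shared`
#' @export
disjoint_gene_sets <- function(set_a, set_b) {
  shared <- intersect(set_a, set_b)
  if (length(shared))
    message(sprintf("removing %d gene(s) present in both sets",
                    length(shared)))
  list(set_a = setdiff(set_a, shared), set_b = setdiff(set_b, shared),
       shared = shared)
}

#' Read a gene set (one gene id per line)
#' @param path file path
#' @return character vector of unique gene ids
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Write a gene set (one gene id per line)
#' @param genes character vector
#' @param path file path
#' @return invisibly, `path`
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
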