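small_cfg <- function(...) {
  sim_config(n_genes = 12, codons_min = 60, codons_max = 90, ...)
}

test_that("simulate_cds produces valid in-frame stop-free CDS on both strands", {
  cfg <- small_cfg(seed = 2)
  sim <- simulate_cds(cfg)
  expect_length(sim$cds, 12)
  expect_setequal(unique(sim$models$strand), c("+", "-"))
  # every CDS validates (no internal stops, frame intact)
  for (g in names(sim$cds)) expect_s3_class(
    coding_sequence(sim$cds[[g]], g), "coding_sequence")
  # model-extracted CDS equals the generated coding sequence
  extracted <- extract_cds(sim$models, sim$genome)
  expect_identical(unname(extracted[names(sim$cds)]), unname(sim$cds))
  # empty configuration
  expect_length(simulate_cds(sim_config(n_genes = 0, seed = 1))$cds, 0)
})

test_that("identical config and seed reproduce datasets byte for byte", {
  cfg <- small_cfg(seed = 19)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim_dataset(simulate_dataset(cfg), d1)
  write_sim_dataset(simulate_dataset(cfg), d2)
  for (f in c("cds.fasta", "genome.fasta", "models.tsv", "snvs.vcf")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("codon usage skewed to fourfold families raises sSite/nsSite", {
  uni <- simulate_cds(small_cfg(seed = 5))
  wts <- setNames(rep(1, 4), c("GGA", "GGC", "GGG", "GGT"))
  skew <- simulate_cds(small_cfg(seed = 5, codon_weights = wts))
  ratio <- function(sim) {
    agg <- attr(site_counts_table(sim$cds), "aggregate")
    agg$sSite / agg$nsSite
  }
  expect_gt(ratio(skew), ratio(uni))
  expect_equal(ratio(skew), 0.5)  # glycine codons: 1 sSite + 2 nsSite per codon
})

test_that("every simulated SNV lies in the CDS with the truth effect", {
  cfg <- small_cfg(seed = 23, pi_intolerant = 0.3, gamma = 1)
  ds <- simulate_dataset(cfg)
  res <- estimate_dataset(ds)
  ann <- res$annotated
  # every VCF record annotates inside a CDS
  expect_equal(nrow(ann), nrow(ds$snvs))
  key <- function(d) paste(d$chrom, d$pos, d$alt)
  m <- match(key(ds$snvs), key(ann))
  expect_false(anyNA(m))
  # annotated effect and channel equal the generator's truth, and both agree
  # with the brute-force codon oracle
  expect_identical(ann$effect[m], ds$snvs$effect)
  expect_identical(ann$channel[m], ds$snvs$channel)
  for (i in seq_len(nrow(ann))) {
    o <- oracle_classify(ann$codon[i], ann$offset[i], ann$cs_alt[i])
    expect_identical(ann$effect[i], o$effect)
  }
  # derived frequency round-trips through AA polarization
  expect_equal(ann$p[m], ds$snvs$p)
  expect_true(all(ann$source == "outgroup"))
})

test_that("intolerance boundary: pi = 1 yields zero nsSNVs and rdnsv 0", {
  cfg <- small_cfg(seed = 31, pi_intolerant = 1)
  ds <- simulate_dataset(cfg)
  expect_true(all(ds$snvs$effect == "synonymous"))
  res <- estimate_dataset(ds)
  expect_equal(res$estimate$rdnsv, 0)
})

test_that("expected_truth reports the tolerated fraction and bin occupancy", {
  expect_equal(expected_truth(small_cfg(pi_intolerant = 0))$expected_rdnsv_0, 1)
  expect_equal(expected_truth(small_cfg(pi_intolerant = 0.55))$expected_rdnsv_0,
               0.45)
  bins <- make_bins(n_chromosomes = 400)
  et <- expected_truth(small_cfg(pi_intolerant = 0.4, gamma = 0,
                                 frac_neutral = 0), bins)
  # gamma = 0: every bin expects rdnsv = 1 - pi
  expect_equal(et$bin_expectation$expected_rdnsv, rep(0.6, 7))
  # gamma > 0 shifts nonsynonymous mass toward rare bins
  et2 <- expected_truth(small_cfg(pi_intolerant = 0, gamma = 6,
                                  frac_neutral = 0), bins)
  expect_gt(et2$bin_expectation$expected_rdnsv[1], 1)
  expect_lt(et2$bin_expectation$expected_rdnsv[7],
            et2$bin_expectation$expected_rdnsv[1])
})

test_that("unattainable SNV density is rejected", {
  cfg <- small_cfg(seed = 40, s_density = 2)
  sim <- simulate_cds(cfg)
  expect_error(simulate_snvs(sim, cfg), "expected SNV per opportunity")
})

test_that("sim_config validates its probability and size fields", {
  expect_error(sim_config(pi_intolerant = 1.2))
  expect_error(sim_config(n_chromosomes = 401))
  expect_error(sim_config(codons_min = 100, codons_max = 50))
})
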