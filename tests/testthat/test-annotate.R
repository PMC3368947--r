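test_that("locate_in_cds maps plus- and minus-strand coordinates", {
  toy <- toy_genome()
  # plus strand, second exon: genomic 14 is CDS position 5, codon GAT offset 2
  loc <- locate_in_cds(toy$models[toy$models$gene_id == "gplus", ],
                       list(chrom = "chr1", pos = 14, ref = "T", alt = "C"),
                       toy$genome)
  expect_equal(loc$codon, "GAT")
  expect_equal(loc$offset, 2)
  expect_equal(loc$cds_pos, 5)
  expect_equal(loc$ref, "T")
  # minus strand: genomic T>C is coding-strand A>G (transition preserved)
  locm <- locate_in_cds(toy$models[toy$models$gene_id == "gminus", ],
                        list(chrom = "chr2", pos = 5, ref = "T", alt = "C"),
                        toy$genome)
  expect_equal(locm$codon, "ATA")
  expect_equal(locm$offset, 2)
  expect_equal(locm$ref, "A")
  expect_equal(locm$alt, "G")
  # intron position: not-coding signal
  expect_null(locate_in_cds(toy$models[toy$models$gene_id == "gplus", ],
                            list(chrom = "chr1", pos = 10, ref = "A",
                                 alt = "G"), toy$genome))
  # reference mismatch is an error naming the site
  expect_error(locate_in_cds(toy$models[toy$models$gene_id == "gplus", ],
                             list(chrom = "chr1", pos = 14, ref = "G",
                                  alt = "C"), toy$genome),
               "chr1:15")
})

test_that("annotate_snvs classifies effects; nonsense counted as nsSNV", {
  toy <- toy_genome()
  snvs <- snv_table(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(14, 17, 20, 5),
    ref = c("T", "T", "A", "T"),
    alt = c("C", "A", "C", "C"),
    ac = c(3, 10, 396, 8), an = 400,
    aa = c("T", NA, "G", "T")))
  ann <- annotate_snvs(toy$models, snvs, toy$genome)
  expect_equal(nrow(ann), 4)
  expect_equal(ann$effect[ann$pos == 14], "synonymous")
  expect_equal(ann$effect[ann$pos == 17], "nonsense")   # TGT -> TGA
  expect_equal(ann$effect[ann$pos == 20], "synonymous") # GGA -> GGC
  expect_equal(ann$effect[ann$pos == 5], "missense")    # ATA -> ATG
  expect_equal(ann$channel[ann$pos == 5], "transition")
  cnt <- count_by_class(ann)
  expect_equal(unname(cnt), c(2, 2))  # missense + nonsense pooled
  # effect agrees with classify_substitution on the located codon
  for (i in seq_len(nrow(ann))) {
    cls <- classify_substitution(ann$codon[i], ann$offset[i], ann$cs_alt[i])
    expect_equal(ann$effect[i], cls$effect)
    expect_equal(ann$channel[i], cls$channel)
  }
})

test_that("strand invariance: minus-strand annotation equals plus-strand", {
  set.seed(9)
  cds <- random_cds(6)
  L <- nchar(cds)
  genome_p <- c(chrP = paste0("AC", cds, "GT"))
  genome_m <- c(chrM = paste0("AC", revcomp(cds), "GT"))
  mp <- transcript_models(data.frame(gene_id = "g", transcript_id = "t",
                                     chrom = "chrP", strand = "+",
                                     start = 2, end = 2 + L))
  mm <- transcript_models(data.frame(gene_id = "g", transcript_id = "t",
                                     chrom = "chrM", strand = "-",
                                     start = 2, end = 2 + L))
  for (cp in c(0, 3, 7, L - 1)) {
    ref_p <- substr(cds, cp + 1, cp + 1)
    for (alt_p in setdiff(c("A", "C", "G", "T"), ref_p)) {
      sp <- make_snv("chrP", 2 + cp, ref_p, alt_p)
      sm <- make_snv("chrM", 2 + (L - 1 - cp), comp_base(ref_p),
                     comp_base(alt_p))
      ap <- annotate_snvs(mp, sp, genome_p, .polarize = FALSE)
      am <- annotate_snvs(mm, sm, genome_m, .polarize = FALSE)
      expect_equal(ap$effect, am$effect)
      expect_equal(ap$channel, am$channel)
      expect_equal(ap$codon, am$codon)
    }
  }
})

test_that("polarize follows outgroup when informative, minor allele otherwise", {
  s <- snv_table(data.frame(chrom = "c", pos = c(1, 2, 3), ref = "A",
                            alt = "G", ac = c(3, 396, 396), an = 400,
                            aa = c("A", "G", NA)))
  p <- polarize(s)
  expect_equal(p$derived, c("G", "A", "A"))
  expect_equal(p$p, c(3 / 400, 4 / 400, 4 / 400))
  expect_equal(p$source, c("outgroup", "outgroup", "minor-allele-fallback"))
  # conservation: p(derived) + p(ancestral) = 1
  k_anc <- ifelse(p$derived == p$alt, p$an - p$ac, p$ac)
  expect_equal(p$p + k_anc / p$an, rep(1, 3))
  # outgroup matching neither allele falls back to the minor allele
  s2 <- snv_table(data.frame(chrom = "c", pos = 9, ref = "A", alt = "G",
                             ac = 10, an = 400, aa = "C"))
  expect_equal(polarize(s2)$source, "minor-allele-fallback")
  # monomorphic record excluded with warning
  s3 <- snv_table(data.frame(chrom = "c", pos = 5, ref = "A", alt = "G",
                             ac = 400, an = 400, aa = "G"))
  expect_warning(p3 <- polarize(s3), "monomorphic")
  expect_equal(nrow(p3), 0)
})

test_that("count_by_class pools missense+nonsense and applies gene filters", {
  ann <- data.frame(gene_id = c("a", "a", "a", "b", "b", "b", "b"),
                    effect = c("missense", "missense", "nonsense",
                               rep("synonymous", 4)))
  expect_equal(unname(count_by_class(ann)), c(3, 4))
  expect_equal(unname(count_by_class(ann[0, ])), c(0, 0))
  expect_equal(unname(count_by_class(ann, genes = "a")), c(3, 0))
})

test_that("snv_table validation and multiallelic/non-SNV handling", {
  expect_message(s <- snv_table(data.frame(
    chrom = "c", pos = c(1, 2), ref = c("A", "AT"), alt = c("G", "A"),
    ac = 1, an = 4)), "dropping 1")
  expect_equal(nrow(s), 1)
  expect_error(snv_table(data.frame(chrom = "c", pos = 1, ref = "A",
                                    alt = "G", ac = 5, an = 4)),
               "allele counts")
})
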