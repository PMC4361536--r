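# SNP effect annotation, per-site Fst, PSS projection, the binned site
# table and MAF summaries.

toy_gene <- function(strand = "+") {
  # chromosome: 5 bp pad + 12 bp CDS (ATG AAA TTT TAG or its revcomp) + pad
  if (strand == "+") {
    genome <- c(chr = paste0("CCCCC", "ATGAAATTTTAG", "GGGGG"))
  } else {
    genome <- c(chr = paste0("CCCCC", "CTAAAATTTCAT", "GGGGG"))
  }
  list(genome = genome,
       gm = gene_model("g", "chr", strand, rbind(c(5, 17))))
}

test_that("SNP effects classify synonymous, nonsense and strand correctly", {
  t1 <- toy_gene("+")
  # third position of codon 2 (AAA -> AAG): synonymous, genomic pos 11 (1-based)
  eff <- annotate_snp_effect(list(chrom = "chr", pos = 11, ref = "A", alt = "G"),
                             t1$gm, t1$genome)
  expect_equal(eff$effect, "synonymous")
  # AAA -> GAA (pos 9): K -> E nonsynonymous
  eff2 <- annotate_snp_effect(list(chrom = "chr", pos = 9, ref = "A", alt = "G"),
                              t1$gm, t1$genome)
  expect_equal(eff2$effect, "nonsynonymous")
  expect_equal(c(eff2$ref_aa, eff2$alt_aa), c("K", "E"))
  # AAA -> TAA (pos 9): nonsense
  eff3 <- annotate_snp_effect(list(chrom = "chr", pos = 9, ref = "A", alt = "T"),
                              t1$gm, t1$genome)
  expect_equal(eff3$effect, "nonsense")
  # outside the gene: noncoding
  eff4 <- annotate_snp_effect(list(chrom = "chr", pos = 2, ref = "C", alt = "A"),
                              t1$gm, t1$genome)
  expect_equal(eff4$effect, "noncoding")
  # ref mismatch is a data-integrity error
  expect_error(annotate_snp_effect(list(chrom = "chr", pos = 11, ref = "T",
                                        alt = "G"), t1$gm, t1$genome),
               "reference allele mismatch")
})

test_that("minus-strand effects are computed on the reverse complement", {
  t2 <- toy_gene("-")
  # genomic pos 12 is the complement of coding codon-2 position 3 (A of AAA);
  # genome T -> C means coding A -> G: synonymous AAA -> AAG
  eff <- annotate_snp_effect(list(chrom = "chr", pos = 12, ref = "T", alt = "C"),
                             t2$gm, t2$genome)
  expect_equal(eff$effect, "synonymous")
  # genome T -> C at pos 14 alters coding codon 2 AAA -> GAA: nonsynonymous
  eff2 <- annotate_snp_effect(list(chrom = "chr", pos = 14, ref = "T", alt = "C"),
                              t2$gm, t2$genome)
  expect_equal(eff2$effect, "nonsynonymous")
  expect_equal(eff2$ref_aa, "K")
})

test_that("splice-flanking intronic SNPs are flagged", {
  genome <- c(chr = paste0("ATGAAA", "GTAAAG", "TTTTAG"))   # exon|intron|exon
  gm <- gene_model("g", "chr", "+", rbind(c(0, 6), c(12, 18)))
  # first two intron bases (pos 7, 8) and last two (pos 11, 12)
  for (p in c(7, 8, 11, 12)) {
    ref <- substring(genome, p, p)
    eff <- annotate_snp_effect(list(chrom = "chr", pos = p, ref = ref,
                                    alt = setdiff(c("A", "C", "G", "T"), ref)[1]),
                               gm, genome)
    expect_equal(eff$effect, "splice_altering")
  }
  # middle of the intron: noncoding
  ref <- substring(genome, 10, 10)
  eff <- annotate_snp_effect(list(chrom = "chr", pos = 10, ref = ref, alt = "C"),
                             gm, genome)
  expect_equal(eff$effect, "noncoding")
})

test_that("per-site Fst follows the closed form and its invariances", {
  expect_equal(fst_site(1, 0), 1)
  expect_equal(fst_site(0.4, 0.4), 0)
  expect_equal(fst_site(0.9, 0.1), (0.5 - 0.18) / 0.5)
  expect_true(is.na(fst_site(0, 0)))
  expect_error(fst_site(1.2, 0.5), "outside")
  # symmetry and allele-relabeling invariance; bounded in [0, 1]
  set.seed(5)
  p1 <- runif(200); p2 <- runif(200)
  expect_equal(fst_site(p1, p2), fst_site(p2, p1))
  expect_equal(fst_site(p1, p2), fst_site(1 - p1, 1 - p2))
  f <- fst_site(p1, p2)
  expect_true(all(f >= 0 & f <= 1, na.rm = TRUE))
})

test_that("PSS projection fractions are simple set arithmetic", {
  snp_keys <- paste0("chr1:", 1:687)
  pss <- paste0("chr1:", 1:885)
  pr <- project_pairwise_pss(pss, snp_keys)
  expect_equal(pr$n_shared, 687)
  expect_equal(pr$n_unshared, 198)
  expect_equal(round(pr$share_fraction, 3), 0.776)
  expect_equal(project_pairwise_pss(paste0("a:", 1:5),
                                    paste0("b:", 1:5))$share_fraction, 0)
  expect_equal(project_pairwise_pss(snp_keys, snp_keys)$share_fraction, 1)
})

test_that("the binned site table partitions sites and reproduces fixtures", {
  counts <- read_tsv(psgscan_example("chr1_fst_bin_counts.tsv"))
  fx <- bin_counts_to_sites(counts)
  bt <- build_fst_bin_table(fx$annotated, fx$pairwise_pss)
  expect_equal(round(bt$bins$probability[1:9], 3),
               c(0.027, 0.089, 0.141, 0.096, 0.230, 0.123, 0.132, 0.140, 0.240))
  expect_equal(sum(bt$bins$total), nrow(fx$annotated))  # partition
  # Fst = 1 lands in the closed top bin
  one <- data.frame(chrom = "c", pos = 1, effect = "nonsynonymous", fst = 1)
  bt1 <- build_fst_bin_table(one, character(0))
  expect_equal(bt1$bins$total[1], 1)
})

test_that("MAF summary counts sites strictly below threshold", {
  ann <- data.frame(maf_total = c(0.5, 0.5, 0.05))
  expect_equal(maf_summary(ann), 1 / 3)
  expect_equal(maf_summary(data.frame(maf_total = rep(0.5, 4))), 0)
  expect_equal(maf_summary(data.frame(maf_total = c(rep(0.05, 5),
                                                    rep(0.3, 3)))), 0.625)
  # low-differentiation simulated data is dominated by rare alleles when
  # ancestral frequencies skew low
  sim <- simulate_population_snps(pop_sim_config(
    n_loci = 2000, f_neutral = 0.05, p_anc_range = c(0.01, 0.2), seed = 8))
  maf <- pmin((sim$snps$alt1 + sim$snps$alt2) / (sim$snps$tot1 + sim$snps$tot2),
              1 - (sim$snps$alt1 + sim$snps$alt2) / (sim$snps$tot1 + sim$snps$tot2))
  expect_gt(mean(maf < 0.1), 0.5)
})

test_that("annotate_snps assigns genes and effects on simulated studies", {
  study <- simulate_snp_study(snp_study_config(
    n_genes = 12, n_snps = 150, n_sel_genes = 4, n_neutral_exonic = 24,
    n1 = 40, n2 = 40, seed = 9))
  ann <- annotate_snps(study$snps, study$models, study$genome)
  m <- match(ann$pos, study$truth$pos)
  intended <- study$truth$effect_intended[m]
  known <- intended %in% c("synonymous", "nonsynonymous")
  expect_identical(ann$effect[known], intended[known])
  # noncoding truth never annotates as exonic
  expect_true(all(ann$effect[intended == "noncoding"] == "noncoding"))
  expect_true(all(ann$fst >= 0 & ann$fst <= 1, na.rm = TRUE))
})
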