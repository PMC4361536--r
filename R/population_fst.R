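# SNP functional-effect annotation inside gene models, per-site
# two-population Fst, projection of pairwise positively selected sites
# (PSSs) onto a SNP table, and the Fst-binned site table with its
# synonymous-site probability and representation summaries.

# Map a 1-based genomic position into a gene model's CDS.
# Returns NULL when the position is not exonic; otherwise a list with the
# 0-based cds_offset (coding orientation), codon_index, and the offset of
# the base inside its codon.
locate_in_cds <- function(pos, gm) {
  pos0 <- pos - 1L
  ex <- gm$exons
  hit <- which(pos0 >= ex[, 1L] & pos0 < ex[, 2L])
  if (length(hit) == 0L) return(NULL)
  lens <- ex[, 2L] - ex[, 1L]
  fwd_off <- sum(lens[seq_len(hit - 1L)]) + (pos0 - ex[hit, 1L])
  total <- sum(lens)
  off <- if (gm$strand == "+") fwd_off else total - 1L - fwd_off
  list(cds_offset = off, codon_index = off %/% 3L, in_codon = off %% 3L)
}

#' Annotate the functional effect of a SNP within a gene model
#'
#' Exonic SNPs rebuild the affected codon with the alternate allele
#' (strand-aware) and compare translations: identical is synonymous, a
#' change to a stop codon is nonsense, any other amino-acid change is
#' nonsynonymous. SNPs in the two intronic bases flanking an exon boundary
#' are splice-altering; everything else is noncoding. The reference allele
#' must match the genome base (data-integrity check).
#'
#' @param snp list or one-row data frame with `chrom`, `pos` (1-based),
#'   `ref`, `alt`.
#' @param gm a `gene_model` on the SNP's chromosome.
#' @param genome named character vector of chromosome sequences.
#' @return list with `effect` (one of `synonymous`, `nonsynonymous`,
#'   `nonsense`, `splice_altering`, `noncoding`), and for exonic SNPs
#'   `cds_offset`, `codon_index`, `ref_aa`, `alt_aa`.
#' @export
annotate_snp_effect <- function(snp, gm, genome) {
  chr <- genome[[gm$chrom]]
  pos <- as.integer(snp$pos)
  genome_base <- toupper(substring(chr, pos, pos))
  if (genome_base != toupper(snp$ref))
    stop("reference allele mismatch at ", gm$chrom, ":", pos,
         " (genome ", genome_base, ", SNP ref ", snp$ref, ")")
  loc <- locate_in_cds(pos, gm)
  if (is.null(loc)) {
    # splice check: 2 intronic bases flanking internal exon boundaries
    if (nrow(gm$exons) >= 2L) {
      pos0 <- pos - 1L
      inner_ends <- gm$exons[-nrow(gm$exons), 2L]   # first intron base = end
      inner_starts <- gm$exons[-1L, 1L]             # intron ends at start - 1
      near <- any(pos0 >= inner_ends & pos0 < inner_ends + 2L) ||
        any(pos0 >= inner_starts - 2L & pos0 < inner_starts)
      if (near) return(list(effect = "splice_altering"))
    }
    return(list(effect = "noncoding"))
  }
  cds <- extract_cds(genome, gm)
  codon <- substring(cds, loc$codon_index * 3L + 1L, loc$codon_index * 3L + 3L)
  alt_base <- toupper(snp$alt)
  if (gm$strand == "-") alt_base <- revcomp(alt_base)
  alt_codon <- codon
  substr(alt_codon, loc$in_codon + 1L, loc$in_codon + 1L) <- alt_base
  ref_aa <- codon_aa(codon)
  alt_aa <- codon_aa(alt_codon)
  effect <- if (alt_aa == ref_aa) "synonymous"
    else if (alt_aa == "*") "nonsense"
    else "nonsynonymous"
  list(effect = effect, cds_offset = loc$cds_offset,
       codon_index = loc$codon_index, ref_aa = ref_aa, alt_aa = alt_aa)
}

#' Per-site two-population Fst
#'
#' Unweighted Nei/Wright estimator: with `pbar = (p1 + p2) / 2`,
#' `Ht = 2 pbar (1 - pbar)`, `Hs = (2 p1 (1 - p1) + 2 p2 (1 - p2)) / 2`,
#' `fst = (Ht - Hs) / Ht`; undefined (`NA`) when `Ht = 0`. A
#' Weir-Cockerham-style sample-size-corrected variant is available for
#' sensitivity analysis.
#'
#' @param p1,p2 alternate-allele frequencies in the two populations.
#' @param n1,n2 haplotype sample sizes (unused by the default estimator).
#' @param method `"nei"` (default) or `"wc"`.
#' @return Fst value(s) in `[0, 1]`, `NA` where undefined. Vectorized.
#' @export
fst_site <- function(p1, p2, n1 = NULL, n2 = NULL, method = c("nei", "wc")) {
  method <- match.arg(method)
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("allele frequencies outside [0, 1]")
  if (method == "nei") {
    pbar <- (p1 + p2) / 2
    ht <- 2 * pbar * (1 - pbar)
    hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
    ifelse(ht == 0, NA_real_, (ht - hs) / ht)
  } else {
    if (is.null(n1) || is.null(n2))
      stop("Weir-Cockerham estimator needs sample sizes")
    # two-population haploid Weir & Cockerham (1984) theta
    nbar <- (n1 + n2) / 2
    r <- 2
    nc <- (n1 + n2 - (n1^2 + n2^2) / (n1 + n2)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- 0   # haploid: no heterozygotes
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2)
    tot <- a + b
    ifelse(tot == 0, NA_real_, pmax(0, pmin(1, a / tot)))
  }
}

#' Annotate a SNP table against gene models
#'
#' Assigns each SNP to the gene model containing it (first containing gene
#' wins; models are assumed non-overlapping), computes its effect, the two
#' population frequencies, Fst, and the pooled minor-allele frequency.
#'
#' @param snps a `snp_table` (see [read_snp_table()]).
#' @param models list of `gene_model`s.
#' @param genome named character vector of chromosomes.
#' @return data frame: SNP columns plus `gene_id`, `effect`, `cds_offset`,
#'   `ref_aa`, `alt_aa`, `p1`, `p2`, `fst`, `maf_total`.
#' @export
annotate_snps <- function(snps, models, genome) {
  n <- nrow(snps)
  gene_id <- rep(NA_character_, n)
  effect <- rep("noncoding", n)
  cds_offset <- rep(NA_integer_, n)
  ref_aa <- rep(NA_character_, n); alt_aa <- rep(NA_character_, n)
  # interval lookup over gene spans
  spans <- data.frame(
    gene = names(models),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    start0 = vapply(models, function(m) m$exons[1L, 1L], numeric(1)),
    end0 = vapply(models, function(m) m$exons[nrow(m$exons), 2L], numeric(1)),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pos0 <- snps$pos[i] - 1L
    cand <- spans$gene[spans$chrom == snps$chrom[i] &
                         spans$start0 <= pos0 & pos0 < spans$end0]
    if (length(cand) == 0L) next
    gm <- models[[cand[1L]]]
    ann <- annotate_snp_effect(snps[i, ], gm, genome)
    gene_id[i] <- gm$gene_id
    effect[i] <- ann$effect
    if (!is.null(ann$cds_offset)) {
      cds_offset[i] <- ann$cds_offset
      ref_aa[i] <- ann$ref_aa; alt_aa[i] <- ann$alt_aa
    }
  }
  p1 <- snps$alt1 / snps$tot1
  p2 <- snps$alt2 / snps$tot2
  p_pool <- (snps$alt1 + snps$alt2) / (snps$tot1 + snps$tot2)
  out <- data.frame(snps, gene_id = gene_id, effect = effect,
                    cds_offset = cds_offset, ref_aa = ref_aa, alt_aa = alt_aa,
                    p1 = p1, p2 = p2, fst = fst_site(p1, p2),
                    maf_total = pmin(p_pool, 1 - p_pool),
                    stringsAsFactors = FALSE)
  attr(out, "pop_names") <- attr(snps, "pop_names")
  out
}

#' Project pairwise positively selected sites onto a SNP set
#'
#' @param pairwise_sites character keys (`chrom:pos`) of the PSSs found in
#'   the two-genome comparison.
#' @param snp_sites character keys of the sites present in the SNP data.
#' @return list with `n_shared`, `n_unshared`, `share_fraction`.
#' @export
project_pairwise_pss <- function(pairwise_sites, snp_sites) {
  pairwise_sites <- unique(pairwise_sites)
  n_shared <- sum(pairwise_sites %in% snp_sites)
  n_unshared <- length(pairwise_sites) - n_shared
  list(n_shared = n_shared, n_unshared = n_unshared,
       share_fraction = if (length(pairwise_sites) == 0L) NA_real_
       else n_shared / (n_shared + n_unshared))
}

# Fst bin edges of the binned site table, highest first. The top bin is
# closed [0.95, 1]; all others are half-open [lo, hi).
FST_BIN_EDGES <- data.frame(
  lo = c(0.95, 0.90, 0.80, 0.70, 0.60, 0.50, 0.40, 0.30, 0.25, 0.00),
  hi = c(1.00, 0.95, 0.90, 0.80, 0.70, 0.60, 0.50, 0.40, 0.30, 0.25),
  label = c(">=0.95-1", "0.9-0.95", "0.8-0.9", "0.7-0.8", "0.6-0.7",
            "0.5-0.6", "0.4-0.5", "0.3-0.4", "0.25-0.3", "<0.25"),
  stringsAsFactors = FALSE)

fst_bin_index <- function(fst) {
  idx <- rep(NA_integer_, length(fst))
  for (b in seq_len(nrow(FST_BIN_EDGES))) {
    lo <- FST_BIN_EDGES$lo[b]; hi <- FST_BIN_EDGES$hi[b]
    inb <- if (b == 1L) fst >= lo & fst <= hi else fst >= lo & fst < hi
    idx[is.na(idx) & !is.na(fst) & inb] <- b
  }
  idx
}

#' Fst-binned table of shared and new sites
#'
#' Bins exonic SNPs (in candidate genes) by Fst, splitting each bin into
#' sites shared with the pairwise PSS set and new nonsynonymous/synonymous
#' sites. The per-bin probability is the fraction of new synonymous sites;
#' `overall_probability` and `representation` (fraction shared) aggregate
#' the bins at Fst >= 0.25.
#'
#' @param annotated data frame from [annotate_snps()] (already restricted
#'   to the genes of interest); only exonic effects with defined Fst are
#'   binned.
#' @param pairwise_pss character keys (`chrom:pos`) of pairwise PSSs.
#' @return list of class `fst_bin_table`: `bins` data frame (`label`,
#'   `n_shared`, `n_new_nonsyn`, `n_new_syn`, `total`, `probability`),
#'   `overall_probability`, `representation`.
#' @export
build_fst_bin_table <- function(annotated, pairwise_pss) {
  exonic <- annotated[annotated$effect %in%
                        c("synonymous", "nonsynonymous", "nonsense") &
                        !is.na(annotated$fst), , drop = FALSE]
  key <- paste0(exonic$chrom, ":", exonic$pos)
  shared <- key %in% pairwise_pss
  syn <- exonic$effect == "synonymous"
  bin <- fst_bin_index(exonic$fst)
  nb <- nrow(FST_BIN_EDGES)
  tab <- data.frame(
    label = FST_BIN_EDGES$label,
    n_shared = vapply(seq_len(nb), function(b) sum(bin == b & shared), numeric(1)),
    n_new_nonsyn = vapply(seq_len(nb),
                          function(b) sum(bin == b & !shared & !syn), numeric(1)),
    n_new_syn = vapply(seq_len(nb),
                       function(b) sum(bin == b & !shared & syn), numeric(1)),
    stringsAsFactors = FALSE)
  tab$total <- tab$n_shared + tab$n_new_nonsyn + tab$n_new_syn
  tab$probability <- ifelse(tab$total > 0, tab$n_new_syn / tab$total, NA_real_)
  high <- seq_len(nb - 1L)   # all bins at Fst >= 0.25
  tot_high <- sum(tab$total[high])
  structure(list(
    bins = tab,
    overall_probability = if (tot_high > 0) sum(tab$n_new_syn[high]) / tot_high
      else NA_real_,
    representation = if (tot_high > 0) sum(tab$n_shared[high]) / tot_high
      else NA_real_),
    class = "fst_bin_table")
}

#' Fraction of SNPs with pooled minor-allele frequency below a threshold
#'
#' @param annotated data frame with a `maf_total` column.
#' @param threshold MAF threshold (default 0.1); the fraction is of sites
#'   strictly below it.
#' @return fraction in `[0, 1]`.
#' @export
maf_summary <- function(annotated, threshold = 0.1) {
  mean(annotated$maf_total < threshold)
}
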