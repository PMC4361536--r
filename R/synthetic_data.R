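# Synthetic-data generators: diverged ortholog pairs with known
# synonymous/nonsynonymous substitution counts, and two-population SNP data
# under a Balding-Nichols island model with a known set of selected loci.
# These supply every input the downstream stages need, with ground truth.

#' Simulate a coding sequence
#'
#' Starts with ATG, ends with a random stop codon, no internal stops.
#'
#' @param length_codons total codon count including start and stop (>= 2).
#' @param seed integer seed.
#' @return nucleotide string of length `3 * length_codons`.
#' @export
simulate_cds <- function(length_codons, seed) {
  stopifnot(length_codons >= 2L)
  with_seed(seed, {
    middle <- if (length_codons > 2L)
      sample(NONSTOP_CODONS, length_codons - 2L, replace = TRUE) else character(0)
    paste(c("ATG", middle, sample(STOP_CODONS, 1L)), collapse = "")
  })
}

# single-base mutants of a codon, annotated syn/nonsyn, never creating a stop
codon_mutants <- function(codon) {
  aa <- codon_aa(codon)
  out <- list()
  for (pos in 1:3) for (b in setdiff(BASES, substr(codon, pos, pos))) {
    mut <- codon
    substr(mut, pos, pos) <- b
    if (mut %in% STOP_CODONS) next
    out[[length(out) + 1L]] <- list(
      pos = pos, base = b, codon = mut,
      effect = if (codon_aa(mut) == aa) "synonymous" else "nonsynonymous")
  }
  out
}

#' Inject substitutions with known effects into a CDS
#'
#' Applies exactly `n_nonsyn` amino-acid-changing and `n_syn` silent
#' single-base substitutions. The start and stop codons are never touched
#' and no substitution creates or destroys a stop codon. By default each
#' substitution lands in a distinct codon, so NG86 pathway averaging
#' recovers the injected counts exactly; `distinct_codons = FALSE` allows
#' same-codon double hits for stress testing.
#'
#' @param cds coding sequence produced by [simulate_cds()] (or any CDS with
#'   start/stop and no internal stop).
#' @param n_nonsyn,n_syn substitution counts to inject.
#' @param seed integer seed.
#' @param distinct_codons place each substitution in its own codon.
#' @return list with `cds` (mutated sequence) and `site_log` (data frame:
#'   `pos` 0-based nucleotide position, `codon_index` 0-based, `old`,
#'   `new`, `effect`).
#' @export
inject_substitutions <- function(cds, n_nonsyn, n_syn, seed,
                                 distinct_codons = TRUE) {
  codons <- split_codons(cds)
  mutable <- seq(2L, length(codons) - 1L)   # spare start and stop codons
  if (distinct_codons && n_nonsyn + n_syn > length(mutable))
    stop("sequence too short for requested substitutions")
  with_seed(seed, {
    log <- data.frame(pos = integer(), codon_index = integer(),
                      old = character(), new = character(),
                      effect = character(), stringsAsFactors = FALSE)
    wanted <- c(rep("nonsynonymous", n_nonsyn), rep("synonymous", n_syn))
    if (length(wanted) == 0L) return(list(cds = cds, site_log = log))
    wanted <- sample(wanted)     # interleave the two kinds randomly
    used <- integer(0)
    for (eff in wanted) {
      cand <- if (distinct_codons) setdiff(mutable, used) else mutable
      cand <- sample(cand)
      placed <- FALSE
      for (ci in cand) {
        muts <- Filter(function(m) m$effect == eff, codon_mutants(codons[ci]))
        if (length(muts) == 0L) next
        m <- muts[[sample.int(length(muts), 1L)]]
        old_base <- substr(codons[ci], m$pos, m$pos)
        codons[ci] <- m$codon
        used <- c(used, ci)
        log <- rbind(log, data.frame(
          pos = (ci - 1L) * 3L + m$pos - 1L, codon_index = ci - 1L,
          old = old_base, new = m$base, effect = eff,
          stringsAsFactors = FALSE))
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place a ", eff,
                        " substitution; sequence too short or constrained")
    }
    list(cds = paste(codons, collapse = ""), site_log = log)
  })
}

#' Configuration for the ortholog-divergence simulator
#'
#' Defaults emulate the empirical regime of a close subspecies pair: a
#' large fraction of identical orthologs, a minority of genes carrying one
#' or two nonsynonymous substitutions and no synonymous one (NSSGs), and a
#' background of genes with a few substitutions of both kinds.
#'
#' @param n_genes number of ortholog pairs.
#' @param cds_length_range codon-count range (including start/stop).
#' @param fraction_identical genes with no substitutions at all.
#' @param fraction_nssg genes forced to `n_syn = 0`, `n_nonsyn` in
#'   `nssg_nonsyn_range`.
#' @param nssg_nonsyn_range nonsynonymous count range for NSSGs (the modal
#'   empirical regime is one or two).
#' @param background_range substitution-count range (each kind) for the
#'   remaining genes.
#' @param n_exons_range exon count per gene.
#' @param seed integer seed.
#' @return config list of class `divergence_sim_config`.
#' @export
divergence_sim_config <- function(n_genes = 50L,
                                  cds_length_range = c(100L, 300L),
                                  fraction_identical = 0.3,
                                  fraction_nssg = 0.1,
                                  nssg_nonsyn_range = c(1L, 2L),
                                  background_range = c(0L, 3L),
                                  n_exons_range = c(1L, 3L),
                                  seed = 1L) {
  stopifnot(n_genes >= 1L, cds_length_range[1L] >= 10L,
            fraction_identical + fraction_nssg <= 1,
            all(background_range >= 0L))
  structure(as.list(environment()), class = "divergence_sim_config")
}

#' Simulate a pair of diverged annotated genomes
#'
#' Builds genome A, derives genome B by injecting known substitution
#' counts per gene, lays the genes out on one chromosome per genome with a
#' gene-model annotation (split into exons with short introns), and emits a
#' perfect reciprocal similarity hit table plus weaker decoy hits. The
#' ortholog truth is the identity pairing gA_i <-> gB_i.
#'
#' @param cfg a `divergence_sim_config`.
#' @return list with `genome_a`, `genome_b` (named character vectors),
#'   `models_a`, `models_b` (gene-model lists), `proteins_a`, `proteins_b`,
#'   `cds_a`, `cds_b`, `hits_ab`, `hits_ba`, and `truth` (per gene:
#'   `gene_a`, `gene_b`, `class`, `n_nonsyn`, `n_syn`).
#' @export
simulate_genome_pair <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    lens <- sample(seq(cfg$cds_length_range[1L], cfg$cds_length_range[2L]),
                   n, replace = TRUE)
    n_ident <- round(cfg$fraction_identical * n)
    n_nssg <- round(cfg$fraction_nssg * n)
    classes <- sample(c(rep("identical", n_ident), rep("NSSG", n_nssg),
                        rep("background", n - n_ident - n_nssg)))
    gene_seeds <- sample.int(2^31 - 2, 3L * n)
    cds_a <- character(n); cds_b <- character(n)
    n_nonsyn <- integer(n); n_syn <- integer(n)
    for (i in seq_len(n)) {
      cds_a[i] <- simulate_cds(lens[i], gene_seeds[i])
      counts <- switch(classes[i],
        identical = c(0L, 0L),
        NSSG = c(sample(seq(cfg$nssg_nonsyn_range[1L],
                            cfg$nssg_nonsyn_range[2L]), 1L), 0L),
        background = c(sample(seq(cfg$background_range[1L],
                                  cfg$background_range[2L]), 1L),
                       sample(seq(max(1L, cfg$background_range[1L]),
                                  cfg$background_range[2L]), 1L)))
      n_nonsyn[i] <- counts[1L]; n_syn[i] <- counts[2L]
      mut <- inject_substitutions(cds_a[i], counts[1L], counts[2L],
                                  gene_seeds[n + i])
      cds_b[i] <- mut$cds
    }
    ids_a <- sprintf("gA%03d", seq_len(n))
    ids_b <- sprintf("gB%03d", seq_len(n))
    lay_a <- layout_genes(cds_a, ids_a, "chrA", cfg$n_exons_range,
                          gene_seeds[2L * n + 1L])
    lay_b <- layout_genes(cds_b, ids_b, "chrB", cfg$n_exons_range,
                          gene_seeds[2L * n + 2L])
    prot_a <- vapply(cds_a, function(x) sub("\\*$", "", translate_cds(x)), character(1))
    prot_b <- vapply(cds_b, function(x) sub("\\*$", "", translate_cds(x)), character(1))
    names(prot_a) <- ids_a; names(prot_b) <- ids_b
    names(cds_a) <- ids_a; names(cds_b) <- ids_b
    hits <- make_hit_tables(ids_a, ids_b, nchar(prot_a))
    truth <- data.frame(gene_a = ids_a, gene_b = ids_b, class = classes,
                        n_nonsyn = n_nonsyn, n_syn = n_syn,
                        stringsAsFactors = FALSE)
    list(genome_a = lay_a$genome, genome_b = lay_b$genome,
         models_a = lay_a$models, models_b = lay_b$models,
         proteins_a = prot_a, proteins_b = prot_b,
         cds_a = cds_a, cds_b = cds_b,
         hits_ab = hits$ab, hits_ba = hits$ba, truth = truth)
  })
}

# Place CDSs on a single chromosome, splitting each into 1..k exons with
# 50 bp introns and 100 bp intergenic spacers; strands alternate. Exon
# intervals are recorded 0-based half-open in genomic order; minus-strand
# genes store the reverse complement of the CDS on the chromosome.
layout_genes <- function(cds_list, ids, chrom, n_exons_range, seed) {
  with_seed(seed, {
    spacer <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")
    models <- list()
    pieces_by_gene <- list()
    cursor <- 0L
    exon_plan <- list()
    for (i in seq_along(cds_list)) {
      cursor <- cursor + 100L                     # intergenic spacer
      cds <- cds_list[[i]]
      strand <- if (i %% 2L == 0L) "-" else "+"
      genomic <- if (strand == "-") revcomp(cds) else cds
      n_ex <- sample(seq(n_exons_range[1L], n_exons_range[2L]), 1L)
      n_ex <- max(1L, min(n_ex, nchar(cds) %/% 30L))
      cuts <- if (n_ex > 1L)
        sort(sample(seq(3L, nchar(cds) - 3L, by = 3L), n_ex - 1L)) else integer(0)
      glen <- diff(c(0L, cuts, nchar(cds)))       # exon lengths, genomic order
      ex <- matrix(0L, nrow = n_ex, ncol = 2L,
                   dimnames = list(NULL, c("start", "end")))
      for (k in seq_len(n_ex)) {
        if (k > 1L) cursor <- cursor + 50L        # intron
        ex[k, ] <- c(cursor, cursor + glen[k])
        cursor <- cursor + glen[k]
      }
      stops <- cumsum(glen)
      pieces_by_gene[[ids[i]]] <- substring(genomic, stops - glen + 1L, stops)
      models[[ids[i]]] <- gene_model(ids[i], chrom, strand, ex)
    }
    total <- cursor + 100L
    chrseq <- strsplit(spacer(total), "")[[1L]]   # random background
    for (id in names(models)) {
      gm <- models[[id]]
      pieces <- pieces_by_gene[[id]]
      for (k in seq_len(nrow(gm$exons))) {
        idx <- (gm$exons[k, 1L] + 1L):gm$exons[k, 2L]
        chrseq[idx] <- strsplit(pieces[k], "")[[1L]]
      }
    }
    genome <- stats::setNames(paste(chrseq, collapse = ""), chrom)
    list(genome = genome, models = models)
  })
}

# Perfect reciprocal hit tables plus weaker decoy hits.
make_hit_tables <- function(ids_a, ids_b, lens) {
  n <- length(ids_a)
  mk <- function(q, s, len, bit, ev) {
    data.frame(query_id = q, subject_id = s, percent_id = 99.0,
               align_len = len, mismatch = 1L, gap_open = 0L,
               q_start = 1L, q_end = len, s_start = 1L, s_end = len,
               evalue = ev, bitscore = bit, stringsAsFactors = FALSE)
  }
  true_ab <- mk(ids_a, ids_b, lens, 2 * lens, 1e-50)
  true_ba <- mk(ids_b, ids_a, lens, 2 * lens, 1e-50)
  decoy_ab <- mk(ids_a, ids_b[c(seq(2L, n), 1L)], lens %/% 2L, lens, 1e-5)
  decoy_ba <- mk(ids_b, ids_a[c(seq(2L, n), 1L)], lens %/% 2L, lens, 1e-5)
  list(ab = rbind(true_ab, decoy_ab), ba = rbind(true_ba, decoy_ba))
}

#' Configuration for the two-population SNP simulator
#'
#' Allele frequencies follow the Balding-Nichols island model: each locus
#' draws an ancestral frequency p uniformly from `p_anc_range`, each
#' population then draws its frequency from
#' `Beta(p (1 - F) / F, (1 - p)(1 - F) / F)`, and haplotype counts are
#' binomial. Selected loci use `f_selected` in place of `f_neutral`.
#' Default sample sizes mirror a large two-subspecies resequencing panel
#' (520 and 409 haploid accessions).
#'
#' @param n_loci total loci.
#' @param n_sel_loci loci simulated at `f_selected`.
#' @param n1,n2 haplotype sample sizes (>= 2).
#' @param f_neutral neutral differentiation parameter in (0, 1).
#' @param f_selected differentiation at selected loci, `> f_neutral`, <= 1.
#' @param p_anc_range ancestral-frequency range.
#' @param seed integer seed.
#' @return config list of class `pop_sim_config`.
#' @export
pop_sim_config <- function(n_loci = 2000L, n_sel_loci = 0L, n1 = 520L,
                           n2 = 409L, f_neutral = 0.1, f_selected = 0.95,
                           p_anc_range = c(0.05, 0.95), seed = 1L) {
  stopifnot(n_loci >= 1L, n_sel_loci >= 0L, n_sel_loci <= n_loci,
            n1 >= 2L, n2 >= 2L, f_neutral > 0, f_neutral < 1,
            f_selected > f_neutral, f_selected <= 1)
  structure(as.list(environment()), class = "pop_sim_config")
}

# Balding-Nichols population frequency draw (F = 1 fixes one allele).
rbn_freq <- function(n, p, f) {
  if (f >= 1 - 1e-12) return(as.numeric(stats::runif(n) < p))
  stats::rbeta(n, p * (1 - f) / f, (1 - p) * (1 - f) / f)
}

#' Simulate two-population biallelic SNP frequencies
#'
#' @param cfg a `pop_sim_config`.
#' @return list with `snps` (a `snp_table`-style data frame: `chrom`, `pos`,
#'   `ref`, `alt`, `alt1`, `tot1`, `alt2`, `tot2`) and `truth` (per locus:
#'   `pos`, `class` in neutral/selected, `F`, `p_anc`).
#' @export
simulate_population_snps <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_loci
    class <- c(rep("selected", cfg$n_sel_loci),
               rep("neutral", n - cfg$n_sel_loci))
    class <- sample(class)
    f <- ifelse(class == "selected", cfg$f_selected, cfg$f_neutral)
    p_anc <- stats::runif(n, cfg$p_anc_range[1L], cfg$p_anc_range[2L])
    p1 <- numeric(n); p2 <- numeric(n)
    for (lev in unique(f)) {
      i <- which(f == lev)
      p1[i] <- rbn_freq(length(i), p_anc[i], lev)
      p2[i] <- rbn_freq(length(i), p_anc[i], lev)
    }
    alt1 <- stats::rbinom(n, cfg$n1, p1)
    alt2 <- stats::rbinom(n, cfg$n2, p2)
    snps <- data.frame(chrom = "sim", pos = seq_len(n), ref = "A", alt = "G",
                       alt1 = alt1, tot1 = cfg$n1, alt2 = alt2,
                       tot2 = cfg$n2, stringsAsFactors = FALSE)
    attr(snps, "pop_names") <- c("pop1", "pop2")
    truth <- data.frame(pos = seq_len(n), class = class, F = f,
                        p_anc = p_anc, stringsAsFactors = FALSE)
    list(snps = snps, truth = truth)
  })
}

#' Configuration for the gene-anchored SNP study simulator
#'
#' Emulates the empirical situation the SNP stages address: a reference
#' genome with annotated genes, a minority of "selected" genes carrying
#' nonsynonymous SNPs near fixation between the two populations, a thin
#' scatter of neutral exonic SNPs, and a noncoding background. Roughly half
#' the genes are selected by default, matching the high positive rate seen
#' among candidate genes in subspecies comparisons.
#'
#' @param n_genes genes on the simulated chromosome.
#' @param n_snps total SNPs.
#' @param n_sel_genes genes under selection (default half).
#' @param sel_loci_per_gene selected nonsynonymous SNPs per selected gene.
#' @param n_neutral_exonic neutral SNPs placed in exons (default 2 per gene);
#'   the remainder of `n_snps` is noncoding.
#' @param f_neutral,f_selected Balding-Nichols differentiation parameters.
#' @param n1,n2 haplotype sample sizes.
#' @param missing_rate per-call missing-genotype rate.
#' @param cds_length_range,n_exons_range passed to the genome layout.
#' @param seed integer seed.
#' @return config list of class `snp_study_config`.
#' @export
snp_study_config <- function(n_genes = 50L, n_snps = 2000L,
                             n_sel_genes = round(n_genes / 2),
                             sel_loci_per_gene = 2L,
                             n_neutral_exonic = 2L * n_genes,
                             f_neutral = 0.1, f_selected = 0.95,
                             n1 = 520L, n2 = 409L, missing_rate = 0.02,
                             cds_length_range = c(100L, 200L),
                             n_exons_range = c(1L, 3L), seed = 1L) {
  stopifnot(n_sel_genes <= n_genes,
            n_sel_genes * sel_loci_per_gene + n_neutral_exonic <= n_snps)
  structure(as.list(environment()), class = "snp_study_config")
}

#' Simulate a gene-anchored two-population SNP study
#'
#' Builds an annotated single-chromosome genome, chooses selected genes,
#' injects selected nonsynonymous SNPs (Balding-Nichols frequencies at
#' `f_selected`), neutral exonic SNPs and noncoding SNPs (at `f_neutral`),
#' and samples per-haplotype genotypes for both populations.
#'
#' @param cfg a `snp_study_config`.
#' @return list with `genome`, `models`, `genotypes` (haplotypes x loci 0/1
#'   matrix with NA missing), `snps` (count table as in
#'   [read_snp_table()]), `pop_assignments`, and `truth` (per SNP: `pos`,
#'   `class`, `gene_id`, `effect_intended`, `F`).
#' @export
simulate_snp_study <- function(cfg) {
  with_seed(cfg$seed, {
    lens <- sample(seq(cfg$cds_length_range[1L], cfg$cds_length_range[2L]),
                   cfg$n_genes, replace = TRUE)
    cds <- vapply(seq_len(cfg$n_genes),
                  function(i) simulate_cds(lens[i], sample.int(2^31 - 2, 1L)),
                  character(1))
    ids <- sprintf("g%03d", seq_len(cfg$n_genes))
    lay <- layout_genes(cds, ids, "chr1", cfg$n_exons_range,
                        sample.int(2^31 - 2, 1L))
    genome <- lay$genome; models <- lay$models
    sel_genes <- sample(ids, cfg$n_sel_genes)
    chrlen <- nchar(genome[[1L]])

    exon_sites <- function(gm) {
      idx <- unlist(lapply(seq_len(nrow(gm$exons)),
                           function(k) (gm$exons[k, 1L] + 1L):gm$exons[k, 2L]))
      idx
    }
    all_exonic <- lapply(models, exon_sites)
    exon_any <- sort(unique(unlist(all_exonic)))
    # 2 intronic bases flanking internal exon boundaries: exclude from the
    # noncoding pool so splice effects stay out of the simulated truth
    splice <- unlist(lapply(models, function(gm) {
      if (nrow(gm$exons) < 2L) return(integer(0))
      inner_ends <- gm$exons[-nrow(gm$exons), 2L]
      inner_starts <- gm$exons[-1L, 1L]
      c(inner_ends + 1L, inner_ends + 2L, inner_starts, inner_starts - 1L)
    }))
    noncoding_pool <- setdiff(seq_len(chrlen), c(exon_any, splice, splice + 1L))

    pick_exonic_snp <- function(gene, effect = NULL) {
      gm <- models[[gene]]
      sites <- all_exonic[[gene]]
      for (try in seq_len(200L)) {
        pos <- sample(sites, 1L)
        ref <- substring(genome[[1L]], pos, pos)
        info <- snp_effect_at(pos, gm, genome)
        if (is.null(info)) next
        alts <- setdiff(BASES, ref)
        effs <- vapply(alts, function(a)
          annotate_snp_effect(list(chrom = gm$chrom, pos = pos, ref = ref,
                                   alt = a), gm, genome)$effect, character(1))
        ok <- if (is.null(effect)) effs != "nonsense" else effs == effect
        if (!any(ok)) next
        alt <- alts[ok][sample.int(sum(ok), 1L)]
        return(list(pos = pos, ref = ref, alt = alt,
                    effect = effs[[which(alts == alt)]], gene = gene))
      }
      stop("could not place an exonic SNP in gene ", gene)
    }

    snp_rows <- list()
    for (g in sel_genes) {
      for (k in seq_len(cfg$sel_loci_per_gene)) {
        s <- pick_exonic_snp(g, effect = "nonsynonymous")
        snp_rows[[length(snp_rows) + 1L]] <-
          c(s, list(class = "selected", F = cfg$f_selected))
      }
    }
    for (k in seq_len(cfg$n_neutral_exonic)) {
      g <- sample(ids, 1L)
      s <- pick_exonic_snp(g, effect = NULL)
      snp_rows[[length(snp_rows) + 1L]] <-
        c(s, list(class = "neutral", F = cfg$f_neutral))
    }
    n_noncoding <- cfg$n_snps - length(snp_rows)
    nc_pos <- sample(noncoding_pool, n_noncoding)
    for (pos in nc_pos) {
      ref <- substring(genome[[1L]], pos, pos)
      alt <- sample(setdiff(BASES, ref), 1L)
      snp_rows[[length(snp_rows) + 1L]] <-
        list(pos = pos, ref = ref, alt = alt, effect = "noncoding",
             gene = NA_character_, class = "neutral", F = cfg$f_neutral)
    }
    pos <- vapply(snp_rows, `[[`, numeric(1), "pos")
    o <- order(pos)
    snp_rows <- snp_rows[o]
    dup <- duplicated(vapply(snp_rows, `[[`, numeric(1), "pos"))
    snp_rows <- snp_rows[!dup]
    n <- length(snp_rows)
    p_anc <- stats::runif(n, 0.05, 0.95)
    fvec <- vapply(snp_rows, `[[`, numeric(1), "F")
    p1 <- numeric(n); p2 <- numeric(n)
    for (lev in unique(fvec)) {
      i <- which(fvec == lev)
      p1[i] <- rbn_freq(length(i), p_anc[i], lev)
      p2[i] <- rbn_freq(length(i), p_anc[i], lev)
    }
    g1 <- matrix(stats::rbinom(n * cfg$n1, 1L, rep(p1, each = cfg$n1)),
                 nrow = cfg$n1)
    g2 <- matrix(stats::rbinom(n * cfg$n2, 1L, rep(p2, each = cfg$n2)),
                 nrow = cfg$n2)
    geno <- rbind(g1, g2)
    # SNP ascertainment: a site monomorphic in the sampled panel would not
    # be in a SNP table at all, so redraw its frequencies until it segregates
    for (tries in seq_len(50L)) {
      ac <- colSums(geno)
      mono <- which(ac == 0L | ac == nrow(geno))
      if (length(mono) == 0L) break
      q1 <- numeric(length(mono)); q2 <- numeric(length(mono))
      for (lev in unique(fvec[mono])) {
        i <- which(fvec[mono] == lev)
        q1[i] <- rbn_freq(length(i), p_anc[mono][i], lev)
        q2[i] <- rbn_freq(length(i), p_anc[mono][i], lev)
      }
      p1[mono] <- q1; p2[mono] <- q2
      geno[seq_len(cfg$n1), mono] <-
        stats::rbinom(length(mono) * cfg$n1, 1L, rep(q1, each = cfg$n1))
      geno[cfg$n1 + seq_len(cfg$n2), mono] <-
        stats::rbinom(length(mono) * cfg$n2, 1L, rep(q2, each = cfg$n2))
    }
    if (cfg$missing_rate > 0)
      geno[stats::runif(length(geno)) < cfg$missing_rate] <- NA
    rownames(geno) <- c(sprintf("ind_%03d", seq_len(cfg$n1)),
                        sprintf("tej_%03d", seq_len(cfg$n2)))
    colnames(geno) <- paste0("chr1:", vapply(snp_rows, `[[`, numeric(1), "pos"))
    pop <- stats::setNames(rep(c("indica", "temperate_japonica"),
                               c(cfg$n1, cfg$n2)), rownames(geno))
    count_pop <- function(rows) {
      sub <- geno[rows, , drop = FALSE]
      list(alt = colSums(sub == 1L, na.rm = TRUE),
           tot = colSums(!is.na(sub)))
    }
    c1 <- count_pop(seq_len(cfg$n1))
    c2 <- count_pop(cfg$n1 + seq_len(cfg$n2))
    snps <- data.frame(
      chrom = "chr1", pos = vapply(snp_rows, `[[`, numeric(1), "pos"),
      ref = vapply(snp_rows, `[[`, character(1), "ref"),
      alt = vapply(snp_rows, `[[`, character(1), "alt"),
      alt1 = c1$alt, tot1 = c1$tot, alt2 = c2$alt, tot2 = c2$tot,
      stringsAsFactors = FALSE)
    attr(snps, "pop_names") <- c("indica", "temperate_japonica")
    truth <- data.frame(
      pos = snps$pos,
      class = vapply(snp_rows, `[[`, character(1), "class"),
      gene_id = vapply(snp_rows, `[[`, character(1), "gene"),
      effect_intended = vapply(snp_rows, `[[`, character(1), "effect"),
      F = vapply(snp_rows, `[[`, numeric(1), "F"),
      stringsAsFactors = FALSE)
    list(genome = genome, models = models, genotypes = geno, snps = snps,
         pop_assignments = pop, truth = truth,
         selected_genes = sort(sel_genes))
  })
}

# quick validity probe used by the study simulator (NULL if the reference
# codon cannot be rebuilt, e.g. ambiguous placement)
snp_effect_at <- function(pos, gm, genome) {
  tryCatch(locate_in_cds(pos, gm), error = function(e) NULL)
}
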