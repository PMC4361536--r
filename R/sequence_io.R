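# Readers and writers for the standard formats the pipeline touches, and the
# gene-model data type. Internal coordinates are 0-based half-open; file I/O
# uses each format's native convention (GFF3 and SNP tables are 1-based).

#' Construct a gene model
#'
#' A gene model is a coding gene reduced to what CDS extraction needs: an
#' identifier, a chromosome, a strand and the ordered CDS exon intervals.
#' Intervals are 0-based half-open and stored in genomic order regardless of
#' strand; the reading frame always starts at the first CDS base.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column integer matrix (`start`, `end`), 0-based half-open.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  gm <- structure(
    list(gene_id = as.character(gene_id), chrom = as.character(chrom),
         strand = strand, exons = exons),
    class = "gene_model")
  problems <- validate_gene_model(gm)
  if (length(problems))
    stop("invalid gene model '", gene_id, "': ",
         paste(problems, collapse = "; "))
  gm
}

#' Validate a gene model
#'
#' @param gm a `gene_model`.
#' @return character vector of problems (empty when valid).
#' @export
validate_gene_model <- function(gm) {
  problems <- character()
  ex <- gm$exons
  if (!gm$strand %in% c("+", "-")) problems <- c(problems, "bad strand")
  if (nrow(ex) == 0L) return(c(problems, "no exons"))
  if (any(ex[, 2L] <= ex[, 1L])) problems <- c(problems, "empty exon interval")
  if (is.unsorted(ex[, 1L], strictly = FALSE))
    problems <- c(problems, "exons not sorted by start")
  if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L]))
    problems <- c(problems, "overlapping exons")
  len <- sum(ex[, 2L] - ex[, 1L])
  if (len <= 0L || len %% 3L != 0L)
    problems <- c(problems, sprintf("CDS length %d not a positive multiple of 3", len))
  problems
}

#' Total CDS length of a gene model
#' @param gm a `gene_model`.
#' @return integer length in nucleotides.
#' @export
cds_length <- function(gm) sum(gm$exons[, 2L] - gm$exons[, 1L])

#' Read a FASTA file into a named character vector
#'
#' Identifiers are the first whitespace-delimited token of each header and
#' must be unique; empty sequences are an error.
#'
#' @param path FASTA file (nucleotide or protein).
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate identifier in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  names(seqs) <- ids
  if (any(nchar(seqs) == 0L))
    stop("empty sequence in FASTA: ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only `CDS` features are used, grouped by their `Parent` attribute (one
#' gene model per parent). Models violating the gene-model invariants
#' (overlapping exons, CDS length not a multiple of 3) are excluded with a
#' warning rather than used silently, mirroring the removal of annotation
#' mistakes from real gene sets.
#'
#' @param path GFF3 file.
#' @return named list of `gene_model` objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) return(list())
  parents <- vapply(gr$Parent, function(p) as.character(p)[1L], character(1))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  start0 <- GenomicRanges::start(gr) - 1L   # 1-based inclusive -> 0-based half-open
  end0 <- GenomicRanges::end(gr)
  models <- list()
  dropped <- character()
  for (p in unique(parents)) {
    i <- which(parents == p)
    o <- order(start0[i])
    i <- i[o]
    ex <- cbind(start0[i], end0[i])
    gm <- structure(
      list(gene_id = p, chrom = chrom[i[1L]], strand = strand[i[1L]],
           exons = matrix(as.integer(ex), ncol = 2L,
                          dimnames = list(NULL, c("start", "end")))),
      class = "gene_model")
    if (length(validate_gene_model(gm)) == 0L) models[[p]] <- gm
    else dropped <- c(dropped, p)
  }
  if (length(dropped))
    warning("excluded ", length(dropped), " invalid gene model(s): ",
            paste(dropped, collapse = ", "))
  models
}

#' Write gene models as GFF3
#'
#' Emits one `CDS` row per exon with a `Parent` attribute, readable by
#' [read_gene_models()].
#'
#' @param models list of `gene_model` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (gm in models) {
    for (k in seq_len(nrow(gm$exons))) {
      writeLines(sprintf("%s\tpsgscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                         gm$chrom, gm$exons[k, 1L] + 1L, gm$exons[k, 2L],
                         gm$strand, gm$gene_id, k, gm$gene_id), con)
    }
  }
  invisible(path)
}

#' Extract the CDS of a gene model from a genome
#'
#' Exon slices are concatenated in genomic order; for minus-strand genes the
#' concatenation is reverse-complemented so the result always reads 5' to 3'
#' in coding orientation.
#'
#' @param genome named character vector of chromosome sequences.
#' @param gm a `gene_model`.
#' @return nucleotide string.
#' @export
extract_cds <- function(genome, gm) {
  chr <- genome[[gm$chrom]]
  if (is.null(chr)) stop("chromosome not in genome: ", gm$chrom)
  n <- nchar(chr)
  if (any(gm$exons[, 1L] < 0L) || any(gm$exons[, 2L] > n))
    stop("exon interval out of chromosome bounds for gene ", gm$gene_id)
  parts <- substring(chr, gm$exons[, 1L] + 1L, gm$exons[, 2L])
  cds <- paste(parts, collapse = "")
  if (gm$strand == "-") cds <- revcomp(cds)
  toupper(cds)
}

#' Read similarity hits in 12-column tabular format
#'
#' The standard tab-separated hit table (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bit score).
#'
#' @param path hit table path.
#' @return data frame with typed columns.
#' @export
read_hits_tabular <- function(path) {
  x <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) != 12L)
    stop("expected 12 columns in tabular hit file, got ", ncol(x))
  names(x) <- c("query_id", "subject_id", "percent_id", "align_len",
                "mismatch", "gap_open", "q_start", "q_end", "s_start",
                "s_end", "evalue", "bitscore")
  if (any(x$evalue < 0)) stop("negative e-value in hit table")
  if (any(!is.finite(x$bitscore))) stop("non-finite bitscore in hit table")
  x
}

# Normalize a population-assignment input (two-column data frame or named
# vector sample -> population) into a named character vector.
normalize_pop_assignments <- function(pop_assignments) {
  if (is.data.frame(pop_assignments)) {
    v <- as.character(pop_assignments[[2L]])
    names(v) <- as.character(pop_assignments[[1L]])
  } else {
    v <- as.character(pop_assignments)
    names(v) <- names(pop_assignments)
  }
  pops <- unique(v)
  if (length(pops) != 2L)
    stop("exactly two populations required, got: ", paste(pops, collapse = ", "))
  v
}

#' Read a biallelic SNP table with per-population allele counts
#'
#' Two dialects are supported. `"matrix"`: a tab-separated table with columns
#' `chrom`, `pos`, `ref`, `alt` followed by one column per haploid sample
#' holding `0` (reference), `1` (alternate) or `.` (missing). `"vcf"`: a
#' minimal VCF subset (`#CHROM POS ID REF ALT QUAL FILTER INFO FORMAT` plus
#' genotype columns; `INFO`/`FILTER` ignored, alleles split on `/` or `|`).
#' Missing calls are excluded from both the alternate count and the total.
#'
#' @param path SNP table path.
#' @param pop_assignments two-column data frame (sample, population) or a
#'   named vector mapping sample to population; exactly two populations.
#' @param format `"auto"`, `"matrix"` or `"vcf"`.
#' @return data frame of class `snp_table` with columns `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `alt1`, `tot1`, `alt2`, `tot2`; the two
#'   population names are stored in `attr(, "pop_names")`.
#' @export
read_snp_table <- function(path, pop_assignments, format = c("auto", "matrix", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "##fileformat") || startsWith(first, "#CHROM"))
      "vcf" else "matrix"
  }
  assign <- normalize_pop_assignments(pop_assignments)
  pops <- unique(assign)
  if (format == "matrix") {
    x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(x)))
      stop("matrix SNP table must have columns chrom, pos, ref, alt")
    samples <- setdiff(names(x), need)
    geno <- as.matrix(x[, samples, drop = FALSE])
    meta <- x[, need]
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(vcf)
    if (is.null(dim(fix)))          # single-variant VCFs drop dimensions
      fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
    gt <- vcf@gt
    samples <- setdiff(colnames(gt), "FORMAT")
    gt <- gt[, samples, drop = FALSE]
    if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix),
                                       dimnames = list(NULL, samples))
    # first FORMAT field is GT; split alleles on / or |
    gt <- sub(":.*$", "", gt)
    geno <- matrix("", nrow = nrow(gt), ncol = 0L)
    gcols <- list()
    for (s in samples) {
      al <- strsplit(gt[, s], "[/|]")
      ploidy <- lengths(al)
      maxp <- max(ploidy)
      for (k in seq_len(maxp)) {
        col <- vapply(al, function(a) if (length(a) >= k) a[k] else ".", character(1))
        gcols[[paste0(s, if (maxp > 1L) paste0("_", k) else "")]] <- col
      }
    }
    geno <- do.call(cbind, gcols)
    # haplotype columns inherit the sample's population
    hap_sample <- sub("_[0-9]+$", "", colnames(geno))
    assign_full <- assign[hap_sample]
    names(assign_full) <- colnames(geno)
    assign <- assign_full
    samples <- colnames(geno)
    meta <- data.frame(chrom = as.character(fix[, "CHROM"]),
                       pos = as.integer(fix[, "POS"]),
                       ref = as.character(fix[, "REF"]),
                       alt = as.character(fix[, "ALT"]),
                       stringsAsFactors = FALSE)
  }
  unknown <- samples[!samples %in% names(assign)]
  if (length(unknown))
    stop("unknown population label for sample(s): ",
         paste(unknown, collapse = ", "))
  if (any(!meta$alt %in% c("A", "C", "G", "T")) ||
      any(!meta$ref %in% c("A", "C", "G", "T")))
    stop("only biallelic single-base SNPs are supported")
  counts <- lapply(pops, function(p) {
    cols <- samples[assign[samples] == p]
    g <- geno[, cols, drop = FALSE]
    alt <- rowSums(g == "1", na.rm = TRUE)        # missing: excluded from
    tot <- rowSums(g == "1" | g == "0", na.rm = TRUE)  # numerator and total
    list(alt = alt, tot = tot)
  })
  bad <- counts[[1L]]$alt > counts[[1L]]$tot | counts[[2L]]$alt > counts[[2L]]$tot
  if (any(bad)) stop("alt count exceeds total")
  out <- data.frame(meta,
                    alt1 = counts[[1L]]$alt, tot1 = counts[[1L]]$tot,
                    alt2 = counts[[2L]]$alt, tot2 = counts[[2L]]$tot,
                    stringsAsFactors = FALSE)
  attr(out, "pop_names") <- pops
  class(out) <- c("snp_table", class(out))
  out
}

#' Read a matrix-dialect SNP table as a haploid genotype matrix
#'
#' Used by the phylogeny stage: rows are accessions, columns are sites keyed
#' `chrom:pos`; entries 0/1 with `NA` for missing.
#'
#' @param path matrix-dialect SNP table (see [read_snp_table()]).
#' @return integer matrix accessions x sites.
#' @export
read_genotype_matrix <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  samples <- setdiff(names(x), need)
  g <- t(as.matrix(x[, samples, drop = FALSE]))
  g[g == "."] <- NA
  mode(g) <- "integer"
  colnames(g) <- paste0(x$chrom, ":", x$pos)
  rownames(g) <- samples
  g
}

#' Write a phylogenetic tree in newick format
#'
#' @param tree an `ape` `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a newick tree
#' @param path newick file.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)
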