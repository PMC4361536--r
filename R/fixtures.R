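# Bundled worked-example tables and their expansion into site-level inputs.
#
# `chr1_fst_bin_counts.tsv` holds the published chromosome-1 bin counts of
# shared and new (nonsynonymous/synonymous) sites per Fst bin between the
# two rice subspecies. `synthetic_chr1_nssg_genes.tsv` is a synthetic
# stand-in for the per-gene supplementary lists (which are not
# redistributable): it encodes, per Fst bin, the published number of
# candidate genes and how many of them carry a selection outlier at their
# top site, with outliers concentrated in the high-Fst bins as reported.

#' Path to a bundled example table
#'
#' @param file file name under the package's `extdata`.
#' @return absolute path.
#' @export
psgscan_example <- function(file) {
  p <- system.file("extdata", file, package = "psgscan", mustWork = TRUE)
  p
}

#' Expand Fst-bin counts into a site-level table
#'
#' Turns a per-bin count table (`label`, `lo`, `hi`, `shared`,
#' `new_nonsyn`, `new_syn`) into the per-site inputs of
#' [build_fst_bin_table()]: one synthetic site per counted unit, placed at
#' its bin's Fst midpoint (the top, closed bin uses 0.975; Fst = 1 sites
#' are represented by the top bin), with shared sites keyed into the
#' returned pairwise-PSS set.
#'
#' @param counts data frame as in `chr1_fst_bin_counts.tsv`.
#' @return list with `annotated` (data frame: `chrom`, `pos`, `effect`,
#'   `fst`) and `pairwise_pss` (character keys).
#' @export
bin_counts_to_sites <- function(counts) {
  rows <- list(); pss <- character(0)
  pos <- 0L
  for (b in seq_len(nrow(counts))) {
    mid <- if (counts$hi[b] >= 1) 0.975 else (counts$lo[b] + counts$hi[b]) / 2
    add <- function(n, effect, shared) {
      if (n == 0L) return(NULL)
      p <- pos + seq_len(n)
      pos <<- pos + n
      if (shared) pss <<- c(pss, paste0("chr1:", p))
      data.frame(chrom = "chr1", pos = p, effect = effect, fst = mid,
                 stringsAsFactors = FALSE)
    }
    rows <- c(rows, list(add(counts$shared[b], "nonsynonymous", TRUE),
                         add(counts$new_nonsyn[b], "nonsynonymous", FALSE),
                         add(counts$new_syn[b], "synonymous", FALSE)))
  }
  list(annotated = do.call(rbind, rows), pairwise_pss = pss)
}

#' Expand per-bin gene counts into a one-site-per-gene call table
#'
#' Each counted gene becomes a single nonsynonymous site at the bin's Fst
#' (the published gene tables consider only the top-Fst site per gene);
#' outlier genes get status `fixed` at Fst 1 and `outlier99` otherwise,
#' the rest `neutral`.
#'
#' @param gene_counts data frame as in `synthetic_chr1_nssg_genes.tsv`
#'   (`fst`, `n_genes`, `n_outlier_genes`).
#' @return data frame with `gene_id`, `effect`, `fst`, `status`,
#'   `cds_offset`, ready for [classify_genes()].
#' @export
gene_counts_to_sites <- function(gene_counts) {
  rows <- list(); g <- 0L
  for (b in seq_len(nrow(gene_counts))) {
    n <- gene_counts$n_genes[b]
    n_out <- gene_counts$n_outlier_genes[b]
    if (n == 0L) next
    ids <- sprintf("nssg_%03d", g + seq_len(n))
    g <- g + n
    status <- rep("neutral", n)
    status[seq_len(n_out)] <- if (gene_counts$fst[b] >= 1) "fixed" else "outlier99"
    rows[[b]] <- data.frame(gene_id = ids, effect = "nonsynonymous",
                            fst = gene_counts$fst[b], status = status,
                            cds_offset = 0L, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
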