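# Gene-level positive-selection classification from annotated, outlier-
# called SNPs, with the synonymous-site exception rules, plus summaries:
# amino-acid substitution types by R-group and chromosome distributions.

OUTLIER_STATUSES <- c("outlier95", "outlier99", "fixed")

# default five-class amino-acid R-group (side-chain) scheme
AA_R_GROUPS <- list(
  nonpolar_aliphatic = c("G", "A", "V", "L", "I", "M", "P"),
  aromatic = c("F", "Y", "W"),
  polar_uncharged = c("S", "T", "C", "N", "Q"),
  positive = c("K", "R", "H"),
  negative = c("D", "E"))

#' Classify a gene from its annotated, outlier-called sites
#'
#' Rules are applied in order on the exonic sites with Fst at or above
#' `fst_threshold` (the "considered" sites):
#' 1. if all considered sites are nonsynonymous, nonsense or
#'    splice-altering and at least one has outlier status (outlier95,
#'    outlier99 or fixed), the gene is a PSG;
#' 2. else if exactly one considered site is synonymous, at least one
#'    nonsynonymous outlier exists, and either the synonymous site's Fst
#'    does not exceed the highest Fst among the nonsynonymous outlier
#'    sites or a stop-gained (nonsense) site lies 5' of it in coding
#'    order, the gene is a PSG candidate under the synonymous-site
#'    exception;
#' 3. else if any synonymous site has outlier status, the gene is flagged
#'    as possible hitchhiking;
#' 4. else the gene is not selected.
#'
#' @param gene_sites data frame of one gene's sites with columns `effect`,
#'   `fst`, `status`, `cds_offset`.
#' @param fst_threshold sites below this Fst are ignored (default 0.25).
#' @return list of class `gene_selection_call`: `verdict`, `rule_fired`,
#'   `n_considered`, `n_nonsyn_outliers`, `max_nonsyn_fst`.
#' @export
classify_gene <- function(gene_sites, fst_threshold = 0.25) {
  exonic <- gene_sites$effect %in% c("synonymous", "nonsynonymous",
                                     "nonsense", "splice_altering")
  cons <- gene_sites[exonic & !is.na(gene_sites$fst) &
                       gene_sites$fst >= fst_threshold, , drop = FALSE]
  nonsynish <- cons$effect %in% c("nonsynonymous", "nonsense", "splice_altering")
  syn <- cons$effect == "synonymous"
  outlier <- !is.na(cons$status) & cons$status %in% OUTLIER_STATUSES
  n_nonsyn_out <- sum(nonsynish & outlier)
  max_nonsyn_fst <- if (n_nonsyn_out > 0) max(cons$fst[nonsynish & outlier]) else NA_real_
  verdict <- "not_selected"; rule <- "no_considered_sites"
  if (nrow(cons) > 0L) {
    if (all(nonsynish) && any(outlier)) {
      verdict <- "PSG"; rule <- "only_nonsynonymous_with_outlier"
    } else if (sum(syn) == 1L && n_nonsyn_out >= 1L) {
      syn_fst <- cons$fst[syn]
      syn_off <- cons$cds_offset[syn]
      stop_before <- any(cons$effect == "nonsense" &
                           !is.na(cons$cds_offset) & !is.na(syn_off) &
                           cons$cds_offset < syn_off)
      if (syn_fst <= max_nonsyn_fst || isTRUE(stop_before)) {
        verdict <- "PSG_candidate_syn_exception"
        rule <- if (syn_fst <= max_nonsyn_fst) "syn_fst_not_highest"
                else "stop_gained_upstream"
      } else {
        verdict <- if (any(syn & outlier)) "hitchhiking_flagged" else "not_selected"
        rule <- if (verdict == "hitchhiking_flagged") "synonymous_outlier"
                else "syn_site_dominates"
      }
    } else if (any(syn & outlier)) {
      verdict <- "hitchhiking_flagged"; rule <- "synonymous_outlier"
    } else {
      rule <- "no_qualifying_outlier"
    }
  }
  structure(list(verdict = verdict, rule_fired = rule,
                 n_considered = nrow(cons),
                 n_nonsyn_outliers = n_nonsyn_out,
                 max_nonsyn_fst = max_nonsyn_fst),
            class = "gene_selection_call")
}

#' Classify every gene in an annotated, outlier-called site table
#'
#' @param called data frame from [call_outliers()] with a `gene_id` column.
#' @param fst_threshold passed to [classify_gene()].
#' @return data frame: `gene_id`, `verdict`, `rule_fired`, `n_sites`,
#'   `n_considered`, `n_nonsyn_outliers`, `max_nonsyn_fst`.
#' @export
classify_genes <- function(called, fst_threshold = 0.25) {
  genes <- sort(unique(called$gene_id[!is.na(called$gene_id)]))
  rows <- lapply(genes, function(g) {
    gs <- called[!is.na(called$gene_id) & called$gene_id == g, , drop = FALSE]
    cl <- classify_gene(gs, fst_threshold)
    data.frame(gene_id = g, verdict = cl$verdict, rule_fired = cl$rule_fired,
               n_sites = nrow(gs), n_considered = cl$n_considered,
               n_nonsyn_outliers = cl$n_nonsyn_outliers,
               max_nonsyn_fst = cl$max_nonsyn_fst, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize amino-acid substitution types at selected sites
#'
#' Counts nonsynonymous outlier substitutions whose two amino acids share
#' an R-group class versus those that do not, plus special categories:
#' substitutions involving proline (structure breakers), stop-gained and
#' splice-altering sites.
#'
#' @param psg_sites data frame of sites with `effect`, `ref_aa`, `alt_aa`.
#' @param aa_classes named list of amino-acid classes (default the
#'   five-class R-group scheme in `AA_R_GROUPS`).
#' @return list of class `substitution_type_summary`: `same_r_group`,
#'   `different_r_group`, `proline_involving`, `stop_gained`,
#'   `splice_altering`, `fraction_same`.
#' @export
summarize_substitution_types <- function(psg_sites, aa_classes = AA_R_GROUPS) {
  stopg <- sum(psg_sites$effect == "nonsense")
  splice <- sum(psg_sites$effect == "splice_altering")
  ns <- psg_sites[psg_sites$effect == "nonsynonymous", , drop = FALSE]
  class_of <- function(aa) {
    hit <- names(aa_classes)[vapply(aa_classes, function(cl) aa %in% cl, logical(1))]
    if (length(hit) == 0L) NA_character_ else hit[1L]
  }
  same <- 0L; diff <- 0L; pro <- 0L
  for (i in seq_len(nrow(ns))) {
    ca <- class_of(ns$ref_aa[i]); cb <- class_of(ns$alt_aa[i])
    if (is.na(ca) || is.na(cb)) next
    if (ca == cb) same <- same + 1L else diff <- diff + 1L
    if (ns$ref_aa[i] == "P" || ns$alt_aa[i] == "P") pro <- pro + 1L
  }
  structure(list(same_r_group = same, different_r_group = diff,
                 proline_involving = pro, stop_gained = stopg,
                 splice_altering = splice,
                 fraction_same = if (same + diff > 0) same / (same + diff)
                 else NA_real_),
            class = "substitution_type_summary")
}

#' Distribution of selected genes along chromosomes
#'
#' @param calls data frame from [classify_genes()].
#' @param models gene-model list covering all genes.
#' @param bin bin width in bases (default 1 Mb).
#' @param positive_verdicts verdicts counted as selected.
#' @return list with `per_chromosome` (chrom, n_genes, n_psg, ratio) and
#'   `per_bin` (chrom, bin_start, n_genes, n_psg, ratio; ratio `NA` in
#'   bins without genes).
#' @export
chromosome_distribution <- function(calls, models, bin = 1e6,
                                    positive_verdicts = c("PSG",
                                      "PSG_candidate_syn_exception")) {
  info <- data.frame(
    gene_id = names(models),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    start = vapply(models, function(m) m$exons[1L, 1L], numeric(1)),
    stringsAsFactors = FALSE)
  info$psg <- info$gene_id %in% calls$gene_id[calls$verdict %in% positive_verdicts]
  per_chrom <- do.call(rbind, lapply(split(info, info$chrom), function(d)
    data.frame(chrom = d$chrom[1L], n_genes = nrow(d), n_psg = sum(d$psg),
               ratio = sum(d$psg) / nrow(d), stringsAsFactors = FALSE)))
  rownames(per_chrom) <- NULL
  info$bin_start <- floor(info$start / bin) * bin
  per_bin <- do.call(rbind, lapply(split(info, list(info$chrom, info$bin_start),
                                         drop = TRUE), function(d)
    data.frame(chrom = d$chrom[1L], bin_start = d$bin_start[1L],
               n_genes = nrow(d), n_psg = sum(d$psg),
               ratio = if (nrow(d) > 0) sum(d$psg) / nrow(d) else NA_real_,
               stringsAsFactors = FALSE)))
  rownames(per_bin) <- NULL
  list(per_chromosome = per_chrom, per_bin = per_bin)
}
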