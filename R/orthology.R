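# Ortholog identification between two annotation sets: reciprocal best
# hits from tabular similarity searches, union across annotation databases,
# global protein alignment, percent identity, and a neighbor-vote
# collinearity filter standing in for manual curation of collinear regions.

# best subject per query: max bitscore, ties by min e-value, then
# lexicographic subject id
best_hits <- function(hits) {
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[o, ]
  h[!duplicated(h$query_id), c("query_id", "subject_id")]
}

#' Reciprocal best hits between two hit tables
#'
#' A pair (a, b) is kept iff b is a's best hit in the forward table and a is
#' b's best hit in the reverse table. "Best" is the maximum bit score, with
#' ties broken by minimum e-value and then lexicographic subject id, so the
#' result is deterministic.
#'
#' @param hits_ab hits of genome A queries against genome B
#'   (see [read_hits_tabular()]).
#' @param hits_ba hits of genome B queries against genome A.
#' @return data frame with columns `gene_a`, `gene_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba) {
  if (nrow(hits_ab) == 0L || nrow(hits_ba) == 0L)
    stop("both hit tables must be non-empty")
  fwd <- best_hits(hits_ab)
  rev <- best_hits(hits_ba)
  back <- rev$subject_id[match(fwd$subject_id, rev$query_id)]
  keep <- !is.na(back) & back == fwd$query_id
  out <- data.frame(gene_a = fwd$query_id[keep], gene_b = fwd$subject_id[keep],
                    stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Merge ortholog pair sets from two annotation databases
#'
#' Takes the union keyed by `gene_a`, with the first set taking precedence
#' when the same `gene_a` maps to different partners. `id_crosswalk`
#' translates the second set's `gene_b` identifiers into the first set's
#' identifier system before comparison; a crosswalk whose output ids are
#' themselves remapped (a cycle/chain) is an error.
#'
#' @param pairs_db1,pairs_db2 data frames with `gene_a`, `gene_b`.
#' @param id_crosswalk named character vector mapping db2 `gene_b` ids to
#'   db1 ids (missing ids pass through unchanged); `NULL` for identity.
#' @return merged data frame `gene_a`, `gene_b`, `source`.
#' @export
merge_pair_sets <- function(pairs_db1, pairs_db2, id_crosswalk = NULL) {
  if (!is.null(id_crosswalk)) {
    chained <- id_crosswalk[id_crosswalk %in% names(id_crosswalk) &
                              id_crosswalk != names(id_crosswalk)]
    if (length(chained))
      stop("crosswalk cycle/chain at: ", paste(names(chained), collapse = ", "))
    hit <- pairs_db2$gene_b %in% names(id_crosswalk)
    pairs_db2$gene_b[hit] <- unname(id_crosswalk[pairs_db2$gene_b[hit]])
  }
  with_source <- function(p, src) {
    data.frame(gene_a = as.character(p$gene_a),
               gene_b = as.character(p$gene_b),
               source = rep(src, nrow(p)), stringsAsFactors = FALSE)
  }
  p1 <- with_source(pairs_db1, "db1")
  p2 <- with_source(pairs_db2, "db2")
  m <- match(p1$gene_a, p2$gene_a)
  agree <- !is.na(m) & p2$gene_b[m] == p1$gene_b
  conflict <- p1$gene_a[!is.na(m) & p2$gene_b[m] != p1$gene_b]
  if (length(conflict))
    message("conflicting partners for ", length(conflict),
            " gene(s); keeping db1: ", paste(conflict, collapse = ", "))
  p1$source[agree] <- "db1+db2"
  out <- rbind(p1, p2[!p2$gene_a %in% p1$gene_a, ])
  out[order(out$gene_a), , drop = FALSE]
}

#' Global protein alignment
#'
#' Needleman-Wunsch global alignment with a BLOSUM62 substitution matrix
#' and affine gap penalties (via `Biostrings::pairwiseAlignment`).
#'
#' @param protein_a,protein_b protein strings over the 20 amino acids plus
#'   `X` and `*`.
#' @param gap_open,gap_extend affine gap penalties (positive costs;
#'   defaults 10 and 0.5).
#' @param substitution_matrix scoring matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @return list with gap-padded strings `a`, `b` and the alignment `score`.
#' @export
global_align <- function(protein_a, protein_b, gap_open = 10, gap_extend = 0.5,
                         substitution_matrix = "BLOSUM62") {
  for (p in c(protein_a, protein_b)) {
    if (!nzchar(p)) stop("empty protein sequence")
    if (grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", p))
      stop("illegal residue in protein sequence")
  }
  pa <- gsub("\\*$", "", protein_a)   # trailing stop, if annotated
  pb <- gsub("\\*$", "", protein_b)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pa), Biostrings::AAString(pb),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  list(a = as.character(Biostrings::alignedPattern(al)),
       b = as.character(Biostrings::alignedSubject(al)),
       score = Biostrings::score(al))
}

#' Percent identity of a pairwise alignment
#'
#' Identical residue columns divided by columns where both sequences are
#' non-gap (gap columns do not enter the denominator).
#'
#' @param alignment list with equal-length gap-padded strings `a`, `b`.
#' @return fraction in `[0, 1]`.
#' @export
percent_identity <- function(alignment) {
  a <- strsplit(alignment$a, "")[[1L]]
  b <- strsplit(alignment$b, "")[[1L]]
  if (length(a) != length(b)) stop("alignment rows differ in length")
  co <- a != "-" & b != "-"
  if (!any(co)) stop("alignment has no co-aligned columns")
  sum(a[co] == b[co]) / sum(co)
}

#' Collinearity filter on ortholog pairs
#'
#' Keeps a pair iff, among its `window` nearest paired neighbors on the
#' gene-A chromosome (by gene order), at least `min_support` map to the
#' pair's gene-B chromosome. Near chromosome ends, where fewer than
#' `window` neighbors exist, the required support is scaled down to
#' `min(min_support, n_neighbors)`.
#'
#' @param pairs data frame with `gene_a`, `gene_b`.
#' @param models_a,models_b gene-model lists (see [read_gene_models()]).
#' @param window number of neighbors examined (default 10).
#' @param min_support neighbors that must agree (default 3).
#' @return filtered pair data frame.
#' @export
collinearity_filter <- function(pairs, models_a, models_b, window = 10L,
                                min_support = 3L) {
  if (nrow(pairs) == 0L) return(pairs)
  chrom_a <- vapply(pairs$gene_a, function(g) models_a[[g]]$chrom, character(1))
  start_a <- vapply(pairs$gene_a, function(g) models_a[[g]]$exons[1L, 1L], numeric(1))
  chrom_b <- vapply(pairs$gene_b, function(g) models_b[[g]]$chrom, character(1))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    same <- which(chrom_a == chrom_a[i])
    same <- same[same != i]
    if (length(same) == 0L) { keep[i] <- TRUE; next }   # no evidence: keep
    nb <- same[order(abs(start_a[same] - start_a[i]))]
    nb <- nb[seq_len(min(window, length(nb)))]
    support <- sum(chrom_b[nb] == chrom_b[i])
    keep[i] <- support >= min(min_support, length(nb))
  }
  pairs[keep, , drop = FALSE]
}

#' Build the ortholog pair table with identities
#'
#' Aligns every pair and records percent identity.
#'
#' @param pairs data frame `gene_a`, `gene_b`.
#' @param proteins_a,proteins_b named character vectors of proteins.
#' @param ... passed to [global_align()].
#' @return list with `table` (pairs + `percent_identity`) and `alignments`
#'   (named by `gene_a`).
#' @export
align_pairs <- function(pairs, proteins_a, proteins_b, ...) {
  alignments <- list()
  pid <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    al <- global_align(proteins_a[[pairs$gene_a[i]]],
                       proteins_b[[pairs$gene_b[i]]], ...)
    alignments[[pairs$gene_a[i]]] <- al
    pid[i] <- percent_identity(al)
  }
  tab <- pairs
  tab$percent_identity <- pid
  list(table = tab, alignments = alignments)
}
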