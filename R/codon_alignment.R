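# Back-translation of a pairwise protein alignment onto the underlying
# coding sequences, producing a codon alignment for Ka/Ks estimation.

#' Strip a terminal stop codon from a CDS
#'
#' @param cds nucleotide string with length a multiple of 3.
#' @return the CDS without its trailing TAA/TAG/TGA, if present.
#' @export
strip_terminal_stop <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  if (n >= 3L && substring(cds, n - 2L, n) %in% STOP_CODONS)
    cds <- substring(cds, 1L, n - 3L)
  cds
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps residue i of each aligned protein to codon i of the corresponding
#' CDS (terminal stop stripped); protein gaps become `"---"` columns.
#' Each CDS must translate exactly to its ungapped protein row; residue `X`
#' is tolerated opposite any codon, but an internal stop codon or any other
#' mismatch is an error naming the first discordant residue. Columns gapped
#' in both rows are dropped.
#'
#' @param protein_alignment list with gap-padded equal-length strings `a`
#'   and `b`.
#' @param cds_a,cds_b coding sequences of the two genes.
#' @return object of class `codon_alignment`: list with character vectors
#'   `codons_a`, `codons_b` (each element a codon or `"---"`).
#' @export
back_translate <- function(protein_alignment, cds_a, cds_b) {
  pa <- protein_alignment$a
  pb <- protein_alignment$b
  if (nchar(pa) != nchar(pb)) stop("alignment rows differ in length")
  codons <- lapply(list(a = list(p = pa, cds = cds_a),
                        b = list(p = pb, cds = cds_b)),
                   function(x) {
    cds <- strip_terminal_stop(x$cds)
    cod <- split_codons(cds)
    res <- strsplit(gsub("-", "", x$p), "")[[1L]]
    if (length(res) != length(cod))
      stop("protein length (", length(res), ") does not match CDS codons (",
           length(cod), ")")
    aa <- codon_aa(cod)
    for (i in seq_along(res)) {
      if (aa[i] == "*")
        stop("internal stop codon at residue ", i)
      if (res[i] != "X" && res[i] != aa[i])
        stop("translation mismatch at residue ", i, ": protein '", res[i],
             "' vs CDS '", aa[i], "'")
    }
    cod
  })
  cols_a <- strsplit(pa, "")[[1L]]
  cols_b <- strsplit(pb, "")[[1L]]
  ia <- 0L; ib <- 0L
  out_a <- character(0); out_b <- character(0)
  for (j in seq_along(cols_a)) {
    ga <- cols_a[j] == "-"; gb <- cols_b[j] == "-"
    if (ga && gb) next                       # mixed-gap column: drop
    if (ga) out_a <- c(out_a, "---") else { ia <- ia + 1L; out_a <- c(out_a, codons$a[ia]) }
    if (gb) out_b <- c(out_b, "---") else { ib <- ib + 1L; out_b <- c(out_b, codons$b[ib]) }
  }
  structure(list(codons_a = out_a, codons_b = out_b),
            class = "codon_alignment")
}
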