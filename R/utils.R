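# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations never leak
#' state into (or absorb state from) the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage-specific seed from a master seed and a label, stably and
# within the 32-bit integer range R requires of set.seed().
derive_seed <- function(master, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(master) * 7919 + h) %% 2147483647L)
}

# Round half up to the nearest integer (round() in R rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Write a data frame as tab-separated values with a header line
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-separated table written by [write_tsv()]
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Reverse complement of a plain nucleotide string.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Split a CDS string into its codons.
split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Translate one codon using the standard genetic code ("*" for stop).
codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

#' Translate a coding sequence
#'
#' Standard genetic code; stop codons translate to `*`.
#'
#' @param cds nucleotide string with length a multiple of 3.
#' @return amino-acid string.
#' @export
translate_cds <- function(cds) {
  paste(codon_aa(split_codons(toupper(cds))), collapse = "")
}
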