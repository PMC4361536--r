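# Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction, a
# one-sided Fisher exact test for Ka/Ks > 1, classification of gene pairs
# with zero synonymous substitutions (NSSGs), and sliding-window scans.

# cache of per-codon site counts and per-codon-pair pathway counts
.ng86_cache <- new.env(parent = emptyenv())

#' NG86 synonymous/nonsynonymous site counts of a codon
#'
#' For each codon position, the synonymous-site contribution is the fraction
#' of the three possible single-base changes that leave the amino acid
#' unchanged; changes to a stop codon count as nonsynonymous. The two counts
#' always sum to 3.
#'
#' @param codon 3-letter string over A/C/G/T, not a stop codon.
#' @return named numeric vector `c(s = , n = )`.
#' @export
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  if (!grepl("^[ACGT]{3}$", codon)) stop("ambiguous or malformed codon: ", codon)
  if (codon %in% STOP_CODONS) stop("stop codon has no site counts: ", codon)
  key <- paste0("s_", codon)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(BASES, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!(mut %in% STOP_CODONS) && codon_aa(mut) == aa) s <- s + 1 / 3
    }
  }
  out <- c(s = s, n = 3 - s)
  .ng86_cache[[key]] <- out
  out
}

#' NG86 substitution counts between two codons
#'
#' If the codons differ at k positions, the synonymous and nonsynonymous
#' step counts are averaged over all k! orderings of the single-base steps.
#' Orderings passing through a stop codon are excluded; if every ordering
#' passes through a stop, all orderings are used (steps to or from a stop
#' count as nonsynonymous).
#'
#' @param codon_a,codon_b codons over A/C/G/T, neither a stop.
#' @return named numeric vector `c(sd = , nd = )`; `sd + nd` equals the
#'   number of differing positions.
#' @export
ng86_diff_counts <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (!grepl("^[ACGT]{3}$", cd)) stop("ambiguous or malformed codon: ", cd)
    if (cd %in% STOP_CODONS) stop("stop codon in pathway counting: ", cd)
  }
  key <- paste0("d_", codon_a, codon_b)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  diff_pos <- which(strsplit(codon_a, "")[[1L]] != strsplit(codon_b, "")[[1L]])
  k <- length(diff_pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- permutations(diff_pos)
  path_sd <- numeric(0); path_nd <- numeric(0); path_ok <- logical(0)
  for (ord in perms) {
    cur <- codon_a
    sd <- 0; nd <- 0; ok <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (cur %in% STOP_CODONS || nxt %in% STOP_CODONS) {
        ok <- FALSE
        nd <- nd + 1          # stop-involving step is nonsynonymous
      } else if (codon_aa(cur) == codon_aa(nxt)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd); path_ok <- c(path_ok, ok)
  }
  use <- if (any(path_ok)) path_ok else rep(TRUE, length(path_ok))
  out <- c(sd = mean(path_sd[use]), nd = mean(path_nd[use]))
  .ng86_cache[[key]] <- out
  out
}

# all orderings of a vector (k <= 3 here, so at most 6)
permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in permutations(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

#' Jukes-Cantor distance correction
#'
#' `d = -(3/4) * log(1 - 4p/3)` for a proportion of differing sites `p`.
#'
#' @param p proportion in `[0, 0.75)`.
#' @return corrected distance, `>= p`.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("negative proportion")
  if (any(p >= 0.75)) stop("Jukes-Cantor saturation: p >= 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks of a pairwise codon alignment
#'
#' Sums site counts (averaged over the two sequences) and pathway-averaged
#' substitution counts over fully ungapped, unambiguous codon columns, then
#' applies the Jukes-Cantor correction and the one-sided Fisher exact test
#' for an excess of nonsynonymous substitutions.
#'
#' @param ca a `codon_alignment` (see [back_translate()]), or any list with
#'   character vectors `codons_a` and `codons_b` (gap columns are `"---"`).
#' @return list of class `substitution_counts` with fields `n_codons_used`,
#'   `S_sites`, `N_sites`, `Sd`, `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`
#'   (`NaN` when `Ks` is 0), `fisher_p`.
#' @export
kaks_pair <- function(ca) {
  a <- toupper(ca$codons_a); b <- toupper(ca$codons_b)
  usable <- grepl("^[ACGT]{3}$", a) & grepl("^[ACGT]{3}$", b) &
    !(a %in% STOP_CODONS) & !(b %in% STOP_CODONS)
  a <- a[usable]; b <- b[usable]
  if (length(a) == 0L) stop("no usable (ungapped, unambiguous) codon columns")
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(a)) {
    sa <- ng86_site_counts(a[i]); sb <- ng86_site_counts(b[i])
    S <- S + (sa[["s"]] + sb[["s"]]) / 2
    N <- N + (sa[["n"]] + sb[["n"]]) / 2
    d <- ng86_diff_counts(a[i], b[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- Sd / S
  pN <- Nd / N
  Ks <- if (pS < 0.75) jukes_cantor(pS) else NA_real_
  Ka <- if (pN < 0.75) jukes_cantor(pN) else NA_real_
  omega <- if (!is.na(Ks) && Ks == 0) NaN else Ka / Ks
  counts <- structure(
    list(n_codons_used = length(a), S_sites = S, N_sites = N,
         Sd = Sd, Nd = Nd, pS = pS, pN = pN, Ks = Ks, Ka = Ka,
         omega = omega, fisher_p = NA_real_),
    class = "substitution_counts")
  counts$fisher_p <- if (Sd + Nd >= 1) fisher_positive_selection(counts) else NA_real_
  counts
}

#' One-sided Fisher exact test for an excess of nonsynonymous substitutions
#'
#' Tests the 2x2 table with rows (synonymous, nonsynonymous) and columns
#' (substitutions, sites minus substitutions). Real-valued NG86 counts are
#' rounded half up to integers; the p-value is the hypergeometric tail
#' probability of a split at least as extreme toward excess nonsynonymous
#' substitutions (i.e. at most the observed number of synonymous ones).
#'
#' @param counts a `substitution_counts` (or list with `Sd`, `Nd`,
#'   `S_sites`, `N_sites`).
#' @return p-value.
#' @export
fisher_positive_selection <- function(counts) {
  Sd <- round_half_up(counts$Sd); Nd <- round_half_up(counts$Nd)
  S <- round_half_up(counts$S_sites); N <- round_half_up(counts$N_sites)
  k <- Sd + Nd
  if (k < 1) stop("no substitutions: Fisher test undefined")
  if (S < Sd || N < Nd) stop("degenerate margins in Fisher table")
  stats::phyper(Sd, S, N, k)
}

#' Classify a gene pair's divergence
#'
#' NSSG (nonsynonymous substitution gene): zero synonymous and at least one
#' nonsynonymous substitution, regardless of the Fisher p-value. A PSG with
#' synonymous substitutions requires `omega > 1` and a significant Fisher
#' test. Everything else is not significant.
#'
#' @param counts a `substitution_counts`.
#' @param alpha significance level (default 0.05).
#' @return one of `"NSSG"`, `"PSG_with_syn"`, `"not_significant"`.
#' @export
classify_divergence <- function(counts, alpha = 0.05) {
  if (counts$Sd == 0 && counts$Nd > 0) return("NSSG")
  if (counts$Sd > 0 && is.finite(counts$omega) && counts$omega > 1 &&
      !is.na(counts$fisher_p) && counts$fisher_p < alpha)
    return("PSG_with_syn")
  "not_significant"
}

#' Sliding-window Ka/Ks scan of a codon alignment
#'
#' Windows of `window` codon columns advance by `step`; the final window is
#' anchored at the alignment end so no tail is dropped. Windows whose gap
#' fraction (columns with a gap in either row) reaches `max_gap` are
#' excluded.
#'
#' @param ca a `codon_alignment`.
#' @param window window size in codon columns (default 100).
#' @param step window shift in codon columns (default 34).
#' @param max_gap windows with gap fraction `>=` this are dropped (default 0.5).
#' @param alpha significance level used for the per-window label.
#' @return data frame with one row per retained window: `start_codon`,
#'   `end_codon` (0-based half-open, in alignment columns), `gap_fraction`,
#'   the `substitution_counts` fields and `label`.
#' @export
sliding_window_scan <- function(ca, window = 100L, step = 34L, max_gap = 0.5,
                                alpha = 0.05) {
  ncol_aln <- length(ca$codons_a)
  if (ncol_aln <= window) starts <- 0L
  else {
    starts <- seq(0L, ncol_aln - window, by = step)
    if (starts[length(starts)] != ncol_aln - window)
      starts <- c(starts, ncol_aln - window)
  }
  rows <- list()
  for (s in starts) {
    e <- min(s + window, ncol_aln)
    wa <- ca$codons_a[(s + 1L):e]; wb <- ca$codons_b[(s + 1L):e]
    gap_frac <- mean(wa == "---" | wb == "---")
    if (gap_frac >= max_gap) next
    usable <- grepl("^[ACGT]{3}$", wa) & grepl("^[ACGT]{3}$", wb) &
      !(wa %in% STOP_CODONS) & !(wb %in% STOP_CODONS)
    if (!any(usable)) next
    k <- kaks_pair(list(codons_a = wa, codons_b = wb))
    rows[[length(rows) + 1L]] <- data.frame(
      start_codon = s, end_codon = e, gap_fraction = gap_frac,
      n_codons_used = k$n_codons_used, S_sites = k$S_sites,
      N_sites = k$N_sites, Sd = k$Sd, Nd = k$Nd, Ka = k$Ka, Ks = k$Ks,
      omega = k$omega, fisher_p = k$fisher_p,
      label = classify_divergence(k, alpha), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(start_codon = integer(), end_codon = integer(),
                      gap_fraction = numeric(), n_codons_used = integer(),
                      S_sites = numeric(), N_sites = numeric(), Sd = numeric(),
                      Nd = numeric(), Ka = numeric(), Ks = numeric(),
                      omega = numeric(), fisher_p = numeric(),
                      label = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Ka/Ks table for a set of ortholog pairs
#'
#' Convenience wrapper running [back_translate()] and [kaks_pair()] over a
#' pair table, producing the per-gene divergence table.
#'
#' @param pairs data frame with columns `gene_a`, `gene_b`.
#' @param alignments named list (by `gene_a`) of protein alignments
#'   (`list(a =, b =)`).
#' @param cds_a,cds_b named character vectors of CDS sequences.
#' @param alpha significance level.
#' @return data frame with the per-pair NG86 quantities and `label`.
#' @export
kaks_table <- function(pairs, alignments, cds_a, cds_b, alpha = 0.05) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    ga <- pairs$gene_a[i]; gb <- pairs$gene_b[i]
    al <- alignments[[ga]]
    ca <- back_translate(al, cds_a[[ga]], cds_b[[gb]])
    k <- kaks_pair(ca)
    data.frame(gene_a = ga, gene_b = gb, n_codons_used = k$n_codons_used,
               S_sites = k$S_sites, N_sites = k$N_sites, Sd = k$Sd, Nd = k$Nd,
               Ka = k$Ka, Ks = k$Ks, omega = k$omega, fisher_p = k$fisher_p,
               label = classify_divergence(k, alpha), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
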