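# Neighbor-joining phylogeny of accessions from their genotypes at
# positively selected sites, using the simple-matching distance, plus
# pairwise group Fst matrices over the same sites.

#' Simple-matching distance matrix of a genotype matrix
#'
#' `d(i, j)` is the fraction of mismatching calls over the sites called in
#' both accessions. Heterozygous or otherwise uncertain calls should
#' already be encoded `NA` (inbred-line convention: haploid 0/1 coding).
#'
#' @param gm matrix accessions x sites with entries 0/1/`NA`.
#' @param min_overlap minimum number of co-called sites per pair
#'   (default 10); a pair below it is an error naming the pair.
#' @return symmetric distance matrix with zero diagonal.
#' @export
simple_matching_distance <- function(gm, min_overlap = 10L) {
  if (nrow(gm) < 2L || ncol(gm) < 1L) stop("need >= 2 accessions and >= 1 site")
  x <- gm
  called <- !is.na(x)
  x0 <- x; x0[!called] <- 0
  # overlap counts and mismatch counts via matrix products
  overlap <- called %*% t(called)
  agree11 <- x0 %*% t(x0)
  agree00 <- (called - x0) %*% t(called - x0)
  mismatch <- overlap - agree11 - agree00
  low <- which(overlap < min_overlap & upper.tri(overlap), arr.ind = TRUE)
  if (nrow(low) > 0L)
    stop("site overlap below ", min_overlap, " for pair ",
         rownames(gm)[low[1L, 1L]], " / ", rownames(gm)[low[1L, 2L]])
  d <- mismatch / overlap
  diag(d) <- 0
  dimnames(d) <- list(rownames(gm), rownames(gm))
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with Q-matrix joins. Ties in the Q matrix
#' are broken by the smallest (row, column) index pair, so the topology is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sister branch, the usual practical
#' correction. The result is an unrooted `ape` `phylo` tree.
#'
#' @param D symmetric nonnegative distance matrix with labeled rows.
#' @return an `ape` `phylo` object.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("distance matrix not symmetric")
  if (any(D < 0)) stop("negative distances")
  n <- nrow(D)
  if (n < 3L) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  nodes <- labels          # newick fragment per active node
  active <- seq_len(n)
  repeat {
    m <- length(active)
    if (m == 3L) break
    d <- D[active, active]
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, `+`)
    diag(q) <- Inf
    # smallest Q; ties by smallest (i, j) in active order
    best <- which(q == min(q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_label <- sprintf("(%s:%.10g,%s:%.10g)", nodes[active[i]], bi,
                         nodes[active[j]], bj)
    duk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    # new node replaces position of i in the active set
    new_idx <- active[i]
    D[new_idx, active[keep]] <- duk[keep]
    D[active[keep], new_idx] <- duk[keep]
    D[new_idx, new_idx] <- 0
    nodes[new_idx] <- new_label
    active <- c(new_idx, active[keep])
  }
  d <- D[active, active]
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", nodes[active[1]], b[1],
                 nodes[active[2]], b[2], nodes[active[3]], b[3])
  ape::read.tree(text = nwk)
}

#' Pairwise group Fst matrix over selected sites
#'
#' For each pair of groups, the mean over sites of the per-site Fst
#' computed from that pair's allele frequencies; sites with undefined Fst
#' (monomorphic in the pooled pair) are skipped.
#'
#' @param genotypes matrix accessions x sites (0/1/`NA`).
#' @param group_assignments named vector mapping accession to group
#'   (>= 2 groups).
#' @return symmetric matrix of mean Fst with `NA` diagonal.
#' @export
group_fst_matrix <- function(genotypes, group_assignments) {
  groups <- unique(group_assignments[rownames(genotypes)])
  groups <- groups[!is.na(groups)]
  if (length(groups) < 2L) stop("need at least 2 groups")
  freqs <- sapply(groups, function(g) {
    rows <- rownames(genotypes)[group_assignments[rownames(genotypes)] == g]
    colMeans(genotypes[rows, , drop = FALSE], na.rm = TRUE)
  })
  out <- matrix(NA_real_, length(groups), length(groups),
                dimnames = list(groups, groups))
  for (a in seq_along(groups)) for (b in seq_along(groups)) {
    if (a >= b) next
    f <- fst_site(freqs[, a], freqs[, b])
    out[a, b] <- out[b, a] <- mean(f, na.rm = TRUE)
  }
  out
}

#' Drop sites with too much missing data in any group
#'
#' @param genotypes matrix accessions x sites.
#' @param group_assignments named vector accession -> group.
#' @param max_missing maximum missing fraction allowed within each group
#'   (default 0.2).
#' @return filtered genotype matrix.
#' @export
filter_sites_by_missingness <- function(genotypes, group_assignments,
                                        max_missing = 0.2) {
  groups <- unique(group_assignments[rownames(genotypes)])
  keep <- rep(TRUE, ncol(genotypes))
  for (g in groups) {
    rows <- rownames(genotypes)[group_assignments[rownames(genotypes)] == g]
    miss <- colMeans(is.na(genotypes[rows, , drop = FALSE]))
    keep <- keep & miss <= max_missing
  }
  genotypes[, keep, drop = FALSE]
}
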