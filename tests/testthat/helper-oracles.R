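# Independent oracles used to cross-check the implementation. These
# deliberately avoid the package's own code paths: translation goes through
# seqinr, combinatorics through lchoose, and alignment scoring through a
# separate memoized recursion.

ORACLE_STOPS <- c("TAA", "TAG", "TGA")

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

# single-mutant enumeration of NG86 site counts
oracle_site_counts <- function(codon) {
  aa <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- b
      if (!(mut %in% ORACLE_STOPS) && oracle_translate(mut) == aa)
        s <- s + 1 / 3
    }
  }
  c(s = s, n = 3 - s)
}

# pathway enumeration of NG86 substitution counts
oracle_diff_counts <- function(ca, cb) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0) return(c(sd = 0, nd = 0))
  perms <- if (k == 1) list(pos) else {
    idx <- gtools_perm(k)
    lapply(seq_len(nrow(idx)), function(i) pos[idx[i, ]])
  }
  res <- lapply(perms, function(ord) {
    cur <- ca; sd <- 0; nd <- 0; ok <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (cur %in% ORACLE_STOPS || nxt %in% ORACLE_STOPS) { ok <- FALSE; nd <- nd + 1 }
      else if (oracle_translate(cur) == oracle_translate(nxt)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd, ok)
  })
  m <- do.call(rbind, res)
  use <- if (any(m[, 3] == 1)) m[, 3] == 1 else rep(TRUE, nrow(m))
  c(sd = mean(m[use, 1]), nd = mean(m[use, 2]))
}

# all permutations of 1..k as a matrix (k <= 3 needed)
gtools_perm <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- gtools_perm(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- setdiff(seq_len(k), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# brute-force hypergeometric tail: P(#synonymous <= sd) drawing sd+nd
# substitutions from S synonymous + N nonsynonymous sites
oracle_hyper_tail <- function(sd, nd, S, N) {
  k <- sd + nd
  j <- 0:sd
  sum(exp(lchoose(S, j) + lchoose(N, k - j) - lchoose(S + N, k)))
}

# optimal global affine-gap alignment score by memoized recursion
# (penalty of a length-L gap run = gap_open + gap_extend * L)
oracle_global_score <- function(a, b, mat, gap_open, gap_extend) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, last) {
    key <- paste(i, j, last)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, mat[av[i], bv[j]] + rec(i + 1, j + 1, "M"))
    if (i <= n) {
      cost <- if (last == "U") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i + 1, j, "U"))
    }
    if (j <= m) {
      cost <- if (last == "L") gap_extend else gap_open + gap_extend
      best <- max(best, -cost + rec(i, j + 1, "L"))
    }
    memo[[key]] <- best
    best
  }
  rec(1, 1, "M")
}

# independent Balding-Nichols realized-Fst mean: fresh draws and an
# algebraically different Fst expression, (p1 - p2)^2 / (2 * Ht)
oracle_bn_mean_fst <- function(f, n1, n2, n_loci, p_range, seed) {
  set.seed(seed)
  p <- runif(n_loci, p_range[1], p_range[2])
  shape1 <- p * (1 - f) / f
  shape2 <- (1 - p) * (1 - f) / f
  p1 <- rbeta(n_loci, shape1, shape2)
  p2 <- rbeta(n_loci, shape1, shape2)
  x1 <- rbinom(n_loci, n1, p1) / n1
  x2 <- rbinom(n_loci, n2, p2) / n2
  pbar <- (x1 + x2) / 2
  ht <- 2 * pbar * (1 - pbar)
  fst <- ifelse(ht == 0, NA, (x1 - x2)^2 / (2 * ht))
  mean(fst, na.rm = TRUE)
}

# small convenience: gapless protein alignment of two equal-length CDSs
identity_alignment <- function(cds_a, cds_b) {
  list(a = sub("\\*$", "", translate_cds(cds_a)),
       b = sub("\\*$", "", translate_cds(cds_b)))
}
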