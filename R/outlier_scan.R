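# FDIST-style Fst-outlier detection: a Balding-Nichols two-population
# neutral null calibrated to the observed mean Fst by bisection, empirical
# heterozygosity-conditional 95%/99% envelopes, and outlier calls with
# special handling of fully fixed (Fst = 1) sites, which sit above any
# simulated quantile and are reported as "fixed" rather than as outliers.

#' Calibrate the neutral differentiation parameter to observed Fst
#'
#' Bisects the Balding-Nichols F parameter until the trimmed mean of
#' simulated per-site Fst matches the trimmed mean of the observed Fst
#' within `tol`. Simulation draws are generated by inverse transform from a
#' fixed set of uniforms (common random numbers), so the objective is a
#' deterministic, monotone function of F and the result is reproducible
#' given `seed`.
#'
#' @param observed_fst observed per-site Fst values (`NA`s dropped; at
#'   least 10 defined values required).
#' @param n1,n2 haplotype sample sizes used for the null draws.
#' @param trim lower/upper quantiles between which the trimmed mean is
#'   taken (default `c(0.05, 0.95)`).
#' @param tol convergence tolerance on the trimmed mean (default 1e-3).
#' @param max_iter bisection iterations before giving up (default 50).
#' @param n_sim loci per objective evaluation (default 5000).
#' @param p_anc_range ancestral-frequency range of the null.
#' @param seed integer seed.
#' @return calibrated F in (0, 1).
#' @export
calibrate_neutral_F <- function(observed_fst, n1, n2, trim = c(0.05, 0.95),
                                tol = 1e-3, max_iter = 50L, n_sim = 5000L,
                                p_anc_range = c(0.05, 0.95), seed = 1L) {
  obs <- observed_fst[!is.na(observed_fst)]
  if (length(obs) < 10L) stop("need at least 10 sites with defined Fst")
  trimmed_mean <- function(x) {
    q <- stats::quantile(x, trim, names = FALSE)
    mean(x[x >= q[1L] & x <= q[2L]])
  }
  target <- trimmed_mean(obs)
  # fixed uniforms for common-random-number draws
  u <- with_seed(seed, list(p = stats::runif(n_sim, p_anc_range[1L], p_anc_range[2L]),
                            u1 = stats::runif(n_sim), u2 = stats::runif(n_sim),
                            b1 = stats::runif(n_sim), b2 = stats::runif(n_sim)))
  objective <- function(f) {
    a1 <- u$p * (1 - f) / f; a2 <- (1 - u$p) * (1 - f) / f
    p1 <- stats::qbeta(u$u1, a1, a2)
    p2 <- stats::qbeta(u$u2, a1, a2)
    c1 <- stats::qbinom(u$b1, n1, p1)
    c2 <- stats::qbinom(u$b2, n2, p2)
    fst <- fst_site(c1 / n1, c2 / n2)
    fst <- fst[!is.na(fst)]
    trimmed_mean(fst)
  }
  lo <- 1e-4; hi <- 0.999
  if (objective(lo) >= target) return(lo)
  if (objective(hi) <= target) return(hi)
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    val <- objective(mid)
    if (abs(val - target) < tol) return(mid)
    if (val < target) lo <- mid else hi <- mid
  }
  stop("calibration did not converge after ", max_iter,
       " iterations (target ", signif(target, 4), ", last value ",
       signif(val, 4), ", bracket [", signif(lo, 4), ", ", signif(hi, 4), "])")
}

#' Simulate the neutral (He, Fst) null distribution
#'
#' Balding-Nichols draws at the calibrated F using the same Fst estimator
#' as the empirical data; monomorphic draws (Fst undefined) are discarded
#' and redrawn until `n_loci` polymorphic loci are obtained.
#'
#' @param f_star calibrated neutral F.
#' @param n_loci simulated polymorphic loci (10^4 or more recommended).
#' @param n1,n2 haplotype sample sizes.
#' @param p_anc_range ancestral-frequency range.
#' @param seed integer seed.
#' @return data frame with `he` (pooled expected heterozygosity
#'   `2 pbar (1 - pbar)`) and `fst`.
#' @export
simulate_null <- function(f_star, n_loci, n1, n2,
                          p_anc_range = c(0.05, 0.95), seed = 1L) {
  with_seed(seed, {
    he <- numeric(0); fst <- numeric(0)
    while (length(fst) < n_loci) {
      m <- max(1000L, ceiling((n_loci - length(fst)) * 1.3))
      p <- stats::runif(m, p_anc_range[1L], p_anc_range[2L])
      p1 <- rbn_freq(m, p, f_star)
      p2 <- rbn_freq(m, p, f_star)
      c1 <- stats::rbinom(m, n1, p1) / n1
      c2 <- stats::rbinom(m, n2, p2) / n2
      f <- fst_site(c1, c2)
      keep <- !is.na(f)
      pbar <- (c1 + c2) / 2
      he <- c(he, (2 * pbar * (1 - pbar))[keep])
      fst <- c(fst, f[keep])
    }
    data.frame(he = he[seq_len(n_loci)], fst = fst[seq_len(n_loci)])
  })
}

#' Build the heterozygosity-conditional quantile envelope
#'
#' Splits the simulated loci into equal-width He bins over the observed He
#' range and records the empirical 0.95 and 0.99 Fst quantiles per bin.
#' Bins with fewer than `min_per_bin` loci are merged with their neighbor
#' until the minimum is met, so the envelope is total over the He range.
#'
#' @param sims data frame from [simulate_null()].
#' @param n_he_bins initial number of He bins (default 20).
#' @param min_per_bin minimum simulated loci per bin (default 200).
#' @return list of class `null_envelope`: `breaks` (He bin edges), `q95`,
#'   `q99`, `n_per_bin`.
#' @export
build_envelope <- function(sims, n_he_bins = 20L, min_per_bin = 200L) {
  if (nrow(sims) < min_per_bin) stop("not enough simulated loci")
  breaks <- seq(0, max(sims$he) + 1e-9, length.out = n_he_bins + 1L)
  # merge sparse bins right-to-left until each holds min_per_bin
  repeat {
    idx <- findInterval(sims$he, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(idx, nbins = length(breaks) - 1L)
    sparse <- which(counts < min_per_bin)
    if (length(sparse) == 0L || length(breaks) <= 2L) break
    b <- sparse[1L]
    drop <- if (b == length(counts)) b else b + 1L   # merge with neighbor
    breaks <- breaks[-drop]
  }
  idx <- findInterval(sims$he, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  nb <- length(breaks) - 1L
  q95 <- vapply(seq_len(nb), function(b)
    stats::quantile(sims$fst[idx == b], 0.95, names = FALSE), numeric(1))
  q99 <- vapply(seq_len(nb), function(b)
    stats::quantile(sims$fst[idx == b], 0.99, names = FALSE), numeric(1))
  structure(list(breaks = breaks, q95 = q95, q99 = q99,
                 n_per_bin = tabulate(idx, nbins = nb)),
            class = "null_envelope")
}

#' Call Fst outliers against a null envelope
#'
#' Sites with Fst = 1 are reported as `fixed`: both populations are fixed
#' for opposite alleles, which no simulated neutral Fst can exceed, so the
#' envelope cannot rank them; they are treated as selected downstream.
#' Otherwise a site is `outlier99` above the 99% quantile of its He bin,
#' `outlier95` above the 95% quantile, else `neutral`. Sites with
#' undefined Fst get `NA`.
#'
#' @param sites data frame with `fst` and the frequency columns `p1`, `p2`
#'   (He is computed as `2 pbar (1 - pbar)`).
#' @param envelope a `null_envelope`.
#' @return the input with columns `he` and `status` appended.
#' @export
call_outliers <- function(sites, envelope) {
  pbar <- (sites$p1 + sites$p2) / 2
  he <- 2 * pbar * (1 - pbar)
  idx <- findInterval(he, envelope$breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  status <- rep(NA_character_, nrow(sites))
  def <- !is.na(sites$fst)
  status[def] <- "neutral"
  q95 <- envelope$q95[idx]; q99 <- envelope$q99[idx]
  status[def & sites$fst > q95] <- "outlier95"
  status[def & sites$fst > q99] <- "outlier99"
  status[def & sites$fst == 1] <- "fixed"
  out <- sites
  out$he <- he
  out$status <- status
  out
}
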