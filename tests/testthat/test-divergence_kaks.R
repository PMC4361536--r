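# NG86 counting, Jukes-Cantor correction, the Fisher test, divergence
# classification and sliding windows.

test_that("site counts match single-mutant enumeration on known codons", {
  expect_equal(ng86_site_counts("TTT"), c(s = 1 / 3, n = 8 / 3))
  expect_equal(ng86_site_counts("TGG"), c(s = 0, n = 3))
  expect_error(ng86_site_counts("TAA"), "stop codon")
  expect_error(ng86_site_counts("TNT"), "ambiguous")
})

test_that("pathway counts handle multi-step differences", {
  expect_equal(ng86_diff_counts("TTT", "TTT"), c(sd = 0, nd = 0))
  expect_equal(ng86_diff_counts("TTT", "TTA"), c(sd = 0, nd = 1))
  expect_equal(ng86_diff_counts("TTT", "GTA"),
               oracle_diff_counts("TTT", "GTA"))
  expect_equal(sum(ng86_diff_counts("TTT", "GTA")), 2)
})

test_that("site and pathway counts equal exhaustive enumeration at scale", {
  set.seed(101)
  codons <- setdiff(apply(expand.grid(c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T"),
                                      c("A", "C", "G", "T")), 1,
                          paste, collapse = ""), c("TAA", "TAG", "TGA"))
  for (cd in sample(codons, 61)) {
    expect_equal(ng86_site_counts(cd), oracle_site_counts(cd),
                 tolerance = 1e-12)
    expect_equal(sum(ng86_site_counts(cd)), 3)
  }
  for (i in 1:200) {
    pair <- sample(codons, 2, replace = TRUE)
    expect_equal(ng86_diff_counts(pair[1], pair[2]),
                 oracle_diff_counts(pair[1], pair[2]), tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction follows the closed form", {
  expect_equal(jukes_cantor(0), 0)
  expect_equal(jukes_cantor(0.3), -0.75 * log(0.6))
  expect_gt(jukes_cantor(0.3), 0.3)
  expect_error(jukes_cantor(0.75), "saturation")
})

test_that("kaks_pair sums counts over ungapped columns", {
  # identical alignment
  cds <- simulate_cds(30, 2)
  ca <- back_translate(identity_alignment(cds, cds), cds, cds)
  k <- kaks_pair(ca)
  expect_equal(c(k$Sd, k$Nd, k$Ka, k$Ks), c(0, 0, 0, 0))
  expect_true(is.nan(k$omega))
  expect_equal(k$S_sites + k$N_sites, 3 * k$n_codons_used)

  # hand-built 2-codon alignment: TTT/GCA vs TTA/GCC -> Nd = 1, Sd = 1
  k2 <- kaks_pair(list(codons_a = c("TTT", "GCA"), codons_b = c("TTA", "GCC")))
  expect_equal(k2$Nd, 1)
  expect_equal(k2$Sd, 1)
  s_exp <- (oracle_site_counts("TTT") + oracle_site_counts("GCA") +
              oracle_site_counts("TTA") + oracle_site_counts("GCC")) / 2
  expect_equal(k2$S_sites, unname(s_exp["s"]))
  expect_equal(k2$N_sites, unname(s_exp["n"]))

  # symmetry in every field
  k2r <- kaks_pair(list(codons_a = c("TTA", "GCC"), codons_b = c("TTT", "GCA")))
  expect_equal(unclass(k2), unclass(k2r))

  expect_error(kaks_pair(list(codons_a = "---", codons_b = "AAA")),
               "no usable")
})

test_that("the Fisher test equals the brute-force hypergeometric tail", {
  p <- fisher_positive_selection(list(Sd = 0, Nd = 5, S_sites = 100,
                                      N_sites = 300))
  expect_equal(p, oracle_hyper_tail(0, 5, 100, 300), tolerance = 1e-12)
  expect_equal(p, choose(300, 5) / choose(400, 5), tolerance = 1e-12)

  expect_lt(fisher_positive_selection(list(Sd = 0, Nd = 30, S_sites = 100,
                                           N_sites = 300)), 0.001)
  # no excess: symmetric table has p >= 0.5
  expect_gte(fisher_positive_selection(list(Sd = 4, Nd = 4, S_sites = 100,
                                            N_sites = 100)), 0.5)
  expect_error(fisher_positive_selection(list(Sd = 0, Nd = 0, S_sites = 10,
                                              N_sites = 10)), "no substitutions")
})

test_that("divergence classification follows the NSSG rule", {
  mk <- function(Sd, Nd, omega, p)
    list(Sd = Sd, Nd = Nd, omega = omega, fisher_p = p)
  expect_equal(classify_divergence(mk(0, 1, NaN, NA)), "NSSG")
  expect_equal(classify_divergence(mk(0, 2, NaN, 0.5)), "NSSG")
  expect_equal(classify_divergence(mk(0, 0, NaN, NA)), "not_significant")
  expect_equal(classify_divergence(mk(1, 30, 9.5, 1e-4)), "PSG_with_syn")
  expect_equal(classify_divergence(mk(1, 30, 9.5, 0.2)), "not_significant")
  expect_equal(classify_divergence(mk(5, 1, 0.1, 0.9)), "not_significant")
})

test_that("adding a nonsynonymous substitution never decreases Nd", {
  cds <- simulate_cds(60, 21)
  prev <- -1
  for (k in 0:4) {
    mut <- inject_substitutions(cds, k, 1, 77)
    ca <- back_translate(identity_alignment(cds, mut$cds), cds, mut$cds)
    nd <- kaks_pair(ca)$Nd
    expect_gte(nd, prev)
    prev <- nd
  }
})

test_that("sliding windows enumerate starts with an end-anchored tail", {
  cds <- simulate_cds(302, 31)             # 300 coding codons after stop strip
  ca <- back_translate(identity_alignment(cds, cds), cds, cds)
  expect_equal(length(ca$codons_a), 301)   # start..301 (stop stripped)
  sw <- sliding_window_scan(list(codons_a = ca$codons_a[1:300],
                                 codons_b = ca$codons_b[1:300]))
  expect_equal(sw$start_codon, c(0, 34, 68, 102, 136, 170, 200))
  expect_true(all(sw$end_codon - sw$start_codon == 100))

  # short alignment: one truncated window
  sw2 <- sliding_window_scan(list(codons_a = ca$codons_a[1:50],
                                  codons_b = ca$codons_b[1:50]))
  expect_equal(nrow(sw2), 1)
  expect_equal(sw2$end_codon, 50)
})

test_that("windows localize an injected selected segment", {
  cds <- simulate_cds(302, 41)
  codons <- split_codons(cds)
  # inject many nonsynonymous changes into codons 101..140 only
  seg <- strip_terminal_stop(cds)
  mut <- seg
  changed <- 0
  for (ci in 101:140) {
    from <- substring(mut, ci * 3 - 2, ci * 3)
    muts <- Filter(function(x) x != from & !(x %in% c("TAA", "TAG", "TGA")) &
                     psgscan::translate_cds(x) != psgscan::translate_cds(from),
                   sapply(c("A", "C", "G", "T"), function(b) {
                     y <- from; substr(y, 3, 3) <- b; y
                   }))
    if (length(muts) == 0) next
    substr(mut, ci * 3 - 2, ci * 3) <- muts[[1]]
    changed <- changed + 1
  }
  expect_gt(changed, 10)
  ca <- list(codons_a = split_codons(seg), codons_b = split_codons(mut))
  sw <- sliding_window_scan(ca, alpha = 0.05)
  inside <- sw$start_codon >= 100 - 60 & sw$start_codon <= 140
  hot <- sw$start_codon == 102            # fully inside the segment
  expect_true(all(sw$label[hot] == "NSSG"))
  expect_true(all(sw$Nd[sw$start_codon == 0] == 0))
})
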