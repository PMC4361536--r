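# Reciprocal best hits, pair-set merging, global alignment and the
# collinearity filter.

mk_hits <- function(q, s, bit, ev = 1e-30) {
  data.frame(query_id = q, subject_id = s, percent_id = 90, align_len = 100,
             mismatch = 0, gap_open = 0, q_start = 1, q_end = 100,
             s_start = 1, s_end = 100, evalue = ev, bitscore = bit,
             stringsAsFactors = FALSE)
}

test_that("reciprocal best hits keep only mutual bests", {
  ab <- rbind(mk_hits("a1", "b1", 200), mk_hits("a1", "b2", 100),
              mk_hits("a2", "b2", 200))
  ba <- rbind(mk_hits("b1", "a1", 200), mk_hits("b2", "a2", 200))
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh$gene_a, c("a1", "a2"))
  expect_equal(rbh$gene_b, c("b1", "b2"))

  # a1 -> b1 but b1's best is a2: a1 unpaired (a2 <-> b2 survives)
  ba2 <- rbind(mk_hits("b1", "a2", 300), mk_hits("b1", "a1", 200),
               mk_hits("b2", "a2", 100))
  rbh2 <- reciprocal_best_hits(ab, ba2)
  expect_false("a1" %in% rbh2$gene_a)
  expect_equal(rbh2$gene_a, "a2")
  expect_equal(rbh2$gene_b, "b2")
})

test_that("hit ties resolve by e-value then subject id, deterministically", {
  ab <- rbind(mk_hits("a1", "b2", 200, ev = 1e-10),
              mk_hits("a1", "b1", 200, ev = 1e-20))
  ba <- rbind(mk_hits("b1", "a1", 200), mk_hits("b2", "a1", 200))
  rbh <- reciprocal_best_hits(ab, ba)
  expect_equal(rbh$gene_b, "b1")           # smaller e-value wins
  ab2 <- rbind(mk_hits("a1", "b2", 200), mk_hits("a1", "b1", 200))
  rbh2 <- reciprocal_best_hits(ab2, ba)
  expect_equal(rbh2$gene_b, "b1")          # then lexicographic subject
})

test_that("RBH is symmetric under swapping the hit tables", {
  gp <- simulate_genome_pair(divergence_sim_config(n_genes = 15, seed = 9))
  fwd <- reciprocal_best_hits(gp$hits_ab, gp$hits_ba)
  swp <- reciprocal_best_hits(gp$hits_ba, gp$hits_ab)
  expect_setequal(paste(fwd$gene_a, fwd$gene_b),
                  paste(swp$gene_b, swp$gene_a))
})

test_that("pair sets merge with db1 precedence and crosswalk translation", {
  p1 <- data.frame(gene_a = c("a1", "a2", "a3"),
                   gene_b = c("b1", "b2", "b3"), stringsAsFactors = FALSE)
  p2 <- data.frame(gene_a = c("a4", "a5"), gene_b = c("x4", "x5"),
                   stringsAsFactors = FALSE)
  xw <- c(x4 = "b4", x5 = "b5")
  merged <- merge_pair_sets(p1, p2, xw)
  expect_equal(nrow(merged), 5)
  expect_equal(merged$gene_b[merged$gene_a == "a4"], "b4")

  # conflict: db1 kept
  p2c <- data.frame(gene_a = "a1", gene_b = "b9", stringsAsFactors = FALSE)
  expect_message(m2 <- merge_pair_sets(p1, p2c), "keeping db1")
  expect_equal(m2$gene_b[m2$gene_a == "a1"], "b1")

  # empty second set: first unchanged
  empty <- p2[0, ]
  expect_equal(merge_pair_sets(p1, empty)$gene_b, p1$gene_b)

  # crosswalk chains are rejected
  expect_error(merge_pair_sets(p1, p2, c(x4 = "x5", x5 = "b5")), "cycle")
})

test_that("global alignment matches a brute-force affine-gap oracle", {
  al <- global_align("MKV", "MKV")
  expect_equal(gsub("-", "", al$a), "MKV")
  expect_false(grepl("-", paste0(al$a, al$b)))

  al2 <- global_align("MKV", "MV")
  expect_equal(al2$a, "MKV")
  expect_equal(al2$b, "M-V")

  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(42)
  aas <- rownames(BLOSUM62)[1:20]
  for (i in 1:15) {
    a <- paste(sample(aas, sample(3:8, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(3:8, 1), replace = TRUE), collapse = "")
    got <- global_align(a, b)$score
    want <- oracle_global_score(a, b, BLOSUM62, 10, 0.5)
    expect_equal(got, want, tolerance = 1e-9)
  }

  expect_error(global_align("MKO", "MK"), "illegal residue")
})

test_that("percent identity uses co-aligned columns only", {
  expect_equal(percent_identity(list(a = "MKVLAAGHTW", b = "MKVLAAGHTW")), 1)
  expect_equal(percent_identity(list(a = "MKVLAAGHTW", b = "MKVLAAGHTY")), 0.9)
  expect_equal(percent_identity(list(a = "MKVL--AAGH", b = "MKVLXXAAGH")), 1)
  # invariant to appending gap-only-in-one columns
  expect_equal(percent_identity(list(a = "MKVLAAGH--", b = "MKVLAAGHTW")), 1)
  expect_error(percent_identity(list(a = "---", b = "MK-")), "co-aligned")
})

test_that("collinearity filter removes translocated singletons", {
  n <- 21
  mk_models <- function(ids, chrom) {
    ms <- lapply(seq_along(ids), function(i)
      gene_model(ids[i], chrom[i], "+", rbind(c(i * 1000, i * 1000 + 300))))
    names(ms) <- ids
    ms
  }
  ids_a <- sprintf("a%02d", 1:n)
  ids_b <- sprintf("b%02d", 1:n)
  chrom_b <- rep("chrB1", n)
  chrom_b[11] <- "chrB2"                      # one translocated partner
  models_a <- mk_models(ids_a, rep("chrA1", n))
  models_b <- mk_models(ids_b, chrom_b)
  pairs <- data.frame(gene_a = ids_a, gene_b = ids_b, stringsAsFactors = FALSE)
  kept <- collinearity_filter(pairs, models_a, models_b)
  expect_false("a11" %in% kept$gene_a)
  expect_equal(nrow(kept), n - 1)

  # fully collinear: everything kept, including chromosome ends
  models_b2 <- mk_models(ids_b, rep("chrB1", n))
  expect_equal(nrow(collinearity_filter(pairs, models_a, models_b2)), n)
})
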