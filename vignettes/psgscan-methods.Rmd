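---
title: "Methods: detecting positively selected genes between diverging rice populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting positively selected genes between diverging rice populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`psgscan` identifies protein-coding genes under positive selection during
the differentiation of two closely related populations — the motivating
case is the *indica* / temperate-*japonica* split in Asian rice, where one
fully sequenced genome represents each subspecies and a large resequencing
panel provides per-accession SNPs. Two lines of evidence are combined: the
divergence between one ortholog pair per gene, and the allele-frequency
differentiation of SNPs segregating in the two populations.

## Divergence evidence: NG86 Ka/Ks

For each ortholog pair, a global protein alignment is back-translated onto
the CDSs and the Nei–Gojobori (1986) counting method is applied to the
fully ungapped codon columns:

* **Sites.** Each codon contributes synonymous sites `s = (number of the 9
  single-base changes that are silent)/3` and `n = 3 − s`; changes to a
  stop codon count as nonsynonymous. Site counts are averaged over the two
  sequences, so `S + N = 3 × (codons used)` exactly.
* **Substitutions.** A codon pair differing at `k` positions is scored by
  averaging the synonymous/nonsynonymous step counts over all `k!`
  orderings of the single-base steps. Orderings passing through a stop
  codon are excluded; if every ordering does, all are used with the
  stop-involving steps counted as nonsynonymous. This is the common
  convention among NG86 implementations; the choice only matters for the
  rare multi-hit codons.
* **Distances.** `pS = Sd/S` and `pN = Nd/N` are Jukes–Cantor corrected,
  `d = −(3/4)·log(1 − 4p/3)`; `p ≥ 0.75` is reported as saturated (`NA`)
  rather than extrapolated. `Ka/Ks` is `NaN` when `Ks = 0`: a ratio with a
  zero denominator is not a number, and the zero-synonymous case gets its
  own class below. (Plotting exports may recode the both-zero case as 0;
  the analysis tables never do.)
* **Significance.** A one-sided Fisher exact test asks whether
  nonsynonymous substitutions are over-represented: the 2×2 table has rows
  (synonymous, nonsynonymous) and columns (substitutions, sites −
  substitutions). Real-valued NG86 counts are rounded half-up to integers
  because the exact test needs integer margins; the p-value is the
  hypergeometric tail toward an excess of nonsynonymous substitutions.

A gene pair with `Sd = 0` and `Nd > 0` is a **nonsynonymous substitution
gene (NSSG)** regardless of the Fisher p-value — with no synonymous signal
the ratio test is powerless, yet these genes are exactly where a short
burst of adaptive change looks like. Pairs with `Sd > 0`, `Ka/Ks > 1` and
a significant Fisher test are PSGs with synonymous substitutions; at the
divergence scale of two rice subspecies these are rare, and NSSGs carry
the analysis. Only NG86 is implemented: downstream analysis depends only
on the `(Sd = 0, Nd > 0)` call, and whether a substitution at a distinct
codon is synonymous is estimator-independent, so the approximate-method
variants (YN, MYN and friends) would not change the gene set that moves
forward.

A sliding-window scan (defaults: 100 codon columns, shift 34, windows with
≥ 50% gap columns dropped) localizes selection inside long alignments. The
final window is anchored at the alignment end rather than dropping the
tail; a window shorter than the alignment is not extended, so short
alignments yield one truncated window.

## Orthology

Ortholog pairs come from 12-column tabular similarity hits in both
directions: a pair is kept iff each gene is the other's best hit (maximum
bit score, ties by minimum e-value then lexicographic subject id —
deterministic by construction). Pair sets from two annotation systems are
merged by union with the first system taking precedence on conflicts,
after identifier translation through a crosswalk. A neighbor-vote
collinearity filter (defaults: 10 nearest paired neighbors, 3 must agree
on the partner chromosome, scaled down near chromosome ends) stands in for
the manual collinear-region curation used with real genomes: it is a
deterministic, testable proxy. Percent identity is computed over
co-aligned (both non-gap) columns; the full-alignment-length denominator
is a defensible alternative, but the co-aligned convention is used
throughout. Alignment itself is standard Needleman–Wunsch with BLOSUM62
and affine gaps (open 10, extend 0.5), and externally produced alignments
can be substituted at scale.

## Population evidence: Fst outliers

SNPs are annotated against gene models by rebuilding the affected codon
with the alternate allele, strand-aware: synonymous, nonsynonymous,
nonsense (to a stop), splice-altering (the two intronic bases flanking an
exon boundary) or noncoding. A reference-allele mismatch against the
genome is an error, not a silent skip. Missing genotype calls are excluded
from both the allele count and the total; heterozygous calls in the
(inbred) accessions are treated as missing in genotype matrices.

Per-site differentiation uses the unweighted Nei/Wright estimator
`Fst = (Ht − Hs)/Ht` with `Ht = 2·p̄(1−p̄)`, `p̄ = (p1+p2)/2`, undefined for
sites monomorphic in the pooled sample. The same estimator — the same
code path — is applied to observed and simulated data, which is what makes
the outlier envelope meaningful. A Weir–Cockerham variant is available
behind a switch for sensitivity analysis.

The neutral null is a two-deme Balding–Nichols model: ancestral frequency
`p ~ U(0.05, 0.95)`, population frequencies
`p_i ~ Beta(p(1−F)/F, (1−p)(1−F)/F)`, binomial sampling at the study's
haplotype counts. The original analyses used Lositan's fdist machinery,
whose island-model parameters are not recoverable from the publication;
replacing it with a calibrated Balding–Nichols null preserves the method's
contract — a heterozygosity-conditional neutral Fst envelope — while being
fully specified and desk-scale. This is the package's largest declared
deviation from the original tooling. `F` is calibrated by bisection until
the trimmed mean (5%–95%) of simulated Fst matches that of the observed
Fst within 1e-3; the objective uses common random numbers (inverse-
transform draws from fixed uniforms), making it deterministic and monotone
in `F`, so bisection converges reliably and the result is reproducible
from the seed. The envelope takes empirical 0.95/0.99 Fst quantiles in 20
equal-width bins of pooled expected heterozygosity, merging sparse bins
(< 200 simulated loci) with their neighbors. Monomorphic null draws are
discarded and redrawn — a monomorphic locus is not a SNP.

Sites with `Fst = 1` are reported as **fixed**, not as outliers: one is
the largest value the statistic can take, so no simulated neutral Fst can
exceed it and the envelope cannot rank it. Fixed sites are treated as
selected downstream.

## Gene-level verdicts

Within each gene, only exonic sites with `Fst ≥ 0.25` are considered —
the working threshold separating differentiated from background sites. In
order:

1. all considered sites nonsynonymous/nonsense/splice and at least one
   with outlier status (95%, 99% or fixed) → **PSG**;
2. exactly one considered synonymous site, at least one nonsynonymous
   outlier, and the synonymous Fst not above the best nonsynonymous
   outlier's Fst *or* a stop-gained site 5′ of it in coding order →
   **PSG candidate** under the synonymous-site exception (the premature
   stop makes downstream "synonymous" changes moot);
3. otherwise a synonymous outlier flags possible **hitchhiking**;
4. otherwise **not selected**.

"5′ of it" is interpreted in coding (CDS) order, strand-aware. The
comparator in rule 2 is required to be an outlier site, the stricter of
the two readings of the original phrasing. Nonsynonymous outlier
substitutions are summarized by amino-acid R-group using a five-class
side-chain scheme (nonpolar-aliphatic, aromatic, polar-uncharged,
positive, negative — configurable, since no published scheme is named),
with proline-involving, stop-gained and splice-altering counts reported
separately.

## Selected-site phylogeny

Accessions are compared at the selected (outlier or fixed nonsynonymous)
sites by simple-matching distance — the fraction of mismatching calls over
sites called in both accessions, with a minimum overlap of 10 co-called
sites — and joined by Saitou–Nei neighbor joining implemented in the
package: Q-matrix joins, ties broken by the smallest index pair, negative
branch lengths clamped to zero with the deficit moved to the sister
branch. On additive distances NJ recovers the generating topology and path
lengths exactly, which the tests exercise, and random matrices are
cross-checked against the classical implementation in `ape`. Group-level
differentiation (e.g. wild-rice subgroups) is summarized as the mean
per-site Fst between each group pair over the same sites, after dropping
sites missing in more than 20% of any group.

## The synthetic-data generators

Because the real genomes and the 4-million-SNP panel are not shipped,
every stage is exercised on synthetic data with known truth:

* `simulate_genome_pair()` builds one chromosome per genome, genes of
  100–300 codons in 1–3 exons on alternating strands, and derives the
  second genome by injecting exact numbers of synonymous and nonsynonymous
  single-base substitutions at distinct codons (never creating or
  destroying a stop). Distinct-codon placement makes NG86 pathway
  averaging exact, so recovery tests can demand equality, not closeness;
  same-codon double hits are available for stress tests. Defaults mirror
  the empirical regime: ~30% identical pairs and ~10% NSSGs carrying one
  or two nonsynonymous changes.
* `simulate_population_snps()` draws Balding–Nichols frequencies
  (defaults: F = 0.1 neutral, 0.95 selected; 520 and 409 haplotypes,
  matching the sizes of the two subspecies panels) and binomial counts.
* `simulate_snp_study()` anchors SNPs in an annotated genome: half the
  genes selected (the published chromosome-1 candidate set is ~55%
  positive, so a high positive rate is the realistic regime), two
  near-fixed nonsynonymous SNPs per selected gene, two neutral exonic
  SNPs per gene on average, the rest noncoding, 2% missing calls. Sites
  monomorphic in the sampled panel are redrawn: a SNP table by definition
  contains segregating sites, and without this ascertainment a selected
  gene whose loci happened to fix the same allele in both populations
  would be unobservable rather than undetected.

What the generators do **not** emulate: linkage and recombination (loci
are independent, so hitchhiking appears only if injected), demographic
history, genotyping error beyond uniform missingness, annotation errors,
and multi-deme structure. Passing tests therefore demonstrate the
statistical machinery under its own model assumptions — calibration of the
null, power at strong differentiation, exact count recovery — not
robustness to the full messiness of real resequencing data.

## Numerical choices and problem sizes

Randomness always flows from explicit integer seeds; the pipeline derives
per-stage seeds from one master seed by stable hashing, and reruns with
the same configuration are byte-identical (manifests deliberately record
no timestamps). Fisher tables round half-up; quantiles are the default
empirical (type-7) quantiles; `NaN`/`NA` conventions are stated on each
function. The bundled test and acceptance workloads use desk-scale sizes
chosen to estimate each quantity with adequate precision: 5,000 observed
loci and 20,000 null simulations for the calibration check (binomial
standard error ≈ 0.0014 on a 1% rate), 2,000 loci for power, 200 genes
for count recovery, and a 50-gene / 2,000-SNP toy pipeline; all complete
in well under a minute each on one core.

## Known limitations

* NG86 only; codon-frequency and transition-bias corrections (YN/MYN) and
  likelihood branch/site models are out of scope.
* The gene-averaged Ka/Ks test is weak when selection touches a few sites
  of a long, conserved protein — the NSSG route exists precisely because
  of this, and the sliding-window scan only partly compensates.
* The two-deme Balding–Nichols null ignores population substructure and
  linkage; outlier rates are calibrated under that model only.
* Indels and presence/absence variation are invisible to every statistic
  here.
* The synonymous-site exception admits genes on an argument (premature
  stop upstream) that annotation errors can also produce; verdicts carry
  the rule that fired so such genes can be audited.
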