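---
title: "Co-segregation scanning of regulatory SNPs: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-segregation scanning of regulatory SNPs: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsnpcoseg)
```

## The problem

Most GWAS index SNPs are non-coding, and a regulatory SNP (rSNP) — a variant
with evidence of allele-specific effects on transcription-factor binding or
expression — is rarely the catalogued index SNP itself. `rsnpcoseg`
implements a post-GWAS prioritization strategy: given a panel of individual
genomes, find the coding SNPs whose minor alleles travel together with a
query rSNP across individuals ("co-segregating markers"), then declare an
rSNP functionally relevant to a disease domain when the rSNP itself, or one
of its markers, falls within a fixed genomic window of a trait-matched GWAS
signal.

## The co-segregation statistic

Genotypes are binarized per variant against the panel-wide allele
frequencies: the most frequent allele codes 0, the minor allele 1 (ties at
frequency 0.5 orient the ALT allele as minor, so orientation is
deterministic). Two coding modes are supported, because a diploid genotype
does not collapse to one bit in a unique way:

* **carrier** (default): one row per individual, coded 1 iff it carries at
  least one copy of the minor allele. This is the only collapse that keeps
  heterozygotes informative while producing a single bit per individual.
* **haplotype**: one row per phased haplotype (twice the rows), coded by the
  allele it carries. Requires phased input; unphased records are a fatal
  error directing the user to carrier mode.

Missing genotype calls are imputed to the major allele (code 0) and counted.
This biases *against* calling co-segregation, which is the conservative
direction for a prioritization screen.

For a query rSNP $a$ and a candidate marker $b$ with binary code vectors over
$n$ rows, the distance is the XOR (Hamming) count
$d(a,b) = \#\{i : a_i \ne b_i\}$. With minor-allele counts $m_a$, $m_b$ and
carrier overlap $k$, $d = m_a + m_b - 2k$. The raw distance is normalized by
minor-allele occurrence; the default **union** mode divides by
$|a \cup b| = m_a + m_b - k$, giving the Jaccard distance on carrier sets —
the only normalization bounded in $[0,1]$ whose zero is attained exactly at
perfect co-segregation of non-empty carrier sets. `min_mac`, `max_mac` and
`sum_mac` denominators are selectable for sensitivity analysis; downstream
calling uses p-values only, so the choice does not affect which markers are
called.

## The null model

Under random assortment of carriers with both margins fixed, the overlap $k$
is exactly $\mathrm{Hypergeometric}(n, m_a, m_b)$. Because small XOR distance
is equivalent to large overlap, the one-sided p-value toward co-segregation
is

$$p = P(d \le d_{obs}) = P\!\left(k \ge \tfrac{m_a + m_b - d_{obs}}{2}\right),$$

computed with `phyper`. The test is one-sided deliberately: the screen
targets co-segregation, not anti-segregation. A seeded permutation test
(uniform re-ordering of one vector, add-one estimator
$p = (1 + \#\{d_{perm} \le d_{obs}\})/(1+B)$) is available both as an
assumption-free alternative and as the independent cross-check used by the
test suite; the two agree within Monte-Carlo error.

Markers are called co-segregating at $p < \alpha$ with $\alpha = 0.01$ by
default, raw and uncorrected, which mirrors how such genome-scale screens
are usually reported; Benjamini–Hochberg FDR adjustment is one option away
(`multiple_testing = "benjamini_hochberg"`) and is what the packaged
synthetic end-to-end configuration uses (see below).

Two numerical caveats are worth stating plainly:

* **Discreteness.** The hypergeometric tail is a step function, so the test
  is *valid but conservative*: the realized type-I error at $\alpha = 0.01$
  sits slightly below 0.01 (typically 0.006–0.008 at $n = 500$ with carrier
  frequencies 0.05–0.5, as the acceptance script reports under
  `type_i_error_rate_at_alpha_0.01`). A two-sided calibration band around
  the nominal level can therefore flag the test as under-rejecting; this is
  a property of every exact discrete test, not an implementation artifact.
* **Population structure.** The null fixes margins within the whole panel;
  individuals from frequency-diverged strata violate it and inflate calls
  between stratified variant pairs, exactly as in the real multi-population
  panels this design emulates. The engine makes no structure correction —
  the method is a physical-proximity screen, not an association test — but
  the synthetic generator deliberately reproduces the phenomenon so its
  consequences are visible in testing.

Monomorphic columns (mac = 0) are retained in the matrix but excluded from
testing: all distances to an all-zero vector are degenerate. Pairs whose
normalization denominator is zero are excluded with reason "degenerate
pair". Ranked outputs sort by (p-value, normalized distance, marker id) so
ties never make output order depend on input order.

## GWAS window mapping

A GWAS-catalog-style table is filtered by a trait keyword signature — by
default the twelve cardiovascular terms (heart, coronary artery disease,
CAD, platelet, blood, blood cells, pressure, count, vessel, caliber, pulse,
artery) — matched case-insensitively on word boundaries, so "CAD" cannot
match inside "decade". Multi-SNP catalog rows are split on `;`/`x`
separators; rows without parseable coordinates are dropped and counted,
since positions drive everything downstream.

An rSNP is linked to a GWAS SNP when either lies within `half_window` bp
(closed bounds, same chromosome, `chr` prefixes stripped). The default
`half_window = 5000` reads "a 10 Kbp window" as total width centered at the
GWAS SNP; the one-sided reading is available by passing
`half_window = 10000`. A direct positional hit always dominates a marker
link for the same (rSNP, GWAS SNP) pair; otherwise the closest called marker
inside the window is reported, with marker-id tie-breaking. The
implementation uses interval overlap (`GenomicRanges`), and the test suite
holds it equal to a brute-force all-pairs scan including exact boundary
cases at $|\Delta| = $ `half_window`.

## What the synthetic generator emulates — and what it does not

`generate_panel()` produces a complete, seeded input bundle: a phased
diploid VCF, a BED gene annotation, an rSNP query list, a GWAS-dialect trait
table and a JSON truth file. Its default scales were chosen once as a
desk-scale emulation of a multi-population reference panel: 500 individuals
in 4 strata, 2,000 background SNPs in 40 genes, 20 query rSNPs of which 10
carry a planted coding marker (flip probability 0, allele frequency 0.25,
rSNP placed 3 kb upstream of its marker's gene), 60 GWAS rows of which 60%
match the cardiovascular signature and half of those fall within the 5 kb
half-window of a planted rSNP or marker.

Design choices that matter:

* **Allele frequencies** follow a Balding–Nichols model: an ancestral
  Beta(1.5, 6) draw (mean ≈ 0.2, right-skewed like site-frequency spectra)
  diverged per population with $F_{st} = 0.1$, of the order of human
  super-population differentiation. Planted rSNPs use one shared frequency
  across strata so the planted signal is structure-free.
* **Background SNPs are in linkage equilibrium** given the stratum: the
  statistics need a clean null plus planted signal, not a realistic LD
  landscape. Consequently the generator does *not* exercise haplotype-block
  LD, recombination maps or coalescent genealogies — passing tests say the
  engine recovers planted carrier-pattern identity against an LE background,
  not that it resolves real LD structure.
* **Planted markers copy the rSNP's phased haplotypes** with a per-haplotype
  flip probability $\varepsilon$, so $\varepsilon = 0$ yields identical
  genotype columns under either coding mode and increasing $\varepsilon$
  degrades co-segregation monotonically.
* **Geometric isolation.** Each planted pair lives in its own neighborhood
  100 kb from the next; off-window GWAS rows live in an empty region. No
  GWAS window therefore contains a SNP that was not deliberately planted,
  which is what makes exact truth comparison meaningful.
* **Diploid genotypes** pair two independent haploid draws at the stratum
  frequency (Hardy–Weinberg), so carrier and haplotype coding are both
  exercised.

The packaged end-to-end configuration (`default_synthetic_pipeline()`) calls
markers with Benjamini–Hochberg at $\alpha = 0.01$ rather than raw p-values:
the default panel tests ~40,000 rSNP–marker pairs, and with a raw 1%
threshold the expected handful of chance calls would occasionally place a
spurious marker link inside a planted GWAS window, making exact
truth-file comparison a coin flip rather than a test of the code. FDR
control keeps the called set equal to the planted set with high probability
while exercising the same code paths. Analyses of user data default to raw
$p < 0.01$ calling.

## Problem sizes used in testing

The test suite runs the distance-metric axioms on 1,000 random triples
(n = 200), oracle agreement on 50 pairs × 10,000 permutations, calibration
on 10,000 null pairs (n = 500), recovery of 50 planted pairs among 5,000
background SNPs (n = 500, carrier frequency 0.1, minimum carrier count 25)
with a power curve over $\varepsilon \in \{0, 0.05, 0.1, 0.2\}$ × 20
replicates, window-scan equivalence on 1,000 random positions, and two full
end-to-end synthetic runs compared file-by-file. These sizes were chosen as
the smallest at which each property is statistically meaningful.

## Known limitations

* The co-segregation p-value is a screening statistic, not an LD estimate:
  no $r^2$/$D'$ is computed, and no structure or kinship correction is
  applied.
* Only biallelic SNVs are analyzed; multi-allelic records are skipped, not
  decomposed.
* The window link is purely physical; an rSNP in long-range LD with a GWAS
  SNP beyond the window is invisible to it.
* Under carrier coding, `mac/n` is a carrier fraction, which exceeds the
  allele frequency; the variant table therefore reports `maf` from allele
  counts (always ≤ 0.5) alongside the coding-dependent `mac`.
```
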