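write_catalog <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("SNPS\tCHR_ID\tCHR_POS\tDISEASE/TRAIT\tMAPPED_GENE", rows), f)
  f
}

test_that("GWAS catalog dialect parses, skipping rows without coordinates", {
  f <- write_catalog(c(
    "rs1\t1\t1000\tSystolic blood pressure\tGENE1",
    "rs2\t2\t2000\tHeight\tGENE2",
    "rs3\t1\t\tPlatelet count\tGENE3",
    "rs4\tX\t4000\tCoronary artery disease\tGENE4, GENE5",
    "rs5\t3\t5000\tResting heart rate\t"))
  g <- load_gwas_table(f)
  expect_equal(nrow(g), 4L)
  expect_equal(attr(g, "n_skipped"), 1L)
  expect_equal(g$pos[g$gwas_snp_id == "rs4"], 4000L)
  expect_equal(g$mapped_genes[[which(g$gwas_snp_id == "rs4")]], c("GENE4", "GENE5"))
})

test_that("multi-SNP rows expand into entries sharing the trait", {
  f <- write_catalog("rs123; rs456\t1; 1\t100; 200\tPulse pressure\tG1")
  g <- load_gwas_table(f)
  expect_equal(g$gwas_snp_id, c("rs123", "rs456"))
  expect_equal(g$pos, c(100L, 200L))
  expect_equal(unique(g$trait), "Pulse pressure")

  # interaction rows split on the 'x' separator
  f2 <- write_catalog("rs7 x rs8\t2; 2\t10; 20\tBlood protein levels\tG")
  g2 <- load_gwas_table(f2)
  expect_equal(g2$gwas_snp_id, c("rs7", "rs8"))
})

test_that("missing mandatory columns are fatal and named", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("SNPS\tCHR_ID\tDISEASE/TRAIT", "rs1\t1\tHeight"), f)
  expect_error(load_gwas_table(f), "CHR_POS")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("foo\tbar", "1\t2"), f2)
  expect_error(load_gwas_table(f2), "snp")
})

test_that("generic minimal header is accepted", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("snp\tchrom\tpos\ttrait\tgenes",
               "rs9\tchr7\t700\tRetinal vessel caliber\tA;B"), f)
  g <- load_gwas_table(f)
  expect_equal(g$chrom, "7") # chr prefix stripped
  expect_equal(g$mapped_genes[[1]], c("A", "B"))
})

test_that("signature filtering matches terms on word boundaries, case-insensitively", {
  entries <- data.frame(
    gwas_snp_id = paste0("rs", 1:5), chrom = "1", pos = 1:5 * 100,
    trait = c("Systolic blood pressure", "Height", "Platelet count",
              "Decade of menopause onset", "CAD severity"),
    stringsAsFactors = FALSE)
  entries$mapped_genes <- I(rep(list(character()), 5))
  out <- filter_by_signature(entries)
  expect_setequal(out$gwas_snp_id, c("rs1", "rs3", "rs5"))
  expect_true(all(c("blood", "pressure") %in% out$matched_terms[[1]]))
  expect_true(all(c("platelet", "count") %in%
                    out$matched_terms[[which(out$gwas_snp_id == "rs3")]]))
  # 'CAD' must not match inside 'Decade'
  expect_false("rs4" %in% out$gwas_snp_id)
  expect_true(all(lengths(out$matched_terms) > 0))
  expect_error(filter_by_signature(entries, character()), "empty")
})

make_assoc_inputs <- function() {
  gwas <- data.frame(
    gwas_snp_id = c("g1", "g2", "g3"), chrom = c("1", "1", "2"),
    pos = c(1000000L, 1000000L, 500000L),
    trait = "Systolic blood pressure", stringsAsFactors = FALSE)
  rsnps <- data.frame(rsnp_id = c("r1", "r2"), chrom = c("1", "1"),
                      pos = c(1000000L, 1020000L), stringsAsFactors = FALSE)
  coseg <- data.frame(
    rsnp_id = c("r2", "r2", "r1"),
    marker_id = c("mA", "mB", "mC"),
    marker_chrom = c("1", "1", "2"),
    marker_pos = c(1004999L, 1003000L, 500000L),
    cosegregating = c(TRUE, TRUE, TRUE), stringsAsFactors = FALSE)
  list(gwas = gwas, rsnps = rsnps, coseg = coseg)
}

test_that("window links prefer direct hits and the closest called marker", {
  x <- make_assoc_inputs()
  out <- window_intersect(x$gwas, x$rsnps, x$coseg, half_window = 5000)
  d <- out[out$rsnp_id == "r1" & out$gwas_snp_id == "g1", ]
  expect_equal(d$link_type, "direct")
  expect_equal(d$bp_distance, 0L) # exact positional coincidence
  # r1 also has a via link on chromosome 2
  expect_equal(out$link_type[out$gwas_snp_id == "g3"], "via_marker")
  # r2 is 20 kb away: linked only via its closest marker (mB at 3000 bp)
  v <- out[out$rsnp_id == "r2" & out$gwas_snp_id == "g1", ]
  expect_equal(v$link_type, "via_marker")
  expect_equal(v$marker_id, "mB")
  expect_equal(v$bp_distance, 3000L)
  # one association per (rSNP, GWAS SNP) pair
  expect_false(any(duplicated(out[, c("rsnp_id", "gwas_snp_id")])))
})

test_that("window bounds are closed at exactly half_window", {
  gwas <- data.frame(gwas_snp_id = "g", chrom = "1", pos = 1000000L,
                     trait = "Blood protein levels", stringsAsFactors = FALSE)
  for (case in list(c(1004999, TRUE), c(1005000, TRUE), c(1005001, FALSE))) {
    rs <- data.frame(rsnp_id = "r", chrom = "1", pos = case[1])
    out <- window_intersect(gwas, rs, NULL, half_window = 5000)
    expect_equal(nrow(out) == 1L, as.logical(case[2]))
  }
})

test_that("window scan is invariant to input row order and matches brute force", {
  set.seed(13)
  gwas <- data.frame(
    gwas_snp_id = paste0("g", 1:80),
    chrom = sample(c("1", "2"), 80, TRUE),
    pos = sample.int(2e5, 80), trait = "Pulse pressure", stringsAsFactors = FALSE)
  rsnps <- data.frame(rsnp_id = paste0("r", 1:30),
                      chrom = sample(c("1", "2"), 30, TRUE),
                      pos = sample.int(2e5, 30), stringsAsFactors = FALSE)
  coseg <- data.frame(
    rsnp_id = sample(rsnps$rsnp_id, 60, TRUE),
    marker_id = paste0("m", 1:60),
    marker_chrom = sample(c("1", "2"), 60, TRUE),
    marker_pos = sample.int(2e5, 60),
    cosegregating = sample(c(TRUE, FALSE), 60, TRUE), stringsAsFactors = FALSE)
  hw <- 4000
  ref <- brute_force_window(gwas, rsnps, coseg[coseg$cosegregating, ], hw)
  out <- window_intersect(gwas, rsnps, coseg, half_window = hw)
  expect_equal(sort_assoc(out), sort_assoc(ref))
  shuffled <- window_intersect(gwas[sample.int(80), ], rsnps[sample.int(30), ],
                               coseg[sample.int(60), ], half_window = hw)
  expect_identical(out, shuffled)
})

test_that("candidate summaries tally rSNPs, direct links and multi-target genes", {
  s0 <- summarize_candidates(window_intersect(
    data.frame(gwas_snp_id = character(), chrom = character(), pos = integer(),
               trait = character()), data.frame(rsnp_id = "r", chrom = "1", pos = 1L)))
  expect_equal(s0$totals$n_candidate_rsnps, 0L)
  expect_equal(s0$totals$n_associations, 0L)

  assoc <- data.frame(
    rsnp_id = c("r1", "r2", "r3", "r4", "r5"),
    gwas_snp_id = paste0("g", 1:5),
    link_type = c("direct", "direct", "direct", "via_marker", "via_marker"),
    marker_id = c(NA, NA, NA, "m4", "m5"),
    bp_distance = c(0L, 10L, 20L, 30L, 40L),
    chrom = "1", pos_gwas = 1:5 * 1000L,
    trait = "Platelet count", target_genes = c("A,B", "C", "", "D", ""),
    stringsAsFactors = FALSE)
  queries <- data.frame(rsnp_id = c("r1", "r2"),
                        target_genes = I(list(c("A", "B"), "C")))
  s <- summarize_candidates(assoc, queries)
  expect_equal(s$totals$n_candidate_rsnps, 5L)
  expect_equal(s$totals$n_direct_rsnps, 3L)
  expect_equal(s$totals$n_via_rsnps, 2L)
  expect_equal(s$totals$n_multi_target, 1L) # only r1 maps to two genes
})

test_that("signature filtering and window intersection commute", {
  x <- make_assoc_inputs()
  x$gwas$trait <- c("Systolic blood pressure", "Height", "Platelet count")
  filtered_first <- window_intersect(filter_by_signature(x$gwas), x$rsnps,
                                     x$coseg, half_window = 5000)
  intersect_first <- window_intersect(x$gwas, x$rsnps, x$coseg, half_window = 5000)
  keep <- intersect_first$gwas_snp_id %in%
    filter_by_signature(x$gwas)$gwas_snp_id
  expect_equal(sort_assoc(filtered_first), sort_assoc(intersect_first[keep, ]))
})
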