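#' Load a diploid variant panel from VCF
#'
#' Reads a VCF 4.x file (plain or bgzipped) with per-individual GT fields and
#' retains biallelic SNV records only. Multi-allelic and non-SNV records
#' (indels, symbolic alleles) are skipped and counted.
#'
#' @param vcf_path Path to a VCF file.
#' @param regions Optional interval restriction: a `GRanges` or a data frame
#'   with columns `chrom`, `start`, `end` (1-based, closed). Only variants
#'   whose position falls inside at least one interval are retained.
#' @return An object of class `coseg_panel`: a list with
#'   * `variants` — data frame with one row per retained record
#'     (`variant_id`, `chrom`, `pos`, `ref_allele`, `alt_allele`),
#'   * `gt` — character matrix of GT strings (variants x individuals),
#'   * `individual_ids` — column names of `gt`,
#'   * `n_skipped` — count of records dropped by the biallelic-SNV filter.
#'   `variant_id` is the VCF ID when present, else `chrom:pos:ref:alt`.
#' @examples
#' vcf <- system.file("extdata", "toy_panel.vcf", package = "rsnpcoseg")
#' p <- load_panel(vcf)
#' p$variants
#' @export
load_panel <- function(vcf_path, regions = NULL) {
  if (!file.exists(vcf_path)) stopf("VCF file not found: %s", vcf_path)
  vcf <- tryCatch(
    vcfR::read.vcfR(vcf_path, verbose = FALSE),
    error = function(e) stopf("malformed VCF '%s': %s", vcf_path, conditionMessage(e))
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- norm_chrom(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  id <- fix[, "ID"]

  nuc <- c("A", "C", "G", "T")
  keep <- !is.na(alt) & ref %in% nuc & alt %in% nuc
  n_skipped <- sum(!keep)
  if (!any(keep)) stopf("zero variants retained from '%s' after the biallelic-SNV filter", vcf_path)

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  if (ncol(gt) == 0L) stopf("VCF '%s' carries no genotype columns", vcf_path)

  chrom <- chrom[keep]; pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  id <- id[keep]; gt <- gt[keep, , drop = FALSE]

  if (!is.null(regions)) {
    gr <- as_granges_regions(regions)
    vr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
    inside <- IRanges::overlapsAny(vr, gr)
    if (!any(inside)) stopf("zero variants inside the requested regions of '%s'", vcf_path)
    chrom <- chrom[inside]; pos <- pos[inside]; ref <- ref[inside]; alt <- alt[inside]
    id <- id[inside]; gt <- gt[inside, , drop = FALSE]
  }

  variant_id <- ifelse(is.na(id) | id == ".", paste(chrom, pos, ref, alt, sep = ":"), id)
  if (anyDuplicated(variant_id))
    stopf("duplicated variant ids in panel: %s",
          paste(unique(variant_id[duplicated(variant_id)]), collapse = ", "))
  rownames(gt) <- variant_id

  structure(list(
    variants = data.frame(
      variant_id = variant_id, chrom = chrom, pos = pos,
      ref_allele = ref, alt_allele = alt, stringsAsFactors = FALSE
    ),
    gt = gt,
    individual_ids = colnames(gt),
    n_skipped = n_skipped
  ), class = "coseg_panel")
}

#' @keywords internal
#' @noRd
as_granges_regions <- function(regions) {
  if (methods::is(regions, "GRanges")) {
    GenomicRanges::GRanges(norm_chrom(GenomicRanges::seqnames(regions)),
                           IRanges::ranges(regions))
  } else {
    GenomicRanges::GRanges(norm_chrom(regions$chrom),
                           IRanges::IRanges(regions$start, regions$end))
  }
}

#' Binarize a diploid genotype panel against the panel-wide minor allele
#'
#' Orients every variant so that the panel-wide most frequent allele codes 0
#' and the minor allele codes 1, then collapses diploid genotypes into one
#' binary code per row. Under `carrier` coding a row is an individual, coded 1
#' iff it carries at least one copy of the minor allele; under `haplotype`
#' coding each phased haplotype is its own row, coded by the allele it
#' carries. Missing genotype calls are imputed to the major allele (code 0)
#' and counted.
#'
#' Allele-frequency ties (alternate allele frequency exactly 0.5) designate
#' the ALT allele as minor, so orientation is deterministic.
#'
#' @param panel A `coseg_panel` from [load_panel()].
#' @param coding_mode `"carrier"` (default) or `"haplotype"`. Haplotype mode
#'   requires fully phased genotypes (`|` separators) and fails otherwise.
#' @return An object of class `coseg_matrix`: a list with
#'   * `codes` — integer 0/1 matrix, rows = individuals (or haplotypes),
#'     columns = variants,
#'   * `variants` — the panel's variant table extended with `minor_allele`,
#'     `mac` (number of rows coded 1; equals the column sum exactly) and
#'     `maf` (panel-wide minor allele frequency, always <= 0.5),
#'   * `coding_mode`, `n_imputed`.
#' @examples
#' vcf <- system.file("extdata", "toy_panel.vcf", package = "rsnpcoseg")
#' bm <- binarize(load_panel(vcf))
#' colSums(bm$codes) == bm$variants$mac
#' @export
binarize <- function(panel, coding_mode = c("carrier", "haplotype")) {
  coding_mode <- match.arg(coding_mode)
  stopifnot(inherits(panel, "coseg_panel"))
  gt <- panel$gt
  m <- nrow(gt); n_ind <- ncol(gt)

  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  a1[is.na(a1)] <- "."
  a2[is.na(a2) | a2 == ""] <- "."
  # haploid records ("0" with no separator) count a single allele
  a2[sep == ""] <- "."

  h1 <- matrix(a1, nrow = m); h2 <- matrix(a2, nrow = m)
  n_imputed <- sum(h1 == ".") + sum(h2 == ".")

  alt_count <- rowSums(h1 == "1") + rowSums(h2 == "1")
  called <- rowSums(h1 != ".") + rowSums(h2 != ".")
  alt_freq <- ifelse(called > 0, alt_count / called, 0)
  minor_is_alt <- alt_freq <= 0.5
  minor_code <- ifelse(minor_is_alt, "1", "0")
  maf <- pmin(alt_freq, 1 - alt_freq)

  if (coding_mode == "carrier") {
    hit <- (h1 == rep(minor_code, n_ind)) | (h2 == rep(minor_code, n_ind))
    codes <- t(matrix(as.integer(hit), nrow = m))
    rownames(codes) <- panel$individual_ids
  } else {
    full <- h1 != "." & h2 != "."
    unphased <- matrix(sep, nrow = m) != "|" & full
    if (any(unphased))
      stopf("haplotype coding requires phased genotypes ('|'); found %d unphased calls — use coding_mode = 'carrier'",
            sum(unphased))
    c1 <- t(matrix(as.integer(h1 == rep(minor_code, n_ind)), nrow = m))
    c2 <- t(matrix(as.integer(h2 == rep(minor_code, n_ind)), nrow = m))
    codes <- matrix(0L, nrow = 2L * n_ind, ncol = m)
    codes[seq(1L, 2L * n_ind, by = 2L), ] <- c1
    codes[seq(2L, 2L * n_ind, by = 2L), ] <- c2
    rownames(codes) <- paste0(rep(panel$individual_ids, each = 2L), c("_h1", "_h2"))
  }
  colnames(codes) <- panel$variants$variant_id

  variants <- panel$variants
  variants$minor_allele <- ifelse(minor_is_alt, variants$alt_allele, variants$ref_allele)
  variants$mac <- as.integer(colSums(codes))
  variants$maf <- maf

  structure(list(codes = codes, variants = variants,
                 coding_mode = coding_mode, n_imputed = n_imputed),
            class = "coseg_matrix")
}

#' @export
print.coseg_matrix <- function(x, ...) {
  cat(sprintf("<coseg_matrix> %d rows (%s coding) x %d variants; %d imputed calls\n",
              nrow(x$codes), x$coding_mode, ncol(x$codes), x$n_imputed))
  invisible(x)
}

#' Load a gene/transcript annotation as genomic intervals
#'
#' Thin wrapper over [rtracklayer::import()]: BED (0-based half-open on disk)
#' and GFF3 (1-based closed) are both returned as 1-based closed `GRanges`,
#' with any `chr` prefix stripped from sequence names.
#'
#' @param path BED or GFF3 file.
#' @return A `GRanges` of transcribed intervals.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  gr <- rtracklayer::import(path)
  GenomicRanges::GRanges(norm_chrom(GenomicRanges::seqnames(gr)), IRanges::ranges(gr),
                         gene = if (!is.null(gr$name)) gr$name else as.character(seq_along(gr)))
}

#' Load rSNP queries from a two-column TSV
#'
#' @param path TSV with columns `rsnp_id` and `target_genes` (comma-separated
#'   gene symbols, possibly empty). A header line is expected.
#' @return Data frame with `rsnp_id` and list-column `target_genes`.
#' @export
load_rsnp_queries <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character", quote = "")
  if (!all(c("rsnp_id", "target_genes") %in% names(df)))
    stopf("rSNP list '%s' must have columns 'rsnp_id' and 'target_genes'", path)
  genes <- lapply(df$target_genes, function(g) {
    g <- trimws(strsplit(g, ",", fixed = TRUE)[[1]])
    g[nzchar(g)]
  })
  data.frame(rsnp_id = df$rsnp_id, target_genes = I(genes), stringsAsFactors = FALSE)
}

#' Restrict a binarized matrix to the analysis universe
#'
#' Retains the columns that are either query rSNPs found in the panel or SNPs
#' whose position falls inside at least one transcribed interval. rSNPs are
#' kept regardless of annotation overlap; query ids absent from the panel are
#' reported, not fatal.
#'
#' @param bm A `coseg_matrix` from [binarize()].
#' @param annotation A `GRanges` (see [load_annotation()]) or a path to a
#'   BED/GFF file.
#' @param rsnp_ids Character vector of query rSNP identifiers.
#' @return A list with
#'   * `matrix` — the restricted `coseg_matrix`, whose variant table gains
#'     logical columns `in_transcribed_region` and `is_rsnp`,
#'   * `absent_rsnps` — query ids not present in the panel.
#' @export
restrict_to_transcribed <- function(bm, annotation, rsnp_ids) {
  stopifnot(inherits(bm, "coseg_matrix"))
  if (is.character(annotation) && length(annotation) == 1L)
    annotation <- load_annotation(annotation)
  v <- bm$variants
  vr <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
  ann <- GenomicRanges::GRanges(norm_chrom(GenomicRanges::seqnames(annotation)),
                                IRanges::ranges(annotation))
  in_region <- IRanges::overlapsAny(vr, ann)
  is_rsnp <- v$variant_id %in% rsnp_ids
  absent <- setdiff(rsnp_ids, v$variant_id)
  keep <- in_region | is_rsnp

  out <- bm
  out$codes <- bm$codes[, keep, drop = FALSE]
  out$variants <- v[keep, , drop = FALSE]
  out$variants$in_transcribed_region <- in_region[keep]
  out$variants$is_rsnp <- is_rsnp[keep]
  rownames(out$variants) <- NULL
  list(matrix = out, absent_rsnps = absent)
}

#' Persist a binarized matrix as a two-part text artifact
#'
#' Writes a variants TSV (`variant_id`, `chrom`, `pos`, `ref`, `alt`, `minor`,
#' `mac`, `maf`, `in_transcribed_region`) and a dense 0/1 matrix TSV with
#' individual-row and variant-column headers.
#'
#' @param bm A `coseg_matrix`.
#' @param variants_file,matrix_file Output paths.
#' @export
write_binary_matrix <- function(bm, variants_file, matrix_file) {
  stopifnot(inherits(bm, "coseg_matrix"))
  v <- bm$variants
  if (is.null(v$in_transcribed_region)) v$in_transcribed_region <- NA
  if (is.null(v$is_rsnp)) v$is_rsnp <- NA
  vt <- data.frame(variant_id = v$variant_id, chrom = v$chrom, pos = v$pos,
                   ref = v$ref_allele, alt = v$alt_allele, minor = v$minor_allele,
                   mac = v$mac, maf = v$maf,
                   in_transcribed_region = v$in_transcribed_region,
                   is_rsnp = v$is_rsnp)
  write.table(vt, variants_file, sep = "\t", quote = FALSE, row.names = FALSE)
  mt <- data.frame(row_id = rownames(bm$codes), bm$codes, check.names = FALSE)
  attr(mt, "coding_mode") <- NULL
  con <- file(matrix_file, "w")
  on.exit(close(con))
  writeLines(paste0("#coding_mode=", bm$coding_mode), con)
  write.table(mt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(variants_file, matrix_file))
}

#' Reload a matrix written by [write_binary_matrix()]
#'
#' @param variants_file,matrix_file Paths written by [write_binary_matrix()].
#' @return A `coseg_matrix`.
#' @export
read_binary_matrix <- function(variants_file, matrix_file) {
  vt <- read.delim(variants_file, stringsAsFactors = FALSE)
  first <- readLines(matrix_file, n = 1L)
  coding_mode <- sub("^#coding_mode=", "", first)
  mt <- data.table::fread(matrix_file, sep = "\t", header = TRUE, skip = 1L,
                          data.table = FALSE, check.names = FALSE)
  codes <- as.matrix(mt[, -1, drop = FALSE])
  storage.mode(codes) <- "integer"
  rownames(codes) <- mt[[1]]
  variants <- data.frame(
    variant_id = vt$variant_id, chrom = as.character(vt$chrom), pos = vt$pos,
    ref_allele = vt$ref, alt_allele = vt$alt, minor_allele = vt$minor,
    mac = vt$mac, maf = vt$maf, stringsAsFactors = FALSE
  )
  if (!all(is.na(vt$in_transcribed_region)))
    variants$in_transcribed_region <- vt$in_transcribed_region
  if (!all(is.na(vt$is_rsnp))) variants$is_rsnp <- vt$is_rsnp
  structure(list(codes = codes, variants = variants, coding_mode = coding_mode,
                 n_imputed = NA_integer_), class = "coseg_matrix")
}
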