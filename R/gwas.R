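#' The cardiovascular trait keyword signature
#'
#' The twelve keywords used to select cardiovascular-relevant rows from a
#' GWAS catalog trait column: heart, coronary artery disease, CAD, platelet,
#' blood, blood cells, pressure, count, vessel, caliber, pulse, artery.
#'
#' @return Character vector of signature terms.
#' @export
cardio_signature <- function() {
  c("heart", "coronary artery disease", "CAD", "platelet", "blood",
    "blood cells", "pressure", "count", "vessel", "caliber", "pulse", "artery")
}

#' Load a GWAS-catalog-style association table
#'
#' Accepts the GWAS Catalog download dialect (columns `SNPS`, `CHR_ID`,
#' `CHR_POS`, `DISEASE/TRAIT`, `MAPPED_GENE`) or a minimal generic header
#' (`snp`, `chrom`, `pos`, `trait`, `genes`). Multi-SNP rows (ids separated
#' by `;` or the interaction marker `x`) are expanded into one entry per SNP,
#' sharing the trait; rows whose coordinates cannot be parsed are dropped and
#' counted.
#'
#' @param path Tab-separated file.
#' @return Data frame with `gwas_snp_id`, `chrom`, `pos`, `trait` and
#'   list-column `mapped_genes`; attribute `"n_skipped"` counts dropped rows.
#' @export
load_gwas_table <- function(path) {
  if (!file.exists(path)) stopf("GWAS table not found: %s", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE,
                          colClasses = "character", quote = "", check.names = FALSE)
  catalog <- all(c("SNPS", "CHR_ID", "CHR_POS", "DISEASE/TRAIT") %in% names(df))
  generic <- all(c("snp", "chrom", "pos", "trait") %in% names(df))
  if (!catalog && !generic) {
    need <- if (any(c("SNPS", "CHR_ID", "CHR_POS") %in% names(df)))
      setdiff(c("SNPS", "CHR_ID", "CHR_POS", "DISEASE/TRAIT"), names(df))
    else setdiff(c("snp", "chrom", "pos", "trait"), names(df))
    stopf("GWAS table '%s' is missing mandatory column(s): %s",
          path, paste(need, collapse = ", "))
  }
  if (catalog) {
    snp <- df$SNPS; chrom <- df$CHR_ID; pos <- df$CHR_POS
    trait <- df[["DISEASE/TRAIT"]]
    genes <- if ("MAPPED_GENE" %in% names(df)) df$MAPPED_GENE else rep("", nrow(df))
  } else {
    snp <- df$snp; chrom <- df$chrom; pos <- df$pos; trait <- df$trait
    genes <- if ("genes" %in% names(df)) df$genes else rep("", nrow(df))
  }

  split_multi <- function(x) {
    parts <- strsplit(x, ";|\\s+x\\s+")
    lapply(parts, function(p) { p <- trimws(p); p[nzchar(p)] })
  }
  snp_l <- split_multi(snp); chrom_l <- split_multi(chrom); pos_l <- split_multi(pos)

  rows <- vector("list", length(snp_l))
  n_skipped <- 0L
  for (i in seq_along(snp_l)) {
    ids <- snp_l[[i]]; ch <- chrom_l[[i]]; ps <- pos_l[[i]]
    k <- length(ids)
    if (k == 0L) { n_skipped <- n_skipped + 1L; next }
    if (length(ch) == 1L) ch <- rep(ch, k)
    if (length(ps) == 1L) ps <- rep(ps, k)
    if (length(ch) != k || length(ps) != k) { n_skipped <- n_skipped + 1L; next }
    ps_int <- suppressWarnings(as.integer(ps))
    ok <- !is.na(ps_int) & nzchar(ch)
    if (!any(ok)) { n_skipped <- n_skipped + 1L; next }
    g <- trimws(strsplit(genes[i], ",|;")[[1]])
    g <- g[nzchar(g)]
    rows[[i]] <- data.frame(gwas_snp_id = ids[ok], chrom = norm_chrom(ch[ok]),
                            pos = ps_int[ok], trait = trait[i],
                            mapped_genes = I(rep(list(g), sum(ok))),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(gwas_snp_id = character(), chrom = character(),
                      pos = integer(), trait = character(),
                      mapped_genes = I(list()), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter GWAS entries by a trait keyword signature
#'
#' An entry is retained iff at least one term matches the trait string
#' case-insensitively as a substring on word boundaries, so the acronym
#' "CAD" matches "CAD risk" but not "decade".
#'
#' @param entries Data frame from [load_gwas_table()].
#' @param terms Signature terms; defaults to [cardio_signature()].
#' @return The retained entries with a list-column `matched_terms`.
#' @export
filter_by_signature <- function(entries, terms = cardio_signature()) {
  if (length(terms) == 0L) stopf("filter_by_signature: empty term list")
  pat <- paste0("\\b", gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", terms), "\\b")
  hit <- matrix(FALSE, nrow(entries), length(terms))
  for (j in seq_along(terms))
    hit[, j] <- grepl(pat[j], entries$trait, ignore.case = TRUE, perl = TRUE)
  keep <- rowSums(hit) > 0
  out <- entries[keep, , drop = FALSE]
  out$matched_terms <- I(lapply(which(keep), function(i) terms[hit[i, ]]))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- attr(entries, "n_skipped")
  out
}

#' Link rSNPs to GWAS signals through a genomic window
#'
#' Emits one candidate association per (rSNP, GWAS SNP) pair when the rSNP
#' itself (link_type `direct`) or, failing that, the closest of its
#' co-segregating coding markers (link_type `via_marker`) lies within
#' `half_window` base pairs of the GWAS SNP on the same chromosome (closed
#' bounds). A direct link always dominates a marker link for the same pair.
#'
#' @param gwas_entries Data frame from [load_gwas_table()] /
#'   [filter_by_signature()].
#' @param rsnp_positions Data frame with columns `rsnp_id`, `chrom`, `pos`.
#' @param coseg_records Data frame of called pairs with columns `rsnp_id`,
#'   `marker_id`, `marker_chrom`, `marker_pos` (see
#'   [attach_marker_positions()]); only rows with `cosegregating = TRUE` are
#'   used if that column is present.
#' @param half_window Window half-width in bp (default 5000, i.e. a 10 Kbp
#'   window centered at the GWAS SNP).
#' @param rsnp_queries Optional data frame from [load_rsnp_queries()] used to
#'   attach known target genes.
#' @return Data frame of candidate associations: `rsnp_id`, `gwas_snp_id`,
#'   `link_type`, `marker_id` (`NA` for direct links), `bp_distance`,
#'   `trait`, `target_genes` (comma-joined), sorted by
#'   (`chrom`, `pos_gwas`, `rsnp_id`).
#' @export
window_intersect <- function(gwas_entries, rsnp_positions, coseg_records = NULL,
                             half_window = 5000L, rsnp_queries = NULL) {
  stopifnot(half_window >= 0)
  g <- gwas_entries
  if (nrow(g) == 0L || nrow(rsnp_positions) == 0L) return(empty_candidates())
  g$chrom <- norm_chrom(g$chrom)
  r <- rsnp_positions
  r$chrom <- norm_chrom(r$chrom)

  win <- GenomicRanges::GRanges(g$chrom,
    IRanges::IRanges(pmax(1L, g$pos - half_window), g$pos + half_window))

  # direct links: rSNP position inside the window
  rp <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos, r$pos))
  h <- GenomicRanges::findOverlaps(win, rp)
  direct <- data.frame(
    gi = S4Vectors::queryHits(h), rsnp_id = r$rsnp_id[S4Vectors::subjectHits(h)],
    link_type = rep("direct", length(h)), marker_id = rep(NA_character_, length(h)),
    bp_distance = abs(g$pos[S4Vectors::queryHits(h)] - r$pos[S4Vectors::subjectHits(h)]),
    stringsAsFactors = FALSE)

  # via-marker links: closest called marker of the rSNP inside the window
  via <- NULL
  if (!is.null(coseg_records) && nrow(coseg_records) > 0L) {
    cs <- coseg_records
    if ("cosegregating" %in% names(cs)) cs <- cs[cs$cosegregating, , drop = FALSE]
    if (!all(c("marker_chrom", "marker_pos") %in% names(cs)))
      stopf("window_intersect: coseg_records need marker_chrom/marker_pos (see attach_marker_positions)")
    if (nrow(cs) > 0L) {
      cs$marker_chrom <- norm_chrom(cs$marker_chrom)
      mp <- GenomicRanges::GRanges(cs$marker_chrom, IRanges::IRanges(cs$marker_pos, cs$marker_pos))
      hm <- GenomicRanges::findOverlaps(win, mp)
      if (length(hm)) {
        via <- data.frame(
          gi = S4Vectors::queryHits(hm),
          rsnp_id = cs$rsnp_id[S4Vectors::subjectHits(hm)],
          link_type = rep("via_marker", length(hm)),
          marker_id = cs$marker_id[S4Vectors::subjectHits(hm)],
          bp_distance = abs(g$pos[S4Vectors::queryHits(hm)] -
                              cs$marker_pos[S4Vectors::subjectHits(hm)]),
          stringsAsFactors = FALSE)
        # keep the closest marker per (GWAS entry, rSNP); break ties by id
        via <- via[order(via$gi, via$rsnp_id, via$bp_distance, via$marker_id), ]
        via <- via[!duplicated(via[, c("gi", "rsnp_id")]), , drop = FALSE]
        # direct dominates
        key <- paste(via$gi, via$rsnp_id)
        via <- via[!key %in% paste(direct$gi, direct$rsnp_id), , drop = FALSE]
      }
    }
  }

  out <- rbind(direct, via)
  if (is.null(out) || nrow(out) == 0L) return(empty_candidates())
  out$gwas_snp_id <- g$gwas_snp_id[out$gi]
  out$trait <- g$trait[out$gi]
  out$chrom <- g$chrom[out$gi]
  out$pos_gwas <- g$pos[out$gi]
  gene_lookup <- NULL
  if (!is.null(rsnp_queries))
    gene_lookup <- setNames(
      vapply(rsnp_queries$target_genes, function(x) paste(x, collapse = ","), character(1)),
      rsnp_queries$rsnp_id)
  out$target_genes <- if (is.null(gene_lookup)) "" else
    unname(ifelse(out$rsnp_id %in% names(gene_lookup), gene_lookup[out$rsnp_id], ""))
  out <- out[order(out$chrom, out$pos_gwas, out$rsnp_id, out$gwas_snp_id), ]
  rownames(out) <- NULL
  out[, c("rsnp_id", "gwas_snp_id", "link_type", "marker_id", "bp_distance",
          "chrom", "pos_gwas", "trait", "target_genes")]
}

#' @keywords internal
#' @noRd
empty_candidates <- function() {
  data.frame(rsnp_id = character(), gwas_snp_id = character(),
             link_type = character(), marker_id = character(),
             bp_distance = integer(), chrom = character(), pos_gwas = integer(),
             trait = character(), target_genes = character(),
             stringsAsFactors = FALSE)
}

#' Attach marker coordinates to co-segregation records
#'
#' @param records Output of [scan_pairs()].
#' @param variants Variant table (from a `coseg_matrix`) with `variant_id`,
#'   `chrom`, `pos`.
#' @return `records` with added `marker_chrom` and `marker_pos`.
#' @export
attach_marker_positions <- function(records, variants) {
  i <- match(records$marker_id, variants$variant_id)
  if (anyNA(i))
    stopf("attach_marker_positions: %d marker ids absent from variant table", sum(is.na(i)))
  records$marker_chrom <- variants$chrom[i]
  records$marker_pos <- variants$pos[i]
  records
}

#' Summarize candidate associations
#'
#' Per-rSNP roll-up (traits, link types, genes) plus global tallies: number
#' of distinct candidate rSNPs, how many have at least one direct positional
#' coincidence with a GWAS SNP, and how many map to more than one known
#' target gene.
#'
#' @param associations Output of [window_intersect()].
#' @param rsnp_queries Optional data frame from [load_rsnp_queries()].
#' @return List with `per_rsnp` (data frame) and `totals` (list:
#'   `n_associations`, `n_candidate_rsnps`, `n_direct_rsnps`,
#'   `n_via_rsnps`, `n_gwas_snps`, `n_multi_target`).
#' @export
summarize_candidates <- function(associations, rsnp_queries = NULL) {
  a <- associations
  if (nrow(a) == 0L) {
    return(list(
      per_rsnp = data.frame(rsnp_id = character(), n_links = integer(),
                            n_direct = integer(), traits = character(),
                            target_genes = character(), stringsAsFactors = FALSE),
      totals = list(n_associations = 0L, n_candidate_rsnps = 0L,
                    n_direct_rsnps = 0L, n_via_rsnps = 0L,
                    n_gwas_snps = 0L, n_multi_target = 0L)))
  }
  gene_of <- function(id) {
    if (!is.null(rsnp_queries) && id %in% rsnp_queries$rsnp_id)
      paste(rsnp_queries$target_genes[[match(id, rsnp_queries$rsnp_id)]], collapse = ",")
    else paste(unique(a$target_genes[a$rsnp_id == id & nzchar(a$target_genes)]), collapse = ",")
  }
  ids <- sort(unique(a$rsnp_id))
  per <- do.call(rbind, lapply(ids, function(id) {
    sub <- a[a$rsnp_id == id, , drop = FALSE]
    data.frame(rsnp_id = id, n_links = nrow(sub),
               n_direct = sum(sub$link_type == "direct"),
               traits = paste(sort(unique(sub$trait)), collapse = "; "),
               target_genes = gene_of(id), stringsAsFactors = FALSE)
  }))
  n_genes <- vapply(strsplit(per$target_genes, ","), function(g) sum(nzchar(g)), integer(1))
  list(per_rsnp = per,
       totals = list(
         n_associations = nrow(a),
         n_candidate_rsnps = length(ids),
         n_direct_rsnps = sum(per$n_direct > 0),
         n_via_rsnps = sum(per$n_direct == 0),
         n_gwas_snps = length(unique(a$gwas_snp_id)),
         n_multi_target = sum(n_genes > 1)))
}

#' Write candidate associations as TSV (and optionally a BED track)
#'
#' @param associations Output of [window_intersect()].
#' @param file TSV path.
#' @param bed_file Optional BED path of candidate rSNP window midpoints.
#' @param rsnp_positions Needed when `bed_file` is given.
#' @export
write_candidates <- function(associations, file, bed_file = NULL, rsnp_positions = NULL) {
  write.table(associations, file, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(bed_file)) {
    if (is.null(rsnp_positions)) stopf("write_candidates: rsnp_positions needed for BED output")
    r <- rsnp_positions[rsnp_positions$rsnp_id %in% associations$rsnp_id, , drop = FALSE]
    bed <- data.frame(r$chrom, r$pos - 1L, r$pos, r$rsnp_id)
    write.table(bed, bed_file, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_candidates
#' @export
read_candidates <- function(file) {
  out <- data.table::fread(file, sep = "\t", header = TRUE, data.table = FALSE,
                           na.strings = "", quote = "")
  out$marker_id <- as.character(out$marker_id)
  out$target_genes <- ifelse(is.na(out$target_genes), "", as.character(out$target_genes))
  out
}
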