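# Fixture builders shared across test files. Everything is generated in code;
# nothing is read from outside the package.

toy_vcf <- function() system.file("extdata", "toy_panel.vcf", package = "rsnpcoseg")

# write a VCF from explicit GT strings; one row per variant
write_test_vcf <- function(path, pos, id, ref, alt, gt_rows,
                           samples = paste0("S", seq_along(gt_rows[[1]]))) {
  body <- vapply(seq_along(pos), function(i)
    paste(c("1", pos[i], id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt_rows[[i]]), collapse = "\t"), character(1))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}

small_sim <- function(seed = 7L, ...) {
  sim_config(n_individuals = 60L, n_populations = 3L, n_background_snps = 200L,
             n_rsnps = 6L, planted_pairs = default_planted_pairs(3L),
             n_genes = 10L, n_gwas_entries = 20L, seed = seed, ...)
}

# reference interval scan: every variant against every interval
brute_force_in_region <- function(pos, chrom, intervals) {
  vapply(seq_along(pos), function(i)
    any(chrom[i] == intervals$chrom & pos[i] >= intervals$start &
          pos[i] <= intervals$end), logical(1))
}

# reference all-pairs window scan mirroring the candidate-association rules
brute_force_window <- function(gwas, rsnps, coseg, half_window) {
  out <- list()
  for (g in seq_len(nrow(gwas))) {
    for (r in seq_len(nrow(rsnps))) {
      direct <- gwas$chrom[g] == rsnps$chrom[r] &&
        abs(gwas$pos[g] - rsnps$pos[r]) <= half_window
      if (direct) {
        out[[length(out) + 1L]] <- data.frame(
          rsnp_id = rsnps$rsnp_id[r], gwas_snp_id = gwas$gwas_snp_id[g],
          link_type = "direct", marker_id = NA_character_,
          bp_distance = abs(gwas$pos[g] - rsnps$pos[r]),
          stringsAsFactors = FALSE)
      } else {
        mk <- coseg[coseg$rsnp_id == rsnps$rsnp_id[r] & coseg$cosegregating, , drop = FALSE]
        if (nrow(mk) == 0) next
        d <- ifelse(mk$marker_chrom == gwas$chrom[g],
                    abs(gwas$pos[g] - mk$marker_pos), Inf)
        if (min(d) <= half_window) {
          best <- which(d == min(d))
          best <- best[order(mk$marker_id[best])][1]
          out[[length(out) + 1L]] <- data.frame(
            rsnp_id = rsnps$rsnp_id[r], gwas_snp_id = gwas$gwas_snp_id[g],
            link_type = "via_marker", marker_id = mk$marker_id[best],
            bp_distance = d[best], stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(rsnp_id = character(), gwas_snp_id = character(),
                      link_type = character(), marker_id = character(),
                      bp_distance = integer(), stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df[order(df$rsnp_id, df$gwas_snp_id), , drop = FALSE]
}

sort_assoc <- function(df) {
  df <- df[order(df$rsnp_id, df$gwas_snp_id), c("rsnp_id", "gwas_snp_id",
                                                "link_type", "marker_id", "bp_distance")]
  df$marker_id <- as.character(df$marker_id)
  df$bp_distance <- as.integer(df$bp_distance)
  rownames(df) <- NULL
  df
}
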