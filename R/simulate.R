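#' Configuration for the synthetic panel generator
#'
#' Describes a multi-population diploid panel with background SNPs in linkage
#' equilibrium, planted co-segregating rSNP/marker pairs, a gene annotation,
#' and a GWAS-style trait table. Generation is a pure function of the
#' configuration: the same seed yields byte-identical output files.
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_populations Number of population strata; per-variant allele
#'   frequencies are drawn independently per stratum (coarse super-population
#'   structure, no migration model).
#' @param n_background_snps Background SNPs placed inside genes, mutually in
#'   linkage equilibrium.
#' @param n_rsnps Number of query rSNPs.
#' @param planted_pairs List of lists with fields `rsnp_index` (which rSNP
#'   carries a planted coding marker), `marker_offset_bp` (rSNP-to-marker
#'   distance; must exceed half the gene length so the rSNP stays outside the
#'   marker's gene), `flip_prob` (per-haplotype copy error, the knob that
#'   degrades co-segregation) and `target_maf` (rSNP allele frequency in
#'   every stratum).
#' @param maf_beta Beta(a, b) parameters of the ancestral background
#'   allele-frequency distribution.
#' @param fst Balding–Nichols divergence of the population strata: each
#'   population's frequency is drawn from
#'   `Beta(f0 (1 - Fst)/Fst, (1 - f0)(1 - Fst)/Fst)` around the ancestral
#'   frequency `f0`. `0` disables structure. Default 0.1, of the order of
#'   human super-population divergence.
#' @param n_genes,gene_length_bp Background gene count and length.
#' @param n_gwas_entries Rows of the synthetic GWAS table.
#' @param fraction_signature_matching Fraction of GWAS rows whose trait
#'   matches the cardiovascular signature.
#' @param fraction_within_window Fraction of the signature-matching rows
#'   placed inside the window of a planted rSNP or marker (the rest are
#'   placed in an empty region far from every SNP).
#' @param half_window_bp Window half-width used when planting GWAS rows.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500L, n_populations = 4L,
                       n_background_snps = 2000L, n_rsnps = 20L,
                       planted_pairs = default_planted_pairs(),
                       maf_beta = c(1.5, 6), fst = 0.1,
                       n_genes = 40L, gene_length_bp = 2000L,
                       n_gwas_entries = 60L,
                       fraction_signature_matching = 0.6,
                       fraction_within_window = 0.5,
                       half_window_bp = 5000L, seed = 1L) {
  cfg <- structure(list(
    n_individuals = as.integer(n_individuals),
    n_populations = as.integer(n_populations),
    n_background_snps = as.integer(n_background_snps),
    n_rsnps = as.integer(n_rsnps),
    planted_pairs = planted_pairs,
    maf_beta = maf_beta,
    fst = fst,
    n_genes = as.integer(n_genes),
    gene_length_bp = as.integer(gene_length_bp),
    n_gwas_entries = as.integer(n_gwas_entries),
    fraction_signature_matching = fraction_signature_matching,
    fraction_within_window = fraction_within_window,
    half_window_bp = as.integer(half_window_bp),
    seed = as.integer(seed)
  ), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' @rdname sim_config
#' @param n_pairs Number of default planted pairs.
#' @param flip_prob,target_maf,marker_offset_bp Shared values for the default
#'   pair list.
#' @export
default_planted_pairs <- function(n_pairs = 10L, flip_prob = 0,
                                  target_maf = 0.25, marker_offset_bp = 3000L) {
  lapply(seq_len(n_pairs), function(i)
    list(rsnp_index = i, marker_offset_bp = as.integer(marker_offset_bp),
         flip_prob = flip_prob, target_maf = target_maf))
}

#' @keywords internal
#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_individuals > 0, cfg$n_populations > 0,
            cfg$n_background_snps > 0, cfg$n_rsnps > 0,
            cfg$n_genes > 0, cfg$gene_length_bp > 0,
            cfg$n_gwas_entries >= 0,
            cfg$fraction_signature_matching >= 0, cfg$fraction_signature_matching <= 1,
            cfg$fraction_within_window >= 0, cfg$fraction_within_window <= 1,
            cfg$fst >= 0, cfg$fst < 1,
            cfg$half_window_bp >= 0)
  idx <- vapply(cfg$planted_pairs, `[[`, numeric(1), "rsnp_index")
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > cfg$n_rsnps))
    stopf("sim_config: planted rsnp_index values must be unique and within 1..n_rsnps")
  for (p in cfg$planted_pairs) {
    if (p$flip_prob < 0 || p$flip_prob > 1)
      stopf("sim_config: flip_prob must be in [0, 1]")
    if (p$marker_offset_bp <= cfg$gene_length_bp / 2)
      stopf("sim_config: infeasible placement — marker_offset_bp (%d) must exceed half the gene length (%d) so the rSNP falls outside the marker's gene",
            p$marker_offset_bp, cfg$gene_length_bp)
  }
  if (cfg$n_background_snps > cfg$n_genes * cfg$gene_length_bp)
    stopf("sim_config: infeasible placement — genes too short for %d background SNPs",
          cfg$n_background_snps)
  invisible(cfg)
}

# Trait string pools used for the synthetic GWAS table.
MATCHING_TRAITS <- c(
  "Systolic blood pressure", "Coronary artery disease", "Platelet count",
  "Resting heart rate", "Pulse pressure", "Retinal vessel caliber",
  "Blood protein levels", "Diastolic blood pressure", "Red blood cell count",
  "CAD in type 2 diabetes")
NONMATCHING_TRAITS <- c(
  "Height", "Educational attainment", "Hair color", "Type 2 diabetes",
  "Bone mineral density", "Decade of menopause onset")

#' Generate a complete synthetic input bundle
#'
#' Writes a phased diploid VCF 4.2 panel, a BED gene annotation, an rSNP
#' query list, a GWAS-Catalog-dialect trait table, and a JSON truth file
#' enumerating the planted co-segregation pairs and the candidate
#' associations the pipeline is expected to recover.
#'
#' Layout (all on one chromosome): background genes carrying background SNPs
#' start at 1 Mb; each planted rSNP/marker pair lives in its own isolated
#' gene 100 kb from its neighbors, with the rSNP placed upstream of the gene;
#' unpaired rSNPs and off-window GWAS rows sit in otherwise empty regions, so
#' no GWAS window ever contains a SNP that was not deliberately planted
#' there. Planted markers copy their rSNP's phased haplotypes with a
#' per-haplotype flip probability `flip_prob`; at `flip_prob = 0` the two
#' genotype columns are identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with `paths` (named: `vcf`, `bed`, `rsnp_tsv`, `gwas_tsv`,
#'   `truth`) and the in-memory `truth` list (`planted_coseg_pairs`,
#'   `planted_candidates`, `variants`).
#' @export
generate_panel <- function(config, out_dir) {
  validate_sim_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(config$seed, generate_panel_impl(config, out_dir))
}

#' @keywords internal
#' @noRd
generate_panel_impl <- function(cfg, out_dir) {
  n <- cfg$n_individuals
  P <- cfg$n_populations
  pop_names <- c("AFR", "AMR", "ASN", "EUR", paste0("POP", seq_len(max(0, P - 4)) + 4))[seq_len(P)]
  pop_of <- sort(rep_len(seq_len(P), n))
  sample_ids <- sprintf("%s_%04d", pop_names[pop_of], seq_len(n))

  K <- length(cfg$planted_pairs)
  glen <- cfg$gene_length_bp

  # --- coordinates -------------------------------------------------------
  bg_gene_start <- 1e6 + (seq_len(cfg$n_genes) - 1) * (glen + 8000)
  bg_gene_end <- bg_gene_start + glen - 1
  gene_names <- sprintf("GENE%03d", seq_len(cfg$n_genes))

  gene_of_snp <- rep_len(seq_len(cfg$n_genes), cfg$n_background_snps)
  bg_pos <- integer(cfg$n_background_snps)
  for (g in seq_len(cfg$n_genes)) {
    idx <- which(gene_of_snp == g)
    bg_pos[idx] <- sort(sample(seq.int(bg_gene_start[g], bg_gene_end[g]), length(idx)))
  }

  pair_base <- 1e8 + (seq_len(K) - 1) * 1e5
  pair_gene_start <- pair_base
  pair_gene_end <- pair_base + glen - 1
  pair_gene_names <- sprintf("PGENE%03d", seq_len(K))
  marker_pos <- as.integer(pair_base + floor(glen / 2))
  offsets <- vapply(cfg$planted_pairs, `[[`, numeric(1), "marker_offset_bp")
  planted_idx <- vapply(cfg$planted_pairs, `[[`, numeric(1), "rsnp_index")
  eps <- vapply(cfg$planted_pairs, `[[`, numeric(1), "flip_prob")

  rsnp_pos <- integer(cfg$n_rsnps)
  rsnp_pos[planted_idx] <- marker_pos - as.integer(offsets)
  free_idx <- setdiff(seq_len(cfg$n_rsnps), planted_idx)
  rsnp_pos[free_idx] <- as.integer(1.5e8 + (seq_along(free_idx) - 1) * 1e5)

  bg_ids <- paste0("rs", 1000000L + seq_len(cfg$n_background_snps))
  rsnp_ids <- paste0("rs", 2000000L + seq_len(cfg$n_rsnps))
  marker_ids <- paste0("rs", 3000000L + seq_len(K))

  # --- haplotypes --------------------------------------------------------
  draw_variant <- function(freqs) {
    # two phased haplotypes per individual; redraw near-monomorphic draws
    for (try in 1:100) {
      f <- freqs[pop_of]
      h1 <- rbinom(n, 1L, f); h2 <- rbinom(n, 1L, f)
      s <- sum(h1) + sum(h2)
      if (s > 0L && s < 2L * n) return(cbind(h1, h2))
    }
    h1[1] <- 1L - h1[1]
    cbind(h1, h2)
  }
  # Balding–Nichols strata: per-population frequencies diverge around an
  # ancestral Beta draw with divergence cfg$fst
  beta_freqs <- function() {
    f0 <- min(max(rbeta(1, cfg$maf_beta[1], cfg$maf_beta[2]), 0.01), 0.99)
    if (cfg$fst <= 0) return(rep(f0, P))
    s <- (1 - cfg$fst) / cfg$fst
    rbeta(P, f0 * s, (1 - f0) * s)
  }

  bg_freq <- matrix(0, cfg$n_background_snps, P)
  bg_h <- vector("list", cfg$n_background_snps)
  for (v in seq_len(cfg$n_background_snps)) {
    bg_freq[v, ] <- beta_freqs()
    bg_h[[v]] <- draw_variant(bg_freq[v, ])
  }

  rsnp_freq <- matrix(0, cfg$n_rsnps, P)
  rsnp_h <- vector("list", cfg$n_rsnps)
  for (i in seq_len(cfg$n_rsnps)) {
    k <- match(i, planted_idx)
    rsnp_freq[i, ] <- if (!is.na(k)) rep(cfg$planted_pairs[[k]]$target_maf, P) else beta_freqs()
    rsnp_h[[i]] <- draw_variant(rsnp_freq[i, ])
  }

  marker_h <- vector("list", K)
  for (k in seq_len(K)) {
    src <- rsnp_h[[planted_idx[k]]]
    if (eps[k] > 0) {
      flip <- matrix(rbinom(2L * n, 1L, eps[k]), n, 2)
      src <- (src + flip) %% 2L
    }
    marker_h[[k]] <- src
  }

  # --- variant table (sorted by position) --------------------------------
  vt <- data.frame(
    variant_id = c(bg_ids, rsnp_ids, marker_ids),
    pos = c(bg_pos, rsnp_pos, marker_pos),
    kind = c(rep("background", cfg$n_background_snps),
             rep("rsnp", cfg$n_rsnps), rep("marker", K)),
    stringsAsFactors = FALSE)
  haps <- c(bg_h, rsnp_h, marker_h)
  freqs <- rbind(bg_freq, rsnp_freq,
                 matrix(rsnp_freq[planted_idx, ], nrow = K))
  ord <- order(vt$pos)
  vt <- vt[ord, ]; haps <- haps[ord]; freqs <- freqs[ord, , drop = FALSE]
  base_pool <- c("A", "C", "G", "T")
  vt$ref <- base_pool[(vt$pos %% 4) + 1]
  vt$alt <- base_pool[((vt$pos + 2) %% 4) + 1]

  alt_count <- vapply(haps, function(h) sum(h), integer(1))
  # minor-allele orientation mirrors binarize(): ALT is minor on ties
  minor_is_alt <- alt_count / (2L * n) <= 0.5
  minor_count <- ifelse(minor_is_alt, alt_count, 2L * n - alt_count)
  minor_carriers <- vapply(seq_along(haps), function(i) {
    h <- haps[[i]]
    code <- if (minor_is_alt[i]) 1L else 0L
    sum(h[, 1] == code | h[, 2] == code)
  }, integer(1))
  vt$true_alt_freq_by_pop <- I(lapply(seq_len(nrow(vt)), function(i) unname(freqs[i, ])))
  vt$realized_alt_count <- alt_count
  vt$realized_minor_count <- minor_count
  vt$realized_minor_carriers <- minor_carriers

  # --- GWAS table --------------------------------------------------------
  n_match <- round(cfg$n_gwas_entries * cfg$fraction_signature_matching)
  n_win <- if (K > 0) round(n_match * cfg$fraction_within_window) else 0L
  n_far <- n_match - n_win
  n_non <- cfg$n_gwas_entries - n_match

  gwas <- list(); truth_cand <- list()
  ok_via <- which(eps == 0)
  hw <- cfg$half_window_bp
  for (j in seq_len(n_win)) {
    k <- ((j - 1) %% K) + 1
    want_via <- (j %% 2 == 0) && (k %in% ok_via)
    trait <- MATCHING_TRAITS[((j - 1) %% length(MATCHING_TRAITS)) + 1]
    gid <- paste0("rs", 9000000L + j)
    if (!want_via) {
      d <- if (j == 1) 0L else sample.int(hw, 1) * sample(c(-1L, 1L), 1)
      pos <- rsnp_pos[planted_idx[k]] + d
      truth_cand[[length(truth_cand) + 1L]] <- data.frame(
        rsnp_id = rsnp_ids[planted_idx[k]], gwas_snp_id = gid,
        link_type = "direct", marker_id = NA_character_,
        bp_distance = abs(d), chrom = "1", pos_gwas = pos, trait = trait,
        stringsAsFactors = FALSE)
    } else {
      lo <- max(1L, hw - as.integer(offsets[k]) + 1L)
      u <- if (j == 2L) hw else sample(seq.int(lo, hw), 1)
      pos <- marker_pos[k] + u
      truth_cand[[length(truth_cand) + 1L]] <- data.frame(
        rsnp_id = rsnp_ids[planted_idx[k]], gwas_snp_id = gid,
        link_type = "via_marker", marker_id = marker_ids[k],
        bp_distance = u, chrom = "1", pos_gwas = pos, trait = trait,
        stringsAsFactors = FALSE)
    }
    gwas[[length(gwas) + 1L]] <- data.frame(
      SNPS = gid, CHR_ID = "1", CHR_POS = pos,
      trait = trait, MAPPED_GENE = pair_gene_names[k], stringsAsFactors = FALSE)
  }
  far_base <- 2.5e8
  for (j in seq_len(n_far)) {
    gwas[[length(gwas) + 1L]] <- data.frame(
      SNPS = paste0("rs", 9500000L + j), CHR_ID = "1",
      CHR_POS = as.integer(far_base + (j - 1) * 5e4),
      trait = MATCHING_TRAITS[((j - 1) %% length(MATCHING_TRAITS)) + 1],
      MAPPED_GENE = "NONE", stringsAsFactors = FALSE)
  }
  for (j in seq_len(n_non)) {
    gwas[[length(gwas) + 1L]] <- data.frame(
      SNPS = paste0("rs", 9800000L + j), CHR_ID = "1",
      CHR_POS = as.integer(far_base + 5e7 + (j - 1) * 5e4),
      trait = NONMATCHING_TRAITS[((j - 1) %% length(NONMATCHING_TRAITS)) + 1],
      MAPPED_GENE = "NONE", stringsAsFactors = FALSE)
  }
  gwas_df <- if (length(gwas)) do.call(rbind, gwas) else
    data.frame(SNPS = character(), CHR_ID = character(), CHR_POS = integer(),
               trait = character(), MAPPED_GENE = character())
  names(gwas_df)[names(gwas_df) == "trait"] <- "DISEASE/TRAIT"

  truth_cand_df <- if (length(truth_cand)) do.call(rbind, truth_cand) else
    data.frame(rsnp_id = character(), gwas_snp_id = character(),
               link_type = character(), marker_id = character(),
               bp_distance = integer(), chrom = character(),
               pos_gwas = integer(), trait = character())
  truth_cand_df <- truth_cand_df[order(truth_cand_df$chrom, truth_cand_df$pos_gwas,
                                       truth_cand_df$rsnp_id), , drop = FALSE]
  rownames(truth_cand_df) <- NULL

  # --- rSNP query list ---------------------------------------------------
  target_genes <- rep("", cfg$n_rsnps)
  target_genes[planted_idx] <- pair_gene_names
  if (K > 0) # one multi-target rSNP, mirroring real panels where a regulator hits two genes
    target_genes[planted_idx[1]] <- paste0(pair_gene_names[1], ",", pair_gene_names[1], "B")
  target_genes[free_idx] <- gene_names[rep_len(seq_len(cfg$n_genes), length(free_idx))]
  rsnp_df <- data.frame(rsnp_id = rsnp_ids, target_genes = target_genes,
                        stringsAsFactors = FALSE)

  # --- write files -------------------------------------------------------
  paths <- list(
    vcf = file.path(out_dir, "panel.vcf"),
    bed = file.path(out_dir, "genes.bed"),
    rsnp_tsv = file.path(out_dir, "rsnps.tsv"),
    gwas_tsv = file.path(out_dir, "gwas.tsv"),
    truth = file.path(out_dir, "truth.json"))

  gt_strings <- vapply(haps, function(h) paste0(h[, 1], "|", h[, 2], collapse = "\t"),
                       character(1))
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##source=rsnpcoseg-synthetic-panel",
    "##contig=<ID=1>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t"),
    paste("1", vt$pos, vt$variant_id, vt$ref, vt$alt, ".", "PASS", ".", "GT",
          gt_strings, sep = "\t"))
  writeLines(vcf_lines, paths$vcf)

  bed <- data.frame(chrom = "1",
                    start = c(bg_gene_start, pair_gene_start) - 1L,
                    end = c(bg_gene_end, pair_gene_end),
                    name = c(gene_names, pair_gene_names))
  bed <- bed[order(bed$start), ]
  write.table(bed, paths$bed, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  write.table(rsnp_df, paths$rsnp_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gwas_df, paths$gwas_tsv, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(
    planted_coseg_pairs = data.frame(
      rsnp_id = rsnp_ids[planted_idx], marker_id = marker_ids,
      epsilon = eps, expected_called = eps == 0, stringsAsFactors = FALSE),
    planted_candidates = truth_cand_df,
    variants = data.frame(
      variant_id = vt$variant_id, pos = vt$pos, kind = vt$kind,
      realized_alt_count = vt$realized_alt_count,
      realized_minor_count = vt$realized_minor_count,
      realized_minor_carriers = vt$realized_minor_carriers,
      stringsAsFactors = FALSE),
    population_alt_freqs = setNames(
      lapply(seq_len(nrow(vt)), function(i) vt$true_alt_freq_by_pop[[i]]),
      vt$variant_id))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")

  list(paths = paths, truth = truth)
}

#' Read a truth file written by [generate_panel()]
#'
#' @param path JSON truth file.
#' @return The truth list with data-frame components restored.
#' @export
read_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Generate independent null carrier-vector pairs
#'
#' Pairs of independent binary carrier vectors with carrier frequencies drawn
#' uniformly from `maf_range`, for type-I-error (calibration) studies of the
#' co-segregation test.
#'
#' @param n_pairs Number of pairs.
#' @param n_rows Vector length (matrix rows).
#' @param maf_range Length-2 range of carrier frequencies.
#' @param seed Integer seed.
#' @return List with 0/1 matrices `a` and `b` (`n_rows` x `n_pairs`) and the
#'   drawn frequencies `freq_a`, `freq_b`.
#' @export
generate_null_pairs <- function(n_pairs, n_rows, maf_range = c(0.05, 0.5), seed = 1L) {
  stopifnot(n_pairs > 0, n_rows > 0, length(maf_range) == 2,
            maf_range[1] <= maf_range[2], maf_range[1] >= 0, maf_range[2] <= 1)
  with_seed(seed, {
    freq_a <- runif(n_pairs, maf_range[1], maf_range[2])
    freq_b <- runif(n_pairs, maf_range[1], maf_range[2])
    a <- matrix(rbinom(n_rows * n_pairs, 1L, rep(freq_a, each = n_rows)), n_rows)
    b <- matrix(rbinom(n_rows * n_pairs, 1L, rep(freq_b, each = n_rows)), n_rows)
    list(a = a, b = b, freq_a = freq_a, freq_b = freq_b)
  })
}

#' Generate planted co-segregating carrier-vector pairs
#'
#' Each pair consists of a carrier vector at the requested carrier frequency
#' and a copy with every row flipped independently with probability
#' `epsilon`; at `epsilon = 0` the copy is exact.
#'
#' @param n_pairs Number of pairs.
#' @param n_rows Vector length.
#' @param carrier_freq Carrier frequency of the source vector.
#' @param epsilon Per-row flip probability in \[0, 1\].
#' @param seed Integer seed.
#' @param min_mac Columns of `a` are redrawn until their carrier count is at
#'   least `min_mac` (default 1, i.e. polymorphic).
#' @return List with 0/1 matrices `a` and `b` (`n_rows` x `n_pairs`).
#' @export
generate_planted_pairs <- function(n_pairs, n_rows, carrier_freq = 0.1,
                                   epsilon = 0, seed = 1L, min_mac = 1L) {
  stopifnot(epsilon >= 0, epsilon <= 1, carrier_freq > 0, carrier_freq < 1)
  with_seed(seed, {
    a <- matrix(rbinom(n_rows * n_pairs, 1L, carrier_freq), n_rows)
    for (j in seq_len(n_pairs)) {
      tries <- 0L
      while (sum(a[, j]) < min_mac && tries < 1000L) {
        a[, j] <- rbinom(n_rows, 1L, carrier_freq)
        tries <- tries + 1L
      }
      if (sum(a[, j]) < min_mac)
        stopf("generate_planted_pairs: cannot reach min_mac = %d at carrier_freq = %g",
              min_mac, carrier_freq)
    }
    flips <- matrix(rbinom(n_rows * n_pairs, 1L, epsilon), n_rows)
    list(a = a, b = (a + flips) %% 2L)
  })
}

#' Build a `coseg_matrix` from a plain 0/1 matrix
#'
#' Convenience constructor for simulation studies that bypass VCF I/O: wraps
#' an integer 0/1 matrix (rows = individuals, columns = variants) into the
#' container the scan functions expect, synthesizing a minimal variant table
#' from the column names.
#'
#' @param codes 0/1 matrix with column names.
#' @param chrom,pos Optional coordinates per column (defaults: chromosome
#'   "1", positions 1..m).
#' @param coding_mode Recorded coding mode label.
#' @return A `coseg_matrix`.
#' @export
as_coseg_matrix <- function(codes, chrom = NULL, pos = NULL, coding_mode = "carrier") {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(colnames(codes))) colnames(codes) <- paste0("v", seq_len(ncol(codes)))
  if (is.null(rownames(codes))) rownames(codes) <- paste0("ind", seq_len(nrow(codes)))
  m <- ncol(codes)
  variants <- data.frame(
    variant_id = colnames(codes),
    chrom = if (is.null(chrom)) rep("1", m) else as.character(chrom),
    pos = if (is.null(pos)) seq_len(m) else as.integer(pos),
    ref_allele = "A", alt_allele = "G", minor_allele = "G",
    mac = as.integer(colSums(codes)),
    maf = colSums(codes) / nrow(codes),
    stringsAsFactors = FALSE)
  structure(list(codes = codes, variants = variants, coding_mode = coding_mode,
                 n_imputed = 0L), class = "coseg_matrix")
}
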