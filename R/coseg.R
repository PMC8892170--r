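#' XOR (Hamming) distance between two binary genotype codes
#'
#' The co-segregation statistic: the number of rows at which two binarized
#' genotype vectors differ, i.e. the population count of their bitwise XOR.
#' Two variants whose minor alleles travel together across individuals have a
#' small XOR distance.
#'
#' @param a,b Binary (0/1) vectors of equal length.
#' @return Non-negative integer Hamming distance.
#' @examples
#' xor_distance(c(0, 1, 1, 0, 1), c(1, 1, 0, 0, 1)) # 2
#' @export
xor_distance <- function(a, b) {
  if (length(a) != length(b))
    stopf("xor_distance: length mismatch (%d vs %d)", length(a), length(b))
  if (!is_binary_vector(a) || !is_binary_vector(b))
    stopf("xor_distance: inputs must be 0/1 vectors without missing values")
  sum(a != b)
}

#' Normalize an XOR distance by minor-allele occurrence
#'
#' Scales the raw Hamming distance by how often the minor alleles occur, so
#' pairs of different frequency become comparable. The default `union` mode
#' divides by the size of the union of the two carrier sets, which is the
#' Jaccard distance on carrier sets: it is bounded in \[0, 1\] and equals 0
#' exactly when the two (non-empty) carrier sets coincide.
#'
#' @param xor Raw XOR distance.
#' @param mac_a,mac_b Minor-allele counts (rows coded 1) of the two variants.
#' @param overlap Number of rows where both codes are 1.
#' @param mode One of `"union"`, `"min_mac"`, `"max_mac"`, `"sum_mac"`.
#' @return Normalized distance (`NA_real_` when the selected denominator is
#'   zero, i.e. both columns are monomorphic — a degenerate pair).
#' @examples
#' normalized_distance(2, 3, 3, 2)            # 2/4 = 0.5
#' normalized_distance(4, 2, 2, 0)            # disjoint carriers -> 1
#' @export
normalized_distance <- function(xor, mac_a, mac_b, overlap,
                                mode = c("union", "min_mac", "max_mac", "sum_mac")) {
  mode <- match.arg(mode)
  if (any(xor != mac_a + mac_b - 2 * overlap))
    stopf("normalized_distance: inconsistent inputs (xor != mac_a + mac_b - 2*overlap)")
  denom <- switch(mode,
    union   = mac_a + mac_b - overlap,
    min_mac = pmin(mac_a, mac_b),
    max_mac = pmax(mac_a, mac_b),
    sum_mac = mac_a + mac_b
  )
  ifelse(denom > 0, xor / denom, NA_real_)
}

#' Exact p-value for co-segregation under random assortment
#'
#' Under the null that the two carrier sets are placed independently at
#' random with their sizes fixed, the carrier overlap follows a
#' hypergeometric distribution with `n_rows` rows, `mac_a` "successes" and
#' `mac_b` draws. Small XOR distance is equivalent to large overlap, so the
#' one-sided p-value toward co-segregation is
#' `P(XOR <= observed) = P(overlap >= (mac_a + mac_b - observed_xor) / 2)`.
#'
#' @param n_rows Number of rows of the binary matrix.
#' @param mac_a,mac_b Minor-allele counts of the two variants (both > 0).
#' @param observed_xor Observed XOR distance; must be feasible for the given
#'   margins (correct parity and range), otherwise a consistency error is
#'   raised.
#' @return p-value in (0, 1]. All arguments are vectorized.
#' @examples
#' exact_pvalue(4, 2, 2, 0)    # 1/6
#' exact_pvalue(4, 2, 2, 4)    # 1
#' @export
exact_pvalue <- function(n_rows, mac_a, mac_b, observed_xor) {
  k <- (mac_a + mac_b - observed_xor) / 2 # implied carrier overlap
  bad <- mac_a <= 0 | mac_b <= 0 | mac_a > n_rows | mac_b > n_rows |
    observed_xor < 0 | k != floor(k) |
    k > pmin(mac_a, mac_b) | k < pmax(0, mac_a + mac_b - n_rows)
  if (any(bad))
    stopf("exact_pvalue: observed_xor infeasible for the given margins (first offending index %d)",
          which(bad)[1])
  phyper(k - 1, mac_a, n_rows - mac_a, mac_b, lower.tail = FALSE)
}

#' Permutation p-value for co-segregation
#'
#' Monte-Carlo reference for [exact_pvalue()]: permutes the row order of one
#' vector uniformly at random and counts permutations whose XOR distance is
#' at most the observed one, with the add-one estimator
#' `p = (1 + #\{xor_perm <= xor_obs\}) / (1 + n_permutations)`, which never
#' returns 0. Reproducible given `seed`; the caller's RNG stream is left
#' untouched.
#'
#' @param a,b Binary vectors of equal length.
#' @param n_permutations Number of random permutations (>= 100).
#' @param seed Integer seed.
#' @return Estimated p-value in (0, 1].
#' @export
permutation_pvalue <- function(a, b, n_permutations = 10000L, seed = 1L) {
  if (length(a) != length(b))
    stopf("permutation_pvalue: length mismatch")
  if (!is_binary_vector(a) || !is_binary_vector(b))
    stopf("permutation_pvalue: inputs must be 0/1 vectors")
  if (n_permutations < 100L)
    stopf("permutation_pvalue: n_permutations must be >= 100")
  obs <- sum(a != b)
  n <- length(a)
  with_seed(seed, {
    hits <- 0L
    for (i in seq_len(n_permutations)) {
      if (sum(a[sample.int(n)] != b) <= obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_permutations)
  })
}

#' Configuration for the co-segregation scan
#'
#' @param alpha Significance level for calling a marker co-segregating
#'   (default 0.01, the raw per-pair call used throughout).
#' @param normalization Distance normalization mode (see
#'   [normalized_distance()]).
#' @param null_model `"hypergeometric_exact"` (default) or `"permutation"`.
#' @param n_permutations Permutations per pair under the permutation null.
#' @param seed Seed for the permutation null.
#' @param multiple_testing `"none"` (raw p < alpha, the default) or
#'   `"benjamini_hochberg"` (FDR-adjusted p < alpha).
#' @return A list of class `coseg_config`.
#' @export
coseg_config <- function(alpha = 0.01,
                         normalization = c("union", "min_mac", "max_mac", "sum_mac"),
                         null_model = c("hypergeometric_exact", "permutation"),
                         n_permutations = 1000L, seed = 1L,
                         multiple_testing = c("none", "benjamini_hochberg")) {
  stopifnot(alpha > 0, alpha < 1)
  null_model <- match.arg(null_model)
  if (null_model == "permutation" && n_permutations < 100L)
    stopf("coseg_config: n_permutations must be >= 100 under the permutation null")
  structure(list(
    alpha = alpha,
    normalization = match.arg(normalization),
    null_model = null_model,
    n_permutations = as.integer(n_permutations),
    seed = as.integer(seed),
    multiple_testing = match.arg(multiple_testing)
  ), class = "coseg_config")
}

#' Scan all rSNP/marker pairs for co-segregation
#'
#' Computes, for every (query rSNP, candidate marker) pair, the XOR distance,
#' carrier-union size, normalized distance and p-value, and flags pairs below
#' the significance threshold as co-segregating. Markers are processed in
#' column chunks so memory stays bounded for large panels. Monomorphic
#' columns (mac = 0) and pairs whose normalization denominator is zero are
#' excluded and reported. A variant appearing in both sets is never paired
#' with itself.
#'
#' @param bm A `coseg_matrix`.
#' @param rsnp_ids Column ids of the query rSNPs.
#' @param marker_ids Column ids of the candidate (coding) markers.
#' @param config A [coseg_config()].
#' @param chunk_size Number of marker columns processed per block.
#' @return Data frame with one row per tested pair: `rsnp_id`, `marker_id`,
#'   `xor_distance`, `union_count`, `normalized_distance`, `p_value`,
#'   `cosegregating`, sorted by (`rsnp_id`, `p_value`,
#'   `normalized_distance`, `marker_id`). Attribute `"excluded"` holds a data
#'   frame of excluded columns/pairs with reasons.
#' @export
scan_pairs <- function(bm, rsnp_ids, marker_ids, config = coseg_config(),
                       chunk_size = 10000L) {
  stopifnot(inherits(bm, "coseg_matrix"))
  if (length(rsnp_ids) == 0L || length(marker_ids) == 0L)
    stopf("scan_pairs: empty rSNP or marker set")
  missing_ids <- setdiff(c(rsnp_ids, marker_ids), colnames(bm$codes))
  if (length(missing_ids))
    stopf("scan_pairs: ids not in matrix: %s", paste(head(missing_ids, 5), collapse = ", "))

  codes <- bm$codes
  n <- nrow(codes)
  mac <- colSums(codes)

  excluded <- list()
  mono_r <- rsnp_ids[mac[rsnp_ids] == 0]
  mono_m <- marker_ids[mac[marker_ids] == 0]
  if (length(mono_r) || length(mono_m))
    excluded[[length(excluded) + 1L]] <- data.frame(
      id = c(mono_r, mono_m), reason = "monomorphic column (mac = 0)")
  rsnp_use <- setdiff(rsnp_ids, mono_r)
  marker_use <- setdiff(marker_ids, mono_m)
  if (length(rsnp_use) == 0L || length(marker_use) == 0L)
    stopf("scan_pairs: no polymorphic rSNP or marker columns left to test")

  res <- vector("list", length(rsnp_use))
  for (ri in seq_along(rsnp_use)) {
    rid <- rsnp_use[ri]
    a <- codes[, rid]
    mac_a <- mac[[rid]]
    chunks <- split(marker_use, ceiling(seq_along(marker_use) / chunk_size))
    parts <- lapply(chunks, function(ids) {
      block <- codes[, ids, drop = FALSE]
      overlap <- as.integer(crossprod(block, a))
      mac_b <- mac[ids]
      xor <- mac_a + mac_b - 2L * overlap
      data.frame(rsnp_id = rid, marker_id = ids,
                 xor_distance = as.integer(xor),
                 union_count = as.integer(mac_a + mac_b - overlap),
                 overlap = overlap, mac_b = as.integer(mac_b),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    part <- do.call(rbind, parts)
    part <- part[part$marker_id != rid, , drop = FALSE]
    part$normalized_distance <- normalized_distance(
      part$xor_distance, mac_a, part$mac_b, part$overlap, config$normalization)
    degen <- is.na(part$normalized_distance)
    if (any(degen))
      excluded[[length(excluded) + 1L]] <- data.frame(
        id = paste(rid, part$marker_id[degen], sep = "/"), reason = "degenerate pair")
    part <- part[!degen, , drop = FALSE]
    if (config$null_model == "hypergeometric_exact") {
      part$p_value <- exact_pvalue(n, mac_a, part$mac_b, part$xor_distance)
    } else {
      part$p_value <- vapply(seq_len(nrow(part)), function(i)
        permutation_pvalue(a, codes[, part$marker_id[i]],
                           config$n_permutations,
                           seed = config$seed + i), numeric(1))
    }
    res[[ri]] <- part
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL

  p_call <- switch(config$multiple_testing,
    none = out$p_value,
    benjamini_hochberg = p.adjust(out$p_value, method = "BH"))
  out$cosegregating <- p_call < config$alpha
  out$mac_b <- NULL
  out$overlap <- NULL
  out <- out[order(out$rsnp_id, out$p_value, out$normalized_distance, out$marker_id), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(id = character(), reason = character())
  out
}

#' Write / read a distance-record table
#'
#' @param records Output of [scan_pairs()].
#' @param file TSV path.
#' @export
write_distance_records <- function(records, file) {
  write.table(records, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_distance_records
#' @export
read_distance_records <- function(file) {
  data.table::fread(file, sep = "\t", header = TRUE, data.table = FALSE)
}
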