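#' Pipeline configuration
#'
#' One structured configuration for the end-to-end run. Either all four
#' input paths are given, or `simulate` carries a [sim_config()] and the
#' inputs are generated under `out_dir/sim` first.
#'
#' @param out_dir Output directory for all artifacts.
#' @param vcf,annotation,rsnp_tsv,gwas_tsv Input paths (ignored when
#'   `simulate` is set).
#' @param simulate Optional [sim_config()].
#' @param coding_mode Binarization mode, see [binarize()].
#' @param alpha,normalization,null_model,n_permutations,multiple_testing
#'   Co-segregation parameters, see [coseg_config()].
#' @param half_window GWAS window half-width in bp.
#' @param signature_terms Trait keywords; default [cardio_signature()].
#' @param seed Top-level seed funneling all randomness.
#' @param validate Require the four inputs (or `simulate`) to be named; set
#'   to `FALSE` when configuring a single downstream stage that only reads
#'   persisted artifacts.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            vcf = NULL, annotation = NULL, rsnp_tsv = NULL,
                            gwas_tsv = NULL, simulate = NULL,
                            coding_mode = "carrier",
                            alpha = 0.01, normalization = "union",
                            null_model = "hypergeometric_exact",
                            n_permutations = 1000L,
                            multiple_testing = "none",
                            half_window = 5000L,
                            signature_terms = cardio_signature(),
                            seed = 1L, validate = TRUE) {
  cfg <- structure(list(
    out_dir = out_dir, vcf = vcf, annotation = annotation,
    rsnp_tsv = rsnp_tsv, gwas_tsv = gwas_tsv, simulate = simulate,
    coding_mode = coding_mode, alpha = alpha, normalization = normalization,
    null_model = null_model, n_permutations = as.integer(n_permutations),
    multiple_testing = multiple_testing, half_window = as.integer(half_window),
    signature_terms = signature_terms, seed = as.integer(seed)
  ), class = "pipeline_config")
  if (validate && is.null(cfg$simulate)) {
    for (f in c("vcf", "annotation", "rsnp_tsv", "gwas_tsv"))
      if (is.null(cfg[[f]]))
        stopf("pipeline_config: input '%s' is required (stage: %s) unless simulate is set",
              f, if (f == "gwas_tsv") "gwas_mapper" else "panel_io")
  }
  cfg
}

#' Default fully-synthetic pipeline configuration
#'
#' The reference end-to-end setup used by the test suite: the default
#' [sim_config()] panel, carrier coding, the exact hypergeometric null, and
#' Benjamini–Hochberg calling (over the ~4x10^4 pair tests of the default
#' panel, raw per-pair calling at alpha would admit a handful of chance
#' markers; FDR control keeps the called set equal to the planted one, so
#' the pipeline's output is comparable with the generator's truth file).
#'
#' @param out_dir Output directory.
#' @param seed Top-level seed.
#' @return A `pipeline_config`.
#' @export
default_synthetic_pipeline <- function(out_dir, seed = 1L) {
  pipeline_config(out_dir = out_dir,
                  simulate = sim_config(seed = seed),
                  multiple_testing = "benjamini_hochberg",
                  seed = seed)
}

#' @keywords internal
#' @noRd
artifact_paths <- function(out_dir) {
  list(variants = file.path(out_dir, "variants.tsv"),
       matrix = file.path(out_dir, "matrix.tsv"),
       absent = file.path(out_dir, "absent_rsnps.txt"),
       distances = file.path(out_dir, "distances.tsv"),
       gwas_filtered = file.path(out_dir, "gwas_filtered.tsv"),
       candidates = file.path(out_dir, "candidates.tsv"),
       candidates_bed = file.path(out_dir, "candidates.bed"),
       summary = file.path(out_dir, "summary.json"),
       manifest = file.path(out_dir, "manifest.json"))
}

#' @keywords internal
#' @noRd
require_artifacts <- function(paths, stage) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing))
    stopf("stage '%s': missing upstream artifact(s): %s — run the previous stage first",
          stage, paste(unlist(missing), collapse = ", "))
}

#' Run one pipeline stage on persisted artifacts
#'
#' `stage_ingest` reads the VCF, rSNP list and annotation and persists the
#' restricted binary matrix; `stage_coseg` scans all rSNP/marker pairs;
#' `stage_map` filters the GWAS table and intersects windows; `stage_report`
#' writes the summary JSON. Each stage reads only the previous stage's
#' files, so they can be driven independently (e.g. from the command line).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the paths written (and for `stage_report`, the summary
#'   list).
#' @export
stage_ingest <- function(config) {
  p <- artifact_paths(config$out_dir)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  msg_stage("ingest", "loading panel ", config$vcf)
  panel <- load_panel(config$vcf)
  bm <- binarize(panel, config$coding_mode)
  queries <- load_rsnp_queries(config$rsnp_tsv)
  res <- restrict_to_transcribed(bm, config$annotation, queries$rsnp_id)
  msg_stage("ingest", sprintf("%d variants retained (%d skipped records, %d absent rSNPs)",
                              ncol(res$matrix$codes), panel$n_skipped, length(res$absent_rsnps)))
  write_binary_matrix(res$matrix, p$variants, p$matrix)
  writeLines(res$absent_rsnps, p$absent)
  invisible(p)
}

#' @rdname stage_ingest
#' @export
stage_coseg <- function(config) {
  p <- artifact_paths(config$out_dir)
  require_artifacts(p[c("variants", "matrix")], "coseg")
  bm <- read_binary_matrix(p$variants, p$matrix)
  v <- bm$variants
  rsnp_ids <- v$variant_id[v$is_rsnp & v$mac > 0]
  marker_ids <- v$variant_id[v$in_transcribed_region & !v$is_rsnp & v$mac > 0]
  cc <- coseg_config(alpha = config$alpha, normalization = config$normalization,
                     null_model = config$null_model,
                     n_permutations = config$n_permutations,
                     seed = config$seed,
                     multiple_testing = config$multiple_testing)
  msg_stage("coseg", sprintf("scanning %d rSNPs x %d markers", length(rsnp_ids),
                             length(marker_ids)))
  rec <- scan_pairs(bm, rsnp_ids, marker_ids, cc)
  write_distance_records(rec, p$distances)
  msg_stage("coseg", sprintf("%d pairs tested, %d called at alpha = %g (%s)",
                             nrow(rec), sum(rec$cosegregating), config$alpha,
                             config$multiple_testing))
  invisible(p)
}

#' @rdname stage_ingest
#' @export
stage_map <- function(config) {
  p <- artifact_paths(config$out_dir)
  require_artifacts(p[c("variants", "matrix", "distances")], "map")
  if (is.null(config$gwas_tsv) || !file.exists(config$gwas_tsv))
    stopf("stage 'map' (gwas_mapper): GWAS table input is missing: %s",
          if (is.null(config$gwas_tsv)) "<unset>" else config$gwas_tsv)
  bm <- read_binary_matrix(p$variants, p$matrix)
  v <- bm$variants
  gwas <- load_gwas_table(config$gwas_tsv)
  gsig <- filter_by_signature(gwas, config$signature_terms)
  msg_stage("map", sprintf("%d/%d GWAS entries match the trait signature",
                           nrow(gsig), nrow(gwas)))
  rec <- read_distance_records(p$distances)
  rec <- attach_marker_positions(rec, v)
  rsnp_positions <- data.frame(rsnp_id = v$variant_id[v$is_rsnp],
                               chrom = v$chrom[v$is_rsnp], pos = v$pos[v$is_rsnp])
  queries <- if (!is.null(config$rsnp_tsv) && file.exists(config$rsnp_tsv))
    load_rsnp_queries(config$rsnp_tsv) else NULL
  cand <- window_intersect(gsig, rsnp_positions, rec,
                           half_window = config$half_window,
                           rsnp_queries = queries)
  gsig_out <- gsig
  gsig_out$mapped_genes <- vapply(gsig_out$mapped_genes, paste, character(1), collapse = ",")
  gsig_out$matched_terms <- vapply(gsig_out$matched_terms, paste, character(1), collapse = ",")
  write.table(gsig_out, p$gwas_filtered, sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidates(cand, p$candidates, p$candidates_bed, rsnp_positions)
  msg_stage("map", sprintf("%d candidate associations", nrow(cand)))
  invisible(p)
}

#' @rdname stage_ingest
#' @export
stage_report <- function(config) {
  p <- artifact_paths(config$out_dir)
  require_artifacts(p["candidates"], "report")
  cand <- read_candidates(p$candidates)
  queries <- if (!is.null(config$rsnp_tsv) && file.exists(config$rsnp_tsv))
    load_rsnp_queries(config$rsnp_tsv) else NULL
  s <- summarize_candidates(cand, queries)
  jsonlite::write_json(s, p$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  msg_stage("report", sprintf("%d candidate rSNPs (%d with a direct positional coincidence)",
                              s$totals$n_candidate_rsnps, s$totals$n_direct_rsnps))
  invisible(s)
}

#' Run the whole pipeline end to end
#'
#' Executes simulate (optional) -> ingest -> coseg -> map -> report, persists
#' every intermediate artifact under `config$out_dir`, and writes a machine-
#' readable run manifest with input checksums and per-stage record counts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the artifact `paths`, the `summary` and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    msg_stage("simulate", "generating synthetic input bundle")
    sim <- generate_panel(config$simulate, file.path(config$out_dir, "sim"))
    config$vcf <- sim$paths$vcf
    config$annotation <- sim$paths$bed
    config$rsnp_tsv <- sim$paths$rsnp_tsv
    config$gwas_tsv <- sim$paths$gwas_tsv
  }
  for (f in c("vcf", "annotation", "rsnp_tsv", "gwas_tsv"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stopf("run_pipeline: input '%s' is missing%s", f,
            if (f == "gwas_tsv") " (stage gwas_mapper)" else "")

  stage_ingest(config)
  stage_coseg(config)
  stage_map(config)
  summary <- stage_report(config)
  manifest <- write_manifest(config)
  invisible(list(paths = artifact_paths(config$out_dir), summary = summary,
                 manifest = manifest))
}

#' @keywords internal
#' @noRd
count_rows <- function(file, header = TRUE, comment = NULL) {
  if (!file.exists(file)) return(NA_integer_)
  lines <- readLines(file)
  if (!is.null(comment)) lines <- lines[!startsWith(lines, comment)]
  lines <- lines[nzchar(lines)]
  max(0L, length(lines) - if (header) 1L else 0L)
}

#' @keywords internal
#' @noRd
write_manifest <- function(config) {
  p <- artifact_paths(config$out_dir)
  inputs <- list(vcf = config$vcf, annotation = config$annotation,
                 rsnp_tsv = config$rsnp_tsv, gwas_tsv = config$gwas_tsv)
  rec <- read_distance_records(p$distances)
  manifest <- list(
    tool = "rsnpcoseg",
    version = as.character(packageVersion("rsnpcoseg")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    config = config[setdiff(names(config), "simulate")],
    sim_config = if (!is.null(config$simulate)) unclass(config$simulate) else NULL,
    input_md5 = setNames(as.list(md5sum(unlist(inputs))), names(inputs)),
    counts = list(
      variants_retained = count_rows(p$variants),
      absent_rsnps = count_rows(p$absent, header = FALSE),
      pairs_tested = count_rows(p$distances),
      pairs_called = sum(rec$cosegregating),
      gwas_entries_retained = count_rows(p$gwas_filtered),
      candidates = count_rows(p$candidates)))
  jsonlite::write_json(manifest, p$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  manifest
}
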