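#' Pipeline run configuration
#'
#' Collects the geometry and policy knobs shared by the pipeline stages.
#' `min_read1_len` must equal `barcode_len + umi_len` (28 cycles for the
#' standard Visium geometry); violations are errors before any work is done.
#'
#' @param barcode_len,umi_len Spatial barcode and UMI lengths.
#' @param min_read1_len Minimum read 1 length in cycles.
#' @param max_hamming Barcode correction radius (0 or 1).
#' @param log_base Logarithm base for the Shannon index.
#' @param dedup_policy Only `"majority_discard_ties"` is implemented: within
#'   a (barcode, UMI) pair the majority clone wins and ties are discarded.
#' @param seed Integer seed echoed into run logs.
#' @return A validated `run_config` list.
#' @export
run_config <- function(barcode_len = 16L, umi_len = 12L, min_read1_len = 28L,
                       max_hamming = 0L, log_base = exp(1),
                       dedup_policy = "majority_discard_ties", seed = 1L) {
  assert_count(barcode_len, "barcode_len", min = 1L)
  assert_count(umi_len, "umi_len", min = 1L)
  assert_count(min_read1_len, "min_read1_len", min = 1L)
  if (min_read1_len != barcode_len + umi_len) {
    stop_tcrspot("`min_read1_len` must equal `barcode_len + umi_len`",
                 "config_error")
  }
  if (!max_hamming %in% c(0L, 1L)) {
    stop_tcrspot("`max_hamming` must be 0 or 1", "config_error")
  }
  if (!identical(dedup_policy, "majority_discard_ties")) {
    stop_tcrspot("unknown dedup policy", "config_error")
  }
  structure(
    list(barcode_len = as.integer(barcode_len), umi_len = as.integer(umi_len),
         min_read1_len = as.integer(min_read1_len),
         max_hamming = as.integer(max_hamming), log_base = log_base,
         dedup_policy = dedup_policy, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Run the complete spatial TCR pipeline
#'
#' Chains the stages of the analysis: clonotype calling on read 2 (native
#' caller, or a MiXCR import when `clones_table`/`reads_dir` are given),
#' read-1 linkage to capture spots, (barcode, UMI) deduplication, the
#' spot-by-clone matrix, and repertoire statistics. Non-TRB clones are
#' flagged and excluded from the matrix. All outputs are written under
#' `out_dir`.
#'
#' @param r1,r2 Paths to the read 1 / read 2 FASTQ(.gz) files (`r2` unused
#'   when importing MiXCR output).
#' @param positions Path to the tissue positions CSV.
#' @param reference_fasta,reference_anchors Segment reference paths (see
#'   [write_reference()]); alternatively pass a `segment_reference` via
#'   `reference`.
#' @param primers Path to the primer manifest TSV (or a `primer_pool` via
#'   `primer_pool`).
#' @param out_dir Output directory.
#' @param clones_table,reads_dir Optional MiXCR-format clone table and
#'   per-clone reads directory; when given they replace the native caller.
#' @param reference,primer_pool Optional in-memory objects overriding the
#'   path arguments.
#' @param config A [run_config()].
#' @return Invisibly, a list: `clones`, `flagged_clones`, `read_map`,
#'   `linked`, `deduped`, `matrix`, `stats`, `paths`.
#' @export
run_spatial_tcr <- function(r1, r2 = NULL, positions, reference_fasta = NULL,
                            reference_anchors = NULL, primers = NULL,
                            out_dir = ".", clones_table = NULL,
                            reads_dir = NULL, reference = NULL,
                            primer_pool = NULL, config = run_config()) {
  for (p in c(r1, positions, clones_table,
              if (is.null(reference)) c(reference_fasta, reference_anchors),
              if (is.null(primer_pool) && is.null(clones_table)) primers)) {
    if (!is.null(p) && !file.exists(p)) {
      stop_tcrspot(sprintf("required input missing: %s", p), "io_error")
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (!is.null(clones_table)) {
    called <- import_mixcr(clones_table, reads_dir)
    called$log <- tibble(n_reads = NA_integer_, no_v = NA_integer_,
                         no_j = NA_integer_, cdr3_fail = NA_integer_,
                         assigned = nrow(called$read_map))
    n_reads_total <- NULL
  } else {
    if (is.null(r2)) stop_tcrspot("required input missing: r2", "io_error")
    if (is.null(reference)) {
      reference <- read_reference(reference_fasta, reference_anchors)
    }
    if (is.null(primer_pool)) primer_pool <- load_primer_pool(primers)
    reads2 <- read_fastq(r2)
    called <- call_clonotypes(reads2, reference, primer_pool)
    n_reads_total <- nrow(reads2)
  }
  spot_map <- read_spot_map(positions)

  parts <- chain_filter(called$clones)
  trb_map <- filter(called$read_map,
                    .data$clone_id %in% parts$kept$clone_id)
  linked <- link_reads(trb_map, r1, spot_map, max_hamming = config$max_hamming)
  deduped <- deduplicate(linked$records)
  mat <- build_matrix(deduped, spot_map)
  stats <- repertoire_stats(called$clones, deduped, linked$log, spot_map,
                            n_reads = n_reads_total, base = config$log_base)

  paths <- list(
    clones = file.path(out_dir, "clones.tsv"),
    flagged = file.path(out_dir, "flagged_clones.tsv"),
    matrix = file.path(out_dir, "spot_clone_matrix.tsv"),
    link_log = file.path(out_dir, "link_log.tsv"),
    stats = file.path(out_dir, "repertoire_stats.tsv"),
    run_log = file.path(out_dir, "run_log.tsv")
  )
  write_clones_table(called$clones, paths$clones)
  write_clones_table(parts$flagged, paths$flagged)
  write_matrix(mat, paths$matrix)
  readr::write_tsv(linked$log, paths$link_log, eol = "\n", progress = FALSE)
  write_stats(stats, paths$stats)
  run_log <- tibble(
    key = c("tcrspot_version", "seed", "max_hamming", "dedup_policy",
            "log_base", "n_reads", "n_clones", "n_flagged_clones"),
    value = c(as.character(utils::packageVersion("tcrspot")),
              config$seed, config$max_hamming, config$dedup_policy,
              format(config$log_base, digits = 10),
              called$log$n_reads %||% NA, nrow(parts$kept), nrow(parts$flagged))
  )
  readr::write_tsv(run_log, paths$run_log, eol = "\n", progress = FALSE)

  invisible(list(clones = called$clones, flagged_clones = parts$flagged,
                 read_map = called$read_map, linked = linked,
                 deduped = deduped, matrix = mat, stats = stats,
                 call_log = called$log, paths = paths))
}
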