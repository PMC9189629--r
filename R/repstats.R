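#' Shannon diversity of a clonal repertoire
#'
#' H = -sum p_i log p_i over clone frequencies p_i, in natural-log units by
#' default (a monoclonal repertoire scores 0; a uniform K-clone repertoire
#' scores log K).
#'
#' @param umi_counts Positive integer vector of per-clone UMI counts.
#' @param base Logarithm base (default `exp(1)`).
#' @return Shannon index (numeric scalar).
#' @export
shannon_diversity <- function(umi_counts, base = exp(1)) {
  if (length(umi_counts) == 0L) {
    stop_tcrspot("clone count vector is empty", "domain_error")
  }
  if (any(umi_counts <= 0) || anyNA(umi_counts)) {
    stop_tcrspot("clone counts must be positive", "domain_error")
  }
  p <- umi_counts / sum(umi_counts)
  -sum(p * log(p)) / log(base)
}

#' TCR sequencing saturation
#'
#' 1 - unique UMIs / clone-supporting reads, with reads counted
#' barcode-matched and pre-deduplication (the 10x-style definition). Equals
#' the fraction of reads that re-observe an already-seen molecule.
#'
#' @param n_clone_reads Barcode-matched clone-supporting reads (pre-dedup).
#' @param n_umis Deduplicated UMI count.
#' @return Fraction in `[0, 1]`, or `NA` when `n_clone_reads` is 0.
#' @export
saturation <- function(n_clone_reads, n_umis) {
  if (n_clone_reads == 0L) {
    return(NA_real_)
  }
  assert_count(n_clone_reads, "n_clone_reads", min = 1L)
  assert_count(n_umis, "n_umis", min = 0L)
  if (n_umis > n_clone_reads) {
    stop_tcrspot("n_umis cannot exceed n_clone_reads", "domain_error")
  }
  1 - n_umis / n_clone_reads
}

#' Mean TCR UMIs per in-tissue spot
#'
#' @param n_umis Deduplicated in-tissue UMI count.
#' @param spot_map A `spot_map` tibble with at least one in-tissue spot.
#' @return UMIs per spot (numeric scalar).
#' @export
umis_per_spot <- function(n_umis, spot_map) {
  n_spots <- sum(spot_map$in_tissue)
  if (n_spots == 0L) {
    stop_tcrspot("spot map has no in-tissue spots", "domain_error")
  }
  n_umis / n_spots
}

#' Fraction of clone-supporting reads in spots under tissue
#'
#' The analogue of Space Ranger's "Fraction Reads in Spots Under Tissue";
#' a low value indicates permeabilisation problems or a mismatched tissue
#' positions list.
#'
#' @param link_log One-row link log from [link_reads()].
#' @return in_tissue / (in_tissue + off_tissue + unmatched).
#' @export
fraction_in_tissue <- function(link_log) {
  total <- link_log$in_tissue + link_log$off_tissue + link_log$unmatched_barcode
  if (length(total) != 1L || total == 0L) {
    stop_tcrspot("link log is empty", "domain_error")
  }
  link_log$in_tissue / total
}

#' Partition clones into TCRbeta and flagged non-TRB chains
#'
#' Targeted TRBV amplification can cross-prime homologous B cell receptor V
#' genes (immunoglobulin light chains especially); only TCRbeta clones should
#' enter downstream analysis, so non-TRB calls are flagged with their V gene
#' rather than silently kept.
#'
#' @param clones Clonotype tibble with a `chain` column.
#' @return A list `kept` (TRB clones) and `flagged` (everything else).
#' @export
chain_filter <- function(clones) {
  list(
    kept = filter(clones, .data$chain == "TRB"),
    flagged = filter(clones, .data$chain != "TRB")
  )
}

#' UMI-weighted clone overlap with a reference repertoire
#'
#' Fraction of deduplicated UMIs whose clone key is found in an independent
#' reference set (e.g. clonotypes from matched single-cell V(D)J sequencing).
#' UMI weighting matches reporting overlap as "% of UMIs"; `clone`
#' weighting counts each clone once.
#'
#' @param deduped Deduplicated linked records (with `clone_id`).
#' @param clones Clonotype tibble mapping `clone_id` to key fields.
#' @param reference_keys Character vector of reference clone keys.
#' @param key `"vj_nt"` (default) keys on `V|J|CDR3nt`; `"aa"` keys on the
#'   CDR3 amino-acid sequence alone.
#' @param weight `"umi"` (default) or `"clone"`.
#' @return Overlap fraction in `[0, 1]`.
#' @export
clone_overlap <- function(deduped, clones, reference_keys,
                          key = c("vj_nt", "aa"), weight = c("umi", "clone")) {
  key <- match.arg(key)
  weight <- match.arg(weight)
  if (nrow(deduped) == 0L) {
    stop_tcrspot("no deduplicated UMIs to compare", "domain_error")
  }
  keys <- clone_keys(clones, key)
  if (weight == "clone") {
    present <- keys[match(unique(deduped$clone_id), clones$clone_id)]
    return(mean(present %in% reference_keys))
  }
  umi_keys <- keys[match(deduped$clone_id, clones$clone_id)]
  mean(umi_keys %in% reference_keys)
}

#' Clone keys at a chosen granularity
#'
#' @param clones Clonotype tibble.
#' @param key `"vj_nt"` or `"aa"` (see [clone_overlap()]).
#' @return Character vector of keys, one per clone row.
#' @export
clone_keys <- function(clones, key = c("vj_nt", "aa")) {
  key <- match.arg(key)
  if (key == "vj_nt") {
    paste(clones$v_gene, clones$j_gene, clones$cdr3_nt, sep = "|")
  } else {
    clones$cdr3_aa
  }
}

#' Repertoire summary statistics
#'
#' Assembles the per-sample summary: total reads, TCR UMIs, clone count,
#' Shannon diversity, sequencing saturation, UMIs per in-tissue spot, the
#' fraction of clone-supporting reads under tissue, and the number of
#' flagged non-TRB clones.
#'
#' @param clones Clonotype tibble.
#' @param deduped Deduplicated linked records from [deduplicate()].
#' @param link_log Link log from [link_reads()].
#' @param spot_map A `spot_map` tibble.
#' @param n_reads Total sequenced read pairs for the sample (defaults to the
#'   link log total, i.e. clone-supporting reads only, when unknown).
#' @param base Logarithm base for the Shannon index.
#' @return One-row `repertoire_stats` tibble.
#' @export
repertoire_stats <- function(clones, deduped, link_log, spot_map,
                             n_reads = NULL, base = exp(1)) {
  in_t <- filter(deduped, .data$matched == "in_tissue")
  umi_per_clone <- count(in_t, .data$clone_id)
  n_umis <- nrow(in_t)
  n_clone_reads <- link_log$in_tissue + link_log$off_tissue
  out <- tibble(
    n_reads = as.integer(n_reads %||% link_log$total),
    n_tcr_umis = n_umis,
    n_clones = nrow(umi_per_clone),
    shannon = if (n_umis > 0L) shannon_diversity(umi_per_clone$n, base) else NA_real_,
    saturation = saturation(n_clone_reads, nrow(deduped)),
    umis_per_spot = umis_per_spot(n_umis, spot_map),
    frac_reads_in_tissue = fraction_in_tissue(link_log),
    n_non_trb_clones = sum(clones$chain != "TRB")
  )
  structure(out, class = c("repertoire_stats", class(out)))
}

#' @rdname repertoire_stats
#' @param x A `repertoire_stats` object.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.repertoire_stats <- function(x, ...) as_tibble(unclass(x))

#' Write repertoire statistics as TSV plus JSON sidecar
#'
#' @param stats A `repertoire_stats` tibble (one row per sample).
#' @param path Output TSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stats <- function(stats, path) {
  readr::write_tsv(as_tibble(unclass(stats)), path, eol = "\n", progress = FALSE)
  jsonlite::write_json(as.list(as_tibble(unclass(stats))[1L, ]),
                       paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
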