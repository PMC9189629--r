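#' Assign a V segment to read 2 sequences
#'
#' Amplicons begin at a TRBV primer, so V identity is read from the 5' end of
#' read 2. For each primer the query is the primer sequence extended through
#' the 3' end of its V segment; the best ungapped placement over start offsets
#' 0-10 (allowing for the partial read 2 tail ahead of the primer) is kept
#' when its mismatch fraction is at most `max_mismatch_frac`. Score ties are
#' broken by lexicographically smallest gene name.
#'
#' @param reads Tibble with columns `read_id`, `sequence` (read 2).
#' @param reference A [segment_reference()].
#' @param primer_pool A `primer_pool` tibble; each `primer_seq` must occur
#'   within its V segment.
#' @param max_mismatch_frac Maximum tolerated mismatch fraction over the
#'   aligned span (default 0.1).
#' @param max_offset Largest scanned start offset on the read (default 10).
#' @return A tibble, one row per read: `read_id`, `v_gene`, `v_score`,
#'   `v_mismatches`, `v_read_start`, `v_read_end`, `v_ref_start`, `v_ref_end`
#'   (0-based half-open; `NA` for no-calls).
#' @export
assign_v <- function(reads, reference, primer_pool, max_mismatch_frac = 0.1,
                     max_offset = 10L) {
  q <- v_queries(reference, primer_pool)
  hit <- scan_ungapped(reads$sequence, q$query, 0L, as.integer(max_offset),
                       min_span = 20L)
  span <- hit$read_end - hit$read_start
  ok <- !is.na(hit$query) & hit$mismatches / span <= max_mismatch_frac
  qi <- ifelse(ok, hit$query, NA_integer_)
  tibble(
    read_id = reads$read_id,
    v_gene = q$v_gene[qi],
    v_score = ifelse(ok, hit$score, NA_integer_),
    v_mismatches = ifelse(ok, hit$mismatches, NA_integer_),
    v_read_start = ifelse(ok, hit$read_start, NA_integer_),
    v_read_end = ifelse(ok, hit$read_end, NA_integer_),
    v_ref_start = q$ref_start[qi],
    v_ref_end = q$ref_start[qi] + ifelse(ok, span, NA_integer_)
  )
}

# one query per primer: primer + V 3' region, sorted by gene name so the
# scan kernel's first-wins tie rule matches "lexicographically smallest"
v_queries <- function(reference, primer_pool) {
  v <- reference$v_segments
  idx <- match(primer_pool$v_gene_name, v$name)
  if (anyNA(idx)) {
    stop_tcrspot(
      sprintf("primer gene '%s' absent from reference",
              primer_pool$v_gene_name[which(is.na(idx))[1L]]),
      "validation_error"
    )
  }
  start <- vapply(seq_along(idx), function(i) {
    p <- regexpr(primer_pool$primer_seq[i], v$sequence[idx[i]], fixed = TRUE)
    as.integer(p)
  }, integer(1))
  if (any(start < 1L)) {
    bad <- primer_pool$v_gene_name[start < 1L][1L]
    stop_tcrspot(
      sprintf("primer for '%s' does not occur in its V segment", bad),
      "validation_error"
    )
  }
  out <- tibble(
    v_gene = primer_pool$v_gene_name,
    query = substr(v$sequence[idx], start, nchar(v$sequence[idx])),
    ref_start = start - 1L
  )
  arrange(out, .data$v_gene)
}

#' Assign a J segment downstream of the V alignment
#'
#' Each J germline sequence is slid ungapped over all read offsets 3' of the
#' V alignment end; the best placement is accepted when it covers at least
#' `min_span` nucleotides with at most `max_mismatch` mismatches. Score ties
#' are broken by lexicographically smallest gene name.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param reference A [segment_reference()].
#' @param v_read_end Integer vector, per read, of the V alignment end (0-based
#'   exclusive); reads with `NA` are skipped.
#' @param max_mismatch Maximum mismatches tolerated (default 2).
#' @param min_span Minimum aligned nucleotides (default 20).
#' @return A tibble: `read_id`, `j_gene`, `j_score`, `j_mismatches`,
#'   `j_read_start`, `j_read_end`, `j_ref_start`, `j_ref_end`.
#' @export
assign_j <- function(reads, reference, v_read_end, max_mismatch = 2L,
                     min_span = 20L) {
  j <- arrange(reference$j_segments, .data$name)
  len <- nchar(reads$sequence)
  omin <- ifelse(is.na(v_read_end), 0L, as.integer(v_read_end))
  omax <- pmax(len - as.integer(min_span), 0L)
  scannable <- !is.na(v_read_end) & omin <= omax
  out <- tibble(
    read_id = reads$read_id,
    j_gene = NA_character_,
    j_score = NA_integer_, j_mismatches = NA_integer_,
    j_read_start = NA_integer_, j_read_end = NA_integer_,
    j_ref_start = NA_integer_, j_ref_end = NA_integer_
  )
  if (!any(scannable)) {
    return(out)
  }
  hit <- scan_ungapped(reads$sequence[scannable], j$sequence,
                       omin[scannable], omax[scannable],
                       min_span = as.integer(min_span))
  ok <- !is.na(hit$query) & hit$mismatches <= max_mismatch
  qi <- ifelse(ok, hit$query, NA_integer_)
  out$j_gene[scannable] <- j$name[qi]
  out$j_score[scannable] <- ifelse(ok, hit$score, NA_integer_)
  out$j_mismatches[scannable] <- ifelse(ok, hit$mismatches, NA_integer_)
  out$j_read_start[scannable] <- ifelse(ok, hit$read_start, NA_integer_)
  out$j_read_end[scannable] <- ifelse(ok, hit$read_end, NA_integer_)
  out$j_ref_start[scannable] <- ifelse(ok, 0L, NA_integer_)
  out$j_ref_end[scannable] <- ifelse(ok, hit$read_end - hit$read_start, NA_integer_)
  out
}
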