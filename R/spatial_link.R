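#' Extract spatial barcode and UMI from read 1
#'
#' Visium read 1 carries the 16-nt spatial barcode in bases 1-16 and the
#' 12-nt UMI in bases 17-28; read 1 must therefore be sequenced for at least
#' 28 cycles, and shorter reads are hard errors, never silently truncated.
#'
#' @param reads Tibble of read 1 records (`read_id`, `sequence`).
#' @param barcode_len,umi_len Barcode and UMI lengths (defaults 16 and 12).
#' @return `reads` with added columns `barcode`, `umi`.
#' @export
extract_barcode_umi <- function(reads, barcode_len = 16L, umi_len = 12L) {
  min_len <- barcode_len + umi_len
  len <- nchar(reads$sequence)
  if (any(len < min_len)) {
    bad <- reads$read_id[len < min_len][1L]
    stop_tcrspot(
      sprintf("read 1 '%s' is shorter than %d nt (barcode + UMI)", bad, min_len),
      "length_error"
    )
  }
  mutate(reads,
         barcode = substr(.data$sequence, 1L, barcode_len),
         umi = substr(.data$sequence, barcode_len + 1L, min_len))
}

#' Match barcodes against the spot whitelist
#'
#' Exact whitelist hits are always preferred. With `max_hamming = 1`, a
#' barcode with no exact hit is corrected to a whitelist barcode at Hamming
#' distance 1 only when that neighbour is unique; two equidistant candidates
#' leave the read unmatched. Barcodes containing N are never matched.
#'
#' @param barcodes Character vector of observed 16-mers.
#' @param spot_map A `spot_map` tibble.
#' @param max_hamming 0 (default; exact only) or 1.
#' @return Tibble `barcode` (observed), `matched_barcode` (whitelist hit or
#'   `NA`), `status` (`"in_tissue"`, `"off_tissue"` or `"unmatched"`).
#' @export
match_barcode <- function(barcodes, spot_map, max_hamming = 0L) {
  if (!max_hamming %in% c(0L, 1L)) {
    stop_tcrspot("`max_hamming` must be 0 or 1", "domain_error")
  }
  idx <- match(barcodes, spot_map$barcode)
  has_n <- grepl("N", barcodes, fixed = TRUE)
  idx[has_n] <- NA_integer_
  if (max_hamming == 1L) {
    todo <- which(is.na(idx) & !has_n)
    for (i in todo) {
      idx[i] <- hamming1_unique(barcodes[i], spot_map$barcode)
    }
  }
  tibble(
    barcode = barcodes,
    matched_barcode = spot_map$barcode[idx],
    status = dplyr::case_when(
      is.na(idx) ~ "unmatched",
      spot_map$in_tissue[idx] ~ "in_tissue",
      TRUE ~ "off_tissue"
    )
  )
}

# index of the unique whitelist barcode at Hamming distance 1, else NA
hamming1_unique <- function(barcode, whitelist) {
  hits <- integer(0)
  for (pos in seq_len(nchar(barcode))) {
    orig <- substr(barcode, pos, pos)
    for (base in setdiff(DNA_BASES, orig)) {
      cand <- barcode
      substr(cand, pos, pos) <- base
      m <- match(cand, whitelist)
      if (!is.na(m)) {
        hits <- c(hits, m)
        if (length(hits) > 1L) return(NA_integer_)
      }
    }
  }
  if (length(hits) == 1L) hits else NA_integer_
}

#' Link clone-supporting reads to capture spots
#'
#' For every read in the clone map, pairs to read 1 by id, extracts the
#' spatial barcode and UMI, and matches the barcode against the whitelist.
#'
#' @param read_map Tibble `read_id`, `clone_id` (clone-supporting reads).
#' @param r1 Read 1 records as a tibble or a FASTQ(.gz) path.
#' @param spot_map A `spot_map` tibble.
#' @param max_hamming Passed to [match_barcode()] (default 0: no barcode
#'   error correction, matching the original analysis).
#' @return A list: `records` (tibble `read_id`, `barcode`, `umi`, `clone_id`,
#'   `matched`) and `log` (one-row tibble `total`, `unmatched_barcode`,
#'   `off_tissue`, `in_tissue`).
#' @export
link_reads <- function(read_map, r1, spot_map, max_hamming = 0L) {
  if (is.character(r1)) r1 <- read_fastq(r1)
  idx <- match(read_map$read_id, r1$read_id)
  if (anyNA(idx)) {
    stop_tcrspot(
      sprintf("clone-supporting read '%s' absent from read 1 file",
              read_map$read_id[which(is.na(idx))[1L]]),
      "pairing_error"
    )
  }
  bu <- extract_barcode_umi(r1[idx, ])
  m <- match_barcode(bu$barcode, spot_map, max_hamming = max_hamming)
  records <- tibble(
    read_id = read_map$read_id,
    barcode = ifelse(is.na(m$matched_barcode), m$barcode, m$matched_barcode),
    umi = bu$umi,
    clone_id = read_map$clone_id,
    matched = m$status
  )
  log <- tibble(
    total = nrow(records),
    unmatched_barcode = sum(records$matched == "unmatched"),
    off_tissue = sum(records$matched == "off_tissue"),
    in_tissue = sum(records$matched == "in_tissue")
  )
  list(records = records, log = log)
}

#' Deduplicate linked records by (barcode, UMI)
#'
#' Each (spatial barcode, UMI) combination is used once. Duplicates within
#' one clone collapse to a single record; when one (barcode, UMI) pair is
#' claimed by several clones, the clone with most supporting reads in that
#' pair wins and ties discard the pair entirely (the conservative choice).
#'
#' @param records Linked-record tibble with `barcode`, `umi`, `clone_id`,
#'   `matched` (unmatched records are dropped first).
#' @return Deduplicated tibble with one row per kept (barcode, UMI):
#'   `barcode`, `umi`, `clone_id`, `matched`, `n_reads`.
#' @export
deduplicate <- function(records) {
  empty <- tibble(barcode = character(), umi = character(),
                  clone_id = integer(), matched = character(),
                  n_reads = integer())
  records <- filter(records, .data$matched != "unmatched")
  if (nrow(records) == 0L) {
    return(empty)
  }
  # if already deduplicated rows carry n_reads, preserve the read tally
  w <- if ("n_reads" %in% names(records)) records$n_reads else rep(1L, nrow(records))
  records |>
    mutate(.w = w) |>
    group_by(.data$barcode, .data$umi, .data$clone_id) |>
    summarise(matched = .data$matched[1L], n_reads = sum(.data$.w),
              .groups = "drop_last") |>
    filter(.data$n_reads == max(.data$n_reads)) |>
    filter(n() == 1L) |>
    ungroup() |>
    arrange(.data$barcode, .data$umi) |>
    select("barcode", "umi", "clone_id", "matched", "n_reads")
}

#' Build the spot-by-clone UMI count matrix
#'
#' Rows are all in-tissue barcodes of the spot map in file order (zero rows
#' included); columns are clones with at least one in-tissue UMI, ordered by
#' clone id. Off-tissue records are routed to a side table, not silently
#' dropped, because off-tissue TCR signal is a permeabilisation diagnostic.
#'
#' @param deduped Deduplicated linked records from [deduplicate()].
#' @param spot_map A `spot_map` tibble.
#' @return A `spot_clone_matrix` object.
#' @export
build_matrix <- function(deduped, spot_map) {
  rows <- in_tissue_barcodes(spot_map)
  in_t <- filter(deduped, .data$matched == "in_tissue")
  if (!all(in_t$barcode %in% rows)) {
    stop_tcrspot("in-tissue record barcode absent from spot map", "internal_error")
  }
  cols <- sort(unique(in_t$clone_id))
  counts <- matrix(0L, nrow = length(rows), ncol = length(cols),
                   dimnames = list(rows, if (length(cols)) paste0("clone", cols)))
  if (nrow(in_t) > 0L) {
    tab <- count(in_t, .data$barcode, .data$clone_id)
    counts[cbind(match(tab$barcode, rows), match(tab$clone_id, cols))] <-
      as.integer(tab$n)
  }
  off <- filter(deduped, .data$matched == "off_tissue") |>
    count(.data$barcode, .data$clone_id, name = "umis")
  new_spot_clone_matrix(counts, off)
}
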