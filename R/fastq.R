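#' Read a FASTQ file into a tibble
#'
#' Reads plain or gzip-compressed four-line FASTQ records. Read identifiers
#' are normalised: everything after the first whitespace is dropped, as is a
#' trailing `/1` or `/2` pairing suffix, so that mates of a pair share one id.
#'
#' @param path Path to a FASTQ or FASTQ.gz file.
#' @return A tibble with columns `read_id`, `sequence`, `qualities`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    stop_tcrspot(sprintf("FASTQ file not found: %s", path), "io_error")
  }
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    out <- tibble(
      read_id = normalize_read_id(names(x)),
      sequence = unname(as.character(x)),
      qualities = unname(as.character(S4Vectors::mcols(x)$qualities))
    )
    if (any(nchar(out$sequence) != nchar(out$qualities))) {
      stop("sequence/quality length mismatch")
    }
    out
  },
  error = function(e) {
    stop_tcrspot(
      sprintf("malformed FASTQ record in %s: %s", path, conditionMessage(e)),
      "parse_error"
    )
  })
}

#' Write a tibble of reads as FASTQ
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `qualities`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("read_id", "sequence", "qualities") %in% names(reads)))
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, path,
    format = "fastq",
    qualities = Biostrings::BStringSet(reads$qualities),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Normalise FASTQ read identifiers
#'
#' Strips the comment (anything after the first whitespace) and a trailing
#' `/1` or `/2` mate suffix.
#'
#' @param ids Character vector of raw FASTQ name lines.
#' @return Character vector of normalised ids.
#' @export
normalize_read_id <- function(ids) {
  sub("/[12]$", "", sub("\\s.*$", "", ids))
}

#' Pair read 1 and read 2 FASTQ files by read name
#'
#' Mates are matched by normalised read id, not by file order, because
#' per-clone read exports (e.g. MiXCR `exportReadsForClones`) do not preserve
#' the original ordering. Output order follows the read 2 file.
#'
#' @param path_r1,path_r2 Paths to the read 1 / read 2 FASTQ(.gz) files.
#' @return A tibble with columns `read_id`, `sequence_r1`, `qualities_r1`,
#'   `sequence_r2`, `qualities_r2`, one row per pair.
#' @export
read_fastq_pairs <- function(path_r1, path_r2) {
  r1 <- read_fastq(path_r1)
  r2 <- read_fastq(path_r2)
  idx <- match(r2$read_id, r1$read_id)
  if (anyNA(idx)) {
    missing_id <- r2$read_id[which(is.na(idx))[1L]]
    stop_tcrspot(
      sprintf("read 2 id '%s' has no mate in read 1 file", missing_id),
      "pairing_error"
    )
  }
  tibble(
    read_id = r2$read_id,
    sequence_r1 = r1$sequence[idx],
    qualities_r1 = r1$qualities[idx],
    sequence_r2 = r2$sequence,
    qualities_r2 = r2$qualities
  )
}
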