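#' Construct a V/J segment reference
#'
#' A segment reference holds the V and J germline sequences the clonotype
#' caller aligns against, together with the CDR3 anchor positions: the 0-based
#' offset of the first base of the conserved V cysteine codon (`cys_offset`)
#' and of the conserved J phenylalanine codon of the FGXG motif
#' (`phe_offset`). `constant_prefix` is the start of the constant region that
#' follows J in the amplicon.
#'
#' @param v_segments Tibble with columns `name`, `sequence`, `cys_offset`.
#' @param j_segments Tibble with columns `name`, `sequence`, `phe_offset`.
#' @param constant_prefix DNA string appended 3' of J in simulated amplicons.
#' @return A `segment_reference` object.
#' @export
segment_reference <- function(v_segments, j_segments, constant_prefix = "") {
  ref <- structure(
    list(
      v_segments = as_tibble(v_segments),
      j_segments = as_tibble(j_segments),
      constant_prefix = constant_prefix
    ),
    class = "segment_reference"
  )
  validate_segment_reference(ref)
}

validate_segment_reference <- function(ref) {
  v <- ref$v_segments
  j <- ref$j_segments
  stopifnot(
    all(c("name", "sequence", "cys_offset") %in% names(v)),
    all(c("name", "sequence", "phe_offset") %in% names(j))
  )
  if (anyDuplicated(v$name) || anyDuplicated(j$name)) {
    stop_tcrspot("segment names must be unique", "validation_error")
  }
  if (any(v$cys_offset + 3L > nchar(v$sequence)) ||
      any(j$phe_offset + 3L > nchar(j$sequence))) {
    stop_tcrspot("anchor codon extends past segment end", "validation_error")
  }
  cys <- substr(v$sequence, v$cys_offset + 1L, v$cys_offset + 3L)
  if (!all(translate_nt(cys) == "C")) {
    stop_tcrspot("V anchor codon must encode cysteine", "validation_error")
  }
  phe <- substr(j$sequence, j$phe_offset + 1L, j$phe_offset + 3L)
  if (!all(translate_nt(phe) == "F")) {
    stop_tcrspot("J anchor codon must encode phenylalanine", "validation_error")
  }
  ref
}

#' @export
print.segment_reference <- function(x, ...) {
  cat(sprintf(
    "<segment_reference> %d V segments, %d J segments, constant prefix %d nt\n",
    nrow(x$v_segments), nrow(x$j_segments), nchar(x$constant_prefix)
  ))
  invisible(x)
}

#' Write a segment reference as FASTA plus anchor TSV
#'
#' The FASTA holds every V and J sequence (and the constant prefix under the
#' name `constant`); the anchor table records, per segment, its type
#' (`V`/`J`/`C`) and the 0-based anchor offset (`NA` for the constant prefix).
#'
#' @param ref A `segment_reference`.
#' @param fasta_path,anchors_path Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_reference <- function(ref, fasta_path, anchors_path) {
  seqs <- c(ref$v_segments$sequence, ref$j_segments$sequence, ref$constant_prefix)
  nm <- c(ref$v_segments$name, ref$j_segments$name, "constant")
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- nm
  Biostrings::writeXStringSet(x, fasta_path)
  anchors <- tibble(
    name = nm,
    segment = c(rep("V", nrow(ref$v_segments)), rep("J", nrow(ref$j_segments)), "C"),
    anchor_offset = c(ref$v_segments$cys_offset, ref$j_segments$phe_offset, NA_integer_)
  )
  readr::write_tsv(anchors, anchors_path, eol = "\n", progress = FALSE)
  invisible(list(fasta = fasta_path, anchors = anchors_path))
}

#' Read a segment reference from FASTA plus anchor TSV
#'
#' @param fasta_path,anchors_path Paths written by [write_reference()].
#' @return A `segment_reference`.
#' @export
read_reference <- function(fasta_path, anchors_path) {
  x <- Biostrings::readDNAStringSet(fasta_path)
  seqs <- setNames(as.character(x), sub("\\s.*$", "", names(x)))
  anchors <- readr::read_tsv(
    anchors_path,
    col_types = readr::cols(name = "c", segment = "c", anchor_offset = "i"),
    progress = FALSE
  )
  if (!all(anchors$name %in% names(seqs))) {
    stop_tcrspot("anchor table names missing from FASTA", "format_error")
  }
  v <- filter(anchors, .data$segment == "V")
  j <- filter(anchors, .data$segment == "J")
  cons <- anchors$name[anchors$segment == "C"]
  segment_reference(
    v_segments = tibble(name = v$name, sequence = unname(seqs[v$name]),
                        cys_offset = v$anchor_offset),
    j_segments = tibble(name = j$name, sequence = unname(seqs[j$name]),
                        phe_offset = j$anchor_offset),
    constant_prefix = if (length(cons)) unname(seqs[cons[1L]]) else ""
  )
}
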