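DNA_BASES <- c("A", "C", "G", "T")

# n random DNA strings of the given length(s)
random_dna <- function(n, len) {
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste0(sample(DNA_BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

#' Translate CDR3 nucleotide sequences
#'
#' Translates in-frame sequences with the standard genetic code; sequences
#' whose length is not a multiple of three yield the empty string. Ambiguous
#' codons (containing N) translate to `X`.
#'
#' @param nt Character vector of DNA sequences.
#' @return Character vector of amino-acid sequences (`""` where out of frame).
#' @export
translate_nt <- function(nt) {
  out <- character(length(nt))
  in_frame <- nchar(nt) > 0L & nchar(nt) %% 3L == 0L
  if (any(in_frame)) {
    aa <- Biostrings::translate(
      Biostrings::DNAStringSet(nt[in_frame]),
      if.fuzzy.codon = "X"
    )
    out[in_frame] <- as.character(aa)
  }
  out
}

stop_tcrspot <- function(msg, class, ...) {
  abort(msg, class = c(paste0("tcrspot_", class), "tcrspot_error"), ...)
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min) {
    stop_tcrspot(
      sprintf("`%s` must be a single integer >= %d", name, min),
      "domain_error"
    )
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    stop_tcrspot(sprintf("`%s` must be a fraction in [0, 1]", name), "domain_error")
  }
  invisible(as.numeric(x))
}
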