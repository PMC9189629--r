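#' Load a TRBV primer-pool manifest
#'
#' The manifest is a TSV with columns `v_gene_name`, `primer_seq` and
#' `read2_tail` (the partial Illumina read 2 sequence joined to the 5' end of
#' each gene-specific primer). Gene names must be unique and sequences must be
#' plain A/C/G/T.
#'
#' @param path Path to the manifest TSV.
#' @return A `primer_pool` tibble; the per-primer concentration attributes are
#'   unset until [pool_concentration()] is applied to the pool.
#' @export
load_primer_pool <- function(path) {
  if (!file.exists(path)) {
    stop_tcrspot(sprintf("primer manifest not found: %s", path), "io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("v_gene_name", "primer_seq", "read2_tail")
  if (!all(need %in% names(df))) {
    stop_tcrspot(
      sprintf("primer manifest must have columns %s", paste(need, collapse = ", ")),
      "format_error"
    )
  }
  validate_primer_pool(as_tibble(df[need]))
}

validate_primer_pool <- function(pool) {
  if (anyDuplicated(pool$v_gene_name)) {
    dup <- pool$v_gene_name[duplicated(pool$v_gene_name)][1L]
    stop_tcrspot(sprintf("duplicate primer gene name '%s'", dup), "validation_error")
  }
  if (any(!nzchar(pool$primer_seq))) {
    stop_tcrspot("primer sequences must be non-empty", "validation_error")
  }
  pool$read2_tail[is.na(pool$read2_tail)] <- ""
  if (any(!is_dna(pool$primer_seq)) || any(!is_dna(pool$read2_tail))) {
    stop_tcrspot("primer sequences must contain only A/C/G/T", "validation_error")
  }
  structure(pool, class = c("primer_pool", class(pool)))
}

#' Per-primer concentration of an equimolar pool
#'
#' An equimolar pool diluted to a total concentration `c` gives each of the
#' `n` primers a final concentration of `c / n`; a 45-primer TRBV pool at a
#' total of 10 uM holds each primer at 10/45 = 0.22 uM.
#'
#' @param n_primers Number of primers in the pool (or a `primer_pool` tibble,
#'   in which case the pool is returned with `total_conc_uM` and
#'   `per_primer_conc_uM` attributes set).
#' @param total_conc_uM Total pool concentration in micromolar.
#' @return The per-primer concentration in uM, or the annotated pool.
#' @export
pool_concentration <- function(n_primers, total_conc_uM) {
  if (is.data.frame(n_primers)) {
    pool <- n_primers
    per <- pool_concentration(nrow(pool), total_conc_uM)
    attr(pool, "total_conc_uM") <- total_conc_uM
    attr(pool, "per_primer_conc_uM") <- per
    return(pool)
  }
  assert_count(n_primers, "n_primers", min = 1L)
  if (!is.numeric(total_conc_uM) || length(total_conc_uM) != 1L ||
      is.na(total_conc_uM) || total_conc_uM <= 0) {
    stop_tcrspot("`total_conc_uM` must be a positive number", "domain_error")
  }
  total_conc_uM / n_primers
}

#' Write a primer-pool manifest TSV
#'
#' @param pool A `primer_pool` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_pool <- function(pool, path) {
  readr::write_tsv(as_tibble(pool)[c("v_gene_name", "primer_seq", "read2_tail")],
                   path, eol = "\n", progress = FALSE)
  invisible(path)
}
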