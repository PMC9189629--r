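SPOT_MAP_COLS <- c("barcode", "in_tissue", "array_row", "array_col",
                   "pxl_row", "pxl_col")

#' Read a Space Ranger tissue positions list
#'
#' Accepts both dialects of `tissue_positions_list.csv`: the headerless
#' six-column v1 file and the v2 file carrying a header line. The dialect is
#' auto-detected from a `barcode` token on the first line. Gem-group suffixes
#' (`-1` and the like) are stripped by default because raw read barcodes carry
#' no suffix.
#'
#' @param path Path to the positions CSV.
#' @param suffix_policy `"strip_gem_suffix"` (default) removes a trailing
#'   `-<digits>` gem-group suffix from each barcode; `"keep"` leaves barcodes
#'   untouched.
#' @return A `spot_map` tibble with columns `barcode` (16-mer), `in_tissue`
#'   (logical), `array_row`, `array_col`, `pxl_row`, `pxl_col`.
#' @export
read_spot_map <- function(path, suffix_policy = c("strip_gem_suffix", "keep")) {
  suffix_policy <- match.arg(suffix_policy)
  if (!file.exists(path)) {
    stop_tcrspot(sprintf("positions file not found: %s", path), "io_error")
  }
  first <- readLines(path, n = 1L)
  has_header <- grepl("barcode", first, ignore.case = TRUE)
  df <- readr::read_csv(
    path,
    col_names = if (has_header) TRUE else SPOT_MAP_COLS,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(df) != 6L) {
    stop_tcrspot(
      sprintf("positions file must have 6 columns, found %d", ncol(df)),
      "format_error"
    )
  }
  names(df) <- SPOT_MAP_COLS
  df <- mutate(
    df,
    barcode = if (suffix_policy == "strip_gem_suffix") {
      sub("-\\d+$", "", .data$barcode)
    } else {
      .data$barcode
    },
    in_tissue = as.integer(.data$in_tissue) == 1L,
    dplyr::across(c("array_row", "array_col", "pxl_row", "pxl_col"), as.integer)
  )
  validate_spot_map(as_tibble(df))
}

validate_spot_map <- function(map) {
  if (anyDuplicated(map$barcode)) {
    dup <- map$barcode[duplicated(map$barcode)][1L]
    stop_tcrspot(sprintf("duplicate spot barcode '%s'", dup), "validation_error")
  }
  bad <- nchar(map$barcode) != 16L | !is_dna(map$barcode)
  if (any(bad)) {
    stop_tcrspot(
      sprintf("barcode '%s' is not a 16-mer over A/C/G/T", map$barcode[bad][1L]),
      "validation_error"
    )
  }
  if (any(map$array_row < 0L | map$array_col < 0L, na.rm = TRUE)) {
    stop_tcrspot("array coordinates must be non-negative", "validation_error")
  }
  structure(map, class = c("spot_map", class(map)))
}

#' Write a spot map as a tissue positions CSV
#'
#' @param map A `spot_map` tibble.
#' @param path Output CSV path.
#' @param dialect `"v1"` writes the headerless file, `"v2"` includes the
#'   header line.
#' @param gem_suffix Suffix appended to each barcode on write (Space Ranger
#'   emits `-1`); `NULL` writes bare barcodes.
#' @return `path`, invisibly.
#' @export
write_spot_map <- function(map, path, dialect = c("v1", "v2"), gem_suffix = "-1") {
  dialect <- match.arg(dialect)
  out <- mutate(
    as_tibble(map)[SPOT_MAP_COLS],
    barcode = if (is.null(gem_suffix)) .data$barcode else paste0(.data$barcode, gem_suffix),
    in_tissue = as.integer(.data$in_tissue)
  )
  readr::write_csv(out, path, col_names = dialect == "v2", eol = "\n",
                   progress = FALSE)
  invisible(path)
}

in_tissue_barcodes <- function(map) {
  map$barcode[map$in_tissue]
}
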