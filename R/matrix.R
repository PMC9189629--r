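new_spot_clone_matrix <- function(counts, off_tissue) {
  stopifnot(is.matrix(counts))
  structure(
    list(counts = counts,
         off_tissue = as_tibble(off_tissue)),
    class = "spot_clone_matrix"
  )
}

#' @export
print.spot_clone_matrix <- function(x, ...) {
  cat(sprintf(
    "<spot_clone_matrix> %d in-tissue spots x %d clones; %d UMIs in tissue, %d off tissue\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts),
    sum(x$off_tissue$umis %||% integer(0))
  ))
  invisible(x)
}

#' @export
dim.spot_clone_matrix <- function(x) dim(x$counts)

#' @export
as.matrix.spot_clone_matrix <- function(x, ...) x$counts

#' Wide tibble view of a spot-by-clone matrix
#'
#' @param x A `spot_clone_matrix`.
#' @param ... Unused.
#' @return A tibble with a `barcode` column followed by one `clone<id>`
#'   column per clone.
#' @exportS3Method tibble::as_tibble
#' @export
as_tibble.spot_clone_matrix <- function(x, ...) {
  out <- as_tibble(as.data.frame(x$counts))
  dplyr::bind_cols(tibble(barcode = rownames(x$counts)), out)
}

#' Tidy a spot-by-clone matrix into long format
#'
#' @param x A `spot_clone_matrix`.
#' @param ... Unused.
#' @return Long tibble `barcode`, `clone_id`, `umis` (all cells, zeros
#'   included).
#' @exportS3Method generics::tidy
tidy.spot_clone_matrix <- function(x, ...) {
  if (ncol(x$counts) == 0L) {
    return(tibble(barcode = character(), clone_id = integer(), umis = integer()))
  }
  as_tibble.spot_clone_matrix(x) |>
    tidyr::pivot_longer(-"barcode", names_to = "clone_id", values_to = "umis") |>
    mutate(clone_id = as.integer(sub("^clone", "", .data$clone_id)))
}

#' One-row summary of a spot-by-clone matrix
#'
#' @param x A `spot_clone_matrix`.
#' @param ... Unused.
#' @return Tibble with `n_spots`, `n_clones`, `n_umis`, `n_off_tissue_umis`,
#'   `n_occupied_spots`.
#' @exportS3Method generics::glance
glance.spot_clone_matrix <- function(x, ...) {
  tibble(
    n_spots = nrow(x$counts),
    n_clones = ncol(x$counts),
    n_umis = sum(x$counts),
    n_off_tissue_umis = sum(x$off_tissue$umis %||% integer(0)),
    n_occupied_spots = sum(rowSums(x$counts) > 0L)
  )
}

#' Write a spot-by-clone matrix as TSV
#'
#' The main file has header `barcode` followed by `clone<id>` labels, one row
#' per in-tissue barcode in spot-map order, integer cells. Off-tissue hits go
#' to a sibling file `<path>.off_tissue.tsv` with columns `barcode`, `clone`,
#' `umis`.
#'
#' @param matrix A `spot_clone_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(matrix, path) {
  readr::write_tsv(as_tibble.spot_clone_matrix(matrix), path, eol = "\n",
                   progress = FALSE)
  off <- matrix$off_tissue
  off_out <- tibble(
    barcode = off$barcode %||% character(),
    clone = paste0("clone", off$clone_id %||% integer()),
    umis = off$umis %||% integer()
  )
  readr::write_tsv(off_out, paste0(path, ".off_tissue.tsv"), eol = "\n",
                   progress = FALSE)
  invisible(path)
}

#' Read a spot-by-clone matrix TSV back into an object
#'
#' @param path Matrix TSV written by [write_matrix()]; the sibling
#'   off-tissue file is read when present.
#' @return A `spot_clone_matrix`.
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    barcode = "c", .default = "i"
  ), progress = FALSE)
  counts <- as.matrix(df[-1L])
  rownames(counts) <- df$barcode
  storage.mode(counts) <- "integer"
  off_path <- paste0(path, ".off_tissue.tsv")
  off <- if (file.exists(off_path)) {
    readr::read_tsv(off_path, col_types = "cci", progress = FALSE) |>
      mutate(clone_id = as.integer(sub("^clone", "", .data$clone))) |>
      select("barcode", "clone_id", "umis")
  } else {
    tibble(barcode = character(), clone_id = integer(), umis = integer())
  }
  new_spot_clone_matrix(counts, off)
}

#' Plot spatial UMI totals per spot
#'
#' Scatter of capture spots on the array grid, sized/coloured by total TCR
#' UMIs; a quick visual analogue of overlaying clone counts on the tissue.
#'
#' @param object A `spot_clone_matrix`.
#' @param spot_map The `spot_map` the matrix was built against.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.spot_clone_matrix <- function(object, spot_map, ...) {
  df <- tibble(barcode = rownames(object$counts),
               umis = rowSums(object$counts)) |>
    left_join(as_tibble(spot_map), by = "barcode")
  ggplot2::ggplot(df, ggplot2::aes(.data$array_col, .data$array_row)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$umis, colour = .data$umis)) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "array column", y = "array row",
                  size = "TCR UMIs", colour = "TCR UMIs") +
    ggplot2::theme_minimal()
}

#' Clone abundance bar plot
#'
#' @param clones Clonotype tibble (with `clone_id`, `read_support`).
#' @param top_n Number of clones shown (default 20).
#' @return A ggplot object.
#' @export
plot_clone_abundance <- function(clones, top_n = 20L) {
  df <- clones |>
    arrange(desc(.data$read_support)) |>
    head(top_n) |>
    mutate(clone = factor(paste0("clone", .data$clone_id),
                          levels = paste0("clone", .data$clone_id)))
  ggplot2::ggplot(df, ggplot2::aes(.data$clone, .data$read_support,
                                   fill = .data$chain)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "supporting reads") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
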