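# shared fixtures and independent oracles for the suite

tiny_reference <- function(seed = 42L, n_v = 4L, n_j = 3L, ...) {
  make_reference(n_v, n_j, seed = seed, ...)
}

tiny_spot_map <- function(barcodes, in_tissue = TRUE) {
  n <- length(barcodes)
  validate_map <- getFromNamespace("validate_spot_map", "tcrspot")
  validate_map(tibble::tibble(
    barcode = barcodes,
    in_tissue = rep_len(in_tissue, n),
    array_row = seq_len(n) - 1L, array_col = rep(0L, n),
    pxl_row = 100L * seq_len(n), pxl_col = rep(100L, n)
  ))
}

random_barcodes <- function(n, seed) {
  withr::with_seed(seed, {
    unique(replicate(n * 2L, paste0(sample(c("A", "C", "G", "T"), 16L,
                                           replace = TRUE), collapse = "")))[1:n]
  })
}

# brute-force all-offsets ungapped scan, independent of the package kernel
oracle_scan <- function(read, queries, omin, omax, min_span) {
  best <- NULL
  rl <- nchar(read)
  for (j in seq_along(queries)) {
    ql <- nchar(queries[j])
    for (o in omin:omax) {
      span <- min(ql, rl - o)
      if (span < min_span) next
      a <- strsplit(substr(read, o + 1L, o + span), "")[[1]]
      b <- strsplit(substr(queries[j], 1L, span), "")[[1]]
      mm <- sum(a != b)
      sc <- span - 2L * mm
      if (is.null(best) || sc > best$score) {
        best <- list(query = j, score = sc, mismatches = mm,
                     read_start = o, read_end = o + span)
      }
    }
  }
  best
}

# brute-force (barcode, UMI) group-by dedup: majority clone, ties discarded
oracle_dedup <- function(records) {
  records <- records[records$matched != "unmatched", , drop = FALSE]
  keys <- paste(records$barcode, records$umi)
  rows <- lapply(unique(keys), function(k) {
    grp <- records[keys == k, , drop = FALSE]
    tab <- table(grp$clone_id)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) != 1L) return(NULL)
    data.frame(barcode = grp$barcode[1L], umi = grp$umi[1L],
               clone_id = as.integer(winners), matched = grp$matched[1L],
               n_reads = as.integer(max(tab)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(barcode = character(), umi = character(),
                      clone_id = integer(), matched = character(),
                      n_reads = integer())
  }
  out[order(out$barcode, out$umi), , drop = FALSE]
}

# remap a called matrix onto truth clone ids via exact clone keys
relabel_by_truth <- function(result_matrix, called_clones, truth_clones) {
  m <- as.matrix(result_matrix)
  called_ids <- as.integer(sub("^clone", "", colnames(m)))
  keys <- clone_keys(called_clones)[match(called_ids, called_clones$clone_id)]
  truth_ids <- truth_clones$clone_id[match(keys, clone_keys(truth_clones))]
  stopifnot(!anyNA(truth_ids))
  colnames(m) <- paste0("clone", truth_ids)
  m[, order(truth_ids), drop = FALSE]
}

write_tmp_fastq <- function(records, path = tempfile(fileext = ".fastq")) {
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    c(paste0("@", records$name[i]), records$sequence[i], "+",
      records$qualities[i])
  }))
  writeLines(lines, path)
  path
}
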