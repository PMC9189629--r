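#' Extract CDR3 sequences from aligned reads
#'
#' The CDR3 spans the conserved V cysteine codon through the conserved J
#' phenylalanine codon, inclusive. Anchor positions are projected from the
#' germline offsets through the ungapped V and J alignments. A clone is
#' productive when the CDR3 is in frame, translates without a stop, and the
#' amino-acid sequence starts with C and ends with F.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param alignments Tibble carrying the [assign_v()]/[assign_j()] columns for
#'   the same reads (joined by position).
#' @param reference A [segment_reference()].
#' @return `alignments` with added columns `cdr3_nt`, `cdr3_aa`, `productive`;
#'   reads where an anchor falls outside the read get `NA` `cdr3_nt`.
#' @export
extract_cdr3 <- function(reads, alignments, reference) {
  v <- reference$v_segments
  j <- reference$j_segments
  cys_off <- v$cys_offset[match(alignments$v_gene, v$name)]
  phe_off <- j$phe_offset[match(alignments$j_gene, j$name)]
  len <- nchar(reads$sequence)

  # 0-based read position of each anchor codon's first base
  cys_pos <- alignments$v_read_start + (cys_off - alignments$v_ref_start)
  phe_pos <- alignments$j_read_start + phe_off

  ok <- !is.na(cys_pos) & !is.na(phe_pos) &
    cys_pos >= alignments$v_read_start & cys_pos + 3L <= len &
    phe_pos + 3L <= len & phe_pos + 3L > cys_pos

  cdr3_nt <- ifelse(ok, substr(reads$sequence, cys_pos + 1L, phe_pos + 3L),
                    NA_character_)
  cdr3_aa <- character(length(cdr3_nt))
  cdr3_aa[ok] <- translate_nt(cdr3_nt[ok])
  cdr3_aa[!ok] <- NA_character_
  productive <- !is.na(cdr3_nt) &
    nchar(cdr3_nt) %% 3L == 0L &
    !grepl("*", cdr3_aa, fixed = TRUE) &
    startsWith(ifelse(is.na(cdr3_aa), "", cdr3_aa), "C") &
    endsWith(ifelse(is.na(cdr3_aa), "", cdr3_aa), "F")

  mutate(alignments,
         cdr3_nt = cdr3_nt,
         cdr3_aa = ifelse(is.na(cdr3_nt), NA_character_, cdr3_aa),
         productive = productive)
}

#' Assemble clonotypes from per-read assignments
#'
#' Reads sharing the exact (V gene, J gene, CDR3 nucleotide) key form one
#' clonotype. Clones are numbered 1..K by descending read support, ties by
#' first-seen order. The chain is `TRB` when the V hit is a TRBV gene and
#' `other` otherwise (flagging B cell receptor cross-calls).
#'
#' @param assignments Tibble with columns `read_id`, `v_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa`, `productive`; rows with any `NA` key component are
#'   dropped (they are unassignable reads).
#' @return A list with `clones` (tibble: `clone_id`, `v_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa`, `productive`, `chain`, `read_support`) and
#'   `read_map` (tibble: `read_id`, `clone_id`).
#' @export
assemble_clones <- function(assignments) {
  usable <- filter(assignments,
                   !is.na(.data$v_gene), !is.na(.data$j_gene), !is.na(.data$cdr3_nt))
  if (nrow(usable) == 0L) {
    return(list(
      clones = tibble(clone_id = integer(), v_gene = character(),
                      j_gene = character(), cdr3_nt = character(),
                      cdr3_aa = character(), productive = logical(),
                      chain = character(), read_support = integer()),
      read_map = tibble(read_id = character(), clone_id = integer())
    ))
  }
  usable <- mutate(usable, .order = row_number())
  clones <- usable |>
    group_by(.data$v_gene, .data$j_gene, .data$cdr3_nt) |>
    summarise(
      cdr3_aa = .data$cdr3_aa[1L],
      productive = .data$productive[1L],
      read_support = n(),
      .first_seen = min(.data$.order),
      .groups = "drop"
    ) |>
    arrange(desc(.data$read_support), .data$.first_seen) |>
    mutate(
      clone_id = row_number(),
      chain = ifelse(startsWith(.data$v_gene, "TRBV"), "TRB", "other")
    ) |>
    select("clone_id", "v_gene", "j_gene", "cdr3_nt", "cdr3_aa",
           "productive", "chain", "read_support")
  read_map <- usable |>
    left_join(clones, by = c("v_gene", "j_gene", "cdr3_nt")) |>
    select("read_id", "clone_id")
  list(clones = clones, read_map = read_map)
}

#' Call clonotypes from read 2 sequences
#'
#' Runs the native front-end: V assignment from the primer-anchored 5' end,
#' J assignment downstream, CDR3 extraction between the conserved anchors,
#' and exact-key clone assembly. Reads failing a stage are counted in the
#' drop log, never silently lost.
#'
#' @param reads Tibble of read 2 records (`read_id`, `sequence`), e.g. from
#'   [read_fastq()].
#' @param reference A [segment_reference()].
#' @param primer_pool A `primer_pool` tibble.
#' @param max_mismatch_frac,max_offset Passed to [assign_v()].
#' @param max_mismatch_j Passed to [assign_j()].
#' @return A list: `clones`, `read_map` (as [assemble_clones()]),
#'   `assignments` (per-read table) and `log` (one-row tibble with `n_reads`,
#'   `no_v`, `no_j`, `cdr3_fail`, `assigned`).
#' @export
call_clonotypes <- function(reads, reference, primer_pool,
                            max_mismatch_frac = 0.1, max_offset = 10L,
                            max_mismatch_j = 2L) {
  va <- assign_v(reads, reference, primer_pool,
                 max_mismatch_frac = max_mismatch_frac, max_offset = max_offset)
  ja <- assign_j(reads, reference, va$v_read_end, max_mismatch = max_mismatch_j)
  aln <- dplyr::bind_cols(va, select(ja, -"read_id"))
  aln <- extract_cdr3(reads, aln, reference)
  res <- assemble_clones(aln)
  log <- tibble(
    n_reads = nrow(reads),
    no_v = sum(is.na(aln$v_gene)),
    no_j = sum(!is.na(aln$v_gene) & is.na(aln$j_gene)),
    cdr3_fail = sum(!is.na(aln$v_gene) & !is.na(aln$j_gene) & is.na(aln$cdr3_nt)),
    assigned = nrow(res$read_map)
  )
  c(res, list(assignments = aln, log = log))
}

#' Export supporting reads per clone
#'
#' Writes one FASTQ.gz per clone, named `reads_cln<N>.fastq.gz` with N
#' 0-based (mirroring MiXCR's `exportReadsForClones` convention; clone ids in
#' tables stay 1-based, so clone k writes `reads_cln<k-1>`).
#'
#' @param read_map Tibble `read_id`, `clone_id` from [assemble_clones()].
#' @param reads Read 2 records as a tibble (`read_id`, `sequence`,
#'   `qualities`) or a FASTQ path.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a tibble `clone_id`, `path`, `n_reads`.
#' @export
export_reads_for_clones <- function(read_map, reads, out_dir) {
  if (is.character(reads)) reads <- read_fastq(reads)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_tcrspot(sprintf("cannot create directory %s", out_dir), "io_error")
  }
  ids <- sort(unique(read_map$clone_id))
  out <- purrr::map(ids, function(cid) {
    rid <- read_map$read_id[read_map$clone_id == cid]
    rec <- reads[match(rid, reads$read_id), ]
    if (anyNA(rec$sequence)) {
      stop_tcrspot("clone-supporting read missing from read set", "pairing_error")
    }
    path <- file.path(out_dir, sprintf("reads_cln%d.fastq.gz", cid - 1L))
    write_fastq(rec, path)
    tibble(clone_id = cid, path = path, n_reads = nrow(rec))
  })
  invisible(bind_rows(out))
}

#' Import MiXCR-format clonotype output
#'
#' Reads a clones table plus a directory of per-clone read files
#' (`reads_cln<N>.fastq.gz`, N 0-based in table row order) as an alternative
#' clonotype front-end. Column names vary across MiXCR versions, so they are
#' configurable; the defaults match this package's [write_clones_table()]
#' layout.
#'
#' @param clones_table Path to the clones TSV.
#' @param reads_dir Directory holding `reads_cln<N>.fastq.gz` files.
#' @param cols Named list mapping the fields `clone_id`, `read_count`,
#'   `v_gene`, `j_gene`, `cdr3_nt`, `cdr3_aa` to column names in the table
#'   (`cdr3_aa` may be absent; it is then translated from `cdr3_nt`).
#' @return A list `clones`, `read_map` in the [assemble_clones()] shape.
#' @export
import_mixcr <- function(clones_table, reads_dir,
                         cols = list(clone_id = "cloneId", read_count = "readCount",
                                     v_gene = "vGene", j_gene = "jGene",
                                     cdr3_nt = "nSeqCDR3", cdr3_aa = "aaSeqCDR3")) {
  df <- readr::read_tsv(clones_table, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- unlist(cols[c("clone_id", "read_count", "v_gene", "j_gene", "cdr3_nt")])
  if (!all(need %in% names(df))) {
    stop_tcrspot(
      sprintf("clones table lacks column(s): %s",
              paste(setdiff(need, names(df)), collapse = ", ")),
      "format_error"
    )
  }
  aa <- if (!is.null(cols$cdr3_aa) && cols$cdr3_aa %in% names(df)) {
    df[[cols$cdr3_aa]]
  } else {
    translate_nt(df[[cols$cdr3_nt]])
  }
  clones <- tibble(
    clone_id = as.integer(df[[cols$clone_id]]),
    v_gene = df[[cols$v_gene]],
    j_gene = df[[cols$j_gene]],
    cdr3_nt = df[[cols$cdr3_nt]],
    cdr3_aa = aa,
    read_support = as.integer(df[[cols$read_count]])
  )
  if (anyNA(clones$clone_id) || anyNA(clones$read_support)) {
    stop_tcrspot("unparseable cloneId/readCount column", "format_error")
  }
  clones <- mutate(
    clones,
    productive = nchar(.data$cdr3_nt) %% 3L == 0L &
      !grepl("*", .data$cdr3_aa, fixed = TRUE) &
      startsWith(.data$cdr3_aa, "C") & endsWith(.data$cdr3_aa, "F"),
    chain = ifelse(startsWith(.data$v_gene, "TRBV"), "TRB", "other")
  )
  maps <- purrr::map(seq_len(nrow(clones)), function(i) {
    path <- file.path(reads_dir, sprintf("reads_cln%d.fastq.gz", i - 1L))
    if (!file.exists(path)) {
      warn(sprintf("no reads file for clone %d (%s); 0 reads mapped",
                   clones$clone_id[i], basename(path)))
      return(tibble(read_id = character(), clone_id = integer()))
    }
    tibble(read_id = read_fastq(path)$read_id, clone_id = clones$clone_id[i])
  })
  list(
    clones = select(clones, "clone_id", "v_gene", "j_gene", "cdr3_nt",
                    "cdr3_aa", "productive", "chain", "read_support"),
    read_map = bind_rows(maps)
  )
}

#' Write a clonotype table
#'
#' TSV with columns `cloneId`, `readCount`, `vGene`, `jGene`, `nSeqCDR3`,
#' `aaSeqCDR3`, `productive`, `chain`, sorted by descending read count with
#' ties by ascending clone id.
#'
#' @param clones Clonotype tibble from [assemble_clones()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clones_table <- function(clones, path) {
  out <- clones |>
    arrange(desc(.data$read_support), .data$clone_id) |>
    mutate(productive = tolower(as.character(.data$productive))) |>
    select(cloneId = "clone_id", readCount = "read_support", vGene = "v_gene",
           jGene = "j_gene", nSeqCDR3 = "cdr3_nt", aaSeqCDR3 = "cdr3_aa",
           productive = "productive", chain = "chain")
  readr::write_tsv(out, path, eol = "\n", progress = FALSE)
  invisible(path)
}
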