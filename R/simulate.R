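#' Simulation configuration
#'
#' Defaults describe a small but realistic Visium-TCR experiment: a 50-spot
#' neighbourhood with 80% of spots under tissue, 20 T cell clones placed on a
#' few spots each, about 2,000 captured molecules, a PCR duplication mean of
#' 3 reads per molecule, and an Illumina-like substitution rate of 1e-3.
#'
#' @param n_spots Number of capture spots on the simulated slide.
#' @param frac_in_tissue Fraction of spots under tissue.
#' @param n_clones Number of TCRbeta clones in the repertoire.
#' @param n_molecules Total captured cDNA molecules (pre-PCR, i.e. UMIs).
#' @param spots_per_clone Spots each clone occupies (capped at the number of
#'   in-tissue spots).
#' @param clone_abundance `"uniform"` or `"geometric"` clone weights.
#' @param geometric_ratio Ratio of the geometric abundance series.
#' @param pcr_duplication_mean Mean reads per molecule (>= 1); each molecule
#'   is sequenced `1 + Poisson(mean - 1)` times.
#' @param seq_error_rate Per-base substitution probability applied to both
#'   reads.
#' @param frac_background_reads Fraction of emitted read pairs whose read 2
#'   is random non-TCR sequence.
#' @param frac_off_tissue Fraction of TCR molecules captured at whitelist
#'   barcodes that are not under tissue.
#' @param frac_bcr_like Fraction of molecules drawn from a decoy (non-TRB)
#'   segment set sharing partial identity with a TRBV gene.
#' @param read1_len,read2_len Read lengths in cycles (read 1 minimum 28).
#' @param seed Integer seed governing all randomness.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_spots = 50L, frac_in_tissue = 0.8, n_clones = 20L,
                       n_molecules = 2000L, spots_per_clone = 4L,
                       clone_abundance = c("uniform", "geometric"),
                       geometric_ratio = 0.7, pcr_duplication_mean = 3,
                       seq_error_rate = 0.001, frac_background_reads = 0,
                       frac_off_tissue = 0, frac_bcr_like = 0,
                       read1_len = 28L, read2_len = 300L, seed = 1L) {
  cfg <- list(
    n_spots = assert_count(n_spots, "n_spots", min = 1L),
    frac_in_tissue = assert_fraction(frac_in_tissue, "frac_in_tissue"),
    n_clones = assert_count(n_clones, "n_clones", min = 1L),
    n_molecules = assert_count(n_molecules, "n_molecules", min = 1L),
    spots_per_clone = assert_count(spots_per_clone, "spots_per_clone", min = 1L),
    clone_abundance = match.arg(clone_abundance),
    geometric_ratio = assert_fraction(geometric_ratio, "geometric_ratio"),
    pcr_duplication_mean = pcr_duplication_mean,
    seq_error_rate = assert_fraction(seq_error_rate, "seq_error_rate"),
    frac_background_reads = assert_fraction(frac_background_reads,
                                            "frac_background_reads"),
    frac_off_tissue = assert_fraction(frac_off_tissue, "frac_off_tissue"),
    frac_bcr_like = assert_fraction(frac_bcr_like, "frac_bcr_like"),
    read1_len = assert_count(read1_len, "read1_len", min = 28L),
    read2_len = assert_count(read2_len, "read2_len", min = 40L),
    seed = assert_count(seed, "seed")
  )
  if (!is.numeric(pcr_duplication_mean) || pcr_duplication_mean < 1) {
    stop_tcrspot("`pcr_duplication_mean` must be >= 1", "domain_error")
  }
  structure(cfg, class = "sim_config")
}

# shared partial read 2 tail carried at the 5' end of every primer
READ2_TAIL <- "GGAGTTCA"

#' Generate a synthetic V/J segment reference
#'
#' V segments are 250-300 nt with the conserved cysteine codon recorded
#' within 10 nt of the 3' end; J segments are 45-60 nt carrying a TTY
#' phenylalanine codon followed by GGN-NNN-GGN, i.e. an FGXG motif, at the
#' recorded offset. Optionally appends decoy segments (named like
#' immunoglobulin kappa V genes) sharing `decoy_identity` with a TRBV
#' segment, to exercise cross-chain flagging. Deterministic given `seed`.
#'
#' @param n_v,n_j Number of V and J segments.
#' @param seed Integer seed.
#' @param n_decoys Number of decoy non-TRB V segments (default 0).
#' @param decoy_identity Approximate sequence identity of decoys to their
#'   TRBV template (default 0.7).
#' @return A [segment_reference()].
#' @export
make_reference <- function(n_v = 45L, n_j = 13L, seed = 1L, n_decoys = 0L,
                           decoy_identity = 0.7) {
  assert_count(n_v, "n_v", min = 1L)
  assert_count(n_j, "n_j", min = 1L)
  withr::with_seed(seed, {
    v <- purrr::map(seq_len(n_v), function(i) {
      len <- sample(250:300, 1L)
      s <- random_dna(1L, len)
      cys_offset <- len - 3L - sample(0:7, 1L)
      substr(s, cys_offset + 1L, cys_offset + 3L) <- sample(c("TGT", "TGC"), 1L)
      tibble(name = sprintf("TRBV%02d", i), sequence = s, cys_offset = cys_offset)
    }) |> bind_rows()
    if (n_decoys > 0L) {
      dec <- purrr::map(seq_len(n_decoys), function(i) {
        tmpl <- v[sample(nrow(v), 1L), ]
        s <- mutate_sequence(tmpl$sequence, 1 - decoy_identity)
        cys_offset <- tmpl$cys_offset
        substr(s, cys_offset + 1L, cys_offset + 3L) <- sample(c("TGT", "TGC"), 1L)
        tibble(name = sprintf("IGKV%02d", i), sequence = s, cys_offset = cys_offset)
      }) |> bind_rows()
      v <- bind_rows(v, dec)
    }
    j <- purrr::map(seq_len(n_j), function(i) {
      len <- sample(45:60, 1L)
      s <- random_dna(1L, len)
      phe_offset <- sample(6:15, 1L)
      motif <- paste0(sample(c("TTT", "TTC"), 1L),
                      "GG", sample(DNA_BASES, 1L),
                      random_dna(1L, 3L),
                      "GG", sample(DNA_BASES, 1L))
      substr(s, phe_offset + 1L, phe_offset + 12L) <- motif
      tibble(name = sprintf("TRBJ%02d", i), sequence = s, phe_offset = phe_offset)
    }) |> bind_rows()
    segment_reference(v, j, constant_prefix = random_dna(1L, 30L))
  })
}

# substitute roughly `rate` of positions with a different base
mutate_sequence <- function(s, rate) {
  n <- nchar(s)
  k <- max(1L, round(rate * n))
  pos <- sample(n, k)
  chars <- strsplit(s, "")[[1]]
  chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(DNA_BASES, b), 1L),
                       character(1))
  paste0(chars, collapse = "")
}

#' Derive a primer pool from a segment reference
#'
#' One gene-specific primer per V segment (decoys included, mimicking
#' cross-priming), taken as a 20-mer upstream of the CDR3 so the amplicon
#' retains the V 3' region, each carrying the shared partial read 2 tail.
#'
#' @param reference A [segment_reference()].
#' @param primer_len Primer length (default 20).
#' @param upstream_of_end Distance from the V 3' end to the primer start
#'   (default 75 nt).
#' @return A `primer_pool` tibble.
#' @export
make_primer_pool <- function(reference, primer_len = 20L, upstream_of_end = 75L) {
  v <- reference$v_segments
  start <- nchar(v$sequence) - upstream_of_end
  if (any(start < 1L)) {
    stop_tcrspot("V segments too short for the requested primer placement",
                 "generation_error")
  }
  validate_primer_pool(tibble(
    v_gene_name = v$name,
    primer_seq = substr(v$sequence, start + 1L, start + primer_len),
    read2_tail = READ2_TAIL
  ))
}

#' Generate a synthetic tissue positions map
#'
#' Random unique 16-mer barcodes laid out on a square array; a fixed number
#' (`round(frac_in_tissue * n_spots)`) of spots are marked under tissue.
#'
#' @param n_spots Number of spots.
#' @param frac_in_tissue Fraction of spots under tissue.
#' @param seed Integer seed.
#' @return A `spot_map` tibble.
#' @export
make_spot_map <- function(n_spots = 50L, frac_in_tissue = 0.8, seed = 1L) {
  assert_count(n_spots, "n_spots", min = 1L)
  assert_fraction(frac_in_tissue, "frac_in_tissue")
  withr::with_seed(seed, {
    barcodes <- unique(random_dna(n_spots * 2L, 16L))[seq_len(n_spots)]
    n_in <- round(frac_in_tissue * n_spots)
    in_tissue <- rep(FALSE, n_spots)
    in_tissue[sample(n_spots, n_in)] <- TRUE
    ncol_grid <- ceiling(sqrt(n_spots))
    idx <- seq_len(n_spots) - 1L
    validate_spot_map(tibble(
      barcode = barcodes,
      in_tissue = in_tissue,
      array_row = idx %/% ncol_grid,
      array_col = idx %% ncol_grid,
      pxl_row = 100L + 120L * (idx %/% ncol_grid),
      pxl_col = 100L + 120L * (idx %% ncol_grid)
    ))
  })
}

#' Generate a synthetic clonal repertoire
#'
#' Each clone pairs a random V and J segment with a CDR3 built as the V
#' cysteine-anchored 3' region, 0-21 random N-region nucleotides (length
#' chosen to keep frame), and the J region through the phenylalanine codon.
#' Productive clones translate C...F with no stop (the N region is redrawn on
#' a stop). Abundance weights are uniform or geometric in clone rank.
#'
#' @param reference A [segment_reference()] (decoy segments are ignored here;
#'   see [emit_reads()] for decoy molecules).
#' @param config A [sim_config()].
#' @return Clonotype tibble with columns `clone_id`, `v_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa`, `productive`, `chain`, `weight`.
#' @export
make_repertoire <- function(reference, config) {
  v <- filter(reference$v_segments, startsWith(.data$name, "TRBV"))
  j <- reference$j_segments
  withr::with_seed(config$seed + 1L, {
    seen <- character(0)
    clones <- purrr::map(seq_len(config$n_clones), function(i) {
      for (try in 1:200) {
        cl <- draw_clone(v, j)
        key <- paste(cl$v_gene, cl$j_gene, cl$cdr3_nt, sep = "|")
        if (!key %in% seen) {
          seen <<- c(seen, key)
          return(cl)
        }
      }
      stop_tcrspot("could not draw a distinct productive clone", "generation_error")
    }) |> bind_rows()
    w <- switch(config$clone_abundance,
                uniform = rep(1, config$n_clones),
                geometric = config$geometric_ratio^(seq_len(config$n_clones) - 1L))
    mutate(clones,
           clone_id = row_number(),
           chain = "TRB",
           weight = w / sum(w)) |>
      select("clone_id", "v_gene", "j_gene", "cdr3_nt", "cdr3_aa",
             "productive", "chain", "weight")
  })
}

# one productive clone from the given segment tables; some (V, J) pairs put
# an unavoidable in-frame stop in the fixed flanks, so the pair is resampled
draw_clone <- function(v, j, max_n_len = 21L) {
  for (try in 1:200) {
    vi <- v[sample(nrow(v), 1L), ]
    ji <- j[sample(nrow(j), 1L), ]
    v_part <- substr(vi$sequence, vi$cys_offset + 1L, nchar(vi$sequence))
    j_part <- substr(ji$sequence, 1L, ji$phe_offset + 3L)
    frame_ok <- (nchar(v_part) + 0:max_n_len + nchar(j_part)) %% 3L == 0L
    lens <- (0:max_n_len)[frame_ok]
    n_len <- if (length(lens) > 1L) sample(lens, 1L) else lens
    cdr3 <- paste0(v_part, if (n_len > 0L) random_dna(1L, n_len) else "", j_part)
    aa <- translate_nt(cdr3)
    if (!grepl("*", aa, fixed = TRUE)) {
      return(tibble(v_gene = vi$name, j_gene = ji$name, cdr3_nt = cdr3,
                    cdr3_aa = aa, productive = TRUE))
    }
  }
  stop_tcrspot("could not draw a stop-free CDR3", "generation_error")
}

#' Emit paired synthetic FASTQ reads with ground truth
#'
#' Places molecules on spots, replicates each `1 + Poisson(mean - 1)` times
#' (the PCR duplication model), applies i.i.d. substitution errors to both
#' mates, optionally adds background and decoy (BCR-like) reads, and writes
#' the read pair plus complete truth tables. Read 1 is barcode + UMI +
#' poly(T) padding; read 2 is primer tail + V 3' region + CDR3 + J + constant
#' prefix, truncated to the configured length. Deterministic given the config
#' seed.
#'
#' @param reference A [segment_reference()].
#' @param repertoire Clonotype tibble from [make_repertoire()].
#' @param spot_map A `spot_map` tibble.
#' @param primer_pool A `primer_pool` tibble covering every V used.
#' @param config A [sim_config()].
#' @param out_dir Directory for the FASTQ files.
#' @return A list: `r1`, `r2` (paths), `truth` (list of `clones`,
#'   `placements` — one row per molecule with `clone_id`, `barcode`, `umi`,
#'   `in_tissue` — and `reads`, one row per emitted pair with `read_id`,
#'   `clone_id` (`NA` for background), `barcode`, `umi`).
#' @export
emit_reads <- function(reference, repertoire, spot_map, primer_pool, config,
                       out_dir = tempfile("simreads")) {
  in_bc <- in_tissue_barcodes(spot_map)
  off_bc <- spot_map$barcode[!spot_map$in_tissue]
  if (length(in_bc) == 0L && config$frac_off_tissue < 1) {
    stop_tcrspot("spot map has no in-tissue spots", "config_error")
  }
  if (config$frac_off_tissue > 0 && length(off_bc) == 0L) {
    stop_tcrspot("frac_off_tissue > 0 but no off-tissue spots", "config_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  withr::with_seed(config$seed + 2L, {
    rep_all <- repertoire
    if (config$frac_bcr_like > 0) {
      decoy_v <- filter(reference$v_segments, !startsWith(.data$name, "TRBV"))
      if (nrow(decoy_v) == 0L) {
        stop_tcrspot("frac_bcr_like > 0 but reference has no decoy segments",
                     "config_error")
      }
      n_dec <- min(3L, nrow(decoy_v))
      dec <- purrr::map(seq_len(n_dec), function(i) {
        draw_clone(decoy_v, reference$j_segments)
      }) |> bind_rows() |>
        mutate(clone_id = nrow(repertoire) + row_number(),
               chain = "other",
               weight = config$frac_bcr_like / n_dec)
      rep_all <- bind_rows(
        mutate(repertoire, weight = .data$weight * (1 - config$frac_bcr_like)),
        dec
      )
    }

    # molecules per clone, then per spot within the clone
    per_clone <- as.integer(rmultinom(1L, config$n_molecules, rep_all$weight))
    placements <- purrr::map(seq_len(nrow(rep_all)), function(i) {
      n_mol <- per_clone[i]
      if (n_mol == 0L) return(NULL)
      spots <- sample(in_bc, min(config$spots_per_clone, length(in_bc)))
      per_spot <- as.integer(rmultinom(1L, n_mol, rep(1, length(spots))))
      tibble(clone_id = rep_all$clone_id[i],
             barcode = rep(spots, per_spot))
    }) |> bind_rows()
    n_mol <- nrow(placements)
    off <- stats::runif(n_mol) < config$frac_off_tissue
    if (any(off)) {
      placements$barcode[off] <- sample(off_bc, sum(off), replace = TRUE)
    }
    placements$in_tissue <- !off
    # unique (barcode, umi) per molecule so truth dedup counts are exact
    repeat {
      placements$umi <- random_dna(n_mol, 12L)
      if (!anyDuplicated(placements[c("barcode", "umi")])) break
    }

    # amplicon per clone
    amplicons <- clone_amplicons(reference, rep_all, primer_pool, config$read2_len)

    copies <- 1L + rpois(n_mol, config$pcr_duplication_mean - 1)
    mol_of_read <- rep(seq_len(n_mol), copies)
    truth_reads <- tibble(
      clone_id = placements$clone_id[mol_of_read],
      barcode = placements$barcode[mol_of_read],
      umi = placements$umi[mol_of_read]
    )
    n_tcr_reads <- nrow(truth_reads)
    f_bg <- config$frac_background_reads
    n_bg <- if (f_bg > 0) round(f_bg / (1 - f_bg) * n_tcr_reads) else 0L
    if (n_bg > 0L) {
      truth_reads <- bind_rows(truth_reads, tibble(
        clone_id = NA_integer_,
        barcode = sample(in_bc, n_bg, replace = TRUE),
        umi = random_dna(n_bg, 12L)
      ))
    }
    n_reads <- nrow(truth_reads)
    ord <- sample(n_reads)
    truth_reads <- truth_reads[ord, ]
    truth_reads$read_id <- sprintf("sim%06d", seq_len(n_reads))

    r1_seq <- pad_polyt(paste0(truth_reads$barcode, truth_reads$umi),
                        config$read1_len)
    r2_seq <- ifelse(is.na(truth_reads$clone_id),
                     random_dna(n_reads, min(config$read2_len, 150L)),
                     amplicons[match(truth_reads$clone_id, rep_all$clone_id)])
    r1_seq <- apply_errors(r1_seq, config$seq_error_rate)
    r2_seq <- apply_errors(r2_seq, config$seq_error_rate)

    r1_path <- file.path(out_dir, "sim_R1.fastq.gz")
    r2_path <- file.path(out_dir, "sim_R2.fastq.gz")
    write_fastq(tibble(read_id = truth_reads$read_id, sequence = r1_seq,
                       qualities = strrep("I", nchar(r1_seq))), r1_path)
    write_fastq(tibble(read_id = truth_reads$read_id, sequence = r2_seq,
                       qualities = strrep("I", nchar(r2_seq))), r2_path)

    list(
      r1 = r1_path, r2 = r2_path,
      truth = list(
        clones = rep_all,
        placements = as_tibble(placements[c("clone_id", "barcode", "umi",
                                            "in_tissue")]),
        reads = as_tibble(truth_reads[c("read_id", "clone_id", "barcode", "umi")])
      )
    )
  })
}

# full read-2 amplicon per clone row
clone_amplicons <- function(reference, repertoire, primer_pool, read2_len) {
  v <- reference$v_segments
  vi <- match(repertoire$v_gene, v$name)
  pi <- match(repertoire$v_gene, primer_pool$v_gene_name)
  if (anyNA(pi)) {
    stop_tcrspot("repertoire uses a V gene with no primer", "config_error")
  }
  p_start <- vapply(seq_along(pi), function(k) {
    as.integer(regexpr(primer_pool$primer_seq[pi[k]], v$sequence[vi[k]],
                       fixed = TRUE))
  }, integer(1))
  if (any(p_start < 1L)) {
    stop_tcrspot("primer does not occur in its V segment", "config_error")
  }
  # V region from primer start through the cysteine anchor, then CDR3 tail
  v_to_cys <- substr(v$sequence[vi], p_start, v$cys_offset[vi])
  amp <- paste0(primer_pool$read2_tail[pi], v_to_cys, repertoire$cdr3_nt,
                j_after_phe(reference, repertoire$j_gene),
                reference$constant_prefix)
  substr(amp, 1L, read2_len)
}

j_after_phe <- function(reference, j_gene) {
  j <- reference$j_segments
  ji <- match(j_gene, j$name)
  substr(j$sequence[ji], j$phe_offset[ji] + 4L, nchar(j$sequence[ji]))
}

pad_polyt <- function(x, len) {
  pad <- pmax(len - nchar(x), 0L)
  paste0(x, strrep("T", pad))
}

# i.i.d. per-base substitutions
apply_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample(nchar(seqs[i]), n_err[i])
    chars <- strsplit(seqs[i], "")[[1]]
    chars[pos] <- vapply(chars[pos],
                         function(b) sample(setdiff(DNA_BASES, b), 1L),
                         character(1))
    seqs[i] <- paste0(chars, collapse = "")
  }
  seqs
}

#' Ground-truth spot-by-clone matrix
#'
#' Builds the matrix the pipeline should recover: distinct (barcode, UMI)
#' molecules per (in-tissue spot, clone), with off-tissue molecules in the
#' side table.
#'
#' @param placements Truth placements from [emit_reads()].
#' @param spot_map The `spot_map` used for the simulation.
#' @return A `spot_clone_matrix`.
#' @export
truth_matrix <- function(placements, spot_map) {
  records <- tibble(
    barcode = placements$barcode,
    umi = placements$umi,
    clone_id = placements$clone_id,
    matched = ifelse(placements$in_tissue, "in_tissue", "off_tissue")
  )
  build_matrix(distinct(records), spot_map)
}

#' Simulate a complete Visium-TCR dataset on disk
#'
#' Convenience wrapper: builds the reference, primer pool, spot map and
#' repertoire, emits reads, and writes every artefact (reference FASTA +
#' anchor TSV, primer manifest, v1 tissue positions CSV, paired FASTQ.gz,
#' truth TSVs) under `out_dir`.
#'
#' @param out_dir Output directory.
#' @param config A [sim_config()].
#' @param n_v,n_j Reference segment counts (defaults 45 and 13).
#' @return Invisibly, a list of paths plus the in-memory objects
#'   (`reference`, `primer_pool`, `spot_map`, `repertoire`, `truth`).
#' @export
simulate_dataset <- function(out_dir, config = sim_config(), n_v = 45L,
                             n_j = 13L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n_decoys <- if (config$frac_bcr_like > 0) 3L else 0L
  reference <- make_reference(n_v, n_j, seed = config$seed, n_decoys = n_decoys)
  primer_pool <- make_primer_pool(reference)
  spot_map <- make_spot_map(config$n_spots, config$frac_in_tissue,
                            seed = config$seed)
  repertoire <- make_repertoire(reference, config)
  sim <- emit_reads(reference, repertoire, spot_map, primer_pool, config,
                    out_dir = out_dir)

  paths <- list(
    r1 = sim$r1, r2 = sim$r2,
    reference_fasta = file.path(out_dir, "reference.fasta"),
    reference_anchors = file.path(out_dir, "reference_anchors.tsv"),
    primers = file.path(out_dir, "primers.tsv"),
    positions = file.path(out_dir, "tissue_positions_list.csv"),
    truth_clones = file.path(out_dir, "truth_clones.tsv"),
    truth_placements = file.path(out_dir, "truth_placements.tsv"),
    truth_reads = file.path(out_dir, "truth_reads.tsv")
  )
  write_reference(reference, paths$reference_fasta, paths$reference_anchors)
  write_primer_pool(primer_pool, paths$primers)
  write_spot_map(spot_map, paths$positions, dialect = "v1")
  readr::write_tsv(sim$truth$clones, paths$truth_clones, eol = "\n",
                   progress = FALSE)
  readr::write_tsv(sim$truth$placements, paths$truth_placements, eol = "\n",
                   progress = FALSE)
  readr::write_tsv(sim$truth$reads, paths$truth_reads, eol = "\n",
                   progress = FALSE)
  invisible(c(paths, list(reference = reference, primer_pool = primer_pool,
                          spot_map = spot_map, repertoire = repertoire,
                          truth = sim$truth)))
}
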