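make_clean_reads <- function(seed = 31L, n_molecules = 300L, n_clones = 8L) {
  cfg <- sim_config(n_spots = 20L, n_clones = n_clones,
                    n_molecules = n_molecules, pcr_duplication_mean = 1,
                    seq_error_rate = 0, seed = seed)
  d <- simulate_dataset(tempfile("clono"), cfg, n_v = 8L, n_j = 4L)
  list(d = d, reads = read_fastq(d$r2),
       truth = d$truth$reads[match(read_fastq(d$r2)$read_id,
                                   d$truth$reads$read_id), ])
}

test_that("error-free reads are assigned their true V with zero mismatches", {
  x <- make_clean_reads()
  truth_v <- x$d$truth$clones$v_gene[match(x$truth$clone_id,
                                           x$d$truth$clones$clone_id)]
  va <- assign_v(x$reads, x$d$reference, x$d$primer_pool)
  expect_equal(va$v_gene, truth_v)
  expect_true(all(va$v_mismatches == 0L))
  # alignment starts where the primer tail ends
  expect_true(all(va$v_read_start == nchar(x$d$primer_pool$read2_tail[1])))
})

test_that("random sequence and truncated reads yield no-calls", {
  ref <- tiny_reference()
  pool <- make_primer_pool(ref)
  rnd <- withr::with_seed(1L, tibble::tibble(
    read_id = paste0("rnd", 1:20),
    sequence = vapply(1:20, function(i) {
      paste0(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
    }, character(1))
  ))
  va <- assign_v(rnd, ref, pool)
  expect_true(all(is.na(va$v_gene)))
  # reads truncated before J give no J call
  x <- make_clean_reads(seed = 33L, n_molecules = 40L, n_clones = 3L)
  short <- dplyr::mutate(x$reads, sequence = substr(sequence, 1, 90))
  va2 <- assign_v(short, x$d$reference, x$d$primer_pool)
  ja2 <- assign_j(short, x$d$reference, va2$v_read_end)
  expect_true(all(is.na(ja2$j_gene)))
})

test_that("J assignment recovers the true J and breaks ties lexicographically", {
  x <- make_clean_reads(seed = 35L)
  truth_j <- x$d$truth$clones$j_gene[match(x$truth$clone_id,
                                           x$d$truth$clones$clone_id)]
  va <- assign_v(x$reads, x$d$reference, x$d$primer_pool)
  ja <- assign_j(x$reads, x$d$reference, va$v_read_end)
  expect_equal(ja$j_gene, truth_j)
  expect_true(all(ja$j_mismatches == 0L))

  # two identical J sequences: the lexicographically smaller name must win
  j2 <- x$d$reference$j_segments[1:2, ]
  j2$sequence[2] <- j2$sequence[1]
  j2$phe_offset[2] <- j2$phe_offset[1]
  ref2 <- segment_reference(x$d$reference$v_segments, j2,
                            x$d$reference$constant_prefix)
  keep <- which(truth_j == j2$name[1])[1:10]
  ja2 <- assign_j(x$reads[keep, ], ref2, va$v_read_end[keep])
  expect_true(all(ja2$j_gene == min(j2$name)))
})

test_that("the scan kernel agrees with a brute-force all-offsets oracle", {
  withr::with_seed(77L, {
    for (i in 1:100) {
      read <- paste0(sample(c("A", "C", "G", "T"), sample(60:120, 1),
                            replace = TRUE), collapse = "")
      queries <- vapply(1:3, function(j) {
        paste0(sample(c("A", "C", "G", "T"), sample(25:50, 1),
                      replace = TRUE), collapse = "")
      }, character(1))
      # plant one query inside some reads so real hits are exercised too
      if (i %% 2 == 0) {
        o <- sample(0:8, 1)
        read <- paste0(substr(read, 1, o), queries[1],
                       substr(read, o + nchar(queries[1]) + 1, nchar(read)))
      }
      omax <- nchar(read) - 20L
      got <- tcrspot:::scan_ungapped(read, queries, 0L, omax, 20L)
      want <- oracle_scan(read, queries, 0L, omax, 20L)
      expect_equal(got$query, want$query)
      expect_equal(got$score, want$score)
      expect_equal(got$mismatches, want$mismatches)
      expect_equal(got$read_start, want$read_start)
      expect_equal(got$read_end, want$read_end)
    }
  })
})

test_that("CDR3 extraction recovers truth sequences and applies frame rules", {
  x <- make_clean_reads(seed = 37L)
  res <- call_clonotypes(x$reads, x$d$reference, x$d$primer_pool)
  truth_cdr3 <- x$d$truth$clones$cdr3_nt[match(x$truth$clone_id,
                                               x$d$truth$clones$clone_id)]
  expect_equal(res$assignments$cdr3_nt, truth_cdr3)
  expect_true(all(res$assignments$productive))

  # frame rule: length not divisible by 3 -> unproductive, empty aa
  aln <- tibble::tibble(
    v_gene = "V", j_gene = "J",
    v_read_start = 0L, v_ref_start = 0L, j_read_start = 4L,
    cdr3 = NA
  )
  ref <- segment_reference(
    tibble::tibble(name = "V", sequence = "TGTG", cys_offset = 0L),
    tibble::tibble(name = "J", sequence = "TTTGGAGCAGGA", phe_offset = 0L)
  )
  reads <- tibble::tibble(read_id = "r", sequence = "TGTGTTTGGAGCAGGA")
  out <- extract_cdr3(reads, aln, ref)
  expect_equal(out$cdr3_nt, "TGTGTTT") # 7 nt, out of frame
  expect_false(out$productive)
  expect_equal(out$cdr3_aa, "")

  # stop rule: in-frame TAA kills productivity
  ref2 <- segment_reference(
    tibble::tibble(name = "V", sequence = "TGT", cys_offset = 0L),
    tibble::tibble(name = "J", sequence = "TTTGGAGCAGGA", phe_offset = 0L)
  )
  reads2 <- tibble::tibble(read_id = "r", sequence = "TGTTAATTTGGAGCAGGA")
  aln2 <- dplyr::mutate(aln, j_read_start = 6L)
  out2 <- extract_cdr3(reads2, aln2, ref2)
  expect_equal(out2$cdr3_nt, "TGTTAATTT")
  expect_equal(out2$cdr3_aa, "C*F")
  expect_false(out2$productive)
})

test_that("clone assembly keys exactly and numbers by support", {
  reads <- tibble::tibble(
    read_id = paste0("r", 1:6),
    v_gene = c("TRBV01", "TRBV01", "TRBV01", "TRBV01", "TRBV02", "TRBV02"),
    j_gene = "TRBJ01",
    cdr3_nt = c("TGTAAATTT", "TGTAAATTT", "TGTAAATTT",
                "TGTAATTTT", "TGTCCCTTT", "TGTCCCTTT"),
    cdr3_aa = c("CKF", "CKF", "CKF", "CNF", "CPF", "CPF"),
    productive = TRUE
  )
  res <- assemble_clones(reads)
  expect_equal(nrow(res$clones), 3L)
  expect_equal(res$clones$read_support, c(3L, 2L, 1L))
  expect_equal(res$clones$clone_id, 1:3)
  # one-nt CDR3 difference keeps clones apart
  expect_equal(sum(res$clones$v_gene == "TRBV01"), 2L)
  # support ties resolve by first-seen order
  expect_equal(res$clones$cdr3_nt[2], "TGTCCCTTT")
  expect_equal(res$read_map$clone_id[reads$cdr3_nt == "TGTAAATTT"],
               rep(1L, 3L))
})

test_that("error-free simulated reads recover the truth clone set exactly", {
  x <- make_clean_reads(seed = 39L, n_molecules = 400L, n_clones = 20L)
  res <- call_clonotypes(x$reads, x$d$reference, x$d$primer_pool)
  expect_equal(nrow(res$clones), 20L)
  truth_support <- table(x$truth$clone_id)
  truth_keys <- clone_keys(x$d$truth$clones)
  expect_setequal(clone_keys(res$clones), truth_keys)
  got_support <- res$clones$read_support[match(truth_keys,
                                               clone_keys(res$clones))]
  expect_equal(got_support,
               as.integer(truth_support[as.character(x$d$truth$clones$clone_id)]))
  expect_true(all(res$clones$productive))
})

test_that("per-clone read export and MiXCR import round-trip", {
  x <- make_clean_reads(seed = 41L, n_molecules = 120L, n_clones = 6L)
  res <- call_clonotypes(x$reads, x$d$reference, x$d$primer_pool)
  out_dir <- tempfile("reads")
  files <- export_reads_for_clones(res$read_map, x$reads, out_dir)
  expect_equal(files$n_reads,
               res$clones$read_support[order(res$clones$clone_id)])
  expect_true(all(file.exists(
    file.path(out_dir, sprintf("reads_cln%d.fastq.gz",
                               res$clones$clone_id - 1L))
  )))
  tab <- file.path(out_dir, "clones.tsv")
  write_clones_table(res$clones, tab)
  imp <- import_mixcr(tab, out_dir)
  expect_setequal(clone_keys(imp$clones), clone_keys(res$clones))
  expect_equal(
    imp$clones$read_support[match(clone_keys(res$clones),
                                  clone_keys(imp$clones))],
    res$clones$read_support
  )
  expect_setequal(imp$read_map$read_id, res$read_map$read_id)
  expect_true(all(imp$clones$chain == "TRB"))
})

test_that("MiXCR import flags non-TRB hits and warns on missing read files", {
  dir <- tempfile("mixcr"); dir.create(dir)
  tab <- file.path(dir, "clones.tsv")
  writeLines(c(
    "cloneId\treadCount\tvGene\tjGene\tnSeqCDR3\taaSeqCDR3",
    "1\t5\tTRBV05\tTRBJ01\tTGTGCATTT\tCAF",
    "2\t2\tIGKV03\tTRBJ02\tTGTGGATTT\tCGF"
  ), tab)
  write_fastq(tibble::tibble(read_id = paste0("r", 1:5),
                             sequence = strrep("A", 30),
                             qualities = strrep("I", 30)),
              file.path(dir, "reads_cln0.fastq.gz"))
  expect_warning(imp <- import_mixcr(tab, dir), "no reads file")
  expect_equal(imp$clones$chain, c("TRB", "other"))
  expect_equal(sum(imp$read_map$clone_id == 1L), 5L)
  expect_equal(sum(imp$read_map$clone_id == 2L), 0L)
})
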