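test_that("barcode and UMI occupy read-1 positions 1-16 and 17-28", {
  reads <- tibble::tibble(read_id = "r1",
                          sequence = paste0(strrep("A", 10), strrep("C", 6),
                                            strrep("G", 12), "TT"))
  out <- extract_barcode_umi(reads)
  expect_equal(nchar(out$barcode), 16L)
  expect_equal(nchar(out$umi), 12L)
  expect_equal(paste0(out$barcode, out$umi), substr(reads$sequence, 1, 28))
})

test_that("read 1 shorter than 28 nt is a named hard error", {
  reads <- tibble::tibble(read_id = "short_read", sequence = strrep("A", 27))
  err <- expect_error(extract_barcode_umi(reads),
                      class = "tcrspot_length_error")
  expect_match(conditionMessage(err), "short_read")
})

test_that("simulated read 1 extraction reproduces the truth barcodes/UMIs", {
  cfg <- sim_config(n_spots = 20L, n_clones = 5L, n_molecules = 150L,
                    seq_error_rate = 0, seed = 51L)
  d <- simulate_dataset(tempfile("bu"), cfg, n_v = 6L, n_j = 3L)
  r1 <- read_fastq(d$r1)
  out <- extract_barcode_umi(r1)
  truth <- d$truth$reads[match(out$read_id, d$truth$reads$read_id), ]
  expect_equal(out$barcode, truth$barcode)
  expect_equal(out$umi, truth$umi)
})

test_that("barcode matching is exact at radius 0 and unique-only at radius 1", {
  bc <- random_barcodes(6L, seed = 52L)
  map <- tiny_spot_map(bc, in_tissue = c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))

  m0 <- match_barcode(bc, map, max_hamming = 0L)
  expect_equal(m0$matched_barcode, bc)
  expect_equal(m0$status, ifelse(map$in_tissue, "in_tissue", "off_tissue"))

  # exact matcher equals plain set membership over random queries
  probes <- c(bc, random_barcodes(20L, seed = 53L))
  m <- match_barcode(probes, map, max_hamming = 0L)
  expect_equal(!is.na(m$matched_barcode), probes %in% bc)

  # one substitution from exactly one whitelist entry: recovered at radius 1
  mut <- bc[1]
  substr(mut, 3, 3) <- setdiff(c("A", "C", "G", "T"),
                               substr(mut, 3, 3))[1]
  expect_equal(match_barcode(mut, map, 0L)$status, "unmatched")
  m1 <- match_barcode(mut, map, 1L)
  expect_equal(m1$matched_barcode, bc[1])
  # brute-force Hamming scan confirms uniqueness of that neighbour
  dists <- vapply(bc, function(w) {
    sum(strsplit(mut, "")[[1]] != strsplit(w, "")[[1]])
  }, integer(1))
  expect_equal(sum(dists == 1L), 1L)

  # equidistant neighbours stay unmatched
  twin_map <- tiny_spot_map(c("AAAAAAAAAAAAAAAA", "CAAAAAAAAAAAAAAG"))
  amb <- "CAAAAAAAAAAAAAAA" # distance 1 from both
  expect_equal(match_barcode(amb, twin_map, 1L)$status, "unmatched")
  # N bases never match
  expect_equal(match_barcode("NAAAAAAAAAAAAAAA", twin_map, 1L)$status,
               "unmatched")
})

test_that("deduplication collapses, majority-votes, and discards ties", {
  rec <- tibble::tibble(
    barcode = rep("AACCGGTTAACCGGTT", 5),
    umi = c("AAAAAAAAAAAA", "AAAAAAAAAAAA", "CCCCCCCCCCCC",
            "CCCCCCCCCCCC", "CCCCCCCCCCCC"),
    clone_id = c(1L, 1L, 2L, 2L, 3L),
    matched = "in_tissue"
  )
  out <- deduplicate(rec)
  expect_equal(nrow(out), 2L)
  expect_equal(out$clone_id[out$umi == "AAAAAAAAAAAA"], 1L)
  expect_equal(out$clone_id[out$umi == "CCCCCCCCCCCC"], 2L) # majority 2 vs 1

  tie <- tibble::tibble(barcode = "AACCGGTTAACCGGTT",
                        umi = rep("GGGGGGGGGGGG", 2),
                        clone_id = 1:2, matched = "in_tissue")
  expect_equal(nrow(deduplicate(tie)), 0L)
  expect_equal(nrow(deduplicate(rec[0, ])), 0L)
})

test_that("deduplication equals the brute-force group-by oracle", {
  withr::with_seed(54L, {
    bc <- random_barcodes(8L, seed = 55L)
    # status is a property of the barcode, as in real data
    status_of <- setNames(sample(c("in_tissue", "off_tissue", "unmatched"),
                                 8L, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
                          bc)
    rec <- tibble::tibble(
      barcode = sample(bc, 500L, replace = TRUE),
      umi = sample(c("AAAAAAAAAAAA", "CCCCCCCCCCCC", "GGGGGGGGGGGG",
                     "TTTTTTTTTTTT"), 500L, replace = TRUE),
      clone_id = sample(1:5, 500L, replace = TRUE),
      matched = unname(status_of[barcode])
    )
    got <- as.data.frame(deduplicate(rec))
    want <- oracle_dedup(as.data.frame(rec))
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  })
})

test_that("deduplication is idempotent", {
  withr::with_seed(56L, {
    rec <- tibble::tibble(
      barcode = sample(random_barcodes(5L, seed = 57L), 200L, replace = TRUE),
      umi = sample(c("AAAAAAAAAAAA", "CCCCCCCCCCCC"), 200L, replace = TRUE),
      clone_id = sample(1:4, 200L, replace = TRUE),
      matched = "in_tissue"
    )
    once <- deduplicate(rec)
    twice <- deduplicate(once)
    expect_equal(twice, once)
  })
})

test_that("linkage conserves reads across the three outcomes", {
  cfg <- sim_config(n_spots = 30L, frac_in_tissue = 0.6, n_clones = 6L,
                    n_molecules = 300L, pcr_duplication_mean = 2,
                    seq_error_rate = 0, frac_off_tissue = 0.25, seed = 58L)
  d <- simulate_dataset(tempfile("lnk"), cfg, n_v = 6L, n_j = 3L)
  res <- call_clonotypes(read_fastq(d$r2), d$reference, d$primer_pool)
  lnk <- link_reads(res$read_map, d$r1, d$spot_map)
  log <- lnk$log
  expect_equal(log$in_tissue + log$off_tissue + log$unmatched_barcode,
               log$total)
  expect_equal(log$total, nrow(res$read_map))
  # error-free: per-read outcomes equal the truth placement flags
  truth <- d$truth$reads[match(lnk$records$read_id, d$truth$reads$read_id), ]
  truth_status <- ifelse(
    d$truth$placements$in_tissue[match(paste(truth$barcode, truth$umi),
                                       paste(d$truth$placements$barcode,
                                             d$truth$placements$umi))],
    "in_tissue", "off_tissue")
  expect_equal(lnk$records$matched, truth_status)
  expect_equal(log$unmatched_barcode, 0L)

  miss <- dplyr::bind_rows(res$read_map,
                           tibble::tibble(read_id = "ghost", clone_id = 1L))
  expect_error(link_reads(miss, d$r1, d$spot_map),
               class = "tcrspot_pairing_error")
})

test_that("matrix building orders rows by spot map and routes off-tissue hits", {
  bc <- random_barcodes(3L, seed = 59L)
  map <- tiny_spot_map(bc, in_tissue = c(TRUE, TRUE, FALSE))
  rec <- tibble::tibble(
    barcode = c(bc[1], bc[3]),
    umi = c("AAAAAAAAAAAA", "CCCCCCCCCCCC"),
    clone_id = c(4L, 4L),
    matched = c("in_tissue", "off_tissue")
  )
  mat <- build_matrix(deduplicate(rec), map)
  expect_equal(rownames(as.matrix(mat)), bc[1:2])
  expect_equal(as.vector(as.matrix(mat)), c(1L, 0L))
  expect_equal(colnames(as.matrix(mat)), "clone4")
  expect_equal(mat$off_tissue$barcode, bc[3])

  # all records off tissue: zero-column matrix, populated side table
  off_only <- dplyr::mutate(rec[2, ], matched = "off_tissue")
  mat2 <- build_matrix(deduplicate(off_only), map)
  expect_equal(ncol(as.matrix(mat2)), 0L)
  expect_equal(nrow(as.matrix(mat2)), 2L)
  expect_equal(sum(mat2$off_tissue$umis), 1L)

  # a record claiming an unknown in-tissue barcode is an internal error
  alien <- tibble::tibble(barcode = random_barcodes(1L, seed = 60L),
                          umi = "GGGGGGGGGGGG", clone_id = 1L,
                          matched = "in_tissue", n_reads = 1L)
  expect_error(build_matrix(alien, map), class = "tcrspot_internal_error")
})

test_that("conservation holds between matrix totals and deduplicated records", {
  cfg <- sim_config(n_spots = 25L, frac_in_tissue = 0.7, n_clones = 5L,
                    n_molecules = 250L, pcr_duplication_mean = 3,
                    seq_error_rate = 0, frac_off_tissue = 0.2, seed = 61L)
  d <- simulate_dataset(tempfile("cons"), cfg, n_v = 6L, n_j = 3L)
  res <- call_clonotypes(read_fastq(d$r2), d$reference, d$primer_pool)
  lnk <- link_reads(res$read_map, d$r1, d$spot_map)
  deduped <- deduplicate(lnk$records)
  mat <- build_matrix(deduped, d$spot_map)
  expect_equal(sum(as.matrix(mat)) + sum(mat$off_tissue$umis), nrow(deduped))
})
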