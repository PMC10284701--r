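mk_tx <- function(id, gene, cds_len, tx_len) {
  tibble::tibble(transcript_id = id, gene_id = gene, length = tx_len,
                 cds_start = 0L, cds_end = cds_len, stop_codon = "UGA")
}

test_that("canonical transcript selection: longest CDS, then longest transcript, then id", {
  anns <- dplyr::bind_rows(
    mk_tx("a1", "gA", 300L, 800L), mk_tx("a2", "gA", 450L, 700L),
    mk_tx("b1", "gB", 300L, 800L), mk_tx("b2", "gB", 300L, 1000L),
    mk_tx("c2", "gC", 300L, 800L), mk_tx("c1", "gC", 300L, 800L),
    mk_tx("d1", "gD", 600L, 900L))
  sel <- select_canonical_transcripts(anns)
  picks <- stats::setNames(sel$transcript_id, sel$gene_id)
  expect_equal(unname(picks["gA"]), "a2")  # longer CDS wins
  expect_equal(unname(picks["gB"]), "b2")  # CDS tie: longer transcript
  expect_equal(unname(picks["gC"]), "c1")  # full tie: lexical id
  expect_equal(unname(picks["gD"]), "d1")  # single transcript: itself
  expect_equal(nrow(sel), 4L)
})

test_that("footprint length filter keeps the inclusive 25-32 window", {
  reads <- tibble::tibble(transcript_id = "t", start = 0L,
                          length = c(24L, 25L, 28L, 32L, 33L))
  expect_equal(filter_footprints(reads)$length, c(25L, 28L, 32L))
  expect_equal(nrow(filter_footprints(reads[0, ])), 0L)
  all28 <- tibble::tibble(transcript_id = "t", start = 0L, length = rep(28L, 5))
  expect_equal(filter_footprints(all28), all28)
  expect_equal(filter_footprints(reads, 20, 40)$length, reads$length)
})

test_that("midpoint assignment uses floor((length-1)/2) from the 5' end", {
  reads <- tibble::tibble(transcript_id = "t",
                          start = c(100L, 0L, 100L),
                          length = c(29L, 1L, 28L))
  mids <- assign_midpoints(reads)$midpoint
  expect_equal(mids, c(114L, 0L, 113L))
  # with an offset map, midpoint = start + offset[length]
  off <- tibble::tibble(length = c(28L, 29L), offset = c(12L, 13L))
  expect_equal(assign_midpoints(reads, off)$midpoint, c(113L, NA, 112L))
})

test_that("stop-codon metagene counts midpoints at offsets from the stop", {
  tx <- toy_transcript(utr5 = 120, cds = 300, ext = 90, tail = 120)
  stop_first <- tx$cds_end - 3L
  # all midpoints exactly at the stop's first nt
  reads <- point_reads("t1", rep(stop_first, 7))
  prof <- stop_codon_metagene(reads, tx, window = 100)
  expect_equal(prof$count[prof$offset == 0], 7L)
  expect_equal(sum(prof$count), 7L)
  expect_equal(attr(prof, "n_reads"), 7L)
  # uniform CDS-only coverage: nothing beyond offset +2
  cds_reads <- point_reads("t1", seq(tx$cds_start, tx$cds_end - 1))
  prof2 <- stop_codon_metagene(cds_reads, tx, window = 100)
  expect_true(all(prof2$count[prof2$offset > 2] == 0))
  # invariant to read order and transcript order
  tx2 <- dplyr::bind_rows(tx, toy_transcript("t2", utr5 = 80))
  reads2 <- dplyr::bind_rows(cds_reads, point_reads("t2", c(100, 110, 120)))
  p_a <- stop_codon_metagene(reads2, tx2)
  p_b <- stop_codon_metagene(reads2[rev(seq_len(nrow(reads2))), ],
                             tx2[rev(seq_len(nrow(tx2))), ])
  expect_equal(p_a$count, p_b$count)
  # stratification by stop identity keeps totals
  p_s <- stop_codon_metagene(reads2, tx2, by_stop = TRUE)
  expect_equal(sum(p_s$count), sum(p_a$count))
  # unknown transcript ids are an error
  expect_error(stop_codon_metagene(point_reads("nope", 1), tx), "absent")
})

test_that("next in-frame stop scanning honours frame and the 4-nt separation rule", {
  base <- toy_transcript(utr5 = 0, cds = 6, ext = 6, tail = 0)
  with_utr3 <- function(utr3) {
    seq <- paste0("AAAUGA", utr3)
    tibble::tibble(transcript_id = "t1", gene_id = "g1", length = nchar(seq),
                   cds_start = 0L, cds_end = 6L, stop_codon = "UGA",
                   sequence = seq)
  }
  # two sense codons then UAG: extension length 6
  ext <- find_next_inframe_stop(with_utr3("AAAAAAUAGCCC"))
  expect_equal(ext$ext_length, 6L)
  expect_equal(ext$ext_start, 6L)
  expect_equal(ext$ext_end, 12L)
  # immediate in-frame stop: separation 0 < 4 -> excluded
  expect_equal(nrow(find_next_inframe_stop(with_utr3("UAGCCCCCC"))), 0L)
  # one codon of separation (3 nt < 4) -> excluded
  expect_equal(nrow(find_next_inframe_stop(with_utr3("AAAUAGCCC"))), 0L)
  # no in-frame stop at all -> excluded
  expect_equal(nrow(find_next_inframe_stop(with_utr3("AAAAAAAAA"))), 0L)
  # out-of-frame stops do not terminate the scan
  ext2 <- find_next_inframe_stop(with_utr3("AUGACCAAAUAACC"))
  expect_equal(ext2$ext_length, 9L)
})

test_that("RRTS matches the hand example and its edge conventions", {
  tx <- toy_transcript(utr5 = 50, cds = 300, ext = 90, tail = 60)
  ext <- find_next_inframe_stop(tx)
  expect_equal(ext$ext_length, 90L)
  # 30 CDS midpoints, 3 extension midpoints -> (3/0.09)/(30/0.3) = 1/3
  reads <- dplyr::bind_rows(
    point_reads("t1", seq(60, 340, length.out = 30)),
    point_reads("t1", c(360, 380, 400)))
  rr <- compute_rrts(reads, tx, ext)
  expect_equal(rr$rrts, 1 / 3, tolerance = 1e-12)
  expect_equal(rr$cds_reads, 30L)
  expect_equal(rr$ext_reads, 3L)
  # no extension reads -> RRTS 0
  rr0 <- compute_rrts(point_reads("t1", seq(60, 340, length.out = 30)), tx, ext)
  expect_equal(rr0$rrts, 0)
  # equal densities -> RRTS 1 (one read per nt everywhere)
  rr1 <- compute_rrts(point_reads("t1", c(seq(50, 349), seq(350, 439))), tx, ext)
  expect_equal(rr1$rrts, 1)
  # a midpoint inside the natural stop codon counts to the CDS
  rr_stop <- compute_rrts(point_reads("t1", c(348, 349)), tx, ext)
  expect_equal(rr_stop$cds_reads, 2L)
  expect_equal(rr_stop$ext_reads, 0L)
  # zero CDS reads -> transcript excluded, not scored
  rr_ex <- compute_rrts(point_reads("t1", c(360, 361)), tx, ext)
  expect_equal(nrow(rr_ex), 0L)
})

test_that("RRTS is monotone in where reads fall", {
  tx <- toy_transcript(utr5 = 50, cds = 300, ext = 90, tail = 60)
  ext <- find_next_inframe_stop(tx)
  base <- dplyr::bind_rows(point_reads("t1", seq(60, 340, length.out = 20)),
                           point_reads("t1", c(355, 375)))
  r0 <- compute_rrts(base, tx, ext)$rrts
  r_ext <- compute_rrts(dplyr::bind_rows(base, point_reads("t1", 390)), tx, ext)$rrts
  r_cds <- compute_rrts(dplyr::bind_rows(base, point_reads("t1", 100)), tx, ext)$rrts
  expect_gte(r_ext, r0)
  expect_lte(r_cds, r0)
})

test_that("vectorized RRTS equals the literal per-position oracle on random libraries", {
  set.seed(42)
  txs <- dplyr::bind_rows(lapply(1:10, function(i) {
    toy_transcript(sprintf("t%02d", i), utr5 = 40 + 5 * i,
                   cds = 60 + 30 * i, ext = 6 + 9 * (i %% 4), tail = 60)
  }))
  exts <- find_next_inframe_stop(txs)
  reads <- tibble::tibble(
    transcript_id = sample(txs$transcript_id, 1000, replace = TRUE)) |>
    dplyr::left_join(txs[c("transcript_id", "length")], by = "transcript_id") |>
    dplyr::mutate(length_read = sample(25:32, 1000, replace = TRUE),
                  start = floor(stats::runif(1000, 0, length - length_read))) |>
    dplyr::transmute(transcript_id, start = as.integer(start),
                     length = length_read)
  rr <- compute_rrts(reads, txs, exts)
  for (id in rr$transcript_id) {
    o <- rrts_oracle(reads, txs[txs$transcript_id == id, ],
                     exts[exts$transcript_id == id, ])
    row <- rr[rr$transcript_id == id, ]
    expect_equal(row$cds_reads, o$cds_reads)
    expect_equal(row$ext_reads, o$ext_reads)
    expect_equal(row$rrts, o$rrts, tolerance = 1e-12)
  }
})

test_that("quantification is definitional and conserves RPM", {
  tx <- dplyr::bind_rows(mk_tx("t1", "g1", 300L, 1000L),
                         mk_tx("t2", "g2", 300L, 2000L))
  # 10 reads on a 1000-nt transcript in a 1e6-read library is RPM 10, RPKM 10
  lib <- tibble::tibble(
    transcript_id = c(rep("t1", 10), rep("t2", 999990)),
    start = 0L, length = 28L)
  q <- quantify_footprints(lib, tx)
  expect_equal(q$rpm[q$transcript_id == "t1"], 10)
  expect_equal(q$rpkm[q$transcript_id == "t1"], 10)
  expect_equal(sum(q$rpm), 1e6)
  # zero-count transcript has RPKM 0 and falls to the expression filter
  tx3 <- dplyr::bind_rows(tx, mk_tx("t3", "g3", 300L, 1000L))
  q3 <- quantify_footprints(lib, tx3, min_rpkm = 0.1)
  expect_false("t3" %in% q3$transcript_id)
  # the filter is strictly greater-than
  small <- tibble::tibble(transcript_id = c("t1", rep("t2", 9999)),
                          start = 0L, length = 28L)
  qs <- quantify_footprints(small, tx)   # t1: rpm 100, rpkm 100
  qf <- quantify_footprints(small, tx, min_rpkm = 100)
  expect_false("t1" %in% qf$transcript_id)
  expect_error(quantify_footprints(lib[0, ], tx), "empty")
})

test_that("A-site offsets are recovered per length, with fallback on poor coverage", {
  tx <- dplyr::bind_rows(mk_tx("t1", "g1", 300L, 400L) |>
                           dplyr::mutate(cds_start = 50L, cds_end = 350L))
  true_off <- c(`28` = 12L, `30` = 13L)
  reads <- dplyr::bind_rows(lapply(names(true_off), function(L) {
    tibble::tibble(transcript_id = "t1",
                   start = rep(50L - true_off[[L]], 40), length = as.integer(L))
  }))
  off <- suppressWarnings(calibrate_asite_offsets(reads, tx))
  expect_equal(off$offset[off$length == 28], 12L)
  expect_equal(off$offset[off$length == 30], 13L)
  expect_equal(off$source[off$length %in% c(28, 30)], rep("calibrated", 2))
  # uninformative input falls back to midpoint defaults with a warning
  noise <- tibble::tibble(transcript_id = "t1", start = 200:220, length = 29L)
  expect_warning(off2 <- calibrate_asite_offsets(noise, tx), "default")
  expect_equal(off2$offset[off2$length == 29], 14L)
})

test_that("condition comparison is symmetric and respects the calling threshold", {
  tx <- dplyr::bind_rows(
    toy_transcript("t1", stop = "UGA"), toy_transcript("t2", stop = "UAG"))
  ext <- find_next_inframe_stop(tx)
  reads <- dplyr::bind_rows(
    point_reads("t1", seq(60, 340, length.out = 25)),
    point_reads("t1", c(360, 370, 380)),
    point_reads("t2", seq(60, 340, length.out = 25)))
  rr <- compute_rrts(reads, tx, ext)
  cmp <- compare_conditions(rr, rr, labels = c("treated", "control"))
  calls <- readthrough_calls(cmp)
  expect_equal(calls$called_treated, calls$called_control)
  expect_equal(sum(calls$called_treated), 1L)  # only t1 has >= 2 ext reads
  # min_ext_reads gates the call
  cmp4 <- compare_conditions(rr, rr, min_ext_reads = 4L)
  expect_equal(sum(readthrough_calls(cmp4)$called_a), 0L)
  # disjoint universes are an error
  rr_other <- dplyr::mutate(rr, transcript_id = paste0("x_", transcript_id))
  expect_error(compare_conditions(rr, rr_other), "no transcripts")
})

test_that("SAM/BAM footprints load through Rsamtools like the TSV path", {
  skip_if_not_installed("Rsamtools")
  tmp_sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:t1\tLN:500",
    paste("r1", 0, "t1", 101, 255, "28M", "*", 0, 0,
          strrep("A", 28), "*", sep = "\t"),
    paste("r2", 0, "t1", 151, 255, "30M", "*", 0, 0,
          strrep("A", 30), "*", sep = "\t")), tmp_sam)
  bam <- Rsamtools::asBam(tmp_sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  fp <- read_footprints(bam)
  expect_equal(fp$start, c(100L, 150L))     # SAM is 1-based, tibble is 0-based
  expect_equal(fp$length, c(28L, 30L))
  expect_equal(fp$transcript_id, c("t1", "t1"))
})
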