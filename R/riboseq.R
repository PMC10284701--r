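#' Read transcript models from a TSV (+ optional FASTA)
#'
#' Transcript models live in transcript coordinates (0-based half-open).
#' The CDS interval includes the stop codon; the last CDS codon must be a
#' stop. Required TSV columns: `transcript_id`, `gene_id`, `length`,
#' `cds_start`, `cds_end`. `stop_codon` and `sequence` are taken from the
#' TSV if present, otherwise derived from / attached via the FASTA.
#'
#' @param path TSV path.
#' @param fasta Optional FASTA of spliced transcript sequences.
#' @return Tibble of transcript models.
#' @export
read_transcript_models <- function(path, fasta = NULL) {
  tx <- readr::read_tsv(path, show_col_types = FALSE)
  if (!is.null(fasta)) {
    seqs <- Biostrings::readBStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    tx$sequence <- as_rna(as.character(seqs[tx$transcript_id]))
  }
  validate_transcripts(tx)
}

validate_transcripts <- function(tx) {
  tx <- tibble::as_tibble(tx)
  req <- c("transcript_id", "gene_id", "length", "cds_start", "cds_end")
  if (!all(req %in% names(tx))) {
    stop("transcript models need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any((tx$cds_end - tx$cds_start) %% 3L != 0L)) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  if (any(tx$cds_end > tx$length)) {
    stop("CDS end beyond transcript length", call. = FALSE)
  }
  if ("sequence" %in% names(tx)) {
    tx$sequence <- as_rna(tx$sequence)
    last_codon <- substr(tx$sequence, tx$cds_end - 2L, tx$cds_end)
    if (!"stop_codon" %in% names(tx)) tx$stop_codon <- last_codon
    if (any(last_codon != tx$stop_codon)) {
      stop("stop_codon column disagrees with the sequence", call. = FALSE)
    }
  }
  if ("stop_codon" %in% names(tx) && !all(tx$stop_codon %in% STOP_CODONS)) {
    stop("last CDS codon must be UGA, UAG or UAA", call. = FALSE)
  }
  tx
}

#' Select one canonical transcript per gene
#'
#' Per gene, keeps the transcript with the longest CDS; ties are broken by
#' the longest transcript (including UTRs), then lexically by id so the
#' choice is deterministic.
#'
#' @param transcripts Transcript-model tibble (see
#'   [read_transcript_models()]).
#' @return One-row-per-gene tibble.
#' @export
select_canonical_transcripts <- function(transcripts) {
  transcripts |>
    dplyr::mutate(.cds_len = .data$cds_end - .data$cds_start) |>
    dplyr::arrange(.data$gene_id, dplyr::desc(.data$.cds_len),
                   dplyr::desc(.data$length), .data$transcript_id) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::select(-".cds_len")
}

#' Read footprint alignments from a TSV or a transcriptome-aligned BAM
#'
#' TSV columns: `transcript_id`, `start` (0-based transcript coordinate of
#' the 5' end), `length`. For BAM input the reference names are transcript
#' ids and the query width is the footprint length (requires Rsamtools).
#'
#' @param path TSV or BAM path.
#' @return Footprint tibble.
#' @export
read_footprints <- function(path) {
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("BAM input requires the Rsamtools package", call. = FALSE)
    }
    p <- Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth"))
    b <- Rsamtools::scanBam(path, param = p)[[1]]
    keep <- !is.na(b$pos)
    tibble::tibble(transcript_id = as.character(b$rname)[keep],
                   start = b$pos[keep] - 1L, length = b$qwidth[keep])
  } else {
    readr::read_tsv(path, show_col_types = FALSE,
                    col_types = readr::cols(transcript_id = readr::col_character(),
                                            start = readr::col_integer(),
                                            length = readr::col_integer()))
  }
}

#' Keep footprints in the standard ribosome-protected length range
#'
#' @param reads Footprint tibble with a `length` column.
#' @param min_len,max_len Inclusive bounds (default 25-32 nt).
#' @return Filtered tibble.
#' @export
filter_footprints <- function(reads, min_len = 25L, max_len = 32L) {
  dplyr::filter(reads, .data$length >= min_len, .data$length <= max_len)
}

#' Assign a ribosome position to each footprint
#'
#' By default the middle nucleotide is used — for even lengths the
#' nucleotide 5' of the middle — i.e. `start + floor((length - 1) / 2)`.
#' Supplying a per-length offset map (see [calibrate_asite_offsets()])
#' instead places reads at `start + offset[length]`.
#'
#' @param reads Footprint tibble.
#' @param offsets Optional tibble with columns `length` and `offset`.
#' @return `reads` with a `midpoint` column added.
#' @export
assign_midpoints <- function(reads, offsets = NULL) {
  if (is.null(offsets)) {
    dplyr::mutate(reads, midpoint = .data$start + (.data$length - 1L) %/% 2L)
  } else {
    reads |>
      dplyr::left_join(dplyr::select(offsets, "length", "offset"), by = "length") |>
      dplyr::mutate(midpoint = .data$start + .data$offset) |>
      dplyr::select(-"offset")
  }
}

#' Metagene profile of footprint density around stop codons
#'
#' Counts assigned footprint positions at each offset from the first
#' nucleotide of the annotated stop codon, aggregated over transcripts,
#' within a window of `window` nt on either side.
#'
#' @param reads Footprint tibble (filtered; midpoints are assigned with
#'   [assign_midpoints()] if absent).
#' @param transcripts Transcript models.
#' @param window Half-width of the window in nt.
#' @param by_stop Stratify by stop-codon identity.
#' @return Tibble of class `metagene_profile` with columns `offset`,
#'   `count` (and `stop_codon` when stratified), attribute `n_reads` = the
#'   number of in-window positions counted.
#' @export
stop_codon_metagene <- function(reads, transcripts, window = 100L,
                                by_stop = FALSE) {
  if (!"midpoint" %in% names(reads)) reads <- assign_midpoints(reads)
  unknown <- setdiff(unique(reads$transcript_id), transcripts$transcript_id)
  if (length(unknown) > 0) {
    stop("reads reference transcripts absent from the models: ",
         paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
  }
  anchor <- transcripts |>
    dplyr::transmute(.data$transcript_id,
                     stop_first = .data$cds_end - 3L,
                     stop_codon = if ("stop_codon" %in% names(transcripts)) {
                       .data$stop_codon
                     } else {
                       NA_character_
                     })
  hits <- reads |>
    dplyr::inner_join(anchor, by = "transcript_id") |>
    dplyr::mutate(offset = .data$midpoint - .data$stop_first) |>
    dplyr::filter(abs(.data$offset) <= window)
  keys <- if (by_stop) c("stop_codon", "offset") else "offset"
  counts <- hits |>
    dplyr::count(dplyr::across(dplyr::all_of(keys)), name = "count")
  grid <- if (by_stop) {
    tidyr::expand_grid(stop_codon = sort(unique(anchor$stop_codon)),
                       offset = seq.int(-window, window))
  } else {
    tibble::tibble(offset = seq.int(-window, window))
  }
  out <- grid |>
    dplyr::left_join(counts, by = keys) |>
    dplyr::mutate(count = tidyr::replace_na(.data$count, 0L))
  structure(out, n_reads = nrow(hits), window = window,
            class = c("metagene_profile", class(out)))
}

#' Find the in-frame readthrough extension region of a transcript
#'
#' Scans the 3'UTR codon-by-codon in the CDS reading frame and returns the
#' extension region: from the first nucleotide after the natural stop
#' codon up to (exclusive) the first next in-frame stop codon. Transcripts
#' whose next in-frame stop is separated from the natural stop by fewer
#' than `min_separation` nucleotides, or that have no in-frame stop in the
#' 3'UTR, yield no region and are excluded from readthrough scoring.
#'
#' @param transcripts Transcript models with a `sequence` column.
#' @param min_separation Minimum extension length in nt (default 4).
#' @return Tibble with `transcript_id`, `ext_start`, `ext_end`,
#'   `ext_length`; one row per transcript that has a usable region.
#' @export
find_next_inframe_stop <- function(transcripts, min_separation = 4L) {
  if (!"sequence" %in% names(transcripts)) {
    stop("find_next_inframe_stop needs transcript sequences", call. = FALSE)
  }
  purrr::pmap_dfr(
    transcripts[c("transcript_id", "sequence", "cds_end", "length")],
    function(transcript_id, sequence, cds_end, length) {
      utr3 <- substr_vec(sequence, cds_end, length)
      codons <- codon_split(utr3)
      hit <- which(codons %in% STOP_CODONS)
      if (length(hit) == 0) return(NULL)
      ext_len <- 3L * (hit[1] - 1L)
      if (ext_len < min_separation) return(NULL)
      tibble::tibble(transcript_id = transcript_id,
                     ext_start = cds_end, ext_end = cds_end + ext_len,
                     ext_length = ext_len)
    })
}

#' Ribosome readthrough score (RRTS) per transcript
#'
#' RRTS is the ratio of the mean footprint density over the readthrough
#' extension region (reads per kilobase, normalized to extension length)
#' to the mean density over the CDS (reads per kilobase of CDS). Higher
#' values mean more readthrough; a transcript with no extension reads
#' scores 0. Reads whose assigned position falls inside the natural stop
#' codon count to the CDS. Transcripts with zero CDS reads are excluded,
#' not scored.
#'
#' @param reads Footprint tibble (midpoints assigned if absent; apply
#'   [filter_footprints()] beforehand).
#' @param transcripts Transcript models.
#' @param extensions Extension regions from [find_next_inframe_stop()];
#'   computed from `transcripts$sequence` when `NULL`.
#' @return Tibble of class `rrts_table`: `transcript_id`, `stop_codon`,
#'   `cds_reads`, `ext_reads`, `cds_rpk`, `ext_rpk`, `rrts`.
#' @export
compute_rrts <- function(reads, transcripts, extensions = NULL) {
  if (!"midpoint" %in% names(reads)) reads <- assign_midpoints(reads)
  if (is.null(extensions)) extensions <- find_next_inframe_stop(transcripts)
  geom <- transcripts |>
    dplyr::inner_join(extensions, by = "transcript_id")
  counts <- reads |>
    dplyr::inner_join(
      dplyr::select(geom, "transcript_id", "cds_start", "cds_end",
                    "ext_start", "ext_end"),
      by = "transcript_id") |>
    dplyr::summarise(
      cds_reads = sum(.data$midpoint >= .data$cds_start[1] &
                        .data$midpoint < .data$cds_end[1]),
      ext_reads = sum(.data$midpoint >= .data$ext_start[1] &
                        .data$midpoint < .data$ext_end[1]),
      .by = "transcript_id")
  out <- geom |>
    dplyr::left_join(counts, by = "transcript_id") |>
    dplyr::mutate(
      cds_reads = tidyr::replace_na(.data$cds_reads, 0L),
      ext_reads = tidyr::replace_na(.data$ext_reads, 0L),
      cds_length = .data$cds_end - .data$cds_start,
      cds_rpk = .data$cds_reads / (.data$cds_length / 1000),
      ext_rpk = .data$ext_reads / (.data$ext_length / 1000),
      rrts = ifelse(.data$cds_rpk > 0, .data$ext_rpk / .data$cds_rpk, NA_real_)) |>
    dplyr::filter(.data$cds_reads > 0L) |>
    dplyr::select(dplyr::any_of(c("transcript_id", "stop_codon")),
                  "cds_reads", "ext_reads", "cds_length", "ext_length",
                  "cds_rpk", "ext_rpk", "rrts")
  structure(out, class = c("rrts_table", class(out)))
}

#' Transcript-level footprint quantification (RPM / RPKM)
#'
#' Every read in `reads` counts toward the library size; per transcript,
#' RPM = count / library size x 1e6 and RPKM = RPM / (transcript length in
#' kb). When all reads are assigned to exactly one transcript the RPM
#' column sums to 1e6.
#'
#' @param reads Footprint tibble.
#' @param transcripts Transcript models.
#' @param min_rpkm Optional expression filter: keep transcripts with RPKM
#'   strictly greater than this (the screen uses 0.1).
#' @return Tibble: `transcript_id`, `count`, `rpm`, `rpkm`; attribute
#'   `library_size`.
#' @export
quantify_footprints <- function(reads, transcripts, min_rpkm = NULL) {
  lib <- nrow(reads)
  if (lib == 0L) stop("empty footprint library", call. = FALSE)
  out <- transcripts |>
    dplyr::select("transcript_id", "length") |>
    dplyr::left_join(dplyr::count(reads, .data$transcript_id),
                     by = "transcript_id") |>
    dplyr::mutate(count = tidyr::replace_na(.data$n, 0L),
                  rpm = .data$count / lib * 1e6,
                  rpkm = .data$rpm / (.data$length / 1000)) |>
    dplyr::select("transcript_id", "count", "rpm", "rpkm")
  if (!is.null(min_rpkm)) out <- dplyr::filter(out, .data$rpkm > min_rpkm)
  structure(out, library_size = lib)
}

#' Calibrate per-length A-site offsets from start-codon metagenes
#'
#' For each footprint length, finds the 5'-end offset that places the most
#' reads exactly on the first nucleotide of annotated start codons. Reads
#' are informative if their implied offset falls in `search`. Lengths with
#' fewer than `min_reads` informative reads fall back (with a warning) to
#' the default midpoint offset `floor((length - 1) / 2)`.
#'
#' @param reads Footprint tibble.
#' @param transcripts Transcript models (`cds_start` marks the start codon).
#' @param lengths Footprint lengths to calibrate.
#' @param search Candidate offsets (nt from the 5' end).
#' @param min_reads Minimum informative reads per length.
#' @return Tibble: `length`, `offset`, `n_reads`, `source`
#'   (`"calibrated"` or `"default"`); usable as the `offsets` argument of
#'   [assign_midpoints()].
#' @export
calibrate_asite_offsets <- function(reads, transcripts, lengths = 25:32,
                                    search = 0:18, min_reads = 10L) {
  d <- reads |>
    dplyr::inner_join(dplyr::select(transcripts, "transcript_id", "cds_start"),
                      by = "transcript_id") |>
    dplyr::mutate(implied = .data$cds_start - .data$start) |>
    dplyr::filter(.data$implied %in% search)
  out <- purrr::map_dfr(lengths, function(L) {
    dL <- d[d$length == L, , drop = FALSE]
    tab <- table(dL$implied)
    if (nrow(dL) >= min_reads && length(tab) > 0) {
      best <- as.integer(names(tab)[which.max(tab)])
      tibble::tibble(length = L, offset = best, n_reads = nrow(dL),
                     source = "calibrated")
    } else {
      tibble::tibble(length = L, offset = (L - 1L) %/% 2L,
                     n_reads = nrow(dL), source = "default")
    }
  })
  if (any(out$source == "default")) {
    warning("insufficient start-codon coverage for length(s) ",
            paste(out$length[out$source == "default"], collapse = ", "),
            "; using default midpoint offsets", call. = FALSE)
  }
  out
}

#' Compare readthrough between two conditions, stratified by stop identity
#'
#' Joins two RRTS tables over their common transcript universe and, per
#' stop-codon identity, counts the transcripts "called" as undergoing
#' readthrough in each condition. A transcript is called when its RRTS
#' exceeds `threshold` and it has at least `min_ext_reads` extension-region
#' reads; the counts are therefore threshold-dependent and reported as
#' such. The comparison is symmetric in the two conditions.
#'
#' @param rrts_a,rrts_b RRTS tables from [compute_rrts()] (e.g. treated
#'   and control).
#' @param labels Length-2 names for the conditions.
#' @param threshold RRTS calling threshold (strictly greater than).
#' @param min_ext_reads Minimum extension reads for a call.
#' @return Tibble of class `rrts_comparison`, one row per transcript with
#'   both conditions' scores and call flags; per-identity counts via
#'   [readthrough_calls()].
#' @export
compare_conditions <- function(rrts_a, rrts_b, labels = c("a", "b"),
                               threshold = 0, min_ext_reads = 2L) {
  common <- intersect(rrts_a$transcript_id, rrts_b$transcript_id)
  if (length(common) == 0L) {
    stop("the two RRTS tables share no transcripts", call. = FALSE)
  }
  pick <- function(x, suffix) {
    x |>
      dplyr::filter(.data$transcript_id %in% common) |>
      dplyr::select(dplyr::any_of(c("transcript_id", "stop_codon")),
                    "rrts", "ext_reads") |>
      dplyr::mutate(called = .data$rrts > threshold &
                      .data$ext_reads >= min_ext_reads) |>
      dplyr::rename_with(~ paste0(.x, "_", suffix),
                         c("rrts", "ext_reads", "called"))
  }
  by_cols <- intersect(c("transcript_id", "stop_codon"), names(rrts_a))
  out <- dplyr::inner_join(pick(rrts_a, labels[1]), pick(rrts_b, labels[2]),
                           by = by_cols)
  structure(out, labels = labels, threshold = threshold,
            min_ext_reads = min_ext_reads,
            class = c("rrts_comparison", class(out)))
}

#' Per-stop-identity called-transcript counts of a comparison
#'
#' @param comparison Result of [compare_conditions()].
#' @return Tibble: `stop_codon`, `n_transcripts`, and one called-count
#'   column per condition.
#' @export
readthrough_calls <- function(comparison) {
  labels <- attr(comparison, "labels")
  comparison |>
    dplyr::summarise(
      n_transcripts = dplyr::n(),
      dplyr::across(dplyr::all_of(paste0("called_", labels)), sum),
      .by = dplyr::any_of("stop_codon"))
}

#' One-line summary of an RRTS table
#' @param x An `rrts_table`.
#' @param ... Unused.
#' @return One-row tibble with transcript count and RRTS moments.
#' @method glance rrts_table
#' @export
glance.rrts_table <- function(x, ...) {
  tibble::tibble(n_transcripts = nrow(x), mean_rrts = mean(x$rrts),
                 median_rrts = stats::median(x$rrts),
                 frac_zero = mean(x$ext_reads == 0L))
}
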