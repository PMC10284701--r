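SENSE_CODONS <- {
  b <- c("A", "C", "G", "U")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("UGA", "UAG", "UAA"))
}

#' Configuration for the synthetic footprint-library generator
#'
#' Holds the generative parameters of the simulated readthrough screen:
#' transcript geometry, the stop-identity mixture, the per-nucleotide CDS
#' expression rate `lambda`, the readthrough rate `rho` (expected
#' extension density as a fraction of CDS density), and the footprint
#' length mixture. Under this model the expected RRTS of a transcript is
#' exactly `rho`, which gives the recovery tests a clean target.
#'
#' @param n_genes Number of genes (one transcript each unless
#'   `n_isoforms > 1`).
#' @param cds_range CDS length range in nt (values are rounded to
#'   multiples of 3; includes the stop codon).
#' @param utr5_range,tail_range 5'UTR and post-extension 3' tail length
#'   ranges (nt). Both minima must be >= 16 so footprints fit.
#' @param ext_range Extension-region length range in nt (rounded to
#'   multiples of 3, minimum 6).
#' @param stop_mix Named fractions for UGA/UAG/UAA; must sum to 1. The
#'   default reflects the reported identity frequencies of disease PTCs
#'   (38.5/40.4/21.1%).
#' @param frac_with_next_stop Fraction of transcripts given a next
#'   in-frame stop in the 3'UTR; the rest have none and exercise the
#'   exclusion path.
#' @param lambda Expected CDS footprints per nt.
#' @param rho Readthrough rate in `[0, 1)`: scalar, or a vector named by
#'   stop identity.
#' @param fp_len_probs Footprint length mixture over 25-32 nt.
#' @param seed Integer seed; every generator output is reproducible
#'   bit-for-bit under a fixed seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 50L,
                       cds_range = c(300L, 1500L),
                       utr5_range = c(100L, 200L),
                       ext_range = c(30L, 150L),
                       tail_range = c(50L, 200L),
                       stop_mix = c(UGA = 0.385, UAG = 0.404, UAA = 0.211),
                       frac_with_next_stop = 0.8,
                       lambda = 0.2,
                       rho = 0.01,
                       fp_len_probs = c(`25` = 0.02, `26` = 0.05, `27` = 0.10,
                                        `28` = 0.25, `29` = 0.30, `30` = 0.15,
                                        `31` = 0.08, `32` = 0.05),
                       seed = 1L) {
  stopifnot(n_genes >= 1, length(cds_range) == 2, cds_range[1] >= 60,
            utr5_range[1] >= 16, tail_range[1] >= 16,
            ext_range[1] >= 6, lambda > 0)
  if (abs(sum(stop_mix) - 1) > 1e-8) {
    stop("stop_mix fractions must sum to 1", call. = FALSE)
  }
  if (!all(names(stop_mix) %in% STOP_CODONS)) {
    stop("stop_mix must be named by UGA/UAG/UAA", call. = FALSE)
  }
  if (any(rho < 0) || any(rho >= 1)) stop("rho must lie in [0, 1)", call. = FALSE)
  stopifnot(identical(names(fp_len_probs), as.character(25:32)),
            abs(sum(fp_len_probs) - 1) < 1e-8)
  structure(list(n_genes = as.integer(n_genes), cds_range = cds_range,
                 utr5_range = utr5_range, ext_range = ext_range,
                 tail_range = tail_range, stop_mix = stop_mix,
                 frac_with_next_stop = frac_with_next_stop, lambda = lambda,
                 rho = rho, fp_len_probs = fp_len_probs,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_len <- function(n, range) {
  sample.int(range[2] - range[1] + 1L, n, replace = TRUE) + range[1] - 1L
}

rand_codons <- function(n) {
  paste(sample(SENSE_CODONS, n, replace = TRUE), collapse = "")
}

rand_nt <- function(n) {
  if (n == 0L) return("")
  paste(sample(RNA_BASES, n, replace = TRUE), collapse = "")
}

#' Simulate a toy transcriptome with controlled stop-codon geometry
#'
#' Generates random transcript sequences with: a CDS of sense codons (no
#' premature in-frame stop) ending in a stop of the configured identity; a
#' 3'UTR that, for a configurable fraction of transcripts, carries a next
#' in-frame stop after an extension region of sense codons (the rest have
#' no in-frame stop at all and are excluded by
#' [find_next_inframe_stop()]).
#'
#' @param config A [sim_config()].
#' @return Transcript-model tibble with a `sequence` column and a `truth`
#'   attribute recording `has_extension`, `ext_start`, `ext_end` per
#'   transcript.
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  cds_len <- 3L * (rand_len(n, config$cds_range) %/% 3L)
  utr5_len <- rand_len(n, config$utr5_range)
  tail_len <- rand_len(n, config$tail_range)
  ext_len <- 3L * (rand_len(n, config$ext_range) %/% 3L)
  ext_len <- pmax(ext_len, 6L)
  stops <- sample(names(config$stop_mix), n, replace = TRUE,
                  prob = config$stop_mix)
  has_ext <- seq_len(n) <= round(config$frac_with_next_stop * n)

  rows <- lapply(seq_len(n), function(i) {
    cds <- paste0(rand_codons(cds_len[i] %/% 3L - 1L), stops[i])
    utr3 <- if (has_ext[i]) {
      next_stop <- sample(names(config$stop_mix), 1L, prob = config$stop_mix)
      # sense codons up to the next in-frame stop, then an unconstrained tail
      paste0(rand_codons(ext_len[i] %/% 3L), next_stop, rand_nt(tail_len[i]))
    } else {
      # in-frame sense codons for the whole UTR: no in-frame stop exists
      paste0(rand_codons(tail_len[i] %/% 3L), rand_nt(tail_len[i] %% 3L))
    }
    seq <- paste0(rand_nt(utr5_len[i]), cds, utr3)
    tibble::tibble(
      transcript_id = sprintf("tx%04d", i), gene_id = sprintf("g%04d", i),
      length = nchar(seq), cds_start = utr5_len[i],
      cds_end = utr5_len[i] + cds_len[i], stop_codon = stops[i],
      sequence = seq)
  })
  tx <- dplyr::bind_rows(rows)
  truth <- tibble::tibble(
    transcript_id = tx$transcript_id, has_extension = has_ext,
    ext_start = ifelse(has_ext, tx$cds_end, NA_integer_),
    ext_end = ifelse(has_ext, tx$cds_end + ext_len, NA_integer_),
    ext_length = ifelse(has_ext, ext_len, NA_integer_))
  structure(validate_transcripts(tx), truth = truth)
}

rho_for <- function(rho, stop_codon) {
  if (is.null(names(rho))) rep(rho, length(stop_codon))
  else unname(rho[stop_codon])
}

#' Simulate a ribosome footprint library with known readthrough
#'
#' CDS footprint counts are Poisson with mean `lambda x CDS length` and
#' assigned positions uniform over the CDS; extension-region counts are
#' Poisson with mean `rho x lambda x extension length`, uniform over the
#' extension. Read lengths are drawn from the configured 25-32 nt mixture
#' and the 5' start is placed so the midpoint convention of
#' [assign_midpoints()] recovers the drawn position. The expected RRTS of
#' every scoreable transcript is therefore exactly `rho`.
#'
#' @param transcriptome Result of [simulate_transcriptome()].
#' @param config The same [sim_config()] (or one with a different `rho`).
#' @param condition Label stored in the ground-truth attribute.
#' @param seed Optional seed override (defaults to `config$seed + 1`).
#' @return Footprint tibble (`transcript_id`, `start`, `length`) with a
#'   `truth` attribute (per-transcript expected densities and `rho`).
#' @export
simulate_footprints <- function(transcriptome, config, condition = "control",
                                seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  truth <- attr(transcriptome, "truth")
  tx <- dplyr::left_join(transcriptome, truth, by = "transcript_id")
  lens <- as.integer(names(config$fp_len_probs))

  make_reads <- function(id, n, lo, hi) {
    if (n == 0L) return(NULL)
    mid <- lo + sample.int(hi - lo, n, replace = TRUE) - 1L
    len <- sample(lens, n, replace = TRUE, prob = config$fp_len_probs)
    tibble::tibble(transcript_id = id, start = mid - (len - 1L) %/% 2L,
                   length = len)
  }

  rho_tx <- rho_for(config$rho, tx$stop_codon)
  n_cds <- stats::rpois(nrow(tx), config$lambda * (tx$cds_end - tx$cds_start))
  n_ext <- ifelse(tx$has_extension,
                  stats::rpois(nrow(tx), rho_tx * config$lambda *
                                 tidyr::replace_na(tx$ext_length, 0L)),
                  0L)
  reads <- dplyr::bind_rows(
    purrr::pmap_dfr(list(tx$transcript_id, n_cds, tx$cds_start, tx$cds_end),
                    make_reads),
    purrr::pmap_dfr(list(tx$transcript_id, n_ext,
                         tidyr::replace_na(tx$ext_start, 0L),
                         tidyr::replace_na(tx$ext_end, 1L)),
                    make_reads))
  gt <- tibble::tibble(transcript_id = tx$transcript_id, condition = condition,
                       rho = rho_tx, lambda = config$lambda,
                       cds_reads_drawn = n_cds, ext_reads_drawn = n_ext)
  structure(reads, truth = gt, condition = condition)
}

#' Simulate reporter, RT-qPCR and microarray assay tables
#'
#' Produces the three small assay inputs with known ground truth: a
#' luciferase plate whose PTC-construct signal is `true_readthrough` times
#' the reference mean, a Ct table consistent with `fold_change`, and a
#' timecourse array with constant spike-ins and a chosen decay profile.
#' With `noise_sd = 0` the corresponding normalizations recover the truth
#' exactly.
#'
#' @param true_readthrough PTC signal as a fraction of the reference mean.
#' @param fold_change Target/control expression fold change for the Ct
#'   table.
#' @param decay_profile Named numeric: percent of the reference timepoint
#'   remaining at each timepoint (reference = first element, 100).
#' @param n_replicates Wells / samples per group.
#' @param noise_sd sdlog of multiplicative lognormal noise.
#' @param seed Integer seed.
#' @return List with tibbles `plate`, `ct`, `array` and a `truth` list.
#' @export
simulate_assays <- function(true_readthrough = 0.05, fold_change = 4,
                            decay_profile = c(`6` = 100, `24` = 80,
                                              `48` = 60, `72` = 50),
                            n_replicates = 4L, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  noise <- function(n) stats::rlnorm(n, meanlog = 0, sdlog = noise_sd)
  ref_mean <- 1e5
  plate <- dplyr::bind_rows(
    tibble::tibble(well = sprintf("A%d", seq_len(n_replicates)),
                   construct = "wild-type", treatment = "mock",
                   fluc_signal = ref_mean * noise(n_replicates),
                   rluc_signal = 1e4),
    tibble::tibble(well = sprintf("B%d", seq_len(n_replicates)),
                   construct = "PTC", treatment = "sup-tRNA",
                   fluc_signal = ref_mean * true_readthrough * noise(n_replicates),
                   rluc_signal = 1e4))
  base_target <- 27; base_ref <- 20
  ct <- dplyr::bind_rows(
    tibble::tibble(sample_id = sprintf("c%d", seq_len(n_replicates)),
                   condition = "control", target_ct = base_target,
                   reference_ct = base_ref),
    tibble::tibble(sample_id = sprintf("t%d", seq_len(n_replicates)),
                   condition = "treated",
                   target_ct = base_target - log2(fold_change),
                   reference_ct = base_ref)) |>
    dplyr::mutate(target_ct = .data$target_ct + log2(noise(dplyr::n())))
  spike_a <- 2000; spike_b <- 2000; sup_base <- 5000
  array <- purrr::map_dfr(names(decay_profile), function(tp) {
    dplyr::bind_rows(
      tibble::tibble(timepoint = tp, probe_id = sprintf("spike%d", 1:3),
                     probe_class = "spike-in", signal_a = spike_a,
                     signal_b = spike_b),
      tibble::tibble(timepoint = tp, probe_id = sprintf("sup%d", 1:3),
                     probe_class = "sup-tRNA",
                     signal_a = sup_base * decay_profile[[tp]] / 100 * noise(3),
                     signal_b = spike_b),
      tibble::tibble(timepoint = tp, probe_id = sprintf("nat%d", 1:4),
                     probe_class = "natural-tRNA",
                     signal_a = 3000 * noise(4), signal_b = 3000))
  })
  list(plate = plate, ct = ct, array = array,
       truth = list(true_readthrough = true_readthrough,
                    fold_change = fold_change, decay_profile = decay_profile))
}

#' Write a simulated dataset to plain-text files
#'
#' Emits transcript FASTA + model TSV, footprint TSV and a ground-truth
#' sidecar TSV so downstream analyses never re-derive truth from the
#' generator internals.
#'
#' @param transcriptome,reads Outputs of [simulate_transcriptome()] and
#'   [simulate_footprints()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_simulation <- function(transcriptome, reads, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(fasta = file.path(dir, "transcripts.fasta"),
             models = file.path(dir, "transcripts.tsv"),
             reads = file.path(dir, "footprints.tsv"),
             truth = file.path(dir, "ground_truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(transcriptome$sequence,
                                           transcriptome$transcript_id)),
    paths[["fasta"]])
  readr::write_tsv(dplyr::select(transcriptome, -"sequence"), paths[["models"]])
  readr::write_tsv(reads, paths[["reads"]])
  truth <- dplyr::left_join(attr(transcriptome, "truth"), attr(reads, "truth"),
                            by = "transcript_id")
  readr::write_tsv(truth, paths[["truth"]])
  invisible(paths)
}
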