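#' @importFrom rlang .data
NULL

TRNA_SEGMENTS <- c("acceptor5", "D-arm", "anticodon-stem5", "anticodon-loop",
                   "anticodon-stem3", "V-region", "T-stem5", "T-loop",
                   "T-stem3", "acceptor3", "discriminator")

#' Parse a tRNA gene into an annotated cloverleaf record
#'
#' Builds a `trna_gene` object from a sequence and a cloverleaf segment
#' table. The segment table addresses the sequence in 0-based half-open
#' coordinates and supplies a canonical position label for every
#' nucleotide, so downstream edits can be addressed by the standard tRNA
#' numbering (anticodon 34-36, T-stem pairs 49-65/50-64/51-63,
#' discriminator 73, and so on). A trailing CCA, if present, is stripped
#' and remembered in `cca_appended`; DNA input is converted to RNA.
#'
#' @param id Identifier for the gene.
#' @param sequence Character scalar, RNA or DNA alphabet. May include the
#'   3' CCA tail, which is stripped.
#' @param segments Data frame with columns `segment`, `start`, `end`
#'   (0-based half-open) and `canonical_labels` (comma-separated labels,
#'   one per nucleotide of the segment). All eleven cloverleaf segments
#'   must be present, non-overlapping and jointly covering the sequence.
#' @param family Amino-acid family of the gene (e.g. `"Ser"`, `"Arg"`,
#'   `"Gly"`); used to select identity-element rules.
#' @return A `trna_gene` object: list with elements `id`, `family`,
#'   `sequence` (RNA, CCA-less), `cca_appended`, `segments` (tibble) and
#'   `numbering` (named integer vector, canonical label to 0-based index).
#' @seealso [read_trna_genes()], [get_pair()], [trna_sequence()]
#' @export
parse_trna <- function(id, sequence, segments, family = NA_character_) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  seq_rna <- as_rna(sequence)
  check_rna_alphabet(seq_rna, sprintf("tRNA '%s'", id))

  segments <- tibble::as_tibble(segments)
  req <- c("segment", "start", "end", "canonical_labels")
  if (!all(req %in% names(segments))) {
    stop("segment table needs columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(TRNA_SEGMENTS, segments$segment)
  if (length(missing) > 0) {
    stop(sprintf("tRNA '%s': missing segment(s): %s", id,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(segments$segment, TRNA_SEGMENTS)
  if (length(extra) > 0) {
    stop(sprintf("tRNA '%s': unknown segment(s): %s", id,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  segments <- segments[match(TRNA_SEGMENTS, segments$segment), , drop = FALSE]

  # contiguity: in order, non-overlapping, covering [0, n)
  if (segments$start[1] != 0L) {
    stop(sprintf("tRNA '%s': segments must start at 0", id), call. = FALSE)
  }
  if (any(segments$end[-nrow(segments)] != segments$start[-1])) {
    stop(sprintf("tRNA '%s': segments must be contiguous and in 5'->3' order", id),
         call. = FALSE)
  }
  if (any(segments$end <= segments$start)) {
    stop(sprintf("tRNA '%s': empty segment interval", id), call. = FALSE)
  }
  n_ann <- segments$end[nrow(segments)]

  cca_appended <- FALSE
  if (nchar(seq_rna) == n_ann + 3L && endsWith(seq_rna, "CCA")) {
    seq_rna <- substr(seq_rna, 1L, n_ann)
    cca_appended <- TRUE
  }
  if (nchar(seq_rna) != n_ann) {
    stop(sprintf("tRNA '%s': annotation covers %d nt but sequence has %d nt",
                 id, n_ann, nchar(seq_rna)), call. = FALSE)
  }

  seg_len <- segments$end - segments$start
  check_len <- function(name, expect) {
    l <- seg_len[segments$segment == name]
    if (l != expect) {
      stop(sprintf("tRNA '%s': %s must have length %d (got %d)", id, name, expect, l),
           call. = FALSE)
    }
  }
  check_len("anticodon-loop", 7L)
  check_len("discriminator", 1L)
  s5 <- seg_len[segments$segment == "anticodon-stem5"]
  s3 <- seg_len[segments$segment == "anticodon-stem3"]
  if (s5 != s3) {
    stop(sprintf("tRNA '%s': anticodon stem halves differ in length (%d vs %d)",
                 id, s5, s3), call. = FALSE)
  }
  check_len("T-stem5", 5L)
  check_len("T-stem3", 5L)

  numbering <- build_numbering(id, segments)

  structure(
    list(id = id, family = family, sequence = seq_rna,
         cca_appended = cca_appended, segments = segments,
         numbering = numbering),
    class = "trna_gene")
}

build_numbering <- function(id, segments) {
  labs <- strsplit(segments$canonical_labels, ",", fixed = TRUE)
  labs <- lapply(labs, trimws)
  seg_len <- segments$end - segments$start
  bad <- which(lengths(labs) != seg_len)
  if (length(bad) > 0) {
    stop(sprintf("tRNA '%s': segment '%s' has %d nt but %d canonical labels",
                 id, segments$segment[bad[1]], seg_len[bad[1]],
                 lengths(labs)[bad[1]]), call. = FALSE)
  }
  labels <- unlist(labs)
  if (anyDuplicated(labels)) {
    stop(sprintf("tRNA '%s': duplicated canonical labels (%s)", id,
                 paste(unique(labels[duplicated(labels)]), collapse = ", ")),
         call. = FALSE)
  }
  idx <- unlist(mapply(function(s, e) seq.int(s, e - 1L), segments$start,
                       segments$end, SIMPLIFY = FALSE))
  stats::setNames(as.integer(idx), labels)
}

#' @export
print.trna_gene <- function(x, ...) {
  cat(sprintf("<trna_gene> %s (%s), %d nt%s\n", x$id,
              ifelse(is.na(x$family), "family unknown", x$family),
              nchar(x$sequence),
              if (x$cca_appended) " [CCA stripped]" else ""))
  cat(" ", x$sequence, "\n", sep = "")
  ac <- tryCatch(anticodon(x), error = function(e) NA_character_)
  if (!is.na(ac)) cat("  anticodon (34-36):", ac, "\n")
  invisible(x)
}

#' Nucleotide at a canonical position
#'
#' @param trna A `trna_gene` (or `suppressor_variant`).
#' @param label Canonical position label (character or integer-like).
#' @return Single RNA base.
#' @export
position_nt <- function(trna, label) {
  idx <- label_index(trna, label)
  substr(trna$sequence, idx + 1L, idx + 1L)
}

label_index <- function(trna, label) {
  label <- as.character(label)
  if (!label %in% names(trna$numbering)) {
    stop(sprintf("tRNA '%s': unknown canonical label '%s'", trna$id, label),
         call. = FALSE)
  }
  unname(trna$numbering[[label]])
}

#' Base pair at two canonical positions
#'
#' Looks up the nucleotides at two canonical labels, e.g. the T-stem pairs
#' (49, 65), (50, 64) and (51, 63) that tune elongation-factor binding.
#'
#' @inheritParams position_nt
#' @param pos5,pos3 Canonical labels; `pos5` must lie 5' of `pos3`.
#' @return One-row tibble with columns `pos5`, `pos3`, `nt5`, `nt3`.
#' @export
#' @examples
#' trna <- read_trna_genes(
#'   system.file("extdata", "scaffolds_synthetic.fasta", package = "suptrna"),
#'   system.file("extdata", "scaffolds_synthetic_segments.tsv", package = "suptrna"))
#' get_pair(trna[["tS_scaffold"]], 49, 65)
get_pair <- function(trna, pos5, pos3) {
  i5 <- label_index(trna, pos5)
  i3 <- label_index(trna, pos3)
  if (i5 >= i3) {
    stop(sprintf("pos5 ('%s') must lie 5' of pos3 ('%s')", pos5, pos3),
         call. = FALSE)
  }
  tibble::tibble(pos5 = as.character(pos5), pos3 = as.character(pos3),
                 nt5 = substr(trna$sequence, i5 + 1L, i5 + 1L),
                 nt3 = substr(trna$sequence, i3 + 1L, i3 + 1L))
}

#' Anticodon of a tRNA (positions 34-36, written 5'->3')
#' @inheritParams position_nt
#' @return 3-nt RNA string.
#' @export
anticodon <- function(trna) {
  paste0(position_nt(trna, "34"), position_nt(trna, "35"), position_nt(trna, "36"))
}

segment_interval <- function(trna, segment) {
  row <- trna$segments[trna$segments$segment == segment, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("tRNA '%s': unknown segment '%s'", trna$id, segment), call. = FALSE)
  }
  c(start = row$start, end = row$end)
}

#' Sequence of one cloverleaf segment
#' @inheritParams position_nt
#' @param segment Segment name (e.g. `"V-region"`, `"T-stem5"`).
#' @return RNA string of the segment.
#' @export
segment_sequence <- function(trna, segment) {
  iv <- segment_interval(trna, segment)
  substr_vec(trna$sequence, iv[["start"]], iv[["end"]])
}

#' Full sequence of a tRNA gene
#' @inheritParams position_nt
#' @param cca Append the universal 3' CCA tail?
#' @param alphabet `"rna"` or `"dna"`.
#' @return Character scalar.
#' @export
trna_sequence <- function(trna, cca = FALSE, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  s <- trna$sequence
  if (cca) s <- paste0(s, "CCA")
  if (alphabet == "dna") as_dna(s) else s
}

#' Read annotated tRNA genes from FASTA plus a segment table
#'
#' @param fasta Path to a FASTA file of tRNA gene sequences (RNA or DNA;
#'   trailing CCA allowed). Record ids up to the first whitespace are used.
#' @param segments_tsv Path to a TSV with columns `trna_id`, `segment`,
#'   `start`, `end`, `canonical_labels`, and optionally `family`.
#' @return Named list of [parse_trna()] objects.
#' @export
read_trna_genes <- function(fasta, segments_tsv) {
  seqs <- Biostrings::readBStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ann <- readr::read_tsv(segments_tsv, show_col_types = FALSE,
                         col_types = readr::cols(
                           start = readr::col_integer(),
                           end = readr::col_integer(),
                           .default = readr::col_character()))
  out <- lapply(names(seqs), function(nm) {
    seg <- ann[ann$trna_id == nm, , drop = FALSE]
    if (nrow(seg) == 0) {
      stop(sprintf("no segment annotation for tRNA '%s'", nm), call. = FALSE)
    }
    fam <- if ("family" %in% names(seg)) seg$family[1] else NA_character_
    parse_trna(nm, as.character(seqs[[nm]]), seg, family = fam)
  })
  stats::setNames(out, names(seqs))
}

#' Write tRNA genes back to a FASTA + segment-table pair
#'
#' Inverse of [read_trna_genes()]; a round trip reproduces the input
#' records exactly (CCA-less).
#'
#' @param trnas List of `trna_gene` objects.
#' @param fasta,segments_tsv Output paths.
#' @param cca Write sequences with the CCA tail appended.
#' @return Invisibly, the paths.
#' @export
write_trna_genes <- function(trnas, fasta, segments_tsv, cca = FALSE) {
  if (inherits(trnas, "trna_gene")) trnas <- list(trnas)
  seqs <- vapply(trnas, trna_sequence, character(1), cca = cca)
  ids <- vapply(trnas, function(x) x$id, character(1))
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, fasta)
  ann <- purrr::map_dfr(trnas, function(x) {
    dplyr::mutate(x$segments, trna_id = x$id, family = x$family,
                  .before = 1L)
  })
  readr::write_tsv(ann, segments_tsv)
  invisible(c(fasta = fasta, segments_tsv = segments_tsv))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tRNA gene into a per-nucleotide tibble
#'
#' @param x A `trna_gene`.
#' @param ... Unused.
#' @return Tibble with one row per nucleotide: `index` (0-based), `nt`,
#'   `segment`, `canonical_label`.
#' @method tidy trna_gene
#' @export
tidy.trna_gene <- function(x, ...) {
  nt <- strsplit(x$sequence, "")[[1]]
  seg <- rep(x$segments$segment, x$segments$end - x$segments$start)
  lab <- names(sort(x$numbering))
  tibble::tibble(index = seq_along(nt) - 1L, nt = nt, segment = seg,
                 canonical_label = lab)
}
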