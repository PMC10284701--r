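T7_PROMOTER <- "TAATACGACTCACTATA"
TSTEM_PAIRS <- list(c("49", "65"), c("50", "64"), c("51", "63"))

#' Suppressor anticodon for a stop codon
#'
#' The anticodon (written 5'->3') that Watson-Crick pairs a premature
#' termination codon is its reverse complement.
#'
#' @param stop_codon One of `"UGA"`, `"UAG"`, `"UAA"` (DNA accepted).
#' @return 3-nt RNA anticodon.
#' @export
#' @examples
#' suppressor_anticodon("UGA")  # "UCA"
suppressor_anticodon <- function(stop_codon) {
  stop_codon <- check_stop_codon(stop_codon)
  revcomp(stop_codon)
}

#' Swap a tRNA's anticodon to target a stop codon
#'
#' Replaces positions 34-36 with the suppressor anticodon for
#' `stop_codon`, leaving every other position untouched. A mismatch
#' control (a suppressor carrying the anticodon for a *different* stop
#' than the one it is tested against) is built by supplying `mismatch_to`.
#'
#' @param trna A `trna_gene` scaffold.
#' @param stop_codon Target stop codon.
#' @param mismatch_to Optional stop codon whose anticodon is installed
#'   instead of the target's; the variant is flagged `is_mismatch`.
#' @return A `suppressor_variant`: a `trna_gene` carrying the edited
#'   sequence plus `parent_id`, `parent`, `stop_codon`, `is_mismatch` and
#'   an `applied_templates` log.
#' @export
apply_anticodon_swap <- function(trna, stop_codon, mismatch_to = NULL) {
  stopifnot(inherits(trna, "trna_gene"))
  stop_codon <- check_stop_codon(stop_codon)
  ac <- if (is.null(mismatch_to)) {
    suppressor_anticodon(stop_codon)
  } else {
    suppressor_anticodon(mismatch_to)
  }
  v <- trna
  for (k in 1:3) {
    idx <- label_index(trna, as.character(33L + k))
    substr(v$sequence, idx + 1L, idx + 1L) <- substr(ac, k, k)
  }
  v$parent_id <- trna$id
  v$parent <- trna
  v$stop_codon <- stop_codon
  v$is_mismatch <- !is.null(mismatch_to)
  v$applied_templates <- character(0)
  v$id <- variant_id(trna, character(0), mismatch = v$is_mismatch)
  class(v) <- c("suppressor_variant", "trna_gene")
  v
}

variant_id <- function(parent, template_ids, mismatch = FALSE) {
  fam <- parent$family
  base <- if (!is.na(fam) && nzchar(fam)) {
    paste0("t", substr(fam, 1, 1))
  } else {
    paste0(parent$id, "_sup")
  }
  id <- paste0(base, paste0(template_ids, collapse = ""))
  if (mismatch) id <- paste0(id, ".mis")
  id
}

#' Read variant edit templates from a YAML config
#'
#' Templates are named edit recipes (e.g. `A1`, `A2`, `T5`): a list of
#' `set-pair` edits (set the bases at a canonical base pair) and
#' `graft-segment` edits (replace a whole cloverleaf segment, e.g. an
#' anticodon-stem half taken from another tRNA).
#'
#' @param path YAML file with a top-level `templates:` list.
#' @return Named list of `variant_template` objects.
#' @export
read_variant_templates <- function(path) {
  cfg <- yaml::read_yaml(path)
  tpls <- lapply(cfg$templates, function(t) {
    structure(list(id = t$id, edits = t$edits), class = "variant_template")
  })
  stats::setNames(tpls, vapply(tpls, function(t) t$id, character(1)))
}

#' Apply an edit template to a suppressor variant
#'
#' Edits are applied in order; repeated `set-pair` edits at the same pair
#' overwrite (last write wins). Grafting a stem half to a length different
#' from its partner's is an error: stems must stay paired in length.
#'
#' @param variant A `suppressor_variant`.
#' @param template A `variant_template` from [read_variant_templates()].
#' @return The edited variant, with `template$id` appended to its
#'   `applied_templates`.
#' @export
apply_template <- function(variant, template) {
  stopifnot(inherits(variant, "suppressor_variant"),
            inherits(template, "variant_template"))
  v <- variant
  for (e in template$edits) {
    kind <- e$kind
    if (identical(kind, "set-pair")) {
      i5 <- label_index(v, e$pos5)
      i3 <- label_index(v, e$pos3)
      if (i5 >= i3) stop("set-pair: pos5 must lie 5' of pos3", call. = FALSE)
      nt5 <- as_rna(e$nt5); nt3 <- as_rna(e$nt3)
      check_rna_alphabet(nt5, "set-pair nt5"); check_rna_alphabet(nt3, "set-pair nt3")
      substr(v$sequence, i5 + 1L, i5 + 1L) <- nt5
      substr(v$sequence, i3 + 1L, i3 + 1L) <- nt3
    } else if (identical(kind, "graft-segment")) {
      v <- graft_segment(v, e$segment, as_rna(e$replacement))
    } else {
      stop(sprintf("unknown edit kind '%s' in template '%s'", kind, template$id),
           call. = FALSE)
    }
  }
  # stems must stay paired in length
  for (halves in list(c("anticodon-stem5", "anticodon-stem3"),
                      c("T-stem5", "T-stem3"))) {
    l5 <- diff(segment_interval(v, halves[1]))
    l3 <- diff(segment_interval(v, halves[2]))
    if (l5 != l3) {
      stop(sprintf("template '%s' leaves %s (%d nt) and %s (%d nt) unpaired in length",
                   template$id, halves[1], l5, halves[2], l3), call. = FALSE)
    }
  }
  v$applied_templates <- c(v$applied_templates, template$id)
  v$id <- variant_id(v$parent, v$applied_templates, mismatch = isTRUE(v$is_mismatch))
  v
}

graft_segment <- function(v, segment, replacement) {
  check_rna_alphabet(replacement, sprintf("graft into '%s'", segment))
  iv <- segment_interval(v, segment)
  old_len <- iv[["end"]] - iv[["start"]]
  new_len <- nchar(replacement)
  v$sequence <- paste0(substr_vec(v$sequence, 0L, iv[["start"]]), replacement,
                       substr_vec(v$sequence, iv[["end"]], nchar(v$sequence)))
  if (new_len != old_len) {
    shift <- new_len - old_len
    seg <- v$segments
    i <- which(seg$segment == segment)
    seg$end[i] <- seg$end[i] + shift
    if (i < nrow(seg)) {
      seg$start[(i + 1):nrow(seg)] <- seg$start[(i + 1):nrow(seg)] + shift
      seg$end[(i + 1):nrow(seg)] <- seg$end[(i + 1):nrow(seg)] + shift
    }
    # relabel the grafted segment with generated opaque labels
    seg$canonical_labels[i] <- paste(sprintf("%s.%d", segment, seq_len(new_len)),
                                     collapse = ",")
    v$segments <- seg
    v$numbering <- build_numbering(v$id, seg)
  }
  v
}

#' Read a T-stem base-pair free-energy table
#'
#' The table gives per-pair free-energy differences (kcal/mol) for
#' elongation-factor binding, one entry per (position class, base pair),
#' relative to the scaffold's wild-type pair at that position class (which
#' therefore scores 0). Columns: `position_class` (`49-65`, `50-64`,
#' `51-63`), `nt5`, `nt3`, `ddg`. `#` lines are treated as comments and
#' kept as a provenance note.
#'
#' @param path TSV path.
#' @return Tibble of class `energy_table` with attribute `provenance`.
#' @export
read_energy_table <- function(path) {
  prov <- grep("^#", readLines(path), value = TRUE)
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = "cccd")
  stopifnot(all(c("position_class", "nt5", "nt3", "ddg") %in% names(tab)))
  structure(tab, provenance = paste(sub("^#\\s*", "", prov), collapse = "\n"),
            class = c("energy_table", class(tab)))
}

#' Additive eEF1A-binding score of a variant's T-stem
#'
#' Sums the tabulated free-energy contributions of the three T-stem base
#' pairs 49-65, 50-64 and 51-63. Lower values mean a more stable
#' interaction with the elongation factor; a wild-type T-stem scores 0 by
#' the table's reference convention. Lookups for pairs missing from the
#' table fail loudly.
#'
#' @param variant A `suppressor_variant` (or any `trna_gene`).
#' @param energy_table An [read_energy_table()] table.
#' @return Numeric scalar, kcal/mol.
#' @export
ddg_eef1a <- function(variant, energy_table) {
  total <- 0
  for (p in TSTEM_PAIRS) {
    bp <- get_pair(variant, p[1], p[2])
    cls <- paste0(p[1], "-", p[2])
    hit <- energy_table$position_class == cls &
      energy_table$nt5 == bp$nt5 & energy_table$nt3 == bp$nt3
    if (sum(hit) != 1L) {
      stop(sprintf("no energy-table entry for pair %s.%s at positions %s",
                   bp$nt5, bp$nt3, cls), call. = FALSE)
    }
    total <- total + energy_table$ddg[hit]
  }
  total
}

#' Read identity-element rules from a YAML config
#'
#' Identity elements are the positions and segments recognized by the
#' cognate aminoacyl-tRNA synthetase; engineered variants must preserve
#' them to stay chargeable. Supported constraint kinds: `position-nt`
#' (fixed base at a label), `position-nt-choice` (one of several bases),
#' `pair` (fixed bases at a base pair) and `segment-preserved` (segment
#' unchanged from the parent scaffold).
#'
#' @param path YAML file with a top-level `families:` list.
#' @return Named list (by family) of constraint lists.
#' @export
read_identity_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  rules <- lapply(cfg$families, function(f) f$constraints)
  stats::setNames(rules, vapply(cfg$families, function(f) f$family, character(1)))
}

#' Check a variant against its family's identity elements
#'
#' @param variant A `suppressor_variant`.
#' @param rules Constraint list for one family (an element of
#'   [read_identity_rules()]), or the full named list, in which case the
#'   variant's `family` selects the element.
#' @return Character vector of violation descriptions; empty if all
#'   constraints hold.
#' @export
check_identity_elements <- function(variant, rules) {
  is_constraints <- length(rules) == 0L ||
    all(vapply(rules, function(r) is.list(r) && !is.null(r$kind), logical(1)))
  if (!is_constraints) {
    if (!isTRUE(variant$family %in% names(rules))) {
      stop(sprintf("no identity rules for family '%s'", variant$family),
           call. = FALSE)
    }
    rules <- rules[[variant$family]]
  }
  out <- character(0)
  for (r in rules) {
    if (identical(r$kind, "position-nt")) {
      obs <- position_nt(variant, r$pos)
      if (obs != as_rna(r$nt)) {
        out <- c(out, sprintf("position %s: expected %s, observed %s",
                              r$pos, as_rna(r$nt), obs))
      }
    } else if (identical(r$kind, "position-nt-choice")) {
      obs <- position_nt(variant, r$pos)
      allowed <- as_rna(unlist(r$nts))
      if (!obs %in% allowed) {
        out <- c(out, sprintf("position %s: expected one of %s, observed %s",
                              r$pos, paste(allowed, collapse = "/"), obs))
      }
    } else if (identical(r$kind, "pair")) {
      bp <- get_pair(variant, r$pos5, r$pos3)
      if (bp$nt5 != as_rna(r$nt5) || bp$nt3 != as_rna(r$nt3)) {
        out <- c(out, sprintf("pair %s-%s: expected %s-%s, observed %s-%s",
                              r$pos5, r$pos3, as_rna(r$nt5), as_rna(r$nt3),
                              bp$nt5, bp$nt3))
      }
    } else if (identical(r$kind, "segment-preserved")) {
      parent <- variant$parent %||% variant
      obs <- segment_sequence(variant, r$segment)
      ref <- segment_sequence(parent, r$segment)
      if (obs != ref) {
        out <- c(out, sprintf("segment %s altered (parent %s, variant %s)",
                              r$segment, ref, obs))
      }
    } else {
      stop(sprintf("unknown identity constraint kind '%s'", r$kind), call. = FALSE)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate and rank suppressor variants for a scaffold
#'
#' Emits the anticodon-swapped base variant, every single-template
#' variant, and every anticodon-stem x T-stem template combination
#' (templates whose ids start with `A` combine pairwise with those
#' starting with `T`). Each variant carries its additive eEF1A-binding
#' score and its identity-element violations; nothing is silently
#' filtered, but `strict` drops violators.
#'
#' @inheritParams apply_anticodon_swap
#' @param templates Named list of templates (possibly empty).
#' @param energy_table An [read_energy_table()] table.
#' @param rules Identity rules (see [check_identity_elements()]); optional.
#' @param strict Drop variants with identity violations.
#' @return Tibble of class `suppressor_variants`, sorted by `ddg_eef1a`
#'   then id, with columns `id`, `parent_id`, `stop_codon`, `anticodon`,
#'   `templates`, `sequence`, `ddg_eef1a`, `identity_violations`
#'   (list-column), `n_violations` and a `variant` list-column holding the
#'   full objects.
#' @export
enumerate_variants <- function(trna, stop_codon, templates = list(),
                               energy_table, rules = NULL, strict = FALSE) {
  base <- apply_anticodon_swap(trna, stop_codon)
  ids <- names(templates) %||% character(0)
  a_ids <- ids[startsWith(ids, "A")]
  t_ids <- ids[startsWith(ids, "T")]
  combos <- c(list(character(0)), as.list(ids),
              unlist(lapply(a_ids, function(a) lapply(t_ids, function(t) c(a, t))),
                     recursive = FALSE))
  variants <- lapply(combos, function(cb) {
    v <- base
    for (tid in cb) v <- apply_template(v, templates[[tid]])
    v
  })
  rows <- purrr::map_dfr(variants, function(v) {
    viol <- if (is.null(rules)) character(0) else check_identity_elements(v, rules)
    tibble::tibble(
      id = v$id, parent_id = v$parent_id, stop_codon = v$stop_codon,
      anticodon = anticodon(v),
      templates = paste(v$applied_templates, collapse = "+"),
      sequence = v$sequence,
      ddg_eef1a = ddg_eef1a(v, energy_table),
      identity_violations = list(viol),
      n_violations = length(viol))
  })
  rows$variant <- variants
  rows <- dplyr::arrange(rows, .data$ddg_eef1a, .data$id)
  if (strict) rows <- dplyr::filter(rows, .data$n_violations == 0L)
  structure(rows, class = c("suppressor_variants", class(rows)))
}

#' Emit a T7 in vitro transcription template for a variant
#'
#' The double-stranded DNA template is the T7 promoter followed by the DNA
#' of the variant (with the CCA tail by default, so transcripts carry a
#' homogeneous 3' end). The reverse primer is the reverse complement of
#' the template's 3' end; 2'-O-methylation of its first two nucleotides
#' (which suppresses untemplated nucleotide addition by the polymerase)
#' can be recorded as metadata.
#'
#' @param variant A `suppressor_variant` (or `trna_gene`).
#' @param cca Append CCA before building the template (default `TRUE`).
#' @param primer_length Length of the forward/reverse primers.
#' @param two_o_methyl Record 2'-O-methyl annotation of the first two
#'   reverse-primer nucleotides (metadata only; the sequence is unchanged).
#' @return List with `template` (DNA, sense strand), `forward_primer`,
#'   `reverse_primer` and `reverse_primer_modification`.
#' @export
make_t7_template <- function(variant, cca = TRUE, primer_length = 20L,
                             two_o_methyl = FALSE) {
  body <- trna_sequence(variant, cca = cca, alphabet = "dna")
  template <- paste0(T7_PROMOTER, body)
  n <- nchar(template)
  list(template = template,
       forward_primer = substr(template, 1L, primer_length),
       reverse_primer = revcomp(substr(template, n - primer_length + 1L, n),
                                alphabet = "dna"),
       reverse_primer_modification = if (two_o_methyl) {
         "2'-O-methyl at reverse-primer nucleotides 1-2"
       } else {
         NA_character_
       })
}

#' Tidy a set of enumerated variants
#'
#' @param x A `suppressor_variants` tibble from [enumerate_variants()].
#' @param ... Unused.
#' @return Plain tibble without the object list-column; violations
#'   collapsed to a `; `-separated string.
#' @method tidy suppressor_variants
#' @export
tidy.suppressor_variants <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out$identity_violations <- vapply(out$identity_violations, paste,
                                    character(1), collapse = "; ")
  out$variant <- NULL
  out
}

#' One-line summary of an enumerated variant set
#' @inheritParams tidy.suppressor_variants
#' @return One-row tibble: number of variants, ddg range, violator count.
#' @method glance suppressor_variants
#' @export
glance.suppressor_variants <- function(x, ...) {
  tibble::tibble(n_variants = nrow(x),
                 ddg_min = min(x$ddg_eef1a), ddg_max = max(x$ddg_eef1a),
                 n_with_violations = sum(x$n_violations > 0L))
}

#' Write enumerated variants as FASTA plus a TSV report
#'
#' @param variants A `suppressor_variants` tibble.
#' @param fasta,tsv Output paths.
#' @param cca Append CCA to the FASTA sequences.
#' @return Invisibly, the paths.
#' @export
write_variants <- function(variants, fasta, tsv, cca = FALSE) {
  seqs <- if (cca) paste0(variants$sequence, "CCA") else variants$sequence
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(seqs, variants$id)), fasta)
  readr::write_tsv(tidy.suppressor_variants(variants), tsv)
  invisible(c(fasta = fasta, tsv = tsv))
}
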