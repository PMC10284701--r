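# Internal sequence helpers. All sequences are handled as plain character
# scalars in the RNA alphabet (A/C/G/U); DNA is converted at the boundary.

RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UGA", "UAG", "UAA")

#' Reverse complement of an RNA or DNA sequence
#'
#' @param x Character scalar in the RNA (`ACGU`) or DNA (`ACGT`) alphabet.
#' @param alphabet Output alphabet, `"rna"` or `"dna"`.
#' @return Character scalar, the reverse complement in the requested alphabet.
#' @export
#' @examples
#' revcomp("UGA")
#' revcomp("TAATACGACTCACTATA", alphabet = "dna")
revcomp <- function(x, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  is_dna <- grepl("T", x, fixed = TRUE)
  s <- if (is_dna) Biostrings::DNAString(x) else Biostrings::RNAString(x)
  rc <- as.character(Biostrings::reverseComplement(s))
  if (alphabet == "rna") chartr("T", "U", rc) else chartr("U", "T", rc)
}

as_rna <- function(x) {
  x <- toupper(x)
  chartr("T", "U", x)
}

as_dna <- function(x) {
  chartr("U", "T", toupper(x))
}

check_rna_alphabet <- function(x, what = "sequence") {
  bad <- setdiff(unique(strsplit(x, "")[[1]]), RNA_BASES)
  if (length(bad) > 0) {
    stop(sprintf("%s contains non-nucleotide characters: %s",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

check_stop_codon <- function(stop_codon) {
  stop_codon <- as_rna(stop_codon)
  if (!stop_codon %in% STOP_CODONS) {
    stop(sprintf("'%s' is not a stop codon (expected one of %s)",
                 stop_codon, paste(STOP_CODONS, collapse = ", ")), call. = FALSE)
  }
  stop_codon
}

substr_vec <- function(x, start0, end0) {
  # 0-based half-open extraction
  substr(x, start0 + 1L, end0)
}

`substr_vec<-` <- function(x, start0, end0, value) {
  substr(x, start0 + 1L, end0) <- value
  x
}

codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character(0))
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}
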