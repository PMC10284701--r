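# Shared fixtures and independent oracles.

ex_file <- function(f) system.file("extdata", f, package = "suptrna")

load_scaffolds <- function() {
  read_trna_genes(ex_file("scaffolds_synthetic.fasta"),
                  ex_file("scaffolds_synthetic_segments.tsv"))
}

load_templates <- function() read_variant_templates(ex_file("templates.yaml"))
load_energy <- function() read_energy_table(ex_file("tstem_ddg_synthetic.tsv"))
load_rules <- function() read_identity_rules(ex_file("identity_rules.yaml"))

# the two tDNA probes printed for the microarray (tRNA + CCA, reverse strand)
PROBE_TSA1T5 <- "TGGCGTAGTCGACGGGATTCGAACCCGTGCGGGGAAACCCCAATGGTTTTGAAGACCATCGCCTTAACCACTCGGCCACGACTAC"
PROBE_TSA2T5 <- "TGGCGTAGTCGACGGGATTCGAACCCGTGCGGGGAAACCCCAACAGGTTTGAAGCCTGCCGCCTTAACCACTCGGCCACGACTAC"

design_variant <- function(template_ids, scaffolds = load_scaffolds(),
                           templates = load_templates()) {
  v <- apply_anticodon_swap(scaffolds$tS_scaffold, "UGA")
  for (id in template_ids) v <- apply_template(v, templates[[id]])
  v
}

# independent ddg oracle: enumerate the three position classes literally
ddg_oracle <- function(variant, table) {
  total <- 0
  for (cls in c("49-65", "50-64", "51-63")) {
    pp <- strsplit(cls, "-")[[1]]
    n5 <- position_nt(variant, pp[1])
    n3 <- position_nt(variant, pp[2])
    row <- table[table$position_class == cls & table$nt5 == n5 & table$nt3 == n3, ]
    stopifnot(nrow(row) == 1)
    total <- total + row$ddg
  }
  total
}

# literal per-position RRTS oracle: loops, no vectorized counting
rrts_oracle <- function(reads, tx_row, ext_row) {
  cds_positions <- seq(tx_row$cds_start, tx_row$cds_end - 1)
  ext_positions <- seq(ext_row$ext_start, ext_row$ext_end - 1)
  cds_n <- 0; ext_n <- 0
  for (i in seq_len(nrow(reads))) {
    if (reads$transcript_id[i] != tx_row$transcript_id) next
    mid <- reads$start[i] + floor((reads$length[i] - 1) / 2)
    if (mid %in% cds_positions) cds_n <- cds_n + 1
    if (mid %in% ext_positions) ext_n <- ext_n + 1
  }
  if (cds_n == 0) return(NULL)
  cds_rpk <- cds_n / (length(cds_positions) / 1000)
  ext_rpk <- ext_n / (length(ext_positions) / 1000)
  list(cds_reads = cds_n, ext_reads = ext_n, rrts = ext_rpk / cds_rpk)
}

toy_transcript <- function(id = "t1", utr5 = 50, cds = 300, ext = 90,
                           tail = 60, stop = "UGA") {
  # deterministic sequence: CDS of AAA codons ending in `stop`, extension of
  # AAA codons, next stop UAA, then Cs
  seq <- paste0(strrep("G", utr5),
                strrep("AAA", cds / 3 - 1), stop,
                strrep("AAA", ext / 3), "UAA",
                strrep("C", tail))
  tibble::tibble(transcript_id = id, gene_id = paste0("g_", id),
                 length = nchar(seq), cds_start = utr5, cds_end = utr5 + cds,
                 stop_codon = stop, sequence = seq)
}

point_reads <- function(id, midpoints, length = 28L) {
  # reads whose assigned midpoint equals the requested positions
  tibble::tibble(transcript_id = id,
                 start = as.integer(midpoints) - (length - 1L) %/% 2L,
                 length = length)
}
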