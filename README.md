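# suptrna

Design of suppressor tRNAs against premature termination codons (PTCs),
and ribosome-profiling analysis of their molecular safety.

Roughly one in ten inherited disease alleles is a nonsense mutation: a
sense codon mutated to a stop codon (UGA, UAG or UAA) that truncates the
protein. One therapeutic route is to re-engineer a natural tRNA so its
anticodon base-pairs the PTC and inserts an amino acid instead of
terminating. Getting this to work well requires more than the anticodon
swap — the anticodon stem (decoding accuracy) and the TΨC-stem (binding
to elongation factor eEF1A) must be re-tuned to the amino acid the tRNA
carries — and it must be shown that the suppressor does **not** cause
readthrough at the thousands of natural stop codons it also encounters.
`suptrna` implements both halves of that workflow:

* **Design.** tRNA genes are parsed into annotated cloverleaves with
  canonical position numbering, so edits are addressed the way the field
  writes them (anticodon 34–36, T-stem pairs 49–65 / 50–64 / 51–63,
  discriminator 73). The engine swaps anticodons (the suppressor
  anticodon is the reverse complement of the target stop), applies named
  edit templates (`A1`: U–A pair at 31/39; `A2`: anticodon stem grafted
  from tRNA-Sec; `T2`/`T5`/`T6`: T-stem pair substitutions), scores each
  variant's eEF1A interaction by the **additive free-energy model**

      ΔΔG = Σ  ΔΔG(pair at 49–65, 50–64, 51–63)     [kcal/mol]

  (per-pair contributions from an editable table, zero at the scaffold's
  wild-type pairs; lower = more stable eEF1A binding), validates
  aminoacyl-tRNA-synthetase identity elements per family (Ser: G73 +
  V-arm; Arg: G73, A20, C35–U/G36; Gly: A73, C2–G71), and emits T7
  in vitro transcription templates with primer pairs.

* **Safety analysis.** From transcriptome-aligned ribosome footprints
  (25–32 nt, assigned at their middle nucleotide or at calibrated A-site
  offsets), the package builds stop-codon metagene profiles (±100 nt) and
  computes the **ribosome readthrough score** per transcript:

      RRTS = (extension reads / extension kb) / (CDS reads / CDS kb)

  where the extension region runs from the natural stop codon to the next
  in-frame stop in the 3′UTR (excluded if separated by < 4 nt). Standard
  RPM/RPKM quantification, an expression filter (> 0.1 RPKM), canonical
  transcript selection (longest CDS, then longest transcript) and a
  stratified treated-vs-control comparison by stop identity complete the
  screen.

* **Support modules.** Exactly specified reporter (% of wild-type
  luciferase), ΔΔCt (fold = 2^−ΔΔCt) and microarray spike-in
  normalizations; and a synthetic-data generator (Poisson coverage,
  uniform positions, known readthrough rate ρ — the expected RRTS is
  exactly ρ) so the whole pipeline runs and is testable offline.

## Worked example

```r
library(suptrna)
ex <- function(f) system.file("extdata", f, package = "suptrna")

scaffolds <- read_trna_genes(ex("scaffolds_synthetic.fasta"),
                             ex("scaffolds_synthetic_segments.tsv"))
templates <- read_variant_templates(ex("templates.yaml"))
energy    <- read_energy_table(ex("tstem_ddg_synthetic.tsv"))
rules     <- read_identity_rules(ex("identity_rules.yaml"))

variants <- enumerate_variants(scaffolds$tS_scaffold, "UGA",
                               templates, energy, rules)
tidy(variants)[, c("id", "anticodon", "templates", "ddg_eef1a", "n_violations")]
#> # A tibble: 12 × 5
#>   id     anticodon templates ddg_eef1a n_violations
#>   <chr>  <chr>     <chr>         <dbl>        <int>
#> 1 tSA1T6 UCA       "A1+T6"        -0.4            0
#> 2 tSA2T6 UCA       "A2+T6"        -0.4            0
#> 3 tST6   UCA       "T6"           -0.4            0
#> 4 tS     UCA       ""              0              0
#> 5 tSA1   UCA       "A1"            0              0
#> # i 7 more rows
```

Every variant carries the UCA anticodon (the reverse complement of the
UGA target), is ranked by its additive T-stem score (negative = more
stable eEF1A binding; the `T6` combinations rank first under the shipped
table), and reports identity-element violations instead of silently
dropping them. The in vitro transcription template for the top combined
variant ends in the expected reverse primer:

```r
make_t7_template(variants$variant[[which(variants$id == "tSA1T5")]])$reverse_primer
#> [1] "TGGCGTAGTCGACGGGATTC"
```

Safety screen on synthetic data with a known readthrough rate:

```r
cfg   <- sim_config(n_genes = 100, rho = 0.01, seed = 7)
tx    <- simulate_transcriptome(cfg)
reads <- simulate_footprints(tx, cfg) |> filter_footprints() |> assign_midpoints()
rrts  <- compute_rrts(reads, tx)
glance(rrts)
#> # A tibble: 1 × 4
#>   n_transcripts mean_rrts median_rrts frac_zero
#>           <int>     <dbl>       <dbl>     <dbl>
#> 1            80   0.00903           0     0.862
```

80 of 100 transcripts are scoreable (the rest have no next in-frame stop
in their 3′UTR), and the mean RRTS recovers the simulated ρ = 0.01.
`stop_codon_metagene()` + `plot_metagene()` draw the footprint profile
around stop codons; `compare_conditions()` + `readthrough_calls()`
contrast treated and control libraries per stop identity.

A thin command-line wrapper over the same functions ships in
`inst/cli/suptrna.R` (subcommands `design`, `rrts`, `metagene`,
`simulate`, `reporter`, `ddct`, `array-stability`); every run writes a
`manifest.json` with parameters and input checksums.

## Not in scope

Upstream read processing (trimming, rRNA depletion, genome alignment),
tRNA secondary-structure prediction, readthrough-efficiency prediction
from sequence, and wet-lab concerns (LNP formulation, animal work) are
outside the package; the pipeline starts from transcript-coordinate
alignments and annotated tRNA genes.
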