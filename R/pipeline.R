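#' Run a complete workflow and write versioned artifacts
#'
#' Single entry point wiring the modules into reproducible runs. Each run
#' writes its result files plus a `manifest.json` recording the workflow,
#' every effective parameter, input-file checksums, the package version
#' and the seed, so identical configurations reproduce identical outputs.
#' Outputs are staged in a temporary directory and moved into place only
#' on success, so a failing run leaves no partial artifacts.
#'
#' Workflows:
#' \describe{
#'   \item{`design`}{Enumerate and score suppressor variants for a
#'     scaffold. Params: `trna_fasta`, `trna_segments`, `trna_id`, `stop`,
#'     `templates` (YAML), `energy_table` (TSV), `identity_rules` (YAML,
#'     optional), `strict` (drop identity violators).}
#'   \item{`rrts`}{Readthrough scoring of a footprint library. Params:
#'     `reads` (TSV/BAM), `transcripts` (TSV), `transcripts_fasta`
#'     (optional), `min_len`, `max_len`, `min_rpkm`.}
#'   \item{`metagene`}{Stop-codon metagene. Params as `rrts` plus
#'     `window`, `by_stop`.}
#'   \item{`simulate`}{Synthetic transcriptome + footprints. Params: any
#'     [sim_config()] argument plus `rho`/`seed` overrides.}
#'   \item{`reporter`, `ddct`, `array-stability`}{The small assay
#'     normalizations, from CSV input (`input`, plus mode/control/
#'     reference-timepoint parameters).}
#' }
#'
#' @param workflow One of `"design"`, `"rrts"`, `"metagene"`,
#'   `"simulate"`, `"reporter"`, `"ddct"`, `"array-stability"`.
#' @param params Named list of workflow parameters (see Details).
#' @param out_dir Output directory (must not exist or be empty).
#' @param seed Integer seed applied to every stochastic step.
#' @return Invisibly, a named vector of written file paths.
#' @export
run_workflow <- function(workflow, params = list(), out_dir, seed = 1L) {
  workflow <- match.arg(workflow, c("design", "rrts", "metagene", "simulate",
                                    "reporter", "ddct", "array-stability"))
  stage <- tempfile("suptrna_run_")
  dir.create(stage, recursive = TRUE)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)

  inputs <- unlist(params[vapply(params, function(p)
    is.character(p) && length(p) == 1 && file.exists(p), logical(1))])
  if (is.null(inputs)) inputs <- character(0)
  runner <- switch(workflow,
                   design = wf_design, rrts = wf_rrts, metagene = wf_metagene,
                   simulate = wf_simulate, reporter = wf_reporter,
                   ddct = wf_ddct, `array-stability` = wf_array)
  files <- runner(params, stage, seed)

  manifest <- list(
    workflow = workflow, seed = seed,
    package_version = as.character(utils::packageVersion("suptrna")),
    parameters = params,
    input_checksums = as.list(tools::md5sum(inputs)),
    outputs = basename(files))
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, manifest = file.path(stage, "manifest.json"))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (length(list.files(out_dir)) > 0) {
    stop(sprintf("output directory '%s' is not empty", out_dir), call. = FALSE)
  }
  out <- file.path(out_dir, basename(files))
  ok <- file.copy(files, out, overwrite = FALSE)
  if (!all(ok)) stop("failed to move outputs into place", call. = FALSE)
  invisible(stats::setNames(out, names(files)))
}

wf_design <- function(p, stage, seed) {
  trnas <- read_trna_genes(p$trna_fasta, p$trna_segments)
  trna <- trnas[[p$trna_id %||% names(trnas)[1]]]
  if (is.null(trna)) stop("trna_id not found in FASTA", call. = FALSE)
  templates <- if (!is.null(p$templates)) read_variant_templates(p$templates) else list()
  energy <- read_energy_table(p$energy_table)
  rules <- if (!is.null(p$identity_rules)) read_identity_rules(p$identity_rules)
  variants <- enumerate_variants(trna, p$stop, templates, energy, rules,
                                 strict = isTRUE(p$strict))
  fa <- file.path(stage, "variants.fasta"); tsv <- file.path(stage, "variants.tsv")
  write_variants(variants, fa, tsv, cca = isTRUE(p$cca))
  t7 <- purrr::map_dfr(variants$variant, function(v) {
    t <- make_t7_template(v)
    tibble::tibble(id = v$id, template = t$template,
                   forward_primer = t$forward_primer,
                   reverse_primer = t$reverse_primer)
  })
  t7_path <- file.path(stage, "t7_templates.tsv")
  readr::write_tsv(t7, t7_path)
  c(variants_fasta = fa, variants_tsv = tsv, t7 = t7_path)
}

load_rrts_inputs <- function(p) {
  tx <- read_transcript_models(p$transcripts, fasta = p$transcripts_fasta)
  reads <- read_footprints(p$reads)
  reads <- filter_footprints(reads, p$min_len %||% 25L, p$max_len %||% 32L)
  list(tx = tx, reads = assign_midpoints(reads))
}

wf_rrts <- function(p, stage, seed) {
  x <- load_rrts_inputs(p)
  quant <- quantify_footprints(x$reads, x$tx, min_rpkm = p$min_rpkm %||% 0.1)
  tx <- dplyr::filter(x$tx, .data$transcript_id %in% quant$transcript_id)
  rrts <- compute_rrts(x$reads, tx)
  path <- file.path(stage, "rrts.tsv"); qpath <- file.path(stage, "quant.tsv")
  readr::write_tsv(rrts, path); readr::write_tsv(quant, qpath)
  c(rrts = path, quant = qpath)
}

wf_metagene <- function(p, stage, seed) {
  x <- load_rrts_inputs(p)
  prof <- stop_codon_metagene(x$reads, x$tx, window = p$window %||% 100L,
                              by_stop = isTRUE(p$by_stop))
  path <- file.path(stage, "metagene.tsv")
  readr::write_tsv(prof, path)
  c(metagene = path)
}

wf_simulate <- function(p, stage, seed) {
  cfg_args <- p[intersect(names(p), names(formals(sim_config)))]
  cfg_args$seed <- seed
  cfg <- do.call(sim_config, cfg_args)
  tx <- simulate_transcriptome(cfg)
  reads <- simulate_footprints(tx, cfg, condition = p$condition %||% "control")
  write_simulation(tx, reads, stage)
}

wf_reporter <- function(p, stage, seed) {
  plate <- readr::read_csv(p$input, show_col_types = FALSE)
  res <- readthrough_percent(plate, mode = p$mode %||% "vs-wild-type",
                             background = p$background)
  path <- file.path(stage, "readthrough_percent.tsv")
  readr::write_tsv(res, path)
  c(reporter = path)
}

wf_ddct <- function(p, stage, seed) {
  ct <- readr::read_csv(p$input, show_col_types = FALSE)
  res <- ddct(ct, control = p$control)
  path <- file.path(stage, "ddct.tsv")
  readr::write_tsv(res, path)
  c(ddct = path)
}

wf_array <- function(p, stage, seed) {
  arr <- readr::read_csv(p$input, show_col_types = FALSE)
  res <- microarray_normalize(arr, reference_timepoint = p$reference_timepoint)
  path <- file.path(stage, "array_stability.tsv")
  readr::write_tsv(res, path)
  c(array = path)
}
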