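#' Reporter readthrough as percent of a reference group
#'
#' Computes, per treatment, `100 x mean(PTC-group signal) /
#' mean(reference-group signal)`. In dual-luciferase mode (when a
#' `rluc_signal` column is present and used) the FLuc/RLuc ratio is formed
#' per well first, then averaged. In `vs-wild-type` mode the reference is
#' the pooled wild-type construct; in `vs-sense-control` mode each
#' treatment is normalized to the sense-control wells of the same
#' treatment (whose mean maps to 100).
#'
#' @param plate Tibble with columns `well`, `construct` (`"PTC"`,
#'   `"sense-control"` or `"wild-type"`), `treatment`, `fluc_signal` and
#'   optionally `rluc_signal`.
#' @param mode `"vs-wild-type"` or `"vs-sense-control"`.
#' @param dual Divide FLuc by RLuc per well first. Default: automatic
#'   (TRUE when `rluc_signal` is present and complete).
#' @param background Optional tibble subset or treatment label whose mean
#'   signal is subtracted from every well (off by default).
#' @return Tibble per treatment: `treatment`, `percent`, `sem`,
#'   `n_replicates`, `mode`.
#' @export
readthrough_percent <- function(plate, mode = c("vs-wild-type", "vs-sense-control"),
                                dual = NULL, background = NULL) {
  mode <- match.arg(mode)
  plate <- tibble::as_tibble(plate)
  if (any(plate$fluc_signal < 0, na.rm = TRUE)) {
    stop("signals must be >= 0", call. = FALSE)
  }
  if (is.null(dual)) {
    dual <- "rluc_signal" %in% names(plate) && !anyNA(plate$rluc_signal)
  }
  plate$signal <- if (dual) {
    plate$fluc_signal / plate$rluc_signal
  } else {
    plate$fluc_signal
  }
  if (!is.null(background)) {
    bg <- mean(plate$signal[plate$treatment == background])
    plate$signal <- pmax(plate$signal - bg, 0)
  }
  ref_construct <- if (mode == "vs-wild-type") "wild-type" else "sense-control"
  ref <- plate[plate$construct == ref_construct, , drop = FALSE]
  if (nrow(ref) == 0L) {
    stop(sprintf("no '%s' reference wells on the plate", ref_construct),
         call. = FALSE)
  }
  ptc <- plate[plate$construct == "PTC", , drop = FALSE]
  purrr::map_dfr(split(ptc, ptc$treatment), function(g) {
    ref_g <- if (mode == "vs-sense-control") {
      ref[ref$treatment == g$treatment[1], , drop = FALSE]
    } else {
      ref
    }
    if (nrow(ref_g) == 0L) {
      stop(sprintf("no reference wells for treatment '%s'", g$treatment[1]),
           call. = FALSE)
    }
    ref_mean <- mean(ref_g$signal)
    if (ref_mean == 0) stop("reference group mean is zero", call. = FALSE)
    pct <- 100 * g$signal / ref_mean
    tibble::tibble(treatment = g$treatment[1], percent = mean(pct),
                   sem = stats::sd(pct) / sqrt(length(pct)),
                   n_replicates = length(pct), mode = mode)
  })
}

#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, `dCt = target Ct - reference-gene Ct` (technical duplicates
#' are averaged per sample first); per condition, `ddCt = mean dCt -
#' mean dCt(control)`; fold change `= 2^(-ddCt)`.
#'
#' @param ct Tibble with columns `sample_id`, `condition`, `target_ct`,
#'   `reference_ct`.
#' @param control Name of the control condition.
#' @return Tibble per condition: `condition`, `delta_ct`, `ddct`, `fold`,
#'   `n_samples`.
#' @export
ddct <- function(ct, control) {
  ct <- tibble::as_tibble(ct)
  if (!control %in% ct$condition) {
    stop(sprintf("control condition '%s' not present", control), call. = FALSE)
  }
  if (any(!is.finite(ct$target_ct)) || any(!is.finite(ct$reference_ct)) ||
      any(ct$target_ct <= 0) || any(ct$reference_ct <= 0)) {
    stop("Ct values must be finite and > 0", call. = FALSE)
  }
  per_sample <- ct |>
    dplyr::summarise(target_ct = mean(.data$target_ct),
                     reference_ct = mean(.data$reference_ct),
                     .by = c("sample_id", "condition")) |>
    dplyr::mutate(dct = .data$target_ct - .data$reference_ct)
  per_cond <- per_sample |>
    dplyr::summarise(delta_ct = mean(.data$dct), n_samples = dplyr::n(),
                     .by = "condition")
  ctrl <- per_cond$delta_ct[per_cond$condition == control]
  per_cond |>
    dplyr::mutate(ddct = .data$delta_ct - ctrl, fold = 2^(-.data$ddct)) |>
    dplyr::select("condition", "delta_ct", "ddct", "fold", "n_samples")
}

#' Spike-in normalization of tRNA microarray timecourses
#'
#' Three-step normalization of two-channel array blocks against constant
#' exogenous spike-in probes: (1) each block is scaled so the median
#' spike-in channel-A/channel-B ratio equals one; (2) each sup-tRNA
#' probe's channel-A signal is divided by the (median) spike-in channel-A
#' signal; (3) each normalized signal is reported as percent of the mean
#' at the reference timepoint (whose mean is 100% by construction).
#' Replicate blocks, if present (a `replicate` column), are normalized
#' independently and pooled afterwards.
#'
#' @param array Tibble with columns `timepoint`, `probe_id`, `probe_class`
#'   (`"spike-in"`, `"sup-tRNA"`, `"natural-tRNA"`), `signal_a`,
#'   `signal_b`, optionally `replicate`.
#' @param reference_timepoint Timepoint whose mean maps to 100%.
#' @return Tibble: `timepoint`, `replicate`, `probe_id`, `percent`.
#' @export
microarray_normalize <- function(array, reference_timepoint) {
  array <- tibble::as_tibble(array)
  if (!"replicate" %in% names(array)) array$replicate <- 1L
  if (!reference_timepoint %in% array$timepoint) {
    stop(sprintf("reference timepoint '%s' absent", reference_timepoint),
         call. = FALSE)
  }
  norm <- array |>
    dplyr::group_by(.data$timepoint, .data$replicate) |>
    dplyr::group_modify(function(block, key) {
      sp <- block[block$probe_class == "spike-in", , drop = FALSE]
      if (nrow(sp) == 0L) {
        stop("spike-in probes missing from a block", call. = FALSE)
      }
      if (any(sp$signal_a <= 0) || any(sp$signal_b <= 0)) {
        stop("zero spike-in signal", call. = FALSE)
      }
      scale <- stats::median(sp$signal_a / sp$signal_b)
      block$signal_a <- block$signal_a / scale        # spike-in A/B ratio -> 1
      sp_a <- stats::median(sp$signal_a / scale)
      sup <- block[block$probe_class == "sup-tRNA", , drop = FALSE]
      tibble::tibble(probe_id = sup$probe_id, value = sup$signal_a / sp_a)
    }) |>
    dplyr::ungroup()
  ref_mean <- mean(norm$value[norm$timepoint == reference_timepoint])
  if (ref_mean == 0) stop("zero signal at the reference timepoint", call. = FALSE)
  dplyr::mutate(norm, percent = 100 * .data$value / ref_mean) |>
    dplyr::select("timepoint", "replicate", "probe_id", "percent")
}
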