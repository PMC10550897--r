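# Mito Stress Test metric extraction from oxygen-consumption-rate traces:
# well QC, protein normalization, the five assay metrics, replicate
# aggregation, non-mitochondrial normalization and treatment comparison.

.check_trace_cols <- function(traces) {
  assert_cols(traces, c("well", "ocr", "phase"), "`traces`")
  missing <- setdiff(ocr_phases(), as.character(unique(traces$phase)))
  if (length(missing)) {
    abort(sprintf("trace is missing injection phase(s): %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(traces)
}

#' Compute Mito Stress Test metrics from OCR traces
#'
#' Per well, the five assay quantities, each computed literally from the
#' injection-phase summaries:
#' * non-mitochondrial respiration: median OCR after rotenone/antimycin A;
#' * basal respiration: median baseline OCR minus non-mitochondrial;
#' * ATP production: basal respiration minus the minimum OCR after oligomycin
#'   (note this mixes the background-subtracted basal with the raw
#'   post-oligomycin minimum; set `atp_convention = "vendor"` for the
#'   alternative raw-difference convention);
#' * maximal respiration: maximum OCR after FCCP minus non-mitochondrial;
#' * proton leak: minimum OCR after oligomycin minus non-mitochondrial.
#'
#' @param traces Long tibble `well, time_min, ocr, phase` plus any of
#'   `protein_ug, treatment, batch` (carried through).
#' @param atp_convention `"paper"` (default; background-subtracted basal minus
#'   raw post-oligomycin minimum) or `"vendor"` (raw baseline median minus raw
#'   post-oligomycin minimum).
#' @return Tibble with one row per well: carried annotations plus `non_mito,
#'   basal, atp_production, maximal, proton_leak` (pmol O2/min).
#' @export
ocr_metrics <- function(traces, atp_convention = c("paper", "vendor")) {
  atp_convention <- match.arg(atp_convention)
  .check_trace_cols(traces)
  carry <- intersect(c("protein_ug", "treatment", "batch"), names(traces))
  per_well_missing <- traces |>
    dplyr::count(.data$well, .data$phase) |>
    tidyr::pivot_wider(names_from = "phase", values_from = "n",
                       values_fill = 0L)
  bad <- per_well_missing$well[apply(
    as.matrix(per_well_missing[ocr_phases()]), 1, function(v) any(v == 0))]
  if (length(bad)) {
    abort(sprintf("well(s) missing a phase: %s", paste(bad, collapse = ", ")))
  }
  traces |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(carry), dplyr::first),
      non_mito = median(.data$ocr[.data$phase == "post_rotenone_antimycinA"]),
      .median_base = median(.data$ocr[.data$phase == "baseline"]),
      .min_oligo = min(.data$ocr[.data$phase == "post_oligomycin"]),
      .max_fccp = max(.data$ocr[.data$phase == "post_FCCP"]),
      .groups = "drop") |>
    dplyr::mutate(
      basal = .data$.median_base - .data$non_mito,
      atp_production = if (atp_convention == "paper") {
        .data$basal - .data$.min_oligo
      } else {
        .data$.median_base - .data$.min_oligo
      },
      maximal = .data$.max_fccp - .data$non_mito,
      proton_leak = .data$.min_oligo - .data$non_mito) |>
    dplyr::select(-dplyr::starts_with("."))
}

#' Exclude non-viable or non-responsive wells
#'
#' A well is excluded when its cells were not viable (median baseline OCR
#' below a near-zero threshold) or did not respond to FCCP (post-FCCP maximum
#' not exceeding the post-oligomycin minimum). All exclusions are logged with
#' their reason in the `"exclusions"` attribute.
#'
#' @param traces Long OCR trace tibble.
#' @param near_zero Near-zero viability threshold in pmol O2/min (default 5).
#' @return The retained traces; attribute `"exclusions"` is a tibble
#'   `well, reason`.
#' @export
ocr_qc <- function(traces, near_zero = 5) {
  .check_trace_cols(traces)
  status <- traces |>
    dplyr::group_by(.data$well) |>
    dplyr::summarise(
      med_base = median(.data$ocr[.data$phase == "baseline"]),
      max_fccp = max(.data$ocr[.data$phase == "post_FCCP"]),
      min_oligo = min(.data$ocr[.data$phase == "post_oligomycin"]),
      .groups = "drop") |>
    dplyr::mutate(reason = dplyr::case_when(
      .data$med_base < near_zero ~ "near-zero OCR",
      .data$max_fccp <= .data$min_oligo ~ "no FCCP response",
      TRUE ~ NA_character_))
  excluded <- status |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select("well", "reason")
  kept <- dplyr::filter(traces, !.data$well %in% excluded$well)
  if (nrow(kept) == 0) abort("all wells failed QC")
  attr(kept, "exclusions") <- excluded
  kept
}

#' Normalize OCR for per-well protein content
#'
#' Each well's OCR is divided by its total protein mass and rescaled by the
#' plate-mean protein mass, correcting intra-plate seeding variation while
#' keeping the units comparable within the plate. Wells with nonpositive
#' protein are excluded and logged.
#'
#' @param traces Long OCR trace tibble with `protein_ug` (and optionally
#'   `batch`, within which the plate mean is taken).
#' @return Protein-normalized traces; attribute `"exclusions"` lists dropped
#'   wells.
#' @export
ocr_normalize_protein <- function(traces) {
  assert_cols(traces, c("well", "ocr", "protein_ug"), "`traces`")
  bad_wells <- unique(traces$well[!is.finite(traces$protein_ug) |
                                    traces$protein_ug <= 0])
  kept <- dplyr::filter(traces, !.data$well %in% bad_wells)
  if (nrow(kept) == 0) abort("no well has a positive protein mass")
  if (!"batch" %in% names(kept)) kept$batch <- "plate1"
  out <- kept |>
    dplyr::group_by(.data$batch) |>
    dplyr::mutate(ocr = .data$ocr / .data$protein_ug *
                    mean(.data$protein_ug[!duplicated(.data$well)])) |>
    dplyr::ungroup()
  attr(out, "exclusions") <- tibble(well = bad_wells,
                                    reason = "nonpositive protein mass")
  out
}

#' Aggregate well metrics into biological replicates
#'
#' A biological replicate is an independent assay (batch) of several wells;
#' its metrics are the arithmetic means of the per-well metrics.
#'
#' @param metrics Per-well metric tibble from [ocr_metrics()].
#' @param by Columns defining a biological replicate (default
#'   `c("batch", "treatment")`).
#' @return Per-replicate metric tibble with an `n_wells` count.
#' @export
ocr_aggregate <- function(metrics, by = c("batch", "treatment")) {
  by <- intersect(by, names(metrics))
  if (length(by) == 0) abort("no replicate-defining columns found")
  metric_cols <- c("non_mito", "basal", "atp_production", "maximal",
                   "proton_leak")
  assert_cols(metrics, metric_cols, "`metrics`")
  metrics |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(n_wells = dplyr::n(),
                     dplyr::across(dplyr::all_of(metric_cols), mean),
                     .groups = "drop")
}

#' Normalize metrics to non-mitochondrial respiration
#'
#' Divides basal, ATP production, maximal and proton leak by the replicate's
#' non-mitochondrial respiration (dimensionless ratios), accounting for batch
#' effects multiplicatively; `non_mito` is recorded as 1. Replicates with
#' nonpositive non-mitochondrial respiration are excluded and logged.
#'
#' @param metrics Per-replicate metric tibble.
#' @return Normalized metrics; attribute `"exclusions"` lists dropped rows.
#' @export
ocr_normalize_nonmito <- function(metrics) {
  assert_cols(metrics, c("non_mito", "basal", "atp_production", "maximal",
                         "proton_leak"), "`metrics`")
  bad <- !is.finite(metrics$non_mito) | metrics$non_mito <= 0
  excluded <- metrics[bad, , drop = FALSE]
  out <- metrics[!bad, , drop = FALSE] |>
    dplyr::mutate(
      basal = .data$basal / .data$non_mito,
      atp_production = .data$atp_production / .data$non_mito,
      maximal = .data$maximal / .data$non_mito,
      proton_leak = .data$proton_leak / .data$non_mito,
      non_mito = 1)
  if (nrow(out) == 0) abort("no replicate has positive non-mitochondrial respiration")
  attr(out, "exclusions") <- excluded
  out
}

#' Compare treatments metric by metric
#'
#' Two-tailed two-sample t-tests (Student's pooled-variance by default, Welch
#' via `var_equal = FALSE`) for basal respiration, maximal respiration, ATP
#' production and proton leak between the two treatment groups.
#'
#' @param metrics Per-replicate (typically non-mito-normalized) metric tibble
#'   with a `treatment` column holding exactly two levels.
#' @param treatment_col Name of the treatment column.
#' @param var_equal Use the pooled-variance Student's test (default `TRUE`).
#' @param alpha Significance level (default 0.05).
#' @return Tibble `metric, mean_<group1>, mean_<group2>, t, df, p,
#'   significant`; degenerate (zero-variance) comparisons carry `p = NA` with
#'   a note, or `p = 1` when both groups are constant and equal.
#' @export
ocr_compare <- function(metrics, treatment_col = "treatment",
                        var_equal = TRUE, alpha = 0.05) {
  assert_cols(metrics, treatment_col, "`metrics`")
  groups <- sort(unique(as.character(metrics[[treatment_col]])))
  if (length(groups) != 2) abort("`metrics` must contain exactly two treatments")
  metric_cols <- c("basal", "maximal", "atp_production", "proton_leak")
  assert_cols(metrics, metric_cols, "`metrics`")
  g1 <- metrics[[treatment_col]] == groups[1]
  purrr::map_dfr(metric_cols, function(mc) {
    a <- metrics[[mc]][g1]
    b <- metrics[[mc]][!g1]
    if (length(a) < 2 || length(b) < 2) abort("need >= 2 replicates per treatment")
    row <- tibble(metric = mc, t = NA_real_, df = NA_real_, p = NA_real_,
                  note = NA_character_)
    row[[paste0("mean_", groups[1])]] <- mean(a)
    row[[paste0("mean_", groups[2])]] <- mean(b)
    if (sd(a) == 0 && sd(b) == 0) {
      row$p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else NA_real_
      row$note <- "zero variance in both groups"
    } else {
      tt <- tryCatch(t.test(a, b, var.equal = var_equal),
                     error = function(e) NULL)
      if (is.null(tt)) {
        row$note <- "degenerate variance"
      } else {
        row$t <- unname(tt$statistic)
        row$df <- unname(tt$parameter)
        row$p <- tt$p.value
      }
    }
    row$significant <- !is.na(row$p) & row$p < alpha
    row
  })
}

#' Run the full Mito Stress Test analysis chain
#'
#' QC -> protein normalization -> per-well metrics -> aggregation into
#' biological replicates -> non-mitochondrial normalization -> treatment
#' comparison.
#'
#' @inheritParams ocr_metrics
#' @inheritParams ocr_qc
#' @inheritParams ocr_compare
#' @param normalize_protein Apply [ocr_normalize_protein()] (default `TRUE`;
#'   requires `protein_ug`).
#' @return List of class `mito_stress`: `metrics` (per replicate, normalized),
#'   `comparison`, `exclusions`.
#' @export
mito_stress <- function(traces, atp_convention = c("paper", "vendor"),
                        near_zero = 5, normalize_protein = TRUE,
                        var_equal = TRUE) {
  traces <- ocr_qc(traces, near_zero = near_zero)
  qc_log <- attr(traces, "exclusions")
  prot_log <- NULL
  if (normalize_protein) {
    traces <- ocr_normalize_protein(traces)
    prot_log <- attr(traces, "exclusions")
  }
  per_rep <- ocr_metrics(traces, atp_convention = atp_convention) |>
    ocr_aggregate() |>
    ocr_normalize_nonmito()
  structure(list(metrics = per_rep,
                 comparison = ocr_compare(per_rep, var_equal = var_equal),
                 exclusions = dplyr::bind_rows(qc_log, prot_log)),
            class = "mito_stress")
}
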