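# Automated multiplex-immunoassay cleaning: detection-limit censoring,
# bead-count filtering, triplicate outlier resolution, replicate averaging and
# sparse-analyte removal, with a full provenance log.

#' Censor concentrations below the assay detection limit
#'
#' Readings below the limit are assigned 0 pg/mL; the comparison is strict, so
#' a value exactly at the limit is retained. Applied per interpolated reading,
#' before triplicate resolution.
#'
#' @param x Numeric vector of concentrations (pg/mL, >= 0).
#' @param limit Detection limit in pg/mL (default 3.2).
#' @return Censored numeric vector.
#' @export
censor_detection <- function(x, limit = 3.2) {
  if (any(x < 0, na.rm = TRUE)) abort("concentrations must be nonnegative")
  ifelse(x < limit, 0, x)
}

#' Remove plate readings acquired from too few beads
#'
#' Readings generated from fewer than `min_beads` beads are unreliable and are
#' removed; the comparison is strict (`bead_count < min_beads`), so a reading
#' at exactly the threshold is retained.
#'
#' @param readings Tibble of plate readings with at least `bead_count`.
#' @param min_beads Minimum acceptable bead count (default 20).
#' @return The retained readings; removed rows are attached as the `"removed"`
#'   attribute.
#' @export
filter_bead_counts <- function(readings, min_beads = 20) {
  assert_cols(readings, "bead_count", "`readings`")
  keep <- readings$bead_count >= min_beads
  out <- readings[keep, , drop = FALSE]
  attr(out, "removed") <- readings[!keep, , drop = FALSE]
  out
}

#' Resolve a technical triplicate by the two-against-one distance rule
#'
#' For three replicates, the closest pair is found (distance `d`); the
#' remaining replicate is removed iff its distance to each member of that pair
#' is strictly greater than `2 * d`. One or two replicates are returned
#' unchanged (the rule is defined only for triplicates), and at most one value
#' is ever removed.
#'
#' @param values Numeric vector of 1-3 replicate concentrations.
#' @return The retained replicate values.
#' @export
resolve_triplicate <- function(values) {
  if (length(values) == 0) abort("no replicate values supplied")
  if (length(values) > 3) abort("more than 3 replicates supplied")
  if (length(values) < 3) return(values)
  d <- c(abs(values[1] - values[2]),
         abs(values[1] - values[3]),
         abs(values[2] - values[3]))
  pairs <- rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 3L, 1L))
  i <- which.min(d)
  pair <- pairs[i, 1:2]
  odd <- pairs[i, 3]
  if (abs(values[odd] - values[pair[1]]) > 2 * d[i] &&
      abs(values[odd] - values[pair[2]]) > 2 * d[i]) {
    values[pair]
  } else {
    values
  }
}

#' Average surviving technical replicates
#'
#' @param values Numeric vector of >= 1 replicate values.
#' @return Arithmetic mean.
#' @export
average_replicates <- function(values) {
  if (length(values) == 0) abort("cannot average zero replicates")
  mean(values)
}

#' Remove analytes that are mostly zero without a group pattern
#'
#' An analyte is dropped iff more than half of its per-sample values are
#' 0 pg/mL AND the zeros do not partition between experimental groups
#' (operationalized as a Fisher exact test of zero/nonzero x group with
#' p >= 0.05). With a single group the partition test is undefined and the
#' analyte is dropped on the majority-zero rule alone, with a warning.
#'
#' @param data Wide tibble, one row per sample, one column per analyte.
#' @param group_col Name of the grouping column in `data`.
#' @param analytes Analyte column names; defaults to all numeric columns other
#'   than `group_col` and the standard metadata columns.
#' @return `data` without the dropped analyte columns; the decisions are
#'   attached as the `"removed_cytokines"` attribute (a tibble with the zero
#'   fraction and Fisher p for every analyte).
#' @export
drop_sparse_cytokines <- function(data, group_col = "genotype",
                                  analytes = NULL) {
  assert_cols(data, group_col, "`data`")
  analytes <- analytes %||% setdiff(
    names(data)[vapply(data, is.numeric, logical(1))],
    c(group_col, "age_days", "replicate", "bead_count"))
  grp <- factor(data[[group_col]])
  single_group <- nlevels(grp) < 2
  if (single_group) {
    warn("single experimental group: sparse analytes dropped on the majority-zero rule alone")
  }
  audit <- purrr::map_dfr(analytes, function(a) {
    zero <- data[[a]] == 0
    frac <- mean(zero)
    p <- NA_real_
    if (frac > 0.5) {
      if (single_group || length(unique(zero)) < 2) {
        p <- 1
      } else {
        p <- fisher.test(table(zero, grp))$p.value
      }
    }
    tibble(analyte = a, zero_fraction = frac, fisher_p = p,
           removed = frac > 0.5 && (is.na(p) || p >= 0.05))
  })
  out <- data[, setdiff(names(data), audit$analyte[audit$removed]),
              drop = FALSE]
  attr(out, "removed_cytokines") <- audit
  out
}

#' Clean a multiplex cytokine dataset end to end
#'
#' Runs the automated cleaning pipeline in fixed order: per-reading
#' detection-limit censoring, bead-count filtering, technical-triplicate
#' outlier resolution, replicate averaging, then sparse-analyte removal. Every
#' removed reading and analyte is logged; retrieve the log with
#' [cleaning_log()].
#'
#' @param readings Long tibble `sample_id, analyte, replicate,
#'   concentration_pg_ml, bead_count`, or a `cytokine_study` from
#'   [simulate_cytokine_study()] (in which case `samples` is taken from it).
#' @param samples Sample metadata tibble with `sample_id` plus e.g. `genotype`,
#'   `age_days`, `sex`.
#' @param min_beads Bead-count threshold (default 20).
#' @param detection_limit Detection limit in pg/mL (default 3.2).
#' @param group_col Metadata column defining the experimental groups used by
#'   the sparse-analyte partition test.
#' @return Wide tibble: one row per sample with metadata columns followed by
#'   one column per surviving analyte (mean of surviving replicates, pg/mL).
#'   The `"provenance"` attribute holds the removal log.
#' @export
clean_cytokines <- function(readings, samples = NULL, min_beads = 20,
                            detection_limit = 3.2, group_col = "genotype") {
  if (inherits(readings, "cytokine_study")) {
    samples <- samples %||% readings$samples
    readings <- readings$readings
  }
  if (is.null(samples)) abort("`samples` metadata is required")
  assert_cols(readings,
              c("sample_id", "analyte", "concentration_pg_ml", "bead_count"),
              "`readings`")
  assert_cols(samples, c("sample_id", group_col), "`samples`")

  n_censored <- sum(readings$concentration_pg_ml < detection_limit &
                      readings$concentration_pg_ml > 0)
  censored <- dplyr::mutate(
    readings,
    concentration_pg_ml = censor_detection(.data$concentration_pg_ml,
                                           detection_limit))

  beaded <- filter_bead_counts(censored, min_beads)
  bead_removed <- attr(beaded, "removed")

  resolved <- beaded |>
    dplyr::group_by(.data$sample_id, .data$analyte) |>
    dplyr::summarise(
      n_in = dplyr::n(),
      kept = list(resolve_triplicate(.data$concentration_pg_ml)),
      .groups = "drop") |>
    dplyr::mutate(n_kept = lengths(.data$kept),
                  value = purrr::map_dbl(.data$kept, average_replicates))
  replicate_removed <- resolved |>
    dplyr::filter(.data$n_kept < .data$n_in) |>
    dplyr::select("sample_id", "analyte", "n_in", "n_kept")

  wide <- resolved |>
    dplyr::select("sample_id", "analyte", "value") |>
    tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  wide <- dplyr::left_join(samples, wide, by = "sample_id")

  out <- drop_sparse_cytokines(wide, group_col = group_col,
                               analytes = setdiff(names(wide), names(samples)))
  provenance <- list(
    n_readings_in = nrow(readings),
    n_censored = n_censored,
    n_bead_removed = nrow(bead_removed),
    n_replicate_removed = sum(resolved$n_in - resolved$n_kept),
    n_readings_used = sum(resolved$n_kept),
    bead_removed = bead_removed,
    replicate_removed = replicate_removed,
    cytokines = attr(out, "removed_cytokines"))
  attr(out, "removed_cytokines") <- NULL
  attr(out, "provenance") <- provenance
  out
}

#' Retrieve the provenance log of a cleaned cytokine matrix
#'
#' @param x Output of [clean_cytokines()].
#' @return A list with censoring counts, removed readings and the per-analyte
#'   sparse-removal audit.
#' @export
cleaning_log <- function(x) {
  attr(x, "provenance") %||%
    abort("no provenance log attached; was this produced by clean_cytokines()?")
}
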