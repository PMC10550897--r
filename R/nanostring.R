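# nCounter-style count normalization and differential-expression filtering:
# background thresholding, two-step positive-control / housekeeping
# normalization, Welch t-tests on log2 counts, and low-expression exclusion.

.count_cols <- function(counts) {
  assert_cols(counts, c("gene", "class"), "`counts`")
  setdiff(names(counts)[vapply(counts, is.numeric, logical(1))],
          c("gene", "class"))
}

#' Reassign sub-background counts to the background threshold
#'
#' Raw counts strictly below `floor` are reassigned the threshold value so
#' that fold changes are computed against a common baseline reading.
#'
#' @param counts Tibble `gene, class, <sample columns>`.
#' @param floor Background threshold (default 20).
#' @return `counts` with thresholded sample columns.
#' @export
ns_threshold <- function(counts, floor = 20) {
  cols <- .count_cols(counts)
  if (any(as.matrix(counts[cols]) < 0)) abort("counts must be nonnegative")
  dplyr::mutate(counts,
                dplyr::across(dplyr::all_of(cols), ~ pmax(.x, floor)))
}

# per-sample scale factors from a set of reference genes: the mean across
# samples of the per-sample geometric means, divided by each sample's
# geometric mean
.reference_factors <- function(counts, ref_rows) {
  cols <- .count_cols(counts)
  gm <- vapply(cols, function(s) geo_mean(counts[[s]][ref_rows]), numeric(1))
  mean(gm) / gm
}

.apply_factors <- function(counts, factors) {
  cols <- .count_cols(counts)
  for (s in cols) counts[[s]] <- counts[[s]] * factors[[s]]
  counts
}

#' Positive-control normalization
#'
#' Each sample is scaled by (mean across samples of the geometric mean of the
#' positive-control probes) / (that sample's positive-control geometric mean),
#' removing lane-to-lane assay efficiency differences.
#'
#' @inheritParams ns_threshold
#' @return Scaled counts; per-sample factors attached as attribute
#'   `"pos_factors"`.
#' @export
ns_positive_normalize <- function(counts) {
  ref <- counts$class == "positive_control"
  if (!any(ref)) abort("no positive_control genes present")
  f <- .reference_factors(counts, ref)
  out <- .apply_factors(counts, f)
  attr(out, "pos_factors") <- f
  out
}

#' Select housekeeping genes for normalization
#'
#' Housekeeping genes with a count under `min_count` in any sample are first
#' removed; of the remainder, genes with a coefficient of variation (SD/mean
#' across samples) of `max_cv` or less are kept.
#'
#' @inheritParams ns_threshold
#' @param min_count Minimum acceptable count in every sample (default 100).
#' @param max_cv Largest acceptable CV (default 0.10).
#' @return Character vector of selected housekeeping gene names.
#' @export
ns_select_housekeeping <- function(counts, min_count = 100, max_cv = 0.10) {
  cols <- .count_cols(counts)
  hk <- dplyr::filter(counts, .data$class == "housekeeping")
  if (nrow(hk) == 0) abort("no housekeeping genes present")
  mat <- as.matrix(hk[cols])
  high <- apply(mat, 1, function(v) all(v >= min_count))
  cv <- apply(mat, 1, function(v) sd(v) / mean(v))
  keep <- high & cv <= max_cv
  if (!any(keep)) {
    abort(sprintf(
      "no housekeeping gene survives selection (>=%d counts in every sample and CV <= %.0f%%); normalization impossible",
      min_count, 100 * max_cv))
  }
  hk$gene[keep]
}

#' Housekeeping-gene normalization
#'
#' Second normalization step, applied after [ns_positive_normalize()]: each
#' sample is scaled so the geometric mean of the selected housekeeping genes
#' is equalized across samples (against the mean of per-sample geometric
#' means).
#'
#' @inheritParams ns_threshold
#' @param hk_genes Housekeeping genes to use; defaults to
#'   [ns_select_housekeeping()].
#' @return Scaled counts; factors attached as attribute `"hk_factors"`.
#' @export
ns_housekeeping_normalize <- function(counts, hk_genes = NULL) {
  hk_genes <- hk_genes %||% ns_select_housekeeping(counts)
  ref <- counts$gene %in% hk_genes
  if (!any(ref)) abort("`hk_genes` not found in `counts`")
  f <- .reference_factors(counts, ref)
  out <- .apply_factors(counts, f)
  attr(out, "hk_factors") <- f
  attr(out, "hk_genes") <- hk_genes
  out
}

#' Full two-step count normalization
#'
#' Background thresholding, positive-control normalization, housekeeping-gene
#' selection and housekeeping normalization, in that order. Operates on one
#' cell-type batch at a time; never pool batches.
#'
#' @inheritParams ns_threshold
#' @inheritParams ns_select_housekeeping
#' @param background_floor Background threshold (default 20).
#' @return Normalized counts with `"pos_factors"`, `"hk_factors"` and
#'   `"hk_genes"` attributes.
#' @export
ns_normalize <- function(counts, background_floor = 20, min_count = 100,
                         max_cv = 0.10) {
  out <- counts |>
    ns_threshold(floor = background_floor) |>
    ns_positive_normalize()
  pf <- attr(out, "pos_factors")
  out <- ns_housekeeping_normalize(
    out, ns_select_housekeeping(out, min_count = min_count, max_cv = max_cv))
  attr(out, "pos_factors") <- pf
  out
}

#' Differential expression between treatment groups
#'
#' Per endogenous gene: group means of the normalized counts, the log2 fold
#' change `log2(mean_case / mean_control)`, and a two-sample two-tailed Welch
#' t-test on log2-transformed normalized counts. A gene is kept when p <=
#' 0.05. When both groups have zero variance the t statistic is undefined:
#' p is 1 if the group means are equal and flagged `NA` otherwise.
#'
#' @param counts Normalized counts (see [ns_normalize()]).
#' @param groups Tibble `sample, group`.
#' @param case,control Group labels for the fold-change numerator and
#'   denominator (defaults `"cytokine"` vs `"vehicle"`).
#' @param log_scale Run the t-test on log2 counts (default) or linear counts.
#' @return Tibble `gene, mean_case, mean_control, log2fc, p, kept`.
#' @export
ns_differential_expression <- function(counts, groups, case = "cytokine",
                                       control = "vehicle",
                                       log_scale = TRUE) {
  assert_cols(groups, c("sample", "group"), "`groups`")
  cols <- .count_cols(counts)
  missing <- setdiff(cols, groups$sample)
  if (length(missing)) {
    abort(sprintf("`groups` does not label sample(s): %s",
                  paste(missing, collapse = ", ")))
  }
  case_cols <- intersect(cols, groups$sample[groups$group == case])
  ctrl_cols <- intersect(cols, groups$sample[groups$group == control])
  if (length(case_cols) < 2 || length(ctrl_cols) < 2) {
    abort("need at least 2 samples per group")
  }
  endo <- dplyr::filter(counts, .data$class == "endogenous")
  a <- as.matrix(endo[case_cols])
  b <- as.matrix(endo[ctrl_cols])
  ta <- if (log_scale) log2(a) else a
  tb <- if (log_scale) log2(b) else b
  pvals <- vapply(seq_len(nrow(endo)), function(i) {
    va <- ta[i, ]; vb <- tb[i, ]
    if (sd(va) == 0 && sd(vb) == 0) {
      return(if (isTRUE(all.equal(mean(va), mean(vb)))) 1 else NA_real_)
    }
    tryCatch(t.test(va, vb)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  tibble(gene = endo$gene,
         mean_case = rowMeans(a), mean_control = rowMeans(b),
         log2fc = log2(rowMeans(a) / rowMeans(b)),
         p = pvals,
         kept = !is.na(pvals) & pvals <= 0.05)
}

#' Exclude near-background differentially expressed genes
#'
#' Genes whose average normalized counts are below `floor` in BOTH groups sit
#' too close to the background threshold to be trusted; their `kept` flag is
#' withdrawn.
#'
#' @param de Output of [ns_differential_expression()].
#' @param floor Mean-count floor (default 30).
#' @return `de` with a `low_expression` flag and updated `kept`.
#' @export
ns_filter_low_expression <- function(de, floor = 30) {
  assert_cols(de, c("mean_case", "mean_control", "kept"), "`de`")
  dplyr::mutate(de,
                low_expression = .data$mean_case < floor &
                  .data$mean_control < floor,
                kept = .data$kept & !.data$low_expression)
}

#' Normalization + differential expression in one call
#'
#' @inheritParams ns_normalize
#' @inheritParams ns_differential_expression
#' @param low_floor Mean-count floor for [ns_filter_low_expression()].
#' @return The filtered DE tibble; the normalized counts are attached as
#'   attribute `"normalized"`.
#' @export
nanostring_de <- function(counts, groups, case = "cytokine",
                          control = "vehicle", background_floor = 20,
                          min_count = 100, max_cv = 0.10, low_floor = 30,
                          log_scale = TRUE) {
  norm <- ns_normalize(counts, background_floor = background_floor,
                       min_count = min_count, max_cv = max_cv)
  de <- ns_differential_expression(norm, groups, case = case,
                                   control = control,
                                   log_scale = log_scale) |>
    ns_filter_low_expression(floor = low_floor)
  attr(de, "normalized") <- norm
  de
}
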