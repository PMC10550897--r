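# End-to-end orchestration: clean matrix -> LV selection -> fit ->
# orthogonalize -> signature -> permutation significance, with a manifest of
# seeds and settings for reproducibility.

.run_pls_analysis <- function(data, response, kind_label, predictors = NULL,
                              max_lv = 5, n_iterations = 100,
                              n_permutations = 1000, seed = 1L,
                              positive_class = NULL) {
  cv <- pls_cv(data, response, predictors = predictors, max_lv = max_lv,
               n_iterations = n_iterations, seed = child_seed(seed, 1),
               positive_class = positive_class)
  model <- pls_fit(data, response, n_lv = cv$chosen_lv,
                   predictors = predictors,
                   positive_class = positive_class) |>
    pls_orthogonalize()
  signature <- pls_signature(model)
  permutation <- pls_permutation(data, response, n_lv = cv$chosen_lv,
                                 predictors = predictors,
                                 n_permutations = n_permutations,
                                 n_iterations = n_iterations,
                                 seed = child_seed(seed, 2),
                                 positive_class = positive_class)
  structure(
    list(cv = cv, model = model, signature = signature,
         permutation = permutation,
         manifest = list(kind = kind_label, response = response,
                         predictors = model$variables, max_lv = max_lv,
                         n_iterations = n_iterations,
                         n_permutations = n_permutations, seed = seed,
                         positive_class = model$positive_class,
                         package_version =
                           as.character(utils::packageVersion("cytosig")),
                         timestamp = format(Sys.time(), tz = "UTC"))),
    class = "pls_analysis")
}

#' Model progression: regress a continuous outcome on cytokine profiles
#'
#' Full PLSR chain on a cleaned cytokine matrix: latent-variable selection by
#' repeated random-subsampling cross-validation (RMSECV over 1..`max_lv`
#' LVs), the final fit at the chosen count, orthogonalization, VIP > 1
#' signature extraction and a permutation significance test at the preserved
#' LV count.
#'
#' @param data Cleaned wide tibble (see [clean_cytokines()]).
#' @param response Continuous response column (default `age_days`).
#' @inheritParams pls_cv
#' @inheritParams pls_permutation
#' @return A `pls_analysis` list: `cv`, `model`, `signature`, `permutation`,
#'   `manifest`.
#' @export
run_progression_model <- function(data, response = "age_days",
                                  predictors = NULL, max_lv = 5,
                                  n_iterations = 100, n_permutations = 1000,
                                  seed = 1L) {
  if (!is.numeric(data[[response]])) {
    abort("`response` must be a continuous (numeric) column; see run_discrimination_model() for classes")
  }
  .run_pls_analysis(data, response, "progression (PLSR)",
                    predictors = predictors, max_lv = max_lv,
                    n_iterations = n_iterations,
                    n_permutations = n_permutations, seed = seed)
}

#' Model discrimination: predict group identity from cytokine profiles
#'
#' Full PLS-DA chain (accuracy metric): LV selection by cross-validation,
#' final fit, orthogonalization, VIP > 1 signature and permutation test.
#' Typically applied to one timepoint with two genotypes.
#'
#' @param data Cleaned wide tibble restricted to the groups of interest.
#' @param response Class column (default `genotype`).
#' @inheritParams pls_fit
#' @inheritParams pls_permutation
#' @return A `pls_analysis` list (see [run_progression_model()]).
#' @export
run_discrimination_model <- function(data, response = "genotype",
                                     predictors = NULL, max_lv = 5,
                                     n_iterations = 100,
                                     n_permutations = 1000, seed = 1L,
                                     positive_class = NULL) {
  if (is.numeric(data[[response]])) {
    abort("`response` must be a class column; see run_progression_model() for continuous outcomes")
  }
  .run_pls_analysis(data, response, "discrimination (PLS-DA)",
                    predictors = predictors, max_lv = max_lv,
                    n_iterations = n_iterations,
                    n_permutations = n_permutations, seed = seed,
                    positive_class = positive_class)
}

#' @export
print.pls_analysis <- function(x, ...) {
  cat(sprintf("%s of %s\n", x$manifest$kind, x$manifest$response))
  best <- x$cv$per_lv$mean_metric[x$cv$per_lv$n_lv == x$cv$chosen_lv]
  cat(sprintf("  %d LV, %s = %.4g, permutation p = %.3g (%d permutations)\n",
              x$cv$chosen_lv, x$cv$metric, best, x$permutation$p,
              x$permutation$n_permutations))
  if (nrow(x$signature)) {
    up <- x$signature$variable[x$signature$direction == "up"]
    down <- x$signature$variable[x$signature$direction == "down"]
    if (length(up)) cat("  up:  ", paste(up, collapse = ", "), "\n")
    if (length(down)) cat("  down:", paste(down, collapse = ", "), "\n")
  } else {
    cat("  empty signature (no VIP > 1 variables)\n")
  }
  invisible(x)
}

#' @export
autoplot.pls_analysis <- function(object, data = NULL, colour = NULL,
                                  shape = NULL, ...) {
  autoplot(object$model, data = data, colour = colour, shape = shape, ...)
}

#' Stimulation recipe used for the signature-treatment experiments
#'
#' Documentation constants: the cytokine concentrations and exposure used to
#' apply a disease-progression signature to primary cultures (5 nM IFN-gamma,
#' 12 nM IP-10/CXCL10, 500 nM IL-9, 72 h). Exposed for reporting; not used in
#' any computation.
#'
#' @return Tibble `component, value, unit`.
#' @export
signature_treatment_recipe <- function() {
  tibble(component = c("IFN-gamma", "IP-10/CXCL10", "IL-9", "exposure"),
         value = c(5, 12, 500, 72),
         unit = c("nM", "nM", "nM", "h"))
}
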