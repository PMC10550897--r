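# Latent-variable selection by repeated random-subsampling cross-validation
# and permutation significance testing.

#' Root mean squared error of cross-validation
#'
#' `sqrt(sum((P_j - A_j)^2) / n)` over a held-out test set, where `P` are
#' predicted and `A` actual values.
#'
#' @param predicted,actual Equal-length nonempty numeric vectors.
#' @return The RMSECV.
#' @export
rmsecv <- function(predicted, actual) {
  if (length(predicted) == 0) abort("empty prediction vector")
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length")
  }
  sqrt(sum((predicted - actual) ^ 2) / length(predicted))
}

#' Classification accuracy
#'
#' @param predicted,actual Equal-length nonempty label vectors.
#' @return Fraction of matching labels.
#' @export
class_accuracy <- function(predicted, actual) {
  if (length(predicted) == 0) abort("empty prediction vector")
  if (length(predicted) != length(actual)) {
    abort("`predicted` and `actual` must have equal length")
  }
  mean(as.character(predicted) == as.character(actual))
}

#' Cross-validation test-set size
#'
#' 1/3 of the samples when n > 30, otherwise 1/5, rounded half away from
#' zero. The n = 30 boundary is assigned to the 1/5 rule (the conservative
#' smaller test set).
#'
#' @param n Number of samples.
#' @return Integer test-set size.
#' @export
cv_test_size <- function(n) {
  as.integer(if (n > 30) round_half_up(n / 3) else round_half_up(n / 5))
}

#' Draw a random cross-validation test set
#'
#' Samples `size` indices uniformly without replacement. For classification,
#' the draw is repeated (up to `max_attempts`) until the training set retains
#' every class.
#'
#' @param n Number of samples (>= 5).
#' @param classes Optional class labels (length n) for the class-presence
#'   guard.
#' @param size Test-set size; defaults to [cv_test_size()].
#' @param max_attempts Redraw limit before declaring the class balance
#'   degenerate.
#' @return Sorted integer vector of test indices.
#' @export
cv_split <- function(n, classes = NULL, size = cv_test_size(n),
                     max_attempts = 100) {
  if (n < 5) abort("need at least 5 samples to split")
  for (i in seq_len(max_attempts)) {
    test <- sort(sample.int(n, size))
    if (is.null(classes)) return(test)
    if (all(unique(as.character(classes)) %in%
              as.character(classes)[-test])) {
      return(test)
    }
  }
  abort("could not draw a split leaving every class in the training set (degenerate class balance)")
}

# one CV pass: n_iter random splits, metric for each LV count 1..max_lv.
# Returns an n_iter x max_lv matrix; NA where a fold's rank ruled an LV out.
.cv_run <- function(x, y, kind, max_lv, n_iter, positive_class = NULL) {
  n <- nrow(x)
  size <- cv_test_size(n)
  classes <- if (kind == "classes") sort(unique(as.character(y)))
  out <- matrix(NA_real_, n_iter, max_lv)
  for (it in seq_len(n_iter)) {
    test <- cv_split(n, classes = if (kind == "classes") y, size = size)
    fit <- .pls_train(x[-test, , drop = FALSE], y[-test], max_lv, kind,
                      classes = classes, positive_class = positive_class)
    pr <- .pls_predict_all(fit, x[test, , drop = FALSE])
    for (a in seq_len(fit$a_used)) {
      out[it, a] <- if (kind == "continuous") {
        rmsecv(pr[, 1, a], as.numeric(y)[test])
      } else {
        yh <- matrix(pr[, , a], ncol = length(classes))
        class_accuracy(.argmax_class(yh, classes), y[test])
      }
    }
  }
  out
}

#' Select the number of latent variables by repeated random-subsampling CV
#'
#' For each of `n_iterations` random test/train splits, PLS models with 1 to
#' `max_lv` latent variables are fitted on the training set and scored on the
#' test set (RMSECV for a continuous response, classification accuracy for
#' classes). The LV count with the best mean metric (lowest error / highest
#' accuracy) is chosen; ties break to the smallest count. Fully reproducible
#' under `seed`.
#'
#' @inheritParams pls_fit
#' @param max_lv Largest LV count to evaluate (default 5).
#' @param n_iterations Number of random splits (default 100).
#' @param seed Integer seed.
#' @return A `pls_cv` object: per-LV mean metrics, the chosen LV count, and
#'   the full iteration-by-LV metric matrix.
#' @export
pls_cv <- function(data, response, predictors = NULL, max_lv = 5,
                   n_iterations = 100, seed = 1L, positive_class = NULL) {
  stopifnot(max_lv >= 1, n_iterations >= 1)
  xy <- .resolve_xy(data, response, predictors)
  if (nrow(xy$x) < 10) abort("need at least 10 samples for cross-validation")
  max_lv <- min(max_lv, nrow(xy$x) - cv_test_size(nrow(xy$x)) - 1L, ncol(xy$x))
  m <- withr::with_seed(seed,
    .cv_run(xy$x, xy$y, xy$kind, max_lv, n_iterations, positive_class))
  metric <- if (xy$kind == "continuous") "rmsecv" else "accuracy"
  per_lv <- tibble(n_lv = seq_len(max_lv),
                   mean_metric = colMeans(m, na.rm = TRUE),
                   n_models = colSums(!is.na(m)))
  ok <- per_lv$n_models > 0
  chosen <- if (metric == "rmsecv") {
    per_lv$n_lv[ok][which.min(per_lv$mean_metric[ok])]
  } else {
    per_lv$n_lv[ok][which.max(per_lv$mean_metric[ok])]
  }
  structure(list(metric = metric, per_lv = per_lv, chosen_lv = chosen,
                 iterations = m, n = nrow(xy$x),
                 test_size = cv_test_size(nrow(xy$x)),
                 n_iterations = n_iterations, response = response,
                 kind = xy$kind, seed = seed),
            class = "pls_cv")
}

#' Permutation significance test for a PLS model
#'
#' The response is randomly shuffled among samples (preserving the predictor
#' landscape); the full cross-validation procedure is re-run at the fixed,
#' previously chosen LV count for each permutation; and the real model's mean
#' CV metric is compared with the mean and standard deviation of the null
#' distribution: `z = (real - mu0) / sd0` for accuracy (sign flipped for
#' RMSECV, where smaller is better) and `p` is the upper normal tail of `z`.
#'
#' @inheritParams pls_cv
#' @param n_lv The LV count of the "real" model (from [pls_cv()]), preserved
#'   across permutations.
#' @param n_permutations Number of label shuffles (default 1000).
#' @return A `pls_permutation` object with the real metric, the null metric
#'   draws, `mu0`, `sd0`, `z` and `p`.
#' @export
pls_permutation <- function(data, response, n_lv, predictors = NULL,
                            n_permutations = 1000, n_iterations = 100,
                            seed = 1L, positive_class = NULL) {
  stopifnot(n_lv >= 1, n_permutations >= 2)
  xy <- .resolve_xy(data, response, predictors)
  res <- withr::with_seed(seed, {
    real <- mean(.cv_run(xy$x, xy$y, xy$kind, n_lv, n_iterations,
                         positive_class)[, n_lv], na.rm = TRUE)
    null <- vapply(seq_len(n_permutations), function(b) {
      yb <- sample(xy$y)
      mean(.cv_run(xy$x, yb, xy$kind, n_lv, n_iterations,
                   positive_class)[, n_lv], na.rm = TRUE)
    }, numeric(1))
    list(real = real, null = null)
  })
  mu0 <- mean(res$null)
  sd0 <- sd(res$null)
  if (!is.finite(sd0) || sd0 == 0) {
    abort("null metric distribution has zero spread; permutation p undefined (all permuted models scored identically)")
  }
  metric <- if (xy$kind == "continuous") "rmsecv" else "accuracy"
  z <- if (metric == "accuracy") (res$real - mu0) / sd0 else
    (mu0 - res$real) / sd0
  structure(list(metric = metric, real = res$real, null = res$null,
                 mu0 = mu0, sd0 = sd0, z = z,
                 p = pnorm(z, lower.tail = FALSE),
                 n_lv = n_lv, n_permutations = n_permutations,
                 n_iterations = n_iterations, seed = seed),
            class = "pls_permutation")
}

#' @export
print.pls_cv <- function(x, ...) {
  cat(sprintf("PLS cross-validation (%s response, n = %d, test size = %d, %d iterations)\n",
              x$kind, x$n, x$test_size, x$n_iterations))
  print(as.data.frame(x$per_lv), row.names = FALSE)
  cat(sprintf("chosen: %d LV (%s = %.4g)\n", x$chosen_lv, x$metric,
              x$per_lv$mean_metric[x$per_lv$n_lv == x$chosen_lv]))
  invisible(x)
}

#' @export
print.pls_permutation <- function(x, ...) {
  cat(sprintf("Permutation test (%d permutations, %d LV)\n",
              x$n_permutations, x$n_lv))
  cat(sprintf("  real %s = %.4g; null %.4g +/- %.4g; z = %.3g; p = %.3g\n",
              x$metric, x$real, x$mu0, x$sd0, x$z, x$p))
  invisible(x)
}

#' @export
tidy.pls_cv <- function(x, ...) x$per_lv

#' @export
glance.pls_cv <- function(x, ...) {
  tibble(metric = x$metric, chosen_lv = x$chosen_lv,
         best_metric = x$per_lv$mean_metric[x$per_lv$n_lv == x$chosen_lv],
         n = x$n, test_size = x$test_size, n_iterations = x$n_iterations)
}

#' @export
glance.pls_permutation <- function(x, ...) {
  tibble(metric = x$metric, real = x$real, null_mean = x$mu0,
         null_sd = x$sd0, z = x$z, p = x$p, n_lv = x$n_lv,
         n_permutations = x$n_permutations)
}
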