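# NIPALS partial least squares core: scaling, PLSR / PLS-DA fitting,
# prediction, post-hoc orthogonalization, VIP scores and signature extraction.

# ---- internal engine ---------------------------------------------------------

# z-scale keeping all columns; constant columns get scale 1 (they become all
# zeros and carry no weight). Used on CV training folds where silent handling
# of degenerate columns is wanted.
.zscale <- function(x) {
  n <- nrow(x)
  center <- colMeans(x)
  ss <- colSums(x ^ 2) - n * center ^ 2
  scl <- sqrt(pmax(ss, 0) / (n - 1))
  scl[!is.finite(scl) | scl < 1e-12] <- 1
  xs <- (x - rep(center, each = n)) / rep(scl, each = n)
  list(x = xs, center = center, scale = scl)
}

.dummy <- function(y, classes) {
  m <- matrix(0, length(y), length(classes),
              dimnames = list(NULL, classes))
  m[cbind(seq_along(y), match(as.character(y), classes))] <- 1
  m
}

# NIPALS with deflation of X only. xs, ys already scaled. Stops early (a_used
# < a) if the score norm collapses, i.e. the requested rank is unavailable.
.nipals <- function(xs, ys, a, tol = 1e-10, max_iter = 500) {
  n <- nrow(xs); p <- ncol(xs); m <- ncol(ys)
  W <- matrix(0, p, a); P <- matrix(0, p, a)
  TT <- matrix(0, n, a); Q <- matrix(0, m, a)
  ssy <- numeric(a)
  xc <- xs
  a_used <- 0L
  # a two-class dummy response has rank 1 after scaling (the columns are
  # exact negatives), so the NIPALS inner loop has a closed-form fixed point
  rank1 <- m == 1L ||
    (m == 2L && max(abs(ys[, 1] + ys[, 2])) < 1e-10)
  for (comp in seq_len(a)) {
    if (rank1) {
      w <- crossprod(xc, ys[, 1])[, 1]
      nw <- sqrt(sum(w ^ 2))
      if (nw < 1e-12) break
      w <- w / nw
      tt <- xc %*% w
      tt2 <- sum(tt ^ 2)
      if (tt2 < 1e-12) break
      q <- crossprod(ys, tt)[, 1] / tt2
    } else {
      u <- ys[, which.max(colSums(ys ^ 2))]
      w_old <- rep(0, p)
      for (it in seq_len(max_iter)) {
        w <- crossprod(xc, u)[, 1]
        nw <- sqrt(sum(w ^ 2))
        if (nw < 1e-12) break
        w <- w / nw
        tt <- xc %*% w
        tt2 <- sum(tt ^ 2)
        if (tt2 < 1e-12) break
        q <- crossprod(ys, tt)[, 1] / tt2
        u <- (ys %*% q) / sum(q ^ 2)
        if (sum((w - w_old) ^ 2) < tol ^ 2) break
        w_old <- w
      }
      if (nw < 1e-12 || tt2 < 1e-12) break
    }
    pp <- crossprod(xc, tt)[, 1] / tt2
    xc <- xc - tcrossprod(tt, pp)
    W[, comp] <- w; P[, comp] <- pp; TT[, comp] <- tt; Q[, comp] <- q
    ssy[comp] <- tt2 * sum(q ^ 2)  # Y sum of squares captured by component
    a_used <- comp
  }
  if (a_used == 0L) abort("NIPALS failed: predictor matrix has no usable variance")
  idx <- seq_len(a_used)
  list(W = W[, idx, drop = FALSE], P = P[, idx, drop = FALSE],
       T = TT[, idx, drop = FALSE], Q = Q[, idx, drop = FALSE],
       ssy = ssy[idx], a_used = a_used)
}

# fit on raw (unscaled) training data; minimal object used by CV loops
.pls_train <- function(x, y, a, kind, classes = NULL,
                       positive_class = NULL) {
  xsc <- .zscale(x)
  if (kind == "classes") {
    classes <- classes %||% sort(unique(as.character(y)))
    if (length(unique(as.character(y))) < 2) {
      abort("PLS-DA requires at least two classes in the training data")
    }
    yraw <- .dummy(y, classes)
  } else {
    yraw <- matrix(as.numeric(y), ncol = 1)
  }
  ysc <- .zscale(yraw)
  a <- min(a, nrow(x) - 1L, ncol(x))
  nip <- .nipals(xsc$x, ysc$x, a)

  # orient LV1 toward the positive response pole: increasing response
  # (continuous) or the positive class (DA; default first sorted class)
  ref <- 1L
  if (kind == "classes" && !is.null(positive_class)) {
    ref <- match(positive_class, classes)
    if (is.na(ref)) abort("`positive_class` is not one of the class labels")
  }
  s <- sum(nip$T[, 1] * ysc$x[, ref])
  if (s < 0) {
    nip$W[, 1] <- -nip$W[, 1]; nip$P[, 1] <- -nip$P[, 1]
    nip$T[, 1] <- -nip$T[, 1]; nip$Q[, 1] <- -nip$Q[, 1]
  }
  B <- nip$W %*% solve(crossprod(nip$P, nip$W), t(nip$Q))
  list(nipals = nip, B = B, kind = kind, classes = classes,
       positive_class = if (kind == "classes") {
         positive_class %||% classes[1]
       },
       x_center = xsc$center, x_scale = xsc$scale,
       y_center = ysc$center, y_scale = ysc$scale,
       a_used = nip$a_used)
}

# per-component test-set predictions: returns array n_new x m x A of
# cumulative predictions on the original response scale
.pls_predict_all <- function(fit, xnew) {
  nip <- fit$nipals
  xn <- sweep(sweep(xnew, 2, fit$x_center), 2, fit$x_scale, "/")
  a <- nip$a_used
  m <- nrow(nip$Q)
  tn <- matrix(0, nrow(xn), a)
  for (comp in seq_len(a)) {
    tn[, comp] <- xn %*% nip$W[, comp]
    xn <- xn - tcrossprod(tn[, comp], nip$P[, comp])
  }
  out <- array(0, c(nrow(xnew), m, a))
  acc <- matrix(0, nrow(xnew), m)
  for (comp in seq_len(a)) {
    acc <- acc + tcrossprod(tn[, comp], nip$Q[, comp])
    out[, , comp] <- sweep(sweep(acc, 2, fit$y_scale, "*"), 2, fit$y_center,
                           "+")
  }
  out
}

.argmax_class <- function(yhat, classes) {
  classes[max.col(yhat, ties.method = "first")]
}

# resolve predictor matrix + response vector from a data frame
.resolve_xy <- function(data, response, predictors = NULL) {
  assert_cols(data, response, "`data`")
  meta <- c("sample_id", "genotype", "age_days", "sex", response)
  predictors <- predictors %||% setdiff(
    names(data)[vapply(data, is.numeric, logical(1))], meta)
  if (length(predictors) == 0) abort("no predictor columns found")
  assert_cols(data, predictors, "`data`")
  x <- as.matrix(data[, predictors, drop = FALSE])
  storage.mode(x) <- "double"
  y <- data[[response]]
  kind <- if (is.numeric(y)) "continuous" else "classes"
  list(x = x, y = y, kind = kind, predictors = predictors)
}

# ---- exported surface --------------------------------------------------------

#' Mean-center and unit-variance scale a predictor matrix
#'
#' Per-column z-scoring with the n-1 SD denominator. Constant columns cannot
#' be scaled and are dropped with a warning. The transform is invertible for
#' retained columns via [pls_unscale()].
#'
#' @param x Numeric matrix or data frame (>= 2 rows).
#' @return A `pls_scaled` list: `x` (scaled matrix), `center`, `scale`,
#'   `dropped` (names of dropped constant columns).
#' @export
pls_scale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("need at least 2 samples to scale")
  scl <- apply(x, 2, sd)
  bad <- !is.finite(scl) | scl < 1e-12
  if (any(bad)) {
    warn(sprintf("dropping constant column(s): %s",
                 paste(colnames(x)[bad], collapse = ", ")))
    x <- x[, !bad, drop = FALSE]
    scl <- scl[!bad]
  }
  center <- colMeans(x)
  structure(list(x = sweep(sweep(x, 2, center), 2, scl, "/"),
                 center = center, scale = scl,
                 dropped = names(bad)[bad] %||% character()),
            class = "pls_scaled")
}

#' Invert the scaling of a [pls_scale()] object
#'
#' @param scaled A `pls_scaled` object.
#' @param x Scaled matrix to back-transform (defaults to `scaled$x`).
#' @return Matrix on the original scale.
#' @export
pls_unscale <- function(scaled, x = NULL) {
  stopifnot(inherits(scaled, "pls_scaled"))
  x <- x %||% scaled$x
  sweep(sweep(x, 2, scaled$scale, "*"), 2, scaled$center, "+")
}

#' Fit a PLS regression or discriminant-analysis model
#'
#' NIPALS components on mean-centered, unit-variance-scaled predictors (and
#' response). A numeric response gives PLS regression; a factor or character
#' response gives PLS-DA via dummy coding (one scaled indicator column per
#' class, argmax classification). X is deflated per component; the first
#' weight vector maximizes the covariance of the predictor projection with
#' the response under a unit-norm constraint.
#'
#' @param data Data frame / tibble, one row per sample.
#' @param response Name of the response column.
#' @param n_lv Number of latent variables (>= 1, <= min(n-1, p)).
#' @param predictors Predictor column names; defaults to all numeric columns
#'   except the response and the standard metadata columns (`sample_id`,
#'   `genotype`, `age_days`, `sex`).
#' @param positive_class For PLS-DA, the class defining the positive pole of
#'   LV1 (signature "up" direction). Defaults to the first sorted class label.
#' @return A `pls_model` object.
#' @export
pls_fit <- function(data, response, n_lv = 2, predictors = NULL,
                    positive_class = NULL) {
  xy <- .resolve_xy(data, response, predictors)
  n <- nrow(xy$x); p <- ncol(xy$x)
  if (n_lv < 1) abort("`n_lv` must be >= 1")
  if (n_lv > min(n - 1, p)) {
    abort(sprintf("`n_lv` = %d exceeds min(n - 1, p) = %d", n_lv,
                  min(n - 1, p)))
  }
  scl <- apply(xy$x, 2, sd)
  if (any(!is.finite(scl) | scl < 1e-12)) {
    warn(sprintf("dropping constant predictor column(s): %s",
                 paste(colnames(xy$x)[!is.finite(scl) | scl < 1e-12],
                       collapse = ", ")))
    xy$x <- xy$x[, is.finite(scl) & scl >= 1e-12, drop = FALSE]
    xy$predictors <- colnames(xy$x)
  }
  fit <- .pls_train(xy$x, xy$y, n_lv, xy$kind,
                    positive_class = positive_class)
  if (fit$a_used < n_lv) {
    warn(sprintf("rank limited the fit to %d latent variable(s)", fit$a_used))
  }
  structure(
    c(fit,
      list(n_lv = fit$a_used, variables = xy$predictors, response = response,
           y = xy$y, x = xy$x,
           pre = list(W = fit$nipals$W, ssy = fit$nipals$ssy),
           orthogonalized = FALSE)),
    class = "pls_model")
}

#' Predict from a PLS model
#'
#' Applies the stored scaling and regression coefficients to new data.
#'
#' @param object A `pls_model`.
#' @param new_data Data frame or matrix containing the model's predictor
#'   variables (any extra columns are ignored).
#' @param type `"response"` for continuous predictions (PLSR) or per-class
#'   scores (PLS-DA); `"class"` for PLS-DA labels; `"scores"` for latent
#'   variable scores.
#' @param ... Unused.
#' @return Numeric vector, per-class score matrix, class label vector, or
#'   score matrix, depending on `type`.
#' @export
predict.pls_model <- function(object, new_data,
                              type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  if (is.data.frame(new_data)) {
    assert_cols(new_data, object$variables, "`new_data`")
    xnew <- as.matrix(new_data[, object$variables, drop = FALSE])
  } else {
    xnew <- as.matrix(new_data)
    if (!is.null(colnames(xnew))) {
      missing <- setdiff(object$variables, colnames(xnew))
      if (length(missing)) {
        abort(sprintf("`new_data` is missing variable(s): %s",
                      paste(missing, collapse = ", ")))
      }
      xnew <- xnew[, object$variables, drop = FALSE]
    } else if (ncol(xnew) != length(object$variables)) {
      abort("`new_data` has the wrong number of columns")
    }
  }
  storage.mode(xnew) <- "double"
  xn <- sweep(sweep(xnew, 2, object$x_center), 2, object$x_scale, "/")
  if (type == "scores") {
    a <- object$n_lv
    tn <- matrix(0, nrow(xn), a,
                 dimnames = list(NULL, paste0("LV", seq_len(a))))
    # score reconstruction uses R = W (P'W)^-1 so it is exact for deflated
    # NIPALS components and remains exact after basis rotation
    R <- object$nipals$W %*% solve(crossprod(object$nipals$P,
                                             object$nipals$W))
    return(xn %*% R)
  }
  ys <- xn %*% object$B
  yhat <- sweep(sweep(ys, 2, object$y_scale, "*"), 2, object$y_center, "+")
  if (object$kind == "continuous") {
    if (type == "class") abort("`type = \"class\"` requires a PLS-DA model")
    return(drop(yhat))
  }
  colnames(yhat) <- object$classes
  if (type == "class") .argmax_class(yhat, object$classes) else yhat
}

#' Classify samples with a PLS-DA model
#'
#' Labels are assigned by the argmax over dummy-column predictions, with a
#' deterministic tie-break to the first class in sorted label order.
#'
#' @param model A PLS-DA `pls_model`.
#' @param new_data Data with the model's predictor variables.
#' @return Character vector of class labels.
#' @export
pls_classify <- function(model, new_data) {
  if (model$kind != "classes") abort("`model` is not a PLS-DA model")
  predict(model, new_data, type = "class")
}

#' Orthogonalize a fitted PLS model
#'
#' Rotates the latent-variable basis so that LV1 carries all of the
#' response-predictive covariation (target-projection style) and the
#' remaining LVs are orthogonal to the fitted response. Predictions and
#' regression coefficients are unchanged to machine precision; scores and
#' loadings plots change. A 1-LV model is returned unchanged (nothing to
#' rotate). VIP scores are always computed from the pre-rotation components.
#'
#' @param model A fitted `pls_model`.
#' @return The rotated `pls_model` with `orthogonalized = TRUE`.
#' @export
pls_orthogonalize <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (model$orthogonalized) return(model)
  a <- model$n_lv
  if (a == 1L) {
    model$orthogonalized <- TRUE
    return(model)
  }
  nip <- model$nipals
  d <- sqrt(colSums(nip$T ^ 2))
  t_til <- sweep(nip$T, 2, d, "/")          # orthonormal score basis
  ref <- if (model$kind == "classes") {
    match(model$positive_class, model$classes)
  } else 1L
  v <- d * nip$Q[ref, ]                      # fitted-response direction in basis
  if (sqrt(sum(v ^ 2)) < 1e-12) {
    warn("response loadings are all ~0; orthogonalization left model unchanged")
    model$orthogonalized <- TRUE
    return(model)
  }
  r1 <- v / sqrt(sum(v ^ 2))
  M <- diag(a); M[, 1] <- r1
  R <- qr.Q(qr(M))
  if (sum(R[, 1] * r1) < 0) R <- -R
  T_new <- t_til %*% R
  P_new <- nip$P %*% (d * R)                 # diag(d) %*% R
  Q_new <- nip$Q %*% (d * R)
  model$nipals$T <- T_new
  model$nipals$P <- P_new
  model$nipals$Q <- Q_new
  model$orthogonalized <- TRUE
  model
}

#' Variable importance in projection (VIP) scores
#'
#' Per-variable summary of contribution to the model's predictive accuracy
#' across latent variables:
#' `VIP_j = sqrt(p * sum_a SS_a w_aj^2 / sum_a SS_a)` with unit-norm weight
#' vectors `w_a` and `SS_a` the response sum of squares captured by component
#' `a`. Computed from the pre-orthogonalization components (the rotation-
#' invariant convention); for a 1-LV model only LV1 enters. The mean squared
#' VIP equals 1 by construction.
#'
#' @param model A fitted `pls_model`.
#' @return Tibble `variable, vip`.
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  W <- model$pre$W
  ssy <- model$pre$ssy
  p <- nrow(W)
  v <- sqrt(p * as.numeric(W ^ 2 %*% ssy) / sum(ssy))
  tibble(variable = model$variables, vip = v)
}

#' Extract the VIP > 1 signature of a PLS model
#'
#' Variables with a VIP score strictly greater than 1 (above-average
#' contribution), annotated with their LV1 loading and direction relative to
#' the positive response pole: positive LV1 loading means up-regulated with
#' increasing response (PLSR) or in the positive class (PLS-DA). The model is
#' orthogonalized first if it is not already, so LV1 carries the predictive
#' covariation.
#'
#' @param model A fitted `pls_model`.
#' @return Tibble `variable, vip, loading_lv1, direction` of class
#'   `pls_signature`, sorted by decreasing VIP.
#' @export
pls_signature <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  model <- pls_orthogonalize(model)
  v <- vip(model)
  load1 <- model$nipals$P[, 1]
  out <- v |>
    dplyr::mutate(loading_lv1 = load1,
                  direction = ifelse(load1 >= 0, "up", "down")) |>
    dplyr::filter(.data$vip > 1) |>
    dplyr::arrange(dplyr::desc(.data$vip))
  class(out) <- c("pls_signature", class(out))
  attr(out, "positive_pole") <- if (model$kind == "classes") {
    model$positive_class
  } else {
    sprintf("increasing %s", model$response)
  }
  out
}
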