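# broom-style and plotting methods for fitted PLS objects

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS %s model: %d latent variable(s), %d variables, n = %d%s\n",
              if (x$kind == "classes") "discriminant-analysis" else "regression",
              x$n_lv, length(x$variables), nrow(x$x),
              if (x$orthogonalized) " (orthogonalized)" else ""))
  if (x$kind == "classes") {
    cat(sprintf("  classes: %s (positive pole: %s)\n",
                paste(x$classes, collapse = ", "), x$positive_class))
  }
  sig <- tryCatch(pls_signature(x), error = function(e) NULL)
  if (!is.null(sig) && nrow(sig)) {
    cat(sprintf("  VIP > 1 signature: %s\n",
                paste(sprintf("%s (%s)", sig$variable, sig$direction),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Tidy a PLS model into a per-variable, per-component tibble
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Tibble `variable, component, weight, loading, vip` (weights are the
#'   pre-orthogonalization NIPALS weights; loadings reflect any rotation).
#' @export
tidy.pls_model <- function(x, ...) {
  a <- x$n_lv
  v <- vip(x)
  tibble(variable = rep(x$variables, a),
         component = rep(seq_len(a), each = length(x$variables)),
         weight = as.numeric(x$pre$W),
         loading = as.numeric(x$nipals$P),
         vip = rep(v$vip, a))
}

#' One-row model summary
#'
#' @param x A `pls_model`.
#' @param ... Unused.
#' @return Tibble with sample/variable counts, LV count, response kind, the
#'   fraction of (scaled) response variance explained, and the
#'   orthogonalization flag.
#' @export
glance.pls_model <- function(x, ...) {
  yraw <- if (x$kind == "classes") .dummy(x$y, x$classes) else
    matrix(as.numeric(x$y), ncol = 1)
  ysc <- .zscale(yraw)
  fitted <- x$nipals$T %*% t(x$nipals$Q)
  r2y <- 1 - sum((ysc$x - fitted) ^ 2) / sum(ysc$x ^ 2)
  tibble(n = nrow(x$x), n_variables = length(x$variables), n_lv = x$n_lv,
         kind = x$kind, r2y = r2y, orthogonalized = x$orthogonalized)
}

# second latent direction computed for display only when a model has 1 LV
# (it enters no error, p-value or VIP computation)
.viz_lv2 <- function(x) {
  xsc <- .zscale(x$x)
  nip <- x$nipals
  x1 <- xsc$x - tcrossprod(nip$T[, 1], nip$P[, 1])
  yraw <- if (x$kind == "classes") .dummy(x$y, x$classes) else
    matrix(as.numeric(x$y), ncol = 1)
  ysc <- .zscale(yraw)
  w2 <- crossprod(x1, ysc$x[, 1])[, 1]
  nw <- sqrt(sum(w2 ^ 2))
  if (nw < 1e-12) return(rep(0, nrow(x$x)))
  as.numeric(x1 %*% (w2 / nw))
}

#' Scores plot of a PLS model
#'
#' LV1 vs LV2 scores, one point per sample. For a 1-LV model a second latent
#' direction is computed for visualization only and labelled as such; it is
#' excluded from error, p-value and VIP computation.
#'
#' @param object A `pls_model`.
#' @param data Optional tibble aligned with the training rows supplying
#'   aesthetic columns.
#' @param colour,shape Optional column names in `data` mapped to colour/shape
#'   (e.g. age and sex).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pls_model <- function(object, data = NULL, colour = NULL,
                               shape = NULL, ...) {
  df <- tibble(LV1 = object$nipals$T[, 1],
               LV2 = if (object$n_lv >= 2) object$nipals$T[, 2] else
                 .viz_lv2(object))
  lab2 <- if (object$n_lv >= 2) "Scores on LV2" else
    "LV2 (visualization only)"
  if (!is.null(data)) df <- dplyr::bind_cols(df, data)
  aes <- ggplot2::aes(x = .data$LV1, y = .data$LV2)
  if (!is.null(colour)) aes$colour <- rlang::sym(colour)
  if (!is.null(shape)) aes$shape <- rlang::sym(shape)
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = "Scores on LV1", y = lab2) +
    ggplot2::theme_classic()
}

#' LV1 loadings plot with the VIP > 1 signature highlighted
#'
#' Bar plot of LV1 loadings ordered by value; variables with VIP score > 1
#' (the signature) are filled by direction, all others grey.
#'
#' @param model A `pls_model` (orthogonalized first if needed, so LV1 carries
#'   the predictive covariation).
#' @return A ggplot object.
#' @export
plot_loadings <- function(model) {
  model <- pls_orthogonalize(model)
  v <- vip(model)
  df <- tibble(variable = model$variables,
               loading = model$nipals$P[, 1],
               vip = v$vip) |>
    dplyr::mutate(signature = dplyr::case_when(
      .data$vip > 1 & .data$loading >= 0 ~ "up",
      .data$vip > 1 ~ "down",
      TRUE ~ "below-average")) |>
    dplyr::arrange(.data$loading) |>
    dplyr::mutate(variable = factor(.data$variable, levels = .data$variable))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$loading,
                                   fill = .data$signature)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(up = "#c0392b", down = "#2980b9",
                                          `below-average` = "grey70")) +
    ggplot2::labs(x = NULL, y = "Loadings on LV1", fill = "VIP > 1") +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' @export
print.pls_signature <- function(x, ...) {
  cat(sprintf("Cytokine signature (VIP > 1; positive pole: %s)\n",
              attr(x, "positive_pole")))
  NextMethod()
}
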