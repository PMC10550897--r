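toy_data <- function(n = 20, p = 6, seed = 1, beta = NULL) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", 1:p)))
    beta <- beta %||% c(2, -1, rep(0, p - 2))
    y <- drop(x %*% beta) + rnorm(n, 0, 0.3)
    dplyr::bind_cols(tibble::as_tibble(x), tibble::tibble(y = y))
  })
}

test_that("scaling z-scores columns, drops constants, and round-trips", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 8, 14))
  expect_warning(s <- pls_scale(x), "constant")
  expect_equal(unname(s$x[, "a"]), c(-1, 0, 1))
  expect_equal(s$dropped, "b")
  expect_equal(colMeans(s$x), c(a = 0, c = 0), tolerance = 1e-10)
  expect_equal(apply(s$x, 2, sd), c(a = 1, c = 1), tolerance = 1e-10)
  expect_equal(pls_unscale(s), x[, c("a", "c")], tolerance = 1e-10)
})

test_that("the first PLS weight is the normalized X'y covariance direction", {
  for (seed in 1:5) {
    d <- toy_data(n = 5, p = 3, seed = seed)
    m <- pls_fit(d, "y", n_lv = 1)
    xs <- cytosig:::.zscale(as.matrix(d[, 1:3]))$x
    ys <- cytosig:::.zscale(matrix(d$y, ncol = 1))$x
    w_direct <- drop(crossprod(xs, ys))
    w_direct <- w_direct / sqrt(sum(w_direct^2))
    w_fit <- m$nipals$W[, 1] * sign(sum(m$nipals$W[, 1] * w_direct))
    expect_equal(w_fit, unname(w_direct), tolerance = 1e-10)
  }
})

test_that("an exactly linear response is fitted perfectly by one LV", {
  # orthogonal predictor columns, so the covariance direction isolates v2
  withr::with_seed(3, {
    x0 <- scale(matrix(rnorm(15 * 4), 15, 4), scale = FALSE)
    x <- qr.Q(qr(x0))  # centered (span of centered columns) and orthogonal
    colnames(x) <- paste0("v", 1:4)
  })
  d <- dplyr::bind_cols(tibble::as_tibble(x), tibble::tibble(y = 3 * x[, 2]))
  m <- pls_fit(d, "y", n_lv = 1)
  expect_equal(predict(m, d), d$y, tolerance = 1e-8)
})

test_that("coefficient and score-loading predictions agree", {
  d <- toy_data(n = 20, p = 6, seed = 4)
  m <- pls_fit(d, "y", n_lv = 3)
  from_b <- predict(m, d)
  from_tq <- drop(m$nipals$T %*% t(m$nipals$Q)) * m$y_scale + m$y_center
  expect_equal(from_b, from_tq, tolerance = 1e-10)
})

test_that("scores are orthogonal and weights unit-norm after every fit", {
  for (a in 1:4) {
    d <- toy_data(n = 25, p = 8, seed = a + 10)
    m <- pls_fit(d, "y", n_lv = a)
    g <- crossprod(m$nipals$T)
    off <- abs(g[upper.tri(g)])
    if (length(off)) expect_lt(max(off / diag(g)[1]), 1e-8)
    expect_equal(colSums(m$nipals$W^2), rep(1, a), tolerance = 1e-10)
  }
})

test_that("prediction handles training data, duplicates, and variable mismatch", {
  d <- toy_data(n = 18, p = 5, seed = 6)
  m <- pls_fit(d, "y", n_lv = 2)
  expect_equal(predict(m, d), unname(drop(m$nipals$T %*% t(m$nipals$Q)) *
                                      m$y_scale + m$y_center),
               tolerance = 1e-10)
  dup <- d[c(1, 1, 2), ]
  pr <- predict(m, dup)
  expect_equal(pr[1], pr[2])
  expect_error(predict(m, d[, 1:3]), "missing")
})

test_that("PLS-DA classifies well-separated groups and respects relabeling", {
  withr::with_seed(8, {
    n <- 20
    x <- rbind(matrix(rnorm(n * 4, 0), n, 4), matrix(rnorm(n * 4, 4), n, 4))
    colnames(x) <- paste0("v", 1:4)
    d <- dplyr::bind_cols(tibble::as_tibble(x),
                          tibble::tibble(grp = rep(c("ctl", "case"), each = n)))
  })
  m <- pls_fit(d, "grp", n_lv = 1)
  expect_equal(class_accuracy(pls_classify(m, d), d$grp), 1)

  # relabeling equivariance: renamed classes give the same partition
  d2 <- d
  d2$grp <- ifelse(d$grp == "ctl", "B", "A")
  m2 <- pls_fit(d2, "grp", n_lv = 1)
  map <- c(ctl = "B", case = "A")
  expect_equal(unname(map[pls_classify(m, d)]), pls_classify(m2, d2))

  expect_error(pls_fit(dplyr::mutate(d, grp = "one"), "grp", n_lv = 1),
               "two classes")
  reg <- pls_fit(toy_data(), "y", n_lv = 1)
  expect_error(pls_classify(reg, toy_data()), "not a PLS-DA")
})

test_that("orthogonalization preserves predictions and isolates Y-covariation on LV1", {
  d <- toy_data(n = 30, p = 10, seed = 9)
  m <- pls_fit(d, "y", n_lv = 3)
  mo <- pls_orthogonalize(m)
  expect_lt(max(abs(predict(m, d) - predict(mo, d))), 1e-10)
  # later LVs carry no response correlation after rotation
  for (a in 2:3) expect_lt(abs(cor(mo$nipals$T[, a], d$y)), 1e-8)
  # scores remain orthonormal-orthogonal
  g <- crossprod(mo$nipals$T)
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8 * max(diag(g)))
  # 1-LV model unchanged
  m1 <- pls_fit(d, "y", n_lv = 1)
  m1o <- pls_orthogonalize(m1)
  expect_equal(m1$nipals$T, m1o$nipals$T)
  expect_equal(m1$nipals$P, m1o$nipals$P)
})

test_that("VIP scores satisfy their closed forms and normalization identity", {
  # weight concentrated on one variable: VIP_1 = sqrt(p), rest 0
  n <- 12
  withr::with_seed(10, {
    v1 <- rnorm(n)
    d <- tibble::tibble(v1 = v1, v2 = rnorm(n, 0, 1), v3 = rnorm(n),
                        v4 = rnorm(n), y = v1)
  })
  # make other columns orthogonal to y so weight concentrates on v1
  for (j in c("v2", "v3", "v4")) {
    d[[j]] <- residuals(lm(d[[j]] ~ d$v1))
  }
  m <- pls_fit(d, "y", n_lv = 1)
  v <- vip(m)
  expect_equal(v$vip[v$variable == "v1"], 2, tolerance = 1e-6)
  expect_lt(max(v$vip[v$variable != "v1"]), 1e-6)

  # normalization: sum of squared VIPs equals p on any fitted model
  for (a in 1:3) {
    m <- pls_fit(toy_data(n = 25, p = 7, seed = a), "y", n_lv = a)
    expect_equal(sum(vip(m)$vip^2), 7, tolerance = 1e-8)
  }
})

test_that("signature extraction uses strict VIP > 1 with signed LV1 directions", {
  # perfectly symmetric equal weights: all VIP exactly 1 -> empty signature
  withr::with_seed(11, {
    z <- rnorm(30)
    d <- tibble::tibble(v1 = z + rnorm(30, 0, 1e-8),
                        v2 = z + rnorm(30, 0, 1e-8), y = z)
  })
  m <- pls_fit(d, "y", n_lv = 1)
  expect_equal(vip(m)$vip, c(1, 1), tolerance = 1e-4)
  expect_equal(nrow(pls_signature(m)), 0)

  # planted directions on a discriminant model
  st <- simulate_cytokine_study(cytokine_sim_spec(n_per_group = 20, seed = 12))
  cl <- clean_cytokines(st)
  sig <- pls_signature(pls_fit(cl, "genotype", n_lv = 2))
  expect_true(all(st$truth$signature_up %in%
                    sig$variable[sig$direction == "up"]))
  expect_true(all(st$truth$signature_down %in%
                    sig$variable[sig$direction == "down"]))
})

test_that("column rescaling leaves scores, VIP and predictions unchanged", {
  d <- toy_data(n = 20, p = 5, seed = 13)
  m1 <- pls_fit(d, "y", n_lv = 2)
  d2 <- dplyr::mutate(d, v1 = v1 * 37.5, v3 = v3 * 0.004)
  m2 <- pls_fit(d2, "y", n_lv = 2)
  expect_equal(m1$nipals$T, m2$nipals$T, tolerance = 1e-9)
  expect_equal(vip(m1)$vip, vip(m2)$vip, tolerance = 1e-9)
  expect_equal(predict(m1, d), predict(m2, d2), tolerance = 1e-9)
})

test_that("rank constraints are enforced at fit time", {
  d <- toy_data(n = 6, p = 3, seed = 14)
  expect_error(pls_fit(d, "y", n_lv = 4), "exceeds")
  expect_error(pls_fit(d, "y", n_lv = 0), ">= 1")
})

test_that("the NIPALS fit matches an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  d <- toy_data(n = 25, p = 8, seed = 15)
  x <- as.matrix(d[, 1:8])
  m <- pls_fit(d, "y", n_lv = 3)
  ref <- mixOmics::pls(x, d$y, ncomp = 3, mode = "regression", scale = TRUE)
  pr_ref <- predict(ref, x)$predict[, 1, 3]
  expect_equal(unname(predict(m, d)), unname(pr_ref), tolerance = 1e-6)
  for (a in 1:3) {
    expect_equal(abs(unname(m$nipals$W[, a])),
                 abs(unname(ref$loadings$X[, a])), tolerance = 1e-6)
  }
})

test_that("tidy and glance summarize fitted models", {
  d <- toy_data(n = 20, p = 5, seed = 16)
  m <- pls_fit(d, "y", n_lv = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 10)
  expect_named(td, c("variable", "component", "weight", "loading", "vip"))
  gl <- glance(m)
  expect_equal(gl$n_lv, 2)
  expect_gt(gl$r2y, 0.9)
})

test_that("scores and loadings plots build without error", {
  st <- simulate_cytokine_study(cytokine_sim_spec(n_per_group = 10, seed = 17))
  cl <- clean_cytokines(st)
  m <- pls_fit(cl, "genotype", n_lv = 1)
  p1 <- autoplot(m, data = cl, colour = "genotype", shape = "sex")
  p2 <- plot_loadings(m)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  expect_no_error(ggplot2::ggplot_build(p1))
  expect_no_error(ggplot2::ggplot_build(p2))
})
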