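test_that("Mito Stress Test metrics follow the five calculation rows exactly", {
  tr <- manual_trace(baseline = c(100, 102, 98), oligo = c(45, 40, 42),
                     fccp = c(140, 150, 148), rot = c(20, 20, 20))
  m <- ocr_metrics(tr)
  expect_equal(m$non_mito, 20)
  expect_equal(m$basal, 80)
  expect_equal(m$atp_production, 40)
  expect_equal(m$maximal, 130)
  expect_equal(m$proton_leak, 20)

  # vendor ATP convention differs by exactly the non-mito term
  mv <- ocr_metrics(tr, atp_convention = "vendor")
  expect_equal(mv$atp_production, 60)

  z <- manual_trace(rep(0, 3), rep(0, 3), rep(0, 3), rep(0, 3))
  expect_true(all(as.matrix(ocr_metrics(z)[, c("non_mito", "basal",
                                               "atp_production", "maximal",
                                               "proton_leak")]) == 0))
  # missing phase errors by name
  expect_error(ocr_metrics(dplyr::filter(tr, phase != "post_FCCP")),
               "post_FCCP")
})

test_that("metric identities hold on arbitrary traces", {
  withr::with_seed(5, {
    for (i in 1:20) {
      tr <- manual_trace(runif(4, 0, 200), runif(3, 0, 200),
                         runif(5, 0, 300), runif(3, 0, 50))
      m <- ocr_metrics(tr)
      base_med <- median(tr$ocr[tr$phase == "baseline"])
      oligo_min <- min(tr$ocr[tr$phase == "post_oligomycin"])
      fccp_max <- max(tr$ocr[tr$phase == "post_FCCP"])
      expect_equal(m$basal + m$non_mito, base_med, tolerance = 1e-12)
      expect_equal(m$proton_leak + m$non_mito, oligo_min, tolerance = 1e-12)
      expect_equal(m$maximal + m$non_mito, fccp_max, tolerance = 1e-12)
      expect_equal(m$atp_production, m$basal - oligo_min, tolerance = 1e-12)
    }
  })
})

test_that("well QC excludes non-viable and FCCP-unresponsive wells with reasons", {
  flat <- manual_trace(rep(1, 3), rep(1, 3), rep(1, 3), rep(1, 3),
                       well = "dead")
  no_resp <- manual_trace(c(100, 100, 100), c(40, 41, 42), c(30, 33, 35),
                          c(20, 20, 20), well = "lazy")
  healthy <- manual_trace(c(100, 100, 100), c(40, 41, 42), c(150, 148, 149),
                          c(20, 20, 20), well = "ok")
  all_tr <- dplyr::bind_rows(flat, no_resp, healthy)
  kept <- ocr_qc(all_tr)
  exc <- attr(kept, "exclusions")
  expect_setequal(unique(kept$well), "ok")
  expect_equal(exc$reason[exc$well == "dead"], "near-zero OCR")
  expect_equal(exc$reason[exc$well == "lazy"], "no FCCP response")
  expect_error(ocr_qc(flat), "all wells failed")
})

test_that("protein normalization rescales by well protein relative to the plate mean", {
  a <- manual_trace(c(100, 100, 100), c(40, 40, 40), c(150, 150, 150),
                    c(20, 20, 20), well = "a", protein_ug = 10)
  b <- dplyr::mutate(manual_trace(c(100, 100, 100), c(40, 40, 40),
                                  c(150, 150, 150), c(20, 20, 20),
                                  well = "b", protein_ug = 20))
  out <- ocr_normalize_protein(dplyr::bind_rows(a, b))
  # plate mean protein = 15; well a scaled by 15/10, b by 15/20
  expect_equal(out$ocr[out$well == "a"][1], 150)
  expect_equal(out$ocr[out$well == "b"][1], 75)
  # equal-protein plate is untouched
  same <- dplyr::bind_rows(a, dplyr::mutate(a, well = "a2"))
  expect_equal(ocr_normalize_protein(same)$ocr, same$ocr)
  # within-well metric ratios preserved
  m_raw <- ocr_metrics(dplyr::bind_rows(a, b))
  m_norm <- ocr_metrics(out)
  expect_equal(m_norm$basal / m_norm$maximal, m_raw$basal / m_raw$maximal,
               tolerance = 1e-12)
  # nonpositive protein excluded and logged
  bad <- dplyr::mutate(a, well = "bad", protein_ug = 0)
  out2 <- ocr_normalize_protein(dplyr::bind_rows(a, bad))
  expect_setequal(unique(out2$well), "a")
  expect_equal(attr(out2, "exclusions")$well, "bad")
})

test_that("replicate aggregation averages well metrics", {
  m <- tibble::tibble(batch = c("B1", "B1", "B2"),
                      treatment = "vehicle",
                      non_mito = c(20, 22, 18), basal = c(70, 90, 80),
                      atp_production = c(40, 42, 41), maximal = c(120, 140, 130),
                      proton_leak = c(18, 20, 19))
  agg <- ocr_aggregate(m)
  expect_equal(agg$basal[agg$batch == "B1"], 80)
  expect_equal(agg$n_wells, c(2L, 1L))
})

test_that("non-mitochondrial normalization produces the hand-computed ratios", {
  m <- tibble::tibble(batch = "B1", treatment = "vehicle", non_mito = 20,
                      basal = 80, atp_production = 40, maximal = 130,
                      proton_leak = 20)
  out <- ocr_normalize_nonmito(m)
  expect_equal(unlist(out[, c("non_mito", "basal", "atp_production",
                              "maximal", "proton_leak")], use.names = FALSE),
               c(1, 4, 2, 6.5, 1))
  # monotone transform: equal non-mito preserves replicate ordering
  m2 <- dplyr::bind_rows(m, dplyr::mutate(m, basal = 60, batch = "B2"))
  out2 <- ocr_normalize_nonmito(m2)
  expect_equal(order(out2$basal), order(m2$basal))
  # nonpositive non-mito excluded
  m3 <- dplyr::bind_rows(m, dplyr::mutate(m, non_mito = 0, batch = "B3"))
  out3 <- ocr_normalize_nonmito(m3)
  expect_equal(out3$batch, "B1")
  expect_equal(attr(out3, "exclusions")$batch, "B3")
})

test_that("treatment comparison reproduces a hand-checked t-test", {
  m <- tibble::tibble(
    batch = paste0("B", 1:6),
    treatment = rep(c("cytokine", "vehicle"), each = 3),
    non_mito = 1,
    basal = c(2.0, 2.1, 1.9, 4.0, 4.1, 3.9),
    maximal = c(6, 6, 6, 6, 6, 6.01),
    atp_production = c(2, 2.1, 1.9, 2, 2.1, 1.9),
    proton_leak = c(1, 1.1, 0.9, 1, 1.05, 0.95))
  cmp <- ocr_compare(m)
  basal <- cmp[cmp$metric == "basal", ]
  expect_lt(basal$p, 0.001)
  expect_equal(basal$df, 4)
  ref <- t.test(c(2.0, 2.1, 1.9), c(4.0, 4.1, 3.9), var.equal = TRUE)
  expect_equal(basal$p, ref$p.value)
  expect_true(basal$significant)
  expect_false(cmp$significant[cmp$metric == "atp_production"])

  # identical zero-variance groups: p = 1 with a note
  same <- dplyr::mutate(m, basal = 5, maximal = 5, atp_production = 5,
                        proton_leak = 5)
  cmp2 <- ocr_compare(same)
  expect_true(all(cmp2$p == 1))
  expect_true(all(cmp2$note == "zero variance in both groups"))
})

test_that("the full chain recovers generator ground truth on noiseless plates", {
  spec <- ocr_sim_spec(phase_levels = c(100, 40, 150, 20), noise_sd = 0,
                       seed = 5)
  traces <- dplyr::bind_rows(
    purrr::map_dfr(1:2, ~ simulate_ocr_plate(spec, n_wells = 4,
                                             treatment = "vehicle",
                                             batch = paste0("V", .x),
                                             protein_cv = 0)),
    purrr::map_dfr(1:2, ~ simulate_ocr_plate(spec, n_wells = 4,
                                             treatment = "cytokine",
                                             batch = paste0("C", .x),
                                             protein_cv = 0)))
  ms <- mito_stress(traces)
  expect_equal(ms$metrics$basal, rep(4, 4))
  expect_equal(ms$metrics$maximal, rep(6.5, 4))
  expect_equal(ms$metrics$atp_production, rep(2, 4))
  expect_equal(ms$metrics$proton_leak, rep(1, 4))
  expect_true(all(ms$comparison$p == 1))
})

test_that("noisy replicate aggregation lands within Monte-Carlo bounds of truth", {
  spec <- ocr_sim_spec(noise_sd = 2, seed = 77)
  tr <- simulate_ocr_plate(spec, n_wells = 8, protein_cv = 0)
  agg <- ocr_aggregate(ocr_metrics(tr))
  # basal truth 80; SEM of a median-based estimate from 8 wells at sd 2 is
  # well under 1, allow 2 * 1
  expect_lt(abs(agg$basal - 80), 2)
})
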