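# Seeded generators for every input the pipeline consumes, with planted ground
# truth so signature recovery, type-I error and metric extraction are testable.

#' Specify a synthetic multiplex cytokine study
#'
#' Describes a two-genotype mouse cohort measured on a multiplex bead panel in
#' technical triplicate. Log-scale concentrations are unit-variance by
#' construction, so `effect_size` is a standardized mean shift (in SD units of
#' log concentration) planted in the 5xFAD group (or along age when
#' `age_trend = TRUE`). Shared latent factors induce the cytokine-cytokine
#' correlation that motivates multivariate modeling of such panels.
#'
#' @param n_per_group Samples per genotype group.
#' @param n_cytokines Panel size (default 32, a typical mouse chemokine panel).
#' @param signature_up,signature_down Disjoint cytokine indices shifted up/down
#'   in the 5xFAD group by `effect_size` log-SD units.
#' @param effect_size Standardized log-scale mean shift (>= 0).
#' @param n_latent_noise Number of shared latent noise factors (they carry 40%
#'   of the log-scale variance, inducing correlated cytokines).
#' @param detection_limit Assay detection limit in pg/mL. The generator does
#'   NOT censor; values below the limit are emitted as-is and zeroing is the
#'   cleaning pipeline's job.
#' @param triplicate_cv Multiplicative coefficient of variation of technical
#'   replicates.
#' @param outlier_rate Probability that a triplicate contains one displaced
#'   replicate (displaced ~4-fold, far beyond the within-pair spread, so the
#'   triplicate rule fires unambiguously).
#' @param low_bead_rate Probability that a single reading is acquired from
#'   fewer than 20 beads.
#' @param age_trend If `TRUE`, the planted shift scales linearly with age
#'   (standardized age in SD units) instead of genotype, emulating a
#'   progression signal for regression models.
#' @param seed Integer seed; the generator uses its own RNG scope and leaves
#'   the global RNG state untouched.
#' @return A `cytokine_sim_spec` object (validated list).
#' @export
cytokine_sim_spec <- function(n_per_group = 20, n_cytokines = 32,
                              signature_up = 1:3, signature_down = 4:5,
                              effect_size = 2, n_latent_noise = 3,
                              detection_limit = 3.2, triplicate_cv = 0.1,
                              outlier_rate = 0.02, low_bead_rate = 0.01,
                              age_trend = FALSE, seed = 1L) {
  stopifnot(n_per_group >= 2, n_cytokines >= 1, n_latent_noise >= 0,
            detection_limit >= 0, triplicate_cv >= 0, is.logical(age_trend))
  if (effect_size < 0) abort("`effect_size` must be >= 0")
  if (length(intersect(signature_up, signature_down)) > 0) {
    abort("`signature_up` and `signature_down` must be disjoint")
  }
  idx <- c(signature_up, signature_down)
  if (length(idx) && (min(idx) < 1 || max(idx) > n_cytokines)) {
    abort("signature cytokine indices out of range 1..n_cytokines")
  }
  for (pr in c(outlier_rate, low_bead_rate)) {
    if (pr < 0 || pr > 1) abort("rates must be probabilities in [0, 1]")
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         n_cytokines = as.integer(n_cytokines),
         signature_up = as.integer(signature_up),
         signature_down = as.integer(signature_down),
         effect_size = effect_size, n_latent_noise = as.integer(n_latent_noise),
         detection_limit = detection_limit, triplicate_cv = triplicate_cv,
         outlier_rate = outlier_rate, low_bead_rate = low_bead_rate,
         age_trend = isTRUE(age_trend), seed = as.integer(seed)),
    class = "cytokine_sim_spec")
}

#' Simulate a multiplex cytokine study with planted signature
#'
#' Draws group-structured, correlated log-normal concentrations and emits each
#' sample x cytokine cell as three replicate plate readings with multiplicative
#' technical noise, occasional displaced-outlier replicates and low-bead-count
#' events. Output mirrors what an xMAP instrument export looks like after
#' standard-curve interpolation, ready for [clean_cytokines()].
#'
#' @param spec A [cytokine_sim_spec()].
#' @return A list of class `cytokine_study`:
#'   * `readings`: tibble `sample_id, analyte, replicate, concentration_pg_ml,
#'      bead_count` (long format, one row per well reading);
#'   * `samples`: tibble `sample_id, genotype, age_days, sex`;
#'   * `truth`: planted ground truth (true per-sample concentrations, planted
#'      signature analytes, per-triplicate outlier indicators, low-bead count).
#' @export
simulate_cytokine_study <- function(spec) {
  stopifnot(inherits(spec, "cytokine_sim_spec"))
  withr::with_seed(spec$seed, {
    p <- spec$n_cytokines
    n <- 2L * spec$n_per_group
    analytes <- sprintf("cyt%02d", seq_len(p))
    genotype <- rep(c("5xFAD", "WT"), each = spec$n_per_group)
    age_days <- rep(rep_len(c(30, 60, 120, 180), spec$n_per_group), 2)
    sex <- rep_len(c("F", "M"), n)
    samples <- tibble(sample_id = sprintf("S%03d", seq_len(n)),
                      genotype = genotype, age_days = age_days, sex = sex)

    # log-scale model: baseline + planted shift + shared latent factors + noise,
    # with unit marginal log-SD (0.4 latent share + 0.6 idiosyncratic)
    k <- spec$n_latent_noise
    mu <- rnorm(p, log(50), 0.5)
    if (k > 0) {
      lambda <- matrix(rnorm(p * k), p, k)
      lambda <- lambda / sqrt(rowSums(lambda ^ 2)) * sqrt(0.4)
      sd_eps <- sqrt(0.6)
      fac <- matrix(rnorm(n * k), n, k)
      latent <- fac %*% t(lambda)
    } else {
      latent <- matrix(0, n, p)
      sd_eps <- 1
    }
    delta <- numeric(p)
    delta[spec$signature_up] <- spec$effect_size
    delta[spec$signature_down] <- -spec$effect_size
    dose <- if (spec$age_trend) {
      as.numeric(scale(age_days))
    } else {
      as.numeric(genotype == "5xFAD")
    }
    z <- matrix(mu, n, p, byrow = TRUE) + outer(dose, delta) + latent +
      matrix(rnorm(n * p, 0, sd_eps), n, p)
    conc <- exp(z)
    dimnames(conc) <- list(samples$sample_id, analytes)

    # technical triplicates: multiplicative log-normal noise; planted outliers
    # displace one replicate 4-fold (up or down), >> 5x the within-pair spread
    n_cells <- n * p
    sdlog <- sqrt(log(1 + spec$triplicate_cv ^ 2))
    cell_sample <- rep(seq_len(n), each = p)
    cell_analyte <- rep(seq_len(p), times = n)
    outlier_cell <- rbinom(n_cells, 1, spec$outlier_rate) == 1
    outlier_rep <- sample.int(3, n_cells, replace = TRUE)
    outlier_dir <- sample(c(-1, 1), n_cells, replace = TRUE)

    rep_idx <- rep(1:3, times = n_cells)
    base <- rep(conc[cbind(cell_sample, cell_analyte)], each = 3)
    vals <- base * exp(rnorm(3 * n_cells, 0, sdlog))
    hit <- rep(outlier_cell, each = 3) & rep_idx == rep(outlier_rep, each = 3)
    vals[hit] <- vals[hit] * 4 ^ rep(outlier_dir, each = 3)[hit]

    low_bead <- rbinom(3 * n_cells, 1, spec$low_bead_rate) == 1
    beads <- 20L + rpois(3 * n_cells, 50)
    beads[low_bead] <- sample(0:19, sum(low_bead), replace = TRUE)

    readings <- tibble(
      sample_id = rep(samples$sample_id[cell_sample], each = 3),
      analyte = rep(analytes[cell_analyte], each = 3),
      replicate = rep_idx,
      concentration_pg_ml = vals,
      bead_count = beads)

    truth <- list(
      concentration = conc,
      signature_up = analytes[spec$signature_up],
      signature_down = analytes[spec$signature_down],
      effect_size = spec$effect_size,
      outliers = tibble(sample_id = samples$sample_id[cell_sample],
                        analyte = analytes[cell_analyte],
                        outlier = outlier_cell),
      n_low_bead = sum(low_bead))
    structure(list(readings = readings, samples = samples, truth = truth),
              class = "cytokine_study")
  })
}

#' Specify a synthetic Mito Stress Test OCR trace
#'
#' Four piecewise-constant oxygen-consumption levels (baseline, after
#' oligomycin, after FCCP, after rotenone/antimycin A) plus Gaussian
#' measurement noise. The expected Mito Stress Test metrics are analytically
#' computable from the levels, e.g. expected non-mitochondrial respiration is
#' the fourth level and expected basal respiration is level 1 minus level 4.
#'
#' @param phase_levels Four nonnegative OCR rates in pmol O2/min:
#'   baseline, post-oligomycin, post-FCCP, post-rotenone/antimycin A.
#' @param readings_per_phase Readings per injection phase (>= 3).
#' @param noise_sd Measurement noise SD in pmol O2/min.
#' @param seed Integer seed.
#' @return An `ocr_sim_spec` object.
#' @export
ocr_sim_spec <- function(phase_levels = c(100, 40, 150, 20),
                         readings_per_phase = 3, noise_sd = 2, seed = 1L) {
  if (length(phase_levels) != 4 || any(phase_levels < 0)) {
    abort("`phase_levels` must be four nonnegative rates")
  }
  if (readings_per_phase < 3) abort("`readings_per_phase` must be >= 3")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  structure(list(phase_levels = as.numeric(phase_levels),
                 readings_per_phase = as.integer(readings_per_phase),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ocr_sim_spec")
}

# canonical injection-phase labels, in assay order
ocr_phases <- function() {
  c("baseline", "post_oligomycin", "post_FCCP", "post_rotenone_antimycinA")
}

.draw_ocr_trace <- function(spec, well_id, treatment, protein_ug, batch) {
  r <- spec$readings_per_phase
  phase <- factor(rep(ocr_phases(), each = r), levels = ocr_phases())
  ocr <- rep(spec$phase_levels, each = r) + rnorm(4 * r, 0, spec$noise_sd)
  tibble(well = well_id,
         time_min = seq(0, by = 6.5, length.out = 4 * r),
         ocr = ocr, phase = phase,
         protein_ug = protein_ug, treatment = treatment, batch = batch)
}

#' Simulate a single OCR trace
#'
#' @param spec An [ocr_sim_spec()].
#' @param well_id,treatment,protein_ug,batch Well annotations carried through
#'   to the metric-extraction functions.
#' @return A tibble with columns `well, time_min, ocr, phase, protein_ug,
#'   treatment, batch` (one row per reading).
#' @export
simulate_ocr_trace <- function(spec, well_id = "A1", treatment = "vehicle",
                               protein_ug = 10, batch = "B1") {
  stopifnot(inherits(spec, "ocr_sim_spec"))
  withr::with_seed(spec$seed,
    .draw_ocr_trace(spec, well_id, treatment, protein_ug, batch))
}

#' Simulate a plate of replicate OCR wells
#'
#' Draws `n_wells` wells from the same trace specification with per-well
#' protein masses (log-normal around `protein_mean`). Useful to emulate one
#' biological replicate (an independent assay of 5-10 wells).
#'
#' @inheritParams simulate_ocr_trace
#' @param n_wells Number of wells.
#' @param protein_mean,protein_cv Mean and CV of per-well protein mass (ug).
#' @param level_scale Multiplier applied to `phase_levels` (e.g. a treatment
#'   effect on all phases).
#' @return A tibble of stacked traces (see [simulate_ocr_trace()]).
#' @export
simulate_ocr_plate <- function(spec, n_wells = 8, treatment = "vehicle",
                               batch = "B1", protein_mean = 10,
                               protein_cv = 0.1, level_scale = 1) {
  stopifnot(inherits(spec, "ocr_sim_spec"), n_wells >= 1, level_scale >= 0)
  spec2 <- spec
  spec2$phase_levels <- spec$phase_levels * level_scale
  withr::with_seed(spec$seed, {
    protein <- rlnorm(n_wells, log(protein_mean), sqrt(log(1 + protein_cv^2)))
    purrr::map_dfr(seq_len(n_wells), function(w) {
      .draw_ocr_trace(spec2, sprintf("%s_W%02d", batch, w), treatment,
                      protein[w], batch)
    })
  })
}

#' Specify a synthetic nCounter-style count matrix
#'
#' Negative-binomial endogenous genes, high-mean/low-CV housekeeping genes, a
#' fixed positive-control ladder shared across samples up to library-size
#' scaling, and planted fold changes in the cytokine-treated group.
#'
#' @param n_genes Endogenous panel size (default 768).
#' @param n_housekeeping Housekeeping genes (default 20).
#' @param n_positive_controls Positive-control probes (<= 6 ladder steps).
#' @param n_per_group Biological replicates per treatment (default 3).
#' @param de_gene_indices Endogenous gene indices with a planted fold change.
#' @param log2fc Planted log2 fold change (cytokine vs vehicle), recycled over
#'   `de_gene_indices`.
#' @param dispersion Negative-binomial overdispersion (> 0); variance is
#'   `mu + mu^2 * dispersion`.
#' @param baseline_mean Typical endogenous expression level (counts).
#' @param seed Integer seed.
#' @return A `count_sim_spec` object.
#' @export
count_sim_spec <- function(n_genes = 768, n_housekeeping = 20,
                           n_positive_controls = 6, n_per_group = 3,
                           de_gene_indices = integer(), log2fc = 0,
                           dispersion = 0.1, baseline_mean = 500, seed = 1L) {
  stopifnot(n_genes >= 1, n_housekeeping >= 1, n_positive_controls >= 1,
            n_positive_controls <= 6, n_per_group >= 2, baseline_mean > 0)
  if (dispersion <= 0) abort("`dispersion` must be > 0")
  if (length(de_gene_indices) &&
      (min(de_gene_indices) < 1 || max(de_gene_indices) > n_genes)) {
    abort("`de_gene_indices` out of range 1..n_genes")
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_housekeeping = as.integer(n_housekeeping),
                 n_positive_controls = as.integer(n_positive_controls),
                 n_per_group = as.integer(n_per_group),
                 de_gene_indices = as.integer(de_gene_indices),
                 log2fc = rep_len(log2fc, length(de_gene_indices)),
                 dispersion = dispersion, baseline_mean = baseline_mean,
                 seed = as.integer(seed)),
            class = "count_sim_spec")
}

#' Simulate an nCounter-style count matrix with planted fold changes
#'
#' @param spec A [count_sim_spec()].
#' @return A list of class `count_study`:
#'   * `counts`: tibble `gene, class, <sample columns>` where `class` is one of
#'     `endogenous`, `housekeeping`, `positive_control`;
#'   * `groups`: tibble `sample, group` with group `cytokine`/`vehicle`;
#'   * `truth`: planted DE gene names, their log2 fold changes, library factors.
#' @export
simulate_count_matrix <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  withr::with_seed(spec$seed, {
    ns <- 2L * spec$n_per_group
    sample_ids <- sprintf("S%02d", seq_len(ns))
    group <- rep(c("cytokine", "vehicle"), each = spec$n_per_group)
    lib <- exp(rnorm(ns, 0, 0.15))

    endo <- sprintf("gene%04d", seq_len(spec$n_genes))
    hk <- sprintf("hk%02d", seq_len(spec$n_housekeeping))
    pos <- sprintf("pos_%s", LETTERS[seq_len(spec$n_positive_controls)])

    mu_endo <- spec$baseline_mean * exp(rnorm(spec$n_genes, 0, 0.4))
    fc <- matrix(1, spec$n_genes, ns)
    if (length(spec$de_gene_indices)) {
      fc[spec$de_gene_indices, group == "cytokine"] <- 2 ^ spec$log2fc
    }
    mu_mat <- outer(mu_endo, lib) * fc
    endo_counts <- matrix(rnbinom(length(mu_mat), mu = mu_mat,
                                  size = 1 / spec$dispersion),
                          spec$n_genes, ns)

    mu_hk <- runif(spec$n_housekeeping, 800, 4000)
    hk_counts <- matrix(rnbinom(spec$n_housekeeping * ns,
                                mu = outer(mu_hk, lib), size = 200),
                        spec$n_housekeeping, ns)

    ladder <- c(8192, 2048, 512, 128, 32, 8)[seq_len(spec$n_positive_controls)]
    pos_counts <- matrix(rpois(spec$n_positive_controls * ns,
                               outer(ladder, lib)),
                         spec$n_positive_controls, ns)

    mat <- rbind(endo_counts, hk_counts, pos_counts)
    counts <- dplyr::bind_cols(
      tibble(gene = c(endo, hk, pos),
             class = rep(c("endogenous", "housekeeping", "positive_control"),
                         c(spec$n_genes, spec$n_housekeeping,
                           spec$n_positive_controls))),
      as_tibble(`colnames<-`(mat, sample_ids)))

    truth <- list(de_genes = endo[spec$de_gene_indices],
                  log2fc = spec$log2fc, library_factor = lib)
    structure(list(counts = counts,
                   groups = tibble(sample = sample_ids, group = group),
                   truth = truth),
              class = "count_study")
  })
}
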