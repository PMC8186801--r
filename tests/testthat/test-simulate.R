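test_that("the simulator is deterministic and leaves the caller's RNG alone", {
  cfg <- simulation_config(n_progressors = 5, n_stable = 5, n_timepoints = 4,
                           rng_seed = 123)
  set.seed(1); before <- .Random.seed
  a <- simulate_cohort(cfg)
  expect_identical(.Random.seed, before)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(simulation_config(n_progressors = 5, n_stable = 5,
                                          n_timepoints = 4, rng_seed = 124))
  expect_false(identical(a$fc, c2$fc))
  expect_identical(nrow(a), 5L * 2L * 4L * 3L)
  expect_setequal(unique(a$pathway),
                  c("SMC_transcallosal", "PCC_AMTL_L", "PCC_AMTL_R"))
})

test_that("degenerate noise yields exactly the configured means", {
  cfg <- simulation_config(n_progressors = 2, n_stable = 2, n_timepoints = 3,
                           fc_baseline_sd = 0, sc_baseline_sd = 0,
                           fc_slope_sd = 0, sc_slope_sd = 0,
                           stable_slope_sd = 0, fc_noise_sd = 0,
                           sc_noise_sd = 0, effect_scale = 0, rng_seed = 2)
  d <- simulate_cohort(cfg)
  expect_true(all(d$fc == cfg$fc_baseline_mean))
  expect_true(all(d$sc == cfg$sc_baseline_mean))
})

test_that("simulated baselines match their configured distribution", {
  cfg <- simulation_config(n_progressors = 1700, n_stable = 1700,
                           n_timepoints = 2, rng_seed = 5)
  d <- simulate_cohort(cfg)
  base <- d[d$visit == 1, ]                 # ~1e4 baselines over 3 pathways
  n <- nrow(base)
  se <- cfg$fc_baseline_sd / sqrt(n)
  expect_lt(abs(mean(base$fc) - cfg$fc_baseline_mean), 4 * se)
  se_sc <- cfg$sc_baseline_sd / sqrt(n)
  expect_lt(abs(mean(base$sc) - cfg$sc_baseline_mean), 4 * se_sc)
})

test_that("progression scores order noise-free decliners above flat subjects", {
  cfg <- simulation_config(n_progressors = 3, n_stable = 3, n_timepoints = 5,
                           fc_baseline_sd = 1e-6, sc_baseline_sd = 1e-9,
                           fc_slope_sd = 0, sc_slope_sd = 0,
                           stable_slope_sd = 0, fc_noise_sd = 0,
                           sc_noise_sd = 0, rng_seed = 9)
  d <- simulate_cohort(cfg)
  # noise-free norming needs nonzero SDs: norm on a jittered copy
  normbase <- d[d$group == "stable" & d$visit == 1, ]
  normbase$fc <- normbase$fc + seq(-0.1, 0.1, length.out = nrow(normbase))
  normbase$sc <- normbase$sc + seq(-1e-5, 1e-5, length.out = nrow(normbase))
  norms <- compute_norms(normbase)
  sc <- detect_progression(d, measure_definition("M1_combined"), 5,
                           norms = norms)
  expect_true(min(sc$score[sc$group == "progressor"]) >
              max(sc$score[sc$group == "stable"]))
})

test_that("the per-subject slope equals the closed-form 3-point OLS", {
  # one subject, values (0, -0.1, -0.2) over visits 1..3 -> slope -0.1
  m <- rbind(measures_row("c1", 1, c(1, 2, 3), c(5e-4, 6e-4, 7e-4)),
             measures_row("c2", 1, c(2, 1, 2), c(6e-4, 5e-4, 6e-4)))
  norms <- compute_norms(m)
  mk_visit <- function(v, drop) {
    d <- measures_row("s1", v, fc = numeric(3), sc = numeric(3))
    i <- match(d$pathway, norms$pathway)
    # fc chosen so every component z equals `drop`, sc at normative mean
    d$fc <- norms$fc_mean[i] + 2 * drop * norms$fc_sd[i]
    d$sc <- norms$sc_mean[i]
    d$group <- "progressor"
    d
  }
  d <- rbind(mk_visit(1, 0), mk_visit(2, -0.1), mk_visit(3, -0.2))
  sc <- detect_progression(d, measure_definition("M1_combined"), 3,
                           norms = norms)
  expect_equal(sc$score, 0.1, tolerance = 1e-12)      # score = -slope
})

test_that("ROC/AUC equals the exhaustive pair-counting oracle, ties included", {
  u_oracle <- function(scores, labels) {
    pos <- scores[labels]; neg <- scores[!labels]
    tot <- 0
    for (p in pos) for (q in neg)
      tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  set.seed(44)
  for (rep in 1:40) {
    n <- sample(4:10, 1)
    scores <- sample(c(rnorm(n), round(rnorm(n), 0)), n)   # induce ties
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, TRUE))
    got <- roc_auc(scores, labels)
    expect_equal(got$auc, u_oracle(scores, labels), tolerance = 1e-12)
    expect_true(all(diff(got$sensitivity) >= 0))  # thresholds descend
    expect_true(got$auc >= 0 && got$auc <= 1)
  }
  # perfect separation and degenerate labels
  expect_equal(roc_auc(c(3, 4, 5, 0, 1, 2), rep(c(TRUE, FALSE), each = 3))$auc,
               1)
  expect_error(roc_auc(1:4, rep(TRUE, 4)), "both classes")
})

test_that("ROC/AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(45)
  scores <- rnorm(40)
  labels <- sample(c(TRUE, FALSE), 40, TRUE)
  ours <- roc_auc(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("labels independent of scores give chance-level AUC", {
  set.seed(46)
  scores <- rnorm(400)
  labels <- rep(c(TRUE, FALSE), 200)
  got <- roc_auc(scores, labels)$auc
  se <- sqrt((400 + 1) / (12 * 200 * 200))   # U-statistic null SE
  expect_lt(abs(got - 0.5), 3 * se)
})

test_that("the measure-level path runs end to end without volumes", {
  cfg <- simulation_config(n_progressors = 8, n_stable = 8, n_timepoints = 6,
                           rng_seed = 31)
  coh <- simulate_cohort(cfg)
  fit <- sfci_fit(coh, norm_group = "stable")
  sc <- detect_progression(coh, measure_definition("M1_combined"), 6)
  r <- roc_auc(sc$score, sc$group == "progressor")
  expect_s3_class(r, "roc_curve")
  expect_identical(nrow(fit$scores), 16L * 6L)
  expect_true(is.finite(r$auc))
})

test_that("auc_vs_timepoints summarises replicates per measure and t", {
  cfg <- simulation_config(n_progressors = 10, n_stable = 10,
                           n_timepoints = 4, rng_seed = 77)
  tab <- auc_vs_timepoints(cfg, max_timepoints = 4, n_replicates = 20)
  expect_identical(nrow(tab), 3L * 3L)            # 3 measures x t in 2..4
  expect_true(all(tab$mean_auc >= 0 & tab$mean_auc <= 1))
  expect_true(all(tab$lo <= tab$mean_auc & tab$mean_auc <= tab$hi))
  expect_error(auc_vs_timepoints(cfg, max_timepoints = 9, n_replicates = 2),
               "exceeds")
})

test_that("image fixtures carry recoverable ground truth", {
  fx <- make_image_fixtures(dim = c(16, 16, 6), n_volumes = 40,
                            task_noise_sd = 0, rng_seed = 13)
  # noise-free activation: the planted peak is recovered exactly
  act <- fit_boxcar_glm(fx$task_series, fx$manifest$task_block,
                        fx$manifest$task_cycles)
  expect_identical(peak_voxel(act, fx$gm_mask), fx$manifest$peak_voxel)
  # constant-RD tract under the track map: the pathway average is exact
  sc <- pathway_average(fx$rd_map, fx$track_map, fx$wm_mask)
  expect_equal(sc$value, fx$manifest$tract_rd, tolerance = 1e-12)
  # determinism
  fx2 <- make_image_fixtures(dim = c(16, 16, 6), n_volumes = 40,
                             task_noise_sd = 0, rng_seed = 13)
  expect_identical(fx$rest_series$values, fx2$rest_series$values)
  # geometric consistency: seed/target inside the grey-matter mask
  expect_true(all(fx$gm_mask$values[fx$seed$voxel_indices + 1L] > 0))
  expect_true(all(fx$gm_mask$values[fx$target$voxel_indices + 1L] > 0))
})

test_that("fixtures write a readable NIfTI + manifest set", {
  dir <- file.path(tempdir(), "fxset")
  fx <- make_image_fixtures(dim = c(12, 12, 6), n_volumes = 20, rng_seed = 4,
                            dir = dir)
  expect_true(file.exists(file.path(dir, "rest_series.nii.gz")))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_volume(file.path(dir, "rest_series.nii.gz"))
  expect_equal(back$values, fx$rest_series$values, tolerance = 1e-6)
  expect_equal(back$tr_s, 2.8, tolerance = 1e-6)
  rd <- read_volume(file.path(dir, "rd_map.nii.gz"), units = "mm2/s")
  expect_equal(rd$values, fx$rd_map$values, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})
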