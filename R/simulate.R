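# Run code under a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards so simulations are reproducible and isolated.
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Configuration for the longitudinal progression simulator
#'
#' Defines a two-group cohort (progressors vs stable) measured on the three
#' pathways at `n_timepoints` visits. Per subject and component, the
#' baseline is drawn from a normal distribution, a subject-specific slope is
#' drawn from the group's slope distribution, and each visit adds
#' independent measurement noise:
#' `value(visit) = baseline + slope * (visit - 1) + noise`.
#'
#' Functional connectivity is in normalised z units; structural
#' connectivity is pathway-averaged radial diffusivity in mm2/s, so decline
#' means `fc` falling and `sc` rising. The defaults place healthy radial
#' diffusivity near 0.55e-3 mm2/s and pathway fc near 2 z, with progressor
#' slopes of about a tenth of a baseline SD per visit — effect sizes chosen
#' to reproduce the qualitative behaviour of a measure-development
#' simulation (discriminating measures whose detection improves with the
#' number of time points), not any specific published cohort.
#'
#' Scenarios: `"uniform_decline"` applies the progressor slopes to all
#' three pathways; `"domain_specific"` restricts decline to the cognitive
#' (PCC-AMTL) pathways, leaving the motor pathway stable.
#'
#' @param n_progressors,n_stable group sizes (defaults 20 and 20).
#' @param n_timepoints visits per subject, 2..9 (default 9).
#' @param fc_baseline_mean,fc_baseline_sd baseline fc distribution (z).
#' @param sc_baseline_mean,sc_baseline_sd baseline sc distribution (mm2/s).
#' @param fc_slope_mean,fc_slope_sd progressor fc slope distribution
#'   (z/visit; negative mean = decline).
#' @param sc_slope_mean,sc_slope_sd progressor sc slope distribution
#'   (mm2/s per visit; positive mean = rising diffusivity).
#' @param stable_slope_sd between-subject slope SD of the stable group
#'   (means are 0), as a fraction of the progressor slope SDs.
#' @param fc_noise_sd,sc_noise_sd per-visit measurement noise SDs.
#' @param effect_scale multiplier on both progressor slope means (1 =
#'   default effect; 0 = null simulation).
#' @param scenario `"uniform_decline"` or `"domain_specific"`.
#' @param rng_seed integer seed making the simulation deterministic.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_progressors = 20, n_stable = 20,
                              n_timepoints = 9,
                              fc_baseline_mean = 2.0, fc_baseline_sd = 0.5,
                              sc_baseline_mean = 0.55e-3,
                              sc_baseline_sd = 0.05e-3,
                              fc_slope_mean = -0.05, fc_slope_sd = 0.03,
                              sc_slope_mean = 4e-6, sc_slope_sd = 3e-6,
                              stable_slope_sd = 0.3,
                              fc_noise_sd = 0.25, sc_noise_sd = 2e-5,
                              effect_scale = 1,
                              scenario = c("uniform_decline",
                                           "domain_specific"),
                              rng_seed = 1L) {
  scenario <- match.arg(scenario)
  if (n_progressors < 1 || n_stable < 1)
    stop("group sizes must be at least 1")
  if (n_timepoints < 1 || n_timepoints > 9)
    stop("'n_timepoints' must be in 1..9")
  sds <- c(fc_baseline_sd, sc_baseline_sd, fc_slope_sd, sc_slope_sd,
           fc_noise_sd, sc_noise_sd, stable_slope_sd)
  if (any(sds < 0))
    stop("standard deviations must be non-negative")
  structure(as.list(environment()), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config> ", x$n_progressors, " progressors + ", x$n_stable,
      " stable, ", x$n_timepoints, " time points, scenario ", x$scenario,
      ", effect x", x$effect_scale, ", seed ", x$rng_seed, "\n", sep = "")
  invisible(x)
}

#' Simulate a longitudinal pathway-measure cohort
#'
#' Draws the cohort described by a [simulation_config()]: per subject,
#' pathway and component, `baseline + slope * (visit - 1) + noise`, with
#' group-specific slope distributions. Deterministic given `cfg$rng_seed`;
#' the caller's RNG stream is left untouched.
#'
#' @param cfg a `simulation_config`.
#' @return Data frame with columns `subject`, `group` (`"progressor"` /
#'   `"stable"`), `visit`, `pathway`, `fc`, `sc` — the schema consumed by
#'   [sfci_fit()] and [score_cohort()].
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$rng_seed, {
    paths <- .sfci_pathways
    declining <- if (cfg$scenario == "uniform_decline") paths else
      c("PCC_AMTL_L", "PCC_AMTL_R")
    ns <- cfg$n_progressors + cfg$n_stable
    subject <- c(sprintf("prog%03d", seq_len(cfg$n_progressors)),
                 sprintf("stab%03d", seq_len(cfg$n_stable)))
    group <- c(rep("progressor", cfg$n_progressors),
               rep("stable", cfg$n_stable))
    prog <- group == "progressor"
    tps <- cfg$n_timepoints
    visits <- seq_len(tps)
    per_path <- function(p) {
      eff <- prog & (p %in% declining)
      fc_mu <- ifelse(eff, cfg$fc_slope_mean * cfg$effect_scale, 0)
      sc_mu <- ifelse(eff, cfg$sc_slope_mean * cfg$effect_scale, 0)
      fc_ssd <- ifelse(prog, cfg$fc_slope_sd,
                       cfg$stable_slope_sd * cfg$fc_slope_sd)
      sc_ssd <- ifelse(prog, cfg$sc_slope_sd,
                       cfg$stable_slope_sd * cfg$sc_slope_sd)
      fc0 <- stats::rnorm(ns, cfg$fc_baseline_mean, cfg$fc_baseline_sd)
      sc0 <- stats::rnorm(ns, cfg$sc_baseline_mean, cfg$sc_baseline_sd)
      fc_sl <- stats::rnorm(ns, fc_mu, fc_ssd)
      sc_sl <- stats::rnorm(ns, sc_mu, sc_ssd)
      # rows ordered subject-major, visit-minor
      data.frame(
        subject = rep(subject, each = tps),
        group = rep(group, each = tps), visit = rep(visits, ns),
        pathway = p,
        fc = rep(fc0, each = tps) + rep(fc_sl, each = tps) *
          (rep(visits, ns) - 1) + stats::rnorm(ns * tps, 0, cfg$fc_noise_sd),
        sc = rep(sc0, each = tps) + rep(sc_sl, each = tps) *
          (rep(visits, ns) - 1) + stats::rnorm(ns * tps, 0, cfg$sc_noise_sd))
    }
    out <- do.call(rbind, lapply(paths, per_path))
    rownames(out) <- NULL
    out
  })
}

#' Candidate progression measures
#'
#' The simulator compares three candidate composites built from the same
#' per-pathway z-scores: the full combined index (functional and structural
#' components), a functional-only analogue (structural terms dropped) and a
#' structural-only analogue. Each keeps the motor / hemisphere-minimum
#' structure of the combined metric.
#'
#' @param name one of `"M1_combined"`, `"M2_fc_only"`, `"M3_sc_only"`.
#' @return A list of class `measure_definition` with `name` and `combiner`,
#'   a function mapping the per-pathway component z-scores
#'   (`z_fc`, `z_sc` for motor / left / right) to a scalar.
#' @export
measure_definition <- function(name = c("M1_combined", "M2_fc_only",
                                        "M3_sc_only")) {
  name <- match.arg(name)
  combiner <- switch(name,
    M1_combined = function(zfc_m, zsc_m, zfc_l, zsc_l, zfc_r, zsc_r)
      0.5 * 0.5 * (zfc_m + zsc_m) +
      0.5 * pmin(0.5 * (zfc_l + zsc_l), 0.5 * (zfc_r + zsc_r)),
    M2_fc_only = function(zfc_m, zsc_m, zfc_l, zsc_l, zfc_r, zsc_r)
      0.5 * zfc_m + 0.5 * pmin(zfc_l, zfc_r),
    M3_sc_only = function(zfc_m, zsc_m, zfc_l, zsc_l, zfc_r, zsc_r)
      0.5 * zsc_m + 0.5 * pmin(zsc_l, zsc_r))
  structure(list(name = name, combiner = combiner),
            class = "measure_definition")
}

# Oriented per-pathway component z-scores for a cohort, wide by pathway.
.component_z <- function(measures, norms) {
  ori <- attr(norms, "orientation")
  i <- match(measures$pathway, norms$pathway)
  if (anyNA(i))
    stop("pathway(s) missing from norms")
  zfc <- ori["fc"] * (measures$fc - norms$fc_mean[i]) / norms$fc_sd[i]
  zsc <- ori["sc"] * (measures$sc - norms$sc_mean[i]) / norms$sc_sd[i]
  data.frame(subject = measures$subject, visit = measures$visit,
             pathway = measures$pathway, z_fc = zfc, z_sc = zsc)
}

#' Per-subject progression score from a simulated cohort
#'
#' Norms the component measures on the stable group's baseline visit,
#' evaluates the candidate measure at every visit, fits a per-subject
#' ordinary-least-squares slope over the first `n_timepoints` visits and
#' returns `score = -slope`, so that faster decline scores higher.
#'
#' @param measures cohort data frame from [simulate_cohort()] (columns
#'   `subject`, `group`, `visit`, `pathway`, `fc`, `sc`).
#' @param measure_def a [measure_definition()].
#' @param n_timepoints number of leading visits used, >= 2.
#' @param norms optional precomputed `sfci_norms`; default: stable-group
#'   baseline records.
#' @return Data frame `subject`, `group`, `score`.
#' @export
detect_progression <- function(measures, measure_def, n_timepoints,
                               norms = NULL) {
  stopifnot(inherits(measure_def, "measure_definition"))
  if (n_timepoints < 2)
    stop("slope detection needs at least 2 time points")
  if (max(measures$visit) < n_timepoints)
    stop("cohort has fewer than ", n_timepoints, " visits")
  if (is.null(norms)) {
    base <- measures[measures$group == "stable" &
                     measures$visit == min(measures$visit), ]
    norms <- compute_norms(base, source = "stable group baseline")
  }
  use <- measures[measures$visit <= n_timepoints, ]
  z <- .component_z(use, norms)
  wide <- function(p, col) {
    zz <- z[z$pathway == p, ]
    zz <- zz[order(zz$subject, zz$visit), ]
    zz[[col]]
  }
  ref <- z[z$pathway == .sfci_pathways[1], ]
  ref <- ref[order(ref$subject, ref$visit), ]
  val <- measure_def$combiner(
    wide("SMC_transcallosal", "z_fc"), wide("SMC_transcallosal", "z_sc"),
    wide("PCC_AMTL_L", "z_fc"), wide("PCC_AMTL_L", "z_sc"),
    wide("PCC_AMTL_R", "z_fc"), wide("PCC_AMTL_R", "z_sc"))
  d <- data.frame(subject = ref$subject, visit = ref$visit, value = val)
  tt <- d$visit - mean(seq_len(n_timepoints))
  sxx <- sum((seq_len(n_timepoints) - mean(seq_len(n_timepoints)))^2)
  slopes <- tapply(d$value * tt, d$subject, sum) / sxx
  grp <- measures$group[match(names(slopes), measures$subject)]
  data.frame(subject = names(slopes), group = grp,
             score = -as.numeric(slopes), row.names = NULL)
}

#' Empirical ROC curve and AUC
#'
#' Threshold sweep over the observed scores (higher score = positive call)
#' with the area computed as the Mann-Whitney U statistic divided by
#' `n1 * n0`; tied score pairs contribute 1/2, which equals the trapezoidal
#' area of the empirical curve.
#'
#' @param scores numeric scores.
#' @param labels binary labels (logical, 0/1, or two-level factor); TRUE /
#'   1 / second level is the positive class.
#' @return A list of class `roc_curve`: `thresholds`, `sensitivity`,
#'   `specificity`, `auc`.
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels))
    labels <- labels == levels(labels)[2]
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop("'scores' and 'labels' must be complete and paired")
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(th) mean(scores[labels] >= th), numeric(1))
  spec <- vapply(thr, function(th) mean(scores[!labels] < th), numeric(1))
  structure(list(thresholds = thr, sensitivity = sens, specificity = spec,
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("<roc_curve> AUC = ", format(x$auc, digits = 4), " (",
      length(x$thresholds), " thresholds)\n", sep = "")
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Detection power as a function of the number of time points
#'
#' Replicates simulate -> score -> ROC for each candidate measure and each
#' number of leading time points, summarising the AUC distribution by its
#' mean and percentile interval. This is the simulator's figure of merit:
#' for informative effect sizes the mean AUC should rise with the number of
#' design points and the combined measure should dominate its single-
#' component analogues when both components carry signal.
#'
#' @param cfg a [simulation_config()]; replicate r uses seed
#'   `cfg$rng_seed + r`.
#' @param measure_defs list of [measure_definition()]s.
#' @param max_timepoints largest number of leading visits evaluated
#'   (default `cfg$n_timepoints`).
#' @param n_replicates Monte-Carlo replicates (default 200).
#' @param ci percentile interval width (default 0.95).
#' @return Data frame: `measure`, `timepoints`, `mean_auc`, `lo`, `hi`,
#'   `n_replicates`.
#' @export
auc_vs_timepoints <- function(cfg, measure_defs = list(
                                measure_definition("M1_combined"),
                                measure_definition("M2_fc_only"),
                                measure_definition("M3_sc_only")),
                              max_timepoints = cfg$n_timepoints,
                              n_replicates = 200, ci = 0.95) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (max_timepoints > cfg$n_timepoints)
    stop("'max_timepoints' exceeds the simulated number of visits")
  tps <- 2:max_timepoints
  acc <- array(NA_real_, c(length(measure_defs), length(tps), n_replicates))
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$rng_seed <- cfg$rng_seed + r
    cohort <- simulate_cohort(cfg_r)
    base <- cohort[cohort$group == "stable" & cohort$visit == 1, ]
    norms <- compute_norms(base, source = "stable group baseline")
    for (it in seq_along(tps)) {
      for (im in seq_along(measure_defs)) {
        sc <- detect_progression(cohort, measure_defs[[im]], tps[it],
                                 norms = norms)
        acc[im, it, r] <- roc_auc(sc$score, sc$group == "progressor")$auc
      }
    }
  }
  alpha <- (1 - ci) / 2
  out <- expand.grid(measure = vapply(measure_defs, `[[`, "", "name"),
                     timepoints = tps, stringsAsFactors = FALSE)
  out$mean_auc <- mapply(function(im, it) mean(acc[im, it, ]),
                         match(out$measure,
                               vapply(measure_defs, `[[`, "", "name")),
                         match(out$timepoints, tps))
  qs <- mapply(function(im, it)
    stats::quantile(acc[im, it, ], c(alpha, 1 - alpha)),
    match(out$measure, vapply(measure_defs, `[[`, "", "name")),
    match(out$timepoints, tps))
  out$lo <- qs[1, ]
  out$hi <- qs[2, ]
  out$n_replicates <- n_replicates
  out
}
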