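#' Motion quality gate for connectivity scans
#'
#' Classifies a scan from its residual-displacement summaries. A scan whose
#' mean and maximum voxel-level residual displacement jointly exceed the
#' thresholds (`td_zmax > 1` mm AND `td_zmean > 0.2` mm, a conjunction)
#' fails: at baseline this withdraws the participant, at follow-up the scan
#' is flagged for visual inspection. A disjunctive mode (either threshold
#' alone fails the scan) is available for sensitivity analyses.
#'
#' @param td_zmean,td_zmax mean / maximum voxel-level residual displacement
#'   (mm); vectorised; `td_zmax >= td_zmean >= 0` required.
#' @param is_baseline logical: baseline scans are withdrawn, follow-ups
#'   flagged.
#' @param max_mm,mean_mm thresholds (defaults 1 and 0.2 mm).
#' @param rule `"conjunctive"` (default) or `"disjunctive"`.
#' @return Character vector in `{"pass", "withdraw", "flag"}`.
#' @export
motion_gate <- function(td_zmean, td_zmax, is_baseline,
                        max_mm = 1, mean_mm = 0.2,
                        rule = c("conjunctive", "disjunctive")) {
  rule <- match.arg(rule)
  if (any(td_zmean < 0) || any(td_zmax < 0))
    stop("displacement summaries must be non-negative")
  if (any(td_zmax < td_zmean))
    stop("'td_zmax' cannot be smaller than 'td_zmean'")
  over <- if (rule == "conjunctive")
    td_zmax > max_mm & td_zmean > mean_mm
  else
    td_zmax > max_mm | td_zmean > mean_mm
  ifelse(over, ifelse(is_baseline, "withdraw", "flag"), "pass")
}

.participant_flags <- c("none", "withdrew", "bdi_gt_20",
                        "low_baseline_cognition", "baseline_motion")
.visit_flags <- c("ok", "not_attended", "missing_dti", "motion_artifact")

#' Cohort exclusion accounting
#'
#' Reproduces the study-style exclusion cascade from enrollment to the
#' usable connectivity scans. Participant-level flags: `withdrew` (left the
#' study), and the administrative removals `bdi_gt_20` (depression score),
#' `low_baseline_cognition`, `baseline_motion` (failed the baseline
#' [motion_gate()]). Visit-level flags on the retained participants:
#' `not_attended`, `missing_dti` (visit removed), `motion_artifact`
#' (connectivity scan excluded after visual inspection; the visit's other
#' data remain usable).
#'
#' @param participants data frame with columns `subject`, `group`, `flag`.
#' @param visits optional data frame with columns `subject`, `visit`,
#'   `flag` listing every scheduled visit of the retained participants.
#' @return A list of class `exclusion_ledger` with per-group data frames
#'   `participants` (enrolled, withdrew, administrative, final) and, when
#'   `visits` is given, `visits` (scheduled, attended, usable,
#'   connectivity_usable).
#' @export
exclusion_cascade <- function(participants, visits = NULL) {
  need <- c("subject", "group", "flag")
  if (!all(need %in% names(participants)))
    stop("participants table needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(participants$flag), .participant_flags)
  if (length(bad))
    stop("unknown participant flag(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.participant_flags, collapse = ", "), ")")
  groups <- sort(unique(participants$group))
  ptab <- do.call(rbind, lapply(groups, function(g) {
    p <- participants[participants$group == g, ]
    enrolled <- nrow(p)
    withdrew <- sum(p$flag == "withdrew")
    admin <- sum(p$flag %in% c("bdi_gt_20", "low_baseline_cognition",
                               "baseline_motion"))
    data.frame(group = g, enrolled = enrolled, withdrew = withdrew,
               administrative = admin, final = enrolled - withdrew - admin)
  }))
  out <- list(participants = ptab)
  if (!is.null(visits)) {
    if (!all(c("subject", "visit", "flag") %in% names(visits)))
      stop("visits table needs columns: subject, visit, flag")
    bad <- setdiff(unique(visits$flag), .visit_flags)
    if (length(bad))
      stop("unknown visit flag(s): ", paste(bad, collapse = ", "))
    kept <- participants$subject[participants$flag == "none"]
    unknown <- setdiff(unique(visits$subject), participants$subject)
    if (length(unknown))
      stop("visits refer to unknown subjects: ",
           paste(unknown, collapse = ", "))
    v <- visits[visits$subject %in% kept, ]
    grp_of <- participants$group[match(v$subject, participants$subject)]
    vtab <- do.call(rbind, lapply(groups, function(g) {
      vg <- v[grp_of == g, ]
      scheduled <- nrow(vg)
      attended <- sum(vg$flag != "not_attended")
      usable <- sum(!vg$flag %in% c("not_attended", "missing_dti"))
      conn <- sum(vg$flag == "ok")
      data.frame(group = g, scheduled = scheduled, attended = attended,
                 usable = usable, connectivity_usable = conn)
    }))
    out$visits <- vtab
  }
  structure(out, class = "exclusion_ledger")
}

#' @export
print.exclusion_ledger <- function(x, ...) {
  cat("Participant accounting\n")
  print(x$participants, row.names = FALSE)
  if (!is.null(x$visits)) {
    cat("\nVisit accounting (retained participants)\n")
    print(x$visits, row.names = FALSE)
  }
  invisible(x)
}

#' The published cohort's exclusion flags
#'
#' The enrollment and exclusion bookkeeping of the two-year MS study the
#' package models, encoded as flag tables consumable by
#' [exclusion_cascade()]: 25 MS participants enrolled (2 withdrew, 2
#' removed for depression scores above 20, 1 for extreme baseline motion)
#' and 12 controls (1 withdrew, 2 removed for very low baseline
#' cognition); 6 scheduled visits per retained MS participant (one subject
#' attended only 4, one visit lost its DTI acquisition) and 2 per control;
#' 3 MS connectivity scans excluded for motion artifact after inspection.
#'
#' @return A list with data frames `participants` and `visits`.
#' @export
study_cohort_flags <- function() {
  ms_flags <- c(rep("none", 20), "withdrew", "withdrew", "bdi_gt_20",
                "bdi_gt_20", "baseline_motion")
  hc_flags <- c(rep("none", 9), "withdrew", "low_baseline_cognition",
                "low_baseline_cognition")
  participants <- data.frame(
    subject = c(sprintf("ms%02d", 1:25), sprintf("hc%02d", 1:12)),
    group = c(rep("MS", 25), rep("HC", 12)),
    flag = c(ms_flags, hc_flags))
  visits <- rbind(
    expand.grid(subject = sprintf("ms%02d", 1:20), visit = 1:6,
                stringsAsFactors = FALSE),
    expand.grid(subject = sprintf("hc%02d", 1:9), visit = 1:2,
                stringsAsFactors = FALSE))
  visits$flag <- "ok"
  # one MS participant withdrew after visit 4 (final cognitive testing only)
  visits$flag[visits$subject == "ms01" & visits$visit %in% c(5, 6)] <-
    "not_attended"
  # one visit lost to a failed DTI acquisition
  visits$flag[visits$subject == "ms02" & visits$visit == 3] <- "missing_dti"
  # three connectivity scans, one in each of three participants, showed
  # severe motion artifact on inspection
  visits$flag[visits$subject == "ms03" & visits$visit == 2] <- "motion_artifact"
  visits$flag[visits$subject == "ms04" & visits$visit == 4] <- "motion_artifact"
  visits$flag[visits$subject == "ms05" & visits$visit == 5] <- "motion_artifact"
  list(participants = participants, visits = visits)
}

#' Longitudinal slope estimation with likelihood-ratio model comparison
#'
#' Fits a linear mixed-effects model of a longitudinal measure with random
#' intercept and slope per subject, compares a full against a reduced
#' fixed-effect structure by the likelihood-ratio test, and extracts
#' per-subject slopes. Models are fitted by maximum likelihood (not REML):
#' likelihoods are only comparable across fixed-effect structures under ML.
#'
#' The default contrast drops the time term (`visit`), testing for change
#' over time; `drop` may name any fixed-effect term(s) of the full model,
#' e.g. `c("group", "group:visit")` for a group contrast. If the
#' mixed-model fit fails, a per-subject ordinary-least-squares fallback is
#' used (per-subject slopes summarised by their mean and standard error,
#' LRT from the pooled fixed-effects linear models) and the result carries
#' `engine = "ols"`.
#'
#' @param data long-format data frame, one row per subject-visit.
#' @param response name of the measured column.
#' @param time name of the (numeric) time column (default `"visit"`).
#' @param subject name of the subject-identifier column.
#' @param covariates character vector of covariate column names.
#' @param drop fixed-effect term(s) omitted in the reduced model.
#' @param interaction optional term like `"group"` crossed with time in the
#'   full model (adds `group + group:time`).
#' @param engine `"lmer"` (default) or `"ols"` to force the fallback.
#' @return A list of class `sfci_lme`: `measure`, `slope_fixed`,
#'   `slope_se`, `subject_slopes` (fixed + BLUP deviation under lmer),
#'   `lrt_stat`, `lrt_df`, `lrt_p`, `engine`, `covariates_used`, `n_subjects`.
#' @export
fit_longitudinal <- function(data, response, time = "visit",
                             subject = "subject", covariates = character(),
                             drop = time, interaction = NULL,
                             engine = c("lmer", "ols")) {
  engine <- match.arg(engine)
  cols <- c(response, time, subject, covariates, interaction)
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  data <- data[stats::complete.cases(data[cols]), ]
  nsub <- length(unique(data[[subject]]))
  if (nsub < 2L)
    stop("need at least 2 subjects for a random-effects structure")
  per <- table(data[[subject]])
  if (any(per < 2L))
    stop("every subject needs at least 2 visits (drop incomplete subjects ",
         "first): ", paste(names(per)[per < 2], collapse = ", "))
  fixed <- c(time, covariates,
             if (!is.null(interaction))
               c(interaction, paste0(interaction, ":", time)))
  full_terms <- fixed
  red_terms <- setdiff(fixed, drop)
  if (identical(full_terms, red_terms))
    stop("'drop' does not name any fixed-effect term of the full model")
  f_full <- stats::reformulate(full_terms, response = response)
  f_red <- if (length(red_terms))
    stats::reformulate(red_terms, response = response)
  else
    stats::reformulate("1", response = response)
  mk_lmer <- function(f) {
    rhs <- paste(c(attr(stats::terms(f), "term.labels"), "1"), collapse = " + ")
    stats::as.formula(paste(response, "~", rhs, "+ (1 +", time, "|",
                            subject, ")"))
  }
  res <- NULL
  if (engine == "lmer") {
    res <- tryCatch({
      full <- suppressWarnings(suppressMessages(
        lme4::lmer(mk_lmer(f_full), data = data, REML = FALSE)))
      red <- suppressWarnings(suppressMessages(
        lme4::lmer(mk_lmer(f_red), data = data, REML = FALSE)))
      ll_f <- as.numeric(stats::logLik(full))
      ll_r <- as.numeric(stats::logLik(red))
      stat <- max(0, 2 * (ll_f - ll_r))
      df <- attr(stats::logLik(full), "df") - attr(stats::logLik(red), "df")
      fe <- lme4::fixef(full)
      re <- lme4::ranef(full)[[subject]]
      slopes <- fe[[time]] + if (time %in% names(re)) re[[time]] else 0
      names(slopes) <- rownames(re)
      list(slope_fixed = unname(fe[[time]]),
           slope_se = sqrt(diag(as.matrix(stats::vcov(full)))[time]),
           subject_slopes = slopes,
           lrt_stat = stat, lrt_df = df,
           lrt_p = stats::pchisq(stat, df, lower.tail = FALSE),
           engine = "lmer", models = list(full = full, reduced = red))
    }, error = function(e) NULL)
  }
  if (is.null(res)) {
    # per-subject OLS fallback: subject slopes from independent straight-line
    # fits, cohort slope = their mean, LRT from pooled fixed-effects lm
    slopes <- vapply(split(data, data[[subject]]), function(d)
      unname(stats::coef(stats::lm(d[[response]] ~ d[[time]]))[2]),
      numeric(1))
    full <- stats::lm(f_full, data = data)
    red <- stats::lm(f_red, data = data)
    stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(red))))
    df <- attr(stats::logLik(full), "df") - attr(stats::logLik(red), "df")
    res <- list(slope_fixed = mean(slopes),
                slope_se = stats::sd(slopes) / sqrt(length(slopes)),
                subject_slopes = slopes,
                lrt_stat = stat, lrt_df = df,
                lrt_p = stats::pchisq(stat, df, lower.tail = FALSE),
                engine = "ols", models = NULL)
  }
  structure(c(list(measure = response, covariates_used = covariates,
                   n_subjects = nsub), res),
            class = "sfci_lme")
}

#' @export
print.sfci_lme <- function(x, ...) {
  cat("Longitudinal model of '", x$measure, "' (", x$n_subjects,
      " subjects, engine: ", x$engine, ")\n", sep = "")
  cat(sprintf("  slope: %.5g (SE %.3g) per visit\n", x$slope_fixed,
              x$slope_se))
  cat(sprintf("  LRT: stat %.4g on %d df, p = %.4g\n", x$lrt_stat,
              x$lrt_df, x$lrt_p))
  if (length(x$covariates_used))
    cat("  covariates:", paste(x$covariates_used, collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.sfci_lme <- function(object, ...) object$subject_slopes

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values for one declared family of tests. Which tests
#' form a family is an analysis decision (e.g. all measures of one table,
#' or each imaging measure's set of behavioural correlations); callers pass
#' each family separately.
#'
#' @param pvalues numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  p <- as.numeric(pvalues)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Imaging-behaviour Pearson correlation with outlier and transform rules
#'
#' Pearson correlation between an imaging measure and a behavioural score,
#' with the analysis rules used for motor-timing measures: optionally
#' natural-log transform the behavioural score first (appropriate for timed
#' scores such as pegboard and walk times), then exclude subjects whose
#' transformed score lies more than `outlier_sd` standard deviations from
#' the sample mean.
#'
#' @param x imaging values, one per subject.
#' @param y behavioural values, paired with `x`.
#' @param log_transform_y natural-log transform `y` first (default FALSE).
#' @param outlier_sd exclusion threshold in SD units (default 3).
#' @param ids optional subject identifiers for reporting exclusions.
#' @return A list: `r`, `p` (two-sided), `n_used`, `excluded` (ids or
#'   indices).
#' @export
behavior_correlation <- function(x, y, log_transform_y = FALSE,
                                 outlier_sd = 3, ids = NULL) {
  if (length(x) != length(y))
    stop("'x' and 'y' must be paired")
  if (is.null(ids))
    ids <- seq_along(x)
  ok <- is.finite(x) & is.finite(y)
  if (log_transform_y) {
    if (any(y[ok] <= 0))
      stop("log transform requires strictly positive behavioural values")
    y <- ifelse(ok, log(y), y)
  }
  yv <- y[ok]
  mu <- mean(yv)
  s <- stats::sd(yv)
  out <- ok & s > 0 & abs(y - mu) > outlier_sd * s
  keep <- ok & !out
  if (sum(keep) < 4L)
    stop("fewer than 4 usable pairs after exclusions")
  ct <- stats::cor.test(x[keep], y[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = sum(keep),
       excluded = ids[out])
}
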