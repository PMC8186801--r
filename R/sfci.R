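.sfci_pathways <- c("SMC_transcallosal", "PCC_AMTL_L", "PCC_AMTL_R")

.check_measures <- function(measures) {
  need <- c("subject", "visit", "pathway", "fc", "sc")
  miss <- setdiff(need, names(measures))
  if (length(miss))
    stop("measures table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(measures[c("subject", "visit", "pathway")]))
    stop("measures must hold one record per (subject, visit, pathway)")
  measures
}

#' Normative statistics for the connectivity components
#'
#' Per-pathway sample means and standard deviations (denominator N - 1) of
#' functional (`fc`) and structural (`sc`) connectivity over a norming
#' sample — typically the healthy-control baseline visits, so that z-scored
#' components read as deviations from normative connectivity.
#'
#' The orientation signs decide how each component enters the composite.
#' The default `c(fc = 1, sc = -1)` makes both components decline with
#' impairment: `sc` is radial diffusivity, which rises with demyelination,
#' so its z-score is negated. `literal = TRUE` sums both z-scores with
#' positive sign instead (the printed-equation form).
#'
#' @param measures data frame with columns `subject`, `visit`, `pathway`,
#'   `fc`, `sc` restricted to the norming sample.
#' @param orientation named numeric signs for `fc` and `sc` components.
#' @param literal if TRUE, use `c(fc = 1, sc = 1)`.
#' @param source free-text description of the norming sample.
#' @return A data frame of class `sfci_norms` (one row per pathway:
#'   `fc_mean`, `fc_sd`, `sc_mean`, `sc_sd`) with attributes `orientation`
#'   and `source`.
#' @export
compute_norms <- function(measures, orientation = c(fc = 1, sc = -1),
                          literal = FALSE, source = "norming sample") {
  measures <- .check_measures(measures)
  if (literal)
    orientation <- c(fc = 1, sc = 1)
  if (!setequal(names(orientation), c("fc", "sc")) ||
      !all(orientation %in% c(-1, 1)))
    stop("'orientation' must be named signs for 'fc' and 'sc'")
  paths <- sort(unique(measures$pathway))
  rows <- lapply(paths, function(p) {
    m <- measures[measures$pathway == p, ]
    if (length(unique(m$subject)) < 2L)
      stop("need at least 2 norming subjects for pathway '", p, "'")
    data.frame(pathway = p,
               fc_mean = mean(m$fc), fc_sd = stats::sd(m$fc),
               sc_mean = mean(m$sc), sc_sd = stats::sd(m$sc))
  })
  norms <- do.call(rbind, rows)
  if (any(norms$fc_sd == 0) || any(norms$sc_sd == 0))
    stop("degenerate norms: zero standard deviation in the norming sample")
  structure(norms, orientation = orientation[c("fc", "sc")], source = source,
            class = c("sfci_norms", "data.frame"))
}

#' @export
print.sfci_norms <- function(x, ...) {
  ori <- attr(x, "orientation")
  cat("Normative connectivity statistics (", attr(x, "source"), ")\n",
      "orientation: fc ", sprintf("%+d", ori["fc"]), ", sc ",
      sprintf("%+d", ori["sc"]), "\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 5)
  invisible(x)
}

#' Z-scored pathway component
#'
#' The per-pathway component entering the composite:
#' `1/2 * (s_fc * (fc - fc_mean) / fc_sd + s_sc * (sc - sc_mean) / sc_sd)`,
#' with orientation signs `s` taken from the norms (see [compute_norms()]).
#' Vectorised over records.
#'
#' @param fc,sc numeric component values.
#' @param pathway pathway label(s) present in `norms`.
#' @param norms an `sfci_norms` object.
#' @return Numeric z-component value(s).
#' @export
z_component <- function(fc, sc, pathway, norms) {
  stopifnot(inherits(norms, "sfci_norms"))
  i <- match(pathway, norms$pathway)
  if (anyNA(i))
    stop("pathway(s) missing from norms: ",
         paste(unique(pathway[is.na(i)]), collapse = ", "))
  ori <- attr(norms, "orientation")
  0.5 * (ori["fc"] * (fc - norms$fc_mean[i]) / norms$fc_sd[i] +
         ori["sc"] * (sc - norms$sc_mean[i]) / norms$sc_sd[i])
}

#' Combine component z-scores into the composite index
#'
#' `SFCI = 1/2 * Z_motor + 1/2 * min(Z_cog_L, Z_cog_R)`: the cognitive term
#' is the worse (minimum) of the two hemispheres, making the composite
#' sensitive to unilateral decline. Vectorised.
#'
#' @param z_motor,z_cog_l,z_cog_r finite numeric component scores.
#' @return Numeric SFCI value(s).
#' @export
combine_sfci <- function(z_motor, z_cog_l, z_cog_r) {
  if (any(!is.finite(z_motor)) || any(!is.finite(z_cog_l)) ||
      any(!is.finite(z_cog_r)))
    stop("all component z-scores must be finite")
  0.5 * z_motor + 0.5 * pmin(z_cog_l, z_cog_r)
}

#' Score a cohort of pathway measures
#'
#' Computes, for every subject-visit that has all three pathways present,
#' the motor and cognitive z-components and the composite SFCI. Subject-
#' visits missing any pathway are skipped — never imputed from the surviving
#' hemisphere — and listed in the `skipped` attribute.
#'
#' @param measures data frame with columns `subject`, `visit`, `pathway`,
#'   `fc`, `sc` (extra columns such as `group` are carried through).
#' @param norms an `sfci_norms` object.
#' @return Data frame of class `sfci_scores`: `subject`, `visit`,
#'   `z_motor`, `z_cog_l`, `z_cog_r`, `sfci`; attribute `skipped` is a data
#'   frame of skipped subject-visits with the missing pathways.
#' @export
score_cohort <- function(measures, norms) {
  measures <- .check_measures(measures)
  stopifnot(inherits(norms, "sfci_norms"))
  key <- interaction(measures$subject, measures$visit, drop = TRUE)
  out <- list()
  skipped <- list()
  for (k in levels(key)) {
    m <- measures[key == k, ]
    miss <- setdiff(.sfci_pathways, m$pathway)
    if (length(miss)) {
      skipped[[k]] <- data.frame(subject = m$subject[1], visit = m$visit[1],
                                 missing = paste(miss, collapse = ";"))
      next
    }
    zc <- function(p) {
      r <- m[m$pathway == p, ]
      z_component(r$fc, r$sc, p, norms)
    }
    zm <- zc("SMC_transcallosal")
    zl <- zc("PCC_AMTL_L")
    zr <- zc("PCC_AMTL_R")
    row <- data.frame(subject = m$subject[1], visit = m$visit[1],
                      z_motor = zm, z_cog_l = zl, z_cog_r = zr,
                      sfci = combine_sfci(zm, zl, zr))
    if ("group" %in% names(m))
      row$group <- m$group[1]
    out[[k]] <- row
  }
  if (!length(out))
    stop("no subject-visit has all three pathways")
  scores <- do.call(rbind, out)
  rownames(scores) <- NULL
  scores <- scores[order(scores$subject, scores$visit), ]
  skipped <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(subject = character(), visit = character(),
               missing = character())
  rownames(skipped) <- NULL
  structure(scores, skipped = skipped, class = c("sfci_scores", "data.frame"))
}

#' Fit the composite connectivity index to a cohort
#'
#' The model-style front end: estimates normative per-pathway means and SDs
#' from the norming sample (by default the control group's baseline visits),
#' then scores every subject-visit in `measures`. New cohorts can be scored
#' against the same norms with `predict()`.
#'
#' @param measures data frame with columns `subject`, `group`, `visit`,
#'   `pathway`, `fc`, `sc`.
#' @param norm_group value of `group` defining the norming sample (default
#'   `"HC"`).
#' @param norm_visits `"baseline"` (first visit of each norming subject,
#'   the default) or `"all"`.
#' @param orientation,literal component orientation, see [compute_norms()].
#' @return An object of class `sfci_fit` with elements `norms`, `scores`,
#'   `skipped`, `call`.
#' @seealso [compute_norms()], [score_cohort()], [combine_sfci()]
#' @examples
#' cohort <- simulate_cohort(simulation_config(rng_seed = 1))
#' fit <- sfci_fit(cohort, norm_group = "stable")
#' print(fit)
#' head(predict(fit))
#' @export
sfci_fit <- function(measures, norm_group = "HC",
                     norm_visits = c("baseline", "all"),
                     orientation = c(fc = 1, sc = -1), literal = FALSE) {
  norm_visits <- match.arg(norm_visits)
  measures <- .check_measures(measures)
  if (!"group" %in% names(measures))
    stop("'measures' needs a 'group' column to identify the norming sample")
  ctl <- measures[measures$group == norm_group, ]
  if (nrow(ctl) == 0L)
    stop("no rows with group == '", norm_group, "'")
  if (norm_visits == "baseline") {
    first <- stats::aggregate(visit ~ subject, ctl, min)
    ctl <- merge(ctl, first, by = c("subject", "visit"))
  }
  desc <- paste0(norm_group, " ", norm_visits, " visits, n = ",
                 length(unique(ctl$subject)))
  norms <- compute_norms(ctl, orientation = orientation, literal = literal,
                         source = desc)
  scores <- score_cohort(measures, norms)
  structure(list(norms = norms, scores = scores,
                 skipped = attr(scores, "skipped"), call = match.call()),
            class = "sfci_fit")
}

#' @export
print.sfci_fit <- function(x, ...) {
  cat("Structural and Functional Connectivity Index fit\n\n")
  print(x$norms)
  cat("\nScored subject-visits:", nrow(x$scores))
  if (nrow(x$skipped))
    cat("  (skipped:", nrow(x$skipped), "incomplete)")
  cat("\n")
  invisible(x)
}

#' @export
summary.sfci_fit <- function(object, ...) {
  s <- object$scores
  grp <- if ("group" %in% names(s)) s$group else rep("all", nrow(s))
  agg <- stats::aggregate(s[c("z_motor", "z_cog_l", "z_cog_r", "sfci")],
                          by = list(group = grp), FUN = mean)
  structure(list(norms = object$norms, group_means = agg,
                 n_scored = nrow(s), skipped = object$skipped),
            class = "summary.sfci_fit")
}

#' @export
print.summary.sfci_fit <- function(x, ...) {
  print(x$norms)
  cat("\nGroup mean scores:\n")
  print(x$group_means, row.names = FALSE, digits = 4)
  if (nrow(x$skipped)) {
    cat("\nSkipped subject-visits (incomplete pathways):\n")
    print(x$skipped, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.sfci_fit <- function(object, ...) {
  m <- as.matrix(object$norms[, c("fc_mean", "fc_sd", "sc_mean", "sc_sd")])
  rownames(m) <- object$norms$pathway
  m
}

#' @export
#' @rdname sfci_fit
#' @param object an `sfci_fit`.
#' @param newdata optional new measures table to score against the fitted
#'   norms; default returns the training-cohort scores.
#' @param ... unused.
predict.sfci_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata))
    return(object$scores)
  score_cohort(newdata, object$norms)
}

#' @export
plot.sfci_fit <- function(x, ...) {
  s <- x$scores
  grp <- if ("group" %in% names(s)) as.character(s$group) else
    rep("all", nrow(s))
  visits <- sort(unique(s$visit))
  groups <- sort(unique(grp))
  means <- sapply(groups, function(g)
    sapply(visits, function(v) mean(s$sfci[grp == g & s$visit == v])))
  means <- matrix(means, nrow = length(visits),
                  dimnames = list(visits, groups))
  graphics::matplot(visits, means, type = "b", pch = 19, lty = 1,
                    xlab = "visit", ylab = "mean SFCI (z units)", ...)
  graphics::legend("bottomleft", legend = groups, col = seq_along(groups),
                   pch = 19, bty = "n")
  invisible(means)
}
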