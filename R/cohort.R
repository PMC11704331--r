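#' Stratify a cohort into score quartile groups
#'
#' Rank-based quartile stratification as used for signature-score survival
#' analysis: with `k = ceiling(n / 4)`, the `k` lowest-scoring samples form
#' the lower quartile group, the `k` highest the upper, and the remainder
#' the mid group. Ties are broken by stable input order, so a cohort of 619
#' samples always splits 155 / 309 / 155. The groups partition the cohort.
#'
#' @param scores Named numeric vector (names = sample ids) or an object of
#'   class `score_vector`.
#' @return An object of class `stratified_cohort`: data.frame `assignment`
#'   (`sample_id`, `group` in lower/mid/upper) and `sizes`.
#' @export
stratify_quartiles <- function(scores) {
  scores <- unclass(scores)
  stopifnot(is.numeric(scores))
  if (!all(is.finite(scores))) stop_spatsig("scores must be finite")
  n <- length(scores)
  if (n < 4L) stop_spatsig("need at least 4 samples for quartile stratification")
  if (is.null(names(scores))) names(scores) <- sprintf("sample_%04d", seq_len(n))
  k <- ceiling(n / 4)
  ord <- order(scores)  # stable: ties keep input order
  group <- rep.int("mid", n)
  group[ord[seq_len(k)]] <- "lower"
  group[ord[seq.int(n - k + 1L, n)]] <- "upper"
  build_stratification(names(scores), group, c("lower", "mid", "upper"))
}

#' Stratify values into tertile groups
#'
#' Rank-based thirds (`k = ceiling(n / 3)` low and high, remainder
#' intermediate) with the same stable-order tie rule as
#' [stratify_quartiles()]. Used e.g. for positive-pixel percentages scored
#' on tissue microarrays.
#'
#' @param values Named numeric vector.
#' @return A `stratified_cohort` with groups low / intermediate / high.
#' @export
stratify_tertiles <- function(values) {
  values <- unclass(values)
  stopifnot(is.numeric(values))
  if (!all(is.finite(values))) stop_spatsig("values must be finite")
  n <- length(values)
  if (n < 3L) stop_spatsig("need at least 3 samples for tertile stratification")
  if (is.null(names(values))) names(values) <- sprintf("sample_%04d", seq_len(n))
  k <- ceiling(n / 3)
  ord <- order(values)
  group <- rep.int("intermediate", n)
  group[ord[seq_len(k)]] <- "low"
  group[ord[seq.int(n - k + 1L, n)]] <- "high"
  build_stratification(names(values), group, c("low", "intermediate", "high"))
}

build_stratification <- function(sample_id, group, levels) {
  group <- factor(group, levels = levels)
  structure(
    list(assignment = data.frame(sample_id = sample_id, group = group,
                                 stringsAsFactors = FALSE),
         sizes = table(group)),
    class = "stratified_cohort"
  )
}

#' @export
print.stratified_cohort <- function(x, ...) {
  cat("Stratified cohort of", nrow(x$assignment), "samples:\n")
  print(x$sizes)
  invisible(x)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function under right censoring.
#' The median survival convention is the smallest time t with S(t) <= 0.5;
#' it is undefined (NA, flagged) when S never reaches 0.5, e.g. with no
#' events.
#'
#' @param surv data.frame with `time` (> 0) and `event` (1 event /
#'   0 censored); an optional `sample_id` column is ignored.
#' @return An object of class `km_curve`: `time`, `surv`, `n_risk`,
#'   `n_event` (step function over distinct event/censoring times),
#'   `median`, `n`, `n_events`.
#' @export
km_estimate <- function(surv) {
  check_survival_table(surv)
  fit <- survival::survfit(survival::Surv(surv$time, surv$event) ~ 1)
  s <- fit$surv
  t <- fit$time
  below <- which(s <= 0.5)
  med <- if (length(below) > 0L) t[below[1L]] else NA_real_
  structure(
    list(time = t, surv = s, n_risk = fit$n.risk, n_event = fit$n.event,
         median = med, n = nrow(surv), n_events = sum(surv$event)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n, "subjects,", x$n_events, "events; median survival",
      if (is.na(x$median)) "not reached" else format(x$median, digits = 4), "\n")
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$surv)), do.points = FALSE,
                 xlab = "time", ylab = "S(t)", ylim = c(0, 1),
                 main = "Kaplan-Meier estimate", ...)
  invisible(x)
}

#' Log-rank test across groups
#'
#' Observed-minus-expected chi-square statistic over distinct event times,
#' with `groups - 1` degrees of freedom.
#'
#' @param surv Survival table (`time`, `event`, optionally `sample_id`).
#' @param groups Factor or character vector aligned with `surv` rows.
#' @return A list with `chi2`, `df`, `p`, `n_groups`.
#' @export
logrank_test <- function(surv, groups) {
  check_survival_table(surv)
  groups <- factor(groups)
  if (length(groups) != nrow(surv)) stop_spatsig("'groups' must match 'surv' rows")
  if (any(table(groups) == 0L)) stop_spatsig("every group must contain subjects")
  if (nlevels(groups) < 2L) stop_spatsig("need at least 2 groups")
  if (sum(surv$event) == 0L) stop_spatsig("need at least one event")
  fit <- survival::survdiff(survival::Surv(surv$time, surv$event) ~ groups)
  df <- nlevels(groups) - 1L
  list(chi2 = fit$chisq, df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(groups))
}

#' Cox proportional-hazards hazard ratio
#'
#' Fits a univariate Cox model by partial-likelihood maximization (Breslow
#' tie handling) and reports the hazard ratio with a 95% Wald interval.
#' For a grouped covariate the hazard ratio is relative to the stated
#' reference group; pass a numeric covariate for a per-unit hazard ratio.
#'
#' @param surv Survival table (`time`, `event`).
#' @param covariate Numeric vector, or factor/character group labels.
#' @param reference Reference group label (grouped covariate only).
#' @return An object of class `cox_result`: `hr`, `ci_low`, `ci_high`,
#'   `log_hr`, `se`, `p_wald`, `reference`, `term`. With more than two
#'   groups, one row per non-reference level in `all_terms` and the first
#'   term in the scalar fields.
#' @export
cox_hr <- function(surv, covariate, reference = NULL) {
  check_survival_table(surv)
  if (length(covariate) != nrow(surv)) {
    stop_spatsig("'covariate' must match 'surv' rows")
  }
  if (sum(surv$event) == 0L) stop_spatsig("need at least one event")
  if (is.character(covariate) || is.factor(covariate)) {
    covariate <- factor(covariate)
    if (!is.null(reference)) {
      if (!reference %in% levels(covariate)) {
        stop_spatsig("reference group '", reference, "' not found")
      }
      covariate <- stats::relevel(covariate, ref = reference)
    }
    reference <- levels(covariate)[1L]
    if (nlevels(covariate) < 2L) stop_spatsig("covariate is constant")
  } else {
    if (stats::var(covariate) == 0) stop_spatsig("covariate is constant")
  }

  fit <- withCallingHandlers(
    survival::coxph(
      survival::Surv(surv$time, surv$event) ~ covariate,
      ties = "breslow",
      control = survival::coxph.control(eps = 1e-10, iter.max = 100L)
    ),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w), ignore.case = TRUE)) {
        stop_spatsig("Cox fit failed (monotone likelihood / non-convergence): ",
                     conditionMessage(w))
      }
      invokeRestart("muffleWarning")
    }
  )
  coefs <- summary(fit)$coefficients
  if (any(abs(coefs[, "coef"]) > 15)) {
    stop_spatsig("Cox fit suggests complete separation (|log HR| > 15)")
  }
  all_terms <- data.frame(
    term = rownames(coefs),
    hr = exp(coefs[, "coef"]),
    ci_low = exp(coefs[, "coef"] - 1.96 * coefs[, "se(coef)"]),
    ci_high = exp(coefs[, "coef"] + 1.96 * coefs[, "se(coef)"]),
    log_hr = coefs[, "coef"],
    se = coefs[, "se(coef)"],
    p_wald = coefs[, "Pr(>|z|)"],
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(hr = all_terms$hr[1L], ci_low = all_terms$ci_low[1L],
         ci_high = all_terms$ci_high[1L], log_hr = all_terms$log_hr[1L],
         se = all_terms$se[1L], p_wald = all_terms$p_wald[1L],
         reference = reference, term = all_terms$term[1L],
         all_terms = all_terms, n = nrow(surv), n_events = sum(surv$event)),
    class = "cox_result"
  )
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox proportional hazards (Breslow ties): HR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$hr, x$ci_low, x$ci_high, x$p_wald))
  if (!is.null(x$reference)) cat("  reference group:", x$reference, "\n")
  cat(sprintf("  n = %d, events = %d\n", x$n, x$n_events))
  invisible(x)
}

check_survival_table <- function(surv) {
  stopifnot(is.data.frame(surv), all(c("time", "event") %in% names(surv)))
  if (nrow(surv) < 1L) stop_spatsig("survival table is empty")
  if (any(!is.finite(surv$time)) || any(surv$time <= 0)) {
    stop_spatsig("survival times must be positive and finite")
  }
  if (!all(surv$event %in% c(0, 1))) {
    stop_spatsig("event indicator must be 0 (censored) or 1 (event)")
  }
  invisible(surv)
}

#' Marker-mean immune population scores
#'
#' MCP-style population abundance proxies: the score of a cell population in
#' a sample is the arithmetic mean of the log-expression of that
#' population's marker genes. Markers absent from the matrix are dropped
#' with a warning; a population with no available marker is flagged absent
#' (all-NA column) rather than scored.
#'
#' @param expr Gene x sample log-expression matrix with rownames.
#' @param marker_sets Named list: population -> character vector of marker
#'   genes.
#' @return Sample x population numeric matrix.
#' @export
mcp_scores <- function(expr, marker_sets) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), is.list(marker_sets))
  out <- matrix(NA_real_, nrow = ncol(expr), ncol = length(marker_sets),
                dimnames = list(colnames(expr), names(marker_sets)))
  for (pop in names(marker_sets)) {
    markers <- marker_sets[[pop]]
    avail <- intersect(markers, rownames(expr))
    missing <- setdiff(markers, avail)
    if (length(missing) > 0L) {
      warning("population '", pop, "': dropped missing marker(s) ",
              paste(missing, collapse = ", "))
    }
    if (length(avail) == 0L) {
      warning("population '", pop, "' has no available markers; flagged absent")
      next
    }
    out[, pop] <- colMeans(expr[avail, , drop = FALSE])
  }
  out
}

#' Harmonize population scores across cohorts
#'
#' Per cohort and population, scores are min-max normalized to [0, 1]; the
#' cohorts are then pooled and standardized to a reference group so that the
#' reference group's mean score is 1 (division; a subtraction alternative
#' makes the reference mean 0). Min-max normalization is affine-invariant,
#' so cohorts whose scores differ only by scale and offset harmonize to
#' identical values.
#'
#' @param scores_by_cohort Named list of sample x population matrices (as
#'   from [mcp_scores()]); sample names must be unique across cohorts.
#' @param reference_assignment Named character vector: sample -> group.
#' @param reference_group Group whose pooled mean becomes the unit.
#' @param method `"divide"` (reference mean -> 1) or `"subtract"`
#'   (reference mean -> 0).
#' @return Pooled sample x population matrix of harmonized scores;
#'   populations constant within a cohort are flagged by NA for that cohort
#'   with a warning.
#' @export
harmonize_scores <- function(scores_by_cohort, reference_assignment,
                             reference_group,
                             method = c("divide", "subtract")) {
  method <- match.arg(method)
  stopifnot(is.list(scores_by_cohort), length(scores_by_cohort) > 0L)
  normed <- lapply(names(scores_by_cohort), function(cohort) {
    m <- scores_by_cohort[[cohort]]
    apply(m, 2L, function(x) {
      rng <- range(x, na.rm = TRUE)
      if (!all(is.finite(rng)) || rng[1L] == rng[2L]) {
        warning("constant scores in cohort '", cohort, "'; population flagged")
        return(rep(NA_real_, length(x)))
      }
      (x - rng[1L]) / (rng[2L] - rng[1L])
    })
  })
  pooled <- do.call(rbind, normed)
  rownames(pooled) <- unlist(lapply(scores_by_cohort, rownames), use.names = FALSE)
  if (anyDuplicated(rownames(pooled))) {
    stop_spatsig("sample names must be unique across cohorts")
  }
  ref_samples <- names(reference_assignment)[reference_assignment == reference_group]
  ref_samples <- intersect(ref_samples, rownames(pooled))
  if (length(ref_samples) == 0L) {
    stop_spatsig("reference group '", reference_group, "' has no samples in the pooled data")
  }
  ref_mean <- colMeans(pooled[ref_samples, , drop = FALSE], na.rm = TRUE)
  if (method == "divide") {
    if (any(ref_mean == 0, na.rm = TRUE)) {
      stop_spatsig("reference-group mean is 0; cannot standardize by division")
    }
    sweep(pooled, 2L, ref_mean, `/`)
  } else {
    sweep(pooled, 2L, ref_mean, `-`)
  }
}
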