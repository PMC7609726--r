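# Validation-phase statistics: efficiency-corrected (Pfaffl) relative
# qPCR quantification, Mann-Whitney group comparison, overall-survival
# binning, expression dichotomisation, Kaplan-Meier estimation and the
# two-group log-rank test with an O/E hazard ratio.

#' Pfaffl efficiency-corrected expression ratio
#'
#' ratio = E_target ^ dCq_target / E_reference ^ dCq_reference, where
#' dCq = Cq(calibrator) - Cq(sample) and E is the amplification
#' efficiency in fold change per cycle (2 = perfect doubling).  With
#' both efficiencies equal to 2 this is exactly the classic 2^-ddCq.
#'
#' @param dcq_target,dcq_reference Cq differences (calibrator minus
#'   sample), in cycles.
#' @param e_target,e_reference Amplification efficiencies in [1, 2]
#'   (default 2).
#' @return Relative expression ratio(s); vectorised.
#' @export
pfaffl_ratio <- function(dcq_target, dcq_reference,
                         e_target = 2, e_reference = 2) {
  if (any(e_target < 1 | e_target > 2) || any(e_reference < 1 | e_reference > 2)) {
    stop("amplification efficiencies must lie in [1, 2]", call. = FALSE)
  }
  e_target ^ dcq_target / e_reference ^ dcq_reference
}

#' Per-sample relative expression from a qPCR Cq table
#'
#' Averages the replicate Cq values per sample (arithmetic mean), then
#' applies \code{\link{pfaffl_ratio}} against a calibrator.  By default
#' the calibrator is the across-sample mean Cq (so the ratios are
#' centred on 1); passing a sample id uses that sample as calibrator.
#'
#' @param qpcr data.frame as returned by \code{\link{read_qpcr_table}}.
#' @param calibrator NULL (mean-Cq calibrator) or a sample id.
#' @return data.frame with columns sample_id and relative_expression.
#' @export
relative_expression <- function(qpcr, calibrator = NULL) {
  tc <- tapply(qpcr$target_cq, qpcr$sample_id, mean)
  rc <- tapply(qpcr$reference_cq, qpcr$sample_id, mean)
  et <- tapply(qpcr$target_efficiency, qpcr$sample_id, mean)
  er <- tapply(qpcr$reference_efficiency, qpcr$sample_id, mean)
  if (is.null(calibrator)) {
    cal_t <- mean(tc)
    cal_r <- mean(rc)
  } else {
    if (!calibrator %in% names(tc)) {
      stop("calibrator sample '", calibrator, "' not in the Cq table",
           call. = FALSE)
    }
    cal_t <- tc[[calibrator]]
    cal_r <- rc[[calibrator]]
  }
  ratio <- pfaffl_ratio(cal_t - tc, cal_r - rc, et, er)
  data.frame(sample_id = names(tc),
             relative_expression = as.numeric(ratio),
             row.names = NULL)
}

#' Mann-Whitney U test
#'
#' Two-sided test of two independent groups.  With a pooled size of at
#' most 12 (mode "auto") the p-value is exact, by enumeration of all
#' choose(n_a + n_b, n_a) rank assignments; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#' Identical values across both groups give p = 1.
#'
#' @param a,b Numeric vectors (non-empty; NAs dropped).
#' @param mode "auto" (default), "exact" or "asymptotic".
#' @return List with \code{U} (for group a), \code{p} and \code{method}.
#' @export
mann_whitney <- function(a, b, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  na <- length(a)
  nb <- length(b)
  if (!na || !nb) stop("both groups must be non-empty", call. = FALSE)
  N <- na + nb
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (length(unique(pooled)) == 1L) {
    return(list(U = U, p = 1, method = "degenerate"))
  }
  exact <- switch(mode, exact = TRUE, asymptotic = FALSE, auto = N <= 12L)
  if (exact) {
    sets <- utils::combn(N, na)
    Us <- colSums(matrix(r[sets], nrow = na)) - na * (na + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U - mu) - 1e-9)
    method <- "exact"
  } else {
    ties <- table(r)
    s2 <- na * nb / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- max((abs(U - mu) - 0.5) / sqrt(s2), 0)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    method <- "asymptotic"
  }
  list(U = U, p = p, method = method)
}

#' Split patients into overall-survival bins
#'
#' Boundary convention: the middle bin is closed, i.e. [low, high]; the
#' outer bins are strict (< low and > high).  Empty bins raise a warning
#' so downstream pairwise comparisons can skip them.
#'
#' @param time Positive survival times (months).
#' @param breaks Two ascending boundaries (default c(12, 24)).
#' @return Factor with the three bin labels as levels.
#' @export
split_by_os <- function(time, breaks = c(12, 24)) {
  if (length(breaks) != 2L || breaks[1] >= breaks[2]) {
    stop("breaks must be two ascending values", call. = FALSE)
  }
  if (any(time <= 0, na.rm = TRUE)) stop("times must be positive",
                                         call. = FALSE)
  labs <- c(sprintf("OS<%g", breaks[1]),
            sprintf("OS%g-%g", breaks[1], breaks[2]),
            sprintf("OS>%g", breaks[2]))
  g <- ifelse(time < breaks[1], labs[1],
              ifelse(time <= breaks[2], labs[2], labs[3]))
  g <- factor(g, levels = labs)
  empty <- labs[tabulate(g, nbins = 3L) == 0L]
  if (length(empty)) {
    warning("empty OS group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  }
  g
}

#' Dichotomise expression into high and low groups
#'
#' The cut-off is the mean of the low-expression group; to make that
#' well defined, a provisional low half is first taken as all values at
#' or below the overall median, the cut-off is the mean of that half,
#' and the final groups are high (> cut-off) and low (<= cut-off).
#'
#' @param values Numeric vector, >= 4 non-missing, not all equal;
#'   optionally named by sample id.
#' @return List with \code{group} (factor "high"/"low", named like
#'   \code{values}) and \code{cutoff}.
#' @export
dichotomize <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 4L) stop("at least 4 values required", call. = FALSE)
  if (max(v) == min(v)) stop("all values identical; cannot dichotomise",
                             call. = FALSE)
  med <- stats::median(v)
  cutoff <- mean(v[v <= med])
  grp <- factor(ifelse(values > cutoff, "high", "low"),
                levels = c("high", "low"))
  names(grp) <- names(values)
  list(group = grp, cutoff = cutoff)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator with the usual convention that events precede
#' censorings at tied times.
#'
#' @param time Positive follow-up times.
#' @param event Logical (or 0/1) event indicators; FALSE = censored.
#' @return data.frame with columns time, n_risk, n_event, n_censor,
#'   survival (the step function; S = 1 before the first event).
#' @export
kaplan_meier <- function(time, event) {
  if (length(time) != length(event)) stop("time and event lengths differ",
                                          call. = FALSE)
  if (any(time <= 0)) stop("times must be positive", call. = FALSE)
  event <- as.logical(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Two-group log-rank test with an O/E hazard ratio
#'
#' Standard log-rank chi-square on the risk-set table, with the hazard
#' ratio of the first group relative to the second estimated as
#' (O1/E1) / (O2/E2) and its 95\% CI as
#' exp(log HR +/- 1.96 sqrt(1/E1 + 1/E2)).  Swapping the group labels
#' inverts the hazard ratio and leaves the p-value unchanged.
#'
#' @param time Positive follow-up times.
#' @param event Logical (or 0/1) event indicators.
#' @param group Factor (or coercible) with exactly two levels.
#' @return List with chi_square, p, hazard_ratio, ci_lower, ci_upper,
#'   observed, expected and groups (the level order used).
#' @export
log_rank <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two groups required",
                                 call. = FALSE)
  event <- as.logical(event)
  if (sum(event) < 1L) stop("at least one observed event required",
                            call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  obs <- unname(sd$obs)
  expct <- unname(sd$exp)
  chisq <- sd$chisq
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  if (any(expct <= 0)) {
    warning("zero expected events in a group; hazard ratio undefined",
            call. = FALSE)
    hr <- lo <- hi <- NA_real_
  } else {
    hr <- (obs[1L] / expct[1L]) / (obs[2L] / expct[2L])
    se <- sqrt(1 / expct[1L] + 1 / expct[2L])
    ci <- exp(log(hr) + c(-1, 1) * 1.96 * se)
    lo <- ci[1L]
    hi <- ci[2L]
    if (any(obs == 0)) {
      warning("no observed events in one group; hazard ratio degenerate",
              call. = FALSE)
    }
  }
  list(chi_square = chisq, p = p, hazard_ratio = hr,
       ci_lower = lo, ci_upper = hi,
       observed = obs, expected = expct, groups = levels(group))
}
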