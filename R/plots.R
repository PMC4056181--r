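#' Risk-allele count distributions among patients and nonpatients
#'
#' Tabulates the unweighted allele-count score separately for patients and
#' nonpatients as two normalized distributions over 0..2G (the histogram
#' routinely shown in prediction studies).
#'
#' @param cohort a [simulate_cohort()] result with at least one case and one
#'   control.
#' @return A data.frame with columns `allele_count`, `prop_patients`,
#'   `prop_nonpatients`; each proportion column sums to 1.
#' @export
allele_count_histogram <- function(cohort) {
  stopifnot(inherits(cohort, "genrisk_cohort"))
  counts <- unweighted_score(cohort$genotypes)
  status <- cohort$status
  if (!sum(status) || !sum(1 - status))
    stop("need at least one patient and one nonpatient", call. = FALSE)
  lev <- 0:(2L * ncol(cohort$genotypes))
  tab <- function(x) tabulate(factor(x, levels = lev), length(lev)) / length(x)
  data.frame(allele_count = lev,
             prop_patients = tab(counts[status == 1L]),
             prop_nonpatients = tab(counts[status == 0L]))
}

#' Empirical ROC curve points
#'
#' One `(1 - specificity, sensitivity)` point per distinct score threshold,
#' anchored at (0, 0) and (1, 1). The trapezoidal area under the returned
#' polyline equals the Mann-Whitney AUC exactly (half-credit ties become the
#' diagonal segments of tied thresholds).
#'
#' @param scores numeric score vector.
#' @param status 0/1 disease status (1 = case).
#' @return A data.frame with columns `fpr` (1 - specificity) and `tpr`
#'   (sensitivity), nondecreasing in both, with the trapezoidal AUC attached
#'   as attribute `"auc"`.
#' @export
roc_points <- function(scores, status) {
  status <- as.integer(status)
  n1 <- sum(status == 1L); n0 <- sum(status == 0L)
  if (n1 < 1L || n0 < 1L)
    stop("ROC curve is undefined without at least one case and one control",
         call. = FALSE)
  ## descending thresholds: classify positive when score >= threshold
  thr <- sort(unique(scores), decreasing = TRUE)
  cases_at <- tabulate(match(scores[status == 1L], thr), length(thr))
  ctrls_at <- tabulate(match(scores[status == 0L], thr), length(thr))
  out <- data.frame(fpr = c(0, cumsum(ctrls_at) / n0),
                    tpr = c(0, cumsum(cases_at) / n1))
  area <- sum(diff(out$fpr) * (utils::head(out$tpr, -1) +
                                 utils::tail(out$tpr, -1)) / 2)
  attr(out, "auc") <- area
  out
}

#' Odds ratios by quintile of genetic risk
#'
#' Splits individuals into five groups by their risk score and reports, per
#' quintile, the case/control counts and the odds ratio against the lowest
#' (reference) quintile with its Woolf 95\% CI ([ci_from_counts()]). Default
#' cut points are the 20/40/60/80 percentiles of the simulated score
#' distribution; external cut points (e.g. a published study's thresholds)
#' can be injected instead.
#'
#' @param scores numeric score vector.
#' @param status 0/1 disease status (1 = case).
#' @param thresholds optional 4 increasing cut points; scores are binned as
#'   `(-Inf, t1], (t1, t2], ..., (t4, Inf)`.
#' @return A data.frame of class `"quintile_or_table"` with columns
#'   `quintile`, `n_cases`, `n_controls`, `or_vs_reference`, `ci_low`,
#'   `ci_high` (reference row: OR 1, no CI); the cut points are attached as
#'   attribute `"thresholds"`.
#' @export
quintile_or_table <- function(scores, status, thresholds = NULL) {
  status <- as.integer(status)
  if (is.null(thresholds)) {
    if (length(unique(scores)) < 5L)
      stop("fewer than 5 distinct score values; supply external thresholds",
           call. = FALSE)
    thresholds <- unname(stats::quantile(scores, c(0.2, 0.4, 0.6, 0.8)))
  }
  if (length(thresholds) != 4L || is.unsorted(thresholds))
    stop("thresholds must be 4 nondecreasing cut points", call. = FALSE)
  ## (a, b] bins so that scores equal to a quantile cut point stay below it;
  ## tied cut points surface as an empty-cell error rather than silently
  bin <- findInterval(scores, thresholds, left.open = TRUE) + 1L
  n_cases <- tabulate(bin[status == 1L], 5L)
  n_ctrls <- tabulate(bin[status == 0L], 5L)
  empty <- which(n_cases == 0L | n_ctrls == 0L)
  if (length(empty))
    stop("empty case or control cell in quintile(s) ",
         paste(empty, collapse = ", "),
         "; no continuity correction is applied", call. = FALSE)
  or <- rep(1, 5L); lo <- rep(NA_real_, 5L); hi <- rep(NA_real_, 5L)
  for (q in 2:5) {
    est <- ci_from_counts(n_cases[q], n_ctrls[q], n_cases[1L], n_ctrls[1L])
    or[q] <- est[["or"]]; lo[q] <- est[["ci_low"]]; hi[q] <- est[["ci_high"]]
  }
  out <- data.frame(quintile = 1:5, n_cases = n_cases, n_controls = n_ctrls,
                    or_vs_reference = or, ci_low = lo, ci_high = hi)
  attr(out, "thresholds") <- thresholds
  class(out) <- c("quintile_or_table", "data.frame")
  out
}

#' Predicted risk against the number of risk alleles
#'
#' The scatter of naive-Bayes posterior risks over unweighted allele counts,
#' plus the squared Pearson correlation between count and risk (the R^2
#' routinely quoted alongside this plot).
#'
#' @param cohort a [simulate_cohort()] result.
#' @return A list with `points` (data.frame `allele_count`, `posterior_risk`)
#'   and `r_squared`.
#' @export
risk_vs_allele_scatter <- function(cohort) {
  stopifnot(inherits(cohort, "genrisk_cohort"))
  counts <- unweighted_score(cohort$genotypes)
  risk <- cohort$posterior_risk
  if (stats::var(counts) == 0)
    stop("allele counts are constant; R^2 is undefined", call. = FALSE)
  if (stats::var(risk) == 0)
    stop("posterior risks are constant; R^2 is undefined", call. = FALSE)
  list(points = data.frame(allele_count = counts, posterior_risk = risk),
       r_squared = stats::cor(counts, risk)^2)
}

#' Standard prediction-study plots for a simulated cohort
#'
#' Draws up to four panels: the risk-allele histogram by disease status, the
#' ROC curve of the study's risk model, the quintile odds-ratio plot, and
#' the risk-versus-allele-count scatter. For comparison against a published
#' figure, regenerate the cohort at the published study's sample size and
#' disease risk first (they drive the CI widths and absolute risks).
#'
#' @param x a [simulate_cohort()] result.
#' @param which subset of 1:4 selecting panels (histogram, ROC, quintiles,
#'   scatter).
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.genrisk_cohort <- function(x, which = 1:4, ...) {
  which <- intersect(which, 1:4)
  if (length(which) > 1L) {
    old <- graphics::par(mfrow = grDevices::n2mfrow(length(which)))
    on.exit(graphics::par(old))
  }
  score <- model_score(x, x$study$model_type)
  if (1 %in% which) {
    h <- allele_count_histogram(x)
    graphics::barplot(t(as.matrix(h[, c("prop_patients", "prop_nonpatients")])),
                      beside = TRUE, names.arg = h$allele_count,
                      col = c("firebrick", "grey70"),
                      xlab = "Number of risk alleles", ylab = "Proportion",
                      main = "Risk alleles by disease status")
    graphics::legend("topright", c("patients", "nonpatients"),
                     fill = c("firebrick", "grey70"), bty = "n")
  }
  if (2 %in% which) {
    roc <- roc_points(score, x$status)
    graphics::plot(roc$fpr, roc$tpr, type = "l", lwd = 2,
                   xlab = "1 - specificity", ylab = "Sensitivity",
                   main = sprintf("ROC (AUC = %.2f)", attr(roc, "auc")))
    graphics::abline(0, 1, lty = 3)
  }
  if (3 %in% which) {
    qt <- quintile_or_table(score, x$status)
    graphics::plot(qt$quintile, qt$or_vs_reference, pch = 19,
                   ylim = range(1, qt$ci_low, qt$ci_high, na.rm = TRUE),
                   xlab = "Quintile of genetic risk",
                   ylab = "Odds ratio vs lowest quintile",
                   main = "Quintile odds ratios")
    graphics::segments(qt$quintile, qt$ci_low, qt$quintile, qt$ci_high)
    graphics::abline(h = 1, lty = 3)
  }
  if (4 %in% which) {
    sc <- risk_vs_allele_scatter(x)
    idx <- if (nrow(sc$points) > 5000L)
      sample.int(nrow(sc$points), 5000L) else seq_len(nrow(sc$points))
    graphics::plot(jitter(sc$points$allele_count[idx], 0.4),
                   sc$points$posterior_risk[idx],
                   pch = ".", col = "steelblue",
                   xlab = "Number of risk alleles", ylab = "Predicted risk",
                   main = sprintf("Risk vs allele count (R² = %.2f)",
                                  sc$r_squared))
  }
  invisible(x)
}
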