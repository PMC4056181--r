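#' Risk-model scores for a simulated cohort
#'
#' The three risk models replicated by the package:
#' \describe{
#'   \item{unweighted}{total number of risk alleles across the panel, an
#'     integer in `[0, 2G]`;}
#'   \item{weighted}{sum of risk-allele counts weighted by the log of the
#'     per-allele odds ratio;}
#'   \item{bayes}{the naive-Bayes posterior disease risk itself (also the
#'     replication path for logistic-regression studies, since in-sample
#'     weights coincide with the generating log odds under linkage
#'     equilibrium and AUC is rank-invariant).}
#' }
#'
#' @param genotypes integer matrix of risk-allele counts, or a
#'   `genrisk_cohort` for `bayes_score()`/`model_score()`.
#' @return Numeric score vector, one value per individual.
#' @name risk_scores
NULL

#' @rdname risk_scores
#' @export
unweighted_score <- function(genotypes) {
  if (inherits(genotypes, "genrisk_cohort")) genotypes <- genotypes$genotypes
  as.numeric(rowSums(genotypes))
}

#' @rdname risk_scores
#' @param panel the [snp_panel] supplying the log-OR weights, aligned with
#'   the genotype columns.
#' @export
weighted_score <- function(genotypes, panel) {
  if (inherits(genotypes, "genrisk_cohort")) genotypes <- genotypes$genotypes
  if (nrow(panel) != ncol(genotypes))
    stop("panel and genotype matrix disagree on the number of SNPs",
         call. = FALSE)
  as.numeric(genotypes %*% log(panel$or_allele))
}

#' @rdname risk_scores
#' @param cohort a [simulate_cohort()] result.
#' @export
bayes_score <- function(cohort) {
  stopifnot(inherits(cohort, "genrisk_cohort"))
  cohort$posterior_risk
}

#' @rdname risk_scores
#' @param model_type which score to compute.
#' @export
model_score <- function(cohort,
                        model_type = c("bayes", "unweighted", "weighted")) {
  model_type <- match.arg(model_type)
  switch(model_type,
         bayes = bayes_score(cohort),
         unweighted = unweighted_score(cohort$genotypes),
         weighted = weighted_score(cohort$genotypes, cohort$study$snps))
}

#' Nonparametric AUC by the Mann-Whitney statistic
#'
#' The area under the empirical ROC curve equals the probability that a
#' randomly chosen case outscores a randomly chosen control, with ties
#' counted half — the Hanley-McNeil/Mann-Whitney estimator. Computed from
#' midrank sums in O(n log n); half-credit ties are essential for integer
#' allele-count scores.
#'
#' @param scores numeric score vector.
#' @param status 0/1 disease status aligned with `scores` (1 = case).
#' @return A list of class `"auc_estimate"` with `auc`, `n_cases`,
#'   `n_controls`.
#' @export
#' @examples
#' auc_mann_whitney(c(2, 3, 1, 2), c(1, 1, 0, 0))
auc_mann_whitney <- function(scores, status) {
  if (length(scores) != length(status))
    stop("scores and status lengths differ", call. = FALSE)
  status <- as.integer(status)
  n1 <- sum(status == 1L)
  n0 <- sum(status == 0L)
  if (n1 < 1L || n0 < 1L)
    stop("AUC is undefined without at least one case and one control",
         call. = FALSE)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[status == 1L]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
  structure(list(auc = auc, n_cases = n1, n_controls = n0),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC = %.2f (%d cases, %d controls)\n",
              x$auc, x$n_cases, x$n_controls))
  invisible(x)
}

#' Exact AUC by genotype enumeration (small panels)
#'
#' An exact oracle for validating the simulator: enumerates all `3^G`
#' genotype combinations of a panel, weights each by its Hardy-Weinberg
#' probability, splits that weight into a case part (probability x risk) and
#' a control part (probability x (1 - risk)) using the same
#' posterior-risk model as the simulator, scores every combination under the
#' requested model, and returns the exact tie-aware probability that a
#' random case outscores a random control. Refuses panels with more than 12
#' SNPs (enumeration grows as `3^G`).
#'
#' @param panel a [snp_panel] with at most 12 SNPs.
#' @param d population disease risk.
#' @param model_type score to evaluate.
#' @return The exact AUC as a single number.
#' @export
#' @examples
#' panel <- snp_panel("rs1", raf = 0.5, or_allele = 2)
#' analytic_auc(panel, d = 0.2)
analytic_auc <- function(panel,
                         d, model_type = c("bayes", "unweighted", "weighted")) {
  model_type <- match.arg(model_type)
  G <- nrow(panel)
  if (G > 12L)
    stop("analytic_auc enumerates 3^G genotype combinations and refuses ",
         "panels with more than 12 SNPs (got ", G, ")", call. = FALSE)
  profiles <- lapply(seq_len(G), function(g)
    solve_baseline_risk(panel$raf[g], panel$or_allele[g], d))
  combos <- as.matrix(expand.grid(rep(list(0:2), G)))
  prob <- rep(1, nrow(combos))
  log_lr <- numeric(nrow(combos))
  for (g in seq_len(G)) {
    prob <- prob * profiles[[g]]$geno_freqs[combos[, g] + 1L]
    log_lr <- log_lr + log(profiles[[g]]$lrs)[combos[, g] + 1L]
  }
  odds <- d / (1 - d) * exp(log_lr)
  risk <- odds / (1 + odds)
  score <- switch(model_type,
                  bayes = risk,
                  unweighted = rowSums(combos),
                  weighted = as.numeric(combos %*% log(panel$or_allele)))
  case_w <- prob * risk
  ctrl_w <- prob * (1 - risk)
  case_w <- case_w / sum(case_w)
  ctrl_w <- ctrl_w / sum(ctrl_w)
  ## collapse to distinct score values, then one pass over the sorted grid
  o <- order(score)
  score <- score[o]; case_w <- case_w[o]; ctrl_w <- ctrl_w[o]
  grp <- cumsum(c(TRUE, diff(score) > 0))
  cw <- tapply(case_w, grp, sum)
  nw <- tapply(ctrl_w, grp, sum)
  ctrl_below <- cumsum(nw) - nw
  sum(cw * (ctrl_below + 0.5 * nw))
}

#' In-sample logistic refit cross-check
#'
#' Fits an additive main-effects logistic regression of disease status on the
#' risk-allele counts within the simulated cohort and returns the AUC of the
#' fitted probabilities. Under linkage equilibrium the jointly estimated
#' weights converge to the generating marginal log odds, so this AUC should
#' agree with the posterior-risk AUC up to Monte-Carlo error — a validation
#' utility, not the replication path.
#'
#' @param cohort a [simulate_cohort()] result.
#' @return An `"auc_estimate"` with an extra `fit` component (the `glm`).
#' @export
refit_logistic_auc <- function(cohort) {
  stopifnot(inherits(cohort, "genrisk_cohort"))
  geno <- cohort$genotypes
  constant <- apply(geno, 2L, function(col) length(unique(col)) == 1L)
  if (any(constant))
    stop("constant genotype column(s): ",
         paste(colnames(geno)[constant], collapse = ", "), call. = FALSE)
  df <- data.frame(status = cohort$status, geno, check.names = TRUE)
  fit <- stats::glm(status ~ ., family = stats::binomial(), data = df)
  if (!fit$converged)
    stop("logistic refit did not converge (possible separation); ",
         "deviance = ", format(fit$deviance), call. = FALSE)
  est <- auc_mann_whitney(stats::fitted(fit), cohort$status)
  est$fit <- fit
  est
}
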