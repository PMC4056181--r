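#' Hardy-Weinberg genotype frequencies
#'
#' Genotype probabilities for 0, 1 and 2 copies of an allele with population
#' frequency `raf`, assuming Hardy-Weinberg equilibrium:
#' `((1 - raf)^2, 2 raf (1 - raf), raf^2)`.
#'
#' @param raf allele frequency in `[0, 1]` (scalar or vector).
#' @return For a scalar, a numeric vector `c(g0, g1, g2)`; for a vector, a
#'   matrix with one row per frequency and columns `g0`, `g1`, `g2`.
#' @export
#' @examples
#' hwe_genotype_freqs(0.3)
hwe_genotype_freqs <- function(raf) {
  if (any(!is.finite(raf) | raf < 0 | raf > 1))
    stop("raf must lie in [0, 1]", call. = FALSE)
  out <- cbind(g0 = (1 - raf)^2, g1 = 2 * raf * (1 - raf), g2 = raf^2)
  if (length(raf) == 1L) out[1L, ] else out
}

## Trinomial genotype draw for one SNP from the current RNG stream.
.draw_genotypes <- function(raf, n) {
  sample.int(3L, n, replace = TRUE, prob = hwe_genotype_freqs(raf)) - 1L
}

.sample_genotypes <- function(panel, n_sim) {
  G <- nrow(panel)
  counts <- matrix(0L, nrow = n_sim, ncol = G,
                   dimnames = list(NULL, panel$snp_id))
  for (g in seq_len(G))
    counts[, g] <- .draw_genotypes(panel$raf[g], n_sim)
  counts
}

#' Sample a genotype matrix under Hardy-Weinberg and linkage equilibrium
#'
#' Each SNP's column is an independent trinomial draw of `n_sim` genotypes
#' (risk-allele counts 0/1/2) from its Hardy-Weinberg frequencies; columns
#' are mutually independent (linkage equilibrium).
#'
#' @param panel a [snp_panel].
#' @param n_sim number of individuals.
#' @param rng_seed integer seed; the same seed reproduces the same matrix.
#' @return Integer matrix of dimension `n_sim` x `nrow(panel)` with SNP ids
#'   as column names.
#' @export
sample_genotypes <- function(panel, n_sim, rng_seed = NULL) {
  stopifnot(n_sim >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  .sample_genotypes(panel, as.integer(n_sim))
}

#' Solve per-genotype disease risks for one SNP
#'
#' Finds the genotype-specific disease risks implied by a per-allele odds
#' ratio under the multiplicative model, constrained so that the
#' genotype-frequency-weighted risk equals the population disease risk `d`.
#' With baseline odds `o0` for the homozygous nonrisk genotype, genotype `i`
#' has odds `o0 * OR^i`; `o0` is the unique root of
#' \deqn{\sum_i g_i \frac{o_0 OR^i}{1 + o_0 OR^i} = d,}
#' located by bisection on `log(o0)` over `[-40, 40]` (the left side is
#' strictly increasing in `o0`). Genotype likelihood ratios follow as
#' `LR_i = p_i (1 - d) / (d (1 - p_i))`, which satisfy `LR_i / LR_0 = OR^i`
#' and average to 1 over the control genotype distribution.
#'
#' @param raf risk-allele frequency of the SNP.
#' @param or_allele per-allele odds ratio (>= 1 after normalization).
#' @param d population disease risk in (0, 1).
#' @return A list of class `"genotype_risk_profile"` with components
#'   `geno_freqs` (g0, g1, g2), `geno_risks` (p0, p1, p2) and
#'   `lrs` (LR0, LR1, LR2).
#' @export
#' @examples
#' solve_baseline_risk(raf = 0.5, or_allele = 2, d = 0.2)
solve_baseline_risk <- function(raf, or_allele, d) {
  stopifnot(d > 0, d < 1, or_allele > 0)
  g <- hwe_genotype_freqs(raf)
  or_pow <- or_allele^(0:2)
  prevalence <- function(log_o0) {
    odds <- exp(log_o0) * or_pow
    sum(g * odds / (1 + odds))
  }
  lo <- -40; hi <- 40
  if (prevalence(lo) > d || prevalence(hi) < d)
    stop("failed to bracket baseline odds root", call. = FALSE)
  mid <- 0
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    f <- prevalence(mid)
    if (abs(f - d) <= 1e-12) break
    if (f < d) lo <- mid else hi <- mid
  }
  odds <- exp(mid) * or_pow
  p <- odds / (1 + odds)
  lr <- p * (1 - d) / (d * (1 - p))
  structure(list(geno_freqs = g, geno_risks = p, lrs = lr,
                 raf = raf, or_allele = or_allele, d = d),
            class = "genotype_risk_profile")
}

#' @export
print.genotype_risk_profile <- function(x, ...) {
  cat(sprintf("Genotype risk profile (raf = %g, OR = %g, d = %g)\n",
              x$raf, x$or_allele, x$d))
  m <- rbind(frequency = x$geno_freqs, risk = x$geno_risks, LR = x$lrs)
  colnames(m) <- paste0("geno", 0:2)
  print(round(m, 4))
  invisible(x)
}

#' Naive-Bayes posterior disease risks
#'
#' For each individual, the posterior odds of disease are the prior odds
#' `d / (1 - d)` multiplied by the genotype likelihood ratios of all SNPs
#' (independent effects, the naive-Bayes assumption); the posterior risk is
#' `odds / (1 + odds)`.
#'
#' @param genotypes integer matrix of risk-allele counts
#'   (from [sample_genotypes()]).
#' @param profiles list of [solve_baseline_risk()] profiles, one per column
#'   of `genotypes`, in column order.
#' @param d population disease risk.
#' @return Numeric vector of posterior risks in (0, 1).
#' @export
posterior_risks <- function(genotypes, profiles, d) {
  if (length(profiles) != ncol(genotypes))
    stop("need one genotype risk profile per SNP column", call. = FALSE)
  log_lr <- numeric(nrow(genotypes))
  for (g in seq_along(profiles))
    log_lr <- log_lr + log(profiles[[g]]$lrs)[genotypes[, g] + 1L]
  odds <- d / (1 - d) * exp(log_lr)
  odds / (1 + odds)
}

.assign_status <- function(risks) {
  as.integer(risks > stats::runif(length(risks)))
}

#' Assign disease status by comparing risks to uniform draws
#'
#' Each individual becomes a patient when their disease risk exceeds an
#' independent uniform(0, 1) draw, so the expected prevalence equals the mean
#' risk.
#'
#' @param risks numeric vector of disease risks in (0, 1).
#' @param rng_seed integer seed for the uniform draws.
#' @return Integer vector of 0/1 status (1 = patient).
#' @export
assign_status <- function(risks, rng_seed = NULL) {
  if (any(risks <= 0 | risks >= 1))
    stop("risks must lie strictly in (0, 1)", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  .assign_status(risks)
}

## Full cohort construction from the current RNG stream (no seeding).
.simulate_cohort <- function(study, seed = NA_integer_) {
  panel <- study$snps
  genotypes <- .sample_genotypes(panel, study$n_sim)
  profiles <- lapply(seq_len(nrow(panel)), function(g)
    solve_baseline_risk(panel$raf[g], panel$or_allele[g], study$d))
  risk <- posterior_risks(genotypes, profiles, study$d)
  status <- .assign_status(risk)
  structure(list(genotypes = genotypes, posterior_risk = risk,
                 status = status, profiles = profiles, study = study,
                 seed = seed),
            class = "genrisk_cohort")
}

#' Simulate a hypothetical cohort
#'
#' Constructs genotypes, naive-Bayes posterior disease risks and disease
#' status for `study$n_sim` individuals, so that allele frequencies,
#' per-allele odds ratios and prevalence re-estimated from the realized data
#' match the generating parameters up to sampling error. The three steps are
#' (1) independent Hardy-Weinberg genotype draws per SNP, (2) posterior risk
#' from Bayes' theorem with per-SNP genotype likelihood ratios, and
#' (3) status assignment against uniform draws.
#'
#' @param study a [study_spec].
#' @param rng_seed integer seed; identical study and seed give an identical
#'   cohort.
#' @return An object of class `"genrisk_cohort"`: a list with `genotypes`
#'   (integer matrix), `posterior_risk`, `status`, the per-SNP `profiles`,
#'   the generating `study` and the `seed`.
#' @export
#' @examples
#' panel <- snp_panel(c("rs1", "rs2"), raf = c(0.3, 0.6),
#'                    or_allele = c(1.4, 1.2))
#' study <- study_spec("toy", panel, d = 0.2, n_sim = 2000)
#' cohort <- simulate_cohort(study, rng_seed = 1)
#' summary(cohort)
simulate_cohort <- function(study, rng_seed) {
  stopifnot(inherits(study, "study_spec"))
  set.seed(rng_seed)
  .simulate_cohort(study, seed = as.integer(rng_seed))
}

#' @export
print.genrisk_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort for study '%s': %d individuals, %d SNPs\n",
              x$study$study_id, nrow(x$genotypes), ncol(x$genotypes)))
  cat(sprintf("  prevalence %.4f (target d = %g), seed %d\n",
              mean(x$status), x$study$d, x$seed))
  invisible(x)
}

#' @export
summary.genrisk_cohort <- function(object, ...) {
  emp_raf <- colMeans(object$genotypes) / 2
  out <- list(
    study_id = object$study$study_id,
    n_sim = nrow(object$genotypes),
    n_cases = sum(object$status),
    prevalence = mean(object$status),
    d = object$study$d,
    raf = data.frame(snp_id = colnames(object$genotypes),
                     input_raf = object$study$snps$raf,
                     empirical_raf = emp_raf, row.names = NULL),
    mean_risk = mean(object$posterior_risk),
    auc_bayes = auc_mann_whitney(object$posterior_risk, object$status)$auc)
  class(out) <- "summary.genrisk_cohort"
  out
}

#' @export
print.summary.genrisk_cohort <- function(x, ...) {
  cat(sprintf("Cohort '%s': %d individuals, %d cases (prevalence %.4f, d = %g)\n",
              x$study_id, x$n_sim, x$n_cases, x$prevalence, x$d))
  cat(sprintf("  mean posterior risk %.4f; AUC of posterior risk %.3f\n",
              x$mean_risk, x$auc_bayes))
  cat("  per-SNP empirical vs input risk-allele frequency:\n")
  print(transform(x$raf, empirical_raf = round(empirical_raf, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Write a simulated cohort to a delimited file
#'
#' Individual-major export: one row per individual with the 0/1/2 risk-allele
#' count per SNP, the posterior risk, and the disease status. With
#' `panel_major = TRUE` the genotype block is transposed (one row per SNP),
#' and risk/status are omitted.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param path output file path.
#' @param panel_major transpose to one row per SNP.
#' @param sep field separator (default tab).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, panel_major = FALSE, sep = "\t") {
  if (panel_major) {
    out <- data.frame(snp_id = colnames(cohort$genotypes),
                      t(cohort$genotypes), check.names = FALSE)
    names(out)[-1L] <- paste0("ind", seq_len(nrow(cohort$genotypes)))
  } else {
    out <- data.frame(cohort$genotypes, check.names = FALSE)
    out$posterior_risk <- cohort$posterior_risk
    out$status <- cohort$status
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
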