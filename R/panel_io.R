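#' Construct a SNP panel
#'
#' A SNP panel is the atomic parameter set of the simulator: one row per SNP
#' with its risk-allele frequency, per-allele odds ratio and (optionally) the
#' 95\% confidence bounds on that odds ratio. Rows whose odds ratio is below 1
#' are reoriented to the risk allele (see [normalize_panel()]), so that after
#' construction every odds ratio is at least 1 and `raf` always refers to the
#' allele that increases disease odds.
#'
#' @param snp_id character vector of SNP identifiers (e.g. rsIDs), unique.
#' @param raf risk-allele frequencies, strictly inside (0, 1).
#' @param or_allele per-allele odds ratios, positive.
#' @param ci_low,ci_high optional 95\% confidence bounds on `or_allele`;
#'   either both present (per row) or both `NA`.
#' @param normalize apply the risk-allele flip rule (default `TRUE`).
#'
#' @return A `data.frame` of class `"snp_panel"` with columns
#'   `snp_id`, `raf`, `or_allele`, `ci_low`, `ci_high`.
#' @seealso [read_panel()], [normalize_panel()]
#' @export
#' @examples
#' snp_panel("rs7903146", raf = 0.30, or_allele = 1.38,
#'           ci_low = 1.31, ci_high = 1.46)
snp_panel <- function(snp_id, raf, or_allele, ci_low = NA_real_,
                      ci_high = NA_real_, normalize = TRUE) {
  panel <- data.frame(
    snp_id    = as.character(snp_id),
    raf       = as.numeric(raf),
    or_allele = as.numeric(or_allele),
    ci_low    = as.numeric(ci_low),
    ci_high   = as.numeric(ci_high),
    stringsAsFactors = FALSE
  )
  validate_panel(panel)
  if (normalize) panel <- normalize_panel(panel)
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

validate_panel <- function(panel) {
  req <- c("snp_id", "raf", "or_allele")
  missing_cols <- setdiff(req, names(panel))
  if (length(missing_cols))
    stop("panel is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!nrow(panel)) stop("panel has no SNPs", call. = FALSE)
  if (anyDuplicated(panel$snp_id))
    stop("duplicated snp_id in panel: ",
         paste(unique(panel$snp_id[duplicated(panel$snp_id)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(panel$raf) | panel$raf <= 0 | panel$raf >= 1)
  if (length(bad))
    stop("raf must lie strictly in (0, 1); offending row(s): ",
         paste(panel$snp_id[bad], collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(panel$or_allele) | panel$or_allele <= 0)
  if (length(bad))
    stop("or_allele must be positive; offending row(s): ",
         paste(panel$snp_id[bad], collapse = ", "), call. = FALSE)
  has_ci <- !is.na(panel$ci_low) | !is.na(panel$ci_high)
  if (any(has_ci & (is.na(panel$ci_low) | is.na(panel$ci_high))))
    stop("ci_low and ci_high must be given together", call. = FALSE)
  both <- !is.na(panel$ci_low) & !is.na(panel$ci_high)
  bad <- which(both & (panel$ci_low <= 0 | panel$ci_low > panel$or_allele |
                         panel$ci_high < panel$or_allele))
  if (length(bad))
    stop("confidence bounds must satisfy 0 < ci_low <= or_allele <= ci_high; ",
         "offending row(s): ", paste(panel$snp_id[bad], collapse = ", "),
         call. = FALSE)
  invisible(panel)
}

#' Reorient a panel to risk alleles
#'
#' If a row's per-allele odds ratio is below 1, the tabulated allele is
#' protective and the other allele is the risk allele. The unique conversion
#' consistent with a biallelic 2x2 table replaces
#' `(raf, or, ci_low, ci_high)` by `(1 - raf, 1/or, 1/ci_high, 1/ci_low)`.
#' Applying the rule twice is the identity on an already-normalized panel.
#'
#' @param panel a `snp_panel` or compatible data.frame.
#' @return The panel with every `or_allele >= 1`.
#' @export
normalize_panel <- function(panel) {
  flip <- which(panel$or_allele < 1)
  if (length(flip)) {
    panel$raf[flip] <- 1 - panel$raf[flip]
    old_lo <- panel$ci_low[flip]
    panel$ci_low[flip]  <- 1 / panel$ci_high[flip]
    panel$ci_high[flip] <- 1 / old_lo
    panel$or_allele[flip] <- 1 / panel$or_allele[flip]
  }
  panel
}

#' Read a SNP panel from a tab-separated file
#'
#' Expects a UTF-8, tab-separated table with a header naming at least
#' `snp_id`, `raf` and `or_allele` (`ci_low`/`ci_high` optional); lines
#' starting with `#` are ignored. Rows are validated and reoriented to the
#' risk allele on the way in.
#'
#' @param path path to the panel file.
#' @return A [snp_panel] in file order.
#' @export
#' @examples
#' godarts <- read_panel(genrisk_extdata("t2d_godarts.tsv"))
#' nrow(godarts)
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  for (col in c("ci_low", "ci_high"))
    if (!col %in% names(raw)) raw[[col]] <- NA_real_
  missing_cols <- setdiff(c("snp_id", "raf", "or_allele"), names(raw))
  if (length(missing_cols))
    stop("panel file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  snp_panel(raw$snp_id, raw$raf, raw$or_allele, raw$ci_low, raw$ci_high)
}

#' Odds ratio and Woolf confidence interval from allele counts
#'
#' Given the 2x2 allele-by-disease-status table (risk / nonrisk allele counts
#' in cases and controls), returns the allelic odds ratio with its Woolf
#' (log-scale normal approximation) 95\% confidence interval:
#' \deqn{OR = \frac{a e}{b c}, \quad
#'   CI = \exp\left(\ln OR \pm 1.96 \sqrt{1/a + 1/b + 1/c + 1/e}\right)}
#'
#' No continuity correction is applied: zero cells are an error, and callers
#' who want a correction must add it to the counts explicitly.
#'
#' @param a risk-allele count in cases.
#' @param b nonrisk-allele count in cases.
#' @param c risk-allele count in controls.
#' @param e nonrisk-allele count in controls.
#' @return A named numeric vector `c(or, ci_low, ci_high)`.
#' @export
#' @examples
#' ci_from_counts(10, 90, 5, 95)
ci_from_counts <- function(a, b, c, e) {
  counts <- c(a = a, b = b, c = c, e = e)
  if (any(!is.finite(counts) | counts < 0))
    stop("allele counts must be finite and non-negative", call. = FALSE)
  if (any(counts == 0))
    stop("zero cell in the 2x2 allele table; apply a continuity correction ",
         "to the counts explicitly before calling ci_from_counts()",
         call. = FALSE)
  or <- (a * e) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / e)
  c(or = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se))
}

#' Standard deviation of the log odds ratio implied by a 95\% CI
#'
#' Inverts the normal-approximation interval: a 95\% CI `(lo, hi)` on an odds
#' ratio corresponds to a log-scale standard error
#' `(log(hi) - log(lo)) / (2 * qnorm(0.975))`. This is the sampling SD used
#' when odds ratios are redrawn from their published intervals
#' (see [sample_ors()]).
#'
#' @param ci_low,ci_high numeric vectors of confidence bounds, recycled.
#' @return Numeric vector of log-OR standard deviations.
#' @export
#' @examples
#' log_or_sd_from_ci(1.31, 1.46)
log_or_sd_from_ci <- function(ci_low, ci_high) {
  if (any(is.na(ci_low) | is.na(ci_high)))
    stop("confidence bounds are absent; use the point-estimate strategy ",
         "for SNPs without a CI", call. = FALSE)
  if (any(ci_low <= 0 | ci_high < ci_low))
    stop("need 0 < ci_low <= ci_high", call. = FALSE)
  (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
}

#' Path to a packaged data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
genrisk_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "genrisksim")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop("no packaged file called ", file, call. = FALSE)
  path
}

#' Population disease risks used in the shipped study configurations
#'
#' Average population risks for the six diseases covered by the packaged
#' panels and benchmark: type 2 diabetes 0.20, prostate cancer 0.15,
#' type 1 diabetes 0.002, age-related macular degeneration 0.065,
#' colorectal cancer 0.048 and Crohn disease 0.002.
#'
#' @return A data.frame with columns `disease` and `d`.
#' @export
disease_risks <- function() {
  utils::read.delim(genrisk_extdata("disease_risks.tsv"), comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Published-versus-simulated AUC benchmark
#'
#' The replication benchmark shipped with the package: one row per published
#' genetic risk prediction study, with the AUC reported by that study
#' (`published_auc`) and the AUC obtained for it by this simulation approach
#' (`simulated_auc`), grouped by how the study built its risk model
#' (unweighted allele score, weighted score, or logistic regression).
#' Feed it to [compare_to_published()] to recover the accuracy summaries.
#'
#' @return A data.frame with columns `study_id`, `disease`, `design`,
#'   `sample_size`, `n_snps`, `model_type`, `published_auc`, `simulated_auc`.
#' @export
replication_benchmark <- function() {
  utils::read.delim(genrisk_extdata("replication_benchmark.tsv"),
                    comment.char = "#", stringsAsFactors = FALSE)
}
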