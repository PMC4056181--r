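## Round half away from zero at `digits` decimals; published AUCs are printed
## at 2 decimals, and R's round() would take 0.015 to 0.01.
round_half_away <- function(x, digits = 2L) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

.sample_ors <- function(panel) {
  sd <- log_or_sd_from_ci(panel$ci_low, panel$ci_high)
  panel$or_allele <- exp(stats::rnorm(nrow(panel), log(panel$or_allele), sd))
  normalize_panel(panel)
}

#' Redraw panel odds ratios from their confidence intervals
#'
#' Draws each SNP's log odds ratio from a normal distribution centred at the
#' published log OR with standard deviation implied by its 95\% CI
#' ([log_or_sd_from_ci()]), i.e. a log-normal draw on the OR scale that can
#' never go negative. Draws that fall below 1 are reoriented to the risk
#' allele by the flip rule rather than truncated, preserving the sampling
#' distribution.
#'
#' @param panel a [snp_panel]; every row must carry a CI.
#' @param rng_seed integer seed.
#' @return The panel with resampled `or_allele` values.
#' @export
sample_ors <- function(panel, rng_seed = NULL) {
  if (any(is.na(panel$ci_low) | is.na(panel$ci_high)))
    stop("every SNP needs a confidence interval to resample odds ratios; ",
         "use the point-estimate strategy otherwise", call. = FALSE)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  .sample_ors(panel)
}

#' Run the repeated-simulation replication protocol for one study
#'
#' Simulates the study `n_iter` times and averages the AUC of its risk model
#' across iterations. Iteration `k` seeds the generator with
#' `base_seed + k`; under the `"ci_sampled"` strategy each iteration first
#' redraws the panel's odds ratios from their 95\% CIs, so the draw defines
#' that iteration's generating model (one redraw per iteration, not per
#' individual).
#'
#' @param study a [study_spec]; its `model_type`, `n_sim` and `n_iter`
#'   control the protocol.
#' @param or_strategy `"point"` (published point estimates throughout) or
#'   `"ci_sampled"` (redraw per iteration).
#' @param base_seed integer; identical study, strategy and seed reproduce
#'   the result bit for bit.
#' @return An object of class `"replication_result"`: `study_id`,
#'   `model_type`, `or_strategy`, `mean_auc`, `per_iteration_auc`,
#'   `published_auc` (may be `NULL`), `abs_diff` (|2-dp mean - published|,
#'   present iff a published AUC is), `base_seed`.
#' @export
#' @examples
#' panel <- snp_panel(c("rs1", "rs2"), raf = c(0.3, 0.6),
#'                    or_allele = c(1.4, 1.2))
#' study <- study_spec("toy", panel, d = 0.2, n_sim = 2000, n_iter = 5)
#' run_replication(study, base_seed = 42)
run_replication <- function(study, or_strategy = c("point", "ci_sampled"),
                            base_seed) {
  stopifnot(inherits(study, "study_spec"))
  or_strategy <- match.arg(or_strategy)
  if (or_strategy == "ci_sampled" &&
      any(is.na(study$snps$ci_low) | is.na(study$snps$ci_high)))
    stop("ci_sampled strategy needs a CI for every SNP; ",
         "use or_strategy = \"point\"", call. = FALSE)
  base_seed <- as.integer(base_seed)
  aucs <- numeric(study$n_iter)
  for (k in seq_len(study$n_iter)) {
    res <- tryCatch({
      set.seed(base_seed + k)
      iter_study <- study
      if (or_strategy == "ci_sampled")
        iter_study$snps <- .sample_ors(study$snps)
      cohort <- .simulate_cohort(iter_study, seed = base_seed + k)
      auc_mann_whitney(model_score(cohort, study$model_type),
                       cohort$status)$auc
    }, error = function(e)
      stop("iteration ", k, ": ", conditionMessage(e), call. = FALSE))
    aucs[k] <- res
  }
  mean_auc <- mean(aucs)
  out <- list(study_id = study$study_id, model_type = study$model_type,
              or_strategy = or_strategy, mean_auc = mean_auc,
              per_iteration_auc = aucs,
              published_auc = study$published_auc,
              abs_diff = if (is.null(study$published_auc)) NULL else
                round_half_away(abs(round_half_away(mean_auc) -
                                      round_half_away(study$published_auc))),
              base_seed = base_seed)
  class(out) <- "replication_result"
  out
}

#' @export
print.replication_result <- function(x, ...) {
  cat(sprintf("Replication of '%s' (%s score, %s ORs, %d iterations)\n",
              x$study_id, x$model_type, x$or_strategy,
              length(x$per_iteration_auc)))
  cat(sprintf("  mean AUC %.2f (full precision %.4f, iteration SD %.4f)\n",
              round_half_away(x$mean_auc), x$mean_auc,
              stats::sd(x$per_iteration_auc)))
  if (!is.null(x$published_auc))
    cat(sprintf("  published AUC %.2f; |difference| %.2f\n",
                x$published_auc, x$abs_diff))
  invisible(x)
}

#' Compare replication results with published AUC values
#'
#' Builds the accuracy report: per-study absolute differences between the
#' published AUC and the simulation estimate, and per-model-type median,
#' minimum and maximum of those differences. All arithmetic is on
#' 2-decimal-rounded AUCs, the precision at which prediction studies report
#' them; medians of even-sized groups use the midpoint of the two central
#' values and are reported rounded to 2 decimals half-away-from-zero.
#'
#' @param results either a list of [run_replication()] results (each with a
#'   published AUC) or a data.frame with columns `model_type`,
#'   `published_auc` and one of `simulated_auc`/`mean_auc` (e.g.
#'   [replication_benchmark()]).
#' @return An object of class `"replication_report"`: `rows` (one per study,
#'   with `abs_diff`) and `summaries` (per model type: `n`,
#'   `median_abs_diff`, `min_abs_diff`, `max_abs_diff`).
#' @export
#' @examples
#' compare_to_published(replication_benchmark())
compare_to_published <- function(results) {
  if (inherits(results, "replication_result")) results <- list(results)
  if (is.data.frame(results)) {
    est_col <- intersect(c("simulated_auc", "mean_auc"), names(results))[1L]
    if (is.na(est_col))
      stop("data.frame input needs a simulated_auc or mean_auc column",
           call. = FALSE)
    rows <- data.frame(
      study_id = if ("study_id" %in% names(results)) results$study_id
                 else paste0("study", seq_len(nrow(results))),
      model_type = results$model_type,
      published_auc = results$published_auc,
      estimated_auc = results[[est_col]],
      stringsAsFactors = FALSE)
  } else {
    if (!length(results)) stop("no replication results given", call. = FALSE)
    rows <- do.call(rbind, lapply(results, function(r) {
      if (is.null(r$published_auc))
        stop("replication result '", r$study_id,
             "' has no published AUC to compare against", call. = FALSE)
      data.frame(study_id = r$study_id, model_type = r$model_type,
                 published_auc = r$published_auc, estimated_auc = r$mean_auc,
                 stringsAsFactors = FALSE)
    }))
  }
  if (!nrow(rows)) stop("no replication results given", call. = FALSE)
  rows$abs_diff <- round_half_away(abs(round_half_away(rows$estimated_auc) -
                                         round_half_away(rows$published_auc)))
  groups <- split(rows$abs_diff, rows$model_type)
  summaries <- data.frame(
    model_type = names(groups),
    n = vapply(groups, length, integer(1)),
    median_abs_diff = vapply(groups, function(x)
      round_half_away(stats::median(x)), numeric(1)),
    min_abs_diff = vapply(groups, min, numeric(1)),
    max_abs_diff = vapply(groups, max, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(rows = rows, summaries = summaries),
            class = "replication_report")
}

#' @export
print.replication_report <- function(x, ...) {
  cat("Replication accuracy report (", nrow(x$rows), " studies)\n", sep = "")
  cat("\nPer-model-type |published - estimated| AUC summaries",
      " (2-decimal values):\n", sep = "")
  print(x$summaries, row.names = FALSE)
  invisible(x)
}

#' @export
summary.replication_report <- function(object, ...) {
  print(object)
  cat("\nPer-study rows:\n")
  print(object$rows, row.names = FALSE)
  invisible(object)
}
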