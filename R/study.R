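#' Define a study to simulate
#'
#' Bundles a SNP panel with the epidemiological context needed to simulate a
#' cohort: the population disease risk `d` (the Bayes prior), the type of risk
#' model the original study used, and the simulation protocol sizes.
#'
#' @param study_id short label for the study.
#' @param snps a [snp_panel].
#' @param d population disease risk, strictly in (0, 1).
#' @param model_type `"unweighted"` (allele count), `"weighted"`
#'   (sum of log odds ratios) or `"bayes"` (posterior risk; also used to
#'   replicate logistic-regression studies, whose in-sample weights coincide
#'   with the generating log odds under linkage equilibrium).
#' @param disease optional disease label.
#' @param n_sim simulated cohort size (default 100000).
#' @param n_iter number of simulation iterations in the replication protocol
#'   (default 100).
#' @param published_auc optional AUC reported by the original study, in
#'   `[0.5, 1]`.
#' @param published_n optional sample size of the original study; only used
#'   when regenerating plots at the published study's size.
#'
#' @return An object of class `"study_spec"`.
#' @seealso [simulate_cohort()], [run_replication()]
#' @export
#' @examples
#' panel <- snp_panel(c("rs1", "rs2"), raf = c(0.3, 0.6),
#'                    or_allele = c(1.4, 1.2))
#' study_spec("toy", panel, d = 0.2, model_type = "bayes", n_sim = 1000)
study_spec <- function(study_id, snps, d,
                       model_type = c("bayes", "unweighted", "weighted"),
                       disease = NA_character_, n_sim = 100000L,
                       n_iter = 100L, published_auc = NULL,
                       published_n = NULL) {
  model_type <- match.arg(model_type)
  stopifnot(is.character(study_id), length(study_id) == 1L)
  if (!inherits(snps, "snp_panel"))
    snps <- snp_panel(snps$snp_id, snps$raf, snps$or_allele,
                      snps$ci_low, snps$ci_high)
  validate_panel(snps)
  if (!is.numeric(d) || length(d) != 1L || d <= 0 || d >= 1)
    stop("d (population disease risk) must lie strictly in (0, 1)",
         call. = FALSE)
  n_sim <- as.integer(n_sim)
  n_iter <- as.integer(n_iter)
  if (n_sim < 1L) stop("n_sim must be a positive integer", call. = FALSE)
  if (n_iter < 1L) stop("n_iter must be a positive integer", call. = FALSE)
  if (!is.null(published_auc) &&
      (published_auc < 0.5 || published_auc > 1))
    stop("published_auc must lie in [0.5, 1]", call. = FALSE)
  if (!is.null(published_n) && published_n < 1)
    stop("published_n must be a positive integer", call. = FALSE)
  structure(
    list(study_id = study_id, disease = disease, d = d,
         model_type = model_type, snps = snps, n_sim = n_sim,
         n_iter = n_iter, published_auc = published_auc,
         published_n = if (is.null(published_n)) NULL
                       else as.integer(published_n)),
    class = "study_spec")
}

#' @export
print.study_spec <- function(x, ...) {
  cat("Study specification:", x$study_id,
      if (!is.na(x$disease)) paste0("(", x$disease, ")"), "\n")
  cat(sprintf("  %d SNPs, population disease risk d = %g\n",
              nrow(x$snps), x$d))
  cat(sprintf("  risk model: %s; n_sim = %d, n_iter = %d\n",
              x$model_type, x$n_sim, x$n_iter))
  if (!is.null(x$published_auc))
    cat(sprintf("  published AUC: %.2f%s\n", x$published_auc,
                if (!is.null(x$published_n))
                  sprintf(" (n = %d)", x$published_n) else ""))
  invisible(x)
}

#' Read a study configuration file
#'
#' A study configuration is a flat YAML file with keys `study_id`, `panel`
#' (path to the panel TSV, relative paths resolved against the config file's
#' directory), `d`, `model_type`, and optionally `disease`, `n_sim`,
#' `n_iter`, `published_auc`, `published_n`.
#'
#' @param path path to the YAML file.
#' @return A [study_spec].
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (key in c("study_id", "panel", "d", "model_type"))
    if (is.null(cfg[[key]]))
      stop("study config is missing required key: ", key, call. = FALSE)
  panel_path <- cfg$panel
  if (!file.exists(panel_path))
    panel_path <- file.path(dirname(path), cfg$panel)
  study_spec(
    study_id = cfg$study_id,
    snps = read_panel(panel_path),
    d = cfg$d,
    model_type = cfg$model_type,
    disease = if (is.null(cfg$disease)) NA_character_ else cfg$disease,
    n_sim = if (is.null(cfg$n_sim)) 100000L else cfg$n_sim,
    n_iter = if (is.null(cfg$n_iter)) 100L else cfg$n_iter,
    published_auc = cfg$published_auc,
    published_n = cfg$published_n)
}
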