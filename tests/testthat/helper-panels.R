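# Shared fixture builders: everything is generated in code.

# Random valid panel with Woolf-consistent CIs.
random_panel <- function(G, seed) {
  set.seed(seed)
  or <- exp(runif(G, 0.02, 0.6))
  se <- runif(G, 0.01, 0.12)
  snp_panel(sprintf("rs%03d", seq_len(G)),
            raf = runif(G, 0.05, 0.95),
            or_allele = or,
            ci_low = exp(log(or) - 1.96 * se),
            ci_high = exp(log(or) + 1.96 * se))
}

null_panel <- function(G = 4) {
  snp_panel(sprintf("rs%03d", seq_len(G)),
            raf = seq(0.2, 0.8, length.out = G),
            or_allele = rep(1, G))
}

# Independent O(n^2) pair-counting AUC oracle.
brute_force_auc <- function(scores, status) {
  cases <- scores[status == 1]
  ctrls <- scores[status == 0]
  total <- 0
  for (x in cases)
    total <- total + sum(x > ctrls) + 0.5 * sum(x == ctrls)
  total / (length(cases) * length(ctrls))
}

godarts_study <- function(n_sim = 100000L, n_iter = 100L,
                          model_type = "bayes") {
  study_spec("t2d_godarts", read_panel(genrisk_extdata("t2d_godarts.tsv")),
             d = 0.20, model_type = model_type, n_sim = n_sim,
             n_iter = n_iter)
}

rotterdam_study <- function(n_sim = 100000L, n_iter = 100L,
                            model_type = "bayes") {
  study_spec("t2d_rotterdam",
             read_panel(genrisk_extdata("t2d_rotterdam.tsv")),
             d = 0.20, model_type = model_type, n_sim = n_sim,
             n_iter = n_iter)
}
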